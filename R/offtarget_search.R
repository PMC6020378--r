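# Genome-wide candidate off-target enumeration: every 23-nt window carrying
# a canonical NGG PAM on either strand, filtered to <= 6 protospacer
# mismatches against a query guide. A direct vectorized scan is used; desk
# scale genomes (<= a few Mb) need no index.

#' Scan a genome for NGG PAM sites on both strands
#'
#' Emits every 23-nt window whose protospacer-strand positions 22-23 read
#' `GG` (i.e. forward-strand `GG` at window offset 21 for `+` sites and
#' forward-strand `CC` at offset 0 for `-` sites). Sequences are reported
#' 5'->3' on the protospacer strand; coordinates stay on the reference
#' (0-based half-open). Windows containing non-ACGT characters are skipped
#' and counted in the `n_skipped` attribute.
#'
#' @param genome named character vector of chromosome sequences (e.g. from
#'   [read_fasta()] or [gen_genome()]).
#' @return data frame with `chrom`, `start`, `end`, `strand`, `sequence23`,
#'   ordered by (chrom, start, strand); attribute `n_skipped` counts
#'   windows dropped for ambiguity codes.
#' @export
scan_pam_sites <- function(genome) {
  if (is.null(names(genome)) || !is.character(genome) || !length(genome)) {
    stop("genome must be a non-empty named character vector", call. = FALSE)
  }
  n_skipped <- 0L
  res <- list()
  for (chrom in sort(names(genome))) {
    s <- toupper(genome[[chrom]])
    L <- nchar(s)
    if (L < GUIDE_LEN) next
    gg <- .overlapping_matches(s, "GG")
    plus_start1 <- gg - 21L                       # 1-based window start
    plus_start1 <- plus_start1[plus_start1 >= 1L & plus_start1 + 22L <= L]
    cc <- .overlapping_matches(s, "CC")
    minus_start1 <- cc[cc + 22L <= L]
    starts1 <- c(plus_start1, minus_start1)
    strands <- rep(c("+", "-"), c(length(plus_start1), length(minus_start1)))
    if (!length(starts1)) next
    win <- substring(s, starts1, starts1 + 22L)
    ok <- !grepl("[^ACGT]", win)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    starts1 <- starts1[ok]; strands <- strands[ok]; win <- win[ok]
    win[strands == "-"] <- reverse_complement(win[strands == "-"])
    ord <- order(starts1, match(strands, c("+", "-")))
    res[[chrom]] <- data.frame(chrom = chrom, start = starts1[ord] - 1L,
                               end = starts1[ord] + 22L,
                               strand = strands[ord],
                               sequence23 = win[ord],
                               stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), sequence23 = character(0))
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

# 1-based start positions of possibly overlapping fixed-pattern matches
.overlapping_matches <- function(s, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Enumerate candidate off-target loci for a guide
#'
#' All PAM sites whose protospacer Hamming distance (positions 1-20 only;
#' the PAM's N is free but GG at 22-23 is required) to the guide is at most
#' `max_mm`. The on-target locus itself appears as a distance-0 candidate
#' when present in the genome.
#'
#' @param guide a [guide_sequence()] or 23-nt string.
#' @param genome named character vector of chromosome sequences.
#' @param max_mm maximum number of protospacer mismatches, 0-6.
#' @param sites optional precomputed [scan_pam_sites()] table (reused when
#'   enumerating many guides against one genome).
#' @return data frame with site coordinates, `site_sequence`,
#'   `mismatch_count` and a `mismatch_profile` string like `"16:G>C;18:A>T"`.
#' @export
enumerate_candidates <- function(guide, genome, max_mm = 6L, sites = NULL) {
  if (max_mm < 0L || max_mm > 6L) stop("max_mm must be in 0..6", call. = FALSE)
  gs <- if (inherits(guide, "guide_sequence")) guide$sequence else guide
  check_dna(gs, GUIDE_LEN, "guide sequence")
  if (is.null(sites)) sites <- scan_pam_sites(genome)
  if (!nrow(sites)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      site_sequence = character(0),
                      mismatch_count = integer(0),
                      mismatch_profile = character(0)))
  }
  gch <- seq_chars(substr(gs, 1L, PROTO_LEN))
  mm <- integer(nrow(sites))
  diff_pos <- matrix(FALSE, nrow(sites), PROTO_LEN)
  for (p in seq_len(PROTO_LEN)) {
    diff_pos[, p] <- substr(sites$sequence23, p, p) != gch[p]
  }
  mm <- rowSums(diff_pos)
  keep <- which(mm <= max_mm)
  out <- sites[keep, , drop = FALSE]
  names(out)[names(out) == "sequence23"] <- "site_sequence"
  out$mismatch_count <- as.integer(mm[keep])
  out$mismatch_profile <- vapply(keep, function(i) {
    ps <- which(diff_pos[i, ])
    if (!length(ps)) return("")
    paste(sprintf("%d:%s>%s", ps, gch[ps],
                  vapply(ps, function(p) substr(sites$sequence23[i], p, p),
                         character(1))),
          collapse = ";")
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Positional mismatch profile between a guide and a site
#'
#' Substitutions over protospacer positions 1-20 only (the PAM is excluded
#' from the distance), in ascending position order.
#'
#' @param guide,site 23-nt strings (or [guide_sequence()] objects).
#' @return data frame with `position`, `from` (guide base), `to`
#'   (site base); zero rows for identical protospacers.
#' @export
mismatch_profile <- function(guide, site) {
  gs <- if (inherits(guide, "guide_sequence")) guide$sequence else guide
  ss <- if (inherits(site, "guide_sequence")) site$sequence else site
  if (nchar(gs) != GUIDE_LEN || nchar(ss) != GUIDE_LEN) {
    stop("guide and site must both be 23 nt", call. = FALSE)
  }
  ga <- seq_chars(substr(gs, 1L, PROTO_LEN))
  sa <- seq_chars(substr(ss, 1L, PROTO_LEN))
  ps <- which(ga != sa)
  data.frame(position = ps, from = ga[ps], to = sa[ps],
             stringsAsFactors = FALSE)
}

#' Assemble a labeled off-target pair dataset
#'
#' Joins enumerated candidates with a detection table keyed by
#' (guide_id, chrom, start, strand). Detected candidates are labeled 1 and
#' carry the assay's indel frequency when provided; all other candidates
#' are labeled 0. Detection rows matching no candidate are kept in the
#' `unmatched` attribute rather than silently dropped; duplicate detection
#' rows collapse to a single positive.
#'
#' @param candidates data frame from [enumerate_candidates()] with an added
#'   `guide_id` column.
#' @param detections data frame with `guide_id`, `chrom`, `start`,
#'   `strand`, and optionally `assay`, `indel_frequency`.
#' @return the candidate table with `detected`, `indel_frequency` and
#'   `assay` columns; attribute `unmatched` holds unmatchable detections.
#' @export
assemble_pair_dataset <- function(candidates, detections) {
  stopifnot(is.data.frame(candidates), "guide_id" %in% names(candidates))
  key <- function(df) paste(df$guide_id, df$chrom, df$start, df$strand,
                            sep = "\r")
  out <- candidates
  out$detected <- 0L
  out$indel_frequency <- NA_real_
  out$assay <- NA_character_
  if (!is.null(detections) && nrow(detections)) {
    need <- c("guide_id", "chrom", "start", "strand")
    if (!all(need %in% names(detections))) {
      stop("detection table needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    detections <- detections[!duplicated(key(detections)), , drop = FALSE]
    idx <- match(key(detections), key(out))
    hit <- !is.na(idx)
    out$detected[idx[hit]] <- 1L
    if ("indel_frequency" %in% names(detections)) {
      out$indel_frequency[idx[hit]] <- detections$indel_frequency[hit]
    }
    if ("assay" %in% names(detections)) {
      out$assay[idx[hit]] <- detections$assay[hit]
    }
    attr(out, "unmatched") <- detections[!hit, , drop = FALSE]
  } else {
    attr(out, "unmatched") <- detections[0, , drop = FALSE]
  }
  out
}

#' Leave-sgRNA-group-out split for pair datasets
#'
#' Holds out all pair records of `k_guides` randomly chosen guides, so
#' every guide's candidates fall entirely in train or entirely in test;
#' `k_guides = 1` gives one fold of leave-one-sgRNA-out testing.
#'
#' @param records pair data frame with a `guide_id` column.
#' @param k_guides number of guides to hold out.
#' @param seed integer RNG seed.
#' @return list with `train`, `test`, and `held_out` (the guide ids).
#' @export
split_leave_guides_out <- function(records, k_guides = 3L, seed = 1L) {
  stopifnot(is.data.frame(records), "guide_id" %in% names(records))
  guides <- unique(records$guide_id)
  if (k_guides < 1L || k_guides > length(guides) - 1L) {
    stop("k_guides must be between 1 and ", length(guides) - 1L, call. = FALSE)
  }
  held <- with_seed(seed, sample(guides, k_guides))
  in_test <- records$guide_id %in% held
  list(train = records[!in_test, , drop = FALSE],
       test = records[in_test, , drop = FALSE],
       held_out = held)
}
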