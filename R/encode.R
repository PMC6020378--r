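# Eight-channel encoding of 23-nt guide windows (20-nt protospacer + NGG
# PAM): four one-hot nucleotide channels plus CTCF / DNase / H3K4me3 binary
# peak-overlap channels and a continuous RRBS methylation-beta channel.
# Positions are numbered 1-20 from the PAM-distal 5' end; the PAM occupies
# positions 21-23. Minus-strand guides are stored as the 5'->3'
# protospacer-strand sequence, so the encoding itself is strand-agnostic;
# strand only matters when lifting epigenetic tracks into window coordinates.

#' Construct a guide-sequence record
#'
#' A guide window is the 23-nt sequence made of the 20-nt protospacer
#' followed by the NGG PAM, stored 5'->3' on the protospacer strand, plus
#' its genomic interval (0-based half-open) and cell type.
#'
#' @param sequence 23-nt uppercase DNA string; positions 21-23 are the PAM.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval on the reference
#'   (`end - start` must be 23).
#' @param strand `"+"` or `"-"`.
#' @param cell_type cell-type identifier used to look up epigenetic tracks.
#' @param check_pam require `GG` at positions 22-23 (canonical NGG PAM).
#' @return an object of class `guide_sequence`.
#' @export
guide_sequence <- function(sequence, chrom = "chr1", start = 0L,
                           end = start + 23L, strand = "+",
                           cell_type = "generic", check_pam = TRUE) {
  check_dna(sequence, len = GUIDE_LEN, what = "guide sequence")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (end - start != GUIDE_LEN) {
    stop("end - start must equal 23 (0-based half-open window)", call. = FALSE)
  }
  if (check_pam && substr(sequence, 22L, 23L) != "GG") {
    stop("positions 22-23 must be 'GG' for a canonical NGG PAM (got '",
         substr(sequence, 22L, 23L), "'); use check_pam = FALSE to override",
         call. = FALSE)
  }
  structure(list(sequence = sequence, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, cell_type = cell_type),
            class = "guide_sequence")
}

#' @export
print.guide_sequence <- function(x, ...) {
  cat(sprintf("<guide %s:%d-%d(%s) %s | %s>\n", x$chrom, x$start, x$end,
              x$strand, x$sequence, x$cell_type))
  invisible(x)
}

#' Construct a per-position epigenetic window
#'
#' Four vectors of length 23 aligned with the guide window in protospacer
#' orientation: binary peak overlap for CTCF, DNase and H3K4me3, and an RRBS
#' methylation beta in `[0, 1]` (0 where no RRBS record covers the position).
#'
#' @param ctcf,dnase,h3k4me3 binary vectors of length 23.
#' @param rrbs numeric vector of length 23 with values in `[0, 1]`.
#' @return an object of class `epi_window`.
#' @export
epi_window <- function(ctcf = numeric(GUIDE_LEN), dnase = numeric(GUIDE_LEN),
                       h3k4me3 = numeric(GUIDE_LEN), rrbs = numeric(GUIDE_LEN)) {
  vecs <- list(ctcf = ctcf, dnase = dnase, h3k4me3 = h3k4me3, rrbs = rrbs)
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (length(v) != GUIDE_LEN || anyNA(v)) {
      stop(nm, " must be a length-23 vector without NA", call. = FALSE)
    }
    if (nm == "rrbs") {
      if (any(v < 0 | v > 1)) stop("rrbs values must lie in [0, 1]", call. = FALSE)
    } else if (!all(v %in% c(0, 1))) {
      stop(nm, " must be binary (0/1)", call. = FALSE)
    }
  }
  structure(vecs, class = "epi_window")
}

#' Encode one guide window as a 23 x 8 channel matrix
#'
#' Rows are window positions 1-23, columns the fixed channel order
#' A, C, G, T, CTCF, DNase, H3K4me3, RRBS. The nucleotide block is one-hot;
#' epigenetic values are copied positionally.
#'
#' @param g a [guide_sequence()] or a plain 23-nt DNA string.
#' @param e an [epi_window()]; all-zero when omitted.
#' @return 23 x 8 numeric matrix with channel column names.
#' @export
encode_guide <- function(g, e = epi_window()) {
  seqstr <- if (inherits(g, "guide_sequence")) g$sequence else {
    check_dna(g, len = GUIDE_LEN, what = "guide sequence")
    g
  }
  if (!inherits(e, "epi_window")) stop("e must be an epi_window", call. = FALSE)
  ch <- seq_chars(seqstr)
  x <- matrix(0, GUIDE_LEN, length(CHANNELS), dimnames = list(NULL, CHANNELS))
  x[cbind(seq_len(GUIDE_LEN), match(ch, BASES))] <- 1
  x[, "CTCF"] <- e$ctcf
  x[, "DNase"] <- e$dnase
  x[, "H3K4me3"] <- e$h3k4me3
  x[, "RRBS"] <- e$rrbs
  x
}

#' Decode a 23 x 8 encoding back to its 23-nt sequence
#'
#' Inverts the one-hot nucleotide block of [encode_guide()]. Columns that
#' are not exactly one-hot are rejected rather than argmax-imputed.
#'
#' @param x a 23 x 8 matrix as produced by [encode_guide()].
#' @return the 23-nt DNA string.
#' @export
decode_guide <- function(x) {
  if (!is.matrix(x) || nrow(x) != GUIDE_LEN || ncol(x) != length(CHANNELS)) {
    stop("x must be a 23 x 8 encoding matrix", call. = FALSE)
  }
  nt <- x[, 1:4, drop = FALSE]
  ok <- abs(rowSums(nt) - 1) < 1e-9 &
    apply(nt, 1L, function(r) sum(abs(r - 1) < 1e-9) == 1L && all(r > -1e-9))
  if (!all(ok)) {
    stop("nucleotide channels are not one-hot at position ", which(!ok)[1],
         call. = FALSE)
  }
  paste(BASES[max.col(nt)], collapse = "")
}

#' Lift epigenetic tracks into a guide window
#'
#' Intersects a guide's genomic interval with the cell type's peak tracks
#' (BED intervals for CTCF/DNase/H3K4me3) and RRBS bedGraph records, and
#' reports per-position values in protospacer orientation: for a `-` strand
#' guide the window vectors are reversed so position 1 stays PAM-distal.
#' When several RRBS records cover the same position the first record in
#' track order wins.
#'
#' @param g a [guide_sequence()].
#' @param tracks nested track list as returned by [read_tracks()] or
#'   [gen_tracks()]: `tracks[[cell_type]][[mark]]` is a data frame with
#'   `chrom`, `start`, `end` (0-based half-open) and, for RRBS, `value`.
#' @return an [epi_window()].
#' @export
extract_epigenetics <- function(g, tracks) {
  stopifnot(inherits(g, "guide_sequence"))
  ct <- tracks[[g$cell_type]]
  if (is.null(ct)) {
    stop("no tracks for cell type '", g$cell_type, "'", call. = FALSE)
  }
  pos <- g$start + seq_len(GUIDE_LEN) - 1L  # 0-based genomic positions
  vals <- list()
  for (mark in EPI_MARKS) {
    df <- ct[[mark]]
    v <- numeric(GUIDE_LEN)
    if (!is.null(df) && nrow(df)) {
      if (!g$chrom %in% df$chrom) {
        stop("chromosome '", g$chrom, "' absent from ", mark, " track",
             call. = FALSE)
      }
      df <- df[df$chrom == g$chrom, , drop = FALSE]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = pos + 1L, width = 1L),
        IRanges::IRanges(start = df$start + 1L, end = df$end))
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      if (mark == "rrbs") {
        first <- !duplicated(qh)
        v[qh[first]] <- df$value[sh[first]]
      } else {
        v[unique(qh)] <- 1
      }
    }
    vals[[mark]] <- if (g$strand == "-") rev(v) else v
  }
  epi_window(ctcf = vals$ctcf, dnase = vals$dnase,
             h3k4me3 = vals$h3k4me3, rrbs = vals$rrbs)
}

#' Encode a (guide, candidate-site) pair for the off-target model
#'
#' The two windows are encoded independently; nothing is mixed between the
#' parts until the network's merge stage. The candidate must lie within 6
#' protospacer mismatches of the guide.
#'
#' @param guide,site [guide_sequence()] objects (or 23-nt strings).
#' @param eg,es epigenetic windows for guide and site.
#' @return an object of class `encoded_pair` with elements `guide_part`
#'   and `site_part`, each a 23 x 8 matrix.
#' @export
encode_pair <- function(guide, site, eg = epi_window(), es = epi_window()) {
  gs <- if (inherits(guide, "guide_sequence")) guide$sequence else guide
  ss <- if (inherits(site, "guide_sequence")) site$sequence else site
  check_dna(gs, GUIDE_LEN, "guide sequence")
  check_dna(ss, GUIDE_LEN, "site sequence")
  d <- hamming20(gs, ss)
  if (d > 6L) {
    stop("guide and site differ at ", d,
         " protospacer positions (maximum is 6)", call. = FALSE)
  }
  structure(list(guide_part = encode_guide(gs, eg),
                 site_part = encode_guide(ss, es)),
            class = "encoded_pair")
}

#' Encode a set of guide records into an n x 23 x 8 array
#'
#' @param sequences character vector of 23-nt windows.
#' @param epi optional list of [epi_window()]s (recycled all-zero when NULL).
#' @return numeric array `c(n, 23, 8)`.
#' @export
encode_guide_set <- function(sequences, epi = NULL) {
  n <- length(sequences)
  x <- array(0, c(n, GUIDE_LEN, length(CHANNELS)))
  zero <- epi_window()
  for (i in seq_len(n)) {
    x[i, , ] <- encode_guide(sequences[i], if (is.null(epi)) zero else epi[[i]])
  }
  x
}
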