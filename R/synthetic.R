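# Seeded synthetic fixtures: random genomes, epigenetic tracks, on-target
# sets with planted linear-logistic efficacy rules, off-target pair sets
# with planted positional substitution effects at realistic class
# imbalance, and multi-experiment efficacy matrices with missing entries.
# Every generator is a pure function of its arguments and seed; the
# caller's RNG state is left untouched.

#' Generate a random genome
#'
#' I.i.d. bases at a fixed GC fraction. The default GC content of 0.41
#' matches the genome-wide human average.
#'
#' @param length chromosome length in bp (>= 23).
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return named character vector of length 1 (the chromosome sequence).
#' @export
gen_genome <- function(length, gc = 0.41, seed = 1L, chrom = "chr1") {
  if (length < GUIDE_LEN) stop("genome length must be >= 23", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- with_seed(seed, paste(sample(BASES, length, replace = TRUE, prob = p),
                             collapse = ""))
  stats::setNames(s, chrom)
}

#' Generate random epigenetic tracks for a genome
#'
#' Emits peak intervals (CTCF, DNase, H3K4me3) with mark-specific genome
#' coverage and width distributions, and RRBS records at a subset of CpG
#' dinucleotides with beta values drawn from a U-shaped Beta(0.4, 0.4)
#' (bisulfite betas are typically bimodal near 0 and 1).
#'
#' @param genome named character vector of chromosome sequences.
#' @param cell_types character vector of cell-type identifiers.
#' @param seed integer seed.
#' @return nested list `tracks[[cell_type]][[mark]]`, each a data frame
#'   with `chrom`, `start`, `end` (0-based half-open) and `value`.
#' @export
gen_tracks <- function(genome, cell_types = "cellA", seed = 1L) {
  coverage <- c(ctcf = 0.03, dnase = 0.10, h3k4me3 = 0.06)
  width_mean <- c(ctcf = 300, dnase = 400, h3k4me3 = 600)
  with_seed(seed, {
    out <- list()
    for (ct in cell_types) {
      marks <- list()
      for (mark in c("ctcf", "dnase", "h3k4me3")) {
        rows <- list()
        for (chrom in names(genome)) {
          L <- nchar(genome[[chrom]])
          n_peaks <- max(1L, round(coverage[[mark]] * L / width_mean[[mark]]))
          w <- pmax(50L, round(stats::rexp(n_peaks, 1 / width_mean[[mark]])))
          st <- sort(sample.int(max(L - max(w), 1L), n_peaks, replace = TRUE))
          rows[[chrom]] <- data.frame(chrom = chrom, start = st - 1L,
                                      end = pmin(st - 1L + w, L),
                                      value = 1, stringsAsFactors = FALSE)
        }
        marks[[mark]] <- do.call(rbind, rows)
      }
      rows <- list()
      for (chrom in names(genome)) {
        cpg <- .overlapping_matches(toupper(genome[[chrom]]), "CG")
        if (length(cpg)) {
          keep <- cpg[stats::runif(length(cpg)) < 0.3]
          if (length(keep)) {
            rows[[chrom]] <- data.frame(
              chrom = chrom, start = keep - 1L, end = keep + 1L,
              value = round(stats::rbeta(length(keep), 0.4, 0.4), 3),
              stringsAsFactors = FALSE)
          }
        }
      }
      marks$rrbs <- if (length(rows)) do.call(rbind, rows) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), value = numeric(0))
      for (nm in names(marks)) rownames(marks[[nm]]) <- NULL
      out[[ct]] <- marks
    }
    out
  })
}

#' Define a planted linear-logistic efficacy rule
#'
#' The rule scores a guide as
#' `sum_p W[p, base_p] + w_epi . channel_means + intercept` plus Gaussian
#' noise; the binary label is 1 where the logistic of the score exceeds
#' 0.5, flipped with the label-noise rate. Linear-logistic rules are
#' simple enough for closed-form sanity checks yet positional enough to
#' exercise saliency recovery.
#'
#' @param position_weights 23 x 4 matrix of per-position nucleotide
#'   weights (rows 21-23 usually zero: the PAM is fixed up to its N).
#' @param epi_weights length-4 weights for the mean CTCF, DNase, H3K4me3
#'   and RRBS channel values.
#' @param intercept scalar offset.
#' @param noise_sd sd of additive Gaussian score noise.
#' @param label_noise probability of flipping the binary label, in
#'   `[0, 0.5)`.
#' @return object of class `planted_rule`.
#' @export
planted_rule <- function(position_weights = matrix(0, GUIDE_LEN, 4L),
                         epi_weights = numeric(4), intercept = 0,
                         noise_sd = 0.25, label_noise = 0) {
  stopifnot(is.matrix(position_weights),
            all(dim(position_weights) == c(GUIDE_LEN, 4L)),
            all(is.finite(position_weights)), length(epi_weights) == 4L)
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must be in [0, 0.5)", call. = FALSE)
  }
  colnames(position_weights) <- BASES
  structure(list(position_weights = position_weights,
                 epi_weights = epi_weights, intercept = intercept,
                 noise_sd = noise_sd, label_noise = label_noise),
            class = "planted_rule")
}

#' Random planted rule with known favored bases
#'
#' Picks `n_positions` protospacer positions and plants weight `+weight`
#' on a favored base (and `-weight/3` on the others) at each, with mild
#' epigenetic weights favoring open chromatin and disfavoring methylation.
#'
#' @param n_positions number of planted positions (within 1-20).
#' @param weight planted weight magnitude.
#' @param seed integer seed.
#' @return a [planted_rule()] whose `planted` attribute records the
#'   positions and favored bases.
#' @export
random_planted_rule <- function(n_positions = 8L, weight = 2, seed = 1L) {
  with_seed(seed, {
    W <- matrix(0, GUIDE_LEN, 4L)
    pos <- sort(sample.int(PROTO_LEN, n_positions))
    fav <- sample.int(4L, n_positions, replace = TRUE)
    for (i in seq_along(pos)) {
      W[pos[i], ] <- -weight / 3
      W[pos[i], fav[i]] <- weight
    }
    rule <- planted_rule(W, epi_weights = c(0.3, 0.8, 0.4, -0.8))
    attr(rule, "planted") <- data.frame(position = pos, base = BASES[fav])
    rule
  })
}

.rule_score <- function(rule, seqs, epi_means) {
  n <- length(seqs)
  sc <- numeric(n)
  for (p in seq_len(GUIDE_LEN)) {
    sc <- sc + rule$position_weights[cbind(p, match(substr(seqs, p, p), BASES))]
  }
  sc + as.numeric(epi_means %*% rule$epi_weights) + rule$intercept
}

# sgRNA collections are not compositionally uniform: NGG protospacers are
# G-rich and T-depleted (poly-T terminates pol III transcription), and the
# PAM's GG is invariant. Sampling with that skew gives the synthetic guides
# the kind of sequence structure a denoiser can actually exploit.
GUIDE_BASE_PROBS <- c(A = 0.21, C = 0.26, G = 0.32, T = 0.21)

.random_guides <- function(n) {
  proto <- matrix(sample(BASES, n * PROTO_LEN, replace = TRUE,
                         prob = GUIDE_BASE_PROBS), n, PROTO_LEN)
  pamN <- sample(BASES, n, replace = TRUE, prob = GUIDE_BASE_PROBS)
  paste0(apply(proto, 1L, paste, collapse = ""), pamN, "GG")
}

# random per-guide epigenetic windows: contiguous peak overlap for binary
# marks, sparse CpG betas for RRBS
.random_epi <- function(n) {
  present_p <- c(0.2, 0.35, 0.3)  # ctcf, dnase, h3k4me3
  epi <- array(0, c(n, GUIDE_LEN, 4L))
  for (k in 1:3) {
    on <- which(stats::runif(n) < present_p[k])
    for (i in on) {
      a <- sample.int(GUIDE_LEN, 1L)
      b <- min(GUIDE_LEN, a + sample.int(GUIDE_LEN, 1L))
      epi[i, a:b, k] <- 1
    }
  }
  on <- which(stats::runif(n) < 0.25)
  for (i in on) {
    np <- sample.int(4L, 1L)
    epi[i, sample.int(GUIDE_LEN, np), 4L] <- round(stats::rbeta(np, 0.4, 0.4), 3)
  }
  epi
}

.epi_to_x <- function(seqs, epi) {
  n <- length(seqs)
  x <- array(0, c(n, GUIDE_LEN, 8L))
  for (i in seq_len(n)) {
    ch <- seq_chars(seqs[i])
    m <- matrix(0, GUIDE_LEN, 4L)
    m[cbind(seq_len(GUIDE_LEN), match(ch, BASES))] <- 1
    x[i, , 1:4] <- m
  }
  x[, , 5:8] <- epi
  x
}

#' Generate a labeled on-target dataset from a planted rule
#'
#' Samples random NGG guides across cell types with random epigenetic
#' windows, scores them with the planted rule, and emits the standard
#' on-target record schema together with ready-to-train encodings.
#'
#' @param rule a [planted_rule()].
#' @param n_guides number of guides.
#' @param cell_types cell-type labels cycled over guides (default four
#'   cell types, mirroring multi-cell-line screen collections).
#' @param seed integer seed.
#' @return object of class `ontarget_sim`: `records` (data frame with
#'   `sequence23`, `cell_type`, `experiment_id`, `raw_efficacy`,
#'   `binary_label`, `normalized_label`, coordinates), `x` (array
#'   `c(n, 23, 8)`), and the rule.
#' @export
gen_ontarget_set <- function(rule, n_guides = 5000L,
                             cell_types = c("cellA", "cellB", "cellC", "cellD"),
                             seed = 1L) {
  stopifnot(inherits(rule, "planted_rule"))
  with_seed(seed, {
    seqs <- .random_guides(n_guides)
    epi <- .random_epi(n_guides)
    epi_means <- cbind(rowMeans(epi[, , 1L]), rowMeans(epi[, , 2L]),
                       rowMeans(epi[, , 3L]), rowMeans(epi[, , 4L]))
    sc <- .rule_score(rule, seqs, epi_means)
    raw <- sc + stats::rnorm(n_guides, sd = rule$noise_sd)
    lab <- as.integer(stats::plogis(raw) > 0.5)
    if (rule$label_noise > 0) {
      flip <- stats::runif(n_guides) < rule$label_noise
      lab[flip] <- 1L - lab[flip]
    }
    ct <- rep_len(cell_types, n_guides)
    records <- data.frame(
      chrom = "chrS", start = seq_len(n_guides) * 30L,
      end = seq_len(n_guides) * 30L + GUIDE_LEN, strand = "+",
      sequence23 = seqs, cell_type = ct,
      experiment_id = paste0("exp_", ct),
      raw_efficacy = raw, binary_label = lab,
      normalized_label = rank_normalize(raw),
      stringsAsFactors = FALSE)
    structure(list(records = records, x = .epi_to_x(seqs, epi), rule = rule,
                   seed = seed),
              class = "ontarget_sim")
  })
}

#' Generate an imbalanced off-target pair dataset with planted zone effects
#'
#' Pairs each sampled guide with mutated candidate sites carrying 0-6
#' protospacer mismatches; a site's detection probability is the logistic
#' of the summed planted positional effects of its mismatches, with the
#' intercept calibrated on the realized pair structure so the positive
#' fraction is about `1/imbalance_ratio`. Detected sites draw a positive
#' indel frequency. The default effects (+1.5 at positions 1-3, -0.5 at
#' 4-15, -4 at 16-20) plant the preference / undetermined / avoiding zone
#' structure of PAM-distal versus PAM-proximal mismatches: seed-region
#' (PAM-proximal) mismatches essentially abolish cleavage, mid-protospacer
#' mismatches cost moderately, and PAM-distal mismatches are tolerated and
#' enriched among detected off-targets.
#'
#' @param zone_effects length-20 per-position effects of a mismatch.
#' @param n_pairs number of pair records.
#' @param imbalance_ratio target negative:positive ratio (default 250).
#' @param n_guides number of distinct guides (default 30).
#' @param mm_probs sampling distribution of mismatch counts 0-6; the
#'   default grows steeply with the count, as genome-wide candidate sets
#'   do.
#' @param seed integer seed.
#' @return object of class `offtarget_sim`: `records` (pair table with
#'   `guide_id`, sequences, `mismatch_count`, `mismatch_profile`,
#'   `detected`, `indel_frequency`), `x_guide`, `x_site` (arrays), the
#'   effects and calibrated intercept.
#' @export
gen_offtarget_set <- function(zone_effects = c(rep(1.5, 3), rep(-0.5, 12), rep(-4, 5)),
                              n_pairs = 20000L, imbalance_ratio = 250,
                              n_guides = 30L,
                              mm_probs = c(0.002, 0.008, 0.04, 0.1, 0.2, 0.3, 0.35),
                              seed = 1L) {
  stopifnot(length(zone_effects) == PROTO_LEN, imbalance_ratio >= 1)
  with_seed(seed, {
    gseqs <- .random_guides(n_guides)
    g_epi <- .random_epi(n_guides)
    gid <- sample.int(n_guides, n_pairs, replace = TRUE)
    mm <- sample(0:6, n_pairs, replace = TRUE, prob = mm_probs)
    site <- character(n_pairs)
    profs <- character(n_pairs)
    esum <- numeric(n_pairs)
    for (i in seq_len(n_pairs)) {
      s <- gseqs[gid[i]]
      if (mm[i] > 0L) {
        ps <- sort(sample.int(PROTO_LEN, mm[i]))
        ch <- seq_chars(s)
        from <- ch[ps]
        to <- vapply(from, function(b) sample(setdiff(BASES, b), 1L),
                     character(1))
        ch[ps] <- to
        s <- paste(ch, collapse = "")
        profs[i] <- paste(sprintf("%d:%s>%s", ps, from, to), collapse = ";")
        esum[i] <- sum(zone_effects[ps])
      }
      site[i] <- s
    }
    # calibrate the logistic intercept on the realized mismatch structure
    target <- 1 / imbalance_ratio
    a <- stats::uniroot(function(a) mean(stats::plogis(a + esum)) - target,
                        c(-40, 10))$root
    detected <- stats::rbinom(n_pairs, 1L, stats::plogis(a + esum))
    indel <- rep(NA_real_, n_pairs)
    npos <- sum(detected)
    if (npos) indel[detected == 1L] <- round(stats::rbeta(npos, 1.2, 8), 4)
    s_epi <- .random_epi(n_pairs)
    records <- data.frame(
      guide_id = paste0("sg", formatC(gid, width = 2, flag = "0")),
      guide_sequence = gseqs[gid], site_sequence = site,
      chrom = "chrS", start = seq_len(n_pairs) * 30L,
      end = seq_len(n_pairs) * 30L + GUIDE_LEN, strand = "+",
      mismatch_count = mm, mismatch_profile = profs,
      detected = detected, indel_frequency = indel,
      assay = ifelse(detected == 1L, "synthetic-detect", NA_character_),
      stringsAsFactors = FALSE)
    structure(list(records = records,
                   x_guide = .epi_to_x(gseqs[gid],
                                       g_epi[gid, , , drop = FALSE]),
                   x_site = .epi_to_x(site, s_epi),
                   zone_effects = zone_effects, intercept = a, seed = seed),
              class = "offtarget_sim")
  })
}

#' Generate a multi-experiment efficacy matrix with missing entries
#'
#' Entries are guide effect + experiment offset + noise; a random mask is
#' applied at the missing rate while guaranteeing every row and column
#' keeps at least one observed entry.
#'
#' @param n_experiments,n_guides matrix dimensions.
#' @param missing_rate fraction of masked entries in `[0, 1)`.
#' @param seed integer seed.
#' @param guide_sd,offset_sd,noise_sd component standard deviations.
#' @return object of class `efficacy_sim`: `Y` (matrix with `NA`s),
#'   `guide_effect`, `experiment_offset`.
#' @export
gen_efficacy_matrix <- function(n_experiments, n_guides, missing_rate = 0.3,
                                seed = 1L, guide_sd = 1, offset_sd = 0.5,
                                noise_sd = 0.2) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    ge <- stats::rnorm(n_guides, sd = guide_sd)
    eo <- stats::rnorm(n_experiments, sd = offset_sd)
    Y <- outer(eo, ge, `+`) +
      matrix(stats::rnorm(n_experiments * n_guides, sd = noise_sd),
             n_experiments, n_guides)
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(Y)) < missing_rate,
                     n_experiments, n_guides)
      # keep at least one observation per row and per column
      for (i in which(rowSums(!mask) == 0)) mask[i, sample.int(n_guides, 1L)] <- FALSE
      for (j in which(colSums(!mask) == 0)) mask[sample.int(n_experiments, 1L), j] <- FALSE
      Y[mask] <- NA_real_
    }
    structure(list(Y = Y, guide_effect = ge, experiment_offset = eo,
                   seed = seed),
              class = "efficacy_sim")
  })
}
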