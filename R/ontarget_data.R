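# On-target training-set construction: binary labels from log-fold-change
# screens, collaborative-filtering normalization of multi-experiment
# efficacy matrices, rank normalization, PAM-distal double-mismatch
# augmentation, and leakage-guarded split schemes.

#' Binarize knockout efficacy at a log-fold-change cutoff
#'
#' @param raw numeric vector of log-fold-change efficacies.
#' @param cutoff efficacy cutoff; the boundary is inclusive
#'   (`raw >= cutoff` maps to 1).
#' @return integer vector of 0/1 labels.
#' @export
binarize_efficacy <- function(raw, cutoff = 1.0) {
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    stop("raw efficacies must be finite numbers", call. = FALSE)
  }
  as.integer(raw >= cutoff)
}

#' Normalize a multi-experiment efficacy matrix
#'
#' Removes experiment- and guide-level offsets from an experiments x guides
#' matrix by subtracting the equal-weight combination of the row mean,
#' column mean and grand mean:
#' `y_norm[i,j] = y[i,j] - (m_row[i] + m_column[j] + m_all) / 3`.
#' With missing entries, all three means run over observed entries only;
#' `y_norm` is defined only where `y` is observed.
#'
#' @param Y numeric matrix (experiments x guides), `NA` for missing entries.
#' @return list with `y_norm` (same shape as `Y`, `NA` where missing),
#'   `m_row`, `m_column`, `m_all`.
#' @export
normalize_efficacy_matrix <- function(Y) {
  if (!is.matrix(Y) || !is.numeric(Y)) stop("Y must be a numeric matrix", call. = FALSE)
  obs <- !is.na(Y)
  empty_row <- which(rowSums(obs) == 0)
  if (length(empty_row)) {
    stop("row ", empty_row[1], " has no observed entries", call. = FALSE)
  }
  empty_col <- which(colSums(obs) == 0)
  if (length(empty_col)) {
    stop("column ", empty_col[1], " has no observed entries", call. = FALSE)
  }
  m_row <- rowMeans(Y, na.rm = TRUE)
  m_column <- colMeans(Y, na.rm = TRUE)
  m_all <- mean(Y, na.rm = TRUE)
  y_norm <- Y - (outer(m_row, m_column, `+`) + m_all) / 3
  y_norm[!obs] <- NA_real_
  list(y_norm = y_norm, m_row = m_row, m_column = m_column, m_all = m_all)
}

#' Rank-normalize a numeric vector into (0, 1)
#'
#' Maps each value to `(rank - 0.5) / n` with average midranks for ties;
#' order-preserving.
#'
#' @param values numeric vector (length >= 1).
#' @return numeric vector of the same length, values in (0, 1).
#' @export
rank_normalize <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  (rank(values, ties.method = "average") - 0.5) / length(values)
}

#' Augment seed guides with PAM-distal double mismatches
#'
#' Mismatches at the two PAM-distal positions (window positions 1-2)
#' generally leave cleavage efficacy unchanged, so each seed spawns the
#' 3 x 3 = 9 variants carrying one substitution at position 1 and one at
#' position 2, inheriting the seed's epigenetic profile, labels and
#' coordinates unchanged. Optionally the 6 single-mismatch variants are
#' added. Output is deduplicated on (sequence23, cell_type), first
#' occurrence winning, in deterministic order (seed order, then a fixed
#' base order).
#'
#' @param records data frame of on-target records with at least
#'   `sequence23` and `cell_type` columns (see [read_ontarget_table()]).
#' @param include_seed also emit each seed itself (default TRUE).
#' @param include_singles additionally emit the 6 single-mismatch variants.
#' @return data frame of the same schema, with an added `seed_sequence`
#'   column naming each record's seed.
#' @export
augment_guides <- function(records, include_seed = TRUE,
                           include_singles = FALSE) {
  stopifnot(is.data.frame(records), "sequence23" %in% names(records))
  if (!"cell_type" %in% names(records)) records$cell_type <- "generic"
  if (any(nchar(records$sequence23) < GUIDE_LEN)) {
    stop("all seed sequences must be 23 nt", call. = FALSE)
  }
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    s <- rec$sequence23
    b1 <- substr(s, 1L, 1L); b2 <- substr(s, 2L, 2L)
    alt1 <- setdiff(BASES, b1); alt2 <- setdiff(BASES, b2)
    variants <- character(0)
    if (include_seed) variants <- s
    if (include_singles) {
      for (a in alt1) variants <- c(variants, paste0(a, substr(s, 2L, GUIDE_LEN)))
      for (b in alt2) variants <- c(variants, paste0(b1, b, substr(s, 3L, GUIDE_LEN)))
    }
    for (a in alt1) for (b in alt2) {
      variants <- c(variants, paste0(a, b, substr(s, 3L, GUIDE_LEN)))
    }
    block <- rec[rep(1L, length(variants)), , drop = FALSE]
    block$sequence23 <- variants
    block$seed_sequence <- s
    out[[i]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[!duplicated(res[, c("sequence23", "cell_type")]), , drop = FALSE]
}

# family key grouping a seed with all its PAM-distal augmentation variants
.family_key <- function(records) {
  paste(substr(records$sequence23, 3L, GUIDE_LEN), records$cell_type, sep = "|")
}

#' Stratified train/test split with augmentation-leakage guard
#'
#' Splits at the level of augmentation families (records identical outside
#' window positions 1-2 within a cell type), stratified by
#' (cell type, binary label), so variants of a test seed can never leak
#' into training and per-stratum label proportions are preserved.
#'
#' @param records on-target data frame with `sequence23`, `cell_type` and
#'   `binary_label` columns.
#' @param test_fraction fraction of records held out (default 0.2).
#' @param seed integer RNG seed; the split is deterministic given the seed.
#' @return list with `train` and `test` data frames.
#' @export
split_stratified <- function(records, test_fraction = 0.2, seed = 1L) {
  stopifnot(is.data.frame(records),
            all(c("sequence23", "cell_type", "binary_label") %in% names(records)))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  fam <- .family_key(records)
  fam_first <- !duplicated(fam)
  fams <- data.frame(key = fam[fam_first],
                     cell_type = records$cell_type[fam_first],
                     label = records$binary_label[fam_first],
                     stringsAsFactors = FALSE)
  strata <- split(seq_len(nrow(fams)),
                  paste(fams$cell_type, fams$label, sep = "|"))
  if (any(vapply(strata, length, integer(1)) < 2L)) {
    stop("each (cell type, label) stratum needs at least 2 guide families",
         call. = FALSE)
  }
  test_keys <- with_seed(seed, {
    unlist(lapply(strata, function(idx) {
      n_test <- max(1L, round(length(idx) * test_fraction))
      fams$key[sample(idx, n_test)]
    }), use.names = FALSE)
  })
  in_test <- fam %in% test_keys
  list(train = records[!in_test, , drop = FALSE],
       test = records[in_test, , drop = FALSE])
}

#' Leave-one-cell-type-out split
#'
#' All records of the held-out cell type form the test set; training keeps
#' the remaining cell types with any sequence overlapping the test set
#' purged.
#'
#' @param records on-target data frame.
#' @param held_out cell-type identifier to hold out.
#' @return list with `train` and `test` data frames.
#' @export
split_leave_cell_type_out <- function(records, held_out) {
  stopifnot(is.data.frame(records), "cell_type" %in% names(records))
  cts <- unique(records$cell_type)
  if (length(cts) < 2L) stop("need at least 2 cell types", call. = FALSE)
  if (!held_out %in% cts) {
    stop("unknown cell type '", held_out, "'", call. = FALSE)
  }
  test <- records[records$cell_type == held_out, , drop = FALSE]
  train <- records[records$cell_type != held_out, , drop = FALSE]
  train <- train[!train$sequence23 %in% test$sequence23, , drop = FALSE]
  list(train = train, test = test)
}
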