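# Per-guide off-target summaries (anti-OT score, severity-banded profile
# export) and the evaluation metrics used throughout: ROC-AUC, PR-AUC,
# Spearman and rank-weighted Spearman correlation.

#' Anti-OT summary score of a guide's off-target profile
#'
#' `S = ln(1 + exp(-sum(OT_i))) / ln 2`, where `OT_i` are the predicted
#' occurrence probabilities of the guide's candidate off-target loci. The
#' score lives in `(0, 1]`, attains 1 exactly when the summed probability
#' is zero, and is strictly decreasing in every `OT_i` — a higher score
#' means a lower genome-wide off-target propensity. The exponent is
#' negated relative to the form `ln(1 + exp(+sum))/ln 2` sometimes quoted
#' for this score, which is >= 1 and increasing and therefore contradicts
#' both the stated range and the intended ordering; that literal variant
#' remains available via `literal = TRUE` for comparison.
#'
#' @param probs numeric vector of occurrence probabilities in `[0, 1]`
#'   (may be empty: the empty profile scores exactly 1).
#' @param literal evaluate the non-negated variant instead.
#' @return scalar score.
#' @export
anti_ot_score <- function(probs, literal = FALSE) {
  if (length(probs) && (any(!is.finite(probs)) || any(probs < 0 | probs > 1))) {
    stop("occurrence probabilities must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(probs)
  if (literal) log1p(exp(s)) / log(2) else log1p(exp(-s)) / log(2)
}

#' Bundle per-site predictions into an off-target profile
#'
#' @param guide_id guide identifier.
#' @param sites data frame of candidate sites (columns `chrom`, `start`,
#'   `end`, `strand`, and optionally `mismatch_count`).
#' @param ot numeric vector of predicted occurrence probabilities, one per
#'   site.
#' @return object of class `offtarget_profile` with the site table, `ot`
#'   column and the anti-OT score `S`.
#' @export
off_target_profile <- function(guide_id, sites, ot) {
  stopifnot(is.data.frame(sites), nrow(sites) == length(ot))
  if (length(ot) && (any(!is.finite(ot)) || any(ot < 0 | ot > 1))) {
    stop("occurrence probabilities must lie in [0, 1]", call. = FALSE)
  }
  sites$ot <- ot
  structure(list(guide_id = guide_id, entries = sites,
                 S = anti_ot_score(ot)),
            class = "offtarget_profile")
}

#' @export
print.offtarget_profile <- function(x, ...) {
  cat(sprintf("Off-target profile of %s: %d candidate sites, anti-OT score %.4f\n",
              x$guide_id, nrow(x$entries), x$S))
  invisible(x)
}

#' Band an off-target profile by predicted severity
#'
#' Labels every candidate site mild (`ot < t1`, green), moderate
#' (`t1 <= ot < t2`, yellow) or severe (`ot >= t2`, red) and orders the
#' table by genomic coordinate for track-style plotting.
#'
#' @param profile an [off_target_profile()].
#' @param thresholds increasing pair `0 < t1 < t2 < 1` (default 1/3, 2/3).
#' @return data frame of the profile entries with `band` and `color`
#'   columns, ordered by (chrom, start).
#' @export
severity_bands <- function(profile, thresholds = c(1/3, 2/3)) {
  stopifnot(inherits(profile, "offtarget_profile"))
  t1 <- thresholds[1]; t2 <- thresholds[2]
  if (!(length(thresholds) == 2L && t1 > 0 && t1 < t2 && t2 < 1)) {
    stop("thresholds must satisfy 0 < t1 < t2 < 1", call. = FALSE)
  }
  df <- profile$entries
  df$band <- cut(df$ot, breaks = c(-Inf, t1, t2, Inf),
                 labels = c("mild", "moderate", "severe"), right = FALSE)
  df$color <- c(mild = "green", moderate = "yellow",
                severe = "red")[as.character(df$band)]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Circular-track plot of a banded off-target profile
#'
#' Draws candidate sites around a circle (ordered by genomic coordinate),
#' colored green/yellow/red by severity band, with radial height
#' proportional to the predicted occurrence probability.
#'
#' @param x an [off_target_profile()].
#' @param thresholds severity thresholds passed to [severity_bands()].
#' @param ... unused.
#' @export
plot.offtarget_profile <- function(x, thresholds = c(1/3, 2/3), ...) {
  df <- severity_bands(x, thresholds)
  n <- nrow(df)
  theta <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  r0 <- 0.6
  r1 <- r0 + 0.35 * df$ot
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("%s (anti-OT %.3f)", x$guide_id, x$S))
  graphics::segments(r0 * cos(theta), r0 * sin(theta),
                     r1 * cos(theta), r1 * sin(theta),
                     col = df$color, lwd = 2)
  graphics::symbols(0, 0, circles = r0, inches = FALSE, add = TRUE,
                    fg = "grey70")
  invisible(x)
}

#' Classification metrics: ROC-AUC and PR-AUC
#'
#' ROC-AUC is computed from the rank statistic with midranks for tied
#' scores (so constant scores give exactly 0.5); PR-AUC integrates the
#' precision-recall curve stepwise over descending score thresholds.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `roc_auc` and `pr_auc`.
#' @export
classification_metrics <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  roc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[grp_end]
  fp <- grp_end - tp
  recall <- tp / n1
  precision <- tp / (tp + fp)
  dr <- diff(c(0, recall))
  pr <- sum(dr * precision)
  list(roc_auc = roc, pr_auc = pr)
}

#' Regression metrics: Spearman and rank-weighted Spearman correlation
#'
#' Spearman correlation is the Pearson correlation of midranks. The
#' weighted variant computes a weighted Pearson correlation of midranks
#' with weights proportional to the rank of the true value (the largest
#' truth carries the largest weight, weights normalized to sum 1),
#' penalizing misranked high-efficacy sites more than low ones; with
#' equal weights it reduces exactly to Spearman.
#'
#' @param preds,truths numeric vectors of equal length (>= 3).
#' @param weights optional explicit weights (default: rank of `truths`).
#' @return list with `spearman` and `weighted_spearman`.
#' @export
regression_metrics <- function(preds, truths, weights = NULL) {
  if (length(preds) != length(truths)) {
    stop("preds and truths must have equal length", call. = FALSE)
  }
  if (length(preds) < 3L) stop("need at least 3 observations", call. = FALSE)
  sp <- stats::cor(preds, truths, method = "spearman")
  rp <- rank(preds, ties.method = "average")
  rt <- rank(truths, ties.method = "average")
  w <- weights %||% rt
  w <- w / sum(w)
  mp <- sum(w * rp); mt <- sum(w * rt)
  cov_w <- sum(w * (rp - mp) * (rt - mt))
  v1 <- sum(w * (rp - mp)^2); v2 <- sum(w * (rt - mt)^2)
  list(spearman = sp, weighted_spearman = cov_w / sqrt(v1 * v2))
}

#' Full metric report for a prediction set
#'
#' @param scores predictions.
#' @param labels 0/1 labels (NULL to skip classification metrics).
#' @param truths continuous truths (NULL to skip regression metrics).
#' @return list of class `metric_report` with the available metrics plus
#'   `n` and `n_positive`.
#' @export
metric_report <- function(scores, labels = NULL, truths = NULL) {
  out <- list(n = length(scores),
              n_positive = if (!is.null(labels)) sum(labels == 1) else NA)
  if (!is.null(labels)) out <- c(out, classification_metrics(scores, labels))
  if (!is.null(truths)) out <- c(out, regression_metrics(scores, truths))
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report (n =", x$n, ")\n")
  for (nm in setdiff(names(x), c("n"))) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) == 1L && is.finite(v)) {
      cat(sprintf("  %-18s %.4f\n", nm, v))
    }
  }
  invisible(x)
}
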