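# Model interpretation: class-specific saliency by activation maximization
# (gradient ascent on the class score over a synthetic input constrained to
# the per-position nucleotide probability simplex), averaged nucleotide
# substitution effect maps with Fisher-exact filtering, substitution zones,
# and the transform between protospacer-strand substitution notation and
# rX:dY RNA:DNA duplex notation.

#' Wrap a fitted model (or plain functions) as a differentiable scorer
#'
#' A scorer exposes `score(g)` and `grad(g)` where `g` is a 23 x 8 matrix
#' (or, for pair models, a list of two such matrices). For fitted models
#' the class score is the pre-softmax logit of the class of interest
#' (classification) or the raw output (regression), and the gradient is
#' obtained by backpropagation to the input.
#'
#' @param model a `crispr_ontarget` or `crispr_offtarget` fit, or a list
#'   with elements `score` and `grad` (used as-is, e.g. toy objectives).
#' @param class class of interest for classification models (default 1,
#'   the positive/efficacious class).
#' @return an object of class `crispr_scorer`.
#' @export
as_scorer <- function(model, class = 1L) {
  if (is.list(model) && !is.null(model$score) && !is.null(model$grad) &&
      !inherits(model, c("crispr_ontarget", "crispr_offtarget"))) {
    return(structure(list(score = model$score, grad = model$grad,
                          pair = isTRUE(model$pair)),
                     class = "crispr_scorer"))
  }
  if (inherits(model, "crispr_ontarget")) {
    enc <- net_from_state(model$encoder_state)
    head <- net_from_state(model$head_state)
    n_out <- if (model$task == "classification") 2L else 1L
    col <- if (model$task == "classification") class + 1L else 1L
    fwd <- function(g) {
      h <- net_forward(enc, array(g, c(1L, GUIDE_LEN, 8L)), train = FALSE)
      net_forward(head, h, train = FALSE)[1L, col]
    }
    grd <- function(g) {
      h <- net_forward(enc, array(g, c(1L, GUIDE_LEN, 8L)), train = FALSE)
      net_forward(head, h, train = FALSE)
      dy <- matrix(0, 1L, n_out); dy[1L, col] <- 1
      dx <- fm_to_array(net_backward(enc, net_backward(head, dy)))
      matrix(dx[1L, , ], GUIDE_LEN, 8L)
    }
    return(structure(list(score = fwd, grad = grd, pair = FALSE),
                     class = "crispr_scorer"))
  }
  if (inherits(model, "crispr_offtarget")) {
    enc1 <- net_from_state(model$enc1_state)
    enc2 <- net_from_state(model$enc2_state)
    head <- net_from_state(model$head_state)
    n_out <- if (model$task == "classification") 2L else 1L
    col <- if (model$task == "classification") class + 1L else 1L
    lat_c <- NULL
    fwd <- function(g) {
      h1 <- net_forward(enc1, array(g[[1]], c(1L, GUIDE_LEN, 8L)), train = FALSE)
      h2 <- net_forward(enc2, array(g[[2]], c(1L, GUIDE_LEN, 8L)), train = FALSE)
      net_forward(head, merge_channels(h1, h2), train = FALSE)[1L, col]
    }
    grd <- function(g) {
      h1 <- net_forward(enc1, array(g[[1]], c(1L, GUIDE_LEN, 8L)), train = FALSE)
      h2 <- net_forward(enc2, array(g[[2]], c(1L, GUIDE_LEN, 8L)), train = FALSE)
      c1 <- ncol(h1$m)
      net_forward(head, merge_channels(h1, h2), train = FALSE)
      dy <- matrix(0, 1L, n_out); dy[1L, col] <- 1
      dh <- net_backward(head, dy)
      parts <- split_channels(dh, c1)
      list(matrix(fm_to_array(net_backward(enc1, parts[[1]]))[1L, , ],
                  GUIDE_LEN, 8L),
           matrix(fm_to_array(net_backward(enc2, parts[[2]]))[1L, , ],
                  GUIDE_LEN, 8L))
    }
    return(structure(list(score = fwd, grad = grd, pair = TRUE),
                     class = "crispr_scorer"))
  }
  stop("cannot build a scorer from this object", call. = FALSE)
}

# Euclidean projection of each row of a k-column block onto the simplex
project_simplex_rows <- function(m) {
  k <- ncol(m)
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_len(k) > 0))
    theta <- (css[rho] - 1) / rho
    m[i, ] <- pmax(v - theta, 0)
  }
  m
}

.am_project <- function(g) {
  g[, 1:4] <- project_simplex_rows(g[, 1:4, drop = FALSE])
  g[, 5:8] <- pmin(pmax(g[, 5:8, drop = FALSE], 0), 1)
  g
}

.am_objective <- function(scorer, g, l2) {
  if (scorer$pair) {
    scorer$score(g) - l2 * (sum(g[[1]]^2) + sum(g[[2]]^2))
  } else {
    scorer$score(g) - l2 * sum(g^2)
  }
}

#' Class-representative synthetic input by activation maximization
#'
#' Starts from the uniform input (every nucleotide channel 0.25, every
#' epigenetic channel 0.5) and performs projected gradient ascent on
#' `S_c(g) - lambda * ||g||^2`: after each step the nucleotide block of
#' every position is Euclidean-projected back onto the probability simplex
#' and the epigenetic channels are clipped to `[0, 1]`. Steps that would
#' decrease the penalized score are rejected and the step size halved, so
#' the recorded score trace is non-decreasing and the final score is at
#' least the initial one.
#'
#' @param model a fitted model or anything [as_scorer()] accepts.
#' @param class class of interest (classification models).
#' @param iterations maximum accepted/attempted ascent iterations.
#' @param step initial step size.
#' @param l2 L2 penalty `lambda`.
#' @param seed unused by the deterministic ascent itself; kept for
#'   configuration provenance.
#' @return object of class `saliency_map`: the optimized input `g`
#'   (23 x 8, or a list of two for pair models), the class, the final
#'   score and the per-iteration `score_trace`.
#' @export
activation_maximize <- function(model, class = 1L, iterations = 500L,
                                step = 0.1, l2 = 1e-3, seed = NULL) {
  scorer <- if (inherits(model, "crispr_scorer")) model else
    as_scorer(model, class)
  uni <- matrix(rep(c(rep(0.25, 4), rep(0.5, 4)), each = GUIDE_LEN),
                GUIDE_LEN, 8L, dimnames = list(NULL, CHANNELS))
  g <- if (scorer$pair) list(uni, uni) else uni
  obj <- .am_objective(scorer, g, l2)
  if (!is.finite(obj)) stop("non-finite initial score", call. = FALSE)
  trace <- obj
  for (it in seq_len(iterations)) {
    gr <- scorer$grad(g)
    if (scorer$pair) {
      if (any(!is.finite(gr[[1]])) || any(!is.finite(gr[[2]]))) {
        stop("non-finite gradient at iteration ", it, "; trace: ",
             paste(round(utils::tail(trace, 5), 4), collapse = ", "),
             call. = FALSE)
      }
      cand <- list(.am_project(g[[1]] + step * (gr[[1]] - 2 * l2 * g[[1]])),
                   .am_project(g[[2]] + step * (gr[[2]] - 2 * l2 * g[[2]])))
    } else {
      if (any(!is.finite(gr))) {
        stop("non-finite gradient at iteration ", it, "; trace: ",
             paste(round(utils::tail(trace, 5), 4), collapse = ", "),
             call. = FALSE)
      }
      cand <- .am_project(g + step * (gr - 2 * l2 * g))
    }
    cobj <- .am_objective(scorer, cand, l2)
    if (is.finite(cobj) && cobj >= obj - 1e-12) {
      g <- cand; obj <- cobj
      step <- step * 1.05
    } else {
      step <- step / 2
    }
    trace <- c(trace, obj)
    if (step < 1e-8) break
  }
  structure(list(g = g, class = class, score = obj, score_trace = trace,
                 pair = scorer$pair),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("Saliency map (class %s): score %.4f after %d iterations\n",
              x$class, x$score, length(x$score_trace) - 1L))
  if (!x$pair) {
    top <- BASES[max.col(x$g[, 1:4, drop = FALSE])]
    cat("  top nucleotide per position: ", paste(top, collapse = ""), "\n")
  }
  invisible(x)
}

#' Nucleotide-substitution effect map of an off-target model
#'
#' For every protospacer position p (1-20) and ordered base pair X -> Y,
#' measures the mean change in predicted off-target probability when the
#' candidate site's base at p is set to Y instead of the matched base X,
#' over the background pairs whose guide carries X at p. Diagonal (X -> X)
#' cells are identically 0 by definition. The averaged map collapses each
#' position's 12 substitution cells to their mean.
#'
#' @param model a fitted `crispr_offtarget` model.
#' @param x_guide,x_site background pair encodings, arrays `c(n, 23, 8)`.
#' @param scale measure effects on the `"probability"` scale (the map's
#'   native definition) or on the `"logit"` scale. Probabilities saturate:
#'   a strong model scores most backgrounds near 0 or 1, which compresses
#'   exactly the largest effects; logit-scale effects stay comparable
#'   across positions and are the better input for zone calling.
#' @return object of class `substitution_map`: `effect` (20 x 16 matrix,
#'   columns `"A>A"`, `"A>C"`, ...), `count` (same shape), and `avg`
#'   (length-20 per-position means over off-diagonal cells).
#' @export
substitution_effect_map <- function(model, x_guide, x_site,
                                    scale = c("probability", "logit")) {
  scale <- match.arg(scale)
  stopifnot(inherits(model, "crispr_offtarget"))
  tx <- if (scale == "logit") {
    function(p) stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))
  } else identity
  n <- dim(x_guide)[1]
  if (n < 1L) stop("background pair set is empty", call. = FALSE)
  cells <- as.vector(t(outer(BASES, BASES, function(a, b) paste0(a, ">", b))))
  effect <- matrix(0, PROTO_LEN, 16L, dimnames = list(NULL, cells))
  count <- matrix(0L, PROTO_LEN, 16L, dimnames = list(NULL, cells))
  for (p in seq_len(PROTO_LEN)) {
    gb <- max.col(matrix(x_guide[, p, 1:4], n, 4L))
    for (xi in 1:4) {
      sub_idx <- which(gb == xi)
      if (!length(sub_idx)) next
      matched <- x_site[sub_idx, , , drop = FALSE]
      matched[, p, 1:4] <- 0
      matched[, p, xi] <- 1
      s_match <- tx(predict(model, x_guide[sub_idx, , , drop = FALSE],
                            matched))
      for (yi in 1:4) {
        cell <- paste0(BASES[xi], ">", BASES[yi])
        count[p, cell] <- length(sub_idx)
        if (yi == xi) next
        mod <- matched
        mod[, p, 1:4] <- 0
        mod[, p, yi] <- 1
        s_mod <- tx(predict(model, x_guide[sub_idx, , , drop = FALSE], mod))
        effect[p, cell] <- mean(s_mod - s_match)
      }
    }
  }
  offdiag <- !cells %in% paste0(BASES, ">", BASES)
  avg <- vapply(seq_len(PROTO_LEN), function(p) {
    ok <- offdiag & count[p, ] > 0
    if (!any(ok)) 0 else mean(effect[p, ok])
  }, numeric(1))
  structure(list(effect = effect, count = count, avg = avg),
            class = "substitution_map")
}

#' @export
print.substitution_map <- function(x, ...) {
  cat("Nucleotide-substitution effect map (20 positions x 16 cells)\n")
  cat("  per-position mean effect:\n  ")
  cat(paste(sprintf("%d:%+.3f", seq_len(PROTO_LEN), x$avg), collapse = " "),
      "\n")
  invisible(x)
}

#' Count tables for Fisher filtering of substitution cells
#'
#' Builds, for every (position, X -> Y) cell, the 2 x 2 contingency table
#' of substitution presence versus detection status over a labeled pair
#' dataset: rows = (pairs carrying that substitution, pairs not carrying
#' it), columns = (detected, not detected).
#'
#' @param records pair data frame with `mismatch_profile` strings (e.g.
#'   `"16:G>C;18:A>T"`) and a 0/1 `detected` column.
#' @return array `c(20, 16, 4)` of counts, cell slices ordered
#'   (with, detected), (with, undetected), (without, detected),
#'   (without, undetected); dimnames carry the cell labels.
#' @export
substitution_detection_tables <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("mismatch_profile", "detected") %in% names(records)))
  cells <- as.vector(t(outer(BASES, BASES, function(a, b) paste0(a, ">", b))))
  n <- nrow(records)
  det <- records$detected == 1
  counts <- array(0L, c(PROTO_LEN, 16L, 4L),
                  dimnames = list(NULL, cells,
                                  c("with_det", "with_undet",
                                    "without_det", "without_undet")))
  tot_det <- sum(det); tot_undet <- n - tot_det
  toks <- strsplit(records$mismatch_profile, ";", fixed = TRUE)
  has <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (tk in toks[[i]]) {
      if (!nchar(tk)) next
      p <- as.integer(sub(":.*", "", tk))
      cell <- sub(".*:", "", tk)
      slot <- if (det[i]) 1L else 2L
      counts[p, cell, slot] <- counts[p, cell, slot] + 1L
    }
  }
  counts[, , 3L] <- tot_det - counts[, , 1L]
  counts[, , 4L] <- tot_undet - counts[, , 2L]
  counts
}

#' Fisher-exact significance filter for substitution cells
#'
#' Two-sided Fisher exact test per 2 x 2 table; cells with `p >= alpha`
#' are masked (rendered as hyphens in text reports). No multiplicity
#' correction by default; `correct = "BH"` applies Benjamini-Hochberg
#' before masking.
#'
#' @param tables a list of 2 x 2 integer matrices, or an array whose last
#'   dimension has length 4 holding `(a, b, c, d)` table cells (as from
#'   [substitution_detection_tables()]).
#' @param alpha significance level (default 0.05).
#' @param correct `"none"` or `"BH"`.
#' @return list with `p` (same leading shape as the input) and logical
#'   `significant` mask.
#' @export
fisher_filter <- function(tables, alpha = 0.05, correct = c("none", "BH")) {
  correct <- match.arg(correct)
  if (is.list(tables)) {
    flat <- t(vapply(tables, function(tb) as.vector(t(tb)), numeric(4)))
    shape <- length(tables); dn <- NULL
  } else {
    d <- dim(tables)
    flat <- matrix(tables, prod(d[-length(d)]), 4L)
    shape <- d[-length(d)]; dn <- dimnames(tables)[-length(d)]
  }
  if (any(flat < 0) || any(flat != round(flat))) {
    stop("table counts must be non-negative integers", call. = FALSE)
  }
  p <- apply(flat, 1L, function(v) {
    tb <- matrix(v, 2L, 2L, byrow = TRUE)
    if (sum(tb) == 0) return(1)
    stats::fisher.test(tb)$p.value
  })
  padj <- if (correct == "BH") stats::p.adjust(p, "BH") else p
  sig <- padj < alpha
  if (length(shape) > 1L) {
    p <- array(p, shape, dimnames = dn)
    sig <- array(sig, shape, dimnames = dn)
  }
  list(p = p, significant = sig)
}

#' Render an effect map with hyphens for non-significant cells
#'
#' @param effects numeric vector/matrix of effects.
#' @param significant logical mask of the same shape.
#' @param digits digits for significant cells.
#' @return character object of the same shape; `"-"` where masked.
#' @export
mask_nonsignificant <- function(effects, significant, digits = 3L) {
  out <- ifelse(significant, formatC(effects, digits = digits, format = "f"),
                "-")
  dim(out) <- dim(effects)
  dimnames(out) <- dimnames(effects)
  out
}

#' Convert a protospacer-strand substitution to rX:dY duplex notation
#'
#' The model's substitution notation fixes the guide and mutates the site's
#' protospacer-strand base; classic mismatch heatmaps describe the
#' RNA:DNA duplex, whose DNA base sits on the target strand. The transform
#' keeps the guide base as the RNA base and complements the substituted
#' site base: X -> Y corresponds to rX:d(complement(Y)). So G -> C is
#' rG:dG and G -> T is rG:dA; the identity A -> A is the Watson-Crick
#' match rA:dT.
#'
#' @param from,to guide and site protospacer-strand bases (A/C/G/T).
#' @return character vector like `"rG:dG"`.
#' @export
substitution_to_duplex <- function(from, to) {
  if (any(!from %in% BASES) || any(!to %in% BASES)) {
    stop("bases must be one of A, C, G, T", call. = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste0("r", from, ":d", comp[to])
}

#' Invert the duplex-notation transform
#'
#' @param duplex character vector like `"rG:dG"`.
#' @return data frame with `from` (guide base) and `to` (site base).
#' @export
duplex_to_substitution <- function(duplex) {
  m <- regmatches(duplex, regexec("^r([ACGT]):d([ACGT])$", duplex))
  if (any(vapply(m, length, integer(1)) != 3L)) {
    stop("duplex notation must look like 'rG:dG'", call. = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  data.frame(from = vapply(m, `[`, character(1), 2L),
             to = unname(comp[vapply(m, `[`, character(1), 3L)]),
             stringsAsFactors = FALSE)
}

#' Partition protospacer positions into substitution zones
#'
#' Labels each position by its mean substitution effect: `preference`
#' where the effect exceeds `tau` (substitutions there are tolerated or
#' enriched among detected off-targets), `avoiding` below `-tau`, and
#' `undetermined` otherwise; adjacent same-label positions merge into
#' contiguous ranges.
#'
#' @param avg_effects numeric vector of 20 per-position mean effects.
#' @param tau threshold; defaults to half the standard deviation of the
#'   map.
#' @return object of class `zone_partition`: data frame with `start`,
#'   `end`, `label`; ranges partition positions 1-20.
#' @export
zone_partition <- function(avg_effects, tau = NULL) {
  if (length(avg_effects) != PROTO_LEN || anyNA(avg_effects)) {
    stop("avg_effects must be 20 finite values", call. = FALSE)
  }
  tau <- tau %||% (stats::sd(avg_effects) / 2)
  lab <- ifelse(avg_effects > tau, "preference",
                ifelse(avg_effects < -tau, "avoiding", "undetermined"))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  out <- data.frame(start = c(1L, utils::head(ends, -1L) + 1L), end = ends,
                    label = r$values, stringsAsFactors = FALSE)
  structure(out, class = c("zone_partition", "data.frame"), tau = tau)
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("Substitution zones (tau = %.4g):\n", attr(x, "tau")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  positions %2d-%2d: %s\n", x$start[i], x$end[i], x$label[i]))
  }
  invisible(x)
}
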