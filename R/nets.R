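# Model definitions and training: the denoising convolutional autoencoder
# whose encoder becomes the pretrained "parent network", the fine-tuned
# on-target predictor, and the two-branch off-target pair predictor whose
# branches start as copies of the parent and are fine-tuned into distinct
# "baby networks". Class imbalance is handled by bootstrap-balanced
# mini-batches.

#' Network and training configuration
#'
#' @param task `"classification"` (softmax head, probabilities) or
#'   `"regression"` (identity head, real scores).
#' @param encoder list of convolution blocks, each a list with `kernel`,
#'   `channels`, `stride`, `batchnorm`. The default is three blocks
#'   (kernel 3, channels 32/64/64, stride 1, batch normalization on),
#'   mapping the 23 x 8 input to a full-resolution 23 x 64 latent feature
#'   map: with a 23-position window there is nothing to gain from
#'   downsampling, and keeping per-position latents is what lets the pair
#'   model localize individual mismatches.
#' @param head list of convolution blocks applied after the (merged)
#'   encoder output, before the readout. When NULL (default) each model
#'   picks its task-appropriate head: the on-target model uses two
#'   kernel-3 batch-normalized blocks; the
#'   off-target pair model uses a kernel-1 comparison block plus a
#'   kernel-3 block, both without batch normalization, with a
#'   kernel-3 block, both without batch normalization. Both heads end in
#'   a position-aware flatten readout and a dense output: nucleotide
#'   preferences and mismatch tolerance are position-dependent, so
#'   neither head may average positions away; the pair head additionally
#'   avoids batch normalization, which would re-center the near-zero
#'   match-versus-mismatch difference signal.
#' @param corruption list with `mask_prob` (per-position probability of
#'   replacing the nucleotide one-hot with a random one-hot, default 0.05)
#'   and `epi_sd` (sd of additive Gaussian noise on epigenetic channels,
#'   clipped back to `[0, 1]`, default 0.1).
#' @param lr_head Adam learning rate for newly initialized layers.
#' @param weight_decay decoupled L2 weight decay applied to convolution and
#'   dense weights (not biases or normalization parameters); the main
#'   regularizer when labeled examples are few.
#' @param head_noise sd of Gaussian noise added to the (frozen) branch
#'   feature maps while training the pair head — feature-space analog of
#'   the denoising objective, discouraging the head from memorizing
#'   individual training pairs. Ignored outside the frozen-branch path.
#' @param lr_parent_ratio fine-tuning learning-rate ratio for pretrained
#'   parent layers relative to `lr_head` (default 0.1).
#' @param batch_size mini-batch size (must be even for balanced batching).
#' @param epochs training epochs; under bootstrap balancing one epoch is
#'   one pass over the majority class.
#' @param seed mandatory integer seed; all training randomness (shuffling,
#'   corruption, bootstrap draws, initialization) derives from it.
#' @return an object of class `network_config`.
#' @export
network_config <- function(task = c("classification", "regression"),
                           encoder = NULL, head = NULL,
                           corruption = list(mask_prob = 0.05, epi_sd = 0.1),
                           lr_head = 2e-3, lr_parent_ratio = 0.1,
                           weight_decay = 1e-3, head_noise = 0,
                           batch_size = 64L, epochs = 20L, seed) {
  task <- match.arg(task)
  if (missing(seed) || !is_count(seed)) {
    stop("an integer seed is mandatory in network_config()", call. = FALSE)
  }
  encoder <- encoder %||% list(
    list(kernel = 3L, channels = 32L, stride = 1L, batchnorm = TRUE),
    list(kernel = 3L, channels = 64L, stride = 1L, batchnorm = TRUE),
    list(kernel = 3L, channels = 64L, stride = 1L, batchnorm = TRUE))
  if (!length(encoder)) stop("need at least one encoder layer", call. = FALSE)
  mp <- corruption$mask_prob %||% 0.05
  es <- corruption$epi_sd %||% 0.1
  if (mp < 0 || mp > 1) stop("mask_prob must be in [0, 1]", call. = FALSE)
  structure(list(task = task, encoder = encoder, head = head,
                 corruption = list(mask_prob = mp, epi_sd = es),
                 lr_head = lr_head, lr_parent_ratio = lr_parent_ratio,
                 weight_decay = weight_decay, head_noise = head_noise,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "network_config")
}

schema_hash <- function() paste0("guide23x8:", paste(CHANNELS, collapse = ","))

# task-appropriate default heads (see network_config() for the rationale)
DEFAULT_ONTARGET_HEAD <- list(
  list(kernel = 3L, channels = 64L, stride = 1L, batchnorm = TRUE),
  list(kernel = 3L, channels = 64L, stride = 1L, batchnorm = TRUE))
DEFAULT_OFFTARGET_HEAD <- list(
  list(kernel = 1L, channels = 64L, stride = 1L, batchnorm = FALSE),
  list(kernel = 3L, channels = 64L, stride = 1L, batchnorm = FALSE))

build_encoder_layers <- function(cfg, c_in = 8L) {
  layers <- list()
  L <- GUIDE_LEN
  for (blk in cfg) {
    layers <- c(layers, list(nn_conv1d(c_in, blk$channels, blk$kernel,
                                       blk$stride)))
    if (isTRUE(blk$batchnorm)) layers <- c(layers, list(nn_bn(blk$channels)))
    layers <- c(layers, list(nn_relu()))
    L <- conv_out_len(L, blk$kernel, blk$stride)
    c_in <- blk$channels
  }
  structure(layers, latent_len = L, latent_channels = c_in)
}

build_head_layers <- function(cfg, c_in, n_out, antisym = FALSE,
                              readout = c("pool", "flatten"), L_in = NULL) {
  readout <- match.arg(readout)
  layers <- list()
  first <- TRUE
  for (blk in cfg) {
    cv <- nn_conv1d(c_in, blk$channels, blk$kernel, blk$stride)
    if (first && antisym) {
      # pair-comparison inductive bias: the head's first convolution sees
      # the channel-wise concatenation [h_guide; h_site] of two branches
      # that start from identical parent weights. Initializing the
      # site-branch block as the negation of the guide-branch block makes
      # the initial head response W (h_guide - h_site): silent wherever
      # the two windows agree, active at mismatches. Training is free to
      # move away from this antisymmetric point.
      half <- c_in %/% 2L
      for (j in seq_len(cv$kernel)) {
        off <- (j - 1L) * c_in
        cv$W[off + half + seq_len(half), ] <- -cv$W[off + seq_len(half), ]
      }
    }
    first <- FALSE
    layers <- c(layers, list(cv))
    if (isTRUE(blk$batchnorm)) layers <- c(layers, list(nn_bn(blk$channels)))
    layers <- c(layers, list(nn_relu()))
    c_in <- blk$channels
    if (!is.null(L_in)) L_in <- conv_out_len(L_in, blk$kernel, blk$stride)
  }
  if (readout == "pool") {
    c(layers, list(nn_pool(), nn_dense(c_in, n_out)))
  } else {
    # position-aware readout: mismatch tolerance is position-dependent, so
    # the pair head keeps the latent positions distinct instead of
    # averaging them away
    c(layers, list(nn_flatten(), nn_dense(L_in * c_in, n_out)))
  }
}

# ---- input corruption ------------------------------------------------------

.corrupt <- function(x, mask_prob, epi_sd) {
  d <- dim(x); n <- d[1]
  if (mask_prob > 0) {
    mask <- matrix(stats::runif(n * GUIDE_LEN) < mask_prob, n, GUIDE_LEN)
    if (any(mask)) {
      idx <- which(mask, arr.ind = TRUE)
      newb <- sample.int(4L, nrow(idx), replace = TRUE)
      for (b in 1:4) x[cbind(idx, b)] <- as.numeric(newb == b)
    }
  }
  if (epi_sd > 0) {
    epi <- x[, , 5:8, drop = FALSE]
    epi <- epi + stats::rnorm(length(epi), sd = epi_sd)
    x[, , 5:8] <- pmin(pmax(epi, 0), 1)
  }
  x
}

#' Corrupt an encoded guide for denoising pretraining
#'
#' Each position's nucleotide one-hot is replaced, with probability
#' `mask_prob`, by a one-hot drawn uniformly over the four bases (so the
#' one-hot invariant is preserved even at mask probability 1); Gaussian
#' noise is added to the epigenetic channels and clipped back to `[0, 1]`.
#'
#' @param x a 23 x 8 encoding matrix or an `n x 23 x 8` array.
#' @param config a [network_config()] supplying the corruption rates.
#' @param seed optional seed for a reproducible corruption.
#' @return corrupted input of the same shape.
#' @export
corrupt_input <- function(x, config, seed = NULL) {
  single <- is.matrix(x)
  if (single) x <- array(x, c(1L, dim(x)))
  out <- with_seed(seed, .corrupt(x, config$corruption$mask_prob,
                                  config$corruption$epi_sd))
  if (single) {
    m <- out[1L, , ]
    dimnames(m) <- list(NULL, CHANNELS)
    m
  } else out
}

# ---- bootstrap-balanced batching -------------------------------------------

.balanced_batches_raw <- function(labels, batch_size) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (!length(pos) || !length(neg)) {
    stop("both classes must be present for balanced batching", call. = FALSE)
  }
  if (batch_size %% 2L != 0L) stop("batch_size must be even", call. = FALSE)
  half <- batch_size %/% 2L
  if (length(pos) <= length(neg)) {
    minor <- pos; major <- neg
  } else {
    minor <- neg; major <- pos
  }
  major <- sample(major)
  n_batches <- length(major) %/% half
  if (n_batches == 0L) {
    stop("majority class smaller than half the batch size", call. = FALSE)
  }
  equal <- length(minor) == length(major)
  if (equal) minor_perm <- sample(minor)
  lapply(seq_len(n_batches), function(b) {
    mj <- major[((b - 1L) * half + 1L):(b * half)]
    mn <- if (equal) minor_perm[((b - 1L) * half + 1L):(b * half)] else {
      minor[sample.int(length(minor), half, replace = TRUE)]
    }
    c(mj, mn)
  })
}

#' Bootstrap-balanced mini-batches for imbalanced data
#'
#' Every batch holds exactly `batch_size/2` positives and `batch_size/2`
#' negatives: the majority class is shuffled and partitioned across the
#' epoch (a trailing remainder smaller than half a batch is dropped) while
#' the minority class is bootstrapped — resampled with replacement — to
#' match. When the classes are already equal both are partitioned, so each
#' sample appears exactly once per epoch.
#'
#' @param labels 0/1 vector.
#' @param batch_size even batch size.
#' @param seed integer seed.
#' @return list of integer index vectors (one per batch), majority indices
#'   first within each batch.
#' @export
balanced_batches <- function(labels, batch_size = 64L, seed = 1L) {
  with_seed(seed, .balanced_batches_raw(labels, batch_size))
}

# ---- denoising-autoencoder pretraining -------------------------------------

recon_loss <- function(y, x) {
  d <- dim(x); n <- d[1]
  yarr <- array(y, d)
  m <- n * GUIDE_LEN
  Z <- matrix(yarr[, , 1:4], m, 4L)
  Tn <- matrix(x[, , 1:4], m, 4L)
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z); P <- P / rowSums(P)
  ce <- -mean(log(pmax(rowSums(Tn * P), 1e-12)))
  dZ <- (P - Tn) / m
  E <- matrix(yarr[, , 5:8], m, 4L)
  Te <- matrix(x[, , 5:8], m, 4L)
  S <- stats::plogis(E)
  l_epi <- mean((S - Te)^2)
  dE <- 2 * (S - Te) * S * (1 - S) / (m * 4L)
  dy <- array(0, d)
  dy[, , 1:4] <- array(dZ, c(n, GUIDE_LEN, 4L))
  dy[, , 5:8] <- array(dE, c(n, GUIDE_LEN, 4L))
  list(loss = ce + l_epi, dy = matrix(dy, n, prod(d[-1])),
       recon = yarr)
}

# decode an AE output array back to hard calls for accuracy audits
ae_reconstruction <- function(y, n) {
  yarr <- array(y, c(n, GUIDE_LEN, 8L))
  yarr
}

#' Pretrain the parent encoder as a denoising autoencoder
#'
#' Trains an encoder-decoder pair to reconstruct clean 23 x 8 encodings
#' from corrupted ones (random one-hot masking plus epigenetic noise); the
#' returned parent network is the trained encoder. The decoder maps the
#' latent feature map through a dense layer back to per-position nucleotide
#' softmaxes and sigmoid epigenetic channels; the reconstruction loss is
#' positionwise cross-entropy plus mean squared error.
#'
#' @param x unlabeled encodings, array `c(n, 23, 8)`.
#' @param config a [network_config()]; `corruption`, `lr_head`,
#'   `batch_size`, `epochs` and `seed` are used.
#' @return object of class `crispr_parent` with the encoder parameters and
#'   the per-epoch training-loss trace.
#' @export
pretrain_parent <- function(x, config) {
  stopifnot(inherits(config, "network_config"), length(dim(x)) == 3L)
  n <- dim(x)[1]
  if (n < config$batch_size) {
    stop("need at least batch_size inputs for pretraining", call. = FALSE)
  }
  set.seed(config$seed)
  enc <- build_encoder_layers(config$encoder)
  lat_dim <- attr(enc, "latent_len") * attr(enc, "latent_channels")
  # a direct linear readout of the full-resolution latent: a narrower
  # hidden layer bottlenecks copy-through precision, which is the whole
  # point of a denoising reconstruction
  dec <- list(nn_flatten(), nn_dense(lat_dim, GUIDE_LEN * 8L))
  all_layers <- c(enc, dec)
  trace <- numeric(config$epochs)
  t <- 0L
  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    losses <- c()
    for (b in seq(1L, n - config$batch_size + 1L, by = config$batch_size)) {
      take <- idx[b:(b + config$batch_size - 1L)]
      xb <- x[take, , , drop = FALSE]
      xc <- .corrupt(xb, config$corruption$mask_prob, config$corruption$epi_sd)
      h <- net_forward(enc, xc, train = TRUE)
      y <- net_forward(dec, h, train = TRUE)
      ls <- recon_loss(y, xb)
      if (!is.finite(ls$loss)) {
        stop("pretraining diverged (non-finite loss) at epoch ", epoch,
             "; last finite losses: ",
             paste(utils::tail(round(losses, 4), 5), collapse = ", "),
             call. = FALSE)
      }
      net_backward(enc, net_backward(dec, ls$dy))
      t <- t + 1L
      adam_step(all_layers, config$lr_head, t,
                weight_decay = config$weight_decay %||% 0)
      losses <- c(losses, ls$loss)
    }
    trace[epoch] <- mean(losses)
  }
  structure(list(encoder_state = net_state(enc),
                 decoder_state = net_state(dec),
                 latent = list(len = attr(enc, "latent_len"),
                               channels = attr(enc, "latent_channels")),
                 config = config, loss_trace = trace,
                 schema = schema_hash()),
            class = "crispr_parent")
}

#' Reconstruct encodings with a pretrained autoencoder
#'
#' Runs corrupted (or clean) inputs through the parent's encoder-decoder
#' and returns the decoder output with the nucleotide block collapsed to
#' hard one-hot calls, for denoising-gain audits.
#'
#' @param parent a [pretrain_parent()] result.
#' @param x array `c(n, 23, 8)`.
#' @return array `c(n, 23, 8)` of reconstructions (one-hot nucleotides,
#'   sigmoid epigenetic channels).
#' @export
reconstruct <- function(parent, x) {
  stopifnot(inherits(parent, "crispr_parent"))
  enc <- net_from_state(parent$encoder_state)
  dec <- net_from_state(parent$decoder_state)
  n <- dim(x)[1]
  y <- net_forward(dec, net_forward(enc, x, train = FALSE), train = FALSE)
  yarr <- array(y, c(n, GUIDE_LEN, 8L))
  out <- array(0, dim(yarr))
  for (i in seq_len(n)) {
    nt <- yarr[i, , 1:4]
    out[i, , 1:4][cbind(seq_len(GUIDE_LEN), max.col(nt))] <- 1
  }
  out[, , 5:8] <- stats::plogis(yarr[, , 5:8, drop = FALSE])
  out
}

#' @export
print.crispr_parent <- function(x, ...) {
  cat("Pretrained parent encoder (denoising convolutional autoencoder)\n")
  cat(sprintf("  latent: %d x %d | epochs: %d | final loss: %.4f\n",
              x$latent$len, x$latent$channels, length(x$loss_trace),
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

# ---- supervised training ---------------------------------------------------

.prep_parent_branch <- function(parent, fine_tune, ratio) {
  enc <- net_from_state(parent$encoder_state)
  if (fine_tune) set_lr_scale(enc, ratio) else freeze_net(enc)
  enc
}

.check_labels <- function(y, task) {
  if (task == "classification") {
    if (!all(y %in% c(0, 1))) {
      stop("classification task requires 0/1 labels", call. = FALSE)
    }
  } else if (!is.numeric(y) || any(!is.finite(y))) {
    stop("regression task requires finite numeric labels", call. = FALSE)
  }
}

.head_loss <- function(out, yb, task) {
  if (task == "classification") softmax_ce(out, as.integer(yb))
  else {
    ls <- mse_loss(out, yb)
    list(loss = ls$loss, dlogits = ls$dpred)
  }
}

#' Train the on-target efficacy predictor
#'
#' Copies the pretrained parent encoder, attaches a convolutional head
#' (softmax output for classification, identity output for regression) and
#' trains on labeled encodings. With `fine_tune = TRUE` (default) the
#' parent copy is updated at `lr_parent_ratio` times the head's learning
#' rate; with `fine_tune = FALSE` the parent is frozen (its parameters and
#' normalization statistics are bit-identical before and after). With
#' `parent = NULL` the encoder is trained from scratch.
#'
#' @param parent a [pretrain_parent()] result, or NULL for from-scratch.
#' @param x training encodings, array `c(n, 23, 8)`.
#' @param y labels: 0/1 for classification, real for regression.
#' @param config a [network_config()]; its `task` selects the head.
#' @param fine_tune update the parent copy's weights (default TRUE).
#' @return object of class `crispr_ontarget`.
#' @export
train_ontarget <- function(parent, x, y, config, fine_tune = TRUE) {
  stopifnot(inherits(config, "network_config"), length(dim(x)) == 3L)
  .check_labels(y, config$task)
  n <- dim(x)[1]
  if (length(y) != n) stop("x and y sizes differ", call. = FALSE)
  set.seed(config$seed)
  if (is.null(parent)) {
    enc <- build_encoder_layers(config$encoder)
  } else {
    stopifnot(inherits(parent, "crispr_parent"))
    enc <- .prep_parent_branch(parent, fine_tune, config$lr_parent_ratio)
  }
  lat_c <- if (is.null(parent)) attr(enc, "latent_channels") else
    parent$latent$channels
  n_out <- if (config$task == "classification") 2L else 1L
  head <- build_head_layers(config$head %||% DEFAULT_ONTARGET_HEAD, lat_c,
                            n_out, readout = "flatten",
                            L_in = if (is.null(parent))
                              attr(enc, "latent_len") else parent$latent$len)
  parent_train_mode <- is.null(parent) || fine_tune
  trace <- numeric(config$epochs)
  t <- 0L
  bs <- config$batch_size
  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    losses <- c()
    for (b in seq(1L, max(n - bs + 1L, 1L), by = bs)) {
      take <- idx[b:min(b + bs - 1L, n)]
      if (length(take) < 2L) next
      h <- net_forward(enc, x[take, , , drop = FALSE], train = parent_train_mode)
      out <- net_forward(head, h, train = TRUE)
      ls <- .head_loss(out, y[take], config$task)
      if (!is.finite(ls$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      }
      dh <- net_backward(head, ls$dlogits)
      net_backward(enc, dh)
      t <- t + 1L
      adam_step(c(enc, head), config$lr_head, t,
                weight_decay = config$weight_decay %||% 0)
      losses <- c(losses, ls$loss)
    }
    trace[epoch] <- mean(losses)
  }
  structure(list(encoder_state = net_state(enc), head_state = net_state(head),
                 config = config, task = config$task,
                 fine_tuned = if (is.null(parent)) NA else fine_tune,
                 pretrained = !is.null(parent),
                 loss_trace = trace, n_train = n, schema = schema_hash()),
            class = "crispr_ontarget")
}

#' Train the two-branch off-target pair predictor
#'
#' Instantiates two copies of the parent encoder — one per input part —
#' which are fine-tuned separately into distinct "baby networks"; their
#' latent feature maps are concatenated channel-wise and fed to a
#' convolutional head. Training consumes bootstrap-balanced batches by
#' default (one epoch = one pass over the majority class); for regression
#' the balancing classes are `y > 0` versus `y == 0`.
#'
#' @param parent a [pretrain_parent()] result, or NULL for from-scratch.
#' @param x_guide,x_site encodings of the guide and candidate-site parts,
#'   arrays `c(n, 23, 8)`.
#' @param y 0/1 detection labels (classification) or indel frequencies
#'   (regression).
#' @param config a [network_config()].
#' @param fine_tune update the branch copies (default TRUE).
#' @param balance use bootstrap-balanced batching (default TRUE).
#' @param ensemble number of independently initialized heads to train;
#'   predictions average over them. With so few positive pair labels a
#'   single head's generalization varies noticeably from seed to seed, and
#'   a small bag of heads stabilizes it. With frozen branches the extra
#'   heads are cheap (branch latents are encoded once).
#' @param branch_latents optional precomputed frozen-branch latents as
#'   returned by [encode_branch_latents()], for repeated fits on the same
#'   (parent, data); only used with `fine_tune = FALSE`.
#' @return object of class `crispr_offtarget`.
#' @export
train_offtarget <- function(parent, x_guide, x_site, y, config,
                            fine_tune = TRUE, balance = TRUE,
                            ensemble = 1L, branch_latents = NULL) {
  stopifnot(inherits(config, "network_config"),
            length(dim(x_guide)) == 3L, length(dim(x_site)) == 3L)
  .check_labels(y, config$task)
  n <- dim(x_guide)[1]
  stopifnot(dim(x_site)[1] == n, length(y) == n)
  set.seed(config$seed)
  if (is.null(parent)) {
    # even without pretraining the two branches must start from identical
    # weights: aligned latent spaces are what makes the merged feature map
    # comparable across the guide and site parts
    enc1 <- build_encoder_layers(config$encoder)
    lat_c <- attr(enc1, "latent_channels")
    enc2 <- clone_net(enc1)
  } else {
    stopifnot(inherits(parent, "crispr_parent"))
    enc1 <- .prep_parent_branch(parent, fine_tune, config$lr_parent_ratio)
    enc2 <- .prep_parent_branch(parent, fine_tune, config$lr_parent_ratio)
    lat_c <- parent$latent$channels
  }
  lat_len <- if (is.null(parent)) attr(enc1, "latent_len") else
    parent$latent$len
  n_out <- if (config$task == "classification") 2L else 1L
  parent_train_mode <- is.null(parent) || fine_tune
  cls <- if (config$task == "classification") y else as.integer(y > 0)
  bs <- config$batch_size
  # frozen branches produce the same latents every epoch: encode each part
  # once in eval mode and train only the head on the cached feature maps
  frozen_cache <- !parent_train_mode
  if (ensemble > 1L && !frozen_cache) {
    stop("ensemble > 1 requires frozen branches (fine_tune = FALSE with a ",
         "pretrained parent)", call. = FALSE)
  }
  if (frozen_cache) {
    if (!is.null(branch_latents)) {
      stopifnot(nrow(branch_latents$guide) == n * lat_len,
                nrow(branch_latents$site) == n * lat_len)
      lat1 <- branch_latents$guide
      lat2 <- branch_latents$site
    } else {
      lat1 <- .encode_latents(enc1, x_guide, lat_len, lat_c)
      lat2 <- .encode_latents(enc2, x_site, lat_len, lat_c)
    }
  }
  head_states <- vector("list", ensemble)
  traces <- vector("list", ensemble)
  for (member in seq_len(ensemble)) {
    set.seed(config$seed + member - 1L)
    head <- build_head_layers(config$head %||% DEFAULT_OFFTARGET_HEAD,
                              2L * lat_c, n_out, antisym = TRUE,
                              readout = "flatten", L_in = lat_len)
    trace <- numeric(config$epochs)
    t <- 0L
    for (epoch in seq_len(config$epochs)) {
      batches <- if (balance) .balanced_batches_raw(cls, bs) else {
        idx <- sample.int(n)
        starts <- seq(1L, max(n - bs + 1L, 1L), by = bs)
        lapply(starts, function(b) idx[b:min(b + bs - 1L, n)])
      }
      losses <- c()
      for (take in batches) {
        if (length(take) < 2L) next
        if (frozen_cache) {
          hm <- cbind(.latent_rows(lat1, take, lat_len),
                      .latent_rows(lat2, take, lat_len))
          noise_sd <- config$head_noise %||% 0
          if (noise_sd > 0) {
            hm <- hm + stats::rnorm(length(hm), sd = noise_sd)
          }
          h <- fm(hm, length(take), lat_len)
        } else {
          h1 <- net_forward(enc1, x_guide[take, , , drop = FALSE],
                            train = parent_train_mode)
          h2 <- net_forward(enc2, x_site[take, , , drop = FALSE],
                            train = parent_train_mode)
          h <- merge_channels(h1, h2)
        }
        out <- net_forward(head, h, train = TRUE)
        ls <- .head_loss(out, y[take], config$task)
        if (!is.finite(ls$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        }
        dh <- net_backward(head, ls$dlogits)
        if (!frozen_cache) {
          parts <- split_channels(dh, lat_c)
          net_backward(enc1, parts[[1]])
          net_backward(enc2, parts[[2]])
        }
        t <- t + 1L
        adam_step(c(enc1, enc2, head), config$lr_head, t,
                  weight_decay = config$weight_decay %||% 0)
        losses <- c(losses, ls$loss)
      }
      trace[epoch] <- mean(losses)
    }
    head_states[[member]] <- net_state(head)
    traces[[member]] <- trace
  }
  structure(list(enc1_state = net_state(enc1), enc2_state = net_state(enc2),
                 head_state = head_states[[1]], head_states = head_states,
                 config = config, task = config$task,
                 fine_tuned = if (is.null(parent)) NA else fine_tune,
                 pretrained = !is.null(parent), balanced = balance,
                 ensemble = as.integer(ensemble),
                 loss_trace = traces[[1]], loss_traces = traces,
                 n_train = n, schema = schema_hash()),
            class = "crispr_offtarget")
}

#' Precompute frozen-branch latents for repeated pair-model fits
#'
#' Encodes the guide and site parts once through the (frozen) parent
#' encoder, for passing to [train_offtarget()] via `branch_latents` when
#' several heads are to be fitted on the same data.
#'
#' @param parent a [pretrain_parent()] result.
#' @param x_guide,x_site pair encodings, arrays `c(n, 23, 8)`.
#' @return list with `guide` and `site` latent matrices.
#' @export
encode_branch_latents <- function(parent, x_guide, x_site) {
  stopifnot(inherits(parent, "crispr_parent"))
  enc <- net_from_state(parent$encoder_state)
  list(guide = .encode_latents(enc, x_guide, parent$latent$len,
                               parent$latent$channels),
       site = .encode_latents(enc, x_site, parent$latent$len,
                              parent$latent$channels))
}

# encode a full input array through a frozen branch (eval mode, chunked);
# result is the fm matrix layout for the whole set: row (i, l) = i + n*(l-1)
.encode_latents <- function(enc, x, lat_len, lat_c, chunk = 4096L) {
  n <- dim(x)[1]
  out <- matrix(0, n * lat_len, lat_c)
  for (b in seq(1L, n, by = chunk)) {
    take <- b:min(b + chunk - 1L, n)
    h <- net_forward(enc, x[take, , , drop = FALSE], train = FALSE)
    out[as.vector(outer(take, (seq_len(lat_len) - 1L) * n, `+`)), ] <- h$m
  }
  out
}

.latent_rows <- function(lat, take, lat_len) {
  n <- nrow(lat) / lat_len
  lat[as.vector(outer(take, (seq_len(lat_len) - 1L) * n, `+`)), , drop = FALSE]
}

# ---- prediction ------------------------------------------------------------

.as_input_array <- function(x) {
  if (is.matrix(x) && all(dim(x) == c(GUIDE_LEN, 8L))) {
    array(x, c(1L, GUIDE_LEN, 8L))
  } else if (is.array(x) && length(dim(x)) == 3L &&
             all(dim(x)[2:3] == c(GUIDE_LEN, 8L))) {
    x
  } else {
    stop("input must be a 23 x 8 matrix or an n x 23 x 8 array", call. = FALSE)
  }
}

.predict_chunks <- function(fun, n, chunk = 2048L) {
  out <- numeric(n)
  for (b in seq(1L, n, by = chunk)) {
    take <- b:min(b + chunk - 1L, n)
    out[take] <- fun(take)
  }
  out
}

#' Predict with an on-target model
#'
#' @param object a [train_ontarget()] fit.
#' @param x encodings (23 x 8 matrix or `n x 23 x 8` array).
#' @param ... unused.
#' @return for classification, the probability of the efficacious class in
#'   `[0, 1]`; for regression, a real score. Deterministic at inference.
#' @export
predict.crispr_ontarget <- function(object, x, ...) {
  x <- .as_input_array(x)
  enc <- net_from_state(object$encoder_state)
  head <- net_from_state(object$head_state)
  n <- dim(x)[1]
  .predict_chunks(function(take) {
    h <- net_forward(enc, x[take, , , drop = FALSE], train = FALSE)
    out <- net_forward(head, h, train = FALSE)
    if (object$task == "classification") softmax_probs(out)[, 2L]
    else as.numeric(out)
  }, n)
}

#' Predict with an off-target pair model
#'
#' @param object a [train_offtarget()] fit.
#' @param x_guide,x_site encodings of the two parts.
#' @param ... unused.
#' @return per-pair occurrence probability (classification) or real score
#'   (regression).
#' @export
predict.crispr_offtarget <- function(object, x_guide, x_site, ...) {
  x_guide <- .as_input_array(x_guide)
  x_site <- .as_input_array(x_site)
  enc1 <- net_from_state(object$enc1_state)
  enc2 <- net_from_state(object$enc2_state)
  heads <- lapply(object$head_states %||% list(object$head_state),
                  net_from_state)
  n <- dim(x_guide)[1]
  .predict_chunks(function(take) {
    h <- merge_channels(
      net_forward(enc1, x_guide[take, , , drop = FALSE], train = FALSE),
      net_forward(enc2, x_site[take, , , drop = FALSE], train = FALSE))
    per_head <- lapply(heads, function(head) {
      out <- net_forward(head, h, train = FALSE)
      if (object$task == "classification") softmax_probs(out)[, 2L]
      else as.numeric(out)
    })
    Reduce(`+`, per_head) / length(per_head)
  }, n)
}

#' @rdname predict.crispr_ontarget
#' @param model a fitted on-target model.
#' @export
predict_ontarget <- function(model, x) predict(model, x)

#' @rdname predict.crispr_offtarget
#' @param model a fitted off-target model.
#' @export
predict_offtarget <- function(model, x_guide, x_site) {
  predict(model, x_guide, x_site)
}

# ---- methods ---------------------------------------------------------------

.print_fit <- function(x, what) {
  cat(sprintf("%s (%s head%s%s)\n", what, x$task,
              if (isTRUE(x$pretrained)) ", pretrained parent" else ", from scratch",
              if (isTRUE(x$fine_tuned)) ", fine-tuned" else ""))
  cat(sprintf("  n = %d | epochs = %d | final loss = %.4f\n",
              x$n_train, length(x$loss_trace), utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
print.crispr_ontarget <- function(x, ...) .print_fit(x, "On-target efficacy model")

#' @export
print.crispr_offtarget <- function(x, ...) {
  .print_fit(x, "Two-branch off-target model")
  if (!is.null(x$balanced)) {
    cat(sprintf("  bootstrap-balanced batches: %s\n", x$balanced))
  }
  invisible(x)
}

#' @export
summary.crispr_ontarget <- function(object, ...) {
  print(object)
  cat("  loss trace: ", paste(round(object$loss_trace, 4), collapse = " "),
      "\n")
  invisible(object)
}

#' @export
summary.crispr_offtarget <- function(object, ...) {
  print(object)
  cat("  loss trace: ", paste(round(object$loss_trace, 4), collapse = " "),
      "\n")
  invisible(object)
}

#' @export
plot.crispr_ontarget <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
                 xlab = "epoch", ylab = "training loss",
                 main = "On-target training loss", ...)
  invisible(x)
}

#' @export
plot.crispr_offtarget <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
                 xlab = "epoch", ylab = "training loss",
                 main = "Off-target training loss", ...)
  invisible(x)
}

#' @export
plot.crispr_parent <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
                 xlab = "epoch", ylab = "reconstruction loss",
                 main = "Denoising-autoencoder pretraining", ...)
  invisible(x)
}
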