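test_that("input corruption preserves the one-hot invariant at any rate", {
  sim <- ontarget_fixture()
  x <- sim$x[1:50, , ]
  cfg0 <- network_config(seed = 1, corruption = list(mask_prob = 0, epi_sd = 0))
  expect_identical(corrupt_input(x, cfg0, seed = 2), x)
  cfg1 <- network_config(seed = 1, corruption = list(mask_prob = 1, epi_sd = 0.3))
  xc <- corrupt_input(x, cfg1, seed = 2)
  expect_equal(apply(xc[, , 1:4], c(1, 2), sum), matrix(1, 50, 23))
  expect_true(all(xc[, , 5:8] >= 0 & xc[, , 5:8] <= 1))
  # deterministic under a fixed seed, different under another
  expect_identical(corrupt_input(x, cfg1, seed = 2), xc)
  expect_false(identical(corrupt_input(x, cfg1, seed = 3), xc))
  # single-matrix form round-trips shape
  m <- corrupt_input(x[1, , ], cfg1, seed = 4)
  expect_equal(dim(m), c(23L, 8L))
})

test_that("balanced batches hold exactly equal class counts at 1:250 imbalance", {
  set.seed(71)
  labels <- c(rep(1L, 4), rep(0L, 1000))
  violations <- 0L
  for (epoch_seed in 1:100) {
    batches <- balanced_batches(labels, batch_size = 64, seed = epoch_seed)
    if (length(batches) != 1000 %/% 32) violations <- violations + 1L
    counts <- vapply(batches, function(b) sum(labels[b]), integer(1))
    negs_seen <- unlist(lapply(batches, function(b) b[labels[b] == 0L]))
    violations <- violations + sum(lengths(batches) != 64L) +
      sum(counts != 32L) + sum(duplicated(negs_seen))
  }
  expect_identical(violations, 0L)
})

test_that("already balanced data is used exactly once per epoch", {
  labels <- rep(c(0L, 1L), each = 50)
  batches <- balanced_batches(labels, batch_size = 20, seed = 5)
  idx <- unlist(batches)
  expect_equal(sort(idx), seq_along(labels))
  expect_error(balanced_batches(rep(1L, 10), 4), "both classes")
  expect_error(balanced_batches(labels, 7), "even")
})

test_that("pretraining reduces reconstruction loss and denoises measurably", {
  sim <- ontarget_fixture()
  cfg <- network_config(epochs = 8, seed = 81, batch_size = 64,
                        corruption = list(mask_prob = 0.3, epi_sd = 0.1))
  parent <- fixture("parent_small", function() pretrain_parent(sim$x, cfg))
  expect_lt(tail(parent$loss_trace, 1), parent$loss_trace[1])
  # denoising gain: reconstruction closer to clean input than the corrupted was
  clean <- sim$x[1:300, , ]
  xc <- corrupt_input(clean, cfg, seed = 82)
  rec <- reconstruct(parent, xc)
  agree <- function(a) {
    mean(apply(a[, , 1:4], c(1, 2), which.max) ==
           apply(clean[, , 1:4], c(1, 2), which.max))
  }
  expect_gt(agree(rec), agree(xc))
  # same seed, same trace
  parent2 <- pretrain_parent(sim$x, cfg)
  expect_identical(parent2$loss_trace, parent$loss_trace)
  expect_error(pretrain_parent(sim$x[1:10, , ], cfg), "batch_size")
})

test_that("a frozen parent is bit-identical after supervised training", {
  sim <- ontarget_fixture()
  cfg <- network_config(epochs = 8, seed = 81, batch_size = 64,
                        corruption = list(mask_prob = 0.3, epi_sd = 0.1))
  parent <- fixture("parent_small", function() pretrain_parent(sim$x, cfg))
  before <- parent$encoder_state
  fit <- train_ontarget(parent, sim$x[1:400, , ],
                        sim$records$binary_label[1:400],
                        network_config(epochs = 2, seed = 83),
                        fine_tune = FALSE)
  expect_identical(parent$encoder_state, before)
  drop_meta <- function(st) lapply(st, function(l) l[setdiff(names(l), c("frozen", "lr_scale"))])
  expect_identical(drop_meta(fit$encoder_state), drop_meta(before))
  # fine-tuning does move the parent copy
  fit2 <- train_ontarget(parent, sim$x[1:400, , ],
                         sim$records$binary_label[1:400],
                         network_config(epochs = 2, seed = 83),
                         fine_tune = TRUE)
  expect_false(identical(drop_meta(fit2$encoder_state), drop_meta(before)))
})

test_that("training is deterministic and rejects mismatched labels", {
  sim <- ontarget_fixture()
  cfg <- network_config(epochs = 2, seed = 84)
  f1 <- train_ontarget(NULL, sim$x[1:300, , ], sim$records$binary_label[1:300], cfg)
  f2 <- train_ontarget(NULL, sim$x[1:300, , ], sim$records$binary_label[1:300], cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$head_state, f2$head_state)
  expect_error(train_ontarget(NULL, sim$x[1:300, , ],
                              sim$records$raw_efficacy[1:300], cfg),
               "0/1 labels")
  expect_error(network_config(), "seed")
})

test_that("on-target predictions are probabilities, deterministic and order-stable", {
  fit <- ontarget_model_fixture()
  sim <- ontarget_fixture()
  x <- sim$x[801:900, , ]
  p <- predict(fit, x)
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict(fit, x), p)
  # duplicated rows score identically; permutation does not change scores
  xd <- x[c(1, 1, 2), , ]
  pd <- predict(fit, xd)
  expect_equal(pd[1], pd[2])
  perm <- sample(nrow(x))
  expect_equal(predict(fit, x[perm, , ]), p[perm], tolerance = 1e-12)
})

test_that("the two off-target branches diverge under fine-tuning", {
  sim <- offtarget_fixture()
  cfg <- network_config(epochs = 8, seed = 81, batch_size = 64,
                        corruption = list(mask_prob = 0.3, epi_sd = 0.1))
  parent <- fixture("parent_small", function() {
    pretrain_parent(ontarget_fixture()$x, cfg)
  })
  tcfg <- network_config(epochs = 1, seed = 85)
  fit <- train_offtarget(parent, sim$x_guide[1:800, , ], sim$x_site[1:800, , ],
                         sim$records$detected[1:800], tcfg, fine_tune = TRUE)
  expect_false(identical(fit$enc1_state, fit$enc2_state))
  p <- predict(fit, sim$x_guide[1:50, , ], sim$x_site[1:50, , ])
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict(fit, sim$x_guide[1:50, , ], sim$x_site[1:50, , ]), p)
})

test_that("regression heads emit real scores trained on indel frequencies", {
  sim <- ontarget_fixture()
  cfg <- network_config(task = "regression", epochs = 3, seed = 86)
  fit <- train_ontarget(NULL, sim$x[1:500, , ],
                        sim$records$normalized_label[1:500], cfg)
  p <- predict(fit, sim$x[501:600, , ])
  expect_true(all(is.finite(p)))
  expect_error(train_ontarget(NULL, sim$x[1:10, , ], rep(Inf, 10), cfg),
               "finite")
})
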