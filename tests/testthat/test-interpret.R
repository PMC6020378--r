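test_that("activation maximization drives a linear objective to the simplex vertex", {
  toy <- list(score = function(g) sum(g[, "A"]),
              grad = function(g) {
                d <- matrix(0, 23, 8, dimnames = list(NULL, colnames(g)))
                d[, "A"] <- 1
                d
              })
  sal <- activation_maximize(toy, iterations = 200, step = 0.2, l2 = 0)
  expect_s3_class(sal, "saliency_map")
  expect_equal(unname(sal$g[, "A"]), rep(1, 23), tolerance = 1e-6)
  expect_equal(unname(rowSums(sal$g[, 1:4])), rep(1, 23), tolerance = 1e-9)
  # ascent contract: trace is non-decreasing, final >= initial
  expect_true(all(diff(sal$score_trace) >= -1e-12))
  expect_gte(sal$score, sal$score_trace[1])
})

test_that("the simplex and clipping constraints hold throughout for a fitted model", {
  fit <- ontarget_model_fixture()
  sal <- activation_maximize(fit, iterations = 60, step = 0.1)
  expect_true(all(sal$g >= -1e-9 & sal$g <= 1 + 1e-9))
  expect_equal(unname(rowSums(sal$g[, 1:4])), rep(1, 23), tolerance = 1e-9)
  expect_true(all(diff(sal$score_trace) >= -1e-12))
})

test_that("Fisher filtering matches hypergeometric enumeration on small tables", {
  # independent oracle: enumerate the hypergeometric support directly
  fisher_oracle <- function(tb) {
    m <- tb[1, 1] + tb[1, 2]; n <- tb[2, 1] + tb[2, 2]; k <- tb[1, 1] + tb[2, 1]
    if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p0 <- dhyper(tb[1, 1], m, n, k)
    sum(probs[probs <= p0 * (1 + 1e-7)])
  }
  expect_equal(fisher_filter(list(matrix(c(5, 5, 5, 5), 2, 2)))$p, 1)
  expect_equal(fisher_filter(list(matrix(c(10, 0, 0, 10), 2, 2)))$p,
               1.082e-5, tolerance = 1e-3)
  expect_equal(fisher_filter(list(matrix(c(0, 0, 3, 4), 2, 2,
                                         byrow = TRUE)))$p, 1)
  set.seed(17)
  tables <- replicate(40, matrix(rpois(4, 6), 2, 2), simplify = FALSE)
  got <- fisher_filter(tables)$p
  want <- vapply(tables, fisher_oracle, numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(fisher_filter(list(matrix(c(-1, 0, 1, 2), 2, 2))),
               "non-negative")
})

test_that("duplex notation matches the published correspondences and is a bijection", {
  expect_equal(substitution_to_duplex("G", "C"), "rG:dG")
  expect_equal(substitution_to_duplex("G", "T"), "rG:dA")
  expect_equal(substitution_to_duplex("A", "A"), "rA:dT")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(from = bases, to = bases, stringsAsFactors = FALSE)
  dup <- substitution_to_duplex(grid$from, grid$to)
  expect_length(unique(dup), 16L)
  back <- duplex_to_substitution(dup)
  expect_equal(back$from, grid$from)
  expect_equal(back$to, grid$to)
  expect_error(substitution_to_duplex("G", "N"), "A, C, G, T")
})

test_that("zone partition thresholds and merges positions", {
  zp0 <- zone_partition(rep(0, 20), tau = 0.1)
  expect_equal(nrow(zp0), 1L)
  expect_equal(zp0$label, "undetermined")
  zp <- zone_partition(c(rep(1, 3), rep(0, 12), rep(-1, 5)), tau = 0.5)
  expect_equal(zp$start, c(1L, 4L, 16L))
  expect_equal(zp$end, c(3L, 15L, 20L))
  expect_equal(zp$label, c("preference", "undetermined", "avoiding"))
  # ranges always partition 1-20
  set.seed(18)
  for (i in 1:25) {
    z <- zone_partition(rnorm(20))
    expect_equal(z$start[1], 1L)
    expect_equal(z$end[nrow(z)], 20L)
    if (nrow(z) > 1) {
      expect_equal(z$start[-1], head(z$end, -1) + 1L)
    }
    expect_true(all(z$label %in% c("preference", "undetermined", "avoiding")))
  }
})

test_that("substitution count tables tally presence by detection status", {
  rec <- data.frame(
    mismatch_profile = c("16:G>C", "16:G>C;2:A>T", "", "3:C>G"),
    detected = c(1L, 0L, 1L, 0L), stringsAsFactors = FALSE)
  ct <- substitution_detection_tables(rec)
  expect_equal(dim(ct), c(20L, 16L, 4L))
  expect_equal(ct[16, "G>C", "with_det"], 1L)
  expect_equal(ct[16, "G>C", "with_undet"], 1L)
  expect_equal(ct[16, "G>C", "without_det"], 1L)
  expect_equal(ct[16, "G>C", "without_undet"], 1L)
  expect_equal(ct[3, "C>G", "with_det"], 0L)
  expect_equal(ct[3, "C>G", "with_undet"], 1L)
  # masking renders non-significant cells as hyphens
  ff <- fisher_filter(ct)
  masked <- mask_nonsignificant(matrix(1.5, 20, 16), ff$significant)
  expect_true(all(masked[ff$significant == FALSE] == "-"))
})

test_that("substitution effect map has the 20 x 16 shape with zero diagonal", {
  sim <- offtarget_fixture()
  cfg <- network_config(task = "classification", epochs = 1, seed = 3)
  fit <- train_offtarget(NULL, sim$x_guide[1:500, , ], sim$x_site[1:500, , ],
                         sim$records$detected[1:500], cfg)
  smap <- substitution_effect_map(fit, sim$x_guide[1:60, , ],
                                  sim$x_site[1:60, , ])
  expect_equal(dim(smap$effect), c(20L, 16L))
  diag_cells <- paste0(c("A", "C", "G", "T"), ">", c("A", "C", "G", "T"))
  expect_true(all(smap$effect[, diag_cells] == 0))
  expect_length(smap$avg, 20L)
  expect_error(substitution_effect_map(fit, sim$x_guide[0, , , drop = FALSE],
                                       sim$x_site[0, , , drop = FALSE]),
               "empty")
})
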