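test_that("sample proportions count correctly and rows sum to one", {
  cells <- data.frame(cell_id = paste0("c", 1:6),
                      sample = c(rep("s1", 4), "s2", "s2"),
                      cluster = c("A", "A", "B", "C", "A", "A"))
  pr <- sample_cluster_proportions(cells)
  expect_equal(pr$props["s1", c("A", "B", "C")], c(A = 0.5, B = 0.25, C = 0.25))
  expect_equal(pr$props["s2", ], c(A = 1, B = 0, C = 0))
  expect_equal(unname(rowSums(pr$props)), c(1, 1))
  expect_equal(pr$n_cells, c(s1 = 4, s2 = 2))
})

test_that("samples without labelled cells are dropped with a warning", {
  cells <- data.frame(cell_id = paste0("c", 1:3),
                      sample = c("s1", "s1", "s2"),
                      cluster = c("A", "B", NA))
  expect_warning(pr <- sample_cluster_proportions(cells), "s2")
  expect_equal(rownames(pr$props), "s1")
})

test_that("arcsin-sqrt transform hits its fixed points and bijects", {
  expect_equal(arcsin_sqrt(0), 0)
  expect_equal(arcsin_sqrt(1), pi / 2)
  expect_equal(arcsin_sqrt(0.25), pi / 6)
  p <- seq(0, 1, by = 0.01)
  y <- arcsin_sqrt(p)
  expect_true(all(diff(y) > 0))
  expect_equal(sin(y)^2, p)
  expect_error(arcsin_sqrt(1.01), "0, 1")
})

test_that("equal variances squeeze to infinite prior df and a common value", {
  sq <- squeeze_variances(rep(2.5, 6), df = 8)
  expect_identical(sq$d0, Inf)
  expect_equal(sq$s2_post, rep(sq$s0_sq, 6))
  # the common value is the bias-corrected log-scale mean, near 2.5
  expect_equal(sq$s0_sq, exp(log(2.5) - digamma(4) + log(4)))
})

test_that("posterior variances interpolate between prior and observed", {
  set.seed(12)
  s2 <- exp(rnorm(50, 0, 1))
  sq <- squeeze_variances(s2, df = 6)
  expect_true(all(sq$s2_post > pmin(s2, sq$s0_sq) - 1e-12))
  expect_true(all(sq$s2_post < pmax(s2, sq$s0_sq) + 1e-12))
  # d0 -> 0 limit contract: the blend collapses to the observed variance
  blend <- function(d0) (d0 * sq$s0_sq + 6 * s2) / (d0 + 6)
  expect_equal(blend(1e-10), s2, tolerance = 1e-9)
})

test_that("variance squeezing agrees with the established moderation oracle", {
  skip_if_not_installed("limma")
  set.seed(77)
  for (df in c(4, 10)) {
    s2 <- 2 * stats::rf(300, df1 = df, df2 = 5)
    got <- squeeze_variances(s2, df)
    ref <- limma::squeezeVar(s2, df)
    expect_equal(got$d0, ref$df.prior, tolerance = 1e-6)
    expect_equal(got$s0_sq, ref$var.prior, tolerance = 1e-6)
    expect_equal(got$s2_post, ref$var.post, tolerance = 1e-6)
  }
})

test_that("squeezing recovers planted prior parameters", {
  set.seed(501)
  d0_hat <- s0_hat <- numeric(50)
  for (r in 1:50) {
    s2 <- 2 * stats::rf(2000, df1 = 10, df2 = 4)  # s0^2 = 2, d0 = 4
    sq <- squeeze_variances(s2, df = 10)
    d0_hat[r] <- sq$d0; s0_hat[r] <- sq$s0_sq
  }
  expect_lt(abs(mean(d0_hat) - 4) / 4, 0.2)
  expect_lt(abs(mean(s0_hat) - 2) / 2, 0.2)
})

test_that("squeezing validates input", {
  expect_error(squeeze_variances(c(1, -1), 5), "positive")
  expect_error(squeeze_variances(c(1, Inf), 5), "finite")
})

test_that("identical groups give zero statistics and p = 1", {
  props <- matrix(c(0.3, 0.3, 0.3, 0.3, 0.7, 0.7, 0.7, 0.7), 4, 2,
                  dimnames = list(paste0("s", 1:4), c("A", "B")))
  res <- suppressWarnings(
    moderated_test(props, c("x", "x", "y", "y")))
  expect_equal(res$statistic, c(0, 0))
  expect_equal(res$p, c(1, 1))
})

test_that("a condition with fewer than two samples is an error", {
  props <- matrix(runif(6), 3, 2, dimnames = list(paste0("s", 1:3), c("A", "B")))
  props <- props / rowSums(props)
  expect_error(moderated_test(props, c("x", "x", "y")), "y")
})

test_that("with moderation disabled the test equals the classical t-test", {
  set.seed(31)
  for (rep in 1:20) {
    props <- matrix(rgamma(8 * 4, 2), 8, 4)
    props <- props / rowSums(props)
    dimnames(props) <- list(paste0("s", 1:8), paste0("C", 1:4))
    cond <- rep(c("a", "b"), each = 4)
    res <- moderated_test(props, cond, prior_df = 0)
    for (k in 1:4) {
      y <- asin(sqrt(props[, k]))
      tt <- stats::t.test(y[cond == "b"], y[cond == "a"], var.equal = TRUE)
      expect_equal(unname(res$statistic[k]), unname(tt$statistic),
                   tolerance = 1e-10)
      expect_equal(res$p[k], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("results are invariant to cluster and sample ordering", {
  set.seed(8)
  props <- matrix(rgamma(10 * 5, 2), 10, 5)
  props <- props / rowSums(props)
  dimnames(props) <- list(paste0("s", 1:10), paste0("C", 1:5))
  cond <- setNames(rep(c("a", "b"), 5), rownames(props))
  base <- moderated_test(props, cond)
  perm_c <- sample(5); perm_s <- sample(10)
  shuf <- moderated_test(props[perm_s, perm_c], cond)
  expect_equal(shuf[match(base$cluster, shuf$cluster), "p"], base$p)
})

test_that("more than two groups yield a moderated F with sane p-values", {
  set.seed(91)
  props <- matrix(rgamma(12 * 4, 2), 12, 4)
  props <- props / rowSums(props)
  dimnames(props) <- list(paste0("s", 1:12), paste0("C", 1:4))
  res <- moderated_test(props, rep(c("a", "b", "c"), each = 4))
  expect_true(all(res$statistic >= 0))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(c("mean_a", "mean_b", "mean_c", "prop_a") %in% names(res)))
})

test_that("a planted composition shift is detected with the smallest q", {
  cfg_hits <- 0L
  for (seed in 1:10) {
    cfg <- sc_sim_config(
      n_studies = 2, n_samples_per_study = 10, n_clusters = 6,
      n_genes = 30, cells_per_sample = c(200, 300), markers_per_cluster = 0,
      marker_log2fc = 0, batch_sd = 0,
      condition_effects = list(ctrl = c(), case = c(C3 = 1.5)), seed = seed)
    sim <- simulate_sc_atlas(cfg)
    pr <- sample_cluster_proportions(sim$cells)
    res <- moderated_test(pr$props, sim$truth$sample_condition[rownames(pr$props)])
    if (res$cluster[which.min(res$q)] == "C3") cfg_hits <- cfg_hits + 1L
  }
  expect_gte(cfg_hits, 9L)
})

test_that("BH adjustment matches step-up arithmetic and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(66)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    q <- bh_adjust(p)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])        # permutation invariance
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))         # monotone in p
    expect_true(all(q >= p - 1e-15 & q <= 1))
  }
  q <- bh_adjust(c(0.01, NaN, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_adjust(c(0.01, 0.04)))  # NaN excluded from n
})
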