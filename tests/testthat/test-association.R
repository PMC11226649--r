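test_that("per-sample aggregation of cell scores is the sample mean", {
  cells <- data.frame(cell_id = paste0("c", 1:4),
                      sample = c("s1", "s1", "s2", "s2"))
  sc <- setNames(c(0, 1, 1, 1), paste0("c", 1:4))
  out <- sample_signature_score(sc, cells)
  expect_equal(out, c(s1 = 0.5, s2 = 1))

  const <- setNames(rep(0.3, 4), paste0("c", 1:4))
  expect_equal(unname(sample_signature_score(const, cells)), c(0.3, 0.3))
})

test_that("bulk-mode scoring gives 1 when signature genes top the profile", {
  prof <- toy_expr(c(9, 8, 7, 1, 2, 3), 1, 6, cells = "s1")
  out <- sample_signature_score(prof, mode = "bulk",
                                sig = c("g01", "g02", "g03"))
  expect_equal(unname(out), 1)
})

test_that("quartile split matches interpolation quantiles with ties to middle", {
  sc <- setNames(as.numeric(1:8), paste0("s", 1:8))
  qs <- quartile_split(sc)
  expect_setequal(qs$sample[qs$stratum == "lower"], c("s1", "s2"))
  expect_setequal(qs$sample[qs$stratum == "upper"], c("s7", "s8"))
  # shift invariance
  qs2 <- quartile_split(sc + 100)
  expect_identical(qs$stratum, qs2$stratum)
  # all-tied scores leave both extreme strata empty
  expect_warning(qe <- quartile_split(setNames(rep(1, 6), 1:6)), "tie")
  expect_true(all(qe$stratum == "middle"))
  expect_error(quartile_split(setNames(1:3, 1:3)), ">= 4 samples")
})

test_that("Mann-Whitney anchors: separation, symmetry, rank-sum reporting", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$W, 6)            # ranks 1+2+3
  same <- mann_whitney_u(c(5, 7, 9), c(9, 5, 7))
  expect_equal(same$U, 3 * 3 / 2)   # identical multisets: U = n1*n2/2
  expect_equal(same$p, 1)
})

test_that("exact two-sided p equals the enumeration oracle (wilcox.test)", {
  # untied case is exact in both implementations
  got <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  ref <- stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p, ref$p.value)
  expect_equal(got$method, "exact enumeration")

  set.seed(40)
  for (i in 1:30) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    got <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation stays within 0.02 of exact enumeration", {
  set.seed(41)
  for (i in 1:40) {
    x <- rnorm(6); y <- rnorm(6)
    exact <- mann_whitney_u(x, y)$p
    # force the approximation path by inflating beyond the exact cutoff
    approx <- mann_whitney_u(c(x, rnorm(0)), y)  # n = 12 -> exact
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    r <- rank(c(x, y)); u <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
    sigma <- sqrt(n1 * n2 * (n + 1) / 12)
    papprox <- min(1, 2 * pnorm(-(abs(u - n1 * n2 / 2) - 0.5) / sigma))
    expect_lt(abs(papprox - exact), 0.02)
  }
})

test_that("large-sample p-values match the reference implementation with ties", {
  set.seed(42)
  x <- sample(1:8, 20, replace = TRUE)
  y <- sample(2:9, 25, replace = TRUE)
  got <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$method, "normal approximation")
})

test_that("Spearman co-occurrence detects monotone coupling", {
  set.seed(5)
  a <- runif(10)
  props <- cbind(A = a, B = a^2 + 1e-3, C = runif(10))
  props <- props / rowSums(props)
  rownames(props) <- paste0("s", 1:10)
  # renormalization breaks perfect monotonicity; test on the raw columns
  raw <- cbind(A = a, B = sqrt(a), C = runif(10))
  rownames(raw) <- paste0("s", 1:10)
  rho <- spearman_cooccurrence(raw)
  expect_equal(rho["A", "B"], 1)
  expect_equal(unname(diag(rho)), rep(1, 3))
  expect_equal(rho, t(rho))
})

test_that("Spearman matches explicit rank arithmetic on a 4-sample toy", {
  props <- cbind(A = c(0.1, 0.4, 0.2, 0.3), B = c(0.5, 0.1, 0.3, 0.1))
  rownames(props) <- paste0("s", 1:4)
  rho <- spearman_cooccurrence(cbind(props, C = 1 - rowSums(props)))
  want <- stats::cor(rank(props[, "A"]), rank(props[, "B"]))
  expect_equal(rho["A", "B"], want)
})

test_that("zero-variance clusters warn and give NA correlations", {
  props <- cbind(A = c(0.2, 0.3, 0.4), B = c(0.5, 0.5, 0.5))
  rownames(props) <- paste0("s", 1:3)
  expect_warning(rho <- spearman_cooccurrence(cbind(props, C = 1 - rowSums(props))),
                 "zero-variance")
  expect_true(is.na(rho["A", "B"]))
  expect_equal(rho["B", "B"], 1)
})

test_that("PCoA reproduces Euclidean configurations", {
  set.seed(17)
  pts <- matrix(rnorm(24), 12, 2)
  rownames(pts) <- paste0("s", 1:12)
  emb <- pcoa(as.matrix(dist(pts)), n_axes = 2)
  expect_lt(max(abs(dist(emb$points) - dist(pts))), 1e-8)
  expect_true(all(emb$eig > -1e-8 * max(emb$eig)))

  two <- pcoa(matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b"))),
              n_axes = 1)
  expect_equal(sort(as.numeric(two$points)), c(-1.5, 1.5))
})

test_that("PCoA agrees with the classical MDS oracle", {
  set.seed(18)
  pts <- matrix(rnorm(30), 10, 3)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:10)
  emb <- pcoa(d, n_axes = 2)
  ref <- stats::cmdscale(d, k = 2, eig = TRUE)
  expect_equal(abs(emb$points), abs(ref$points), ignore_attr = TRUE,
               tolerance = 1e-8)  # up to per-axis reflection
  expect_equal(emb$eig[1:2], ref$eig[1:2], tolerance = 1e-8)
})

test_that("cluster-mean dendrogram follows forced geometry", {
  m <- rbind(toy_expr(0, 4, 3), toy_expr(0, 4, 3))
  cells <- data.frame(cell_id = sprintf("c%02d", 1:8),
                      cluster = rep(c("A", "B", "C", "D"), 2))
  rownames(m) <- cells$cell_id
  m[cells$cluster == "B", ] <- 1
  m[cells$cluster == "C", ] <- 10
  m[cells$cluster == "D", ] <- 1      # D identical to B
  hc <- hierarchical_cluster_means(m, cells)
  expect_equal(min(hc$height), 0)     # identical clusters merge at height 0
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("B", "D"))
})

test_that("merge sequence matches a brute-force complete-linkage oracle", {
  set.seed(6)
  m <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("c%02d", 1:20), sprintf("g%d", 1:6)))
  cells <- data.frame(cell_id = rownames(m),
                      cluster = rep(c("A", "B", "C", "D", "E"), 4))
  hc <- hierarchical_cluster_means(m, cells)
  means <- t(sapply(sort(unique(cells$cluster)), function(k)
    colMeans(m[cells$cluster == k, , drop = FALSE])))
  oracle <- oracle_complete_linkage(as.matrix(dist(means)))
  expect_equal(sort(hc$height),
               sort(sapply(oracle, `[[`, "height")), tolerance = 1e-10)
})

test_that("marker percentile membership is pure for an exclusive marker", {
  set.seed(2)
  n <- 60
  cells <- data.frame(cell_id = sprintf("c%02d", 1:n),
                      cluster = rep(c("A", "B", "C"), each = n / 3))
  m <- matrix(0, n, 2, dimnames = list(cells$cell_id, c("mk", "other")))
  m[cells$cluster == "B", "mk"] <- runif(n / 3, 0.5, 3)
  pm <- suppressWarnings(marker_percentile_membership(m, cells, "mk", n_bins = 10))
  expect_true(all(pm[, "B"] == 1))
  expect_equal(unname(rowSums(pm)), rep(1, nrow(pm)))
})

test_that("strictly ordered clusters split cleanly across bins", {
  n <- 40
  cells <- data.frame(cell_id = sprintf("c%02d", 1:n),
                      cluster = rep(c("lo", "hi"), each = n / 2))
  m <- matrix(0, n, 1, dimnames = list(cells$cell_id, "mk"))
  m[cells$cluster == "lo", 1] <- seq(0.1, 1, length.out = n / 2)
  m[cells$cluster == "hi", 1] <- seq(5, 6, length.out = n / 2)
  pm <- marker_percentile_membership(m, cells, "mk", n_bins = 4)
  expect_equal(unname(pm[1:2, "lo"]), c(1, 1))
  expect_equal(unname(pm[3:4, "hi"]), c(1, 1))
})

test_that("20-cell toy bins match direct enumeration and pooling invariant", {
  cells <- data.frame(cell_id = sprintf("c%02d", 1:20),
                      cluster = rep(c("A", "B"), 10))
  expr_v <- c(5, 1, 4, 2, 3, 6, 0, 7, 8, 1.5, 2.5, 0, 9, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5, 9.5)
  m <- matrix(expr_v, 20, 1, dimnames = list(cells$cell_id, "mk"))
  pm <- marker_percentile_membership(m, cells, "mk", n_bins = 3)
  # 18 positive cells into 3 equal-count bins of 6 by increasing expression
  pos <- cells$cluster[expr_v > 0][order(expr_v[expr_v > 0])]
  want <- t(sapply(split(pos, rep(1:3, each = 6)), function(g)
    table(factor(g, levels = c("A", "B"))) / 6))
  expect_equal(unclass(pm), unclass(want), ignore_attr = TRUE)
  # pooled composition equals the composition of all positive cells
  pooled <- colSums(pm * 6) / 18
  expect_equal(pooled, table(factor(pos, levels = c("A", "B"))) / 18,
               ignore_attr = TRUE)
})

test_that("unexpressed markers and unknown genes raise errors", {
  cells <- data.frame(cell_id = c("c1", "c2"), cluster = c("A", "B"))
  m <- matrix(0, 2, 1, dimnames = list(cells$cell_id, "mk"))
  expect_error(marker_percentile_membership(m, cells, "mk"), "unexpressed")
  expect_error(marker_percentile_membership(m, cells, "zz"), "not in matrix")
})
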