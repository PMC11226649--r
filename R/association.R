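# Quartile-stratified comparisons, rank tests, cluster co-occurrence,
# ordination, cluster-mean dendrograms, and marker-percentile membership.

#' Per-sample signature score
#'
#' Two aggregation modes: `"cell_mean"` averages per-cell scores over a
#' designated cell population within each sample (e.g. the mean
#' neoantigen-reactivity module score over CD8 T cells); `"bulk"` applies the
#' rank-based scorer to each sample's expression profile treated as a single
#' cell.
#'
#' @param x For `cell_mean`: named per-cell score vector. For `bulk`:
#'   samples x genes expression matrix.
#' @param cells For `cell_mean`: data.frame with `cell_id` and `sample`,
#'   already restricted to the designated population.
#' @param mode `"cell_mean"` or `"bulk"`.
#' @param sig For `bulk` mode, the signature to score.
#' @param r_max Rank cap for `bulk` mode; defaults to the number of genes so
#'   a whole-profile ranking is used.
#' @return Named numeric vector of per-sample scores.
#' @export
sample_signature_score <- function(x, cells = NULL,
                                   mode = c("cell_mean", "bulk"),
                                   sig = NULL, r_max = NULL) {
  mode <- match.arg(mode)
  if (mode == "cell_mean") {
    smp <- cells$sample[match(names(x), cells$cell_id)]
    drop <- is.na(smp)
    if (all(drop)) stopf("no scored cells belong to `cells`")
    if (any(drop)) {
      warnf("%d scored cells not in the designated population; dropped", sum(drop))
      x <- x[!drop]; smp <- smp[!drop]
    }
    m <- tapply(x, smp, mean)
    return(stats::setNames(as.numeric(m), names(m)))
  }
  stopifnot(!is.null(sig))
  x <- as_dense_expr(x)
  if (is.null(r_max)) r_max <- ncol(x)
  rank_cell_scores(x, sig, r_max = r_max)
}

#' Quartile split of sample scores
#'
#' Thresholds are the 25th and 75th percentiles (linear-interpolation
#' quantiles). Samples strictly below the lower threshold form the lower
#' stratum and strictly above the upper threshold the upper stratum; ties at
#' a threshold go to the middle. Invariant to adding a constant to all
#' scores.
#'
#' @param sample_scores Named numeric vector (>= 4 samples).
#' @return Data.frame (sample, score, stratum in {lower, middle, upper}).
#' @export
quartile_split <- function(sample_scores) {
  if (length(sample_scores) < 4) stopf("need >= 4 samples for a quartile split")
  qs <- stats::quantile(sample_scores, c(0.25, 0.75), names = FALSE)
  stratum <- rep("middle", length(sample_scores))
  stratum[sample_scores < qs[1]] <- "lower"
  stratum[sample_scores > qs[2]] <- "upper"
  if (!any(stratum == "lower") && !any(stratum == "upper"))
    warnf("all scores tie; lower and upper strata are empty")
  data.frame(sample = names(sample_scores) %||% seq_along(sample_scores),
             score = as.numeric(sample_scores), stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test
#'
#' U is computed from pooled ranks with average-rank tie handling; `W` is
#' reported as the rank-sum statistic of the first sample. The p-value uses
#' exact enumeration of all group labellings when `n1 + n2 <= 12` (two-sided
#' via the symmetry of the permutation null around `n1*n2/2`), otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @return List with `U`, `W`, `p` and `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2

  if (n <= 12) {
    combs <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mid) >= abs(u - mid) - 1e-12),
      greater   = mean(u_all >= u - 1e-12),
      less      = mean(u_all <= u + 1e-12))
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
    if (sigma == 0) return(list(U = u, W = w, p = 1, method = "degenerate"))
    cc <- 0.5
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-(abs(u - mid) - cc) / sigma),
      greater   = stats::pnorm((u - mid - cc) / sigma, lower.tail = FALSE),
      less      = stats::pnorm((u - mid + cc) / sigma))
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(U = u, W = w, p = p, method = method)
}

#' Cluster co-occurrence by Spearman correlation
#'
#' Pairwise Spearman's rho between cluster fractions across samples.
#' Zero-variance clusters give `NA` rows/columns with a warning; the
#' diagonal is always 1.
#'
#' @param props Samples x clusters fraction matrix (or
#'   [sample_cluster_proportions()] output).
#' @return Symmetric clusters x clusters correlation matrix.
#' @export
spearman_cooccurrence <- function(props) {
  if (is.list(props) && !is.null(props$props)) props <- props$props
  props <- as.matrix(props)
  if (nrow(props) < 3) stopf("need >= 3 samples")
  sds <- apply(props, 2L, stats::sd)
  if (any(sds == 0))
    warnf("zero-variance cluster(s): %s",
          paste(colnames(props)[sds == 0], collapse = ", "))
  rho <- suppressWarnings(stats::cor(props, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centres `-0.5 * D^2`, eigendecomposes, and embeds on the top
#' positive eigenvalues as eigenvector * sqrt(eigenvalue). Negative
#' eigenvalues are reported but never embedded.
#'
#' @param d Distance matrix (symmetric, zero diagonal) or `dist` object.
#' @param n_axes Number of axes requested (capped at the number of positive
#'   eigenvalues).
#' @return List with `points` (samples x axes) and `eig` (all eigenvalues,
#'   descending).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stopf("distance matrix must be symmetric")
  b <- -0.5 * d^2
  # two successive sweeps give B = A - rowmean - colmean + grandmean
  b <- sweep(b, 1L, rowMeans(b))
  b <- sweep(b, 2L, colMeans(b))
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(eg$values > 1e-8 * max(abs(eg$values)))
  if (length(pos) == 0) stopf("no positive eigenvalues; nothing to embed")
  k <- min(n_axes, length(pos))
  pts <- eg$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(eg$values[pos[seq_len(k)]]), k)
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eig = eg$values)
}

#' Hierarchical clustering of cluster mean-expression profiles
#'
#' Mean log-normalized expression per cluster, Euclidean distances and
#' agglomerative clustering. Rows are ordered by cluster label before
#' clustering so merges are deterministic under label-order tie-breaking.
#'
#' @param expr Cells x genes log-normalized matrix.
#' @param cells Data.frame with `cell_id` and `cluster`.
#' @param linkage Agglomeration method (default `"complete"`; also
#'   `"average"`, `"ward.D2"`, ...).
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster_means <- function(expr, cells, linkage = "complete") {
  expr <- as_dense_expr(expr)
  cl <- cells$cluster[match(rownames(expr), cells$cell_id)]
  if (anyNA(cl)) stopf("all expr rows must have a cluster annotation")
  labs <- sort(unique(cl))
  if (length(labs) < 2) stopf("need >= 2 clusters")
  means <- t(vapply(labs, function(k) colMeans(expr[cl == k, , drop = FALSE]),
                    numeric(ncol(expr))))
  rownames(means) <- labs
  stats::hclust(stats::dist(means, method = "euclidean"), method = linkage)
}

#' Cluster membership along expression percentiles of a marker gene
#'
#' Cells positively expressing the marker are ordered by expression and
#' partitioned into `n_bins` equal-count bins (cells tied in expression stay
#' together in the lower bin); within each bin, cluster-membership fractions
#' are reported. Answers "which clusters do the top-percentile expressors of
#' this marker belong to".
#'
#' @param expr Cells x genes matrix (log-normalized layer).
#' @param cells Data.frame with `cell_id` and `cluster`.
#' @param gene Marker gene symbol (must be expressed in >= 1 cell).
#' @param n_bins Number of percentile bins (default 100; reduced with a
#'   warning when fewer positive cells exist).
#' @return Matrix bins x clusters of fractions (rows sum to 1), with bin 1
#'   the lowest-expression bin.
#' @export
marker_percentile_membership <- function(expr, cells, gene, n_bins = 100) {
  expr <- as_dense_expr(expr)
  if (!gene %in% colnames(expr)) stopf("gene '%s' not in matrix", gene)
  v <- expr[, gene]
  pos <- v > 0
  if (!any(pos)) stopf("gene '%s' is unexpressed everywhere", gene)
  cl <- cells$cluster[match(rownames(expr), cells$cell_id)]
  v <- v[pos]; cl <- cl[pos]
  n <- length(v)
  if (n < n_bins) {
    warnf("only %d positive cells; reducing to %d bins", n, n)
    n_bins <- n
  }
  ord <- order(v)
  vv <- v[ord]
  bin <- ceiling(seq_len(n) * n_bins / n)
  bin <- stats::ave(bin, vv, FUN = min)  # ties stay together in the lower bin
  labs <- sort(unique(cl))
  tab <- table(factor(bin, levels = seq_len(n_bins)),
               factor(cl[ord], levels = labs))
  out <- sweep(unclass(tab), 1L, pmax(rowSums(tab), 1), `/`)
  out[rowSums(tab) > 0, , drop = FALSE]
}
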