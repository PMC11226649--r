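# Differential cluster-composition testing: arcsin-sqrt transformed
# proportions, empirical-Bayes variance moderation, moderated t/F tests,
# and BH FDR control.

#' Per-sample cluster proportions
#'
#' @param cells Data.frame with `cell_id`, `sample` and `cluster`. Cells with
#'   missing cluster labels are ignored; samples left with zero labelled
#'   cells are dropped with a warning.
#' @return List with `props` (samples x clusters matrix of fractions, rows
#'   summing to 1) and `n_cells` (named vector of labelled cells per sample).
#' @export
sample_cluster_proportions <- function(cells) {
  keep <- !is.na(cells$cluster) & nzchar(cells$cluster)
  dropped_samples <- setdiff(unique(cells$sample), unique(cells$sample[keep]))
  if (length(dropped_samples))
    warnf("samples with no labelled cells dropped: %s",
          paste(dropped_samples, collapse = ", "))
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0) stopf("no labelled cells")
  tab <- table(cells$sample, cells$cluster)
  n_cells <- rowSums(tab)
  props <- sweep(unclass(tab), 1L, n_cells, `/`)
  list(props = props, n_cells = stats::setNames(as.numeric(n_cells), rownames(tab)))
}

#' Arcsin-square-root transform
#'
#' Variance-stabilizing transform for proportions: `asin(sqrt(p))`, a strictly
#' increasing bijection from \[0, 1\] to \[0, pi/2\].
#'
#' @param p Numeric proportions in \[0, 1\] (tolerance 1e-12).
#' @export
arcsin_sqrt <- function(p) {
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE))
    stopf("proportions must lie in [0, 1]")
  asin(sqrt(pmin(pmax(p, 0), 1)))
}

#' Empirical-Bayes variance squeezing
#'
#' Fits a scaled-F prior to a set of residual variances by moment matching on
#' `e_g = log(s_g^2) - digamma(df/2) + log(df/2)`: the prior degrees of
#' freedom `d0` solve `trigamma(d0/2) = max(0, var(e) - mean(trigamma(df/2)))`
#' (monotone Newton inversion of the trigamma function), and the prior
#' variance `s0^2` comes from `mean(e) + digamma(d0/2) - log(d0/2)`. When the
#' spread of the observed log-variances is no larger than expected under a
#' common variance, `d0 = Inf` and every posterior variance equals
#' `s0^2 = exp(mean(e))`. Otherwise posterior variances are the precision-
#' weighted blend `(d0*s0^2 + df*s_g^2) / (d0 + df)`.
#'
#' @param s2 Positive residual variances (one per cluster or gene).
#' @param df Residual degrees of freedom (scalar or vector).
#' @return List with `d0` (prior df, possibly `Inf`), `s0_sq` (prior
#'   variance) and `s2_post` (posterior variances, same length as `s2`).
#' @export
squeeze_variances <- function(s2, df) {
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stopf("all variances must be finite and positive")
  n <- length(s2)
  df <- rep_len(df, n)
  if (any(df <= 0)) stopf("residual df must be positive")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  if (n == 1L) {
    s0 <- exp(e)
    return(list(d0 = Inf, s0_sq = s0, s2_post = rep(s0, n)))
  }
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar <= 0) {
    s0 <- exp(mean(e))
    return(list(d0 = Inf, s0_sq = s0, s2_post = rep(s0, n)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0, s2_post = (d0 * s0 + df * s2) / (d0 + df))
}

# Monotone Newton inversion of trigamma (decreasing, convex on (0, Inf)).
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Moderated test for cluster-composition differences
#'
#' Per cluster, arcsin-sqrt transformed proportions are regressed on the
#' condition factor (ordinary least squares on group means); residual
#' variances are moderated jointly across clusters via
#' [squeeze_variances()]. With two conditions the statistic is a moderated t
#' with `d0 + df_res` degrees of freedom (two-sided); with more it is a
#' moderated F with `(k - 1, d0 + df_res)` degrees of freedom.
#' Benjamini-Hochberg q-values are computed across clusters.
#'
#' @param props Samples x clusters matrix of fractions (or the list returned
#'   by [sample_cluster_proportions()]).
#' @param condition Condition labels, named by sample or aligned to the rows
#'   of `props`. Every condition needs at least two samples.
#' @param prior_df Optional override of the estimated prior df; `0` disables
#'   moderation (classical t/F).
#' @return Data.frame: cluster, statistic, df_prior, df_residual, p, q, and
#'   one `mean_<condition>` column per condition on the transformed scale
#'   plus `prop_<condition>` on the raw fraction scale.
#' @export
moderated_test <- function(props, condition, prior_df = NULL) {
  if (is.list(props) && !is.null(props$props)) props <- props$props
  props <- as.matrix(props)
  if (!is.null(names(condition)) && !is.null(rownames(props))) {
    if (!all(rownames(props) %in% names(condition)))
      stopf("condition labels missing for some samples")
    condition <- condition[rownames(props)]
  }
  condition <- factor(condition)
  k <- nlevels(condition)
  if (k < 2) stopf("need >=2 conditions")
  small <- table(condition) < 2
  if (any(small))
    stopf("condition(s) with fewer than 2 samples: %s",
          paste(names(small)[small], collapse = ", "))
  n <- nrow(props)
  df_res <- n - k
  if (df_res < 1) stopf("no residual degrees of freedom")

  y <- arcsin_sqrt(props)
  gm <- apply(y, 2L, function(col) tapply(col, condition, mean))   # k x clusters
  fitted <- gm[condition, , drop = FALSE]
  res <- y - fitted
  s2 <- colSums(res^2) / df_res
  # guard exact-zero residual variance (degenerate all-equal input)
  s2 <- pmax(s2, 1e-300)

  if (!is.null(prior_df)) {
    d0 <- prior_df
    if (is.finite(d0) && d0 == 0) {
      s2_post <- s2; s0 <- NA_real_
    } else {
      sq <- squeeze_variances(s2, df_res)
      s0 <- sq$s0_sq
      s2_post <- if (is.finite(d0)) (d0 * s0 + df_res * s2) / (d0 + df_res) else rep(s0, length(s2))
    }
  } else {
    sq <- squeeze_variances(s2, df_res)
    d0 <- sq$d0; s0 <- sq$s0_sq; s2_post <- sq$s2_post
  }
  df_total <- if (is.finite(d0)) d0 + df_res else Inf

  n_per <- as.numeric(table(condition))
  if (k == 2) {
    delta <- gm[2L, ] - gm[1L, ]
    se <- sqrt(s2_post * (1 / n_per[1] + 1 / n_per[2]))
    statistic <- ifelse(se > 0, delta / se, 0)
    p <- 2 * stats::pt(-abs(statistic), df = df_total)
    p[delta == 0] <- 1
  } else {
    ssb <- apply(y, 2L, function(col) {
      m <- tapply(col, condition, mean)
      sum(as.numeric(table(condition)) * (m - mean(col))^2)
    })
    statistic <- (ssb / (k - 1)) / s2_post
    p <- stats::pf(statistic, df1 = k - 1, df2 = df_total, lower.tail = FALSE)
    p[ssb == 0] <- 1
  }
  q <- bh_adjust(p)

  out <- data.frame(cluster = colnames(props), statistic = statistic,
                    df_prior = d0, df_residual = df_res, s0_sq = s0,
                    p = p, q = q, stringsAsFactors = FALSE, row.names = NULL)
  for (lev in levels(condition)) {
    out[[paste0("mean_", lev)]] <- gm[lev, ]
    out[[paste0("prop_", lev)]] <- colMeans(props[condition == lev, , drop = FALSE])
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH q-values. `NA`/`NaN` p-values propagate and are excluded from
#' the family size.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}
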