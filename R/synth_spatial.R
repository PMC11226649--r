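# Synthetic spatial point patterns with co-located cell-type niches and
# per-cell expression profiles, for testing threshold assignment and
# neighbourhood composition.

#' Configuration for the spatial simulator
#'
#' Cells are placed uniformly: background cells over the whole arena at
#' `background_density`, plus circular niches each with its own cell count
#' and cell-type mixture. Expression per cell is its type's mean profile
#' times log-normal noise.
#'
#' @param width,height Arena dimensions in micrometres.
#' @param niches List of niches, each a list with `center` (length-2 numeric),
#'   `radius` (> 0), `n_cells` (int) and `mixture` (named numeric summing
#'   to 1 over cell types). Overlapping niches are allowed.
#' @param background_density Background cells per square micrometre (may be 0
#'   if niches supply cells).
#' @param background_mixture Named cell-type mixture for background cells.
#' @param celltype_profiles Named list: cell type -> named numeric vector of
#'   mean expression per gene. All types used must have a profile.
#' @param noise_sd SD of the log-normal expression noise.
#' @param seed Integer seed.
#' @export
spatial_sim_config <- function(width = 1000, height = 1000, niches = list(),
                               background_density = 0,
                               background_mixture = NULL,
                               celltype_profiles = list(), noise_sd = 0.3,
                               seed = 1L) {
  stopifnot(width > 0, height > 0, background_density >= 0, noise_sd >= 0)
  for (ni in niches) {
    stopifnot(length(ni$center) == 2, ni$radius > 0, ni$n_cells >= 0)
    if (abs(sum(ni$mixture) - 1) > 1e-8)
      stopf("niche mixture must sum to 1")
  }
  if (background_density > 0 && is.null(background_mixture))
    stopf("background_mixture required when background_density > 0")
  if (!is.null(background_mixture) && abs(sum(background_mixture) - 1) > 1e-8)
    stopf("background_mixture must sum to 1")
  types <- unique(c(unlist(lapply(niches, function(n) names(n$mixture))),
                    names(background_mixture)))
  missing <- setdiff(types, names(celltype_profiles))
  if (length(missing))
    stopf("celltype_profiles missing for: %s", paste(missing, collapse = ", "))
  structure(list(width = width, height = height, niches = niches,
                 background_density = background_density,
                 background_mixture = background_mixture,
                 celltype_profiles = celltype_profiles,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "spatial_sim_config")
}

#' Simulate a spatial cell table
#'
#' @param config A [spatial_sim_config()].
#' @return List with `cells` (data.frame: cell_id, x, y, celltype) and
#'   `expr` (dense cells x genes expression matrix).
#' @export
simulate_spatial <- function(config) {
  stopifnot(inherits(config, "spatial_sim_config"))
  c0 <- config
  local_seed(c0$seed, {
    xs <- ys <- numeric(0); ct <- character(0)
    n_bg <- stats::rpois(1L, c0$background_density * c0$width * c0$height)
    if (n_bg > 0) {
      xs <- stats::runif(n_bg, 0, c0$width)
      ys <- stats::runif(n_bg, 0, c0$height)
      ct <- sample(names(c0$background_mixture), n_bg, replace = TRUE,
                   prob = c0$background_mixture)
    }
    for (ni in c0$niches) {
      if (ni$n_cells == 0) next
      r <- ni$radius * sqrt(stats::runif(ni$n_cells))  # uniform in disk
      th <- stats::runif(ni$n_cells, 0, 2 * pi)
      xs <- c(xs, ni$center[1] + r * cos(th))
      ys <- c(ys, ni$center[2] + r * sin(th))
      ct <- c(ct, sample(names(ni$mixture), ni$n_cells, replace = TRUE,
                         prob = ni$mixture))
    }
    if (length(xs) == 0L) stopf("configuration produced zero cells")

    gene_names <- unique(unlist(lapply(c0$celltype_profiles, names)))
    profiles <- matrix(0, length(c0$celltype_profiles), length(gene_names),
                       dimnames = list(names(c0$celltype_profiles), gene_names))
    for (tp in names(c0$celltype_profiles)) {
      pr <- c0$celltype_profiles[[tp]]
      profiles[tp, names(pr)] <- pr
    }
    expr <- profiles[ct, , drop = FALSE] *
      matrix(exp(stats::rnorm(length(xs) * length(gene_names), 0, c0$noise_sd)),
             nrow = length(xs))
    ids <- sprintf("spot%06d", seq_along(xs))
    rownames(expr) <- ids
    list(cells = data.frame(cell_id = ids, x = xs, y = ys, celltype = ct,
                            stringsAsFactors = FALSE),
         expr = expr)
  })
}
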