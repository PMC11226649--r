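# Synthetic bulk RNA-seq cohort with a binary response label, a cancer-type
# covariate, and signature-linked expression shifts in responders.

#' Configuration for the bulk cohort simulator
#'
#' Emulates an immunotherapy cohort: negative-binomial counts, per-gene
#' relative abundances, mild cancer-type baseline offsets, and responder
#' samples whose signature genes shift by a configured log2 fold change.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes (universe `gene0001..`).
#' @param cancer_types Character vector of cancer-type labels; samples are
#'   assigned round-robin.
#' @param response_rate Fraction of responders, in (0, 1); responders are
#'   balanced within cancer type to avoid confounding by construction.
#' @param signatures Named list of character gene vectors (or
#'   [gene_signature] objects) whose genes receive responder effects.
#' @param signature_effect_log2fc Named numeric: signature -> log2 fold
#'   change of its genes' mean in responders (may be empty).
#' @param library_size_mean Mean library size (counts per sample).
#' @param nb_dispersion Negative-binomial dispersion.
#' @param seed Integer seed.
#' @export
bulk_sim_config <- function(n_samples = 100, n_genes = 2000,
                            cancer_types = c("bladder", "lung", "melanoma"),
                            response_rate = 0.35,
                            signatures = list(),
                            signature_effect_log2fc = numeric(0),
                            library_size_mean = 2e5, nb_dispersion = 0.2,
                            seed = 1L) {
  stopifnot(n_samples >= 4, n_genes >= 10, length(cancer_types) >= 1,
            response_rate > 0, response_rate < 1,
            all(is.finite(signature_effect_log2fc)),
            library_size_mean > 0, nb_dispersion > 0)
  signatures <- lapply(signatures, sig_genes)
  universe <- sprintf("gene%04d", seq_len(n_genes))
  unknown <- setdiff(unique(unlist(signatures)), universe)
  if (length(unknown))
    stopf("signature genes absent from the simulated universe: %s",
          paste(utils::head(unknown, 10), collapse = ", "))
  eff_names <- names(signature_effect_log2fc)
  if (length(signature_effect_log2fc) && !all(eff_names %in% names(signatures)))
    stopf("signature_effect_log2fc names signatures without gene lists: %s",
          paste(setdiff(eff_names, names(signatures)), collapse = ", "))
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes), cancer_types = cancer_types,
                 response_rate = response_rate, signatures = signatures,
                 signature_effect_log2fc = signature_effect_log2fc,
                 library_size_mean = library_size_mean,
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Simulate a bulk responder/non-responder cohort
#'
#' @param config A [bulk_sim_config()].
#' @return List with `counts` (dense samples x genes integer matrix) and
#'   `samples` (data.frame: sample, response in {R, NR}, cancer_type).
#' @export
simulate_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "bulk_sim_config"))
  c0 <- config
  local_seed(c0$seed, {
    genes <- sprintf("gene%04d", seq_len(c0$n_genes))
    samples <- sprintf("sample%04d", seq_len(c0$n_samples))
    ctype <- rep(c0$cancer_types, length.out = c0$n_samples)

    # balanced responder assignment within each cancer type
    response <- rep("NR", c0$n_samples)
    for (tp in unique(ctype)) {
      idx <- which(ctype == tp)
      n_r <- round(length(idx) * c0$response_rate)
      response[sample(idx, n_r)] <- "R"
    }

    rel <- exp(stats::rnorm(c0$n_genes, 0, 0.7))          # gene abundance
    rel <- rel / sum(rel)
    type_off <- matrix(exp(stats::rnorm(length(c0$cancer_types) * c0$n_genes,
                                        0, 0.1)),
                       nrow = length(c0$cancer_types),
                       dimnames = list(c0$cancer_types, genes))
    lib <- c0$library_size_mean * exp(stats::rnorm(c0$n_samples, 0, 0.3))

    effect <- rep(1, c0$n_genes); names(effect) <- genes
    for (sg in names(c0$signature_effect_log2fc)) {
      gs <- c0$signatures[[sg]]
      effect[gs] <- effect[gs] * 2^c0$signature_effect_log2fc[[sg]]
    }

    counts <- matrix(0L, c0$n_samples, c0$n_genes,
                     dimnames = list(samples, genes))
    for (i in seq_len(c0$n_samples)) {
      mu <- lib[i] * rel * type_off[ctype[i], ]
      if (response[i] == "R") mu <- mu * effect
      counts[i, ] <- stats::rnbinom(c0$n_genes, mu = mu,
                                    size = 1 / c0$nb_dispersion)
    }
    list(counts = counts,
         samples = data.frame(sample = samples, response = response,
                              cancer_type = ctype, stringsAsFactors = FALSE))
  })
}
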