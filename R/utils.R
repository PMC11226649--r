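# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' perturb an enclosing simulation stream.
#' @noRd
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Dense cells x genes matrix from whatever the caller supplied.
as_dense_expr <- function(x) {
  if (methods::is(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) stop("expression input must be a matrix", call. = FALSE)
  x
}

# Sparse dgC coercion that accepts base matrices as well as Matrix classes.
as_sparse <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Resolve a signature's genes against the columns of an expression matrix.
# Policy: error when no gene or fewer than half of the signature is present;
# otherwise drop the missing genes with a warning stating the fraction kept.
match_signature_genes <- function(genes, universe, sig_name = "signature",
                                  min_frac = 0.5) {
  genes <- unique(genes)
  present <- genes[genes %in% universe]
  if (length(present) == 0L)
    stopf("none of the %d genes of %s are present in the matrix",
          length(genes), sig_name)
  frac <- length(present) / length(genes)
  if (frac < min_frac)
    stopf("only %.0f%% of %s genes are present (< 50%%)", 100 * frac, sig_name)
  if (frac < 1)
    warnf("%s: %d/%d genes present in matrix; missing genes dropped",
          sig_name, length(present), length(genes))
  present
}
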