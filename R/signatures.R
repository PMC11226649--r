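#' Construct a gene signature
#'
#' A signature is a named, ordered gene list, optionally tied to the cluster
#' it was derived from (its "own" cluster), which the specificity metrics use
#' as the expected best hit.
#'
#' @param name Signature name (single string).
#' @param genes Character vector of gene symbols (order preserved; duplicates
#'   dropped with a warning).
#' @param own_cluster Optional cluster label the signature describes.
#' @return An object of class `gene_signature`: a list with elements `name`,
#'   `genes`, `own_cluster`.
#' @examples
#' sig <- gene_signature("ECMMac", c("COL1A1", "COL1A2", "COL3A1"))
#' @export
gene_signature <- function(name, genes, own_cluster = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) == 0L) stopf("signature '%s' has an empty gene list", name)
  if (anyDuplicated(genes)) {
    warnf("signature '%s': duplicated genes removed", name)
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes, own_cluster = own_cluster),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes%s\n", x$name, length(x$genes),
              if (is.null(x$own_cluster)) "" else
                sprintf(" (own cluster: %s)", x$own_cluster)))
  invisible(x)
}

sig_genes <- function(sig) if (inherits(sig, "gene_signature")) sig$genes else as.character(sig)
sig_name <- function(sig, default = "signature") {
  if (inherits(sig, "gene_signature")) sig$name else default
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Gene order is preserved. Duplicate genes within a line are removed with a
#' warning; duplicate signature names or empty gene lists are errors.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_signature] objects.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("GMT file is empty: %s", path)
  sigs <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stopf("malformed GMT line (need name, description, >=1 gene): %s",
            substr(ln, 1, 60))
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stopf("signature '%s' has an empty gene list", parts[1L])
    gene_signature(parts[1L], genes)
  })
  nm <- vapply(sigs, function(s) s$name, character(1L))
  if (anyDuplicated(nm))
    stopf("duplicate signature names in GMT: %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sigs) <- nm
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param sigs List of [gene_signature] objects (or named list of character
#'   vectors).
#' @param path Output path.
#' @export
write_signatures <- function(sigs, path) {
  if (is.null(names(sigs))) names(sigs) <- vapply(sigs, sig_name, character(1L))
  lines <- vapply(seq_along(sigs), function(i) {
    paste(c(names(sigs)[i], "na", sig_genes(sigs[[i]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
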