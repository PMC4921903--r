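#' Build a connectivity matrix from a regulon network and expression data
#'
#' Restricts the regulon network to genes present in the expression matrix
#' and assembles the binary connectivity matrix X (genes x TFs) plus the
#' parallel sign matrix. TFs left with no surviving target are excluded and
#' reported (never silently dropped). Genes and TFs are ordered
#' lexicographically so the result — and any downstream fit — is invariant
#' to the row order of the inputs.
#'
#' @param network a [regulon_network()].
#' @param expr an [expression_timecourse()].
#' @return An object of class `"connectivity_matrix"`: list with `X` (0/1
#'   matrix, genes x TFs), `sign` (+1/-1/`NA` matrix), `genes`, `tfs`, and
#'   `dropped_tfs` (TF ids with no target in the expression matrix).
#' @export
build_connectivity <- function(network, expr) {
  stopifnot(inherits(network, "regulon_network"),
            inherits(expr, "expression_timecourse"))
  edges <- network$edges
  keep <- edges$gene %in% expr$genes
  if (!any(keep))
    stop("no regulon target genes are present in the expression matrix")
  surviving <- edges[keep, , drop = FALSE]
  dropped <- setdiff(network$tf_ids, unique(surviving$tf))
  if (length(dropped))
    message("dropping TF(s) with no target in the expression matrix: ",
            paste(dropped, collapse = ", "))
  genes <- sort(unique(surviving$gene))
  tfs <- sort(unique(surviving$tf))
  X <- matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
  S <- matrix(NA_integer_, length(genes), length(tfs), dimnames = list(genes, tfs))
  gi <- match(surviving$gene, genes); ti <- match(surviving$tf, tfs)
  X[cbind(gi, ti)] <- 1
  S[cbind(gi, ti)] <- surviving$sign
  structure(list(X = X, sign = S, genes = genes, tfs = tfs,
                 dropped_tfs = dropped),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("Connectivity matrix:", length(x$genes), "genes x", length(x$tfs), "TFs,",
      sum(x$X), "edges\n")
  if (length(x$dropped_tfs))
    cat("  dropped TFs (no targets in expression matrix):",
        paste(x$dropped_tfs, collapse = ", "), "\n")
  invisible(x)
}
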