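#' Classify per-gene regulation by fold-change thresholds
#'
#' Applies the conventional fold-ratio rule to each gene at each
#' post-treatment timepoint: a gene is called "up" when its linear ratio to
#' the minute-0 baseline is at least `up_threshold` (default 2-fold) and
#' "down" when the ratio is at most `down_threshold` (default 0.5, i.e. at or
#' below half the control transcript level). Both boundaries are inclusive.
#' Missing measurements propagate as "missing" calls, never as "unchanged".
#'
#' @param expr an [expression_timecourse()] of log2 ratios to baseline.
#' @param up_threshold linear-ratio threshold for upregulation (>= 1).
#' @param down_threshold linear-ratio threshold for downregulation (<= 1).
#' @return An object of class `"regulation_calls"`: list with `genes`,
#'   `time` (non-baseline timepoints), `calls` (character matrix with values
#'   `"up"`, `"down"`, `"unchanged"`, `"missing"`), `ratio` (linear fold
#'   ratios) and the thresholds used.
#' @export
classify_regulation <- function(expr, up_threshold = 2.0, down_threshold = 0.5) {
  stopifnot(inherits(expr, "expression_timecourse"))
  if (!(down_threshold <= 1 && 1 <= up_threshold))
    stop("thresholds must satisfy down_threshold <= 1 <= up_threshold")
  keep <- expr$time > 0
  if (!any(keep))
    stop("no non-baseline timepoints to classify")
  ratio <- 2^expr$values[, keep, drop = FALSE]
  calls <- matrix("unchanged", nrow(ratio), ncol(ratio), dimnames = dimnames(ratio))
  calls[!is.na(ratio) & ratio >= up_threshold] <- "up"
  calls[!is.na(ratio) & ratio <= down_threshold] <- "down"
  calls[is.na(ratio)] <- "missing"
  structure(list(genes = expr$genes, time = expr$time[keep], calls = calls,
                 ratio = ratio, up_threshold = up_threshold,
                 down_threshold = down_threshold, condition = expr$condition),
            class = "regulation_calls")
}

#' @export
print.regulation_calls <- function(x, ...) {
  cat("Regulation calls (ratio >=", x$up_threshold, "up, <=", x$down_threshold,
      "down):", length(x$genes), "genes x", length(x$time), "timepoints\n")
  tab <- apply(x$calls, 2, function(col) table(factor(col, c("up", "down", "unchanged", "missing"))))
  colnames(tab) <- paste0(x$time, "min")
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.regulation_calls <- function(x, ...) {
  data.frame(gene = rep(x$genes, times = length(x$time)),
             minute = rep(x$time, each = length(x$genes)),
             ratio = as.vector(x$ratio),
             call = as.vector(x$calls),
             stringsAsFactors = FALSE)
}

#' Fraction of genes changed at a timepoint
#'
#' The proportion of genes called up- or downregulated at one timepoint,
#' relative to the genes with a non-missing measurement there (genes absent
#' from the array at that timepoint do not enter the denominator).
#'
#' @param calls a [classify_regulation()] result.
#' @param timepoint timepoint in minutes; must exist in `calls`.
#' @return Proportion in `[0, 1]`.
#' @export
fraction_changed <- function(calls, timepoint) {
  stopifnot(inherits(calls, "regulation_calls"))
  j <- match(timepoint, calls$time)
  if (is.na(j))
    stop("timepoint ", timepoint, " not in calls (available: ",
         paste(calls$time, collapse = ", "), ")")
  col <- calls$calls[, j]
  n <- sum(col != "missing")
  if (n == 0L) stop("all genes missing at timepoint ", timepoint)
  sum(col %in% c("up", "down")) / n
}

#' Per-category up/down percentages
#'
#' For each functional category, the percentage of its genes (among those
#' present in the expression matrix) called up and down at one timepoint.
#' Genes absent from the map count as `"unclassified"`. Up and down are
#' reported separately and need not sum to 100.
#'
#' @param calls a [classify_regulation()] result.
#' @param categories named character vector mapping gene id -> category
#'   (see [read_category_map()]).
#' @param timepoint timepoint in minutes.
#' @return data frame with columns `category`, `n_genes`, `n_up`, `n_down`,
#'   `percent_up`, `percent_down`; categories with no genes in the matrix
#'   are reported with `n_genes = 0` and zero percentages.
#' @export
category_summary <- function(calls, categories, timepoint) {
  stopifnot(inherits(calls, "regulation_calls"))
  j <- match(timepoint, calls$time)
  if (is.na(j)) stop("timepoint ", timepoint, " not in calls")
  cat_of <- categories[calls$genes]
  cat_of[is.na(cat_of)] <- "unclassified"
  all_cats <- sort(unique(c(unname(categories), cat_of)))
  col <- calls$calls[, j]
  res <- lapply(all_cats, function(cc) {
    sel <- cat_of == cc
    n <- sum(sel)
    n_up <- sum(col[sel] == "up"); n_dn <- sum(col[sel] == "down")
    data.frame(category = cc, n_genes = n, n_up = n_up, n_down = n_dn,
               percent_up = if (n) 100 * n_up / n else 0,
               percent_down = if (n) 100 * n_dn / n else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-gene time strips
#'
#' Extracts, for each requested gene, the ordered log2 values across the
#' post-treatment sampling points (e.g. 2.5 ... 80 min) — the vertical-strip
#' representation used for heat-scale figures. Requested genes absent from
#' the matrix are reported in the `not_found` attribute, never dropped
#' silently.
#'
#' @param expr an [expression_timecourse()].
#' @param gene_list character vector of gene ids.
#' @return Matrix (found genes x non-baseline timepoints) of log2 ratios,
#'   with attribute `not_found` listing missing gene ids.
#' @export
time_strip <- function(expr, gene_list) {
  stopifnot(inherits(expr, "expression_timecourse"))
  gene_list <- trimws(as.character(gene_list))
  keep <- expr$time > 0
  idx <- match(gene_list, expr$genes)
  not_found <- gene_list[is.na(idx)]
  found <- gene_list[!is.na(idx)]
  strips <- expr$values[idx[!is.na(idx)], keep, drop = FALSE]
  rownames(strips) <- found
  colnames(strips) <- format(expr$time[keep], trim = TRUE)
  attr(strips, "not_found") <- not_found
  strips
}
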