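#' Construct an expression time course
#'
#' A genes x timepoints matrix of log2 expression ratios relative to the
#' pre-treatment (minute 0) sample, with timepoint labels in minutes.
#'
#' @param values numeric matrix (genes x timepoints); `NA` marks missing
#'   measurements. Row names, if present, must agree with `gene_ids`.
#' @param gene_ids character vector of unique gene identifiers.
#' @param timepoints_min numeric vector of timepoints in minutes; stored in
#'   strictly ascending order (columns of `values` are permuted to match).
#' @param condition_label free-text condition label (e.g. `"aerobic"`).
#' @return An object of class `"expression_timecourse"` with elements
#'   `genes`, `time`, `values` and `condition`.
#' @export
expression_timecourse <- function(values, gene_ids = rownames(values),
                                  timepoints_min = as.numeric(colnames(values)),
                                  condition_label = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- trimws(as.character(gene_ids))
  timepoints_min <- as.numeric(timepoints_min)
  if (length(gene_ids) != nrow(values))
    stop("length of 'gene_ids' (", length(gene_ids), ") does not match rows of 'values' (",
         nrow(values), ")")
  if (length(timepoints_min) != ncol(values))
    stop("length of 'timepoints_min' does not match columns of 'values'")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicated gene ids: ", paste(dup, collapse = ", "))
  if (anyNA(timepoints_min))
    stop("timepoint labels must be numeric minutes")
  if (any(timepoints_min < 0))
    stop("timepoints must be non-negative minutes")
  if (anyDuplicated(timepoints_min))
    stop("duplicated timepoints: ",
         paste(unique(timepoints_min[duplicated(timepoints_min)]), collapse = ", "))
  ord <- order(timepoints_min)
  values <- values[, ord, drop = FALSE]
  timepoints_min <- timepoints_min[ord]
  dimnames(values) <- list(gene_ids, format(timepoints_min, trim = TRUE))
  structure(list(genes = gene_ids, time = timepoints_min, values = values,
                 condition = as.character(condition_label)[1],
                 has_baseline = timepoints_min[1] == 0),
            class = "expression_timecourse")
}

#' @export
print.expression_timecourse <- function(x, ...) {
  cat("Expression time course", if (nzchar(x$condition)) paste0("(", x$condition, ")"), "\n")
  cat("  ", length(x$genes), "genes x", length(x$time), "timepoints:",
      paste(x$time, collapse = ", "), "min\n")
  if (!x$has_baseline) cat("  no minute-0 baseline column\n")
  n_na <- sum(is.na(x$values))
  if (n_na) cat("  ", n_na, "missing cells\n")
  invisible(x)
}

#' Read an expression time-course table
#'
#' Expects delimited text whose first column holds gene identifiers and whose
#' remaining column headers are bare timepoints in minutes (e.g.
#' `gene  0  2.5  5  10  20  40  80`). Values are log2 ratios to the minute-0
#' sample. Columns are reordered to ascending time; empty cells or `NA` are
#' recorded as missing (never imputed).
#'
#' @param path file path.
#' @param condition_label condition label to attach (e.g. `"anoxic"`).
#' @param delim field delimiter; tab by default, use `","` for CSV.
#' @return An [expression_timecourse()] object.
#' @export
read_expression_table <- function(path, condition_label = "", delim = "\t") {
  raw <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                    colClasses = "character", comment.char = "#",
                    strip.white = TRUE, na.strings = c("NA", ""))
  if (ncol(raw) < 2)
    stop("expression table needs a gene-id column plus at least one timepoint column: ", path)
  gene_ids <- trimws(raw[[1]])
  tp <- suppressWarnings(as.numeric(colnames(raw)[-1]))
  if (anyNA(tp))
    stop("timepoint headers must be numeric minutes; offending headers: ",
         paste(colnames(raw)[-1][is.na(tp)], collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric expression value '", vals[bad[1, 1], bad[1, 2]], "' at row ",
         bad[1, 1], " (gene ", gene_ids[bad[1, 1]], "), column '",
         colnames(raw)[-1][bad[1, 2]], "' in ", path)
  expression_timecourse(num, gene_ids, tp, condition_label)
}

#' Construct a regulon network
#'
#' A set of TF -> target-gene edges with an optional regulatory sign.
#' Duplicate (tf, gene) pairs are collapsed; if duplicates disagree on sign
#' the edge is kept with unknown sign and a warning is raised.
#'
#' @param tf,gene character vectors of equal length.
#' @param sign integer vector: `+1` activation, `-1` repression, `NA` unknown.
#' @return An object of class `"regulon_network"`: a list with `edges`
#'   (data.frame `tf`, `gene`, `sign`), `tf_ids`, `gene_ids`.
#' @export
regulon_network <- function(tf, gene, sign = NA_integer_) {
  tf <- trimws(as.character(tf)); gene <- trimws(as.character(gene))
  if (length(tf) != length(gene)) stop("'tf' and 'gene' must have equal length")
  if (length(tf) == 0L) stop("regulon network has no edges")
  sign <- rep_len(as.integer(sign), length(tf))
  if (any(!is.na(sign) & !sign %in% c(-1L, 1L)))
    stop("sign must be +1, -1 or NA")
  key <- paste(tf, gene, sep = "\r")
  if (anyDuplicated(key)) {
    agg_sign <- vapply(split(sign, key), function(s) {
      u <- unique(s[!is.na(s)])
      if (length(u) == 1L && all(!is.na(s))) u else NA_integer_
    }, integer(1))
    conflicts <- vapply(split(sign, key),
                        function(s) length(unique(s[!is.na(s)])) > 1L, logical(1))
    if (any(conflicts)) {
      off <- sub("\r", " -> ", names(conflicts)[conflicts])
      warning("conflicting signs for edge(s) ", paste(off, collapse = ", "),
              "; kept with unknown sign")
    }
    first <- !duplicated(key)
    tf <- tf[first]; gene <- gene[first]
    sign <- unname(agg_sign[match(key[first], names(agg_sign))])
  }
  ord <- order(tf, gene)
  edges <- data.frame(tf = tf[ord], gene = gene[ord], sign = sign[ord],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, tf_ids = sort(unique(edges$tf)),
                 gene_ids = sort(unique(edges$gene))),
            class = "regulon_network")
}

#' @export
print.regulon_network <- function(x, ...) {
  cat("Regulon network:", nrow(x$edges), "edges,", length(x$tf_ids), "TFs,",
      length(x$gene_ids), "target genes\n")
  ns <- table(factor(x$edges$sign, levels = c(1, -1)), useNA = "always")
  cat("  signs: +", ns[[1]], " / -", ns[[2]], " / unknown ", ns[[3]], "\n", sep = "")
  invisible(x)
}

#' Read a regulon (TF -> target) table
#'
#' Expects delimited text with columns `tf`, `gene` and optionally `sign`
#' (`+`, `-` or `?`/empty for unknown), the conventional layout of
#' RegulonDB/EcoCyc regulon exports.
#'
#' @inheritParams read_expression_table
#' @return A [regulon_network()] object.
#' @export
read_regulon_table <- function(path, delim = "\t") {
  raw <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                    colClasses = "character", comment.char = "#",
                    strip.white = TRUE, na.strings = c("NA", ""))
  if (nrow(raw) == 0L) stop("regulon table is empty: ", path)
  if (ncol(raw) < 2L) stop("regulon table needs columns tf, gene[, sign]: ", path)
  sgn <- if (ncol(raw) >= 3L) {
    s <- trimws(raw[[3]])
    out <- rep(NA_integer_, length(s))
    out[!is.na(s) & s %in% c("+", "+1", "1")] <- 1L
    out[!is.na(s) & s %in% c("-", "-1", "−", "−1")] <- -1L
    bad <- !is.na(s) & !s %in% c("+", "+1", "1", "-", "-1", "−", "−1", "?")
    if (any(bad)) stop("unrecognised sign value(s): ",
                       paste(unique(s[bad]), collapse = ", "))
    out
  } else NA_integer_
  regulon_network(raw[[1]], raw[[2]], sgn)
}

#' Read a gene -> functional-category map
#'
#' Two-column delimited text (`gene`, `category`). Genes not listed are later
#' treated as `"unclassified"` by [category_summary()].
#'
#' @inheritParams read_expression_table
#' @return Named character vector: names are gene ids, values category names.
#' @export
read_category_map <- function(path, delim = "\t") {
  raw <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                    colClasses = "character", comment.char = "#",
                    strip.white = TRUE, na.strings = c("NA", ""))
  if (ncol(raw) < 2L) stop("category map needs columns gene, category: ", path)
  if (any(is.na(raw[[2]]) | !nzchar(raw[[2]]))) stop("empty category names in ", path)
  setNames(raw[[2]], trimws(raw[[1]]))
}

#' Write a pipeline table deterministically
#'
#' Writes a data frame (or any pipeline record type with an
#' `as.data.frame` method) as tab-separated text with a leading `#` comment
#' line recording the package version plus any provenance fields supplied.
#' Rows are sorted by the first (primary-key) column and numbers are printed
#' with a fixed 15-significant-digit format, so identical records always
#' produce byte-identical files.
#'
#' @param records a data frame or coercible record set.
#' @param path output file path.
#' @param provenance named list appended to the comment line (e.g.
#'   `list(seed = 1)`).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, provenance = list()) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(df) > 1L && ncol(df) >= 1L)
    df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.15g", df[[j]])
    if (is.logical(df[[j]])) df[[j]] <- ifelse(df[[j]], "TRUE", "FALSE")
  }
  meta <- c(list(tool = paste0("tfactivity ", as.character(packageVersion("tfactivity")))),
            provenance)
  header <- paste0("# ", paste(names(meta), unlist(lapply(meta, as.character)),
                               sep = "=", collapse = " "))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path, "' for writing"),
                  warning = function(w) stop("cannot open '", path, "' for writing"))
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path file path.
#' @return data frame with the comment line skipped and numeric columns
#'   restored.
#' @export
read_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}
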