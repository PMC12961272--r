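#' Expression matrix with two-group sample annotation
#'
#' Container for a log2-scale feature-by-sample expression matrix together
#' with a two-level group label per sample. Expression values are assumed to
#' be already normalized and log2-transformed (e.g. limma/DESeq2 output);
#' no preprocessing is performed here. Missing values are not supported.
#'
#' @param values Numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames). All values must be finite.
#' @param groups Character or factor vector of group labels, either named by
#'   sample id or in column order of `values`. At most two distinct labels;
#'   every operation downstream requires exactly two with >= 2 samples each.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `groups` (factor named by sample id, level
#'   order = order of first appearance).
#' @export
ExpressionMatrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    ml_stop_format("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    ml_stop_format("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    ml_stop_format("duplicated feature ids: %s",
                   paste(unique(rownames(values)[duplicated(rownames(values))]),
                         collapse = ", "))
  if (anyDuplicated(colnames(values)))
    ml_stop_format("duplicated sample ids: %s",
                   paste(unique(colnames(values)[duplicated(colnames(values))]),
                         collapse = ", "))
  if (!all(is.finite(values)))
    ml_stop_value("expression values must be finite (NA/NaN/Inf found)")
  g <- as.character(groups)
  if (is.null(names(groups)) || all(names(groups) == "")) {
    if (length(g) != ncol(values))
      ml_stop_consistency("length(groups) [%d] != number of samples [%d]",
                          length(g), ncol(values))
    names(g) <- colnames(values)
  } else {
    names(g) <- names(groups)
  }
  missing <- setdiff(colnames(values), names(g))
  if (length(missing))
    ml_stop_consistency("samples without a group label: %s",
                        paste(missing, collapse = ", "))
  g <- g[colnames(values)]
  lev <- unique(g)
  if (length(lev) > 2L)
    ml_stop_value("more than two group labels: %s", paste(lev, collapse = ", "))
  tab <- table(g)
  if (length(lev) == 2L && any(tab < 2L))
    ml_stop_value("each group needs >= 2 samples (got %s)",
                  paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  structure(list(values = values, groups = factor(g, levels = lev)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples; groups: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s (n=%d)", levels(x$groups),
                            tabulate(x$groups)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Accessors for ExpressionMatrix ids
#' @param x An [ExpressionMatrix].
#' @return Character vector of feature or sample ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids  <- function(x) colnames(x$values)

#' Read an expression matrix and its sample groups from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and the
#' feature id in the first column. The groups file has two columns,
#' `sample_id` and `group` (header required). Row and column order are
#' preserved.
#'
#' @param path Path to the expression TSV.
#' @param groups_path Path to the two-column sample/group TSV.
#' @return An [ExpressionMatrix].
#' @export
read_expression_matrix <- function(path, groups_path) {
  d <- read_tsv_checked(path, min_cols = 2L)
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m))
    ml_stop_format("non-numeric expression values in '%s'", path)
  rownames(m) <- ids
  g <- read_tsv_checked(groups_path, min_cols = 2L)
  grp <- as.character(g[[2L]])
  names(grp) <- as.character(g[[1L]])
  if (anyDuplicated(names(grp)))
    ml_stop_format("duplicated sample ids in groups file '%s'", groups_path)
  missing <- setdiff(colnames(m), names(grp))
  if (length(missing))
    ml_stop_consistency("samples in '%s' missing from groups file: %s",
                        path, paste(missing, collapse = ", "))
  ExpressionMatrix(m, grp[colnames(m)])
}

## Shared strict TSV reader: header required, no quoting surprises,
## empty file is a format error that names the path.
read_tsv_checked <- function(path, min_cols = 1L) {
  if (!file.exists(path)) ml_stop_format("file not found: '%s'", path)
  if (file.size(path) == 0L) ml_stop_format("empty file: '%s'", path)
  d <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = ""),
    error = function(e) ml_stop_format("cannot parse '%s': %s", path,
                                       conditionMessage(e)))
  if (nrow(d) == 0L) ml_stop_format("no data rows in '%s'", path)
  if (ncol(d) < min_cols)
    ml_stop_format("'%s' has %d column(s), need >= %d", path, ncol(d), min_cols)
  d
}

#' Construct a differential-expression table
#'
#' @param feature_id Character vector of unique feature ids.
#' @param log2fc Numeric log2 fold changes.
#' @param pvalue,padj Numeric, in \[0, 1\].
#' @return A `data.frame` of class `DETable` with columns `feature_id`,
#'   `log2fc`, `pvalue`, `padj` and `direction` (`sign(log2fc)`).
#' @export
DETable <- function(feature_id, log2fc, pvalue, padj) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id))
    ml_stop_format("duplicated feature ids: %s",
                   paste(unique(feature_id[duplicated(feature_id)]),
                         collapse = ", "))
  for (nm in c("log2fc", "pvalue", "padj")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != length(feature_id))
      ml_stop_format("'%s' must be numeric, same length as feature_id", nm)
    if (anyNA(v)) ml_stop_value("NA in '%s'", nm)
  }
  if (any(pvalue < 0 | pvalue > 1)) ml_stop_value("pvalue outside [0, 1]")
  if (any(padj < 0 | padj > 1)) ml_stop_value("padj outside [0, 1]")
  structure(data.frame(feature_id = feature_id, log2fc = log2fc,
                       pvalue = pvalue, padj = padj,
                       direction = sign(log2fc),
                       stringsAsFactors = FALSE),
            class = c("DETable", "data.frame"))
}

#' Read a differential-expression table from TSV
#'
#' Requires columns `feature_id`, `log2fc`, `pvalue`, `padj` (extra columns
#' are ignored). The `direction` column is recomputed as `sign(log2fc)`.
#'
#' @param path Path to the TSV file.
#' @return A [DETable].
#' @export
read_de_table <- function(path) {
  d <- read_tsv_checked(path)
  need <- c("feature_id", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(d))
  if (length(miss))
    ml_stop_format("'%s' lacks mandatory column(s): %s", path,
                   paste(miss, collapse = ", "))
  for (nm in c("log2fc", "pvalue", "padj"))
    if (!is.numeric(d[[nm]]))
      ml_stop_format("column '%s' in '%s' is not numeric", nm, path)
  DETable(d$feature_id, d$log2fc, d$pvalue, d$padj)
}

#' Construct a miRNA-to-target map
#'
#' Duplicate pairs are collapsed silently, with the number of duplicates
#' reported via `message()`. Id matching throughout the package is exact,
#' case-sensitive string match; no miRBase alias resolution is attempted.
#'
#' @param mirna_id,gene_id Character vectors of equal length; non-empty ids.
#' @return A `data.frame` of class `TargetMap` with columns `mirna_id` and
#'   `gene_id`, one row per unique pair.
#' @export
TargetMap <- function(mirna_id, gene_id) {
  mirna_id <- as.character(mirna_id)
  gene_id <- as.character(gene_id)
  if (length(mirna_id) != length(gene_id))
    ml_stop_format("mirna_id and gene_id lengths differ")
  if (any(!nzchar(mirna_id)) || any(!nzchar(gene_id)))
    ml_stop_format("empty ids in target map")
  dup <- duplicated(paste(mirna_id, gene_id, sep = "\r"))
  if (any(dup))
    message(sprintf("TargetMap: collapsed %d duplicate pair(s)", sum(dup)))
  structure(data.frame(mirna_id = mirna_id[!dup], gene_id = gene_id[!dup],
                       stringsAsFactors = FALSE),
            class = c("TargetMap", "data.frame"))
}

#' @rdname TargetMap
#' @param targets A `TargetMap`.
#' @param mirna,gene Single id to look up.
#' @export
targets_of <- function(targets, mirna) targets$gene_id[targets$mirna_id == mirna]

#' @rdname TargetMap
#' @export
mirnas_of <- function(targets, gene) targets$mirna_id[targets$gene_id == gene]

#' Read a miRNA-target map from a two-column TSV
#'
#' Columns: miRNA id, gene id (header required; extra columns ignored).
#'
#' @param path Path to the TSV file.
#' @return A [TargetMap].
#' @export
read_target_map <- function(path) {
  d <- read_tsv_checked(path, min_cols = 2L)
  TargetMap(d[[1L]], d[[2L]])
}

#' Read gene sets in GMT format
#'
#' Standard Broad GMT: one set per line, tab-separated fields
#' `name`, `description`, then member ids. Lines with fewer than three
#' fields are a format error.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of class `GeneSetCollection`,
#'   with a `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) ml_stop_format("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) ml_stop_format("empty file: '%s'", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    ml_stop_format("GMT line(s) with < 3 fields in '%s' (line %d)",
                   path, which(short)[1L])
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    ml_stop_format("duplicated set names in '%s'", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- nm
  structure(sets, descriptions = desc, class = "GeneSetCollection")
}

#' Write a result table to TSV
#'
#' Emits a header and fixed 6-decimal formatting for real-valued columns,
#' so a write/read round trip preserves values to 1e-6.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], format = "f", digits = 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
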