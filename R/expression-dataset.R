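#' Two-group expression dataset
#'
#' Container for a probes x samples matrix of continuous (normalized)
#' expression values together with a two-level group assignment of the
#' samples, e.g. nulliparous vs parous breast tissue donors. This is the
#' universal input of every analysis stage in the package.
#'
#' The first level of `groups` is treated as the reference group throughout
#' (all deltas, ratios and direction flags are "group 2 relative to
#' group 1").
#'
#' @param values numeric matrix, probes in rows, samples in columns. Row and
#'   column names are used as probe and sample identifiers; defaults are
#'   generated when absent.
#' @param groups factor (or vector coercible to one) of length
#'   `ncol(values)` with exactly two levels assigning each sample to a group.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `groups` (named factor), `probe_ids`, `sample_ids`.
#' @examples
#' m <- matrix(rnorm(40), nrow = 4)
#' ds <- expression_dataset(m, rep(c("nulliparous", "parous"), each = 5))
#' n_samples(ds)
#' @export
expression_dataset <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (probes x samples)")
  if (any(!is.finite(values)))
    stop("`values` must be finite throughout")
  if (length(groups) != ncol(values))
    stop("length(groups) must equal ncol(values)")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("`groups` must have exactly two levels, got ", nlevels(groups))
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("probe_%d", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe identifiers")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample_%d", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  names(groups) <- colnames(values)
  structure(
    list(values = values, groups = groups,
         probe_ids = rownames(values), sample_ids = colnames(values)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$groups)
  cat("<expression_dataset> ", nrow(x$values), " probes x ",
      ncol(x$values), " samples (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Number of samples per group
#'
#' @param ds an [expression_dataset()].
#' @return named integer vector of group sizes, in level order.
#' @export
n_samples <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  tab <- table(ds$groups)
  stats::setNames(as.integer(tab), names(tab))
}

#' Extract the sub-matrix of one group
#'
#' @param ds an [expression_dataset()].
#' @param group group level name, or 1/2 for the first/second level.
#' @return numeric matrix of the group's columns.
#' @export
group_values <- function(ds, group) {
  stopifnot(inherits(ds, "expression_dataset"))
  lv <- levels(ds$groups)
  if (is.numeric(group)) group <- lv[group]
  if (!group %in% lv) stop("unknown group: ", group)
  ds$values[, ds$groups == group, drop = FALSE]
}

#' Read an expression matrix and sample sheet from TSV
#'
#' Reads the canonical tabular interchange format: a tab-separated expression
#' matrix whose first column holds probe identifiers and whose header row
#' holds sample identifiers, plus a two-column sample sheet (`sample_id`,
#' `group`) assigning every sample to one of two groups.
#'
#' @param path path to the expression TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return an [expression_dataset()].
#' @seealso [write_expression_dataset()]
#' @export
read_expression_matrix <- function(path, sample_sheet_path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (!file.exists(sample_sheet_path))
    stop("sample sheet not found: ", sample_sheet_path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("expression matrix needs >= 2 sample columns")
  probe_ids <- as.character(tab[[1L]])
  if (anyDuplicated(probe_ids)) {
    dup <- probe_ids[duplicated(probe_ids)][1L]
    stop("duplicate probe id in ", path, ": ", dup)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                 !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("non-numeric cell at probe '%s', sample '%s'",
                   probe_ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    m <- array(as.numeric(m), dim(m), dimnames = dimnames(m))
  }
  rownames(m) <- probe_ids
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet must have columns 'sample_id' and 'group'")
  unknown <- setdiff(sheet$sample_id, colnames(m))
  if (length(unknown) > 0L)
    stop("sample sheet names a sample absent from the matrix: ",
         unknown[1L])
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing) > 0L)
    stop("sample without a group label: ", missing[1L])
  grp <- sheet$group[match(colnames(m), sheet$sample_id)]
  expression_dataset(m, grp)
}

#' Write an expression dataset as TSV
#'
#' Writes the expression matrix (first column `probe_id`, header of sample
#' identifiers) and the matching sample sheet, the inverse of
#' [read_expression_matrix()].
#'
#' @param ds an [expression_dataset()].
#' @param path output path for the expression TSV.
#' @param sample_sheet_path output path for the sample sheet TSV.
#' @return invisibly, `c(path, sample_sheet_path)`.
#' @export
write_expression_dataset <- function(ds, path, sample_sheet_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  tab <- data.frame(probe_id = ds$probe_ids, ds$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample_id = ds$sample_ids,
                      group = as.character(ds$groups),
                      stringsAsFactors = FALSE)
  utils::write.table(sheet, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, sample_sheet_path))
}
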