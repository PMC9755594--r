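#' Construct an expression dataset
#'
#' Bundles a genes-by-samples matrix of log2-scale expression values with a
#' two-group sample annotation. This is the container consumed by
#' [differential_expression()] and [screen_triplets()].
#'
#' @param values Numeric matrix of log2 expression, rows named by gene (or
#'   miRNA) id, columns named by sample id. All values must be finite and both
#'   dimnames unique.
#' @param groups Named character vector mapping every sample id in
#'   `colnames(values)` to one of exactly two group labels (e.g. `"IDD"` for
#'   degenerated and `"IDnD"` for control discs).
#' @param kind Either `"mrna"` or `"mirna"`; recorded so downstream stages can
#'   refuse mismatched inputs.
#' @param case The group label that plays the role of "case"; log2 fold
#'   changes are case minus control.
#'
#' @return An object of class `cerna_expression`: a list with elements
#'   `values`, `groups`, `kind` and `case`.
#' @export
expression_dataset <- function(values, groups, kind = c("mrna", "mirna"),
                               case = "IDD") {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    ct_stop("'values' must be a numeric matrix", class = "cerna_bad_input")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    ct_stop("expression matrix is empty", class = "cerna_bad_input")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    ct_stop("expression matrix needs row (gene) and column (sample) names",
            class = "cerna_bad_input")
  }
  if (anyDuplicated(gid)) {
    ct_stop("duplicate gene id: ", gid[duplicated(gid)][1L],
            class = "cerna_bad_input")
  }
  if (anyDuplicated(sid)) {
    ct_stop("duplicate sample id: ", sid[duplicated(sid)][1L],
            class = "cerna_bad_input")
  }
  if (!all(is.finite(values))) {
    ct_stop("expression matrix contains non-finite values",
            class = "cerna_bad_input")
  }
  if (is.null(names(groups))) {
    ct_stop("'groups' must be a named vector (sample id -> group)",
            class = "cerna_bad_input")
  }
  missing <- setdiff(sid, names(groups))
  if (length(missing)) {
    ct_stop("sample missing from group annotation: ", missing[1L],
            class = "cerna_bad_input")
  }
  groups <- as.character(groups[sid])
  names(groups) <- sid
  lev <- unique(groups)
  if (length(lev) != 2L) {
    ct_stop("expected exactly 2 groups, found ", length(lev),
            class = "cerna_bad_input")
  }
  if (!case %in% lev) {
    ct_stop("case label '", case, "' not present in groups",
            class = "cerna_bad_input")
  }
  structure(list(values = values, groups = groups, kind = kind, case = case),
            class = "cerna_expression")
}

#' @export
print.cerna_expression <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("<cerna_expression: %s> %d features x %d samples (%s)\n",
              x$kind, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  cat(sprintf("  case group: %s\n", x$case))
  invisible(x)
}

# sample ids of the case / control columns, in matrix column order
case_samples <- function(ds) names(ds$groups)[ds$groups == ds$case]
control_samples <- function(ds) names(ds$groups)[ds$groups != ds$case]
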