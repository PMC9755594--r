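#' Two-group differential expression on log2 expression
#'
#' Per-gene case-vs-control comparison on a log2-scale expression matrix:
#' the log2 fold change is the difference of group means (case minus
#' control) and the p-value comes from a two-sided Welch two-sample t-test.
#' Genes with zero variance in both groups get `p = 1` when the group means
#' are equal (no evidence, no signal) and `p = 0` when they differ (an
#' exact separation). A Benjamini-Hochberg adjusted column is carried along
#' for information; significance is always called on the raw p-value, as is
#' conventional for this screening chain.
#'
#' @param ds An [expression_dataset()] with at least 2 samples per group.
#' @param p_max,lfc_min Significance cutoffs applied by [filter_degs()]:
#'   a gene is significant iff `pvalue < p_max` and `|log2fc| > lfc_min`
#'   (both strict). Defaults 0.05 and 1.
#' @return A data frame of class `cerna_de` with columns `gene_id`,
#'   `log2fc`, `pvalue`, `padj_bh`, `significant`, `direction`
#'   (`"up"`/`"down"`/`"none"`), carrying the thresholds and the test name
#'   as attributes. Row order follows the expression matrix.
#' @export
differential_expression <- function(ds, p_max = 0.05, lfc_min = 1) {
  stopifnot(inherits(ds, "cerna_expression"))
  ci <- which(ds$groups == ds$case)
  ki <- which(ds$groups != ds$case)
  if (length(ci) < 2L || length(ki) < 2L) {
    ct_stop("each group needs >= 2 samples (case=", length(ci),
            ", control=", length(ki), ")", class = "cerna_bad_input")
  }
  x1 <- ds$values[, ci, drop = FALSE]
  x2 <- ds$values[, ki, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2

  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate & lfc == 0] <- 1
  p[degenerate & lfc != 0] <- 0

  tab <- data.frame(gene_id = rownames(ds$values), log2fc = unname(lfc),
                    pvalue = unname(p),
                    padj_bh = stats::p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  filter_degs(tab, p_max = p_max, lfc_min = lfc_min)
}

#' Apply significance cutoffs to a differential-expression table
#'
#' Recomputes the `significant` and `direction` flags of a DE table under
#' the given cutoffs. Inequalities are strict on both sides: a gene is
#' significant iff `pvalue < p_max` and `|log2fc| > lfc_min`, so `p` equal
#' to the cutoff or `|log2fc|` exactly at the fold-change bound never
#' passes.
#'
#' @param tab A `cerna_de` table or any data frame with `gene_id`, `log2fc`
#'   and `pvalue` columns.
#' @param p_max Raw p-value cutoff (strict), default 0.05.
#' @param lfc_min Absolute log2 fold-change bound (strict), default 1.
#' @return The table with `significant` and `direction` recomputed and the
#'   thresholds recorded as attributes `p_max` / `lfc_min`.
#' @export
filter_degs <- function(tab, p_max = 0.05, lfc_min = 1) {
  if (!all(c("gene_id", "log2fc", "pvalue") %in% names(tab))) {
    ct_stop("DE table needs columns gene_id, log2fc, pvalue",
            class = "cerna_bad_input")
  }
  if (!is.numeric(p_max) || p_max <= 0 || !is.numeric(lfc_min) || lfc_min <= 0) {
    ct_stop("thresholds must be > 0", class = "cerna_bad_input")
  }
  if (is.null(tab$padj_bh)) {
    tab$padj_bh <- stats::p.adjust(tab$pvalue, method = "BH")
  }
  sig <- tab$pvalue < p_max & abs(tab$log2fc) > lfc_min
  tab$significant <- sig
  tab$direction <- ifelse(sig & tab$log2fc > 0, "up",
                          ifelse(sig & tab$log2fc < 0, "down", "none"))
  attr(tab, "p_max") <- p_max
  attr(tab, "lfc_min") <- lfc_min
  class(tab) <- unique(c("cerna_de", class(tab)))
  tab
}

#' @export
print.cerna_de <- function(x, ...) {
  cat(sprintf(
    "<cerna_de> %d genes; %d significant (%d up, %d down) at p < %g, |log2FC| > %g\n",
    nrow(x), sum(x$significant), sum(x$direction == "up"),
    sum(x$direction == "down"), attr(x, "p_max"), attr(x, "lfc_min")))
  NextMethod()
}

#' Cross-dataset consensus of differentially expressed genes
#'
#' Intersection of the significant genes of two or more DE tables,
#' additionally requiring the same direction of change in every table
#' (the Venn step of the screening chain: only genes dysregulated the same
#' way in all cohorts are carried forward). Genes absent from any table are
#' excluded.
#'
#' @param tables List of two or more `cerna_de` tables (see
#'   [differential_expression()]) sharing a gene-id namespace.
#' @return A data frame of class `cerna_consensus` with columns `gene_id`
#'   and `direction`, sorted by gene id; the number of source tables is in
#'   attribute `n_sources`.
#' @export
consensus_degs <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L) {
    ct_stop("need at least 2 DE tables for a consensus",
            class = "cerna_bad_input")
  }
  sig <- lapply(tables, function(t) {
    if (!all(c("gene_id", "significant", "direction") %in% names(t))) {
      ct_stop("input is not a flagged DE table", class = "cerna_bad_input")
    }
    t[t$significant, c("gene_id", "direction"), drop = FALSE]
  })
  keys <- lapply(sig, function(s) paste(s$gene_id, s$direction, sep = "\t"))
  common <- Reduce(intersect, keys)
  parts <- strsplit(common, "\t", fixed = TRUE)
  out <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                    direction = vapply(parts, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  out <- out[ct_order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sources") <- length(tables)
  class(out) <- unique(c("cerna_consensus", class(out)))
  out
}

#' @export
print.cerna_consensus <- function(x, ...) {
  cat(sprintf("<cerna_consensus> %d genes shared by %d tables (%d up, %d down)\n",
              nrow(x), attr(x, "n_sources"), sum(x$direction == "up"),
              sum(x$direction == "down")))
  NextMethod()
}
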