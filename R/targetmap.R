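#' Construct a miRNA-to-mRNA target map
#'
#' A bipartite relation of predicted miRNA/mRNA targeting interactions (the
#' shape of a miRTarBase or starBase export), together with explicit
#' universes. The miRNA universe is the population size `N` of the
#' hypergeometric shared-miRNA test, so it may be wider than the miRNAs that
#' actually carry edges.
#'
#' @param edges Data frame with character columns `mirna_id` and `gene_id`
#'   (extra columns are dropped). Duplicate edges are removed.
#' @param mirna_universe,mrna_universe Character vectors of ids; default to
#'   the ids observed in `edges`. Must contain every edge endpoint.
#'
#' @return An object of class `cerna_target_map`: list with `edges` (sorted,
#'   deduplicated data frame), `mirna_universe`, `mrna_universe`.
#' @export
target_map <- function(edges, mirna_universe = NULL, mrna_universe = NULL) {
  if (!is.data.frame(edges) || !all(c("mirna_id", "gene_id") %in% names(edges))) {
    ct_stop("'edges' must be a data.frame with columns mirna_id, gene_id",
            class = "cerna_bad_input")
  }
  edges <- data.frame(mirna_id = as.character(edges$mirna_id),
                      gene_id = as.character(edges$gene_id),
                      stringsAsFactors = FALSE)
  if (anyNA(edges) || any(edges$mirna_id == "") || any(edges$gene_id == "")) {
    ct_stop("target map edges contain missing or empty ids",
            class = "cerna_bad_input")
  }
  edges <- edges[!duplicated(paste(edges$mirna_id, edges$gene_id, sep = "\t")), ,
                 drop = FALSE]
  edges <- edges[ct_order(edges$mirna_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(mirna_universe)) mirna_universe <- unique(edges$mirna_id)
  if (is.null(mrna_universe)) mrna_universe <- unique(edges$gene_id)
  mirna_universe <- ct_sort(unique(as.character(mirna_universe)))
  mrna_universe <- ct_sort(unique(as.character(mrna_universe)))
  if (!all(edges$mirna_id %in% mirna_universe)) {
    ct_stop("edge miRNA outside the miRNA universe", class = "cerna_bad_input")
  }
  if (!all(edges$gene_id %in% mrna_universe)) {
    ct_stop("edge mRNA outside the mRNA universe", class = "cerna_bad_input")
  }
  structure(list(edges = edges, mirna_universe = mirna_universe,
                 mrna_universe = mrna_universe),
            class = "cerna_target_map")
}

#' @export
print.cerna_target_map <- function(x, ...) {
  cat(sprintf("<cerna_target_map> %d edges, %d miRNAs x %d mRNAs in universe\n",
              nrow(x$edges), length(x$mirna_universe), length(x$mrna_universe)))
  invisible(x)
}

#' miRNAs targeting a given mRNA
#'
#' Inverse index of the targeting relation: the set of miRNAs with an edge
#' to `mrna`. An id absent from the map yields an empty set (with a
#' message), not an error, so callers can probe freely.
#'
#' @param map A [target_map()].
#' @param mrna A single mRNA id.
#' @return Character vector of miRNA ids (sorted; possibly empty).
#' @export
targets_of <- function(map, mrna) {
  stopifnot(inherits(map, "cerna_target_map"), length(mrna) == 1L)
  if (!mrna %in% map$mrna_universe) {
    message("targets_of: '", mrna, "' not in the mRNA universe")
  }
  ct_sort(map$edges$mirna_id[map$edges$gene_id == mrna])
}
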