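#' Construct a gene-set collection
#'
#' Holds named gene sets (GO-term-like or pathway-like) against a universe
#' of assayable genes. Set members outside the universe are clipped with a
#' message; sets left empty are dropped.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Character vector of gene ids; defaults to the union of
#'   all set members.
#' @param descriptions Optional named character vector of set descriptions.
#' @return Object of class `cerna_genesets`: list with `sets`,
#'   `descriptions`, `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    ct_stop("'sets' must be a named list", class = "cerna_bad_input")
  }
  if (anyDuplicated(names(sets))) {
    ct_stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1L],
            class = "cerna_bad_input")
  }
  sets <- lapply(sets, function(s) ct_sort(unique(as.character(s))))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- ct_sort(unique(as.character(universe)))
  clipped <- vapply(sets, function(s) sum(!s %in% universe), 0L)
  if (any(clipped > 0L)) {
    message("gene_set_collection: clipped ", sum(clipped),
            " member(s) outside the universe")
    sets <- lapply(sets, function(s) s[s %in% universe])
  }
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    message("gene_set_collection: dropped ", sum(empty), " empty set(s)")
    sets <- sets[!empty]
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
    descriptions[is.na(descriptions)] <- ""
    names(descriptions) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe),
            class = "cerna_genesets")
}

#' @export
print.cerna_genesets <- function(x, ...) {
  cat(sprintf("<cerna_genesets> %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set of a collection for over-representation in a query
#' gene list using the upper-tail hypergeometric probability
#' ([hypergeom_shared_pvalue()] with `k` = overlap, `K` = set size, `n` =
#' query size, `N` = universe size), with Benjamini-Hochberg adjustment
#' across the collection. Query genes outside the universe are dropped with
#' a message; an empty query after clipping is an error.
#'
#' @param query Character vector of gene ids (or a `cerna_consensus`
#'   table).
#' @param coll A [gene_set_collection()].
#' @param directions Optional named vector (gene id -> `"up"`/`"down"`)
#'   used to report per-set direction counts.
#' @return Data frame of class `cerna_enrichment`, one row per set, sorted
#'   by `pvalue` then set name: `set_name`, `description`, `k`, `K`, `n`,
#'   `N`, `pvalue`, `padj_bh`, `overlap` (comma-joined ids) and, when
#'   directions are supplied, `n_up`/`n_down`.
#' @export
ora_enrich <- function(query, coll, directions = NULL) {
  stopifnot(inherits(coll, "cerna_genesets"))
  if (inherits(query, "cerna_consensus")) {
    if (is.null(directions)) {
      directions <- stats::setNames(query$direction, query$gene_id)
    }
    query <- query$gene_id
  }
  query <- unique(as.character(query))
  outside <- setdiff(query, coll$universe)
  if (length(outside)) {
    message("ora_enrich: dropped ", length(outside),
            " query gene(s) outside the universe")
    query <- setdiff(query, outside)
  }
  if (length(query) == 0L) {
    ct_stop("empty query after clipping to the universe",
            class = "cerna_bad_input")
  }
  N <- length(coll$universe)
  n <- length(query)
  rows <- lapply(names(coll$sets), function(nm) {
    s <- coll$sets[[nm]]
    ov <- ct_sort(intersect(query, s))
    data.frame(set_name = nm, description = unname(coll$descriptions[nm]),
               k = length(ov), K = length(s), n = n, N = N,
               pvalue = hypergeom_shared_pvalue(length(ov), length(s), n, N),
               overlap = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj_bh <- stats::p.adjust(out$pvalue, method = "BH")
  if (!is.null(directions)) {
    ovl <- strsplit(out$overlap, ",", fixed = TRUE)
    out$n_up <- vapply(ovl, function(g) sum(directions[g] == "up",
                                            na.rm = TRUE), 0L)
    out$n_down <- vapply(ovl, function(g) sum(directions[g] == "down",
                                              na.rm = TRUE), 0L)
  }
  out <- out[ct_order(out$pvalue, out$set_name), , drop = FALSE]
  cols <- c("set_name", "description", "k", "K", "n", "N", "pvalue",
            "padj_bh", "overlap",
            intersect(c("n_up", "n_down"), names(out)))
  out <- out[, cols, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("cerna_enrichment", class(out)))
  out
}

#' Degree-ranked hub genes of an interaction network
#'
#' Computes node degrees on the simple undirected graph of an edge list
#' (self-loops dropped with a message, duplicate edges — in either
#' orientation — counted once) and flags the `top_k` nodes by degree as
#' hubs. Ties at the hub boundary are broken by lexicographic node id and
#' reported with a message.
#'
#' @param edges Data frame whose first two columns are node ids (a score
#'   column, if present, can be thresholded with `min_score`).
#' @param top_k Number of hubs to flag (default 10).
#' @param min_score Optional lower bound applied to the third (score)
#'   column before building the graph.
#' @return Data frame of class `cerna_degree` with columns `node`,
#'   `degree`, `rank`, `is_hub`, sorted by decreasing degree then node id.
#' @export
hub_genes <- function(edges, top_k = 10L, min_score = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    ct_stop("'edges' must be a data.frame with >= 2 columns",
            class = "cerna_bad_input")
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  if (!is.null(min_score)) {
    if (ncol(edges) < 3L) {
      ct_stop("no score column to filter on", class = "cerna_bad_input")
    }
    keep <- as.numeric(edges[[3L]]) >= min_score
    a <- a[keep]; b <- b[keep]
  }
  loops <- a == b
  if (any(loops)) {
    message("hub_genes: dropped ", sum(loops), " self-loop(s)")
    a <- a[!loops]; b <- b[!loops]
  }
  empty <- data.frame(node = character(0), degree = integer(0),
                      rank = integer(0), is_hub = logical(0),
                      stringsAsFactors = FALSE)
  if (length(a) == 0L) {
    class(empty) <- unique(c("cerna_degree", class(empty)))
    return(empty)
  }
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(g)
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[ct_order(-out$degree, out$node), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  k <- min(top_k, nrow(out))
  out$is_hub <- out$rank <= k
  if (k > 0L && k < nrow(out) && out$degree[k] == out$degree[k + 1L]) {
    message("hub_genes: degree tie at the top-", k,
            " boundary broken by node id")
  }
  rownames(out) <- NULL
  class(out) <- unique(c("cerna_degree", class(out)))
  out
}
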