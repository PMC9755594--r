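#' Candidate mRNA pairs sharing targeting miRNAs
#'
#' Enumerates every unordered pair of consensus DEGs that share at least
#' `min_shared` targeting miRNAs in the map. For each pair the shared count
#' and the two marginal target counts are returned — the sufficient
#' statistics of the hypergeometric shared-miRNA test.
#'
#' @param degs A `cerna_consensus` table (see [consensus_degs()]) or a
#'   character vector of gene ids.
#' @param map A [target_map()].
#' @param min_shared Minimum shared-miRNA count for a pair to be listed
#'   (default 1).
#' @return Data frame with columns `mrna_a`, `mrna_b` (canonical order,
#'   `mrna_a < mrna_b`, no self-pairs), `shared_k`, `K` (miRNAs targeting
#'   `mrna_a`), `n` (miRNAs targeting `mrna_b`), sorted by (`mrna_a`,
#'   `mrna_b`).
#' @export
candidate_pairs <- function(degs, map, min_shared = 1L) {
  stopifnot(inherits(map, "cerna_target_map"))
  ids <- if (inherits(degs, "cerna_consensus")) degs$gene_id
         else as.character(degs)
  ids <- ct_sort(unique(ids))
  genes <- ids[ids %in% map$edges$gene_id]
  empty <- data.frame(mrna_a = character(0), mrna_b = character(0),
                      shared_k = integer(0), K = integer(0), n = integer(0),
                      stringsAsFactors = FALSE)
  if (length(genes) < 2L) return(empty)

  e <- map$edges[map$edges$gene_id %in% genes, , drop = FALSE]
  mirs <- unique(e$mirna_id)
  inc <- matrix(0L, length(mirs), length(genes),
                dimnames = list(mirs, genes))
  inc[cbind(match(e$mirna_id, mirs), match(e$gene_id, genes))] <- 1L
  shared <- crossprod(inc)                     # genes x genes shared counts
  deg_cnt <- colSums(inc)

  idx <- which(upper.tri(shared) & shared >= min_shared, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  out <- data.frame(mrna_a = genes[idx[, 1L]], mrna_b = genes[idx[, 2L]],
                    shared_k = as.integer(shared[idx]),
                    K = as.integer(deg_cnt[idx[, 1L]]),
                    n = as.integer(deg_cnt[idx[, 2L]]),
                    stringsAsFactors = FALSE)
  out <- out[ct_order(out$mrna_a, out$mrna_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen candidate triplets into a ceRNA network
#'
#' The core inference step. Every candidate DEG pair (sharing at least
#' `min_shared` targeting miRNAs) is expanded into one triplet per shared
#' miRNA with measured expression, and a triplet
#' (mRNA A, miRNA, mRNA B) is accepted into the network iff all four
#' conditions hold at level `alpha`:
#' \enumerate{
#'   \item the hypergeometric shared-miRNA p-value is `< alpha`;
#'   \item the two mRNAs are positively co-expressed: `r_ab > 0` and
#'     `p_ab < alpha`;
#'   \item the miRNA is negatively correlated with mRNA A: `r_ma < 0`,
#'     `p_ma < alpha`;
#'   \item likewise with mRNA B: `r_mb < 0`, `p_mb < alpha`.
#' }
#' Correlations are Pearson, computed over all samples of the designated
#' dataset with case and control pooled (the disease shift is part of the
#' co-expression signal being screened). p-values are two-sided by default;
#' `one_sided = TRUE` uses the tail matching the required sign.
#'
#' The audit table records every tested triplet with all statistics, the
#' first failed condition, and BH-adjusted companions of the three p-value
#' families (informational; acceptance always uses the raw p).
#'
#' @param mrna_ds,mirna_ds [expression_dataset()]s over identical samples
#'   and groups.
#' @param degs Consensus DEG set ([consensus_degs()]) or character vector of
#'   gene ids; ids without expression rows are dropped with a log entry.
#' @param map A [target_map()].
#' @param alpha Per-condition significance level (default 0.05).
#' @param min_shared Minimum shared-miRNA count (default 1).
#' @param universe `"map"` (default) sizes the hypergeometric universe `N`
#'   as the map's full miRNA universe; `"expressed"` restricts the map — and
#'   `N` — to miRNAs with measured expression.
#' @param one_sided Use one-sided correlation p-values in the sign
#'   direction being tested (default `FALSE`: sign constraint plus
#'   two-sided p).
#' @param either_endpoint Accept the negative-correlation condition if it
#'   holds for at least one of the two mRNAs rather than both (default
#'   `FALSE`).
#' @return An object of class `cerna_screen`: list with `network` (a
#'   `cerna_network`), `audit` (data frame of all tested triplets sorted by
#'   `mrna_a`, `mirna`, `mrna_b`), `n_candidate_pairs`,
#'   `n_pairs_hypergeom`, `n_edges_hypergeom` (pair relations and
#'   miRNA-mRNA edges surviving the hypergeometric stage alone), `alpha`,
#'   and `log`.
#' @export
screen_triplets <- function(mrna_ds, mirna_ds, degs, map, alpha = 0.05,
                            min_shared = 1L,
                            universe = c("map", "expressed"),
                            one_sided = FALSE, either_endpoint = FALSE) {
  stopifnot(inherits(mrna_ds, "cerna_expression"),
            inherits(mirna_ds, "cerna_expression"),
            inherits(map, "cerna_target_map"))
  universe <- match.arg(universe)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    ct_stop("'alpha' must lie in [0, 1]", class = "cerna_bad_input")
  }
  samples <- colnames(mrna_ds$values)
  if (!setequal(samples, colnames(mirna_ds$values))) {
    ct_stop("mRNA and miRNA datasets must cover the same samples",
            class = "cerna_bad_input")
  }
  mirna_vals <- mirna_ds$values[, samples, drop = FALSE]
  if (!identical(unname(mrna_ds$groups[samples]),
                 unname(mirna_ds$groups[samples]))) {
    ct_stop("mRNA and miRNA datasets disagree on group labels",
            class = "cerna_bad_input")
  }
  log <- character(0)

  deg_ids <- if (inherits(degs, "cerna_consensus")) degs$gene_id
             else as.character(degs)
  deg_ids <- ct_sort(unique(deg_ids))
  missing_expr <- setdiff(deg_ids, rownames(mrna_ds$values))
  if (length(missing_expr)) {
    log <- ct_log(log, "dropped ", length(missing_expr),
                  " DEG(s) without mRNA expression")
    deg_ids <- setdiff(deg_ids, missing_expr)
  }

  expressed_mirs <- rownames(mirna_vals)
  if (universe == "expressed") {
    keep <- map$edges$mirna_id %in% expressed_mirs
    map <- target_map(map$edges[keep, , drop = FALSE],
                      mirna_universe = intersect(map$mirna_universe,
                                                 expressed_mirs),
                      mrna_universe = map$mrna_universe)
  }
  N <- length(map$mirna_universe)

  pairs <- candidate_pairs(deg_ids, map, min_shared = min_shared)
  audit_cols <- c("mrna_a", "mirna", "mrna_b", "shared_k", "K", "n", "N",
                  "hyper_p", "r_ab", "p_ab", "r_ma", "p_ma", "r_mb", "p_mb",
                  "accepted", "first_fail")
  empty_audit <- data.frame(
    mrna_a = character(0), mirna = character(0), mrna_b = character(0),
    shared_k = integer(0), K = integer(0), n = integer(0), N = integer(0),
    hyper_p = numeric(0), r_ab = numeric(0), p_ab = numeric(0),
    r_ma = numeric(0), p_ma = numeric(0), r_mb = numeric(0),
    p_mb = numeric(0), accepted = logical(0), first_fail = character(0),
    stringsAsFactors = FALSE)

  if (nrow(pairs) == 0L) {
    log <- ct_log(log, "no candidate pairs")
    return(new_cerna_screen(empty_audit, alpha, 0L, 0L, 0L, log))
  }
  pairs$hyper_p <- hypergeom_shared_pvalue(pairs$shared_k, pairs$K, pairs$n, N)

  # hypergeometric-stage network size, both ways the pair count can be read:
  hyp_pairs <- pairs[pairs$hyper_p < alpha, , drop = FALSE]
  n_pairs_hyp <- nrow(hyp_pairs)

  # expand each pair into triplets over its expressed shared miRNAs
  by_gene <- split(map$edges$mirna_id, map$edges$gene_id)
  shared_list <- mapply(function(a, b) {
    s <- intersect(by_gene[[a]], by_gene[[b]])
    ct_sort(s[s %in% expressed_mirs])
  }, pairs$mrna_a, pairs$mrna_b, SIMPLIFY = FALSE)
  n_shared_expr <- lengths(shared_list)
  dropped_unexpressed <- sum(pairs$shared_k) - sum(n_shared_expr)
  if (dropped_unexpressed > 0L) {
    log <- ct_log(log, "dropped ", dropped_unexpressed,
                  " shared-miRNA occurrence(s) without miRNA expression")
  }
  n_edges_hyp <- {
    hs <- shared_list[pairs$hyper_p < alpha]
    ha <- rep(pairs$mrna_a[pairs$hyper_p < alpha], lengths(hs))
    hb <- rep(pairs$mrna_b[pairs$hyper_p < alpha], lengths(hs))
    hm <- unlist(hs, use.names = FALSE)
    length(unique(c(paste(hm, ha), paste(hm, hb))))
  }

  keep <- n_shared_expr > 0L
  if (!any(keep)) {
    log <- ct_log(log, "no triplet has an expressed shared miRNA")
    return(new_cerna_screen(empty_audit, alpha, nrow(pairs), n_pairs_hyp,
                            n_edges_hyp, log))
  }
  reps <- n_shared_expr[keep]
  aud <- data.frame(
    mrna_a = rep(pairs$mrna_a[keep], reps),
    mirna = unlist(shared_list[keep], use.names = FALSE),
    mrna_b = rep(pairs$mrna_b[keep], reps),
    shared_k = rep(pairs$shared_k[keep], reps),
    K = rep(pairs$K[keep], reps),
    n = rep(pairs$n[keep], reps),
    N = N,
    hyper_p = rep(pairs$hyper_p[keep], reps),
    stringsAsFactors = FALSE)

  # correlations over pooled samples of the designated dataset
  ns <- length(samples)
  genes <- unique(c(aud$mrna_a, aud$mrna_b))
  mirs <- unique(aud$mirna)
  Xg <- t(mrna_ds$values[genes, samples, drop = FALSE])
  Xm <- t(mirna_vals[mirs, , drop = FALSE])
  const_g <- genes[apply(Xg, 2L, stats::sd) == 0]
  const_m <- mirs[apply(Xm, 2L, stats::sd) == 0]
  if (length(const_g) || length(const_m)) {
    drop_row <- aud$mrna_a %in% const_g | aud$mrna_b %in% const_g |
      aud$mirna %in% const_m
    log <- ct_log(log, "dropped ", sum(drop_row),
                  " triplet(s) involving constant expression")
    aud <- aud[!drop_row, , drop = FALSE]
    if (nrow(aud) == 0L) {
      return(new_cerna_screen(empty_audit, alpha, nrow(pairs), n_pairs_hyp,
                              n_edges_hyp, log))
    }
    genes <- unique(c(aud$mrna_a, aud$mrna_b))
    mirs <- unique(aud$mirna)
    Xg <- Xg[, genes, drop = FALSE]
    Xm <- Xm[, mirs, drop = FALSE]
  }
  Cgg <- stats::cor(Xg)
  Cmg <- stats::cor(Xm, Xg)

  ia <- match(aud$mrna_a, genes); ib <- match(aud$mrna_b, genes)
  im <- match(aud$mirna, mirs)
  aud$r_ab <- Cgg[cbind(ia, ib)]
  aud$r_ma <- Cmg[cbind(im, ia)]
  aud$r_mb <- Cmg[cbind(im, ib)]
  if (one_sided) {
    aud$p_ab <- one_sided_cor_p(aud$r_ab, ns, positive = TRUE)
    aud$p_ma <- one_sided_cor_p(aud$r_ma, ns, positive = FALSE)
    aud$p_mb <- one_sided_cor_p(aud$r_mb, ns, positive = FALSE)
  } else {
    aud$p_ab <- cor_pvalue(aud$r_ab, ns)
    aud$p_ma <- cor_pvalue(aud$r_ma, ns)
    aud$p_mb <- cor_pvalue(aud$r_mb, ns)
  }

  pass_hyp <- aud$hyper_p < alpha
  pass_ab <- aud$r_ab > 0 & aud$p_ab < alpha
  pass_ma <- aud$r_ma < 0 & aud$p_ma < alpha
  pass_mb <- aud$r_mb < 0 & aud$p_mb < alpha
  pass_neg <- if (either_endpoint) pass_ma | pass_mb else pass_ma & pass_mb
  aud$accepted <- pass_hyp & pass_ab & pass_neg
  aud$first_fail <- ifelse(!pass_hyp, "hypergeom",
                    ifelse(!pass_ab, "pair_correlation",
                    ifelse(!pass_ma, "mirna_mrna_a_correlation",
                    ifelse(!pass_mb, "mirna_mrna_b_correlation", "none"))))
  if (either_endpoint) {
    aud$first_fail[aud$accepted] <- "none"
  }

  # informational BH companions, one family per p-value column
  aud$hyper_padj <- stats::p.adjust(aud$hyper_p, method = "BH")
  aud$p_ab_adj <- stats::p.adjust(aud$p_ab, method = "BH")
  aud$p_ma_adj <- stats::p.adjust(aud$p_ma, method = "BH")
  aud$p_mb_adj <- stats::p.adjust(aud$p_mb, method = "BH")

  aud <- aud[ct_order(aud$mrna_a, aud$mirna, aud$mrna_b), , drop = FALSE]
  rownames(aud) <- NULL
  new_cerna_screen(aud, alpha, nrow(pairs), n_pairs_hyp, n_edges_hyp, log)
}

one_sided_cor_p <- function(r, n, positive) {
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  tt[abs(r) >= 1] <- sign(r[abs(r) >= 1]) * Inf
  if (positive) stats::pt(tt, df = n - 2, lower.tail = FALSE)
  else stats::pt(tt, df = n - 2, lower.tail = TRUE)
}

new_cerna_screen <- function(audit, alpha, n_candidate_pairs,
                             n_pairs_hypergeom, n_edges_hypergeom, log) {
  net <- cerna_network(audit[isTRUE_vec(audit$accepted), , drop = FALSE])
  structure(list(network = net, audit = audit, alpha = alpha,
                 n_candidate_pairs = n_candidate_pairs,
                 n_pairs_hypergeom = n_pairs_hypergeom,
                 n_edges_hypergeom = n_edges_hypergeom, log = log),
            class = "cerna_screen")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Assemble a ceRNA network from accepted triplets
#'
#' The node and edge sets are exactly those induced by the triplet list: an
#' mRNA or miRNA appears iff it belongs to an accepted triplet, and a
#' (miRNA, mRNA) edge appears iff some accepted triplet contains it
#' (deduplicated across triplets).
#'
#' @param triplets Data frame with at least `mrna_a`, `mirna`, `mrna_b`.
#' @return Object of class `cerna_network`: list with `triplets`,
#'   `mrna_nodes`, `mirna_nodes`, `edges` (data frame `mirna_id`,
#'   `gene_id`).
#' @export
cerna_network <- function(triplets) {
  stopifnot(is.data.frame(triplets),
            all(c("mrna_a", "mirna", "mrna_b") %in% names(triplets)))
  rownames(triplets) <- NULL
  edges <- unique(data.frame(
    mirna_id = rep(triplets$mirna, 2L),
    gene_id = c(triplets$mrna_a, triplets$mrna_b),
    stringsAsFactors = FALSE))
  edges <- edges[ct_order(edges$mirna_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(triplets = triplets,
                 mrna_nodes = ct_sort(unique(c(triplets$mrna_a,
                                               triplets$mrna_b))),
                 mirna_nodes = ct_sort(unique(triplets$mirna)),
                 edges = edges),
            class = "cerna_network")
}

#' Summarize a ceRNA network
#'
#' @param net A `cerna_network`.
#' @return Named integer vector: `n_triplets`, `n_mrna_nodes`,
#'   `n_mirna_nodes`, `n_edges` (each miRNA-mRNA edge counted once however
#'   many triplets contain it).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  c(n_triplets = nrow(net$triplets),
    n_mrna_nodes = length(net$mrna_nodes),
    n_mirna_nodes = length(net$mirna_nodes),
    n_edges = nrow(net$edges))
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("<cerna_network> %d ceRNA axes; %d mRNA + %d miRNA nodes, %d edges\n",
              s["n_triplets"], s["n_mrna_nodes"], s["n_mirna_nodes"],
              s["n_edges"]))
  invisible(x)
}

#' @export
print.cerna_screen <- function(x, ...) {
  cat(sprintf(
    "<cerna_screen> alpha=%g: %d candidate pairs -> %d tested triplets -> %d accepted\n",
    x$alpha, x$n_candidate_pairs, nrow(x$audit), nrow(x$network$triplets)))
  invisible(x)
}

#' @export
summary.cerna_screen <- function(object, ...) {
  s <- network_summary(object$network)
  cat(sprintf("ceRNA screen at alpha = %g\n", object$alpha))
  cat(sprintf("  candidate DEG pairs (>= min shared miRNAs): %d\n",
              object$n_candidate_pairs))
  cat(sprintf("  hypergeometric stage: %d significant pairs, %d miRNA-mRNA edges\n",
              object$n_pairs_hypergeom, object$n_edges_hypergeom))
  cat(sprintf("  tested triplets: %d\n", nrow(object$audit)))
  if (nrow(object$audit)) {
    ff <- table(object$audit$first_fail)
    for (nm in names(ff)) cat(sprintf("    %s: %d\n", nm, ff[[nm]]))
  }
  cat(sprintf("  accepted network: %d axes, %d mRNAs, %d miRNAs, %d edges\n",
              s["n_triplets"], s["n_mrna_nodes"], s["n_mirna_nodes"],
              s["n_edges"]))
  for (l in object$log) cat("  note: ", l, "\n", sep = "")
  invisible(s)
}

#' Precision/recall of accepted triplets against planted truth
#'
#' Compares a set of accepted ceRNA axes with the generator's planted
#' triplets, both in canonical (mrna_a < mrna_b) order. By convention an
#' empty accepted set has precision 1 (nothing asserted, nothing wrong;
#' logged via message when truth is nonempty) and an empty truth has
#' recall 1.
#'
#' @param accepted A `cerna_screen`, `cerna_network`, or data frame with
#'   `mrna_a`, `mirna`, `mrna_b`.
#' @param truth The `truth` element of a [simulate_paired_datasets()]
#'   result, or any data frame of planted triplets.
#' @return Named numeric vector: `precision`, `recall`, `f1`.
#' @export
recovery_metrics <- function(accepted, truth) {
  if (inherits(accepted, "cerna_screen")) accepted <- accepted$network
  if (inherits(accepted, "cerna_network")) accepted <- accepted$triplets
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$triplets)) {
    truth <- truth$triplets
  }
  acc <- unique(triplet_key(accepted$mrna_a, accepted$mirna, accepted$mrna_b))
  tru <- unique(triplet_key(truth$mrna_a, truth$mirna, truth$mrna_b))
  hits <- length(intersect(acc, tru))
  precision <- if (length(acc) == 0L) {
    if (length(tru)) message("recovery_metrics: empty accepted set, ",
                             "precision 1 by convention")
    1
  } else hits / length(acc)
  recall <- if (length(tru) == 0L) 1 else hits / length(tru)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}
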