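# Shared fixtures and independent oracles. Everything is built in code; no
# stored data files.

# Exhaustive-enumeration oracle for the upper-tail hypergeometric
# probability: over all C(N, n) subsets of {1..N} (special items 1..K),
# the fraction with at least k special members. Independent of phyper.
hyper_enum_oracle <- function(k, K, n, N) {
  if (n == 0L) return(if (k == 0L) 1 else 0)
  sub <- utils::combn(N, n)
  mean(colSums(sub <= K) >= k)
}

# quick two-group expression dataset from a matrix (first n_case columns
# are cases, labelled IDD)
make_ds <- function(m, n_case, kind = "mrna", case = "IDD") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  groups <- stats::setNames(
    rep(c(case, "IDnD"), c(n_case, ncol(m) - n_case)), colnames(m))
  expression_dataset(m, groups, kind = kind, case = case)
}

# hand-built DE table with given flags already applied
make_de <- function(gene_id, log2fc, pvalue, p_max = 0.05, lfc_min = 1) {
  filter_degs(data.frame(gene_id = gene_id, log2fc = log2fc,
                         pvalue = pvalue, stringsAsFactors = FALSE),
              p_max = p_max, lfc_min = lfc_min)
}

# small, fast simulation config for unit tests
tiny_config <- function(...) {
  sim_config(n_case = 10L, n_control = 10L, n_mrna = 60L, n_mirna = 20L,
             n_planted_triplets = 4L, de_fraction = 0.3,
             n_datasets = 2L, ...)
}

# run DE + consensus + screen on a simulated study, correlations from
# dataset 1
run_chain <- function(sim, alpha = 0.05) {
  de <- lapply(sim$datasets, function(d) differential_expression(d$mrna))
  degs <- consensus_degs(de)
  list(degs = degs,
       screen = screen_triplets(sim$datasets[[1L]]$mrna,
                                sim$datasets[[1L]]$mirna,
                                degs, sim$target_map, alpha = alpha))
}
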