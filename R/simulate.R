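#' Simulation configuration for planted ceRNA data
#'
#' Parameters of the generative model used by [simulate_paired_datasets()]
#' and [simulate_null()]. Defaults describe the reference conditions used
#' throughout the package's validation: two cohorts of 30 degenerated (IDD)
#' vs 30 control (IDnD) samples, 400 mRNAs, 80 miRNAs, 20 planted ceRNA
#' triplets with sponge loading 1.2, a log2 shift of 2 on 25% of mRNAs, a
#' residual sd of 0.5 and a 2% decoy rate in the target map.
#'
#' @param n_case,n_control Samples per group in every emitted dataset.
#' @param n_mrna,n_mirna Number of mRNA genes and miRNAs.
#' @param n_planted_triplets Number of true ceRNA modules planted.
#' @param sponge_strength Loading `beta >= 0` of each planted triplet's
#'   shared miRNA activity on its two mRNAs (subtracted, so the miRNA
#'   represses both).
#' @param de_fraction Fraction of mRNAs given a case-vs-control shift.
#' @param de_effect Log2-scale mean shift `delta` applied to case samples of
#'   differentially expressed genes (sign drawn per gene).
#' @param noise_sd Residual standard deviation `sigma` on log2 scale.
#' @param decoy_edge_prob Probability `rho` that any non-planted
#'   (miRNA, mRNA) pair enters the target map as a decoy edge.
#' @param n_datasets Number of independent paired datasets to emit (the
#'   reference design uses two cohorts).
#' @param seed Integer RNG seed; equal seeds give byte-identical output.
#'
#' @return A validated list of class `cerna_sim_config`.
#' @export
sim_config <- function(n_case = 30L, n_control = 30L, n_mrna = 400L,
                       n_mirna = 80L, n_planted_triplets = 20L,
                       sponge_strength = 1.2, de_fraction = 0.25,
                       de_effect = 2, noise_sd = 0.5,
                       decoy_edge_prob = 0.02, n_datasets = 2L, seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_mrna = as.integer(n_mrna), n_mirna = as.integer(n_mirna),
              n_planted_triplets = as.integer(n_planted_triplets),
              sponge_strength = as.numeric(sponge_strength),
              de_fraction = as.numeric(de_fraction),
              de_effect = as.numeric(de_effect),
              noise_sd = as.numeric(noise_sd),
              decoy_edge_prob = as.numeric(decoy_edge_prob),
              n_datasets = as.integer(n_datasets), seed = as.integer(seed))
  counts <- c("n_case", "n_control", "n_mrna", "n_mirna", "n_datasets")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      ct_stop("'", f, "' must be a count >= 1", class = "cerna_bad_config")
    }
  }
  if (is.na(cfg$n_planted_triplets) || cfg$n_planted_triplets < 0L) {
    ct_stop("'n_planted_triplets' must be >= 0", class = "cerna_bad_config")
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    ct_stop("'de_fraction' must lie in [0, 1]", class = "cerna_bad_config")
  }
  if (cfg$decoy_edge_prob < 0 || cfg$decoy_edge_prob > 1) {
    ct_stop("'decoy_edge_prob' must lie in [0, 1]", class = "cerna_bad_config")
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0) {
    ct_stop("'noise_sd' must be > 0", class = "cerna_bad_config")
  }
  if (!is.finite(cfg$sponge_strength) || cfg$sponge_strength < 0) {
    ct_stop("'sponge_strength' must be >= 0", class = "cerna_bad_config")
  }
  if (cfg$n_planted_triplets * 2L > cfg$n_mrna) {
    ct_stop("not enough mRNAs for the requested planted triplets",
            class = "cerna_bad_config")
  }
  if (cfg$n_planted_triplets > cfg$n_mirna) {
    ct_stop("need at least one distinct miRNA per planted triplet",
            class = "cerna_bad_config")
  }
  structure(cfg, class = "cerna_sim_config")
}

#' Simulate paired case-control datasets with planted ceRNA modules
#'
#' Generates `n_datasets` independent paired (mRNA, miRNA) expression
#' datasets on log2 scale, a bipartite miRNA-to-mRNA target map, and the
#' record of planted truth.
#'
#' The generative model is a single latent factor per planted triplet: for
#' each sample, an activity `u ~ N(0, 1)` is added to the shared miRNA's
#' log2 expression and subtracted, scaled by `sponge_strength`, from both of
#' its target mRNAs, on top of per-gene baselines `N(8, 1)` and residual
#' noise `N(0, noise_sd^2)`. In expectation this makes the two mRNAs
#' positively correlated and each negatively correlated with the miRNA —
#' exactly the co-expression signature the screening chain looks for.
#' Differentially expressed genes receive a `±de_effect` shift in the case
#' group; the two mRNAs of every planted triplet are drawn from the DE set
#' with same-direction shifts so they survive the cross-dataset consensus.
#' The target map is the union of the planted edges and uniform Bernoulli
#' decoy edges, deduplicated. All datasets share one truth but use
#' independent baselines, factors and noise.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `cerna_sim` with elements:
#'   \describe{
#'     \item{datasets}{List of length `n_datasets`; each element has `$mrna`
#'       and `$mirna`, both [expression_dataset()] objects over the same
#'       samples.}
#'     \item{target_map}{A [target_map()] whose universes are all simulated
#'       miRNAs and mRNAs.}
#'     \item{truth}{List with `de_genes` (data.frame `gene_id`, `sign`),
#'       `triplets` (data.frame `mrna_a`, `mirna`, `mrna_b`, endpoints in
#'       canonical order) and `planted_edges` (data.frame `mirna_id`,
#'       `gene_id`).}
#'   }
#' @seealso [simulate_null()] for the matched no-signal generator.
#' @export
simulate_paired_datasets <- function(config) {
  stopifnot(inherits(config, "cerna_sim_config"))
  simulate_core(config, null = FALSE)
}

#' Simulate matched null datasets
#'
#' Same generative pipeline as [simulate_paired_datasets()] but with
#' `sponge_strength` and `de_fraction` forced to zero: no gene carries a
#' group effect and no mRNA pair is coupled. The planted triplet structure
#' still exists in the target map (as inert edges, with the triplet mRNAs
#' drawn from all genes), so the screen faces the same candidate topology
#' with no true signal; `truth$triplets` is empty.
#'
#' @inheritParams simulate_paired_datasets
#' @return Same shape as [simulate_paired_datasets()].
#' @export
simulate_null <- function(config) {
  stopifnot(inherits(config, "cerna_sim_config"))
  config$sponge_strength <- 0
  config$de_fraction <- 0
  simulate_core(config, null = TRUE)
}

simulate_core <- function(cfg, null) {
  set.seed(cfg$seed)
  mrna_ids <- sprintf("gene%04d", seq_len(cfg$n_mrna))
  mirna_ids <- sprintf("hsa-mir-%04d", seq_len(cfg$n_mirna))
  np <- cfg$n_planted_triplets

  # --- truth: DE genes, triplet membership, planted edges -------------------
  if (null) {
    n_de <- 0L
    de_genes <- character(0)
    de_sign <- integer(0)
  } else {
    n_de <- as.integer(round(cfg$de_fraction * cfg$n_mrna))
    if (np > 0L && 2L * np > n_de) {
      ct_stop("impossible configuration: 2 * n_planted_triplets (", 2L * np,
              ") exceeds the number of DE genes (", n_de, ")",
              class = "cerna_bad_config")
    }
    de_genes <- sample(mrna_ids, n_de)
    de_sign <- sample(c(-1L, 1L), n_de, replace = TRUE)
    names(de_sign) <- de_genes
  }

  trip_pool <- if (null) mrna_ids else de_genes
  if (np > 0L) {
    trip_genes <- sample(trip_pool, 2L * np)
    trip_mirnas <- sample(mirna_ids, np)
    trip_a <- trip_genes[seq_len(np) * 2L - 1L]
    trip_b <- trip_genes[seq_len(np) * 2L]
    if (!null) {
      # the two sponging mRNAs must shift in the same direction, or the
      # consensus screen (which requires direction agreement) would drop them
      trip_dir <- sample(c(-1L, 1L), np, replace = TRUE)
      de_sign[trip_a] <- trip_dir
      de_sign[trip_b] <- trip_dir
    }
    lo <- pmin(trip_a, trip_b)
    hi <- pmax(trip_a, trip_b)
    triplets <- data.frame(mrna_a = lo, mirna = trip_mirnas, mrna_b = hi,
                           stringsAsFactors = FALSE)
    triplets <- triplets[ct_order(triplets$mrna_a, triplets$mirna,
                                  triplets$mrna_b), , drop = FALSE]
    rownames(triplets) <- NULL
    # under the null the planted topology is inert: edges stay in the map
    # but no triplet is true
    if (null) triplets <- triplets[0L, , drop = FALSE]
    planted_edges <- data.frame(
      mirna_id = rep(trip_mirnas, 2L),
      gene_id = c(trip_a, trip_b),
      stringsAsFactors = FALSE)
  } else {
    trip_a <- trip_b <- trip_mirnas <- character(0)
    triplets <- data.frame(mrna_a = character(0), mirna = character(0),
                           mrna_b = character(0), stringsAsFactors = FALSE)
    planted_edges <- data.frame(mirna_id = character(0),
                                gene_id = character(0),
                                stringsAsFactors = FALSE)
  }

  # --- target map: planted edges + Bernoulli decoys -------------------------
  # Decoys are drawn over miRNA x mRNA pairs but never onto the planted
  # triplet mRNAs: a planted module's targeting evidence is exactly its true
  # regulator, so the planted shared-miRNA signal (k = K = n = 1, upper-tail
  # p = 1/N) stays unambiguously significant while the rest of the map
  # carries realistic random clutter.
  if (cfg$decoy_edge_prob > 0) {
    draw <- stats::runif(cfg$n_mirna * cfg$n_mrna) < cfg$decoy_edge_prob
    hit <- which(draw)
    decoys <- data.frame(
      mirna_id = mirna_ids[((hit - 1L) %% cfg$n_mirna) + 1L],
      gene_id = mrna_ids[((hit - 1L) %/% cfg$n_mirna) + 1L],
      stringsAsFactors = FALSE)
    decoys <- decoys[!decoys$gene_id %in% c(trip_a, trip_b), , drop = FALSE]
  } else {
    decoys <- planted_edges[0L, , drop = FALSE]
  }
  edges <- rbind(planted_edges, decoys)
  edges <- edges[!duplicated(paste(edges$mirna_id, edges$gene_id, sep = "\t")), ,
                 drop = FALSE]
  map <- target_map(edges, mirna_universe = mirna_ids,
                    mrna_universe = mrna_ids)

  # --- expression: baselines + DE shift + latent sponge factor + noise ------
  ns <- cfg$n_case + cfg$n_control
  datasets <- vector("list", cfg$n_datasets)
  for (d in seq_len(cfg$n_datasets)) {
    samples <- c(sprintf("d%d_IDD_%02d", d, seq_len(cfg$n_case)),
                 sprintf("d%d_IDnD_%02d", d, seq_len(cfg$n_control)))
    groups <- stats::setNames(rep(c("IDD", "IDnD"),
                                  c(cfg$n_case, cfg$n_control)), samples)
    case_cols <- seq_len(cfg$n_case)

    m_base <- stats::rnorm(cfg$n_mrna, 8, 1)
    mi_base <- stats::rnorm(cfg$n_mirna, 8, 1)
    m_vals <- matrix(stats::rnorm(cfg$n_mrna * ns, 0, cfg$noise_sd),
                     cfg$n_mrna, ns) + m_base
    mi_vals <- matrix(stats::rnorm(cfg$n_mirna * ns, 0, cfg$noise_sd),
                      cfg$n_mirna, ns) + mi_base
    dimnames(m_vals) <- list(mrna_ids, samples)
    dimnames(mi_vals) <- list(mirna_ids, samples)

    if (n_de > 0L) {
      m_vals[de_genes, case_cols] <- m_vals[de_genes, case_cols] +
        de_sign[de_genes] * cfg$de_effect
    }
    if (np > 0L) {
      u <- matrix(stats::rnorm(np * ns), np, ns)
      mi_vals[trip_mirnas, ] <- mi_vals[trip_mirnas, , drop = FALSE] + u
      m_vals[trip_a, ] <- m_vals[trip_a, , drop = FALSE] -
        cfg$sponge_strength * u
      m_vals[trip_b, ] <- m_vals[trip_b, , drop = FALSE] -
        cfg$sponge_strength * u
    }

    datasets[[d]] <- list(
      mrna = expression_dataset(m_vals, groups, "mrna", case = "IDD"),
      mirna = expression_dataset(mi_vals, groups, "mirna", case = "IDD"))
  }

  de_df <- data.frame(gene_id = de_genes,
                      sign = if (n_de > 0L) unname(de_sign[de_genes])
                             else integer(0),
                      stringsAsFactors = FALSE)
  de_df <- de_df[ct_order(de_df$gene_id), , drop = FALSE]
  rownames(de_df) <- NULL
  pe <- planted_edges[ct_order(planted_edges$mirna_id, planted_edges$gene_id), ,
                      drop = FALSE]
  rownames(pe) <- NULL

  structure(list(datasets = datasets, target_map = map,
                 truth = list(de_genes = de_df, triplets = triplets,
                              planted_edges = pe),
                 config = cfg),
            class = "cerna_sim")
}

#' @export
print.cerna_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<cerna_sim> %d paired dataset(s), %d mRNAs x %d miRNAs, %d+%d samples\n",
    cfg$n_datasets, cfg$n_mrna, cfg$n_mirna, cfg$n_case, cfg$n_control))
  cat(sprintf("  planted: %d triplets, %d DE genes; target map: %d edges\n",
              nrow(x$truth$triplets), nrow(x$truth$de_genes),
              nrow(x$target_map$edges)))
  invisible(x)
}
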