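test_that("nothing planted and no decoys gives an empty target map", {
  sim <- simulate_paired_datasets(
    sim_config(n_planted_triplets = 0, decoy_edge_prob = 0, seed = 1))
  expect_identical(nrow(sim$target_map$edges), 0L)
  expect_identical(nrow(sim$truth$triplets), 0L)
})

test_that("equal seeds reproduce the simulation exactly", {
  cfg <- sim_config(n_case = 30, n_control = 30, sponge_strength = 1.2,
                    noise_sd = 0.5, seed = 7)
  a <- simulate_paired_datasets(cfg)
  b <- simulate_paired_datasets(cfg)
  expect_identical(a, b)
  c <- simulate_paired_datasets(sim_config(seed = 8))
  expect_false(identical(a$datasets[[1]]$mrna$values,
                         c$datasets[[1]]$mrna$values))
})

test_that("truth is internally consistent and canonical", {
  sim <- simulate_paired_datasets(tiny_config(seed = 21))
  tr <- sim$truth
  expect_true(all(tr$triplets$mrna_a < tr$triplets$mrna_b))
  edge_keys <- paste(sim$target_map$edges$mirna_id,
                     sim$target_map$edges$gene_id)
  # both target edges of every planted triplet are in the map
  expect_true(all(paste(tr$triplets$mirna, tr$triplets$mrna_a) %in% edge_keys))
  expect_true(all(paste(tr$triplets$mirna, tr$triplets$mrna_b) %in% edge_keys))
  expect_true(all(paste(tr$planted_edges$mirna_id,
                        tr$planted_edges$gene_id) %in% edge_keys))
  # triplet mRNAs carry same-direction effects
  sgn <- stats::setNames(tr$de_genes$sign, tr$de_genes$gene_id)
  expect_true(all(sgn[tr$triplets$mrna_a] == sgn[tr$triplets$mrna_b]))
})

test_that("zero sponge loading and zero DE shift decouple planted pairs", {
  rs <- numeric(0)
  for (s in 1:200) {
    sim <- simulate_paired_datasets(
      sim_config(n_case = 8, n_control = 8, n_mrna = 30, n_mirna = 10,
                 n_planted_triplets = 2, sponge_strength = 0, de_effect = 0,
                 de_fraction = 0.3, decoy_edge_prob = 0, seed = s))
    v <- sim$datasets[[1]]$mrna$values
    tr <- sim$truth$triplets
    rs <- c(rs, vapply(seq_len(nrow(tr)), function(i) {
      stats::cor(v[tr$mrna_a[i], ], v[tr$mrna_b[i], ])
    }, 0))
  }
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("planted correlations have the sponge signature signs", {
  # beta >= 1, sigma <= 0.5, n = 30/group: every planted pair positively,
  # every planted miRNA-mRNA pair negatively correlated
  for (s in 1:3) {
    sim <- simulate_paired_datasets(sim_config(seed = 300 + s))
    v <- sim$datasets[[1]]$mrna$values
    w <- sim$datasets[[1]]$mirna$values
    tr <- sim$truth$triplets
    for (i in seq_len(nrow(tr))) {
      expect_gt(stats::cor(v[tr$mrna_a[i], ], v[tr$mrna_b[i], ]), 0)
      expect_lt(stats::cor(w[tr$mirna[i], ], v[tr$mrna_a[i], ]), 0)
      expect_lt(stats::cor(w[tr$mirna[i], ], v[tr$mrna_b[i], ]), 0)
    }
  }
})

test_that("null generator keeps the topology but no signal or truth", {
  cfg <- tiny_config(seed = 31)
  nul <- simulate_null(cfg)
  expect_identical(nrow(nul$truth$triplets), 0L)
  expect_identical(nrow(nul$truth$de_genes), 0L)
  expect_gt(nrow(nul$target_map$edges), 0L)
  # boundary: 3 samples per group still yields usable correlations (n = 6)
  small <- simulate_null(sim_config(n_case = 3, n_control = 3, n_mrna = 10,
                                    n_mirna = 5, n_planted_triplets = 2,
                                    seed = 32))
  v <- small$datasets[[1]]$mrna$values
  expect_true(is.finite(stats::cor(v[1, ], v[2, ])))
})

test_that("impossible or invalid configurations are rejected", {
  # more planted triplet mRNAs than DE genes
  expect_error(simulate_paired_datasets(
    sim_config(n_mrna = 100, n_planted_triplets = 20, de_fraction = 0.2)),
    class = "cerna_bad_config")
  expect_error(sim_config(noise_sd = 0), class = "cerna_bad_config")
  expect_error(sim_config(sponge_strength = -1), class = "cerna_bad_config")
  expect_error(sim_config(de_fraction = 1.5), class = "cerna_bad_config")
  expect_error(sim_config(n_case = 0), class = "cerna_bad_config")
  expect_error(sim_config(n_mrna = 10, n_planted_triplets = 6),
               class = "cerna_bad_config")
})

test_that("simulated datasets round-trip through the TSV writers", {
  sim <- simulate_paired_datasets(
    sim_config(n_case = 4, n_control = 4, n_mrna = 12, n_mirna = 6,
               n_planted_triplets = 2, de_fraction = 0.5, seed = 41))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  ds <- read_expression(file.path(dir, "dataset1_mrna.tsv"),
                        file.path(dir, "dataset1_groups.tsv"), kind = "mrna")
  orig <- sim$datasets[[1]]$mrna
  expect_equal(ds$values[rownames(orig$values), colnames(orig$values)],
               orig$values, tolerance = 0)
  expect_identical(ds$groups[names(orig$groups)], orig$groups)
  map <- read_target_map(file.path(dir, "target_map.tsv"))
  expect_identical(map$edges, sim$target_map$edges)
  tr <- read_truth(file.path(dir, "truth.json"))
  expect_identical(tr$triplets, sim$truth$triplets)
  expect_identical(tr$de_genes, sim$truth$de_genes)
})
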