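toy_map <- function() {
  target_map(data.frame(mirna_id = c("m1", "m2", "m1", "m2"),
                        gene_id = c("gA", "gA", "gB", "gC"),
                        stringsAsFactors = FALSE))
}

test_that("targets_of reads the inverse targeting index", {
  map <- toy_map()
  expect_identical(targets_of(map, "gA"), c("m1", "m2"))
  expect_identical(targets_of(map, "gB"), "m1")
  expect_message(out <- targets_of(map, "nope"), "not in the mRNA universe")
  expect_identical(out, character(0))
  empty <- target_map(data.frame(mirna_id = character(0),
                                 gene_id = character(0)))
  expect_message(expect_identical(targets_of(empty, "gA"), character(0)))
})

test_that("candidate pairs enumerate shared targeting without duplicates", {
  map <- target_map(data.frame(mirna_id = c("m1", "m1", "m2", "m2"),
                               gene_id = c("gA", "gB", "gB", "gC"),
                               stringsAsFactors = FALSE))
  cp <- candidate_pairs(c("gA", "gB", "gC"), map)
  expect_identical(cp$mrna_a, c("gA", "gB"))
  expect_identical(cp$mrna_b, c("gB", "gC"))
  expect_identical(cp$shared_k, c(1L, 1L))
  expect_identical(cp$K, c(1L, 2L))   # miRNAs targeting gA, gB
  expect_identical(cp$n, c(2L, 1L))
  # canonical order, no pair twice in either orientation, no self-pairs
  expect_true(all(cp$mrna_a < cp$mrna_b))
  expect_false(any(duplicated(rbind(cp[, 1:2],
                                    setNames(cp[, 2:1], names(cp)[1:2])))))
  # DEGs with no targeting miRNAs yield nothing
  expect_identical(nrow(candidate_pairs(c("gX", "gY"), map)), 0L)
})

test_that("one-triplet network has the forced summary (1, 2, 1, 2)", {
  expect_identical(
    unname(network_summary(cerna_network(
      data.frame(mrna_a = "gA", mirna = "m1", mrna_b = "gB")))),
    c(1L, 2L, 1L, 2L))
  empty <- cerna_network(data.frame(mrna_a = character(0),
                                    mirna = character(0),
                                    mrna_b = character(0)))
  expect_identical(unname(network_summary(empty)), c(0L, 0L, 0L, 0L))
})

test_that("shared edges are deduplicated across triplets", {
  net <- cerna_network(data.frame(mrna_a = c("gA", "gA"),
                                  mirna = c("m1", "m1"),
                                  mrna_b = c("gB", "gC")))
  # (m1,gA) appears in both triplets but counts once: 3 edges, not 4
  expect_identical(unname(network_summary(net)), c(2L, 3L, 1L, 3L))
})

test_that("recovery metrics count planted-axis overlap", {
  tru <- data.frame(mrna_a = c("a", "a", "c", "d"),
                    mirna = c("m1", "m2", "m3", "m4"),
                    mrna_b = c("b", "c", "e", "f"))
  acc <- tru[c(1, 2), ]
  acc <- rbind(acc, data.frame(mrna_a = "x", mirna = "m9", mrna_b = "y"))
  m <- recovery_metrics(acc, tru)
  expect_equal(unname(m), c(2 / 3, 1 / 2, 2 * (2/3) * (1/2) / (2/3 + 1/2)))
  expect_equal(unname(recovery_metrics(tru, tru)), c(1, 1, 1))
  disjoint <- data.frame(mrna_a = "x", mirna = "m9", mrna_b = "y")
  expect_equal(unname(recovery_metrics(disjoint, tru))[1:2], c(0, 0))
  # endpoint order is canonicalized before comparison
  flipped <- data.frame(mrna_a = "b", mirna = "m1", mrna_b = "a")
  expect_equal(unname(recovery_metrics(flipped, tru))[1], 1)
})

test_that("alpha = 0 accepts nothing", {
  sim <- simulate_paired_datasets(tiny_config(seed = 61))
  out <- run_chain(sim, alpha = 0)
  expect_identical(nrow(out$screen$network$triplets), 0L)
  expect_true(nrow(out$screen$audit) > 0L)
})

test_that("accepted triplets re-satisfy all four recorded inequalities", {
  sim <- simulate_paired_datasets(sim_config(seed = 11))
  out <- run_chain(sim)
  aud <- out$screen$audit
  alpha <- out$screen$alpha
  acc <- aud[aud$accepted, ]
  expect_gt(nrow(acc), 0L)
  expect_true(all(acc$hyper_p < alpha))
  expect_true(all(acc$r_ab > 0 & acc$p_ab < alpha))
  expect_true(all(acc$r_ma < 0 & acc$p_ma < alpha))
  expect_true(all(acc$r_mb < 0 & acc$p_mb < alpha))
  # no hidden filtering: everything satisfying the conditions is accepted
  should <- aud$hyper_p < alpha & aud$r_ab > 0 & aud$p_ab < alpha &
    aud$r_ma < 0 & aud$p_ma < alpha & aud$r_mb < 0 & aud$p_mb < alpha
  expect_identical(aud$accepted, should)
  # failure labelling is consistent
  expect_true(all(aud$first_fail[aud$accepted] == "none"))
  expect_true(all(aud$first_fail[!aud$accepted] != "none"))
})

test_that("audit statistics match pearson_test recomputed per triplet", {
  sim <- simulate_paired_datasets(tiny_config(seed = 62))
  out <- run_chain(sim)
  aud <- out$screen$audit
  v <- sim$datasets[[1]]$mrna$values
  w <- sim$datasets[[1]]$mirna$values
  take <- head(seq_len(nrow(aud)), 20)
  for (i in take) {
    pt <- pearson_test(v[aud$mrna_a[i], ], v[aud$mrna_b[i], ])
    expect_equal(aud$r_ab[i], pt$r, tolerance = 1e-12)
    expect_equal(aud$p_ab[i], pt$p, tolerance = 1e-12)
    pm <- pearson_test(w[aud$mirna[i], ], v[aud$mrna_a[i], ])
    expect_equal(aud$r_ma[i], pm$r, tolerance = 1e-12)
    expect_equal(aud$p_ma[i], pm$p, tolerance = 1e-12)
  }
})

test_that("screen output is deterministic and canonically sorted", {
  sim <- simulate_paired_datasets(tiny_config(seed = 63))
  a <- run_chain(sim)$screen
  b <- run_chain(sim)$screen
  expect_identical(a$audit, b$audit)
  ord <- order(a$audit$mrna_a, a$audit$mirna, a$audit$mrna_b,
               method = "radix")
  expect_identical(ord, seq_len(nrow(a$audit)))
})

test_that("mismatched sample sets are refused", {
  sim <- simulate_paired_datasets(tiny_config(seed = 64))
  d1 <- sim$datasets[[1]]
  d2 <- sim$datasets[[2]]
  expect_error(
    screen_triplets(d1$mrna, d2$mirna, rownames(d1$mrna$values),
                    sim$target_map),
    class = "cerna_bad_input")
})

test_that("DEGs without expression are dropped with a log entry", {
  sim <- simulate_paired_datasets(tiny_config(seed = 65))
  d1 <- sim$datasets[[1]]
  degs <- c(rownames(d1$mrna$values)[1:10], "ghost_gene")
  scr <- screen_triplets(d1$mrna, d1$mirna, degs, sim$target_map)
  expect_true(any(grepl("without mRNA expression", scr$log)))
})
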