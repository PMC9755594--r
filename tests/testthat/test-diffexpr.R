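test_that("a gene identical in both groups has log2fc 0 and direction none", {
  m <- rbind(flat = rep(5, 8), shifted = c(rep(7, 4), rep(5, 4)))
  colnames(m) <- sprintf("s%d", 1:8)
  de <- differential_expression(make_ds(m, n_case = 4))
  expect_equal(de$log2fc[de$gene_id == "flat"], 0)
  expect_equal(de$pvalue[de$gene_id == "flat"], 1)
  expect_equal(de$direction[de$gene_id == "flat"], "none")
  # exact separation with zero within-group variance
  expect_equal(de$log2fc[de$gene_id == "shifted"], 2)
  expect_equal(de$pvalue[de$gene_id == "shifted"], 0)
})

test_that("swapping group labels negates log2fc and keeps p-values", {
  set.seed(501)
  m <- matrix(rnorm(20 * 10, 8), 20, 10)
  ds <- make_ds(m, n_case = 5)
  swapped <- expression_dataset(ds$values, ds$groups, kind = "mrna",
                                case = "IDnD")
  a <- differential_expression(ds)
  b <- differential_expression(swapped)
  expect_equal(b$log2fc, -a$log2fc, tolerance = 1e-12)
  expect_equal(b$pvalue, a$pvalue, tolerance = 1e-12)
})

test_that("jittered step gene recovers its fold change, matching t.test", {
  set.seed(502)
  vals <- c(3, 3, 3, 3, 1, 1, 1, 1) + rnorm(8, 0, 0.01)
  m <- matrix(vals, 1, 8, dimnames = list("g", sprintf("s%d", 1:8)))
  de <- differential_expression(make_ds(m, n_case = 4))
  expect_equal(de$log2fc, 2, tolerance = 0.02)
  expect_lt(de$pvalue, 1e-4)
  tt <- stats::t.test(vals[1:4], vals[5:8])  # Welch is t.test's default
  expect_equal(de$pvalue, tt$p.value, tolerance = 1e-12)
  expect_equal(de$log2fc, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
})

test_that("vectorized Welch test equals per-gene t.test on random data", {
  set.seed(503)
  m <- matrix(rnorm(15 * 11, 8, 1.3), 15, 11)
  ds <- make_ds(m, n_case = 5)
  de <- differential_expression(ds)
  for (i in seq_len(nrow(m))) {
    tt <- stats::t.test(m[i, 1:5], m[i, 6:11])
    expect_equal(de$pvalue[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("groups with fewer than 2 samples are refused", {
  m <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], c("a", "b", "c")))
  expect_error(differential_expression(make_ds(m, n_case = 1)),
               class = "cerna_bad_input")
})

test_that("threshold filter applies strict inequalities as printed", {
  de <- make_de(sprintf("g%d", 1:6),
                log2fc = c(2, -3, 0.5, -1.2, 1.5, 4),
                pvalue = c(0.01, 0.2, 0.001, 0.04, 0.03, 0.6))
  expect_identical(de$gene_id[de$significant], c("g1", "g4", "g5"))
  expect_identical(de$direction, c("up", "none", "none", "down", "up", "none"))
  # boundary cases never pass: p exactly at the cutoff, |lfc| exactly 1
  edge <- make_de(c("p_edge", "lfc_edge"), log2fc = c(2, 1),
                  pvalue = c(0.05, 0.01))
  expect_false(any(edge$significant))
})

test_that("consensus keeps genes significant with the same trend everywhere", {
  t1 <- make_de(c("a", "b", "c"), c(2, -2, 2), c(0.01, 0.01, 0.01))
  t2 <- make_de(c("b", "c", "d"), c(-2, -2, 2), c(0.01, 0.01, 0.01))
  cons <- consensus_degs(list(t1, t2))
  # c clashes in direction, a and d are absent from one table
  expect_identical(cons$gene_id, "b")
  expect_identical(cons$direction, "down")
})

test_that("consensus of identical tables is the significant set itself", {
  t1 <- make_de(sprintf("g%d", 1:5), c(2, -2, 0.3, 3, -4),
                c(0.01, 0.2, 0.01, 0.001, 0.04))
  cons <- consensus_degs(list(t1, t1))
  expect_identical(cons$gene_id, sort(t1$gene_id[t1$significant]))
  expect_error(consensus_degs(list(t1)), class = "cerna_bad_input")
})

test_that("consensus is a subset of every input's significant set", {
  set.seed(504)
  sim <- simulate_paired_datasets(tiny_config(seed = 504))
  tabs <- lapply(sim$datasets, function(d) differential_expression(d$mrna))
  cons <- consensus_degs(tabs)
  for (t in tabs) {
    expect_true(all(cons$gene_id %in% t$gene_id[t$significant]))
  }
})
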