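toy_coll <- function() {
  universe <- sprintf("g%02d", 1:20)
  gene_set_collection(
    list(setA = universe[1:5], setB = universe[6:10], setC = universe[1:12]),
    universe = universe)
}

test_that("ORA p-value matches the exhaustive hypergeometric tail", {
  # universe 20, set of 5, query of 5, overlap 3:
  # sum_{i=3..5} C(5,i) C(15,5-i) / C(20,5) = 1126/15504
  universe <- sprintf("g%02d", 1:20)
  coll <- gene_set_collection(list(s = universe[1:5]), universe = universe)
  enr <- ora_enrich(c(universe[1:3], universe[11:12]), coll)
  expect_equal(enr$pvalue, 1126 / 15504, tolerance = 1e-12)
  expect_equal(enr$pvalue, hyper_enum_oracle(3, 5, 5, 20), tolerance = 1e-12)
  expect_identical(enr$k, 3L)
})

test_that("a set queried by itself is the most enriched in the collection", {
  coll <- toy_coll()
  enr <- ora_enrich(coll$sets$setA, coll)
  expect_identical(enr$set_name[1], "setA")
  expect_equal(enr$k[enr$set_name == "setB"], 0L)
  expect_equal(enr$pvalue[enr$set_name == "setB"], 1)
})

test_that("BH adjustment is monotone in the raw p-value", {
  set.seed(701)
  universe <- sprintf("g%02d", 1:40)
  sets <- lapply(1:8, function(i) sample(universe, sample(4:12, 1)))
  names(sets) <- sprintf("s%d", 1:8)
  coll <- gene_set_collection(sets, universe = universe)
  enr <- ora_enrich(sample(universe, 10), coll)
  expect_true(all(diff(enr$pvalue) >= 0))       # sorted by raw p
  expect_true(all(diff(enr$padj_bh) >= -1e-15)) # BH non-decreasing along it
  expect_equal(enr$padj_bh, p.adjust(enr$pvalue, "BH"), tolerance = 1e-15)
})

test_that("query genes outside the universe are clipped, empty query errors", {
  coll <- toy_coll()
  expect_message(enr <- ora_enrich(c("g01", "outsider"), coll),
                 "outside the universe")
  expect_identical(enr$n[1], 1L)
  expect_error(suppressMessages(ora_enrich("outsider", coll)),
               class = "cerna_bad_input")
})

test_that("per-set direction counts follow the supplied labels", {
  coll <- toy_coll()
  dirs <- setNames(rep(c("up", "down"), 3), sprintf("g%02d", 1:6))
  enr <- ora_enrich(sprintf("g%02d", 1:6), coll, directions = dirs)
  row <- enr[enr$set_name == "setA", ]
  expect_identical(row$n_up + row$n_down, row$k)
})

test_that("star graph ranks its center as the hub", {
  edges <- data.frame(a = "center", b = sprintf("leaf%d", 1:5))
  hubs <- hub_genes(edges, top_k = 1)
  expect_identical(hubs$node[hubs$is_hub], "center")
  expect_identical(hubs$degree[1], 5L)
  expect_true(all(hubs$degree[-1] == 1L))
})

test_that("duplicate and reversed edges count once; degree sum = 2 x edges", {
  edges <- data.frame(a = c("a", "b", "a", "c"), b = c("b", "a", "b", "a"))
  hubs <- hub_genes(edges)
  expect_identical(sum(hubs$degree), 2L * 2L)  # simple graph: a-b, a-c
  set.seed(702)
  for (i in 1:5) {
    nn <- sample(4:9, 1)
    e <- data.frame(a = sample(letters[1:nn], 15, TRUE),
                    b = sample(letters[1:nn], 15, TRUE))
    e <- e[e$a != e$b, ]
    h <- hub_genes(e)
    k <- nrow(unique(data.frame(pmin(e$a, e$b), pmax(e$a, e$b))))
    expect_identical(sum(h$degree), 2L * k)
  }
})

test_that("ties at the hub boundary break lexicographically and are logged", {
  tri <- data.frame(a = c("x", "y", "z"), b = c("y", "z", "x"))
  expect_message(hubs <- hub_genes(tri, top_k = 1), "tie")
  expect_identical(hubs$node[hubs$is_hub], "x")
  expect_true(all(hubs$degree == 2L))
})

test_that("self-loops are dropped and an empty graph gives an empty table", {
  expect_message(h <- hub_genes(data.frame(a = c("a", "a"), b = c("a", "b"))),
                 "self-loop")
  expect_identical(sum(h$degree), 2L)
  empty <- hub_genes(data.frame(a = character(0), b = character(0)))
  expect_identical(nrow(empty), 0L)
})
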