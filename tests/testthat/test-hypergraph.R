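test_that("triples are canonicalized, deduplicated and validated", {
  G <- ddi_hypergraph(letters[1:3], c("s1"),
                      rbind(c(1, 2, 1), c(2, 1, 1), c(1, 3, 1)))
  expect_equal(nrow(G$edges), 2L)
  expect_true(all(G$edges[, 1] < G$edges[, 2]))
  expect_error(ddi_hypergraph(letters[1:2], "s1", rbind(c(1, 1, 1))),
               "self-pair")
  expect_error(ddi_hypergraph(letters[1:2], "s1", rbind(c(1, 3, 1))),
               "out of range")
})

test_that("loading collapses symmetric duplicates and aligns features", {
  td <- withr::local_tempdir()
  tp <- file.path(td, "t.tsv"); fp <- file.path(td, "f.tsv")
  writeLines(c("a\tb\ts1", "b\ta\ts1", "a\tc\ts1", "c\td\ts2"), tp)
  writeLines(sprintf("%s\t%g\t%g", c("a", "b", "c", "d", "e"),
                     1:5 / 10, 5:1 / 10), fp)
  out <- load_hypergraph(tp, fp)
  expect_equal(nrow(out$graph$edges), 3L)
  expect_equal(length(out$graph$drug_ids), 5L)  # e retained, isolated
  expect_equal(rownames(out$features), out$graph$drug_ids)

  # round trip preserves the canonical edge set
  tp2 <- file.path(td, "t2.tsv"); fp2 <- file.path(td, "f2.tsv")
  write_hypergraph(out$graph, tp2, out$features, fp2)
  again <- load_hypergraph(tp2, fp2)
  expect_equal(again$graph$edges, out$graph$edges)

  # five drugs, three side effects, seven canonical triples (set oracle)
  raw <- rbind(c("a","b","x"), c("b","a","x"), c("a","c","x"), c("a","b","y"),
               c("c","d","y"), c("d","e","z"), c("b","e","z"), c("a","e","z"))
  writeLines(paste(raw[, 1], raw[, 2], raw[, 3], sep = "\t"), tp)
  out2 <- load_hypergraph(tp, fp)
  canon <- unique(t(apply(raw, 1, function(r) c(sort(r[1:2]), r[3]))))
  expect_equal(nrow(out2$graph$edges), nrow(canon))
  expect_equal(length(out2$graph$side_effect_ids), 3L)
})

test_that("loader errors name the offence", {
  td <- withr::local_tempdir()
  tp <- file.path(td, "t.tsv"); fp <- file.path(td, "f.tsv")
  writeLines(c("a\tb\ts1", "a\tb"), tp)
  writeLines(c("a\t1\t2", "b\t1\t1"), fp)
  expect_error(load_hypergraph(tp, fp), "line 2")
  writeLines(c("a\ta\ts1"), tp)
  expect_error(load_hypergraph(tp, fp), "self-pair")
  writeLines(c("a\tb\ts1"), tp)
  writeLines(c("a\t-1\t2", "b\t1\t1"), fp)
  expect_error(load_hypergraph(tp, fp), "negative")
  writeLines(c("a\t1\t2"), fp)
  expect_error(load_hypergraph(tp, fp), "lack feature rows")
})

test_that("data sparsity matches the closed form and its limits", {
  # published counts for the largest DDI benchmark
  expect_equal(round(100 * data_sparsity(n_drugs = 557, n_side_effects = 964,
                                         n_edges = 3606046), 1), 97.6)
  G_empty <- ddi_hypergraph(letters[1:3], "s1", matrix(integer(), ncol = 3))
  expect_equal(data_sparsity(G_empty), 1)
  full <- enumerate_canonical_triples(3, 2)
  G_full <- ddi_hypergraph(letters[1:3], c("s1", "s2"), full)
  expect_equal(data_sparsity(G_full), 0)
  expect_error(data_sparsity(n_drugs = 1, n_side_effects = 5, n_edges = 0),
               "undefined")
  # strictly decreasing in the edge count
  s <- sapply(0:6, function(e) data_sparsity(n_drugs = 3, n_side_effects = 2,
                                             n_edges = e))
  expect_true(all(diff(s) < 0))
})

test_that("stratified folds partition edges with per-side-effect balance", {
  for (seed in 1:3) {
    inst <- toy_instance(n_d = 12, n_s = 5, n_e = 60, seed = seed)
    G <- inst$G
    k <- 4
    folds <- stratified_kfold(G, k, seed = seed)
    expect_equal(sort(unlist(folds)), seq_len(nrow(G$edges)))
    expect_equal(sum(lengths(folds)), nrow(G$edges))
    for (t in seq_along(G$side_effect_ids)) {
      per_fold <- vapply(folds, function(f) sum(G$edges[f, 3] == t), 0L)
      expect_lte(max(per_fold) - min(per_fold), 1L)
    }
    expect_identical(folds, stratified_kfold(G, k, seed = seed))
  }
  # forced counts: 40 edges of one side effect over 20 folds -> 2 each
  edges <- cbind(t(combn(10, 2))[1:40, ], 1L)
  G1 <- ddi_hypergraph(paste0("d", 1:10), "s1", edges)
  f20 <- stratified_kfold(G1, 20, seed = 1)
  expect_true(all(lengths(f20) == 2L))
  expect_error(stratified_kfold(G1, 41, seed = 1), "exceeds")
})

test_that("non-edge sampling avoids positives and is reproducible", {
  inst <- toy_instance(n_d = 6, n_s = 3, n_e = 10, seed = 2)
  neg <- sample_non_edges(inst$G, 15, seed = 5)
  expect_equal(nrow(neg), 15L)
  expect_true(all(edge_indicator(inst$G, neg) == 0L))
  expect_true(all(neg[, 1] < neg[, 2]))
  expect_identical(neg, sample_non_edges(inst$G, 15, seed = 5))
})
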