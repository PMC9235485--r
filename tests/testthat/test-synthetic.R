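test_that("planted latent interactions respect the counting rules", {
  cfg <- synthetic_config(K_D = 5, K_S = 3, M = 1, seed = 2)
  A <- generate_latent_interactions(cfg)
  expect_equal(nrow(A), 3L)               # M = 1 forces one pair per k
  expect_equal(sort(unique(A[, 3])), 1:3)
  cfg2 <- synthetic_config(K_D = 2, K_S = 6, M = 3, seed = 3)
  A2 <- generate_latent_interactions(cfg2)
  expect_true(all(A2[, 1] <= A2[, 2]))
  expect_true(all(A2[, 1:2] %in% 1:2))    # only pairs over {1, 2}
  # expected support size: n_k uniform on {1..M} -> K_S (M+1)/2 on average
  cfgM <- synthetic_config(K_D = 6, K_S = 4, M = 5, seed = 1)
  sizes <- vapply(1:500, function(s)
    nrow(generate_latent_interactions(cfgM, seed = s)), numeric(1))
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 4 * (5 + 1) / 2), 3 * se)
})

test_that("drug features are noisy block indicators of the latents", {
  cfg <- synthetic_config(n_drugs = 200, n_side_effects = 10, K_D = 3,
                          K_S = 3, N1 = 2, N2 = 2, delta = 0, c = 2, seed = 4)
  out <- generate_node_latents_and_features(cfg)
  expect_equal(dim(out$features), c(200L, 6L))
  for (u in c(1, 17, 58)) {
    m <- numeric(6)
    for (b in out$g_u[[u]]) m[(b - 1) * 2 + 1:2] <- 1
    expect_equal(out$features[u, ], m, ignore_attr = TRUE)
    # thresholding recovers g_u exactly in the noiseless case
    expect_equal(which(colSums(matrix(out$features[u, ], nrow = 2)) > 1),
                 out$g_u[[u]])
  }
  expect_true(all(lengths(out$g_u) <= 2))
  expect_true(all(lengths(out$g_t) <= 2))
  # noise: empirical sd of an always-one block entry approaches delta
  cfg2 <- synthetic_config(n_drugs = 4, n_side_effects = 4, K_D = 2, K_S = 2,
                           N1 = 2, N2 = 2, delta = 0.1, c = 5, seed = 5)
  vals <- vapply(1:400, function(s) {
    out2 <- generate_node_latents_and_features(cfg2, seed = s)
    u <- which(lengths(out2$g_u) == 2)[1]
    if (is.na(u)) return(NA_real_)
    out2$features[u, 1]
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  expect_lt(abs(sd(vals) - 0.1), 0.02)    # clipping at 0 is immaterial here
})

test_that("true triples equal the exhaustive latent-overlap oracle", {
  for (seed in 1:4) {
    cfg <- synthetic_config(n_drugs = 15, n_side_effects = 6, K_D = 4,
                            K_S = 3, M = 2, N1 = 2, N2 = 2, seed = seed)
    A <- generate_latent_interactions(cfg)
    nodes <- generate_node_latents_and_features(cfg, seed = seed + 50)
    E <- generate_true_triples(A, nodes$g_u, nodes$g_t, cfg$K_D, cfg$K_S)
    want <- oracle_true_triples(A, nodes$g_u, nodes$g_t)
    expect_equal(unname(E[order(E[, 1], E[, 2], E[, 3]), , drop = FALSE]),
                 unname(want))
  }
  expect_equal(nrow(generate_true_triples(matrix(integer(), ncol = 3),
                                          list(1L, 2L), list(1L), 2, 1)), 0L)
})

test_that("noise swaps edges at rate r while conserving the edge count", {
  cfg <- synthetic_config(n_drugs = 30, n_side_effects = 10, K_D = 4,
                          K_S = 4, M = 3, N1 = 2, N2 = 2, seed = 6)
  A <- generate_latent_interactions(cfg)
  nodes <- generate_node_latents_and_features(cfg)
  E_star <- generate_true_triples(A, nodes$g_u, nodes$g_t, cfg$K_D, cfg$K_S)
  expect_identical(apply_noise(E_star, 0, 30, 10, seed = 1), E_star)
  E1 <- apply_noise(E_star, 1, 30, 10, seed = 1)
  expect_equal(nrow(E1), nrow(E_star))
  keys <- function(m) sparseddi:::triple_key(m[, 1], m[, 2], m[, 3], 30, 10)
  expect_length(intersect(keys(E1), keys(E_star)), 0L)
  # empirical replacement fraction over seeds within 3 standard errors of r
  r <- 0.2
  fr <- vapply(1:60, function(s) {
    E <- apply_noise(E_star, r, 30, 10, seed = s)
    1 - length(intersect(keys(E), keys(E_star))) / nrow(E_star)
  }, numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - r), 3 * se)
})

test_that("the expected-sparsity formula has the stated limits and values", {
  expect_equal(as.numeric(expected_sparsity(1, 2, 2, 5, 5)), 1)
  expect_equal(as.numeric(expected_sparsity(0, 5, 5, 5, 5)), 0)
  e <- expected_sparsity(0.98, 2, 2, 5, 5)
  expect_equal(as.numeric(e), 1 - 0.02 * 8 / 125)
  expect_equal(attr(e, "p1"), 8 / 125)
})

test_that("datasets are reproducible and carry consistent ground truth", {
  cfg <- synthetic_config(n_drugs = 40, n_side_effects = 12, K_D = 4, K_S = 4,
                          M = 2, N1 = 2, N2 = 2, r = 0.01, seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$graph$edges, d2$graph$edges)
  expect_identical(d1$features, d2$features)
  expect_equal(nrow(d1$graph$edges), nrow(d1$truth$E_star))
  expect_equal(d1$achieved_sparsity, data_sparsity(d1$graph))
  # write/reload round trip through the standard TSVs
  td <- withr::local_tempdir()
  write_synthetic_dataset(d1, td)
  back <- load_hypergraph(file.path(td, "triples.tsv"),
                          file.path(td, "features.tsv"), header = TRUE)
  expect_equal(nrow(back$graph$edges), nrow(d1$graph$edges))
  expect_equal(unname(back$features[d1$graph$drug_ids, ]),
               unname(d1$features), tolerance = 1e-6)
})

test_that("calibration lands the achieved sparsity near the target", {
  cfg <- synthetic_config(n_drugs = 100, n_side_effects = 60, K_D = 5,
                          K_S = 5, seed = 5)
  cal <- calibrate_generator(cfg, target = 0.98)
  expect_lt(abs(cal$achieved - 0.98), 0.005)
  expect_equal(generate_dataset(cal$config)$achieved_sparsity, cal$achieved)
})
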