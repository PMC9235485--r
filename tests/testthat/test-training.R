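test_that("fitting ascends the objective and is seed-deterministic", {
  inst <- toy_instance(n_d = 8, n_s = 3, n_e = 20, seed = 30)
  cfg <- train_config(variant = "SPARSEO", latent_dim = 3, n_layers = 1,
                      epochs = 120, seed = 5)
  m1 <- sparse_fit(inst$G, inst$F_d, cfg)
  # ascent sanity after a short burn-in (fresh negatives add noise)
  tr <- m1$trace
  expect_gte(tail(tr$objective, 1), tr$objective[10])
  m2 <- sparse_fit(inst$G, inst$F_d, cfg)
  expect_identical(m1$B, m2$B)
  expect_identical(m1$Hd, m2$Hd)
  expect_true(all(m1$B >= 0) && all(m1$Hd >= 0) && all(m1$Hs >= 0))
})

test_that("predictions are symmetric, order-preserving and model-consistent", {
  inst <- toy_instance(n_d = 8, n_s = 3, n_e = 18, seed = 31)
  cfg <- train_config(variant = "SPARSEO", latent_dim = 3, n_layers = 1,
                      epochs = 60, seed = 6)
  m <- sparse_fit(inst$G, inst$F_d, cfg)
  trips <- rbind(c(1, 5, 2), c(3, 7, 1), c(2, 4, 3))
  swapped <- trips[, c(2, 1, 3)]
  expect_equal(predict_scores(m, trips), predict_scores(m, swapped))
  # agrees with the tensor-ops scorer on the extracted (B, H)
  want <- vapply(1:3, function(r)
    triple_score(m$B, m$Hd[trips[r, 1], ], m$Hd[trips[r, 2], ],
                 m$Hs[trips[r, 3], ]), numeric(1))
  expect_equal(predict_scores(m, trips), want, tolerance = 1e-12)
  # id-based interface and unknown-id error
  byid <- cbind(m$drug_ids[trips[, 1]], m$drug_ids[trips[, 2]],
                m$side_effect_ids[trips[, 3]])
  expect_equal(predict_scores(m, byid), predict_scores(m, trips))
  expect_error(predict_scores(m, cbind("nope", m$drug_ids[2],
                                       m$side_effect_ids[1])), "nope")
})

test_that("ranking returns non-edges sorted by score with lexicographic ties", {
  inst <- toy_instance(n_d = 6, n_s = 2, n_e = 10, seed = 32)
  cfg <- train_config(variant = "SPARSEO", latent_dim = 2, n_layers = 1,
                      epochs = 40, seed = 7)
  m <- sparse_fit(inst$G, inst$F_d, cfg)
  n_unknown <- 6 * 5 / 2 * 2 - nrow(inst$G$edges)
  top <- rank_unknown_triples(m, top_n = 1000)
  expect_equal(nrow(top), n_unknown)       # top_n larger than the universe
  expect_true(all(diff(top$score) <= 1e-12))
  # none of the returned triples is a known edge
  idx <- cbind(match(top$drug_a, m$drug_ids), match(top$drug_b, m$drug_ids),
               match(top$side_effect, m$side_effect_ids))
  expect_true(all(edge_indicator(inst$G, idx) == 0L))
})

test_that("checkpoints round-trip predictions bit-exactly", {
  inst <- toy_instance(n_d = 7, n_s = 3, n_e = 15, seed = 33)
  cfg <- train_config(variant = "SPARSE", latent_dim = 3, n_layers = 1,
                      epochs = 50, tau = 0.05, seed = 8)
  m <- sparse_fit(inst$G, inst$F_d, cfg)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  trips <- sample_non_edges(inst$G, 10, seed = 1)
  expect_identical(predict_scores(m, trips), predict_scores(m2, trips))
  expect_true(all(m$Lambda > 0))
})

test_that("the horseshoe variant prunes at least as hard as no prior", {
  ds <- generate_dataset(synthetic_config(n_drugs = 40, n_side_effects = 15,
                                          K_D = 3, K_S = 3, M = 1, N1 = 1,
                                          N2 = 2, r = 0, seed = 40))
  cfgO <- train_config(variant = "SPARSEO", latent_dim = 3, n_layers = 1,
                       epochs = 150, seed = 9)
  cfgH <- cfgO; cfgH$variant <- "SPARSE"; cfgH$tau <- 0.02
  mO <- sparse_fit(ds$graph, ds$features, cfgO)
  mH <- sparse_fit(ds$graph, ds$features, cfgH)
  expect_gte(sum(abs(mH$B) < 1e-3), sum(abs(mO$B) < 1e-3))
})

test_that("divergent optimization aborts with a diagnostic", {
  inst <- toy_instance(n_d = 6, n_s = 2, n_e = 8, seed = 34)
  cfg <- train_config(variant = "SPARSEO", latent_dim = 2, n_layers = 1,
                      epochs = 5, seed = 10, b_init = 30, sigma = 1e-300)
  expect_error(sparse_fit(inst$G, inst$F_d, cfg), "diverged|finite")
})
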