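test_that("triple log-likelihood is the Gaussian residual density", {
  expect_equal(triple_log_likelihood(1, 1, 1), log(1 / sqrt(2 * pi)))
  expect_equal(triple_log_likelihood(0, 1, 1), log(1 / sqrt(2 * pi)) - 0.5)
  withr::local_seed(1)
  sc <- rnorm(50); lab <- rbinom(50, 1, 0.5); sg <- runif(1, 0.5, 2)
  expect_equal(triple_log_likelihood(sc, lab, sg),
               dnorm(lab - sc, sd = sg, log = TRUE))
  expect_error(triple_log_likelihood(0, 1, 0), "positive")
})

test_that("exhaustive reconstruction likelihood equals the loop-everything oracle", {
  withr::local_seed(2)
  inst <- toy_instance(n_d = 4, n_s = 2, n_e = 5, seed = 7)
  B <- rand_tensor(3, 3, 3)
  Hd <- matrix(runif(4 * 3), 4, 3); Hs <- matrix(runif(2 * 3), 2, 3)
  sf <- function(trips) sparseddi:::score_triples(B, Hd, Hs, trips)
  cfg <- objective_config(exhaustive = TRUE)
  got <- reconstruction_log_likelihood(inst$G, sf, cfg)
  expect_equal(as.numeric(got), oracle_exhaustive_ll(inst$G, sf),
               tolerance = 1e-10)
  expect_equal(attr(got, "n_terms"), 4 * 3 / 2 * 2)
  # sampled mode evaluates exactly (1 + neg_ratio) |E| terms
  cfg2 <- objective_config(neg_ratio = 2, neg_seed = 3)
  got2 <- reconstruction_log_likelihood(inst$G, sf, cfg2)
  expect_equal(attr(got2, "n_terms"), 3L * nrow(inst$G$edges))
})

test_that("horseshoe log-prior matches closed forms and curvature", {
  N <- 8
  B0 <- array(0, c(2, 2, 2)); L1 <- array(1, c(2, 2, 2))
  expect_equal(horseshoe_log_prior(B0, L1, tau = 0.5), -N * log(2))
  # quadratic decrease in the scale of B (finite-difference curvature)
  withr::local_seed(3)
  B <- rand_tensor(2, 2, 2); L <- array(runif(8, 0.5, 2), c(2, 2, 2))
  tau <- 0.3
  f <- function(s) horseshoe_log_prior(s * B, L, tau)
  drop12 <- f(1) - f(2)
  expect_equal(drop12, 3 / 2 * sum((B / (tau * L))^2), tolerance = 1e-10)
  # half-Cauchy density normalizes over [0, Inf)
  expect_equal(integrate(function(l) 2 / pi / (1 + l^2), 0, Inf)$value, 1,
               tolerance = 1e-8)
  # zero local scale with nonzero coefficient is impossible
  L0 <- L; L0[1] <- 0; Bnz <- B; Bnz[1] <- 1
  expect_equal(horseshoe_log_prior(Bnz, L0, tau), -Inf)
})

test_that("laplace log-prior is the L1 penalty", {
  expect_equal(laplace_log_prior(array(0, c(2, 2, 2)), 1), 0)
  expect_equal(laplace_log_prior(array(1, c(2, 2, 2)), 1), -8)
  withr::local_seed(4)
  B <- rand_tensor(3, 2, 2) - 0.5
  sc <- runif(1, 0.2, 2)
  expect_equal(laplace_log_prior(B, sc), -sum(abs(B)) / sc)
})

test_that("the MAP objective adds the selected prior to the likelihood", {
  withr::local_seed(5)
  inst <- toy_instance(n_d = 5, n_s = 2, n_e = 6, seed = 9)
  B <- rand_tensor(3, 3, 3); L <- array(runif(27, 0.5, 2), c(3, 3, 3))
  Hd <- matrix(runif(5 * 3), 5, 3); Hs <- matrix(runif(2 * 3), 2, 3)
  sf <- function(trips) sparseddi:::score_triples(B, Hd, Hs, trips)
  cfg0 <- objective_config(prior_kind = "none", exhaustive = TRUE)
  cfgH <- objective_config(prior_kind = "horseshoe", tau = 0.1,
                           exhaustive = TRUE)
  cfgL <- objective_config(prior_kind = "laplace", tau = 0.1,
                           exhaustive = TRUE)
  o0 <- map_objective(inst$G, sf, B, config = cfg0)
  expect_equal(as.numeric(o0), attr(o0, "likelihood"))
  oH <- map_objective(inst$G, sf, B, Lambda = L, config = cfgH)
  expect_equal(as.numeric(oH),
               attr(o0, "likelihood") + horseshoe_log_prior(B, L, 0.1))
  oL <- map_objective(inst$G, sf, B, config = cfgL)
  expect_equal(as.numeric(oL),
               attr(o0, "likelihood") + laplace_log_prior(B, 0.1))
  # prior terms here are negative, so regularized objectives are smaller
  expect_lt(as.numeric(oH), as.numeric(o0))
  expect_lt(as.numeric(oL), as.numeric(o0))
})

test_that("full-model gradients match central finite differences", {
  withr::local_seed(6)
  inst <- toy_instance(n_d = 6, n_s = 3, n_e = 8, seed = 11)
  gs <- sparseddi:::build_graph_struct(inst$G)
  relist_par <- function(flat, skel) {
    pos <- 0
    rec <- function(x) {
      if (is.list(x)) return(lapply(x, rec))
      n <- length(x); v <- flat[(pos + 1):(pos + n)]; pos <<- pos + n
      if (!is.null(dim(x))) dim(v) <- dim(x)
      v
    }
    rec(skel)
  }
  for (pk in c("none", "laplace", "horseshoe")) {
    cfg <- encoder_config(latent_dim = 3, n_layers = 2, b_init = -1)
    par <- sparseddi:::init_encoder_params(gs, ncol(inst$F_d), cfg, seed = 13)
    if (pk == "horseshoe")
      par$lambda_log <- array(rnorm(27, sd = 0.3), c(3, 3, 3))
    trips <- rbind(inst$G$edges, sample_non_edges(inst$G, 6, seed = 3))
    labs <- c(rep(1, nrow(inst$G$edges)), rep(0, 6))
    f <- function(p) sparseddi:::model_objective_grad(
      p, gs, inst$F_d, cfg, trips, labs, sigma = 1, prior_kind = pk,
      tau = 0.05, laplace_scale = 0.05, want_grad = FALSE)$value
    res <- sparseddi:::model_objective_grad(
      par, gs, inst$F_d, cfg, trips, labs, sigma = 1, prior_kind = pk,
      tau = 0.05, laplace_scale = 0.05)
    gflat <- unlist(sparseddi:::align_grads(par, res$grads))
    flat <- unlist(par)
    idx <- sort(sample(length(flat), 40))
    eps <- 1e-5
    num <- vapply(idx, function(i) {
      p1 <- flat; p1[i] <- p1[i] + eps
      p2 <- flat; p2[i] <- p2[i] - eps
      (f(relist_par(p1, par)) - f(relist_par(p2, par))) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - gflat[idx]) / (1 + abs(num))), 1e-6)
    expect_true(all(is.finite(gflat)))
  }
})

test_that("shrinkage factors are clipped relative reductions", {
  withr::local_seed(7)
  B <- rand_tensor(3, 3, 2) + 0.1
  expect_true(all(shrinkage_profile(B, B)$kappa == 0))
  expect_true(all(shrinkage_profile(B * 0, B)$kappa == 1))
  Bz <- B; Bz[1, 1, 1] <- 0
  pr <- shrinkage_profile(B, Bz)
  expect_equal(pr$n_excluded, 1L)
  expect_equal(length(pr$kappa), length(B) - 1L)
})
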