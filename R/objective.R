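# Reconstruction likelihood, sparsity priors and the MAP objective.
#
# Each triple's reconstruction likelihood is Gaussian in the residual
# between the membership indicator i(e) in {0, 1} and the model score m(e);
# scores are used raw (no link function).  The full product over every
# canonical triple is intractable at real scale, so the default evaluates
# all positives plus seeded uniformly sampled negatives (neg_ratio per
# positive, redrawn each epoch); an exhaustive mode evaluates the literal
# product on small instances.

#' Objective configuration
#'
#' @param sigma Gaussian likelihood scale (> 0).  Fixed at 1 by default; it
#'   only rescales the likelihood/prior trade-off.
#' @param prior_kind sparsity prior on the interaction tensor: `"none"`
#'   (variant SPARSEO), `"laplace"` (SPARSEL) or `"horseshoe"` (SPARSE).
#' @param tau global scale of the horseshoe prior (> 0); also reused as the
#'   Laplace scale so the two sparse variants share one hyperparameter grid.
#' @param laplace_scale Laplace prior scale; defaults to `tau`.
#' @param neg_ratio negatives sampled per positive (>= 1).
#' @param neg_seed integer seed for negative sampling.
#' @param exhaustive evaluate every canonical triple instead of sampling
#'   negatives; refused above `exhaustive_limit` triples.
#' @param exhaustive_limit size guard for the exhaustive mode.
#' @return list of class `objective_config`.
#' @export
objective_config <- function(sigma = 1, prior_kind = c("none", "laplace", "horseshoe"),
                             tau = 0.02, laplace_scale = NULL, neg_ratio = 1L,
                             neg_seed = 1L, exhaustive = FALSE,
                             exhaustive_limit = 2e5) {
  if (sigma <= 0) stop_sparseddi("sigma must be positive")
  prior_kind <- match.arg(prior_kind)
  if (tau <= 0) stop_sparseddi("tau must be positive")
  neg_ratio <- as.integer(neg_ratio)
  if (neg_ratio < 1L) stop_sparseddi("neg_ratio must be >= 1")
  structure(list(sigma = sigma, prior_kind = prior_kind, tau = tau,
                 laplace_scale = laplace_scale %||% tau,
                 neg_ratio = neg_ratio, neg_seed = as.integer(neg_seed),
                 exhaustive = exhaustive, exhaustive_limit = exhaustive_limit),
            class = "objective_config")
}

#' Gaussian log-likelihood of a scored triple
#'
#' Log density of the residual `label - score` under a centered Gaussian of
#' scale `sigma`.
#'
#' @param score model score(s) m(e).
#' @param label membership indicator(s) i(e), 0 or 1.
#' @param sigma Gaussian scale (> 0).
#' @return log-likelihood, vectorized over inputs.
#' @export
triple_log_likelihood <- function(score, label, sigma = 1) {
  if (sigma <= 0) stop_sparseddi("sigma must be positive")
  stats::dnorm(label - score, mean = 0, sd = sigma, log = TRUE)
}

# Assemble the triple set the likelihood is evaluated on.  Returns a list
# with `triples` and `labels`; exhaustive mode enumerates everything.
likelihood_triples <- function(G, config, seed = NULL) {
  pos <- G$edges
  if (config$exhaustive) {
    nd <- n_drugs(G); ns <- n_side_effects(G)
    total <- nd * (nd - 1) / 2 * ns
    if (total > config$exhaustive_limit)
      stop_sparseddi("triple universe too large for exhaustive likelihood")
    all_t <- enumerate_canonical_triples(nd, ns)
    list(triples = all_t, labels = edge_indicator(G, all_t))
  } else {
    n_neg <- nrow(pos) * config$neg_ratio
    neg <- sample_non_edges(G, n_neg, seed = seed)
    list(triples = rbind(pos, neg),
         labels = c(rep(1L, nrow(pos)), rep(0L, n_neg)))
  }
}

#' Reconstruction log-likelihood of a hypergraph
#'
#' Sum of [triple_log_likelihood()] over the evaluated triple set: all
#' positives plus sampled negatives (default) or every canonical triple
#' (`exhaustive = TRUE` in the config).
#'
#' @param G a [ddi_hypergraph()].
#' @param score_fun function taking a triple matrix (u, v, t) and returning
#'   scores, e.g. a closure over a trained model.
#' @param config an [objective_config()].
#' @return scalar log-likelihood, with the evaluated triple count as
#'   attribute `n_terms`.
#' @export
reconstruction_log_likelihood <- function(G, score_fun, config = objective_config()) {
  ev <- likelihood_triples(G, config, seed = config$neg_seed)
  ll <- sum(triple_log_likelihood(score_fun(ev$triples), ev$labels, config$sigma))
  attr(ll, "n_terms") <- nrow(ev$triples)
  ll
}

#' Horseshoe log-prior of the interaction tensor
#'
#' `sum(-(B/(tau*Lambda))^2/2 - log(Lambda)) + sum(log(1/(1 + Lambda^2)))`,
#' i.e. the Gaussian scale-mixture term plus the half-Cauchy log-density of
#' the local scales, with additive constants dropped.
#'
#' @param B interaction tensor.
#' @param Lambda local scales, same shape as `B`, strictly positive (a zero
#'   local scale with a nonzero coefficient gives `-Inf`).
#' @param tau global scale (> 0).
#' @return scalar log-prior.
#' @export
horseshoe_log_prior <- function(B, Lambda, tau) {
  if (tau <= 0) stop_sparseddi("tau must be positive")
  if (any(Lambda < 0)) stop_sparseddi("Lambda must be nonnegative")
  if (any(Lambda == 0)) {
    if (any(B[Lambda == 0] != 0)) return(-Inf)
  }
  L <- pmax(Lambda, .Machine$double.xmin)
  sum(-0.5 * (B / (tau * L))^2 - log(L)) + sum(-log1p(Lambda^2))
}

#' Laplace log-prior of the interaction tensor
#'
#' `-sum(|B|)/scale` (constant dropped): the L1 penalty behind Lasso
#' regularization.
#'
#' @param B interaction tensor.
#' @param scale Laplace scale (> 0).
#' @return scalar log-prior.
#' @export
laplace_log_prior <- function(B, scale) {
  if (scale <= 0) stop_sparseddi("scale must be positive")
  -sum(abs(B)) / scale
}

#' MAP objective
#'
#' Reconstruction log-likelihood plus the configured sparsity prior term:
#' none (SPARSEO), Laplace (SPARSEL) or horseshoe (SPARSE).  The returned
#' value is to be maximized.
#'
#' @param G a [ddi_hypergraph()].
#' @param score_fun scoring closure as in [reconstruction_log_likelihood()].
#' @param B interaction tensor.
#' @param Lambda horseshoe local scales (required for the horseshoe prior).
#' @param config an [objective_config()].
#' @return scalar objective with attributes `likelihood` and `prior`.
#' @export
map_objective <- function(G, score_fun, B, Lambda = NULL,
                          config = objective_config()) {
  ll <- as.numeric(reconstruction_log_likelihood(G, score_fun, config))
  pr <- switch(config$prior_kind,
               none = 0,
               laplace = laplace_log_prior(B, config$laplace_scale),
               horseshoe = {
                 if (is.null(Lambda)) stop_sparseddi("horseshoe prior needs Lambda")
                 horseshoe_log_prior(B, Lambda, config$tau)
               })
  out <- ll + pr
  attr(out, "likelihood") <- ll
  attr(out, "prior") <- pr
  out
}

#' Shrinkage factors between a regularized and an unregularized fit
#'
#' Per-entry `kappa = 1 - B_map/B_ml`, clipped into \[0, 1\]: 0 means no
#' shrinkage, 1 complete shrinkage.  Entries where the unregularized
#' coefficient is (numerically) zero are excluded and counted.  The
#' horseshoe characteristically piles mass near both 0 and 1, while the
#' Laplace prior concentrates near 1 only; `mass_low` (fraction of kappa in
#' \[0, 0.1\]) summarizes that contrast.
#'
#' @param B_map tensor fitted under a sparsity prior.
#' @param B_ml tensor fitted without a prior, same shape.
#' @param zero_tol entries of `B_ml` at or below this magnitude are excluded.
#' @return list with `kappa` (vector), `n_excluded`, and `mass_low`.
#' @export
shrinkage_profile <- function(B_map, B_ml, zero_tol = 1e-12) {
  if (!identical(dim(B_map), dim(B_ml)))
    stop_sparseddi("tensor shapes differ")
  ok <- abs(B_ml) > zero_tol
  kappa <- 1 - B_map[ok] / B_ml[ok]
  kappa <- pmin(pmax(kappa, 0), 1)
  list(kappa = kappa, n_excluded = sum(!ok),
       mass_low = if (length(kappa)) mean(kappa <= 0.1) else NA_real_)
}
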