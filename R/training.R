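# Model fitting by MAP gradient ascent, prediction and checkpointing.
#
# The three variants share one architecture and differ only in the sparsity
# prior on the interaction tensor: SPARSE (horseshoe), SPARSEL (Laplace),
# SPARSEO (none).  Optimization is full-batch adaptive gradient ascent
# (Adam) on the sampled-negative MAP objective, with fresh negatives drawn
# every epoch; horseshoe local scales are optimized jointly through the
# unconstrained parameterization Lambda = exp(lambda).

#' Training configuration
#'
#' @param variant `"SPARSE"` (horseshoe prior), `"SPARSEL"` (Laplace) or
#'   `"SPARSEO"` (no prior).
#' @param latent_dim latent feature size, shared by all layers.  The
#'   reference grid is 30/40/50/60 for real-scale data; synthetic planted
#'   regimes typically match the generator's latent dimension.
#' @param n_layers number of message-passing layers (reference grid 1-3).
#' @param tau global sparsity scale (reference grid 0.01-0.1); also the
#'   Laplace scale for SPARSEL.
#' @param learning_rate Adam step size.
#' @param lr_decay multiplicative decay applied to the step size late in
#'   training (1 = constant); helps the final parameters settle despite the
#'   per-epoch resampling of negatives.
#' @param lr_decay_from fraction of the epoch budget after which the decayed
#'   step size applies.
#' @param epochs number of epochs (one pass over positives plus fresh
#'   negatives each).
#' @param batches number of minibatch updates per epoch; stochastic updates
#'   escape the poor basins a single full-batch step per epoch can settle
#'   into.
#' @param seed integer seed governing initialization and negative sampling.
#' @param neg_ratio negatives sampled per positive each epoch.
#' @param sigma Gaussian likelihood scale.
#' @param activation,b_parameterization,hidden_dim,b_init passed to
#'   [encoder_config()].
#' @return list of class `train_config`.
#' @export
train_config <- function(variant = c("SPARSE", "SPARSEL", "SPARSEO"),
                         latent_dim = 50L, n_layers = 2L, tau = 0.02,
                         learning_rate = 1e-2, lr_decay = 0.2,
                         lr_decay_from = 0.7, epochs = 500L, batches = 2L,
                         seed = 1L,
                         neg_ratio = 1L, sigma = 1,
                         activation = "leaky_relu",
                         b_parameterization = "free_parameter",
                         hidden_dim = NULL, b_init = NULL) {
  variant <- match.arg(variant)
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop_sparseddi("epochs must be >= 1")
  if (learning_rate <= 0) stop_sparseddi("learning_rate must be positive")
  if (tau <= 0) stop_sparseddi("tau must be positive")
  structure(list(variant = variant, latent_dim = as.integer(latent_dim),
                 n_layers = as.integer(n_layers), tau = tau,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 lr_decay_from = lr_decay_from, epochs = epochs,
                 batches = max(1L, as.integer(batches)),
                 seed = as.integer(seed), neg_ratio = as.integer(neg_ratio),
                 sigma = sigma, activation = activation,
                 b_parameterization = b_parameterization,
                 hidden_dim = hidden_dim, b_init = b_init),
            class = "train_config")
}

prior_kind_of <- function(variant) {
  switch(variant, SPARSE = "horseshoe", SPARSEL = "laplace", SPARSEO = "none")
}

# Recursive Adam ascent step over arbitrarily nested parameter lists.
adam_zero <- function(par) rapply(par, function(x) x * 0, how = "replace")

adam_step <- function(par, gr, m, v, step, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  rec <- function(p, g, mm, vv) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], mm[[i]], vv[[i]])
        p[[i]] <- r[[1]]; mm[[i]] <- r[[2]]; vv[[i]] <- r[[3]]
      }
      list(p, mm, vv)
    } else {
      mm <- b1 * mm + (1 - b1) * g
      vv <- b2 * vv + (1 - b2) * g * g
      mhat <- mm / (1 - b1^step)
      vhat <- vv / (1 - b2^step)
      list(p + lr * mhat / (sqrt(vhat) + eps), mm, vv)  # ascent
    }
  }
  rec(par, gr, m, v)
}

# Reorder the gradient list to mirror the parameter structure exactly
# (recursively, by name where names exist), filling absent fields with
# zeros so the optimizer state lines up element by element.
align_grads <- function(par, gr) {
  rec <- function(p, g) {
    if (!is.list(p)) return(g %||% (p * 0))
    nms <- names(p)
    out <- p
    for (i in seq_along(p)) {
      gi <- if (!is.null(nms) && nzchar(nms[i])) g[[nms[i]]] else g[[i]]
      out[[i]] <- rec(p[[i]], gi)
    }
    out
  }
  rec(par, gr)
}

#' Fit a sparse hypergraph interaction model
#'
#' Maximizes the MAP objective (reconstruction log-likelihood plus the
#' variant's prior) by full-batch Adam ascent, drawing `neg_ratio` fresh
#' uniform negatives per positive each epoch.  Deterministic given
#' `config$seed`.
#'
#' @param G a [ddi_hypergraph()] (nonempty).
#' @param F_d nonnegative drug feature matrix aligned to `G$drug_ids`.
#' @param config a [train_config()].
#' @param trace_every record the objective every this many epochs.
#' @return object of class `sparse_ddi_model`: learned parameters, final
#'   latent matrices `Hd`/`Hs`, interaction tensor `B`, horseshoe scales
#'   `Lambda` (SPARSE only), the objective `trace` data frame, config and
#'   vocabularies.
#' @export
sparse_fit <- function(G, F_d, config = train_config(), trace_every = 1L) {
  if (nrow(G$edges) == 0L) stop_sparseddi("cannot fit an empty hypergraph")
  if (nrow(F_d) != n_drugs(G))
    stop_sparseddi("feature matrix rows do not match drug vocabulary")
  enc_cfg <- encoder_config(latent_dim = config$latent_dim,
                            n_layers = config$n_layers,
                            activation = config$activation,
                            b_parameterization = config$b_parameterization,
                            hidden_dim = config$hidden_dim,
                            b_init = config$b_init)
  gs <- build_graph_struct(G)
  prior_kind <- prior_kind_of(config$variant)
  pos <- G$edges
  n_neg <- nrow(pos) * config$neg_ratio
  trace <- list()

  withr::with_seed(config$seed, {
    par <- init_encoder_params(gs, ncol(F_d), enc_cfg, seed = NULL)
    if (prior_kind == "horseshoe")
      # local scales start at Lambda = 1/tau so the initial per-cell prior
      # sd (tau * Lambda) is 1: a weakly informative start that lets the
      # likelihood grow genuine signal before the scales adapt downward
      par$lambda_log <- array(log(1 / config$tau),
                              dim(par$B_raw) %||% rep(config$latent_dim, 3))
    m <- adam_zero(par); v <- adam_zero(par)
    nb <- config$batches
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      neg <- sample_non_edges(G, n_neg, seed = NULL)
      triples <- rbind(pos, neg)
      labels <- c(rep(1, nrow(pos)), rep(0, n_neg))
      perm <- sample.int(nrow(triples))
      chunks <- split(perm, rep(seq_len(nb), length.out = length(perm)))
      lr_ep <- if (ep > config$lr_decay_from * config$epochs)
        config$learning_rate * (config$lr_decay %||% 1)
      else config$learning_rate
      ep_lik <- 0; ep_prior <- NA_real_
      for (ch in chunks) {
        res <- model_objective_grad(par, gs, F_d, enc_cfg,
                                    triples[ch, , drop = FALSE], labels[ch],
                                    sigma = config$sigma,
                                    prior_kind = prior_kind, tau = config$tau,
                                    laplace_scale = config$tau,
                                    prior_weight = 1 / nb)
        if (!is.finite(res$value))
          stop_sparseddi(sprintf("objective diverged (non-finite) at epoch %d", ep))
        step <- step + 1L
        gr <- align_grads(par, res$grads)
        st <- adam_step(par, gr, m, v, step = step, lr = lr_ep)
        par <- st[[1]]; m <- st[[2]]; v <- st[[3]]
        ep_lik <- ep_lik + res$likelihood
        ep_prior <- res$prior * nb
      }
      if (ep %% trace_every == 0L || ep == config$epochs)
        trace[[length(trace) + 1L]] <-
          data.frame(epoch = ep, likelihood = ep_lik,
                     prior = ep_prior, objective = ep_lik + ep_prior)
    }
  })

  fw <- encoder_forward(par, gs, F_d, enc_cfg)
  structure(list(par = par, config = config, enc_cfg = enc_cfg,
                 drug_ids = G$drug_ids, side_effect_ids = G$side_effect_ids,
                 edges = G$edges, F_d = F_d,
                 Hd = fw$Hd, Hs = fw$Hs, B = fw$B,
                 Lambda = if (prior_kind == "horseshoe") exp(par$lambda_log),
                 trace = do.call(rbind, trace)),
            class = "sparse_ddi_model")
}

#' @export
print.sparse_ddi_model <- function(x, ...) {
  cat(sprintf("%s model: %d drugs, %d side effects, latent dim %d, %d layers\n",
              x$config$variant, length(x$drug_ids), length(x$side_effect_ids),
              x$config$latent_dim, x$config$n_layers))
  tr <- utils::tail(x$trace, 1)
  cat(sprintf("final objective %.2f (likelihood %.2f, prior %.2f) after %d epochs\n",
              tr$objective, tr$likelihood, tr$prior, tr$epoch))
  invisible(x)
}

# Resolve triples given as ids or indices into an index matrix.
resolve_triples <- function(model, triples) {
  if (is.data.frame(triples)) triples <- as.matrix(triples)
  if (is.character(triples)) {
    u <- match(triples[, 1], model$drug_ids)
    v <- match(triples[, 2], model$drug_ids)
    t <- match(triples[, 3], model$side_effect_ids)
    bad <- which(is.na(u) | is.na(v) | is.na(t))
    if (length(bad)) {
      row <- triples[bad[1], ]
      miss <- c(row[1][is.na(u[bad[1]])], row[2][is.na(v[bad[1]])],
                row[3][is.na(t[bad[1]])])
      stop_sparseddi("unknown identifier: ", miss[1])
    }
    cbind(u, v, t)
  } else {
    storage.mode(triples) <- "integer"
    if (any(triples[, 1:2] < 1L) || any(triples[, 1:2] > length(model$drug_ids)) ||
        any(triples[, 3] < 1L) || any(triples[, 3] > length(model$side_effect_ids)))
      stop_sparseddi("triple index out of range")
    triples
  }
}

#' Predict interaction scores for triples
#'
#' Symmetrized tensor-contraction scores from the trained model's latent
#' snapshot; invariant to drug order and order-preserving with the input.
#'
#' @param model a fitted [sparse_fit()] model.
#' @param triples matrix or data frame of triples, either identifier strings
#'   or 1-based indices, columns (drug A, drug B, side effect).
#' @return numeric vector of scores.
#' @export
predict_scores <- function(model, triples) {
  idx <- resolve_triples(model, triples)
  score_triples(model$B, model$Hd, model$Hs, idx, symmetrize = TRUE)
}

#' Rank unknown triples by predicted score
#'
#' Enumerates canonical non-edges (or uniformly samples `sample_size` of
#' them above the enumeration guard), scores them, and returns the top
#' `top_n` in descending score order, ties broken by lexicographic (u, v, t)
#' order so the ranking is deterministic.
#'
#' @param model a fitted model.
#' @param top_n number of predictions to return.
#' @param enumerate_limit maximum universe size enumerated exhaustively.
#' @param sample_size pool size drawn when the universe exceeds the limit.
#' @param seed seed for the sampled mode.
#' @return data frame: drug_a, drug_b, side_effect, score, sorted.
#' @export
rank_unknown_triples <- function(model, top_n = 100L, enumerate_limit = 2e6,
                                 sample_size = 1e6, seed = 1L) {
  if (top_n < 1L) stop_sparseddi("top_n must be >= 1")
  G <- ddi_hypergraph(model$drug_ids, model$side_effect_ids, model$edges)
  nd <- n_drugs(G); ns <- n_side_effects(G)
  total <- nd * (nd - 1) / 2 * ns
  n_unknown <- total - nrow(G$edges)
  if (total <= enumerate_limit) {
    all_t <- enumerate_canonical_triples(nd, ns)
    unknown <- all_t[edge_indicator(G, all_t) == 0L, , drop = FALSE]
  } else {
    unknown <- sample_non_edges(G, min(sample_size, n_unknown), seed = seed)
  }
  sc <- predict_scores(model, unknown)
  ord <- order(-sc, unknown[, 1], unknown[, 2], unknown[, 3])
  take <- utils::head(ord, top_n)
  data.frame(drug_a = model$drug_ids[unknown[take, 1]],
             drug_b = model$drug_ids[unknown[take, 2]],
             side_effect = model$side_effect_ids[unknown[take, 3]],
             score = sc[take], stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' Single-file archive of the parameters, configuration and vocabularies;
#' a load/predict round trip reproduces scores bit-exactly.
#'
#' @param model a fitted model.
#' @param path checkpoint path.
#' @return `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sparse_ddi_model"))
    stop_sparseddi("not a sparseddi checkpoint")
  model
}

#' Grid search over the reference hyperparameter grids
#'
#' Reruns [cross_validate()] over the requested grid and reports the mean
#' metrics per combination plus the best by mean AUC.
#'
#' @param G,F_d data as in [sparse_fit()].
#' @param base_config a [train_config()] supplying everything not on a grid.
#' @param latent_dims,taus,n_layers grids to sweep.
#' @param k folds; passed to [cross_validate()].
#' @param ... further arguments to [cross_validate()].
#' @return list with `results` (one row per combination) and `best`.
#' @export
grid_search <- function(G, F_d, base_config = train_config(),
                        latent_dims = c(30L, 40L, 50L, 60L),
                        taus = c(0.01, 0.02, 0.03, 0.05, 0.1),
                        n_layers = 1:3, k = 20L, ...) {
  grid <- expand.grid(latent_dim = latent_dims, tau = taus,
                      n_layers = n_layers)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_config
    cfg$latent_dim <- grid$latent_dim[i]
    cfg$tau <- grid$tau[i]
    cfg$n_layers <- grid$n_layers[i]
    cv <- cross_validate(G, F_d, cfg, k = k, ...)
    cbind(grid[i, , drop = FALSE],
          auc = cv$summary$auc_mean, aupr = cv$summary$aupr_mean)
  })
  results <- do.call(rbind, rows)
  list(results = results, best = results[which.max(results$auc), ])
}
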