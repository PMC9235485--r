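# Message-passing hypergraph encoder.
#
# Drug nodes carry observable features; side-effect nodes carry one-hot
# features, realized as a learned embedding row per side effect.  Each
# message-passing layer sends, for every node a and every incident hyperedge
# e, one message that sums a two-layer feedforward map over the co-members b
# of e (including b = a), applied to (c(a), c(b), h(a), h(b)) where c is the
# node type (+1 drug, -1 side effect).  Messages are aggregated across
# incident hyperedges by their arithmetic mean and passed through an
# activation.  Isolated nodes keep their previous state.  A final smooth
# nonnegative emission (softplus) enforces the nonnegative codomain of the
# latent matrices.

#' Encoder configuration
#'
#' @param latent_dim size of the latent space, shared by all layers and by
#'   drugs and side effects.
#' @param n_layers number of message-passing layers (>= 1).
#' @param aggregation message aggregation across incident hyperedges;
#'   currently the arithmetic mean.
#' @param activation hidden-layer activation: `"leaky_relu"` (default;
#'   rectifier with a small negative-side slope so units cannot die),
#'   `"relu"` or `"softplus"`.  The final emission is always softplus,
#'   which guarantees nonnegative latents.
#' @param b_parameterization how the interaction tensor is produced:
#'   `"free_parameter"` (default; B is a free nonnegative parameter) or
#'   `"network"` (B derived from a pooled graph representation).
#' @param hidden_dim width of the two-layer message network; defaults to
#'   `latent_dim`.
#' @param b_init mean of the raw (pre-softplus) interaction tensor at
#'   initialization.  The default (`NULL`) solves `softplus(b_init) = 2/d^3`
#'   so the summed initial tensor mass, and with it the dense baseline
#'   score, stays O(1) at every latent dimension; early training is then
#'   driven by the positives instead of having to demolish a large baseline.
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(latent_dim = 50L, n_layers = 2L,
                           aggregation = "mean",
                           activation = c("leaky_relu", "relu", "softplus"),
                           b_parameterization = c("free_parameter", "network"),
                           hidden_dim = NULL, b_init = NULL) {
  latent_dim <- as.integer(latent_dim)
  n_layers <- as.integer(n_layers)
  if (latent_dim < 1L) stop_sparseddi("latent_dim must be >= 1")
  if (n_layers < 1L) stop_sparseddi("n_layers must be >= 1")
  aggregation <- match.arg(aggregation, "mean")
  structure(list(latent_dim = latent_dim, n_layers = n_layers,
                 aggregation = aggregation,
                 activation = match.arg(activation),
                 b_parameterization = match.arg(b_parameterization),
                 hidden_dim = as.integer(hidden_dim %||% latent_dim),
                 b_init = b_init %||% log(expm1(2 / latent_dim^3))),
            class = "encoder_config")
}

# Incidence structures reused by forward and backward passes.
# For every hyperedge e = (u, v, t) and ordered slot pair (a, b) in the
# 3 x 3 grid we precompute the node ids and grouping indices.
build_graph_struct <- function(G) {
  nd <- n_drugs(G); ns <- n_side_effects(G)
  n <- nd + ns
  ne <- nrow(G$edges)
  nodes <- cbind(G$edges[, 1], G$edges[, 2], nd + G$edges[, 3])  # ne x 3
  if (ne) {
    # rows ordered: edge e, then slot a, then b over the 3 slots of e
    a_node <- integer(9 * ne); b_node <- integer(9 * ne)
    idx <- seq_len(ne)
    for (a in 1:3) for (b in 1:3) {
      rows <- (idx - 1L) * 9L + (a - 1L) * 3L + b
      a_node[rows] <- nodes[, a]
      b_node[rows] <- nodes[, b]
    }
    group_ea <- rep(seq_len(3 * ne), each = 3L)        # (e, a) group per row
    node_of_ea <- as.vector(t(nodes))                  # node of group (e, a)
    deg <- tabulate(node_of_ea, nbins = n)
  } else {
    a_node <- b_node <- integer(0)
    group_ea <- integer(0); node_of_ea <- integer(0)
    deg <- integer(n)
  }
  cvec <- c(rep(1, nd), rep(-1, ns))
  list(n_drugs = nd, n_side_effects = ns, n = n, n_edges = ne,
       a_node = a_node, b_node = b_node, group_ea = group_ea,
       node_of_ea = node_of_ea, deg = deg, isolated = deg == 0L, cvec = cvec)
}

# Fan-in-scaled normal initialization of all encoder parameters.
init_encoder_params <- function(gs, K0, config, seed = NULL) {
  d <- config$latent_dim; m <- config$hidden_dim
  in_dim <- 2L + 2L * d
  with_seed_or_not(seed, {
    par <- list(
      W_lift = matrix(stats::rnorm(K0 * d, sd = 1 / sqrt(K0)), K0, d),
      b_lift = rep(0, d),
      E_s = matrix(stats::rnorm(gs$n_side_effects * d, sd = 0.5),
                   gs$n_side_effects, d),
      layers = lapply(seq_len(config$n_layers), function(l) list(
        W1 = matrix(stats::rnorm(in_dim * m, sd = 1 / sqrt(in_dim)), in_dim, m),
        b1 = rep(0, m),
        W2 = matrix(stats::rnorm(m * d, sd = 1 / sqrt(m)), m, d),
        b2 = rep(0, d))),
      # raw (pre-softplus) interaction tensor; starts small and nonuniform
      B_raw = array(stats::rnorm(d * d * d, mean = config$b_init, sd = 0.3),
                    c(d, d, d)))
    if (config$b_parameterization == "network") {
      par$W_B <- matrix(stats::rnorm(d^3 * d, sd = 1 / sqrt(d)), d^3, d)
      par$b_B <- rep(config$b_init, d^3)
    }
    par
  })
}

# Forward pass.  Returns H_final (n x d, nonnegative), B (d x d x d,
# nonnegative) and, when keep_cache, everything the backward pass needs.
encoder_forward <- function(par, gs, F_d, config, keep_cache = FALSE) {
  d <- config$latent_dim
  act <- config$activation
  H <- rbind(F_d %*% par$W_lift + rep(par$b_lift, each = gs$n_drugs), par$E_s)
  cache <- list(H0 = H, layers = vector("list", config$n_layers))
  upd <- !gs$isolated
  for (l in seq_len(config$n_layers)) {
    lay <- par$layers[[l]]
    if (gs$n_edges > 0) {
      # The first MLP matmul factors through the (small) node matrix:
      # Z1pre[r, ] = b1 + c(a_r) W1[1,] + c(b_r) W1[2,] + (H W1a)[a_r,] +
      # (H W1b)[b_r,], so only per-node products and row gathers touch the
      # 9|E| pair rows.
      W1a <- lay$W1[3:(2 + d), , drop = FALSE]
      W1b <- lay$W1[(3 + d):(2 + 2 * d), , drop = FALSE]
      An <- H %*% W1a + gs$cvec %o% lay$W1[1, ]
      Bn <- H %*% W1b + gs$cvec %o% lay$W1[2, ]
      Z1pre <- An[gs$a_node, , drop = FALSE] + Bn[gs$b_node, , drop = FALSE] +
        rep(lay$b1, each = length(gs$a_node))
      Z1 <- leaky_relu(Z1pre)
      Mrows <- Z1 %*% lay$W2 + rep(lay$b2, each = nrow(Z1))
      # mean over incident hyperedges == sum over all (a, b) rows of the
      # node's slots divided by its degree (each message is itself a sum)
      aggs <- rowsum(Mrows, gs$a_node, reorder = TRUE)
      touched <- sort(unique(gs$a_node))
      Hpre <- matrix(0, gs$n, d)
      Hpre[touched, ] <- aggs / gs$deg[touched]
      Hnew <- H
      Hnew[upd, ] <- switch(act,
        relu = pmax(Hpre[upd, , drop = FALSE], 0),
        leaky_relu = leaky_relu(Hpre[upd, , drop = FALSE]),
        softplus = softplus(Hpre[upd, , drop = FALSE]))
      if (keep_cache)
        cache$layers[[l]] <- list(H_in = H, Z1pre = Z1pre, Z1 = Z1,
                                  Hpre = Hpre, W1a = W1a, W1b = W1b)
      H <- Hnew
    } else if (keep_cache) {
      cache$layers[[l]] <- list(H_in = H, Z1pre = NULL)
    }
  }
  Hpre_fin <- H
  Hfin <- softplus(H)
  if (config$b_parameterization == "network") {
    pooled <- colMeans(Hfin)
    B_pre <- array(par$W_B %*% pooled + par$b_B, c(d, d, d))
    B <- softplus(B_pre)
  } else {
    B_pre <- par$B_raw
    B <- softplus(B_pre)
  }
  out <- list(H = Hfin, B = B,
              Hd = Hfin[seq_len(gs$n_drugs), , drop = FALSE],
              Hs = Hfin[gs$n_drugs + seq_len(gs$n_side_effects), , drop = FALSE])
  if (keep_cache) {
    cache$Hpre_fin <- Hpre_fin
    cache$B_pre <- B_pre
    out$cache <- cache
  }
  out
}

#' Encode a DDI hypergraph into latent representations
#'
#' Initializes encoder parameters under the seed and runs the forward pass:
#' drug features are lifted linearly into the latent space, side effects get
#' learned embedding rows, `n_layers` message-passing layers refine the
#' states, and a final softplus emission yields the nonnegative latent
#' matrices.  The interaction tensor is a free nonnegative parameter by
#' default (or network-derived, see [encoder_config()]).
#'
#' Mostly useful for inspecting an untrained model; [sparse_fit()] learns
#' the parameters.
#'
#' @param G a [ddi_hypergraph()].
#' @param F_d drug feature matrix aligned to `G$drug_ids`.
#' @param config an [encoder_config()].
#' @param seed integer seed for the parameter initialization.
#' @return list with `Hd` (|V_D| x K), `Hs` (|V_S| x K), `B` (K x K x K),
#'   the parameter list `par` and the incidence structure `gs`.
#' @export
encode <- function(G, F_d, config = encoder_config(), seed = 1L) {
  if (nrow(F_d) != n_drugs(G))
    stop_sparseddi("feature matrix rows do not match drug vocabulary")
  gs <- build_graph_struct(G)
  par <- init_encoder_params(gs, ncol(F_d), config, seed = seed)
  fw <- encoder_forward(par, gs, F_d, config)
  list(Hd = fw$Hd, Hs = fw$Hs, B = fw$B, par = par, gs = gs)
}
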