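# Reverse-mode gradients for the MAP objective.
#
# The model is small and regular enough that the backward pass is written by
# hand, layer by layer, against the cached forward quantities.  Everything
# is dense matrix algebra; scatter/gather steps use rowsum() over
# precomputed incidence groupings.

# Accumulate `rows` into M at (possibly repeated) row indices `idx`.
scatter_add <- function(M, idx, rows) {
  r <- rowsum(rows, idx, reorder = TRUE)
  at <- as.integer(rownames(r))
  M[at, ] <- M[at, , drop = FALSE] + r
  M
}

# Objective value and gradients w.r.t. every parameter.
# triples/labels define the likelihood terms for this evaluation (epoch).
model_objective_grad <- function(par, gs, F_d, enc_cfg, triples, labels,
                                 sigma = 1, prior_kind = "none", tau = 0.02,
                                 laplace_scale = tau, prior_weight = 1,
                                 want_grad = TRUE) {
  d <- enc_cfg$latent_dim
  nd <- gs$n_drugs; ns <- gs$n_side_effects; n <- gs$n
  fw <- encoder_forward(par, gs, F_d, enc_cfg, keep_cache = want_grad)
  sc <- score_triples(fw$B, fw$Hd, fw$Hs, triples, symmetrize = TRUE,
                      keep_factors = TRUE)
  resid <- labels - sc$score
  m_terms <- length(resid)
  ll <- -m_terms * log(sigma * sqrt(2 * pi)) - sum(resid^2) / (2 * sigma^2)

  Lambda <- NULL
  prior <- prior_weight * switch(prior_kind,
    none = 0,
    laplace = -sum(abs(fw$B)) / laplace_scale,
    horseshoe = {
      Lambda <- exp(par$lambda_log)
      sum(-0.5 * (fw$B / (tau * Lambda))^2 - par$lambda_log) +
        sum(-log1p(Lambda^2))
    })
  value <- ll + prior
  if (!want_grad)
    return(list(value = value, likelihood = ll, prior = prior,
                B = fw$B, Hd = fw$Hd, Hs = fw$Hs, scores = sc$score))

  rho <- resid / sigma^2                       # d(ll)/d(score)
  U <- sc$U; V <- sc$V; S <- sc$S; P <- sc$P; Bmat <- sc$Bmat

  # --- score gradients ---
  dBmat <- crossprod(P * rho, S)               # (d^2) x d
  dB <- array(dBmat, c(d, d, d))
  Q <- S %*% t(Bmat)                           # m x d^2 ; Q[,i+(j-1)d]=sum_k B_ijk S_k
  QV1 <- matrix(0, m_terms, d); QV2 <- matrix(0, m_terms, d)
  QU1 <- matrix(0, m_terms, d); QU2 <- matrix(0, m_terms, d)
  for (j in seq_len(d)) {
    blk <- Q[, ((j - 1) * d + 1):(j * d), drop = FALSE]
    QV1 <- QV1 + blk * V[, j]                  # sum_j Q[,(i,j)] V_j -> index i
    QV2[, j] <- rowSums(blk * V)               # sum_i Q[,(i,j)] V_i -> index j
    QU1 <- QU1 + blk * U[, j]
    QU2[, j] <- rowSums(blk * U)
  }
  dU <- 0.5 * (QV1 + QV2) * rho
  dV <- 0.5 * (QU2 + QU1) * rho
  dS <- (P %*% Bmat) * rho

  dHd <- matrix(0, nd, d); dHs <- matrix(0, ns, d)
  dHd <- scatter_add(dHd, triples[, 1], dU)
  dHd <- scatter_add(dHd, triples[, 2], dV)
  dHs <- scatter_add(dHs, triples[, 3], dS)
  dHfin <- rbind(dHd, dHs)

  # --- prior gradients on B (and Lambda) ---
  gr <- list()
  if (prior_kind == "laplace") {
    dB <- dB - prior_weight * sign(fw$B) / laplace_scale
  } else if (prior_kind == "horseshoe") {
    dB <- dB - prior_weight * fw$B / (tau^2 * Lambda^2)
    dLambda <- fw$B^2 / (tau^2 * Lambda^3) - 1 / Lambda -
      2 * Lambda / (1 + Lambda^2)
    gr$lambda_log <- prior_weight * dLambda * Lambda
  }

  cache <- fw$cache
  # --- B parameterization ---
  if (enc_cfg$b_parameterization == "network") {
    dB_pre <- dB * softplus_grad(cache$B_pre)
    pooled <- colMeans(fw$H)
    gr$W_B <- as.numeric(dB_pre) %o% pooled
    gr$b_B <- as.numeric(dB_pre)
    dpooled <- drop(t(par$W_B) %*% as.numeric(dB_pre))
    dHfin <- dHfin + matrix(dpooled / n, n, d, byrow = TRUE)
  } else {
    gr$B_raw <- dB * softplus_grad(par$B_raw)
  }

  # --- emission ---
  dH <- dHfin * softplus_grad(cache$Hpre_fin)

  # --- message-passing layers, reversed ---
  # mirrors the factored forward pass: everything per-pair-row is reduced to
  # per-node sums (rowsum) before touching the weight matrices
  gr$layers <- vector("list", enc_cfg$n_layers)
  for (l in rev(seq_len(enc_cfg$n_layers))) {
    lay <- par$layers[[l]]
    lc <- cache$layers[[l]]
    if (is.null(lc$Z1pre)) {        # no edges: layer was the identity
      gr$layers[[l]] <- list(W1 = lay$W1 * 0, b1 = lay$b1 * 0,
                             W2 = lay$W2 * 0, b2 = lay$b2 * 0)
      next
    }
    upd <- !gs$isolated
    dHpre <- matrix(0, n, d)
    act_grad <- switch(enc_cfg$activation,
      relu = (lc$Hpre > 0) * 1,
      leaky_relu = leaky_relu_grad(lc$Hpre),
      softplus = softplus_grad(lc$Hpre))
    dHpre[upd, ] <- dH[upd, , drop = FALSE] * act_grad[upd, , drop = FALSE]
    dH_in <- matrix(0, n, d)
    dH_in[!upd, ] <- dH[!upd, , drop = FALSE]      # isolated: pass-through
    # every pair row of node a receives dHpre[a, ] / deg[a]
    dM <- (dHpre / pmax(gs$deg, 1L))[gs$a_node, , drop = FALSE]
    gr_l <- list()
    gr_l$W2 <- crossprod(lc$Z1, dM)
    gr_l$b2 <- colSums(dM)
    dZ1 <- (dM %*% t(lay$W2)) * leaky_relu_grad(lc$Z1pre)
    Ra <- matrix(0, n, ncol(dZ1)); Rb <- matrix(0, n, ncol(dZ1))
    Ra <- scatter_add(Ra, gs$a_node, dZ1)
    Rb <- scatter_add(Rb, gs$b_node, dZ1)
    H_in <- lc$H_in
    gr_l$W1 <- rbind(colSums(Ra * gs$cvec),
                     colSums(Rb * gs$cvec),
                     crossprod(H_in, Ra),
                     crossprod(H_in, Rb))
    gr_l$b1 <- colSums(dZ1)
    dH_in <- dH_in + Ra %*% t(lc$W1a) + Rb %*% t(lc$W1b)
    gr$layers[[l]] <- gr_l
    dH <- dH_in
  }

  # --- input lifts ---
  dH0_drug <- dH[seq_len(nd), , drop = FALSE]
  gr$W_lift <- crossprod(F_d, dH0_drug)
  gr$b_lift <- colSums(dH0_drug)
  gr$E_s <- dH[nd + seq_len(ns), , drop = FALSE]

  list(value = value, likelihood = ll, prior = prior, grads = gr,
       B = fw$B, Hd = fw$Hd, Hs = fw$Hs, scores = sc$score)
}

# Flatten/unflatten parameter lists (used by the Adam updates and tests).
flatten_params <- function(par) {
  unlist(par, use.names = FALSE)
}

relist_params <- function(flat, skeleton) {
  utils::relist(flat, skeleton)
}
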