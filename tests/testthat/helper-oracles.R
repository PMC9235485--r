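# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (explicit loops, pairwise comparisons) so they cannot
# share a bug with the vectorized implementations they check.

oracle_n_mode <- function(B, H, n) {
  d <- dim(B)
  tt <- nrow(H)
  out_dim <- d; out_dim[n] <- tt
  out <- array(0, out_dim)
  for (i in seq_len(out_dim[1])) for (j in seq_len(out_dim[2]))
    for (k in seq_len(out_dim[3])) {
      s <- 0
      for (q in seq_len(d[n])) {
        s <- s + switch(n,
                        B[q, j, k] * H[i, q],
                        B[i, q, k] * H[j, q],
                        B[i, j, q] * H[k, q])
      }
      out[i, j, k] <- s
    }
  out
}

oracle_triple_score <- function(B, a, b, s) {
  d <- dim(B)
  acc <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    acc <- acc + B[i, j, k] * a[i] * b[j] * s[k]
  acc
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_aupr <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(ths))
  n_pos <- sum(labels == 1)
  for (i in seq_along(ths)) {
    sel <- scores >= ths[i]
    prec[i] <- sum(labels[sel] == 1) / sum(sel)
    rec[i] <- sum(labels[sel] == 1) / n_pos
  }
  sum(diff(c(0, rec)) * prec)
}

oracle_exhaustive_ll <- function(G, score_fun, sigma = 1) {
  nd <- length(G$drug_ids); ns <- length(G$side_effect_ids)
  tot <- 0
  for (u in seq_len(nd - 1)) for (v in (u + 1):nd) for (t in seq_len(ns)) {
    trip <- matrix(c(u, v, t), 1)
    lab <- edge_indicator(G, trip)
    tot <- tot + dnorm(lab - score_fun(trip), sd = sigma, log = TRUE)
  }
  tot
}

# Exhaustive reference for the planted-triple rule: (u, v, t) is true iff
# some (i, j, k) with i in g_u, j in g_v (either orientation), k in g_t is
# planted.
oracle_true_triples <- function(A, g_u, g_t) {
  n_d <- length(g_u); n_s <- length(g_t)
  out <- NULL
  for (u in seq_len(n_d - 1)) for (v in (u + 1):n_d) for (t in seq_len(n_s)) {
    hit <- FALSE
    for (r in seq_len(nrow(A))) {
      i <- A[r, 1]; j <- A[r, 2]; k <- A[r, 3]
      if (k %in% g_t[[t]] &&
          ((i %in% g_u[[u]] && j %in% g_u[[v]]) ||
           (j %in% g_u[[u]] && i %in% g_u[[v]])))
        hit <- TRUE
    }
    if (hit) out <- rbind(out, c(u, v, t))
  }
  if (is.null(out)) matrix(integer(), ncol = 3) else out
}

rand_tensor <- function(d1, d2, d3) array(runif(d1 * d2 * d3), c(d1, d2, d3))

# Small random hypergraph plus nonnegative features, for encoder/training
# tests.
toy_instance <- function(n_d = 8, n_s = 4, n_e = 12, K0 = 6, seed = 1) {
  withr::with_seed(seed, {
    edges <- unique(cbind(sample.int(n_d, 3 * n_e, TRUE),
                          sample.int(n_d, 3 * n_e, TRUE),
                          sample.int(n_s, 3 * n_e, TRUE)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- edges[seq_len(min(n_e, nrow(edges))), , drop = FALSE]
    G <- ddi_hypergraph(paste0("d", seq_len(n_d)), paste0("s", seq_len(n_s)),
                        edges)
    F_d <- matrix(abs(rnorm(n_d * K0)), n_d, K0,
                  dimnames = list(G$drug_ids, paste0("f", seq_len(K0))))
    list(G = G, F_d = F_d)
  })
}
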