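# n-mode tensor products and triple scoring.
#
# The latent interaction tensor B is a nonnegative 3-way array of shape
# K_D x K_D x K_S; entry (i, j, k) weights the interaction between drug
# latent features i and j and side-effect latent feature k.  A triple
# (u, v, t) is scored by contracting B with the three latent vectors:
# B x1 h_d(u) x2 h_d(v) x3 h_s(t).

#' n-mode product of a 3-way tensor with a matrix
#'
#' Contracts mode `n` of `B` (shape K1 x K2 x K3) with the columns of `H`
#' (shape T x Kn); the result replaces mode `n`'s extent with T.  For mode 1:
#' `(B x1 H)[t, j, k] = sum_i B[i, j, k] H[t, i]`, and analogously for modes
#' 2 and 3.
#'
#' @param B numeric 3-way array.
#' @param H numeric matrix whose column count equals `dim(B)[n]`.
#' @param n mode, one of 1, 2, 3.
#' @return numeric 3-way array.
#' @export
n_mode_product <- function(B, H, n) {
  if (!is.array(B) || length(dim(B)) != 3L)
    stop_sparseddi("B must be a 3-way array")
  if (is.vector(H)) H <- matrix(H, nrow = 1)
  n <- as.integer(n)
  if (!n %in% 1:3) stop_sparseddi("mode must be 1, 2 or 3")
  d <- dim(B)
  if (ncol(H) != d[n])
    stop_sparseddi(sprintf("mode-%d mismatch: tensor extent %d, matrix columns %d",
                           n, d[n], ncol(H)))
  tt <- nrow(H)
  if (n == 1L) {
    # unfold along mode 1: B is already (K1) x (K2*K3) column-major
    out <- H %*% matrix(B, d[1], d[2] * d[3])
    array(out, c(tt, d[2], d[3]))
  } else if (n == 2L) {
    Bp <- aperm(B, c(2, 1, 3))
    out <- H %*% matrix(Bp, d[2], d[1] * d[3])
    aperm(array(out, c(tt, d[1], d[3])), c(2, 1, 3))
  } else {
    Bp <- aperm(B, c(3, 1, 2))
    out <- H %*% matrix(Bp, d[3], d[1] * d[2])
    aperm(array(out, c(tt, d[1], d[2])), c(2, 3, 1))
  }
}

#' Interaction score of a single triple
#'
#' Computes `sum_{i,j,k} B[i,j,k] hd_u[i] hd_v[j] hs_t[k]`, i.e. the full
#' contraction `B x1 hd_u x2 hd_v x3 hs_t`.  With `symmetrize = TRUE`
#' (default) the mean of the (u, v) and (v, u) orientations is returned, so
#' the score does not depend on drug order; the raw asymmetric score is
#' available for debugging.
#'
#' @param B interaction tensor (K_D x K_D x K_S).
#' @param hd_u,hd_v drug latent vectors of length K_D.
#' @param hs_t side-effect latent vector of length K_S.
#' @param symmetrize average over both drug orientations?
#' @return scalar score (nonnegative whenever all inputs are nonnegative).
#' @export
triple_score <- function(B, hd_u, hd_v, hs_t, symmetrize = TRUE) {
  d <- dim(B)
  if (length(hd_u) != d[1] || length(hd_v) != d[2] || length(hs_t) != d[3])
    stop_sparseddi("latent vector length does not match tensor shape")
  raw <- function(a, b) sum(B * outer(outer(a, b), hs_t))
  if (symmetrize) (raw(hd_u, hd_v) + raw(hd_v, hd_u)) / 2 else raw(hd_u, hd_v)
}

# Vectorized symmetrized scores for a batch of triples.  Hd: |V_D| x K,
# Hs: |V_S| x K, triples: matrix (u, v, t).  Returns list(score, P, S) where
# P is the symmetrized row-wise Kronecker factor reused by the gradient.
score_triples <- function(B, Hd, Hs, triples, symmetrize = TRUE,
                          keep_factors = FALSE) {
  d <- dim(B)
  Bmat <- matrix(B, d[1] * d[2], d[3])
  U <- unname(Hd[triples[, 1], , drop = FALSE])
  V <- unname(Hd[triples[, 2], , drop = FALSE])
  S <- unname(Hs[triples[, 3], , drop = FALSE])
  i_rep <- rep(seq_len(d[1]), times = d[2])
  j_rep <- rep(seq_len(d[2]), each = d[1])
  P <- U[, i_rep, drop = FALSE] * V[, j_rep, drop = FALSE]
  if (symmetrize) {
    P2 <- V[, i_rep, drop = FALSE] * U[, j_rep, drop = FALSE]
    P <- (P + P2) / 2
  }
  score <- rowSums((P %*% Bmat) * S)
  if (keep_factors) list(score = score, P = P, S = S, U = U, V = V, Bmat = Bmat)
  else score
}

#' Support set of an interaction tensor
#'
#' Index triples whose tensor entry exceeds the threshold:
#' `A = {(i, j, k) : B[i,j,k] > threshold}`.  The default threshold is a
#' small epsilon absorbing floating-point dust.
#'
#' @param B interaction tensor.
#' @param threshold nonnegative scalar.
#' @return integer matrix with columns (i, j, k); zero rows when empty.
#' @export
support_set <- function(B, threshold = 1e-8) {
  if (threshold < 0) stop_sparseddi("threshold must be nonnegative")
  idx <- which(B > threshold, arr.ind = TRUE)
  colnames(idx) <- c("i", "j", "k")
  idx
}

#' Latent sparsity of a support set
#'
#' Fraction of latent-feature triples carrying no interaction.  The support
#' is read as unordered drug-feature pairs: an off-diagonal pair (i, j),
#' i != j, accounts for both orientations (weight 2) while a diagonal pair
#' (i, i) is a single cell (weight 1), so a full tensor returns exactly 0 and
#' an empty one exactly 1; the result is capped into \[0, 1\].
#'
#' @param A support set: integer matrix with columns (i, j, k), e.g. from
#'   [support_set()]; orientation duplicates (i, j, k)/(j, i, k) are
#'   collapsed before counting.
#' @param K_D,K_S latent dimensions.
#' @return sparsity in \[0, 1\].
#' @export
latent_sparsity <- function(A, K_D, K_S) {
  A <- matrix(as.integer(A), ncol = 3)
  if (nrow(A) == 0) return(1)
  if (any(A[, 1:2] < 1) || any(A[, 1:2] > K_D) || any(A[, 3] < 1) || any(A[, 3] > K_S))
    stop_sparseddi("support index out of range")
  i <- pmin(A[, 1], A[, 2]); j <- pmax(A[, 1], A[, 2])
  key <- (i - 1) * K_D * K_S + (j - 1) * K_S + A[, 3]
  keep <- !duplicated(key)
  i <- i[keep]; j <- j[keep]
  w <- ifelse(i == j, 1, 2)
  max(0, min(1, 1 - sum(w) / (K_D^2 * K_S)))
}

#' Serialize / deserialize an interaction tensor
#'
#' Plain-text JSON container holding the shape and entries at full double
#' precision; the round trip is exact.
#'
#' @param B tensor to write.
#' @param path file path.
#' @return `read_tensor` returns the tensor.
#' @export
write_tensor <- function(B, path) {
  # doubles stored as %.17g strings: shortest text form that round-trips
  # IEEE doubles exactly
  obj <- list(dim = dim(B), values = sprintf("%.17g", as.numeric(B)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  array(as.numeric(obj$values), obj$dim)
}
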