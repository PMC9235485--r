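# Internal numerical helpers shared across modules.

softplus <- function(x) {
  # log(1 + exp(x)) computed stably; large x returns x + log1p(exp(-x))
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

softplus_grad <- function(x) stats::plogis(x)

relu <- function(x) pmax(x, 0)

# leaky rectifier: keeps a small gradient on the negative side so units
# cannot die irreversibly
leaky_relu <- function(x, slope = 0.01) pmax(x, 0) + slope * pmin(x, 0)

leaky_relu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; NULL seed evaluates in the current stream.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sparseddi <- function(..., class = "sparseddi_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Canonical integer key for a triple (u < v assumed), safe as a double for
# all realistic sizes (|V_D|^2 |V_S| < 2^53).
triple_key <- function(u, v, t, n_drugs, n_side_effects) {
  ((u - 1) * n_drugs + (v - 1)) * n_side_effects + (t - 1)
}

key_to_triple <- function(key, n_drugs, n_side_effects) {
  t <- key %% n_side_effects
  uv <- (key - t) / n_side_effects
  v <- uv %% n_drugs
  u <- (uv - v) / n_drugs
  cbind(u = u + 1, v = v + 1, t = t + 1)
}
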