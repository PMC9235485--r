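# From predicted triples back to observable drug features.
#
# A trained model ties each drug latent feature to the observable features
# most correlated with it across drugs; a predicted triple activates a small
# set of latent interactions (the nonzero cells of B weighted by the
# triple's latent vectors); chaining the two yields the pairs of observable
# feature groups potentially responsible for the prediction.

#' Explanation configuration
#'
#' @param top_T number of top-correlated observable features kept per
#'   latent feature (the reference analysis uses 20).
#' @param correlation `"pearson"` (default) or `"spearman"`.
#' @param activity_threshold minimum weighted activation for a latent
#'   interaction to count as active.
#' @param literal_k debug flag: pair the second drug's features with the
#'   side-effect latent index's feature set (the pseudocode's literal
#'   indexing) instead of the second drug-latent index.
#' @return list of class `explanation_config`.
#' @export
explanation_config <- function(top_T = 20L,
                               correlation = c("pearson", "spearman"),
                               activity_threshold = 0, literal_k = FALSE) {
  top_T <- as.integer(top_T)
  if (top_T < 1L) stop_sparseddi("top_T must be >= 1")
  structure(list(top_T = top_T, correlation = match.arg(correlation),
                 activity_threshold = activity_threshold,
                 literal_k = literal_k),
            class = "explanation_config")
}

#' Top observable features correlated with each latent feature
#'
#' For every latent column k of `H_d`, ranks the observable feature columns
#' of `F_d` by correlation across drugs and returns the indices of the top
#' `top_T`.  Zero-variance columns (of either matrix) get correlation 0 and
#' sink in the ranking; ties break by ascending feature index.
#'
#' @param H_d drug latent matrix (|V_D| x K_D).
#' @param F_d drug feature matrix (|V_D| x K0).
#' @param top_T features kept per latent.
#' @param method correlation method.
#' @return list of K_D integer vectors of length `min(top_T, K0)`.
#' @export
top_correlated_features <- function(H_d, F_d, top_T = 20L,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(H_d) < 3L) stop_sparseddi("need at least 3 drugs for correlations")
  keep <- min(top_T, ncol(F_d))
  lapply(seq_len(ncol(H_d)), function(k) {
    h <- H_d[, k]
    cors <- if (stats::sd(h) == 0) rep(0, ncol(F_d)) else
      suppressWarnings(as.numeric(stats::cor(h, F_d, method = method)))
    cors[is.na(cors)] <- 0
    order(-cors, seq_along(cors))[seq_len(keep)]
  })
}

#' Active latent interactions of a triple
#'
#' The weighted activation tensor is the entrywise product of `B` with the
#' rank-1 outer product of the three latent vectors,
#' `ss = B * (hd_u o hd_v o hs_t)`; its entries sum to the unsymmetrized
#' triple score exactly.  Cells exceeding the threshold form the active set.
#'
#' @param B interaction tensor.
#' @param hd_u,hd_v,hs_t latent vectors of the triple.
#' @param threshold activity threshold (>= 0).
#' @return list: `ss` (weighted activation tensor) and `tt` (integer matrix
#'   of active cells, columns i, j, k).
#' @export
active_latent_interactions <- function(B, hd_u, hd_v, hs_t, threshold = 0) {
  d <- dim(B)
  if (length(hd_u) != d[1] || length(hd_v) != d[2] || length(hs_t) != d[3])
    stop_sparseddi("latent vector length does not match tensor shape")
  ss <- B * outer(outer(hd_u, hd_v), hs_t)
  tt <- which(ss > threshold, arr.ind = TRUE)
  colnames(tt) <- c("i", "j", "k")
  list(ss = ss, tt = tt)
}

#' Explain a predicted triple by associated observable features
#'
#' Maps each active latent interaction (i, j, k) of the triple to the pair
#' (nonzero observable features of drug A within the top-correlated set of
#' latent i, nonzero observable features of drug B within that of latent j)
#' and returns the union.  The drug pair is canonicalized first, so the
#' explanation does not depend on drug order.
#'
#' @param model a fitted [sparse_fit()] model.
#' @param triple one triple: character ids or indices (drug, drug,
#'   side effect).
#' @param config an [explanation_config()].
#' @param F_d feature matrix override; defaults to the model's.
#' @return object of class `ddi_explanation`: the triple, the active set
#'   `tt` with activation values, the feature-pair records `Re`, and a
#'   status (`"ok"` or `"no active interaction"`).
#' @export
explain_triple <- function(model, triple, config = explanation_config(),
                           F_d = model$F_d) {
  idx <- resolve_triples(model, matrix(triple, nrow = 1))
  u <- min(idx[1, 1:2]); v <- max(idx[1, 1:2]); t <- idx[1, 3]
  a_sets <- top_correlated_features(model$Hd, F_d, top_T = config$top_T,
                                    method = config$correlation)
  act <- active_latent_interactions(model$B, model$Hd[u, ], model$Hd[v, ],
                                    model$Hs[t, ],
                                    threshold = config$activity_threshold)
  feat_names <- colnames(F_d) %||% paste0("f", seq_len(ncol(F_d)))
  Re <- list()
  if (nrow(act$tt)) {
    for (r in seq_len(nrow(act$tt))) {
      i <- act$tt[r, 1]; j <- act$tt[r, 2]; k <- act$tt[r, 3]
      second <- if (config$literal_k) a_sets[[min(k, length(a_sets))]]
                else a_sets[[j]]
      fu <- intersect(which(F_d[u, ] > 0), a_sets[[i]])
      fv <- intersect(which(F_d[v, ] > 0), second)
      Re[[length(Re) + 1L]] <- list(
        i = i, j = j, k = k, activation = act$ss[i, j, k],
        features_a = feat_names[fu], features_b = feat_names[fv])
    }
  }
  structure(list(
    triple = c(drug_a = model$drug_ids[u], drug_b = model$drug_ids[v],
               side_effect = model$side_effect_ids[t]),
    tt = act$tt, Re = Re,
    status = if (length(Re)) "ok" else "no active interaction"),
    class = "ddi_explanation")
}

#' @export
print.ddi_explanation <- function(x, ...) {
  cat(sprintf("Explanation for (%s, %s) -> %s [%s]\n", x$triple["drug_a"],
              x$triple["drug_b"], x$triple["side_effect"], x$status))
  for (re in x$Re) {
    cat(sprintf("  latent (%d, %d, %d), activation %.4g\n",
                re$i, re$j, re$k, re$activation))
    cat("    drug A features: ", paste(re$features_a, collapse = ", "), "\n")
    cat("    drug B features: ", paste(re$features_b, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write explanation reports as JSON
#'
#' @param explanations list of [explain_triple()] results (or one).
#' @param path output path.
#' @export
write_explanations <- function(explanations, path) {
  if (inherits(explanations, "ddi_explanation"))
    explanations <- list(explanations)
  jsonlite::write_json(lapply(explanations, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
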