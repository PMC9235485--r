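# AUC / AUPR and the stratified cross-validation protocol.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with tied scores averaged.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_sparseddi("AUC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated average precision: descending unique score thresholds
#' define blocks (ties are handled jointly), and each block contributes its
#' recall increment times the precision at the block boundary.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return AUPR in \[0, 1\].
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L || n1 == length(labels))
    stop_sparseddi("AUPR undefined: only one class present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  boundary <- c(s[-length(s)] != s[-1], TRUE)   # last index of each tie block
  tp <- cumsum(y)[boundary]
  fp <- cumsum(1L - y)[boundary]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Stratified cross-validation of a model variant
#'
#' Splits hyperedges with [stratified_kfold()]; for each fold the model is
#' trained on the remaining folds' edges and evaluated on the held-out
#' positives plus uniformly sampled non-edges (`eval_neg_ratio` per
#' positive, disjoint from all known positives), or on every canonical
#' non-edge in exhaustive mode.  Metrics pool all test triples within a fold
#' (micro); a per-side-effect macro average is available.
#'
#' @param G a [ddi_hypergraph()].
#' @param F_d drug feature matrix.
#' @param config a [train_config()]; fold f trains with seed
#'   `config$seed + f` so folds are independent but reproducible.
#' @param k number of folds (the reference protocol uses 20).
#' @param eval_neg_ratio evaluation negatives per positive.
#' @param seed seed for the fold split and evaluation negatives.
#' @param exhaustive_negatives evaluate against every canonical non-edge
#'   (small instances only).
#' @param macro also compute per-side-effect macro-averaged metrics.
#' @param verbose print per-fold progress.
#' @return list: `folds` (per-fold metric data frame) and `summary` (means
#'   and across-fold standard deviations).
#' @export
cross_validate <- function(G, F_d, config = train_config(), k = 20L,
                           eval_neg_ratio = 1L, seed = 1L,
                           exhaustive_negatives = FALSE, macro = FALSE,
                           verbose = FALSE) {
  folds <- stratified_kfold(G, k, seed = seed)
  all_rows <- seq_len(nrow(G$edges))
  res <- vector("list", k)
  for (f in seq_len(k)) {
    train_G <- subset_edges(G, setdiff(all_rows, folds[[f]]))
    cfg <- config
    cfg$seed <- config$seed + f
    model <- sparse_fit(train_G, F_d, cfg)
    pos <- G$edges[folds[[f]], , drop = FALSE]
    if (exhaustive_negatives) {
      all_t <- enumerate_canonical_triples(n_drugs(G), n_side_effects(G))
      neg <- all_t[edge_indicator(G, all_t) == 0L, , drop = FALSE]
    } else {
      neg <- sample_non_edges(G, nrow(pos) * eval_neg_ratio, seed = seed + f)
    }
    triples <- rbind(pos, neg)
    labels <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
    sc <- predict_scores(model, triples)
    row <- data.frame(fold = f, n_pos = nrow(pos),
                      auc = auc_score(sc, labels),
                      aupr = aupr_score(sc, labels))
    if (macro) {
      per_se <- vapply(unique(triples[, 3]), function(t) {
        sel <- triples[, 3] == t
        if (length(unique(labels[sel])) < 2L) return(c(NA_real_, NA_real_))
        c(auc_score(sc[sel], labels[sel]), aupr_score(sc[sel], labels[sel]))
      }, numeric(2))
      row$auc_macro <- mean(per_se[1, ], na.rm = TRUE)
      row$aupr_macro <- mean(per_se[2, ], na.rm = TRUE)
    }
    res[[f]] <- row
    if (verbose)
      message(sprintf("fold %d/%d: AUC %.4f, AUPR %.4f", f, k, row$auc, row$aupr))
  }
  folds_df <- do.call(rbind, res)
  list(folds = folds_df,
       summary = list(auc_mean = mean(folds_df$auc),
                      auc_sd = stats::sd(folds_df$auc),
                      aupr_mean = mean(folds_df$aupr),
                      aupr_sd = stats::sd(folds_df$aupr)))
}
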