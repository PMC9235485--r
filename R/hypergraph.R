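# DDI hypergraph data model and I/O.
#
# A DDI hypergraph joins two drugs and one side effect per hyperedge.  The
# two drug slots are unordered: (u, v, t) and (v, u, t) denote the same
# interaction, so every edge is stored once in canonical orientation with
# u < v by drug index.  Self-pairs (u, u, t) are invalid.

#' Construct a DDI hypergraph
#'
#' Builds the canonical hypergraph container used throughout the package:
#' ordered drug and side-effect vocabularies plus a set of hyperedges, each a
#' triple (drug, drug, side effect).  Triples are canonicalized so that the
#' smaller drug index comes first, and duplicates (including duplicates under
#' drug-order symmetry) are collapsed.
#'
#' @param drug_ids character vector of drug identifiers; defines the row
#'   order of any aligned drug feature matrix.
#' @param side_effect_ids character vector of side-effect identifiers.
#' @param edges integer matrix with three columns (u, v, t): two drug indices
#'   and one side-effect index, 1-based.  May be empty.
#' @return An object of class `ddi_hypergraph` with elements `drug_ids`,
#'   `side_effect_ids` and `edges` (canonical, deduplicated, row-sorted
#'   integer matrix).
#' @export
ddi_hypergraph <- function(drug_ids, side_effect_ids, edges) {
  drug_ids <- as.character(drug_ids)
  side_effect_ids <- as.character(side_effect_ids)
  if (anyDuplicated(drug_ids)) stop_sparseddi("duplicated drug identifiers")
  if (anyDuplicated(side_effect_ids)) stop_sparseddi("duplicated side-effect identifiers")
  edges <- matrix(as.integer(edges), ncol = 3,
                  dimnames = list(NULL, c("u", "v", "t")))
  n_d <- length(drug_ids)
  n_s <- length(side_effect_ids)
  if (nrow(edges)) {
    if (any(edges[, 1:2] < 1L) || any(edges[, 1:2] > n_d) ||
        any(edges[, 3] < 1L) || any(edges[, 3] > n_s))
      stop_sparseddi("hyperedge index out of range")
    if (any(edges[, 1] == edges[, 2]))
      stop_sparseddi("self-pair hyperedge (u, u, t) is invalid")
    u <- pmin(edges[, 1], edges[, 2])
    v <- pmax(edges[, 1], edges[, 2])
    edges <- cbind(u = u, v = v, t = edges[, 3])
    key <- triple_key(u, v, edges[, 3], n_d, n_s)
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    edges <- edges[order(key[keep]), , drop = FALSE]
  }
  structure(list(drug_ids = drug_ids, side_effect_ids = side_effect_ids,
                 edges = edges),
            class = "ddi_hypergraph")
}

#' @export
print.ddi_hypergraph <- function(x, ...) {
  cat(sprintf("DDI hypergraph: %d drugs, %d side effects, %d hyperedges\n",
              length(x$drug_ids), length(x$side_effect_ids), nrow(x$edges)))
  cat(sprintf("data sparsity: %.4f\n", data_sparsity(x)))
  invisible(x)
}

n_drugs <- function(G) length(G$drug_ids)
n_side_effects <- function(G) length(G$side_effect_ids)

edge_keys <- function(G) {
  triple_key(G$edges[, 1], G$edges[, 2], G$edges[, 3],
             n_drugs(G), n_side_effects(G))
}

#' Hyperedge membership indicator
#'
#' Returns the indicator i(e) for each queried triple: 1 if the triple (in
#' either drug order) is a hyperedge of `G`, else 0.
#'
#' @param G a [ddi_hypergraph()].
#' @param triples integer matrix with columns (u, v, t).
#' @return integer vector of 0/1.
#' @export
edge_indicator <- function(G, triples) {
  triples <- matrix(as.integer(triples), ncol = 3)
  u <- pmin(triples[, 1], triples[, 2])
  v <- pmax(triples[, 1], triples[, 2])
  key <- triple_key(u, v, triples[, 3], n_drugs(G), n_side_effects(G))
  as.integer(key %in% edge_keys(G))
}

#' Load a DDI hypergraph and aligned drug features from TSV files
#'
#' The triples file has three columns (drug A, drug B, side effect); the
#' features file has a drug-id column followed by numeric feature columns.
#' Triples are canonicalized and deduplicated.  Every drug occurring in the
#' triples must have a feature row; feature rows for drugs absent from the
#' triples are retained (their drugs become isolated nodes).
#'
#' @param triples_path path to the delimited triples file.
#' @param features_path path to the delimited features file.
#' @param header logical; whether the files carry a header line.
#' @param sep field separator, tab by default.
#' @param min_interactions optional integer; when positive, drugs appearing
#'   in at most this many hyperedges are dropped (with their edges) before
#'   alignment, mirroring the usual dataset-construction filter.  Applied
#'   once, at load time.
#' @return list with elements `graph` (a [ddi_hypergraph()]) and `features`
#'   (numeric matrix, rows aligned to `graph$drug_ids`).
#' @export
load_hypergraph <- function(triples_path, features_path, header = FALSE,
                            sep = "\t", min_interactions = 0L) {
  lines <- readLines(triples_path)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop_sparseddi(sprintf("malformed triple at line %d: expected 3 columns, got %d",
                           bad[1] + as.integer(header), lengths(parts)[bad[1]]),
                   class = "sparseddi_parse_error")
  trip <- do.call(rbind, parts)
  if (is.null(trip)) trip <- matrix(character(), ncol = 3)
  trip <- apply(trip, 2, trimws)
  if (!is.matrix(trip)) trip <- matrix(trip, ncol = 3)
  if (any(trip[, 1] == trip[, 2]))
    stop_sparseddi("self-pair triple (same drug twice) in input")

  feat <- utils::read.delim(features_path, header = header, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
  feat_ids <- as.character(feat[[1]])
  fmat <- as.matrix(feat[, -1, drop = FALSE])
  storage.mode(fmat) <- "double"
  if (anyNA(fmat)) stop_sparseddi("non-numeric or missing feature value")
  if (any(fmat < 0))
    stop_sparseddi("negative drug feature value", class = "sparseddi_validation_error")
  rownames(fmat) <- feat_ids
  if (!header) colnames(fmat) <- paste0("f", seq_len(ncol(fmat)))

  trip_drugs <- unique(c(trip[, 1], trip[, 2]))
  missing <- setdiff(trip_drugs, feat_ids)
  if (length(missing))
    stop_sparseddi("drugs in triples lack feature rows: ",
                   paste(utils::head(missing, 5), collapse = ", "),
                   class = "sparseddi_alignment_error")

  drug_ids <- feat_ids
  se_ids <- unique(trip[, 3])
  edges <- cbind(match(trip[, 1], drug_ids), match(trip[, 2], drug_ids),
                 match(trip[, 3], se_ids))
  G <- ddi_hypergraph(drug_ids, se_ids, edges)

  if (min_interactions > 0L && nrow(G$edges)) {
    repeat {
      deg <- tabulate(c(G$edges[, 1], G$edges[, 2]), nbins = n_drugs(G))
      drop <- which(deg > 0 & deg <= min_interactions)
      if (!length(drop)) break
      keep_edge <- !(G$edges[, 1] %in% drop | G$edges[, 2] %in% drop)
      G <- ddi_hypergraph(G$drug_ids, G$side_effect_ids,
                          G$edges[keep_edge, , drop = FALSE])
    }
    used_se <- sort(unique(G$edges[, 3]))
    if (length(used_se) < n_side_effects(G)) {
      remap <- match(G$edges[, 3], used_se)
      G <- ddi_hypergraph(G$drug_ids, G$side_effect_ids[used_se],
                          cbind(G$edges[, 1:2], remap))
    }
  }
  list(graph = G, features = fmat[G$drug_ids, , drop = FALSE])
}

#' Write hypergraph triples and drug features back to TSV
#'
#' Inverse of [load_hypergraph()]; a load/write/load round trip reproduces
#' the canonical hyperedge set exactly.
#'
#' @param G a [ddi_hypergraph()].
#' @param features drug feature matrix aligned to `G$drug_ids` (optional).
#' @param triples_path,features_path output paths.
#' @param header write a header line?
#' @export
write_hypergraph <- function(G, triples_path, features = NULL,
                             features_path = NULL, header = FALSE) {
  df <- data.frame(a = G$drug_ids[G$edges[, 1]],
                   b = G$drug_ids[G$edges[, 2]],
                   t = G$side_effect_ids[G$edges[, 3]])
  utils::write.table(df, triples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  if (!is.null(features)) {
    fd <- data.frame(drug = rownames(features), features, check.names = FALSE)
    utils::write.table(fd, features_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = header)
  }
  invisible(G)
}

#' Data sparsity of a DDI hypergraph
#'
#' Fraction of all possible canonical (drug, drug, side effect) triples that
#' are not observed hyperedges:
#' \deqn{s_d = 1 - \frac{2|E|}{|V_D|(|V_D|-1)|V_S|}.}
#'
#' @param G a [ddi_hypergraph()], or `NULL` when explicit counts are given.
#' @param n_drugs,n_side_effects,n_edges explicit counts, used when `G` is
#'   `NULL` (e.g. to evaluate the formula on published dataset statistics).
#' @return sparsity in \[0, 1\].
#' @export
data_sparsity <- function(G = NULL, n_drugs = NULL, n_side_effects = NULL,
                          n_edges = NULL) {
  if (!is.null(G)) {
    n_drugs <- length(G$drug_ids)
    n_side_effects <- length(G$side_effect_ids)
    n_edges <- nrow(G$edges)
  }
  n_drugs <- as.numeric(n_drugs)
  n_side_effects <- as.numeric(n_side_effects)
  n_edges <- as.numeric(n_edges)
  if (n_drugs < 2 || n_side_effects < 1)
    stop_sparseddi("data sparsity undefined for fewer than 2 drugs or no side effects")
  1 - 2 * n_edges / (n_drugs * (n_drugs - 1) * n_side_effects)
}

#' Stratified k-fold split of hyperedges
#'
#' Partitions the hyperedges of `G` into `k` disjoint folds such that, for
#' every side effect, its hyperedges are spread across folds with per-fold
#' counts differing by at most one.  Within each side effect the edges are
#' shuffled under the seed and dealt round-robin, starting at the currently
#' least-loaded fold so that overall fold sizes stay balanced too.
#'
#' @param G a [ddi_hypergraph()].
#' @param k number of folds (>= 2).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list of `k` integer vectors of edge row indices into `G$edges`.
#' @export
stratified_kfold <- function(G, k, seed = 1L) {
  k <- as.integer(k)
  m <- nrow(G$edges)
  if (k < 2L) stop_sparseddi("k must be >= 2")
  if (k > m) stop_sparseddi("k exceeds the number of hyperedges")
  folds <- vector("list", k)
  load <- integer(k)
  with_seed_or_not(seed, {
    for (t in seq_len(n_side_effects(G))) {
      idx <- which(G$edges[, 3] == t)
      if (!length(idx)) next
      idx <- idx[sample.int(length(idx))]
      start <- which.min(load)  # deterministic tie-break: lowest fold index
      f <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
      for (j in seq_len(k)) {
        sel <- idx[f == j]
        if (length(sel)) folds[[j]] <- c(folds[[j]], sel)
      }
      load <- load + tabulate(f, nbins = k)
    }
  })
  lapply(folds, sort)
}

# Hypergraph restricted to a subset of edge rows (same vocabularies).
subset_edges <- function(G, rows) {
  ddi_hypergraph(G$drug_ids, G$side_effect_ids, G$edges[rows, , drop = FALSE])
}

#' Enumerate all canonical triples
#'
#' All (u, v, t) with u < v over the given vocabulary sizes.  Guarded: the
#' enumeration refuses to materialize more than `limit` triples.
#'
#' @param n_drugs,n_side_effects vocabulary sizes.
#' @param limit maximum number of triples to materialize.
#' @return integer matrix with columns (u, v, t).
#' @export
enumerate_canonical_triples <- function(n_drugs, n_side_effects,
                                        limit = 5e6) {
  total <- n_drugs * (n_drugs - 1) / 2 * n_side_effects
  if (total > limit)
    stop_sparseddi("canonical triple universe too large to enumerate (",
                   format(total, big.mark = ","), ")")
  pairs <- which(upper.tri(matrix(0, n_drugs, n_drugs)), arr.ind = TRUE)
  u <- rep(pairs[, 1], times = n_side_effects)
  v <- rep(pairs[, 2], times = n_side_effects)
  t <- rep(seq_len(n_side_effects), each = nrow(pairs))
  cbind(u = u, v = v, t = t)
}

#' Sample canonical non-edges uniformly
#'
#' Draws `n` distinct canonical triples that are not hyperedges of `G`
#' (collisions with positives or with already-drawn triples are rejected and
#' resampled).  Deterministic given the seed.
#'
#' @param G a [ddi_hypergraph()].
#' @param n number of negatives to draw.
#' @param seed integer seed or `NULL` to use the current RNG stream.
#' @param exclude_keys additional triple keys to avoid (optional).
#' @return integer matrix with columns (u, v, t).
#' @export
sample_non_edges <- function(G, n, seed = NULL, exclude_keys = NULL) {
  nd <- n_drugs(G)
  ns <- n_side_effects(G)
  total <- nd * (nd - 1) / 2 * ns
  avoid <- c(edge_keys(G), exclude_keys)
  if (total - length(avoid) < n)
    stop_sparseddi("not enough canonical non-edges to sample")
  out <- numeric(0)
  with_seed_or_not(seed, {
    while (length(out) < n) {
      m <- max(16L, ceiling((n - length(out)) * 1.3))
      a <- sample.int(nd, m, replace = TRUE)
      b <- sample.int(nd, m, replace = TRUE)
      t <- sample.int(ns, m, replace = TRUE)
      ok <- a != b
      u <- pmin(a, b)[ok]; v <- pmax(a, b)[ok]; t <- t[ok]
      key <- triple_key(u, v, t, nd, ns)
      key <- key[!(key %in% avoid) & !(key %in% out)]
      key <- key[!duplicated(key)]
      out <- c(out, key)
    }
  })
  out <- out[seq_len(n)]
  key_to_triple(out, nd, ns)
}
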