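#' Top-k lifespan feature vector of a persistence diagram
#'
#' The lifespan of a point is |death - birth| (extended points store
#' birth >= death). The k largest lifespans, sorted descending and
#' zero-padded to length k, form the feature vector. Essential points
#' (infinite death) have no finite lifespan and are dropped by default;
#' `essential = "truncate"` first caps their death at the diagram's largest
#' finite death (or birth), as in [wasserstein_distance()].
#'
#' @param diagram Diagram tibble holding a single dimension and kind.
#' @param k Number of features (default 10).
#' @param essential `"drop"` (default) or `"truncate"`.
#' @return Numeric vector of length `k`, non-negative, descending.
#' @examples
#' d <- tibble::tibble(dimension = 1L, birth = c(1, 2), death = c(4, 3),
#'                     kind = "ordinary")
#' top_k_lifespans(d, k = 4)   # 3 1 0 0
#' @export
top_k_lifespans <- function(diagram, k = 10, essential = c("drop", "truncate")) {
  essential <- match.arg(essential)
  k <- assert_count(k, "k")
  d <- diagram
  if (essential == "drop") d <- d[is.finite(d$death), , drop = FALSE]
  else d <- resolve_essential(d, d[0, ], "truncate_to_max_finite")
  life <- sort(abs(d$death - d$birth), decreasing = TRUE)
  out <- rep(0, k)
  out[seq_len(min(k, length(life)))] <- life[seq_len(min(k, length(life)))]
  out
}

#' Lifespan feature matrix for a diagram table
#'
#' @param diagrams Tibble with `subject_id` and `diagram` list-column
#'   (e.g. from [graph_diagrams_panel()]).
#' @param dimension Homology dimension to extract from each diagram.
#' @param k,essential Passed to [top_k_lifespans()].
#' @return Numeric matrix, one row per subject (rownames = subject ids),
#'   columns `life01`...`life<k>`.
#' @export
lifespan_features <- function(diagrams, dimension = 1, k = 10,
                              essential = "drop") {
  feats <- t(vapply(diagrams$diagram, function(d)
    top_k_lifespans(d[d$dimension == dimension, , drop = FALSE],
                    k = k, essential = essential),
    numeric(k)))
  rownames(feats) <- diagrams$subject_id
  colnames(feats) <- sprintf("life%02d", seq_len(k))
  feats
}

#' Recursive feature elimination with a random-forest ranker
#'
#' Iteratively drops the feature with the smallest random-forest importance
#' (mean decrease in Gini) until `n_selected` remain. Deterministic for a
#' fixed seed.
#'
#' @param x Numeric feature matrix (subjects x features).
#' @param y Class labels (two or more classes).
#' @param n_selected Number of features to keep.
#' @param seed Integer seed.
#' @param n_trees Trees per forest fit.
#' @return Integer indices of the selected columns (ascending).
#' @export
rfe_select <- function(x, y, n_selected = 5, seed = 1, n_trees = 300) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) abort("need at least two classes",
                             class = "topofc_validation_error")
  if (!all(is.finite(x))) abort("features must be finite")
  n_selected <- assert_count(n_selected, "n_selected")
  if (n_selected > ncol(x)) abort("n_selected exceeds feature count")
  keep <- seq_len(ncol(x))
  with_preserved_rng({
    set.seed(as.integer(seed))
    while (length(keep) > n_selected) {
      fit <- randomForest::randomForest(x[, keep, drop = FALSE], y,
                                        ntree = n_trees)
      imp <- fit$importance[, "MeanDecreaseGini"]
      keep <- keep[-which.min(imp)]
    }
  })
  sort(keep)
}
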