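#' Marginal (Pearson) correlation matrix of ROI series
#'
#' @param x Numeric ROI x time matrix, rows named by ROI.
#' @return A correlation matrix with attribute `flavor = "marginal"`,
#'   unit diagonal, symmetric.
#' @export
marginal_correlation <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3L) abort("need at least 3 timepoints")
  v <- apply(x, 1, var)
  if (any(v == 0)) {
    bad <- rownames(x)[v == 0] %||% which(v == 0)
    abort(paste0("zero-variance ROI(s): ", paste(bad, collapse = ", ")),
          class = "topofc_validation_error")
  }
  r <- cor(t(x))
  diag(r) <- 1
  r <- (r + t(r)) / 2
  attr(r, "flavor") <- "marginal"
  r
}

#' Partial correlation matrix via the (shrunk) precision matrix
#'
#' Controls each pairwise association for all remaining ROIs:
#' \eqn{\rho_{ij} = -P_{ij} / \sqrt{P_{ii} P_{jj}}} with P the inverse
#' covariance. A zero partial correlation indicates the absence of a direct
#' connection, which is why it supplies the default edge weight of the
#' positive connectivity graph. When ROIs rival timepoints in number the
#' sample covariance is ill-conditioned, so a Ledoit-Wolf-style shrinkage
#' toward the scaled identity is applied before inversion
#' (`shrinkage = "auto"`); pass a number in [0, 1] to fix the intensity, or
#' 0 to invert the raw covariance.
#'
#' @param x Numeric ROI x time matrix, rows named by ROI.
#' @param shrinkage `"auto"` or a number in [0, 1].
#' @return A partial-correlation matrix, attribute `flavor = "partial"`.
#' @export
partial_correlation <- function(x, shrinkage = "auto") {
  x <- as.matrix(x)
  if (ncol(x) < 3L) abort("need at least 3 timepoints")
  p <- nrow(x); n <- ncol(x)
  xc <- x - rowMeans(x)
  s <- tcrossprod(xc) / n                       # ML covariance, p x p
  lambda <-
    if (identical(shrinkage, "auto")) ledoit_wolf_lambda(xc, s)
    else assert_prob(shrinkage, "shrinkage")
  target <- diag(mean(diag(s)), p)
  sh <- (1 - lambda) * s + lambda * target
  prec <- tryCatch(solve(sh), error = function(e)
    abort("covariance not invertible even after shrinkage",
          class = "topofc_singular_error"))
  dd <- sqrt(diag(prec))
  r <- -prec / outer(dd, dd)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- list(rownames(x), rownames(x))
  attr(r, "flavor") <- "partial"
  attr(r, "shrinkage") <- lambda
  r
}

# Ledoit-Wolf (2004) optimal intensity for shrinkage toward mu * I,
# estimated from the centred data xc (p x n) and its ML covariance s.
ledoit_wolf_lambda <- function(xc, s) {
  p <- nrow(xc); n <- ncol(xc)
  mu <- mean(diag(s))
  d2 <- sum((s - diag(mu, p))^2)
  if (d2 < .Machine$double.eps) return(0)
  b2 <- 0
  for (t in seq_len(n)) {
    st <- tcrossprod(xc[, t])
    b2 <- b2 + sum((st - s)^2)
  }
  b2 <- b2 / n^2
  max(0, min(1, b2 / d2))
}

new_fc_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "fc_graph")
}

#' Construct a weighted graph by hand
#'
#' Builds the `fc_graph` structure used by the graph-filtration functions
#' from an explicit node list and edge table, validating that edges are
#' positive-weight, free of self-loops, and canonicalising the undirected
#' orientation (from before to in node order).
#'
#' @param nodes Character vector of node identifiers.
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @return An `fc_graph`.
#' @examples
#' fc_graph(c("a", "b", "c"),
#'          data.frame(from = c("a", "b"), to = c("b", "c"), weight = c(1, 2)))
#' @export
fc_graph <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node identifiers")
  edges <- as_tibble(edges)[, c("from", "to", "weight")]
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (!all(c(edges$from, edges$to) %in% nodes))
    abort("edge endpoints must appear in `nodes`")
  if (any(edges$from == edges$to)) abort("self-loops are not allowed")
  if (any(edges$weight <= 0)) abort("edge weights must be strictly positive")
  ii <- match(edges$from, nodes); jj <- match(edges$to, nodes)
  flip <- ii > jj
  tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]; edges$to[flip] <- tmp
  if (anyDuplicated(paste(edges$from, edges$to))) abort("duplicate edges")
  edges <- dplyr::arrange(edges, match(.data$from, nodes), match(.data$to, nodes))
  new_fc_graph(nodes, edges)
}

#' @export
print.fc_graph <- function(x, ...) {
  cat(sprintf("<fc_graph> %d nodes, %d edges, %d component(s)\n",
              length(x$nodes), nrow(x$edges), graph_components(x)$n))
  invisible(x)
}

# connected components via union-find; returns n and a membership vector
graph_components <- function(graph) {
  n <- length(graph$nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ii <- match(graph$edges$from, graph$nodes)
  jj <- match(graph$edges$to, graph$nodes)
  for (k in seq_along(ii)) {
    a <- find(ii[k]); b <- find(jj[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  list(n = length(unique(roots)), membership = match(roots, unique(roots)))
}

#' Positively correlated connectivity graph
#'
#' Keeps the edge (i, j) exactly when both the marginal and the partial
#' correlation are strictly positive -- agreement of the two estimators on a
#' positive association. The retained edge carries the partial-correlation
#' value by default (the estimator of direct connectivity), or the marginal
#' value via `weight_source`.
#'
#' @param marginal Matrix from [marginal_correlation()].
#' @param partial Matrix from [partial_correlation()].
#' @param weight_source `"partial"` (default) or `"marginal"`.
#' @return An `fc_graph`: list with `nodes` (character) and `edges`
#'   (tibble `from`, `to`, `weight`, canonical from < to in node order).
#' @export
positive_graph <- function(marginal, partial,
                           weight_source = c("partial", "marginal")) {
  weight_source <- match.arg(weight_source)
  if (!identical(rownames(marginal), rownames(partial)))
    abort("marginal and partial matrices must share roi_order",
          class = "topofc_validation_error")
  nodes <- rownames(marginal) %||% as.character(seq_len(nrow(marginal)))
  p <- nrow(marginal)
  keep <- which(upper.tri(marginal) & marginal > 0 & partial > 0, arr.ind = TRUE)
  w <- if (weight_source == "partial") partial[keep] else marginal[keep]
  edges <- tibble(from = nodes[keep[, 1]], to = nodes[keep[, 2]],
                  weight = as.numeric(w))
  edges <- dplyr::arrange(edges, match(.data$from, nodes), match(.data$to, nodes))
  new_fc_graph(nodes, edges)
}

#' Positive connectivity graphs for every subject x network of a panel
#'
#' @param panel Panel tibble.
#' @param networks Networks to include (default all in the panel).
#' @param shrinkage Passed to [partial_correlation()].
#' @param weight_source Passed to [positive_graph()].
#' @return Tibble `subject_id`, `group`, `network`, `graph` (list-column).
#' @export
connectivity_graphs <- function(panel, networks = NULL, shrinkage = "auto",
                                weight_source = "partial") {
  networks <- networks %||% unique(panel$network)
  grid <- tidyr::expand_grid(subject_id = panel_subjects(panel),
                             network = networks)
  groups <- panel_groups(panel)
  grid$group <- unname(groups[grid$subject_id])
  grid$graph <- purrr::map2(grid$subject_id, grid$network, function(s, nw) {
    m <- panel_matrix(panel, s, nw)
    positive_graph(marginal_correlation(m),
                   partial_correlation(m, shrinkage = shrinkage),
                   weight_source = weight_source)
  })
  grid[, c("subject_id", "group", "network", "graph")]
}
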