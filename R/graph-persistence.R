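#' Filter function on a weighted graph
#'
#' Assigns the filtration value f(e) = transform(w(e)) to every edge and
#' f(v) = min over incident edges of f(e) to every vertex; isolated vertices
#' carry f(v) = 0 by convention. With `transform = "identity"` weak edges
#' enter the sublevel filtration first; `"one_minus_w"` (1 - w) reverses
#' that, letting strong correlations enter first -- both readings of
#' correlation-as-filtration are supported.
#'
#' @param graph An `fc_graph` from [positive_graph()].
#' @param transform `"identity"` (default) or `"one_minus_w"`.
#' @return A `graph_filter`: list with `nodes`, `edges` (tibble `from`,
#'   `to`, `value`), `vertex_value` (named numeric), `transform`.
#' @export
build_graph_filter <- function(graph, transform = c("identity", "one_minus_w")) {
  transform <- match.arg(transform)
  edges <- graph$edges
  value <- switch(transform, identity = edges$weight,
                  one_minus_w = 1 - edges$weight)
  vv <- setNames(rep(0, length(graph$nodes)), graph$nodes)
  if (nrow(edges)) {
    inc <- tapply(c(value, value), c(edges$from, edges$to), min)
    vv[names(inc)] <- inc
  }
  structure(list(nodes = graph$nodes,
                 edges = tibble(from = edges$from, to = edges$to, value = value),
                 vertex_value = vv, transform = transform),
            class = "graph_filter")
}

# edges sorted by (value, canonical lexicographic node order) -- the
# deterministic tie-break used by both persistence sweeps.
sorted_filter_edges <- function(filter) {
  e <- filter$edges
  ii <- match(e$from, filter$nodes)
  jj <- match(e$to, filter$nodes)
  ord <- order(e$value, ii, jj)
  list(i = ii[ord], j = jj[ord], value = e$value[ord])
}

#' 0-th ordinary persistence diagram of a graph filtration
#'
#' Sweeps the sublevel sets of the filter: every vertex is born at its filter
#' value; when an edge merges two components the elder rule applies -- the
#' component with the larger birth dies at the edge value (ties broken toward
#' the component whose earliest-born vertex is lexicographically larger).
#' Each connected component contributes one essential pair (min birth, Inf).
#' Zero-persistence merge pairs are retained, so the number of bars equals
#' the number of vertices.
#'
#' @param filter A `graph_filter` from [build_graph_filter()].
#' @return Diagram tibble (`dimension` 0, `kind` `"ordinary"`).
#' @examples
#' g <- fc_graph(letters[1:4],
#'               data.frame(from = c("a", "c", "b"), to = c("b", "d", "c"),
#'                          weight = c(1, 2, 4)))
#' ordinary_persistence_0(build_graph_filter(g))  # (2, 4) plus (1, Inf)
#' @export
ordinary_persistence_0 <- function(filter) {
  nodes <- filter$nodes
  n <- length(nodes)
  birth <- unname(filter$vertex_value[nodes])
  parent <- seq_len(n)
  comp_birth <- birth          # birth value of each root's component
  comp_minv <- seq_len(n)      # index of earliest-born (tie: smallest) vertex
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }

  se <- sorted_filter_edges(filter)
  pairs_b <- numeric(0); pairs_d <- numeric(0)
  for (k in seq_along(se$value)) {
    a <- find(se$i[k]); b <- find(se$j[k])
    if (a == b) next
    # decide which component dies: larger birth; tie -> the one whose
    # earliest vertex is lexicographically larger
    die_a <-
      if (comp_birth[a] != comp_birth[b]) comp_birth[a] > comp_birth[b]
      else comp_minv[a] > comp_minv[b]
    dead <- if (die_a) a else b
    live <- if (die_a) b else a
    pairs_b <- c(pairs_b, comp_birth[dead])
    pairs_d <- c(pairs_d, se$value[k])
    parent[dead] <- live
    comp_birth[live] <- min(comp_birth[live], comp_birth[dead])
    comp_minv[live] <- min(comp_minv[live], comp_minv[dead])
  }
  roots <- unique(vapply(seq_len(n), find, integer(1)))
  out <- tibble(dimension = 0L,
                birth = c(pairs_b, comp_birth[roots]),
                death = c(pairs_d, rep(Inf, length(roots))),
                kind = "ordinary")
  dplyr::arrange(out, .data$birth, .data$death)
}

#' 1-st extended persistence diagram of a graph filtration
#'
#' Captures every independent cycle of the graph as one point with
#' birth >= death: the loop is born in the ascending (sublevel) pass at its
#' largest filter value and dies in the descending (superlevel) pass at the
#' relative-homology event paired with it. Computed by the standard cone
#' construction: the boundary matrix of the graph followed by the cone of
#' its superlevel filtration is reduced over GF(2); each pair of an edge in
#' the ascending half with a coned edge in the descending half is one
#' extended point (birth = the edge's filter value, death = the coned
#' edge's). The diagram size always equals the first Betti number
#' |E| - |V| + #components.
#'
#' Note the death values form a valid global pairing: two independent loops
#' sharing their weakest edge die at distinct events, which is why the
#' pairing cannot be read off cycle-by-cycle from a spanning forest.
#'
#' @param filter A `graph_filter`.
#' @return Diagram tibble (`dimension` 1, `kind` `"extended"`).
#' @export
extended_persistence_1 <- function(filter) {
  nodes <- filter$nodes
  nv <- length(nodes)
  se <- sorted_filter_edges(filter)
  ne <- length(se$value)
  fv <- unname(filter$vertex_value[nodes])
  if (ne == 0L)
    return(tibble(dimension = integer(0), birth = numeric(0),
                  death = numeric(0), kind = character(0)))

  # superlevel entry values: a vertex enters the descending pass with its
  # largest incident edge (isolated vertices with their own value)
  gv <- fv
  for (k in seq_len(ne)) {
    gv[se$i[k]] <- max(gv[se$i[k]], se$value[k])
    gv[se$j[k]] <- max(gv[se$j[k]], se$value[k])
  }

  # global column order: ascending vertices/edges, apex, descending cones.
  # Positions 1..nv: vertices by (f, index); edges se are value-sorted.
  v_ord <- order(fv, seq_len(nv))
  v_pos <- integer(nv); v_pos[v_ord] <- seq_len(nv)
  # interleave vertices before equal-valued edges: vertices at (f, dim 0),
  # edges at (f, dim 1); realised by sorting the combined keys
  all_val <- c(fv, se$value)
  all_dim <- c(rep(0L, nv), rep(1L, ne))
  all_lex <- c(seq_len(nv), nv + seq_len(ne))
  a_ord <- order(all_val, all_dim, all_lex)
  a_pos <- integer(nv + ne); a_pos[a_ord] <- seq_len(nv + ne)
  apex <- nv + ne + 1L
  b_val <- c(gv, se$value)
  b_dim <- c(rep(1L, nv), rep(2L, ne))
  b_ord <- order(-b_val, b_dim, c(seq_len(nv), nv + seq_len(ne)))
  b_pos <- integer(nv + ne); b_pos[b_ord] <- seq_len(nv + ne)

  n_total <- 2L * (nv + ne) + 1L
  cols <- vector("list", n_total)
  is_edge <- logical(n_total); edge_of <- integer(n_total)
  is_cone_edge <- logical(n_total); cone_edge_of <- integer(n_total)
  for (k in seq_len(nv)) cols[[a_pos[k]]] <- integer(0)
  for (k in seq_len(ne)) {
    p <- a_pos[nv + k]
    cols[[p]] <- sort(c(a_pos[se$i[k]], a_pos[se$j[k]]))
    is_edge[p] <- TRUE; edge_of[p] <- k
  }
  cols[[apex]] <- integer(0)
  for (k in seq_len(nv))
    cols[[apex + b_pos[k]]] <- sort(c(a_pos[k], apex))
  for (k in seq_len(ne)) {
    p <- apex + b_pos[nv + k]
    cols[[p]] <- sort(c(a_pos[nv + k],
                        apex + b_pos[se$i[k]], apex + b_pos[se$j[k]]))
    is_cone_edge[p] <- TRUE; cone_edge_of[p] <- k
  }

  pivots <- .reduce_columns_cpp(cols, n_total)
  births <- numeric(0); deaths <- numeric(0)
  for (j in which(is_cone_edge)) {
    piv <- pivots[j]
    if (piv > 0L && is_edge[piv]) {
      births <- c(births, se$value[edge_of[piv]])
      deaths <- c(deaths, se$value[cone_edge_of[j]])
    }
  }
  out <- tibble(dimension = 1L, birth = births, death = deaths,
                kind = "extended")
  dplyr::arrange(out, .data$birth, .data$death)
}

#' Both persistence diagrams of a weighted graph
#'
#' Convenience wrapper: builds the filter and returns the 0-th ordinary and
#' 1-st extended diagrams stacked in one tibble.
#'
#' @inheritParams build_graph_filter
#' @return Diagram tibble with dimensions 0 (ordinary) and 1 (extended).
#' @export
graph_diagrams <- function(graph, transform = "identity") {
  f <- build_graph_filter(graph, transform)
  dplyr::bind_rows(ordinary_persistence_0(f), extended_persistence_1(f))
}

#' Persistence diagrams for every graph of a connectivity table
#'
#' @param graphs Tibble from [connectivity_graphs()].
#' @param transform Passed to [build_graph_filter()].
#' @return The input tibble with a `diagram` list-column replacing `graph`.
#' @export
graph_diagrams_panel <- function(graphs, transform = "identity") {
  out <- graphs
  out$diagram <- lapply(graphs$graph, graph_diagrams, transform = transform)
  out$graph <- NULL
  out
}
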