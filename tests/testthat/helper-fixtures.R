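# Small generators used across test files; all seeded by the caller.

random_diagram <- function(n, dimension = 1L, kind = "ordinary",
                           extended = FALSE) {
  b <- round(runif(n, 0, 5), 3)
  gap <- round(runif(n, 0, 3), 3)
  if (extended) tibble::tibble(dimension = dimension, birth = b + gap,
                               death = b, kind = kind)
  else tibble::tibble(dimension = dimension, birth = b, death = b + gap,
                      kind = kind)
}

random_graph <- function(n_nodes, edge_prob = 0.5, max_weight = 10L) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- utils::combn(n_nodes, 2)
  keep <- runif(ncol(pairs)) < edge_prob
  edges <- data.frame(from = nodes[pairs[1, keep]],
                      to = nodes[pairs[2, keep]],
                      weight = sample.int(max_weight, sum(keep),
                                          replace = TRUE))
  fc_graph(nodes, edges)
}

tiny_cohort <- function(seed = 1, n_per_group = 4, n_roi = 6, T = 60,
                        shift = 0.3) {
  generate_cohort(cohort_spec(
    n_subjects_per_group = n_per_group, groups = c("HC", "MCI"),
    networks = c(NET = n_roi), n_timepoints = T,
    coupling_base = 0.3, coupling_shift_per_group = c(MCI = shift),
    seed = seed))
}

diagram_key <- function(d) {
  fin <- d[order(d$dimension, d$birth, d$death), ]
  paste(sprintf("%d|%.9f|%.9f", fin$dimension, fin$birth,
                ifelse(is.infinite(fin$death), 1e18, fin$death)),
        collapse = ";")
}
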