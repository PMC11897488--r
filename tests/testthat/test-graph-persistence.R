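fig3_graph <- function() {
  fc_graph(c("a", "b", "c", "d"),
           data.frame(from = c("a", "c", "b"), to = c("b", "d", "c"),
                      weight = c(1, 2, 4)))
}

test_that("vertex values follow the min-incident-edge rule", {
  g <- fc_graph(c("a", "b", "c", "d"),
                data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                           weight = c(1, 4, 2)))
  f <- build_graph_filter(g)
  expect_equal(unname(f$vertex_value[c("a", "b", "c", "d")]), c(1, 1, 2, 2))
  # one_minus_w transform
  g2 <- fc_graph(c("x", "y"), data.frame(from = "x", to = "y", weight = 0.3))
  f2 <- build_graph_filter(g2, transform = "one_minus_w")
  expect_equal(f2$edges$value, 0.7)
  expect_equal(unname(f2$vertex_value), c(0.7, 0.7))
  # isolated vertices carry 0
  g3 <- fc_graph(c("u", "v", "w"),
                 data.frame(from = "u", to = "v", weight = 5))
  f3 <- build_graph_filter(g3)
  expect_equal(unname(f3$vertex_value[c("u", "v", "w")]), c(5, 5, 0))
})

test_that("the worked four-vertex example yields (2,4) and (1,Inf)", {
  dg0 <- ordinary_persistence_0(build_graph_filter(fig3_graph()))
  pos <- dg0[dg0$death > dg0$birth, ]
  fin <- pos[is.finite(pos$death), ]
  expect_equal(nrow(fin), 1)
  expect_equal(c(fin$birth, fin$death), c(2, 4))
  ess <- dg0[is.infinite(dg0$death), ]
  expect_equal(nrow(ess), 1)
  expect_equal(ess$birth, 1)
  # bar count equals vertex count
  expect_equal(nrow(dg0), 4)
})

test_that("degenerate 0-dimensional cases follow the conventions", {
  single <- fc_graph("a", data.frame(from = character(0), to = character(0),
                                     weight = numeric(0)))
  dg0 <- ordinary_persistence_0(build_graph_filter(single))
  expect_equal(dg0$birth, 0)
  expect_equal(dg0$death, Inf)
  # tree with equal edge values: one essential, rest zero-persistence
  tree <- fc_graph(letters[1:5],
                   data.frame(from = c("a", "a", "b", "b"),
                              to = c("b", "c", "d", "e"),
                              weight = rep(3, 4)))
  dg0 <- ordinary_persistence_0(build_graph_filter(tree))
  ess <- dg0[is.infinite(dg0$death), ]
  expect_equal(nrow(ess), 1)
  expect_equal(ess$birth, 3)
  fin <- dg0[is.finite(dg0$death), ]
  expect_true(all(fin$death == fin$birth))
})

test_that("the worked 3-cycle yields the extended point (7,4)", {
  tri <- fc_graph(c("a", "b", "c"),
                  data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                             weight = c(4, 5, 7)))
  ex1 <- extended_persistence_1(build_graph_filter(tri))
  expect_equal(nrow(ex1), 1)
  expect_equal(c(ex1$birth, ex1$death), c(7, 4))
  expect_equal(ex1$kind, "extended")
})

test_that("trees have empty extended diagrams", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    # random tree: connect each node to a random earlier node
    edges <- data.frame(from = sprintf("n%02d",
                          vapply(2:n, function(i) sample.int(i - 1, 1),
                                 integer(1))),
                        to = sprintf("n%02d", 2:n),
                        weight = sample.int(10, n - 1, replace = TRUE))
    g <- fc_graph(sprintf("n%02d", 1:n), edges)
    expect_equal(nrow(extended_persistence_1(build_graph_filter(g))), 0)
  }
})

test_that("extended diagrams equal the cone-reduction oracle on random graphs", {
  set.seed(32)
  for (rep in 1:50) {
    g <- random_graph(sample(4:10, 1), edge_prob = runif(1, 0.3, 0.8))
    f <- build_graph_filter(g)
    ex1 <- extended_persistence_1(f)
    oracle <- cone_extended_oracle(f)
    a <- ex1[order(ex1$birth, ex1$death), c("birth", "death")]
    b <- oracle$ex1[order(oracle$ex1$birth, oracle$ex1$death), ]
    expect_equal(unname(as.matrix(a)), unname(as.matrix(b)),
                 info = sprintf("rep %d", rep))
    # first Betti number
    comp <- topofc:::graph_components(g)$n
    expect_equal(nrow(ex1), nrow(g$edges) - length(g$nodes) + comp)
    # ordinary finite positive-persistence pairs also match the reduction
    dg0 <- ordinary_persistence_0(f)
    fin <- dg0[is.finite(dg0$death), ]
    oral <- oracle$dg0_finite
    expect_equal(sort(fin$death - fin$birth),
                 sort(oral$death - oral$birth))
    # essential pairs count components
    expect_equal(sum(is.infinite(dg0$death)), comp)
    # sign conventions
    expect_true(all(fin$birth <= fin$death))
    expect_true(all(ex1$birth >= ex1$death))
  }
})

test_that("tie-breaking does not change the multiset of pairs", {
  set.seed(33)
  for (rep in 1:10) {
    g <- random_graph(7, edge_prob = 0.6, max_weight = 3L)  # many ties
    f <- build_graph_filter(g)
    base0 <- ordinary_persistence_0(f)
    base1 <- extended_persistence_1(f)
    perm <- sample(nrow(g$edges))
    g2 <- fc_graph(g$nodes, as.data.frame(g$edges[perm, ]))
    f2 <- build_graph_filter(g2)
    expect_equal(diagram_key(as.data.frame(base0)),
                 diagram_key(as.data.frame(ordinary_persistence_0(f2))))
    expect_equal(diagram_key(as.data.frame(base1)),
                 diagram_key(as.data.frame(extended_persistence_1(f2))))
  }
})
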