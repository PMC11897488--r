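test_that("marginal correlation handles the degenerate directions", {
  x <- rbind(a = 1:10, b = 1:10, c = -(1:10))
  r <- marginal_correlation(x + 0)   # identical and mirrored series
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_error(marginal_correlation(rbind(a = 1:5, b = rep(1, 5))), "b")
})

test_that("independent series have near-zero correlations", {
  set.seed(21)
  x <- matrix(rnorm(3 * 10000), 3)
  rownames(x) <- c("a", "b", "c")
  r <- marginal_correlation(x)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
  rho <- partial_correlation(x, shrinkage = 0)
  expect_lt(max(abs(rho[upper.tri(rho)])), 0.05)
})

test_that("partial correlation removes chain confounding", {
  set.seed(22)
  n <- 10000
  x <- rnorm(n)
  y <- x + rnorm(n)
  z <- y + rnorm(n)
  m <- rbind(X = x, Y = y, Z = z)
  marg <- marginal_correlation(m)
  part <- partial_correlation(m, shrinkage = 0)
  expect_gt(marg["X", "Z"], 0.3)
  expect_lt(abs(part["X", "Z"]), 0.05)
  # residual-correlation oracle agreement
  oracle <- residual_partial_correlation(m)
  expect_equal(part[upper.tri(part)], oracle[upper.tri(oracle)],
               tolerance = 1e-6)
})

test_that("partial equals marginal for two ROIs and matches the oracle broadly", {
  set.seed(23)
  m2 <- matrix(rnorm(40), 2)
  rownames(m2) <- c("a", "b")
  expect_equal(partial_correlation(m2, shrinkage = 0)["a", "b"],
               marginal_correlation(m2)["a", "b"], tolerance = 1e-10)
  for (rep in 1:5) {
    m <- matrix(rnorm(6 * 500), 6)
    rownames(m) <- letters[1:6]
    part <- partial_correlation(m, shrinkage = 0)
    oracle <- residual_partial_correlation(m)
    expect_equal(part[upper.tri(part)], oracle[upper.tri(oracle)],
                 tolerance = 1e-6)
  }
})

test_that("positive graph requires agreement of both correlation flavours", {
  marg <- matrix(c(1, 0.5, 0.6,
                   0.5, 1, 0.4,
                   0.6, 0.4, 1), 3, dimnames = list(letters[1:3], letters[1:3]))
  part <- matrix(c(1, -0.1, 0.2,
                   -0.1, 1, 0.3,
                   0.2, 0.3, 1), 3, dimnames = list(letters[1:3], letters[1:3]))
  g <- positive_graph(marg, part)
  expect_equal(nrow(g$edges), 2)                       # a-b dropped
  expect_false(any(g$edges$from == "a" & g$edges$to == "b"))
  expect_equal(g$edges$weight[g$edges$from == "a"], 0.2)  # partial weight
  gm <- positive_graph(marg, part, weight_source = "marginal")
  expect_equal(gm$edges$weight[gm$edges$from == "a"], 0.6)
  # all-positive correlations give the complete graph
  ap <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(ap) <- 1
  expect_equal(nrow(positive_graph(ap, ap)$edges), 3)
  # roi_order mismatch
  bad <- part[c(2, 1, 3), c(2, 1, 3)]
  expect_error(positive_graph(marg, bad), class = "topofc_validation_error")
})

test_that("edge set is monotone in the correlations", {
  set.seed(24)
  base <- matrix(runif(25, -0.5, 0.8), 5)
  base <- (base + t(base)) / 2; diag(base) <- 1
  dimnames(base) <- list(letters[1:5], letters[1:5])
  g1 <- positive_graph(base, base)
  raised <- pmin(base + 0.3, 1); diag(raised) <- 1
  g2 <- positive_graph(raised, raised)
  key <- function(g) paste(g$edges$from, g$edges$to)
  expect_true(all(key(g1) %in% key(g2)))
})
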