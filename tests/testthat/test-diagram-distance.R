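test_that("identity, empty and singleton cases are exact", {
  set.seed(41)
  d <- random_diagram(4)
  expect_equal(wasserstein_distance(d, d), 0)
  empty <- d[0, ]
  expect_equal(wasserstein_distance(empty, empty), 0)
  one <- tibble::tibble(dimension = 1L, birth = 0, death = 2, kind = "ordinary")
  expect_equal(wasserstein_distance(one, empty, q = 1), 1)
  expect_equal(wasserstein_distance(empty, one, q = 1), 1)
  # mismatched dimension/kind is refused
  other <- tibble::tibble(dimension = 0L, birth = 0, death = 1,
                          kind = "ordinary")
  expect_error(wasserstein_distance(one, other),
               class = "topofc_validation_error")
})

test_that("exact assignment equals exhaustive matching on random diagrams", {
  set.seed(42)
  for (rep in 1:100) {
    q <- sample(c(1, 2), 1)
    ext <- runif(1) < 0.3
    X <- random_diagram(sample(0:5, 1), extended = ext,
                        kind = if (ext) "extended" else "ordinary")
    Y <- random_diagram(sample(0:5, 1), extended = ext,
                        kind = if (ext) "extended" else "ordinary")
    fast <- wasserstein_distance(X, Y, q = q)
    slow <- brute_wasserstein(as.matrix(X[, c("birth", "death")]),
                              as.matrix(Y[, c("birth", "death")]), q = q)
    expect_equal(fast, slow, tolerance = 1e-9,
                 info = sprintf("rep %d q=%d", rep, q))
  }
})

test_that("metric axioms hold on random triples", {
  set.seed(43)
  for (rep in 1:25) {
    X <- random_diagram(sample(1:4, 1))
    Y <- random_diagram(sample(1:4, 1))
    Z <- random_diagram(sample(1:4, 1))
    dxy <- wasserstein_distance(X, Y)
    dyx <- wasserstein_distance(Y, X)
    expect_equal(dxy, dyx, tolerance = 1e-12)
    dxz <- wasserstein_distance(X, Z)
    dyz <- wasserstein_distance(Y, Z)
    expect_lte(dxz, dxy + dyz + 1e-9)
    expect_equal(wasserstein_distance(X, X), 0)
    if (nrow(X) == nrow(Y) &&
        diagram_key(as.data.frame(X)) != diagram_key(as.data.frame(Y)))
      expect_gt(dxy, 0)
  }
})

test_that("moving a point farther from its target never lowers the distance", {
  set.seed(44)
  base <- random_diagram(3)
  other <- random_diagram(3)
  d0 <- wasserstein_distance(base, other)
  moved <- base
  moved$death[1] <- moved$death[1] + 10   # far from everything
  expect_gte(wasserstein_distance(moved, other), d0 - 1e-9)
})

test_that("essential points follow the infinite-death policy", {
  x <- tibble::tibble(dimension = 0L, birth = c(0, 0), death = c(2, Inf),
                      kind = "ordinary")
  y <- tibble::tibble(dimension = 0L, birth = 0, death = 3, kind = "ordinary")
  # truncate: Inf -> 3 (max finite death across both)
  d_trunc <- wasserstein_distance(x, y)
  xt <- x; xt$death[2] <- 3
  expect_equal(d_trunc,
               brute_wasserstein(as.matrix(xt[, c("birth", "death")]),
                                 as.matrix(y[, c("birth", "death")])))
  # drop: essential point vanishes
  d_drop <- wasserstein_distance(x, y, infinite_death_policy = "drop_essential")
  expect_equal(d_drop,
               brute_wasserstein(matrix(c(0, 2), 1),
                                 as.matrix(y[, c("birth", "death")])))
})

test_that("distance matrices are symmetric, zero-diagonal, order-equivariant", {
  set.seed(45)
  dgs <- list(s1 = random_diagram(2), s2 = random_diagram(3),
              s3 = random_diagram(1))
  m <- inter_subject_matrix(dgs)
  expect_equal(m, t(m), ignore_attr = TRUE)
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_true(all(m >= 0))
  expect_equal(attr(m, "axis"), "subjects")
  # permutation equivariance
  m2 <- inter_subject_matrix(dgs[c(3, 1, 2)])
  expect_equal(unclass(m2)[, ], unclass(m)[c(3, 1, 2), c(3, 1, 2)],
               ignore_attr = TRUE)
  # identical diagrams give the zero matrix
  mz <- inter_subject_matrix(list(a = dgs$s1, b = dgs$s1))
  expect_equal(max(mz), 0)
  # known pair value
  da <- tibble::tibble(dimension = 1L, birth = 0, death = 1, kind = "ordinary")
  db <- tibble::tibble(dimension = 1L, birth = 0, death = 3, kind = "ordinary")
  mm <- inter_subject_matrix(list(a = da, b = db))
  expect_equal(mm["a", "b"], brute_wasserstein(matrix(c(0, 1), 1),
                                               matrix(c(0, 3), 1)))
})

test_that("inter_roi_matrix mirrors the subject construction on the ROI axis", {
  set.seed(46)
  tbl <- tibble::tibble(roi_id = c("r1", "r2", "r3"),
                        diagram = list(random_diagram(2), random_diagram(2),
                                       random_diagram(2)))
  m <- inter_roi_matrix(tbl, context = list(network = "NET", dimension = 1L))
  expect_equal(attr(m, "axis"), "rois")
  expect_equal(rownames(m), tbl$roi_id)
  expect_equal(m, t(m), ignore_attr = TRUE)
  # missing diagram errors with the label
  tbl$diagram[2] <- list(NULL)
  expect_error(inter_roi_matrix(tbl), "r2")
})
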