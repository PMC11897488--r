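subject_matrix <- function(values, labels) {
  m <- matrix(values, length(labels), length(labels))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  attr(m, "axis") <- "subjects"
  class(m) <- c("fc_distmat", class(m))
  m
}

test_that("separated samples reach the exact extreme p-value", {
  # 4 subjects/group: 6 within-block distances each; construct blocks with
  # values {1..6} vs {101..106}
  labs <- sprintf("S%02d", 1:8)
  groups <- setNames(rep(c("A", "B"), each = 4), labs)
  m <- matrix(0, 8, 8, dimnames = list(labs, labs))
  m[1:4, 1:4][upper.tri(m[1:4, 1:4])] <- 1:6
  m[5:8, 5:8][upper.tri(m[5:8, 5:8])] <- 101:106
  m <- m + t(m)
  m[1:4, 5:8] <- 50; m[5:8, 1:4] <- 50
  attr(m, "axis") <- "subjects"
  res <- wilcoxon_contrast(m, groups, c("A", "B"))
  # exact two-sided rank-sum with 6 vs 6 fully separated: p = 2/choose(12,6)
  expect_equal(res$p_value, 2 / choose(12, 6), tolerance = 1e-12)
  expect_equal(res$n_a, 6)
  expect_true(res$significant)
})

test_that("3 vs 3 separated samples give exact p = 0.1", {
  # enumeration oracle: all C(6,3) allocations, two-sided
  oracle_p <- {
    vals <- c(1, 2, 3, 101, 102, 103)
    obs <- sum(rank(vals)[1:3])
    perms <- utils::combn(6, 3)
    stat <- apply(perms, 2, function(ix) sum(rank(vals)[ix]))
    mean(abs(stat - mean(stat)) >= abs(obs - mean(stat)))
  }
  expect_equal(oracle_p, 0.1)
  labs <- sprintf("S%02d", 1:6)
  groups <- setNames(rep(c("A", "B"), each = 3), labs)
  m <- matrix(0, 6, 6, dimnames = list(labs, labs))
  m[1:3, 1:3][upper.tri(m[1:3, 1:3])] <- c(1, 2, 3)
  m[4:6, 4:6][upper.tri(m[4:6, 4:6])] <- c(101, 102, 103)
  m <- m + t(m)
  attr(m, "axis") <- "subjects"
  res <- wilcoxon_contrast(m, groups, c("A", "B"))
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
})

test_that("label swap flips nothing but the statistic's direction", {
  set.seed(51)
  labs <- sprintf("S%02d", 1:10)
  groups <- setNames(rep(c("A", "B"), each = 5), labs)
  m <- subject_matrix(runif(100, 1, 2), labs)
  r1 <- wilcoxon_contrast(m, groups, c("A", "B"))
  r2 <- wilcoxon_contrast(m, groups, c("B", "A"))
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  # centred Mann-Whitney statistics are negatives of each other
  expect_equal(r1$statistic - r1$n_a * r1$n_b / 2,
               -(r2$statistic - r2$n_a * r2$n_b / 2), tolerance = 1e-12)
})

test_that("the test is scale-invariant (rank-based)", {
  set.seed(52)
  labs <- sprintf("S%02d", 1:10)
  groups <- setNames(rep(c("A", "B"), each = 5), labs)
  m <- subject_matrix(runif(100, 1, 2), labs)
  r1 <- wilcoxon_contrast(m, groups, c("A", "B"))
  r2 <- wilcoxon_contrast(m * 37.5, groups, c("A", "B"))
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$statistic, r2$statistic)
})

test_that("identical constant samples are maximally non-significant", {
  labs <- sprintf("S%02d", 1:8)
  groups <- setNames(rep(c("A", "B"), each = 4), labs)
  m <- subject_matrix(rep(1, 64), labs)
  res <- wilcoxon_contrast(m, groups, c("A", "B"))
  expect_gte(res$p_value, 0.99)
  expect_false(res$significant)
})

test_that("validation: group sizes and labels are checked", {
  labs <- c("S1", "S2", "S3")
  groups <- setNames(c("A", "A", "B"), labs)
  m <- subject_matrix(runif(9), labs)
  expect_error(wilcoxon_contrast(m, groups, c("A", "B")), "B")
  expect_error(wilcoxon_contrast(m, groups, c("A", "C")), "C")
  # mean policy works with one subject per group
  res <- wilcoxon_contrast(m, groups, c("A", "B"),
                           policy = "mean_distance_per_subject")
  expect_equal(res$n_b, 1)
})

test_that("group_statistics maps over tables and adjusts when asked", {
  set.seed(53)
  labs <- sprintf("S%02d", 1:12)
  groups <- setNames(rep(c("HC", "MCI"), each = 6), labs)
  wd <- tibble::tibble(
    network = c("N1", "N1"), dimension = c(0L, 1L),
    wd = list(subject_matrix(runif(144), labs),
              subject_matrix(runif(144), labs)))
  out <- group_statistics(wd, groups)
  expect_equal(nrow(out), 2)
  expect_true(all(c("label", "p_value", "network", "dimension") %in% names(out)))
  adj <- group_statistics(wd, groups, adjust = "BH")
  expect_true(all(adj$p_value >= out$p_value - 1e-12))
})
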