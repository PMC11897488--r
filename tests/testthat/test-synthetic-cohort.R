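test_that("cohort_spec validates fields and names the offender", {
  expect_error(cohort_spec(n_subjects_per_group = 0), "n_subjects_per_group")
  expect_error(cohort_spec(ar_coefficient = 1), "ar_coefficient")
  expect_error(cohort_spec(coupling_base = 0.9,
                           coupling_shift_per_group = c(MCI = 0.3)),
               "coupling_base")
  expect_error(cohort_spec(coupling_shift_per_group = c(XX = 0.1)), "XX")
  expect_error(cohort_spec(networks = c(3, 4)), "networks")
})

test_that("default network partition matches the six-network parcellation", {
  nw <- dosenbach_networks()
  expect_identical(unname(nw),
                   c(18L, 32L, 34L, 21L, 22L, 33L))
  expect_identical(names(nw), c("CB", "CO", "DMN", "FP", "OP", "SM"))
  expect_identical(sum(nw), 160L)
})

test_that("generated panels are deterministic, balanced and complete", {
  sp <- cohort_spec(n_subjects_per_group = 3, groups = c("HC", "EMCI", "LMCI"),
                    networks = c(A = 4, B = 3), n_timepoints = 30,
                    coupling_shift_per_group = c(EMCI = 0.15, LMCI = 0.3),
                    seed = 11)
  p1 <- generate_cohort(sp)
  p2 <- generate_cohort(sp)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 9 * 7)
  expect_equal(length(time_cols <- grep("^t[0-9]+$", names(p1))), 30)
  groups <- p1$group[!duplicated(p1$subject_id)]
  expect_equal(unname(table(groups)[c("HC", "EMCI", "LMCI")]),
               rep(3L, 3), ignore_attr = TRUE)
  vals <- as.matrix(p1[, grep("^t", names(p1))])
  expect_false(anyNA(vals))
  expect_true(all(apply(vals, 1, stats::var) > 0))
  # different seeds give different data
  expect_false(identical(p1, generate_cohort(
    cohort_spec(n_subjects_per_group = 3, groups = c("HC", "EMCI", "LMCI"),
                networks = c(A = 4, B = 3), n_timepoints = 30,
                coupling_shift_per_group = c(EMCI = 0.15, LMCI = 0.3),
                seed = 12))))
})

test_that("planted coupling shift raises within-network correlations", {
  sp <- cohort_spec(n_subjects_per_group = 20, groups = c("HC", "MCI"),
                    networks = c(NET = 8), n_timepoints = 150,
                    coupling_base = 0.3,
                    coupling_shift_per_group = c(MCI = 0.3), seed = 1)
  panel <- generate_cohort(sp)
  mean_r <- function(subj) {
    m <- topofc:::panel_matrix(panel, subj)
    r <- stats::cor(t(m))
    mean(r[upper.tri(r)])
  }
  subjects <- unique(panel$subject_id)
  groups <- topofc:::panel_groups(panel)
  r_hc <- vapply(subjects[groups == "HC"], mean_r, numeric(1))
  r_mci <- vapply(subjects[groups == "MCI"], mean_r, numeric(1))
  expect_gt(mean(r_mci), mean(r_hc))
})

test_that("effect monotonicity: larger shift, larger correlation gap", {
  gap_for_shift <- function(shift, seed) {
    panel <- tiny_cohort(seed = seed, n_per_group = 6, n_roi = 8, T = 100,
                         shift = shift)
    groups <- topofc:::panel_groups(panel)
    mean_r <- function(subj) {
      r <- stats::cor(t(topofc:::panel_matrix(panel, subj)))
      mean(r[upper.tri(r)])
    }
    subjects <- names(groups)
    mean(vapply(subjects[groups == "MCI"], mean_r, numeric(1))) -
      mean(vapply(subjects[groups == "HC"], mean_r, numeric(1)))
  }
  gaps <- vapply(c(0, 0.2, 0.4), function(s)
    mean(vapply(1:5, function(seed) gap_for_shift(s, seed), numeric(1))),
    numeric(1))
  expect_true(all(diff(gaps) > 0))
})
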