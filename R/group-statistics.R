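#' Wilcoxon rank-sum contrast on an inter-subject distance matrix
#'
#' Tests whether the distribution of inter-subject Wasserstein distances
#' differs between two groups. Under the default
#' `"within_block_upper_triangle"` policy the two samples are the
#' within-group distances (upper triangle of each group's block of the
#' matrix); the alternative `"mean_distance_per_subject"` policy uses one
#' number per subject, its mean distance to all other subjects. The
#' two-sided rank-sum test is exact (full enumeration) when the smaller
#' sample has at most 10 values and the data are tie-free, and otherwise
#' uses the normal approximation with continuity and tie correction.
#'
#' @param mat An `fc_distmat` with subject axis.
#' @param groups Named character vector mapping subject to group, or a data
#'   frame with `subject_id` and `group` columns.
#' @param contrast Length-2 character vector (groupA, groupB).
#' @param policy Sample-assembly policy (see above).
#' @param alpha Significance threshold used only for the `significant`
#'   label.
#' @return One-row tibble: `network`, `dimension`, `group_a`, `group_b`,
#'   `statistic` (Mann-Whitney U of group A), `p_value`, `n_a`, `n_b`,
#'   `sample_policy`, `significant`.
#' @export
wilcoxon_contrast <- function(mat, groups, contrast,
                              policy = c("within_block_upper_triangle",
                                         "mean_distance_per_subject"),
                              alpha = 0.05) {
  policy <- match.arg(policy)
  if (!is.null(attr(mat, "axis")) && attr(mat, "axis") != "subjects")
    abort("`mat` must be an inter-subject distance matrix")
  if (is.data.frame(groups))
    groups <- setNames(groups$group, groups$subject_id)
  if (length(contrast) != 2L)
    abort("`contrast` must name exactly two groups")
  labs <- rownames(mat)
  g <- unname(groups[labs])
  if (anyNA(g)) abort("every subject in the matrix needs a group label")
  if (!all(contrast %in% g))
    abort(paste0("contrast group(s) absent from the matrix: ",
                 paste(setdiff(contrast, g), collapse = ", ")))

  pull_sample <- function(label) {
    idx <- which(g == label)
    if (policy == "within_block_upper_triangle") {
      if (length(idx) < 2L)
        abort(sprintf("group %s has < 2 subjects under the within-block policy",
                      label))
      blk <- mat[idx, idx, drop = FALSE]
      blk[upper.tri(blk)]
    } else {
      # mean distance from each subject to every other subject
      rowSums(mat[idx, , drop = FALSE]) / (ncol(mat) - 1)
    }
  }
  xa <- pull_sample(contrast[1])
  xb <- pull_sample(contrast[2])
  has_ties <- anyDuplicated(c(xa, xb)) > 0
  exact <- min(length(xa), length(xb)) <= 10 && !has_ties
  if (length(unique(c(xa, xb))) == 1L) {
    # fully tied data carry no rank information: statistic at its centre
    wt <- list(statistic = length(xa) * length(xb) / 2, p.value = 1)
  } else {
    wt <- suppressWarnings(
      wilcox.test(xa, xb, alternative = "two.sided", exact = exact,
                  correct = TRUE))
  }
  ctx <- attr(mat, "context")
  tibble(network = ctx$network %||% NA_character_,
         dimension = ctx$dimension %||% NA_integer_,
         group_a = contrast[1], group_b = contrast[2],
         statistic = unname(wt$statistic),
         p_value = wt$p.value,
         n_a = length(xa), n_b = length(xb),
         sample_policy = policy,
         significant = wt$p.value < alpha)
}

#' Wilcoxon contrasts across networks, dimensions and group pairs
#'
#' Maps [wilcoxon_contrast()] over a table of distance matrices, yielding a
#' summary table with one row per network x dimension x contrast and an
#' `NS` label for p >= 0.05. Raw p-values are reported; pass
#' `adjust = "BH"` for Benjamini-Hochberg correction across the rows.
#'
#' @param wd Tibble with columns `network`, `dimension` and a `wd`
#'   list-column of `fc_distmat` objects.
#' @param groups Subject-to-group map (see [wilcoxon_contrast()]).
#' @param contrasts List of length-2 character vectors; default all
#'   unordered pairs of observed groups.
#' @param policy,alpha Passed to [wilcoxon_contrast()].
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return Tibble of test results with a `label` column (`p` or `"NS"`).
#' @export
group_statistics <- function(wd, groups, contrasts = NULL,
                             policy = "within_block_upper_triangle",
                             alpha = 0.05, adjust = "none") {
  if (is.data.frame(groups))
    groups <- setNames(groups$group, groups$subject_id)
  if (is.null(contrasts)) {
    gl <- unique(unname(groups))
    contrasts <- combn(gl, 2, simplify = FALSE)
  }
  rows <- purrr::pmap(list(wd$network, wd$dimension, wd$wd),
                      function(nw, dim, m) {
    dplyr::bind_rows(lapply(contrasts, function(ct) {
      out <- wilcoxon_contrast(m, groups, ct, policy = policy, alpha = alpha)
      out$network <- nw
      out$dimension <- dim
      out
    }))
  })
  out <- dplyr::bind_rows(rows)
  if (!identical(adjust, "none")) {
    out$p_value <- stats::p.adjust(out$p_value, method = adjust)
    out$significant <- out$p_value < alpha
  }
  out$label <- ifelse(out$p_value < alpha,
                      sprintf("p = %.3g", out$p_value), "NS")
  out
}
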