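#' Specify a synthetic fMRI cohort
#'
#' Parameters of the latent-factor generative model used by
#' [generate_cohort()]. Each brain network is driven by `latent_rank` shared
#' AR(1) factors; every ROI series is a coupling-weighted mixture of its
#' network's factors and an idiosyncratic AR(1) term. Group structure enters
#' through the coupling coefficient only, so groups differ in connectivity,
#' not in signal mean -- mirroring the connectivity-topological character of
#' the downstream analyses.
#'
#' @param n_subjects_per_group Number of subjects in each group.
#' @param groups Ordered character vector of group labels.
#' @param networks Named integer vector mapping network name to ROI count.
#'   Defaults to the six-network parcellation used throughout the package
#'   (CB 18, CO 32, DMN 34, FP 21, OP 22, SM 33 -- 160 ROIs).
#' @param n_timepoints Length of every ROI series (TR-resolution samples).
#' @param latent_rank Number of shared AR(1) drivers per network.
#' @param coupling_base Baseline coupling \eqn{c \in [0,1]}: the fraction of
#'   each ROI's variance explained by its network's shared drivers.
#' @param coupling_shift_per_group Named numeric vector of additive shifts to
#'   `coupling_base`, one entry per group (missing groups shift by 0).
#' @param noise_sd Standard deviation of the idiosyncratic AR(1) term, in
#'   signal units (the shared drivers have unit variance).
#' @param ar_coefficient AR(1) coefficient of drivers and noise, |phi| < 1.
#'   Gives the band-limited, temporally smooth character of fMRI series.
#' @param seed Integer master seed; one sub-seed per subject is derived from
#'   it so individual subjects are reproducible.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects_per_group = 20,
                        groups = c("HC", "MCI"),
                        networks = dosenbach_networks(),
                        n_timepoints = 150,
                        latent_rank = 2,
                        coupling_base = 0.3,
                        coupling_shift_per_group = c(MCI = 0.3),
                        noise_sd = 1,
                        ar_coefficient = 0.4,
                        seed = 1) {
  n_subjects_per_group <- assert_count(n_subjects_per_group, "n_subjects_per_group")
  n_timepoints <- assert_count(n_timepoints, "n_timepoints")
  latent_rank <- assert_count(latent_rank, "latent_rank")
  if (!is.character(groups) || length(groups) < 1L || anyDuplicated(groups))
    abort("`groups` must be distinct group labels", class = "topofc_validation_error")
  if (is.null(names(networks)) || any(names(networks) == "") ||
      anyDuplicated(names(networks)))
    abort("`networks` must be a named vector of ROI counts",
          class = "topofc_validation_error")
  networks <- vapply(networks, assert_count, integer(1), name = "networks")
  coupling_base <- assert_prob(coupling_base, "coupling_base")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    abort("`noise_sd` must be > 0", class = "topofc_validation_error")
  if (!is.numeric(ar_coefficient) || abs(ar_coefficient) >= 1)
    abort("`ar_coefficient` must satisfy |phi| < 1",
          class = "topofc_validation_error")
  if (length(coupling_shift_per_group)) {
    if (is.null(names(coupling_shift_per_group)))
      abort("`coupling_shift_per_group` must be named by group",
            class = "topofc_validation_error")
    unknown <- setdiff(names(coupling_shift_per_group), groups)
    if (length(unknown))
      abort(paste0("`coupling_shift_per_group` names unknown group(s): ",
                   paste(unknown, collapse = ", ")),
            class = "topofc_validation_error")
  }
  shifts <- setNames(rep(0, length(groups)), groups)
  shifts[names(coupling_shift_per_group)] <- coupling_shift_per_group
  bad <- coupling_base + shifts
  if (any(bad < 0 | bad > 1))
    abort("`coupling_base` plus every group shift must lie in [0, 1]",
          class = "topofc_validation_error")
  structure(
    list(n_subjects_per_group = n_subjects_per_group, groups = groups,
         networks = networks, n_timepoints = n_timepoints,
         latent_rank = latent_rank, coupling_base = coupling_base,
         coupling_shift_per_group = shifts, noise_sd = noise_sd,
         ar_coefficient = ar_coefficient, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' The six-network ROI partition
#'
#' ROI counts of the six classical resting-state networks used throughout:
#' cerebellum (CB), cingulo-opercular (CO), default mode (DMN),
#' fronto-parietal (FP), occipital (OP) and sensorimotor (SM) -- 160 ROIs in
#' total.
#'
#' @return Named integer vector of ROI counts.
#' @export
dosenbach_networks <- function() {
  c(CB = 18L, CO = 32L, DMN = 34L, FP = 21L, OP = 22L, SM = 33L)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d subjects/group x %s; T = %d, phi = %.2f\n",
              x$n_subjects_per_group, paste(x$groups, collapse = "/"),
              x$n_timepoints, x$ar_coefficient))
  cat(sprintf("  networks: %s\n",
              paste(sprintf("%s(%d)", names(x$networks), x$networks),
                    collapse = " ")))
  cat(sprintf("  coupling: base %.2f, shifts %s; rank %d; noise sd %.2f; seed %d\n",
              x$coupling_base,
              paste(sprintf("%s%+.2f", names(x$coupling_shift_per_group),
                            x$coupling_shift_per_group), collapse = " "),
              x$latent_rank, x$noise_sd, x$seed))
  invisible(x)
}

# unit-variance AR(1) path of length n
ar1_series <- function(n, phi) {
  innov_sd <- sqrt(1 - phi^2)
  as.numeric(stats::arima.sim(list(ar = phi), n = n, sd = innov_sd,
                              n.start = 50))
}

#' Generate a synthetic ROI time-series cohort
#'
#' Draws one panel of ROI time series under the latent-factor AR(1) model of
#' [cohort_spec()]. For a subject in group g with coupling
#' \eqn{c = c_{base} + shift(g)}, ROI i of network k is
#' \deqn{x_i(t) = \sqrt{c}\, m_i(t) + \sqrt{1 - c}\, \sigma\, \epsilon_i(t)}
#' where \eqn{m_i} is a unit-variance mixture (random unit weights) of the
#' network's `latent_rank` shared AR(1) drivers and \eqn{\epsilon_i} is an
#' independent AR(1) series. Higher coupling therefore raises within-network
#' correlations without changing means. Identical specs (including seed)
#' yield bit-identical panels.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject x ROI: columns `subject_id`,
#'   `group`, `roi_id`, `network`, then time columns `t0001`...`tNNNN`.
#' @examples
#' sp <- cohort_spec(n_subjects_per_group = 2, networks = c(DMN = 4),
#'                   n_timepoints = 30, seed = 7)
#' panel <- generate_cohort(sp)
#' dim(panel)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    abort("`spec` must be created by cohort_spec()",
          class = "topofc_validation_error")
  n_total <- spec$n_subjects_per_group * length(spec$groups)
  subject_seeds <- derive_seeds(spec$seed, n_total)
  subject_ids <- sprintf("S%03d", seq_len(n_total))
  subject_groups <- rep(spec$groups, each = spec$n_subjects_per_group)

  roi_ids <- unlist(lapply(names(spec$networks), function(nw)
    sprintf("%s_%02d", nw, seq_len(spec$networks[[nw]]))), use.names = FALSE)
  roi_network <- rep(names(spec$networks), spec$networks)

  tn <- spec$n_timepoints
  phi <- spec$ar_coefficient

  rows <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    g <- subject_groups[s]
    cc <- spec$coupling_base + spec$coupling_shift_per_group[[g]]
    vals <- with_preserved_rng({
      set.seed(subject_seeds[s])
      do.call(rbind, lapply(names(spec$networks), function(nw) {
        p <- spec$networks[[nw]]
        drivers <- vapply(seq_len(spec$latent_rank), function(i)
          ar1_series(tn, phi), numeric(tn))       # tn x rank
        # non-negative mixing weights: within-network correlations lean
        # positive, as resting-state networks do and the positive-graph
        # construction assumes
        w <- matrix(abs(rnorm(p * spec$latent_rank)), p)
        w <- w / sqrt(rowSums(w^2))                # unit mixing weights
        mix <- w %*% t(drivers)                    # p x tn, unit variance
        eps <- t(vapply(seq_len(p), function(i)
          ar1_series(tn, phi), numeric(tn)))       # p x tn
        sqrt(cc) * mix + sqrt(1 - cc) * spec$noise_sd * eps
      }))
    })
    colnames(vals) <- sprintf("t%04d", seq_len(tn))
    rows[[s]] <- dplyr::bind_cols(
      tibble(subject_id = subject_ids[s], group = g,
             roi_id = roi_ids, network = roi_network),
      as_tibble(vals))
  }
  dplyr::bind_rows(rows)
}
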