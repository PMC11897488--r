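#' Inter-subject distance tables from graph-filtration diagrams
#'
#' For each network and homology dimension, assembles the subjects x
#' subjects Wasserstein matrix from the diagrams of
#' [graph_diagrams_panel()].
#'
#' @param diagrams Tibble with `subject_id`, `network`, `diagram` columns.
#' @param dimensions Homology dimensions to process (0 = ordinary
#'   components, 1 = extended loops).
#' @param q,infinite_death_policy Passed to [wasserstein_distance()].
#' @return Tibble `network`, `dimension`, `wd` (list of `fc_distmat`).
#' @export
wd_subject_tables <- function(diagrams, dimensions = c(0, 1), q = 1,
                              infinite_death_policy = "truncate_to_max_finite") {
  grid <- tidyr::expand_grid(network = unique(diagrams$network),
                             dimension = as.integer(dimensions))
  grid$wd <- purrr::map2(grid$network, grid$dimension, function(nw, dim) {
    sl <- diagrams[diagrams$network == nw, ]
    dg <- lapply(sl$diagram, function(d) d[d$dimension == dim, , drop = FALSE])
    inter_subject_matrix(
      tibble(subject_id = sl$subject_id, diagram = dg), q = q,
      infinite_death_policy = infinite_death_policy,
      context = list(network = nw, dimension = dim,
                     kind = if (dim == 0) "ordinary" else "extended"))
  })
  grid
}

#' Inter-ROI distance tables from Vietoris-Rips diagrams
#'
#' For each subject, network and homology dimension, assembles the ROI x ROI
#' Wasserstein matrix from the diagrams of [rips_panel()].
#'
#' @param diagrams Tibble with `subject_id`, `roi_id`, `network`, `diagram`.
#' @param dimensions Homology dimensions (0, 1, 2).
#' @param q,infinite_death_policy Passed to [wasserstein_distance()].
#' @return Tibble `subject_id`, `group`, `network`, `dimension`, `wd`.
#' @export
wd_roi_tables <- function(diagrams, dimensions = 0:1, q = 1,
                          infinite_death_policy = "truncate_to_max_finite") {
  subj <- unique(diagrams[, c("subject_id", "group")])
  grid <- tidyr::expand_grid(subject_id = subj$subject_id,
                             network = unique(diagrams$network),
                             dimension = as.integer(dimensions))
  grid <- dplyr::left_join(grid, subj, by = "subject_id")
  grid$wd <- purrr::pmap(list(grid$subject_id, grid$network, grid$dimension),
                         function(s, nw, dim) {
    sl <- diagrams[diagrams$subject_id == s & diagrams$network == nw, ]
    dg <- lapply(sl$diagram, function(d) d[d$dimension == dim, , drop = FALSE])
    inter_roi_matrix(
      tibble(roi_id = sl$roi_id, diagram = dg), q = q,
      infinite_death_policy = infinite_death_policy,
      context = list(network = nw, dimension = dim, subject = s,
                     kind = "ordinary"))
  })
  grid[, c("subject_id", "group", "network", "dimension", "wd")]
}

stage_manifest <- function(dir, stage, params, files) {
  list(stage = stage, params = params,
       files = lapply(files, function(f)
         list(path = basename(f), md5 = unname(tools::md5sum(f)))),
       package_version = as.character(utils::packageVersion("topofc")))
}

manifest_path <- function(dir, stage) file.path(dir, paste0(stage, ".manifest.json"))

stage_cached <- function(dir, stage, params) {
  mp <- manifest_path(dir, stage)
  if (!file.exists(mp)) return(FALSE)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (!identical(jsonlite::toJSON(man$params, auto_unbox = TRUE),
                 jsonlite::toJSON(params, auto_unbox = TRUE))) return(FALSE)
  all(vapply(seq_len(nrow(man$files)), function(i) {
    f <- file.path(dir, man$files$path[i])
    file.exists(f) && unname(tools::md5sum(f)) == man$files$md5[i]
  }, logical(1)))
}

write_stage_manifest <- function(dir, stage, params, files) {
  jsonlite::write_json(stage_manifest(dir, stage, params, files),
                       manifest_path(dir, stage), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

#' Run the graph-filtration arm end to end
#'
#' Panel -> positive connectivity graphs -> ordinary/extended persistence ->
#' inter-subject Wasserstein matrices -> Wilcoxon contrasts -> stacked
#' ensemble per network x dimension. Every stage writes its artifacts and a
#' manifest (file hashes + parameters) under `out_dir`; a rerun with
#' identical inputs and parameters skips completed stages unless
#' `force = TRUE`.
#'
#' @param panel Panel tibble.
#' @param out_dir Output directory (created if missing).
#' @param networks Networks to include (default all).
#' @param transform Filter transform for [build_graph_filter()].
#' @param weight_source,shrinkage Passed to [connectivity_graphs()].
#' @param dimensions Homology dimensions for the distance stage.
#' @param q Wasserstein order.
#' @param contrasts Group contrasts (default all pairs).
#' @param stats_policy Sample policy for [wilcoxon_contrast()].
#' @param ensemble An [ensemble_config()] or `NULL` to skip classification.
#' @param seed Seed forwarded to the stochastic stages.
#' @param force Recompute even when cached.
#' @return List with `graphs`, `diagrams`, `wd`, `stats`, `ensembles` and
#'   the artifact directory.
#' @export
run_graph_arm <- function(panel, out_dir, networks = NULL,
                          transform = "identity",
                          weight_source = "partial", shrinkage = "auto",
                          dimensions = c(0, 1), q = 1, contrasts = NULL,
                          stats_policy = "within_block_upper_triangle",
                          ensemble = ensemble_config(), seed = 1,
                          force = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  networks <- networks %||% unique(panel$network)
  params <- list(networks = networks, transform = transform,
                 weight_source = weight_source,
                 shrinkage = if (identical(shrinkage, "auto")) "auto" else shrinkage,
                 dimensions = dimensions, q = q, seed = seed,
                 panel_hash = digest_panel(panel))

  message("graph arm: connectivity graphs")
  graphs <- connectivity_graphs(panel, networks, shrinkage, weight_source)
  message("graph arm: persistence diagrams")
  diagrams <- graph_diagrams_panel(graphs, transform)
  dg_files <- purrr::map2_chr(diagrams$subject_id, diagrams$network,
                              function(s, nw) {
    f <- file.path(out_dir, sprintf("graph_diagram_%s_%s.tsv", s, nw))
    f
  })
  if (force || !stage_cached(out_dir, "graph_diagrams", params)) {
    purrr::walk2(diagrams$diagram, dg_files, write_diagram)
    write_stage_manifest(out_dir, "graph_diagrams", params, dg_files)
  }

  message("graph arm: Wasserstein matrices")
  wd <- wd_subject_tables(diagrams, dimensions, q)
  wd_files <- purrr::map2_chr(wd$network, wd$dimension, function(nw, dim)
    file.path(out_dir, sprintf("wd_subjects_%s_H%d.tsv", nw, dim)))
  if (force || !stage_cached(out_dir, "wd_subjects", params)) {
    purrr::walk2(wd$wd, wd_files, write_distance_matrix)
    write_stage_manifest(out_dir, "wd_subjects", params, wd_files)
  }

  groups <- panel_groups(panel)
  stats <- group_statistics(wd, groups, contrasts, policy = stats_policy)
  stats_file <- file.path(out_dir, "group_statistics.tsv")
  write.table(stats, stats_file, sep = "\t", quote = FALSE, row.names = FALSE)

  ensembles <- NULL
  if (!is.null(ensemble)) {
    message("graph arm: stacked ensembles")
    gl <- unique(unname(groups))
    cts <- contrasts %||% combn(gl, 2, simplify = FALSE)
    ens_grid <- tidyr::expand_grid(network = networks,
                                   dimension = as.integer(dimensions))
    ensembles <- purrr::pmap(list(ens_grid$network, ens_grid$dimension),
                             function(nw, dim) {
      feats <- lifespan_features(diagrams[diagrams$network == nw, ],
                                 dimension = dim)
      lapply(cts, function(ct) {
        keep <- names(groups)[groups %in% ct]
        xs <- feats[keep, , drop = FALSE]
        ys <- groups[keep]
        sel <- rfe_select(xs, ys, ensemble$n_selected_features, seed = seed)
        fit_stacked_ensemble(xs[, sel, drop = FALSE], ys, ensemble)
      })
    })
    ens_grid$fits <- ensembles
    ensembles <- ens_grid
    report <- dplyr::bind_rows(purrr::pmap(
      list(ens_grid$network, ens_grid$dimension, ens_grid$fits),
      function(nw, dim, fits)
        dplyr::bind_rows(lapply(fits, function(f)
          dplyr::mutate(glance(f), network = nw, dimension = dim,
                        .before = 1)))))
    jsonlite::write_json(report, file.path(out_dir, "ensemble_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(graphs = graphs, diagrams = diagrams, wd = wd,
                 stats = stats, ensembles = ensembles, out_dir = out_dir))
}

#' Run the Vietoris-Rips arm end to end
#'
#' Panel -> sliding-window clouds -> Vietoris-Rips diagrams -> inter-ROI
#' Wasserstein matrices per subject -> hybrid network per network x
#' dimension. Artifacts and manifests as in [run_graph_arm()].
#'
#' @inheritParams run_graph_arm
#' @param m,tau Embedding parameters.
#' @param max_dim Highest homology dimension of the Rips stage.
#' @param max_points Subsample cap for the Rips stage.
#' @param hybrid A [hybrid_net_config()] or `NULL` to skip classification.
#' @param hybrid_dimensions Dimensions fed to the classifier.
#' @return List with `clouds`, `diagrams`, `wd`, `hybrids` and the artifact
#'   directory.
#' @export
run_vr_arm <- function(panel, out_dir, networks = NULL, m = 2, tau = 1,
                       max_dim = 1, max_points = NULL, q = 1,
                       hybrid = hybrid_net_config(),
                       hybrid_dimensions = 0, seed = 1, force = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  networks <- networks %||% unique(panel$network)
  panel <- panel[panel$network %in% networks, , drop = FALSE]
  params <- list(networks = networks, m = m, tau = tau, max_dim = max_dim,
                 q = q, seed = seed, panel_hash = digest_panel(panel))

  message("VR arm: sliding-window embedding")
  clouds <- embed_panel(panel, m = m, tau = tau)
  message("VR arm: Vietoris-Rips diagrams")
  diagrams <- rips_panel(clouds, max_dim = max_dim, max_points = max_points,
                         subsample_seed = seed)
  message("VR arm: inter-ROI Wasserstein matrices")
  wd <- wd_roi_tables(diagrams, dimensions = 0:max_dim, q = q)
  wd_files <- purrr::pmap_chr(list(wd$subject_id, wd$network, wd$dimension),
                              function(s, nw, dim)
    file.path(out_dir, sprintf("wd_roi_%s_%s_H%d.tsv", s, nw, dim)))
  if (force || !stage_cached(out_dir, "wd_roi", params)) {
    purrr::walk2(wd$wd, wd_files, write_distance_matrix)
    write_stage_manifest(out_dir, "wd_roi", params, wd_files)
  }

  hybrids <- NULL
  if (!is.null(hybrid)) {
    message("VR arm: hybrid networks")
    groups <- panel_groups(panel)
    gl <- unique(unname(groups))
    cts <- combn(gl, 2, simplify = FALSE)
    grid <- tidyr::expand_grid(network = networks,
                               dimension = as.integer(hybrid_dimensions))
    grid$fits <- purrr::pmap(list(grid$network, grid$dimension),
                             function(nw, dim) {
      sl <- wd[wd$network == nw & wd$dimension == dim, ]
      lapply(cts, function(ct) {
        keep <- sl$subject_id %in% names(groups)[groups %in% ct]
        mats <- sl$wd[keep]
        names(mats) <- sl$subject_id[keep]
        fit_hybrid_net(mats, groups[names(mats)], hybrid)
      })
    })
    hybrids <- grid
    report <- dplyr::bind_rows(purrr::pmap(
      list(grid$network, grid$dimension, grid$fits),
      function(nw, dim, fits)
        dplyr::bind_rows(lapply(fits, function(f)
          dplyr::mutate(glance(f), network = nw, dimension = dim,
                        .before = 1)))))
    jsonlite::write_json(report, file.path(out_dir, "hybrid_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(clouds = clouds, diagrams = diagrams, wd = wd,
                 hybrids = hybrids, out_dir = out_dir))
}

#' Run one or both analysis arms
#'
#' @inheritParams run_graph_arm
#' @param arm `"both"`, `"vr"` or `"graph"`.
#' @param ... Forwarded to [run_vr_arm()] and [run_graph_arm()].
#' @return Named list of the arms' results.
#' @export
run_pipeline <- function(panel, out_dir, arm = c("both", "vr", "graph"),
                         seed = 1, ...) {
  arm <- match.arg(arm)
  res <- list()
  dots <- list(...)
  if (arm %in% c("both", "graph")) {
    keep <- intersect(names(dots), names(formals(run_graph_arm)))
    res$graph <- do.call(run_graph_arm,
                         c(list(panel = panel,
                                out_dir = file.path(out_dir, "graph"),
                                seed = seed), dots[keep]))
  }
  if (arm %in% c("both", "vr")) {
    keep <- intersect(names(dots), names(formals(run_vr_arm)))
    res$vr <- do.call(run_vr_arm,
                      c(list(panel = panel,
                             out_dir = file.path(out_dir, "vr"),
                             seed = seed), dots[keep]))
  }
  invisible(res)
}

digest_panel <- function(panel) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(panel, f)
  unname(tools::md5sum(f))
}
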