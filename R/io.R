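#' Write / read a time-series panel
#'
#' The on-disk format is a TSV with columns `subject_id`, `roi_id`, then
#' `t0001`...`tNNNN`, plus a JSON sidecar (same path with extension `.json`)
#' holding `roi_network` and `subject_group` maps. `read_panel()` validates
#' the sidecar against the TSV and reconstructs the panel tibble.
#'
#' @param panel Panel tibble as produced by [generate_cohort()].
#' @param path Path of the TSV file; the sidecar path is derived from it.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns
#'   the panel tibble.
#' @export
write_panel <- function(panel, path) {
  stopifnot(is.data.frame(panel))
  need <- c("subject_id", "roi_id", "group", "network")
  if (!all(need %in% names(panel)))
    abort("panel must have subject_id, group, roi_id, network columns")
  tc <- time_cols(panel)
  if (length(tc) == 0L) abort("panel has no time columns (t0001...)")
  out <- panel[, c("subject_id", "roi_id", tc)]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- panel_sidecar_path(path)
  idx_r <- !duplicated(panel$roi_id)
  idx_s <- !duplicated(panel$subject_id)
  jsonlite::write_json(
    list(roi_network = as.list(setNames(panel$network[idx_r], panel$roi_id[idx_r])),
         subject_group = as.list(setNames(panel$group[idx_s], panel$subject_id[idx_s]))),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

panel_sidecar_path <- function(path) {
  sub("\\.[^./\\\\]+$", "", path) |> paste0(".json")
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sidecar <- panel_sidecar_path(path)
  if (!file.exists(sidecar)) abort(paste0("missing sidecar: ", sidecar))
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!all(c("roi_network", "subject_group") %in% names(side)))
    abort("sidecar must contain roi_network and subject_group maps")
  roi_network <- unlist(side$roi_network)
  subject_group <- unlist(side$subject_group)

  if (anyDuplicated(paste(raw$subject_id, raw$roi_id)))
    abort("duplicate subject x roi rows in panel file")
  missing_roi <- setdiff(unique(raw$roi_id), names(roi_network))
  if (length(missing_roi))
    abort(paste0("sidecar is missing network assignment for ROI(s): ",
                 paste(missing_roi, collapse = ", ")))
  missing_subj <- setdiff(unique(raw$subject_id), names(subject_group))
  if (length(missing_subj))
    abort(paste0("sidecar is missing group assignment for subject(s): ",
                 paste(missing_subj, collapse = ", ")))
  tc <- grep("^t[0-9]+$", names(raw), value = TRUE)
  if (length(tc) == 0L) abort("panel file has no time columns")
  vals <- as.matrix(raw[, tc, drop = FALSE])
  if (anyNA(vals)) abort("panel contains missing values")

  # per-ROI count consistency: every subject carries every ROI
  tab <- table(raw$subject_id)
  if (length(unique(tab)) != 1L)
    abort("panel dimension mismatch: subjects carry different ROI counts")

  dplyr::bind_cols(
    tibble(subject_id = raw$subject_id,
           group = unname(subject_group[raw$subject_id]),
           roi_id = raw$roi_id,
           network = unname(roi_network[raw$roi_id])),
    as_tibble(as.data.frame(vals)))
}

#' Write / read a persistence diagram table
#'
#' Diagrams are tibbles with columns `dimension`, `birth`, `death`, `kind`;
#' infinite deaths are serialised as the string `"inf"`.
#'
#' @param diagram Diagram tibble (may hold several dimensions).
#' @param path TSV path.
#' @export
write_diagram <- function(diagram, path) {
  out <- diagram
  out$death <- ifelse(is.infinite(out$death), "inf",
                      format(out$death, digits = 17))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(death = "character"))
  death <- ifelse(raw$death == "inf", Inf, as.numeric(raw$death))
  tibble(dimension = as.integer(raw$dimension),
         birth = as.numeric(raw$birth), death = death,
         kind = as.character(raw$kind))
}

#' Write / read a labelled distance matrix
#'
#' The TSV carries labels in the header row and first column; the axis and
#' context (network, homology dimension, filtration kind) go to a JSON
#' sidecar.
#'
#' @param mat Matrix from [inter_subject_matrix()] or [inter_roi_matrix()].
#' @param path TSV path.
#' @export
write_distance_matrix <- function(mat, path) {
  df <- data.frame(label = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ctx <- attributes(mat)[c("axis", "context")]
  jsonlite::write_json(ctx, panel_sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "double"
  sidecar <- panel_sidecar_path(path)
  if (file.exists(sidecar)) {
    ctx <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(m, "axis") <- ctx$axis
    attr(m, "context") <- ctx$context
  }
  class(m) <- c("fc_distmat", class(m))
  m
}

#' Write a weighted graph as an edge list (plus node list)
#'
#' @param graph An `fc_graph` from [positive_graph()].
#' @param path TSV path for the edge list; a `<path>.nodes` file keeps the
#'   full node list (isolated nodes included).
#' @export
write_graph_edges <- function(graph, path) {
  write.table(graph$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(graph$nodes, paste0(path, ".nodes"))
  invisible(path)
}

#' @rdname write_graph_edges
#' @export
read_graph_edges <- function(path) {
  edges <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  nodes <- readLines(paste0(path, ".nodes"))
  new_fc_graph(nodes, edges)
}
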