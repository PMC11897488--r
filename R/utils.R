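# Internal helpers shared across modules.

# Derive a reproducible stream of sub-seeds from one master seed, so that e.g.
# each subject's series can be regenerated individually. Uses R's RNG once,
# in a local scope, without disturbing the caller's RNG state.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  with_preserved_rng({
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max - 1L, n)
  })
}

# Evaluate expr, restoring .Random.seed afterwards.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "topofc_validation_error")
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single number in [0, 1]", name),
          class = "topofc_validation_error")
  as.numeric(x)
}

# Names of the time-point columns of a panel tibble (t0001, t0002, ...).
time_cols <- function(panel) {
  grep("^t[0-9]+$", names(panel), value = TRUE)
}

# Extract the ROI x time numeric matrix for one subject (optionally one
# network) from a panel tibble, rows named by roi_id.
panel_matrix <- function(panel, subject, network = NULL) {
  rows <- panel$subject_id == subject
  if (!is.null(network)) rows <- rows & panel$network == network
  sl <- panel[rows, , drop = FALSE]
  if (nrow(sl) == 0L) abort("no panel rows match the requested subject/network")
  m <- as.matrix(sl[, time_cols(sl), drop = FALSE])
  rownames(m) <- sl$roi_id
  storage.mode(m) <- "double"
  m
}

panel_subjects <- function(panel) unique(panel$subject_id)

panel_groups <- function(panel) {
  idx <- !duplicated(panel$subject_id)
  setNames(panel$group[idx], panel$subject_id[idx])
}
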