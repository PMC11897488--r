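#' Vietoris-Rips persistence diagrams of a point cloud
#'
#' Builds the Vietoris-Rips filtration of a finite point cloud (a simplex
#' enters when its largest pairwise distance reaches the scale) and computes
#' persistent homology over GF(2) by boundary-matrix reduction, for homology
#' dimensions 0 up to `max_dim`.
#'
#' Edge inclusion uses a non-strict comparison (distance <= scale); for a
#' finite point set this changes the diagram only on a measure-zero set of
#' scales and matches standard practice. The default scale cap is the
#' enclosing radius (the smallest radius at which some point is within reach
#' of all others), beyond which no finite feature survives; the single
#' essential H0 class is reported with death `Inf`. Zero-persistence pairs
#' are kept in dimension 0 (so the H0 bar count equals the point count) and
#' dropped in higher dimensions.
#'
#' When `max_dim = 2` the 3-simplex enumeration grows quartically, so clouds
#' are first reduced to `max_points` (default 60) by seeded farthest-point
#' subsampling; set `max_points = Inf` to disable.
#'
#' @param cloud Numeric matrix, one point per row, or a `dist` object.
#' @param max_dim Highest homology dimension (0, 1 or 2).
#' @param max_scale Filtration cap; `NULL` means the enclosing radius.
#' @param max_points Subsample cap; default 60 when `max_dim = 2`, unlimited
#'   otherwise.
#' @param subsample_seed Seed for the farthest-point start.
#' @param simplex_budget Refuse to enumerate more than this many simplices.
#' @return Tibble with columns `dimension`, `birth`, `death`, `kind`
#'   (`"ordinary"`), sorted by (dimension, birth, death).
#' @examples
#' eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
#' rips_diagrams(eq, max_dim = 1)   # H0: (0,1) x2 and (0,Inf); H1 empty
#' @export
rips_diagrams <- function(cloud, max_dim = 1, max_scale = NULL,
                          max_points = NULL, subsample_seed = 1,
                          simplex_budget = 5e6) {
  max_dim <- assert_count(max_dim, "max_dim", min = 0L)
  if (max_dim > 2) abort("max_dim must be 0, 1 or 2")
  if (inherits(cloud, "dist")) {
    d <- as.matrix(cloud)
  } else {
    cloud <- as.matrix(cloud)
    if (nrow(cloud) < 1L) abort("cloud must contain at least one point")
    if (is.null(max_points)) max_points <- if (max_dim == 2) 60 else Inf
    if (nrow(cloud) > max_points)
      cloud <- subsample_farthest(cloud, max_points, seed = subsample_seed)
    d <- as.matrix(stats::dist(cloud))
  }
  n <- nrow(d)
  if (is.null(max_scale)) max_scale <- enclosing_radius(d)
  if (max_scale <= 0) abort("max_scale must be > 0")

  n_simp <- .count_rips_simplices_cpp(d, max_dim, max_scale)
  if (n_simp > simplex_budget)
    abort(sprintf(paste0("Rips complex would hold %.0f simplices ",
                         "(budget %.0f); reduce max_scale or set max_points"),
                  n_simp, simplex_budget),
          class = "topofc_budget_error")

  raw <- .rips_pairs_cpp(d, max_dim, max_scale, simplex_budget)
  dplyr::bind_rows(lapply(seq_along(raw), function(k) {
    m <- raw[[k]]
    tb <- tibble(dimension = k - 1L,
                 birth = m[, 1], death = m[, 2],
                 kind = "ordinary")
    dplyr::arrange(tb, .data$birth, .data$death)
  }))
}

# smallest radius at which the complex is a cone over some vertex
enclosing_radius <- function(d) {
  if (nrow(d) == 1L) return(1)  # any positive scale; singleton has no edges
  min(apply(d, 1, max))
}

#' Farthest-point subsample of a point cloud
#'
#' Greedy farthest-point traversal from a seeded random start; keeps the
#' cloud's extent while thinning dense regions, and never decreases the
#' minimum pairwise distance. Identity when the cloud is already small
#' enough.
#'
#' @param cloud Numeric matrix, one point per row.
#' @param max_points Number of points to keep.
#' @param seed Seed choosing the starting point.
#' @return The subsampled matrix (row order = selection order with the
#'   original first rows preserved when no subsampling happens).
#' @export
subsample_farthest <- function(cloud, max_points, seed = 1) {
  cloud <- as.matrix(cloud)
  max_points <- assert_count(max_points, "max_points")
  n <- nrow(cloud)
  if (n <= max_points) return(cloud)
  start <- with_preserved_rng({ set.seed(as.integer(seed)); sample.int(n, 1) })
  chosen <- integer(max_points)
  chosen[1] <- start
  # running minimum distance to the chosen set
  dmin <- sqrt(rowSums(sweep(cloud, 2, cloud[start, ])^2))
  for (k in 2:max_points) {
    nxt <- which.max(dmin)
    chosen[k] <- nxt
    dn <- sqrt(rowSums(sweep(cloud, 2, cloud[nxt, ])^2))
    dmin <- pmin(dmin, dn)
  }
  cloud[sort(chosen), , drop = FALSE]
}

#' Vietoris-Rips diagrams for every cloud of an embedded panel
#'
#' @param clouds Tibble from [embed_panel()].
#' @inheritParams rips_diagrams
#' @return The input tibble with a `diagram` list-column replacing `cloud`.
#' @export
rips_panel <- function(clouds, max_dim = 1, max_scale = NULL,
                       max_points = NULL, subsample_seed = 1) {
  out <- clouds
  out$diagram <- lapply(clouds$cloud, rips_diagrams, max_dim = max_dim,
                        max_scale = max_scale, max_points = max_points,
                        subsample_seed = subsample_seed)
  out$cloud <- NULL
  out
}
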