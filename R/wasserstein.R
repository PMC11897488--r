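#' q-Wasserstein distance between two persistence diagrams
#'
#' Exact optimal partial matching between two diagrams of the same homology
#' dimension and kind: each diagram is augmented with the diagonal
#' projections of the other's points (which makes unequal cardinalities
#' well-defined), the cost of matching two points is the q-th power of their
#' L-infinity distance (a point's distance to the diagonal is half its
#' persistence), and the minimum-total-cost matching is found with an exact
#' assignment solver. Returns (minimal total cost)^(1/q).
#'
#' Essential points (infinite death) must be resolved first:
#' `"truncate_to_max_finite"` (default) replaces infinite deaths with the
#' largest finite death seen across the two diagrams being compared (or the
#' largest birth when no death is finite), keeping distances finite and
#' comparable; `"drop_essential"` removes them.
#'
#' @param x,y Diagram tibbles (columns `dimension`, `birth`, `death`,
#'   `kind`), each holding a single dimension and kind.
#' @param q Order of the distance, q >= 1.
#' @param infinite_death_policy `"truncate_to_max_finite"` or
#'   `"drop_essential"`.
#' @return A single non-negative number.
#' @examples
#' d1 <- tibble::tibble(dimension = 1L, birth = 0, death = 2, kind = "ordinary")
#' d0 <- d1[0, ]
#' wasserstein_distance(d1, d0)   # 1: (0,2) moves to the diagonal
#' @export
wasserstein_distance <- function(x, y, q = 1,
                                 infinite_death_policy =
                                   c("truncate_to_max_finite", "drop_essential")) {
  infinite_death_policy <- match.arg(infinite_death_policy)
  if (!is.numeric(q) || length(q) != 1L || q < 1)
    abort("`q` must be a single number >= 1")
  check_same_context(x, y)
  px <- resolve_essential(x, y, infinite_death_policy)
  py <- resolve_essential(y, x, infinite_death_policy)
  wasserstein_core(px$birth, px$death, py$birth, py$death, q)
}

# lean numeric core shared by wasserstein_distance and the matrix builders
wasserstein_core <- function(bx, dx, by, dy, q) {
  m <- length(bx); n <- length(by)
  if (m == 0L && n == 0L) return(0)

  # persistence-to-diagonal costs (L-infinity distance is half the gap)
  gx <- (abs(dx - bx) / 2)^q
  gy <- (abs(dy - by) / 2)^q
  size <- m + n
  cost <- matrix(0, size, size)
  if (m > 0L && n > 0L)
    cost[seq_len(m), seq_len(n)] <-
      pmax(abs(outer(bx, by, "-")), abs(outer(dx, dy, "-")))^q
  # each real point gets one dedicated diagonal slot; a large finite penalty
  # blocks the others (any diagonal slot is equivalent, pinning one keeps the
  # assignment square); ghost-to-ghost entries stay 0
  big <- 1 + 2 * size * max(cost, gx, gy, 1)
  if (m > 0L) {
    blk <- matrix(big, m, m); diag(blk) <- gx
    cost[seq_len(m), n + seq_len(m)] <- blk
  }
  if (n > 0L) {
    blk <- matrix(big, n, n); diag(blk) <- gy
    cost[m + seq_len(n), seq_len(n)] <- blk
  }
  assign_cols <- .solve_assignment_cpp(cost)
  total <- sum(cost[cbind(seq_len(size), assign_cols)])
  total^(1 / q)
}

check_same_context <- function(x, y) {
  dx <- unique(x$dimension); dy <- unique(y$dimension)
  kx <- unique(x$kind); ky <- unique(y$kind)
  if (length(dx) > 1L || length(dy) > 1L || length(kx) > 1L || length(ky) > 1L)
    abort("each diagram must hold a single homology dimension and kind")
  if (length(dx) && length(dy) && (dx != dy || kx != ky))
    abort(sprintf("diagrams disagree: dimension %s/%s, kind %s/%s",
                  dx, dy, kx, ky),
          class = "topofc_validation_error")
}

resolve_essential <- function(x, other, policy) {
  inf <- is.infinite(x$death)
  if (!any(inf)) return(x)
  if (policy == "drop_essential") return(x[!inf, , drop = FALSE])
  fin <- c(x$death[is.finite(x$death)], other$death[is.finite(other$death)])
  cap <- if (length(fin)) max(fin) else max(x$birth, other$birth, 0)
  x$death[inf] <- pmax(cap, x$birth[inf])
  x
}

#' Pairwise Wasserstein distance matrix over subjects or ROIs
#'
#' Assembles the symmetric matrix of pairwise diagram distances. All
#' diagrams must share homology dimension and kind; each unordered pair is
#' computed once.
#'
#' @param diagrams Tibble with a label column (`subject_id` or `roi_id`) and
#'   a `diagram` list-column, or a named list of diagram tibbles.
#' @param q,infinite_death_policy Passed to [wasserstein_distance()].
#' @param context Optional named list (network, dimension, kind) recorded on
#'   the result.
#' @return An `fc_distmat`: symmetric matrix with zero diagonal, labelled by
#'   subjects/ROIs, attributes `axis` and `context`.
#' @export
inter_subject_matrix <- function(diagrams, q = 1,
                                 infinite_death_policy = "truncate_to_max_finite",
                                 context = NULL) {
  wd_matrix(diagrams, "subject_id", "subjects", q, infinite_death_policy, context)
}

#' @rdname inter_subject_matrix
#' @export
inter_roi_matrix <- function(diagrams, q = 1,
                             infinite_death_policy = "truncate_to_max_finite",
                             context = NULL) {
  wd_matrix(diagrams, "roi_id", "rois", q, infinite_death_policy, context)
}

wd_matrix <- function(diagrams, label_col, axis, q, policy, context) {
  if (is.data.frame(diagrams)) {
    if (!label_col %in% names(diagrams))
      abort(paste0("expected a `", label_col, "` column"))
    labels <- diagrams[[label_col]]
    dg <- diagrams$diagram
  } else {
    labels <- names(diagrams)
    dg <- diagrams
  }
  if (is.null(labels) || anyNA(labels) || anyDuplicated(labels))
    abort(paste0("missing or duplicated ", axis, " labels: ",
                 paste(labels[duplicated(labels) | is.na(labels)], collapse = ", ")))
  bad <- vapply(dg, is.null, logical(1))
  if (any(bad))
    abort(paste0("missing diagram for: ", paste(labels[bad], collapse = ", ")))
  dims <- unlist(lapply(dg, function(d) unique(d$dimension)))
  kinds <- unlist(lapply(dg, function(d) unique(d$kind)))
  if (length(unique(dims)) > 1L || length(unique(kinds)) > 1L)
    abort("all diagrams must share homology dimension and kind",
          class = "topofc_validation_error")
  # precompute per-diagram finite parts and essential births
  pre <- lapply(dg, function(d) {
    fin <- is.finite(d$death)
    list(b = d$birth[fin], d = d$death[fin], eb = d$birth[!fin],
         maxfin = if (any(fin)) max(d$death[fin]) else -Inf,
         maxb = if (nrow(d)) max(d$birth) else 0)
  })
  n <- length(dg)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    idx <- combn(n, 2)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      pi <- pre[[i]]; pj <- pre[[j]]
      if (policy == "drop_essential") {
        val <- wasserstein_core(pi$b, pi$d, pj$b, pj$d, q)
      } else {
        cap <- max(pi$maxfin, pj$maxfin)
        if (!is.finite(cap)) cap <- max(pi$maxb, pj$maxb, 0)
        val <- wasserstein_core(c(pi$b, pi$eb), c(pi$d, pmax(cap, pi$eb)),
                                c(pj$b, pj$eb), c(pj$d, pmax(cap, pj$eb)), q)
      }
      m[i, j] <- m[j, i] <- val
    }
  }
  attr(m, "axis") <- axis
  attr(m, "context") <- context
  class(m) <- c("fc_distmat", class(m))
  m
}

#' Long-format view of a distance matrix
#'
#' @param mat An `fc_distmat`.
#' @return Tibble `from`, `to`, `distance` over the upper triangle.
#' @export
tidy_distance_matrix <- function(mat) {
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  tibble(from = rownames(mat)[idx[, 1]], to = colnames(mat)[idx[, 2]],
         distance = mat[idx])
}
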