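# Independent oracles, deliberately naive: full boundary-matrix reductions
# and exhaustive matchings that the fast implementations are checked against.

# ---- generic GF(2) column reduction --------------------------------------
# cols: list of integer vectors (sorted row indices). Returns for each column
# its pivot row (0 if the column reduced to zero).
reduce_columns_gf2 <- function(cols, n_rows) {
  pivot_owner <- integer(n_rows)
  pivots <- integer(length(cols))
  for (j in seq_along(cols)) {
    col <- cols[[j]]
    repeat {
      if (length(col) == 0L) break
      piv <- max(col)
      own <- pivot_owner[piv]
      if (own == 0L) break
      col <- sort(union(setdiff(col, cols[[own]]), setdiff(cols[[own]], col)))
    }
    cols[[j]] <- col
    if (length(col)) {
      piv <- max(col)
      pivot_owner[piv] <- j
      pivots[j] <- piv
    }
  }
  list(pivots = pivots, cols = cols)
}

# ---- naive Vietoris-Rips persistence -------------------------------------
# Enumerates every simplex up to dimension max_dim + 1, runs one global
# reduction, and assembles diagrams with the same conventions as
# rips_diagrams (zero-persistence kept in dim 0, dropped above).
naive_rips_diagrams <- function(cloud, max_dim = 1, max_scale = NULL) {
  d <- as.matrix(stats::dist(cloud))
  n <- nrow(d)
  if (is.null(max_scale)) max_scale <- if (n > 1) min(apply(d, 1, max)) else 1
  simps <- lapply(seq_len(n), function(v) list(verts = v, value = 0))
  for (k in seq_len(min(max_dim + 1, n - 1))) {
    for (vs in utils::combn(n, k + 1, simplify = FALSE)) {
      val <- max(d[vs, vs])
      if (val <= max_scale)
        simps[[length(simps) + 1L]] <- list(verts = vs, value = val)
    }
  }
  dims <- vapply(simps, function(s) length(s$verts) - 1L, integer(1))
  vals <- vapply(simps, function(s) s$value, numeric(1))
  lex <- vapply(simps, function(s)
    paste(sprintf("%04d", s$verts), collapse = ""), character(1))
  ord <- order(vals, dims, lex)
  simps <- simps[ord]; dims <- dims[ord]; vals <- vals[ord]
  key <- vapply(simps, function(s) paste(s$verts, collapse = "-"), character(1))
  index <- setNames(seq_along(simps), key)
  cols <- lapply(simps, function(s) {
    if (length(s$verts) == 1L) return(integer(0))
    facets <- utils::combn(s$verts, length(s$verts) - 1L, simplify = FALSE)
    sort(unname(index[vapply(facets, paste, character(1), collapse = "-")]))
  })
  red <- reduce_columns_gf2(cols, length(simps))
  paired_birth <- red$pivots            # col j kills row pivots[j]
  killed <- logical(length(simps))
  out <- list()
  for (j in seq_along(simps)) {
    i <- paired_birth[j]
    if (i > 0L) {
      killed[i] <- TRUE
      dim_i <- dims[i]
      if (dim_i <= max_dim && (dim_i == 0L || vals[j] > vals[i]))
        out[[length(out) + 1L]] <-
          c(dimension = dim_i, birth = vals[i], death = vals[j])
    }
  }
  for (i in seq_along(simps)) {
    creates <- length(red$cols[[i]]) == 0L
    if (creates && !killed[i] && dims[i] <= max_dim)
      out[[length(out) + 1L]] <-
        c(dimension = dims[i], birth = vals[i], death = Inf)
  }
  df <- as.data.frame(do.call(rbind, out))
  df <- df[order(df$dimension, df$birth, df$death), ]
  rownames(df) <- NULL
  df
}

# ---- extended persistence of a graph filter by cone reduction ------------
# Ascending pass: graph simplices by (f, dim, lex). Descending pass: cone
# simplices keyed by the superlevel entry value (vertices at their maximum
# incident edge value, edges at their own value), larger values first.
# An (edge-in-A, cone-edge-in-B) pair is an extended dim-1 point
# (birth = f(edge), death = superlevel key of the cone column's base edge).
cone_extended_oracle <- function(filter) {
  nodes <- filter$nodes
  nv <- length(nodes)
  e <- filter$edges
  ne <- nrow(e)
  ii <- match(e$from, nodes); jj <- match(e$to, nodes)
  fv <- unname(filter$vertex_value[nodes])
  gv <- fv
  for (k in seq_len(ne)) {
    gv[ii[k]] <- max(gv[ii[k]], e$value[k])
    gv[jj[k]] <- max(gv[jj[k]], e$value[k])
  }
  # part A: vertices then edges by (value, dim, lex)
  a_kind <- c(rep("v", nv), rep("e", ne))
  a_id <- c(seq_len(nv), seq_len(ne))
  a_val <- c(fv, e$value)
  a_dim <- c(rep(0L, nv), rep(1L, ne))
  a_lex <- c(sprintf("%04d", seq_len(nv)), sprintf("%04d%04d", ii, jj))
  a_ord <- order(a_val, a_dim, a_lex)
  # part B: cone simplices by descending key, dim ascending, lex
  b_kind <- c(rep("cv", nv), rep("ce", ne))
  b_id <- c(seq_len(nv), seq_len(ne))
  b_val <- c(gv, e$value)
  b_dim <- c(rep(1L, nv), rep(2L, ne))
  b_lex <- c(sprintf("%04d", seq_len(nv)), sprintf("%04d%04d", ii, jj))
  b_ord <- order(-b_val, b_dim, b_lex)

  kind <- c(a_kind[a_ord], "w", b_kind[b_ord])
  id <- c(a_id[a_ord], 0L, b_id[b_ord])
  val <- c(a_val[a_ord], NA, b_val[b_ord])
  pos_of <- function(knd, i) which(kind == knd & id == i)

  cols <- vector("list", length(kind))
  for (s in seq_along(kind)) {
    cols[[s]] <- switch(
      kind[s],
      v = integer(0),
      e = sort(c(pos_of("v", ii[id[s]]), pos_of("v", jj[id[s]]))),
      w = integer(0),
      cv = sort(c(pos_of("v", id[s]), which(kind == "w"))),
      ce = sort(c(pos_of("e", id[s]), pos_of("cv", ii[id[s]]),
                  pos_of("cv", jj[id[s]]))))
  }
  red <- reduce_columns_gf2(cols, length(kind))
  ex1 <- list(); dg0 <- list()
  for (j in seq_along(kind)) {
    i <- red$pivots[j]
    if (i == 0L) next
    if (kind[j] == "ce" && kind[i] == "e")
      ex1[[length(ex1) + 1L]] <- c(birth = val[i], death = e$value[id[j]])
    if (kind[j] == "e" && kind[i] == "v")
      dg0[[length(dg0) + 1L]] <- c(birth = val[i], death = val[j])
  }
  list(ex1 = if (length(ex1)) as.data.frame(do.call(rbind, ex1))
             else data.frame(birth = numeric(0), death = numeric(0)),
       dg0_finite = if (length(dg0)) as.data.frame(do.call(rbind, dg0))
                    else data.frame(birth = numeric(0), death = numeric(0)))
}

# ---- exhaustive Wasserstein / bottleneck ---------------------------------
# Enumerates every partial matching (points matched across or to the
# diagonal); feasible for diagrams with <= 5 points or so.
brute_wasserstein <- function(X, Y, q = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  dcost <- function(p) (abs(p[2] - p[1]) / 2)^q
  pcost <- function(p, r) max(abs(p - r))^q
  m <- nrow(X); n <- nrow(Y)
  if (m == 0L && n == 0L) return(0)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return(invisible())
    if (i > m) {
      rest <- if (any(!used)) sum(apply(Y[!used, , drop = FALSE], 1, dcost)) else 0
      best <<- min(best, acc + rest)
      return(invisible())
    }
    rec(i + 1L, used, acc + dcost(X[i, ]))
    if (n > 0) for (j in which(!used)) {
      u <- used; u[j] <- TRUE
      rec(i + 1L, u, acc + pcost(X[i, ], Y[j, ]))
    }
  }
  rec(1L, rep(FALSE, max(n, 1L))[seq_len(n)], 0)
  if (m == 0L) best <- sum(apply(Y, 1, dcost))
  best^(1 / q)
}

brute_bottleneck <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  dcost <- function(p) abs(p[2] - p[1]) / 2
  pcost <- function(p, r) max(abs(p - r))
  m <- nrow(X); n <- nrow(Y)
  if (m == 0L && n == 0L) return(0)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return(invisible())
    if (i > m) {
      rest <- if (any(!used)) max(apply(Y[!used, , drop = FALSE], 1, dcost)) else 0
      best <<- min(best, max(acc, rest))
      return(invisible())
    }
    rec(i + 1L, used, max(acc, dcost(X[i, ])))
    if (n > 0) for (j in which(!used)) {
      u <- used; u[j] <- TRUE
      rec(i + 1L, u, max(acc, pcost(X[i, ], Y[j, ])))
    }
  }
  rec(1L, rep(FALSE, max(n, 1L))[seq_len(n)], 0)
  if (m == 0L) best <- max(apply(Y, 1, dcost))
  best
}

# ---- partial correlation by regression residuals -------------------------
residual_partial_correlation <- function(x) {
  p <- nrow(x)
  out <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    others <- setdiff(seq_len(p), c(i, j))
    resid_on <- function(target) {
      if (length(others) == 0L) return(target - mean(target))
      stats::lm.fit(cbind(1, t(x[others, , drop = FALSE])), target)$residuals
    }
    r <- stats::cor(resid_on(x[i, ]), resid_on(x[j, ]))
    out[i, j] <- out[j, i] <- r
  }
  dimnames(out) <- list(rownames(x), rownames(x))
  out
}
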