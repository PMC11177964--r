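# Filtered simplicial complexes (Vietoris-Rips and Alpha) and their signed
# boundary matrices.
#
# A filtration_complex stores, per dimension k, an n_k x (k+1) matrix of
# vertex indices (rows sorted ascending -- the orientation convention) and a
# parallel vector of filtration values in angstrom. Within each dimension
# simplices are ordered by (value, lexicographic vertex tuple).

new_filtration_complex <- function(n_vertices, simplices, values, source) {
  max_dim <- length(simplices) - 1L
  for (k in seq_along(simplices)) {
    if (nrow(simplices[[k]]) == 0) next
    ord <- do.call(order, c(list(values[[k]]),
                            lapply(seq_len(ncol(simplices[[k]])),
                                   function(j) simplices[[k]][, j])))
    simplices[[k]] <- simplices[[k]][ord, , drop = FALSE]
    values[[k]] <- values[[k]][ord]
  }
  structure(list(n_vertices = n_vertices, simplices = simplices,
                 values = values, max_dim = max_dim, source = source),
            class = "filtration_complex")
}

#' @export
print.filtration_complex <- function(x, ...) {
  cat("filtration_complex (", x$source, "), ", x$n_vertices,
      " vertices\n", sep = "")
  for (k in 0:x$max_dim) {
    cat("  dim ", k, ": ", nrow(x$simplices[[k + 1]]), " simplices\n",
        sep = "")
  }
  invisible(x)
}

n_simplices <- function(cx, k) {
  if (k < 0 || k > cx$max_dim) return(0L)
  nrow(cx$simplices[[k + 1]])
}

simplex_keys <- function(mat) {
  if (nrow(mat) == 0) return(character(0))
  do.call(paste, c(lapply(seq_len(ncol(mat)), function(j) mat[, j]),
                   sep = "-"))
}

#' Vietoris-Rips filtration from a distance matrix
#'
#' Each simplex enters the filtration at its diameter: the maximum pairwise
#' distance among its vertices. Pairs at infinite distance (the modified
#' cross-group distance) never form an edge, and no simplex containing such a
#' pair ever appears.
#'
#' @param dist A `DistanceMatrix` (square, symmetric) or plain numeric
#'   matrix; `Inf` entries allowed, negatives are not.
#' @param max_dim Highest simplex dimension to build (0 to 3).
#' @param max_filtration Largest diameter (angstrom) to include.
#' @return A `filtration_complex` with `source = "rips"`.
#' @export
build_rips <- function(dist, max_dim = 2, max_filtration = Inf) {
  if (inherits(dist, "DistanceMatrix")) dist <- dist$entries
  if (nrow(dist) != ncol(dist)) stop("distance matrix must be square")
  if (any(dist[is.finite(dist)] < 0)) stop("negative distances")
  finite <- is.finite(dist)
  dfin <- dist
  dfin[!finite] <- 0
  if (!identical(finite, t(finite)) || max(abs(dfin - t(dfin))) > 1e-9) {
    stop("distance matrix must be symmetric")
  }
  if (max_dim < 0 || max_dim > 3) stop("max_dim must be in 0..3")
  n <- nrow(dist)

  simplices <- list(matrix(seq_len(n), ncol = 1))
  values <- list(rep(0, n))

  if (max_dim >= 1 && n >= 2) {
    pr <- which(upper.tri(dist), arr.ind = TRUE)
    dv <- dist[pr]
    keep <- is.finite(dv) & dv <= max_filtration
    e <- cbind(pr[keep, 1], pr[keep, 2])
    e <- t(apply(e, 1, sort))
    if (nrow(e) == 0) e <- matrix(integer(0), ncol = 2)
    simplices[[2]] <- e
    values[[2]] <- dv[keep]
  }
  for (k in 2:3) {
    if (max_dim < k || n < k + 1 || nrow(simplices[[k]]) == 0) break
    cand <- utils::combn(n, k + 1)
    diam <- apply(cand, 2, function(v) {
      max(dist[t(utils::combn(v, 2))])
    })
    keep <- is.finite(diam) & diam <= max_filtration
    simplices[[k + 1]] <- t(cand[, keep, drop = FALSE])
    values[[k + 1]] <- diam[keep]
  }
  while (length(simplices) < max_dim + 1) {
    simplices[[length(simplices) + 1]] <-
      matrix(integer(0), ncol = length(simplices) + 1)
    values[[length(values) + 1]] <- numeric(0)
  }
  new_filtration_complex(n, simplices, values, "rips")
}

vcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# Circumcenters/radii of tetrahedra given as an m x 4 index matrix.
tet_circumspheres <- function(P, T) {
  a <- P[T[, 1], , drop = FALSE]
  r1 <- P[T[, 2], , drop = FALSE] - a
  r2 <- P[T[, 3], , drop = FALSE] - a
  r3 <- P[T[, 4], , drop = FALSE] - a
  b <- cbind(rowSums(r1^2), rowSums(r2^2), rowSums(r3^2)) / 2
  det <- rowSums(r1 * vcross(r2, r3))
  # Cramer's rule for the 3x3 system 2(p_i - a) . x = |p_i - a|^2 / ... (b)
  x1 <- rowSums(cbind(b[, 1], b[, 2], b[, 3]) *
                cbind(vcross(r2, r3)[, 1], vcross(r3, r1)[, 1],
                      vcross(r1, r2)[, 1]))
  x2 <- rowSums(b * cbind(vcross(r2, r3)[, 2], vcross(r3, r1)[, 2],
                          vcross(r1, r2)[, 2]))
  x3 <- rowSums(b * cbind(vcross(r2, r3)[, 3], vcross(r3, r1)[, 3],
                          vcross(r1, r2)[, 3]))
  ok <- abs(det) > 1e-12 * pmax(1, rowSums(r1^2))^1.5
  center <- a + cbind(x1 / det, x2 / det, x3 / det)
  radius2 <- rowSums((center - a)^2)
  list(center = center, radius2 = radius2, ok = ok)
}

# Circumcenters (within the affine hull) of triangles, m x 3 index matrix.
tri_circumspheres <- function(P, T) {
  a <- P[T[, 1], , drop = FALSE]
  u <- P[T[, 2], , drop = FALSE] - a
  v <- P[T[, 3], , drop = FALSE] - a
  uu <- rowSums(u^2); vv <- rowSums(v^2); uv <- rowSums(u * v)
  det <- uu * vv - uv^2
  ok <- det > 1e-12 * pmax(1, uu * vv)
  alpha <- (uu * vv - uv * vv) / (2 * det)
  beta <- (vv * uu - uv * uu) / (2 * det)
  center <- a + alpha * u + beta * v
  radius2 <- rowSums((center - a)^2)
  list(center = center, radius2 = radius2, ok = ok)
}

sphere_is_empty <- function(P, centers, radius2, tol = 1e-9,
                            chunk = 2e6) {
  # TRUE when no point of P lies strictly inside the sphere (relative
  # tolerance keeps the simplex's own on-sphere vertices out); chunked to
  # bound memory
  m <- nrow(centers)
  if (m == 0) return(logical(0))
  pn <- rowSums(P^2)
  out <- logical(m)
  step <- max(1, floor(chunk / nrow(P)))
  for (s in seq(1, m, by = step)) {
    e <- min(m, s + step - 1)
    ctr <- centers[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ctr^2), rep(1, nrow(P))) - 2 * tcrossprod(ctr, P) +
      outer(rep(1, e - s + 1), pn)
    out[s:e] <- rowSums(d2 < radius2[s:e] * (1 - tol) - tol) == 0
  }
  out
}

deterministic_jitter <- function(coords, scale) {
  n <- nrow(coords)
  # fixed quasi-random perturbation, independent of the RNG state
  i <- seq_len(n)
  coords + scale * cbind(sin(1000 * i + 1), sin(2000 * i + 2),
                         sin(3000 * i + 3))
}

#' Alpha complex of a 3-D point cloud
#'
#' Builds the alpha filtration by exact empty-circumsphere enumeration and
#' assigns standard filtration values on the radius scale (angstrom): a
#' simplex whose smallest circumscribing sphere is empty of other points
#' (Gabriel) enters at its circumradius; any other Delaunay simplex enters
#' at the smallest value among its cofaces. With a finite `max_filtration`
#' the search is restricted to cliques of the `2 * max_filtration` neighbor
#' graph, which contains every simplex that can enter the filtration below
#' the cutoff. Degenerate inputs (collinear/coplanar clouds, duplicate
#' points) are perturbed by a tiny deterministic jitter, with a message.
#'
#' Intended for the local atom subsets this package featurizes (up to a few
#' hundred points with a finite cutoff); the enumeration is exact but not
#' asymptotically efficient.
#'
#' @param coords Numeric matrix, one 3-D point per row.
#' @param max_dim Highest simplex dimension retained (0 to 3, default 3 so
#'   that dimension-2 Laplacians have their up-part).
#' @param max_filtration Largest filtration value (angstrom, radius scale)
#'   that needs to be represented; simplices entering later are omitted.
#' @return A `filtration_complex` with `source = "alpha"`.
#' @export
build_alpha <- function(coords, max_dim = 3, max_filtration = Inf) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be n x 3")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (max_dim < 0 || max_dim > 3) stop("max_dim must be in 0..3")
  n <- nrow(coords)
  if (n > 80 && !is.finite(max_filtration)) {
    stop("for clouds above 80 points give a finite max_filtration")
  }
  if (n > 400) {
    stop("alpha builder is intended for local subsets (<= 400 points), ",
         "got ", n)
  }

  empty_dims <- function(sl, vl, upto) {
    while (length(sl) < upto + 1) {
      sl[[length(sl) + 1]] <- matrix(integer(0), ncol = length(sl) + 1)
      vl[[length(vl) + 1]] <- numeric(0)
    }
    list(simplices = sl, values = vl)
  }
  simplices <- list(matrix(seq_len(n), ncol = 1))
  values <- list(rep(0, n))
  if (n == 1) {
    ed <- empty_dims(simplices, values, max_dim)
    return(new_filtration_complex(n, ed$simplices, ed$values, "alpha"))
  }

  # general position: affine rank 3 and no duplicate points
  ctr <- sweep(coords, 2, colMeans(coords))
  scale <- max(1e-6, max(abs(ctr)))
  if (n >= 4 && qr(ctr, tol = 1e-9)$rank < 3) {
    message("degenerate (collinear/coplanar) point cloud; applying a ",
            "deterministic general-position perturbation")
    coords <- deterministic_jitter(coords, 1e-4 * scale)
  }
  if (anyDuplicated(round(coords, 9))) {
    message("duplicate points; applying a deterministic general-position ",
            "perturbation")
    coords <- deterministic_jitter(coords, 1e-4 * scale)
  }

  # a simplex with circumradius <= cutoff has all edges <= 2 * cutoff, so
  # every candidate is a clique of the neighbor graph at that range
  D <- euclid_cross(coords, coords)
  adj <- D <= 2 * max_filtration
  diag(adj) <- FALSE
  nb_above <- lapply(seq_len(n), function(i) which(adj[i, ] & seq_len(n) > i))

  ep <- which(upper.tri(D) & adj, arr.ind = TRUE)
  edges <- ep[order(ep[, 1], ep[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL

  tris <- matrix(integer(0), ncol = 3)
  if (n >= 3 && nrow(edges) > 0) {
    tl <- vector("list", nrow(edges))
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      ks <- nb_above[[j]][adj[i, nb_above[[j]]]]
      if (length(ks) > 0) tl[[e]] <- cbind(i, j, ks)
    }
    tl <- tl[!vapply(tl, is.null, TRUE)]
    if (length(tl) > 0) tris <- do.call(rbind, tl)
  }

  tets <- matrix(integer(0), ncol = 4)
  tet_val <- numeric(0)
  if (n >= 4 && nrow(tris) > 0) {
    ql <- vector("list", nrow(tris))
    for (t3 in seq_len(nrow(tris))) {
      i <- tris[t3, 1]; j <- tris[t3, 2]; k <- tris[t3, 3]
      ls <- nb_above[[k]][adj[i, nb_above[[k]]] & adj[j, nb_above[[k]]]]
      if (length(ls) > 0) ql[[t3]] <- cbind(i, j, k, ls)
    }
    ql <- ql[!vapply(ql, is.null, TRUE)]
    if (length(ql) > 0) {
      cand <- do.call(rbind, ql)
      cs <- tet_circumspheres(coords, cand)
      keep <- cs$ok & cs$radius2 <= max_filtration^2
      if (any(keep)) {
        cand <- cand[keep, , drop = FALSE]
        r2 <- cs$radius2[keep]
        # a tetrahedron's circumsphere is unique: Delaunay iff it is empty
        del <- sphere_is_empty(coords, cs$center[keep, , drop = FALSE], r2)
        tets <- cand[del, , drop = FALSE]
        tet_val <- sqrt(r2[del])
      }
    }
  }

  faces_of <- function(mat) {
    do.call(rbind, lapply(seq_len(ncol(mat)),
                          function(i) mat[, -i, drop = FALSE]))
  }

  # triangles: Gabriel within the cutoff -> own circumradius (an empty
  # smallest circumsphere also certifies Delaunay membership); otherwise
  # inherit the smallest incident Delaunay tetrahedron value
  tri_val <- numeric(0)
  if (nrow(tris) > 0) {
    cs <- tri_circumspheres(coords, tris)
    own_ok <- cs$ok & cs$radius2 <= max_filtration^2
    gab <- own_ok
    gab[own_ok] <- sphere_is_empty(coords, cs$center[own_ok, , drop = FALSE],
                                   cs$radius2[own_ok])
    val <- rep(NA_real_, nrow(tris))
    val[gab] <- sqrt(cs$radius2[gab])
    if (nrow(tets) > 0 && any(!gab)) {
      inherited <- tapply(rep(tet_val, 4), simplex_keys(faces_of(tets)), min)
      tk <- simplex_keys(tris)
      idx <- which(!gab)
      val[idx] <- as.numeric(inherited[tk[idx]])
    }
    keep <- !is.na(val)
    tris <- tris[keep, , drop = FALSE]
    tri_val <- val[keep]
  }

  # edges: Gabriel (empty diametral sphere) -> half-length; otherwise
  # inherit the smallest incident triangle value
  edge_val <- numeric(0)
  if (nrow(edges) > 0) {
    mid <- (coords[edges[, 1], , drop = FALSE] +
            coords[edges[, 2], , drop = FALSE]) / 2
    r2 <- rowSums((coords[edges[, 1], , drop = FALSE] - mid)^2)
    own_ok <- r2 <= max_filtration^2
    gab <- own_ok
    gab[own_ok] <- sphere_is_empty(coords, mid[own_ok, , drop = FALSE],
                                   r2[own_ok])
    val <- rep(NA_real_, nrow(edges))
    val[gab] <- sqrt(r2[gab])
    if (nrow(tris) > 0 && any(!gab)) {
      inherited <- tapply(rep(tri_val, 3), simplex_keys(faces_of(tris)), min)
      ek <- simplex_keys(edges)
      idx <- which(!gab)
      val[idx] <- as.numeric(inherited[ek[idx]])
    }
    keep <- !is.na(val)
    edges <- edges[keep, , drop = FALSE]
    edge_val <- val[keep]
  }

  simplices[[2]] <- edges; values[[2]] <- edge_val
  simplices[[3]] <- tris; values[[3]] <- tri_val
  simplices[[4]] <- tets; values[[4]] <- tet_val
  simplices <- simplices[seq_len(max_dim + 1)]
  values <- values[seq_len(max_dim + 1)]
  ed <- empty_dims(simplices, values, max_dim)
  new_filtration_complex(n, ed$simplices, ed$values, "alpha")
}

#' Remove simplices carrying same-group edges
#'
#' Applies the modified-distance exclusion rule to a geometric complex:
#' every simplex containing two vertices of the same group is removed, so
#' only cross-group edges (and all vertices) survive. Faces of removed
#' simplices are kept whenever they satisfy the rule themselves, so the
#' result is a valid closed complex.
#'
#' @param cx A `filtration_complex`.
#' @param grouping Character vector of group labels indexed by vertex.
#' @return A pruned `filtration_complex`.
#' @export
prune_cross_only <- function(cx, grouping) {
  if (length(grouping) < cx$n_vertices || any(is.na(grouping[seq_len(
      cx$n_vertices)]))) {
    stop("every vertex needs a group label")
  }
  simplices <- cx$simplices
  values <- cx$values
  for (k in seq(2, length(simplices))) {
    mat <- simplices[[k]]
    if (nrow(mat) == 0) next
    keep <- apply(mat, 1, function(v) !anyDuplicated(grouping[v]))
    simplices[[k]] <- mat[keep, , drop = FALSE]
    values[[k]] <- values[[k]][keep]
  }
  new_filtration_complex(cx$n_vertices, simplices, values, cx$source)
}

#' Snapshot of a filtration at a scale value
#'
#' The subcomplex of all simplices with filtration value at most `t`.
#'
#' @param cx A `filtration_complex`.
#' @param t Scale (angstrom), non-negative.
#' @return A `filtration_complex` restricted to values `<= t`.
#' @export
snapshot <- function(cx, t) {
  if (t < 0) stop("snapshot scale must be non-negative")
  simplices <- cx$simplices
  values <- cx$values
  for (k in seq_along(simplices)) {
    keep <- values[[k]] <= t
    simplices[[k]] <- simplices[[k]][keep, , drop = FALSE]
    values[[k]] <- values[[k]][keep]
  }
  out <- new_filtration_complex(cx$n_vertices, simplices, values, cx$source)
  attr(out, "t") <- t
  out
}

#' Signed boundary matrix of a complex in dimension k
#'
#' Rows are the (k-1)-simplices, columns the k-simplices, in the complex's
#' stored order; the i-th vertex of a sorted tuple is dropped with sign
#' `(-1)^i`. For `k = 0` the boundary is the zero map, represented as a
#' matrix with zero rows.
#'
#' @param cx A `filtration_complex` (typically a [snapshot()]).
#' @param k Dimension, `0 <= k <= max_dim`.
#' @return A `BoundaryMatrix` list: `k`, `entries`, and the row/column
#'   simplex keys (`bases`).
#' @export
boundary_matrix <- function(cx, k) {
  if (k < 0 || k > cx$max_dim) stop("dimension k out of range")
  cols <- cx$simplices[[k + 1]]
  nk <- nrow(cols)
  if (k == 0) {
    return(structure(list(k = 0L,
                          entries = matrix(0, nrow = 0, ncol = nk),
                          bases = list(rows = character(0),
                                       cols = simplex_keys(cols))),
                     class = "BoundaryMatrix"))
  }
  rows <- cx$simplices[[k]]
  row_keys <- simplex_keys(rows)
  col_keys <- simplex_keys(cols)
  B <- matrix(0, nrow = nrow(rows), ncol = nk)
  if (nk > 0 && nrow(rows) > 0) {
    for (i in seq_len(k + 1)) {
      face_keys <- simplex_keys(cols[, -i, drop = FALSE])
      ridx <- match(face_keys, row_keys)
      if (anyNA(ridx)) stop("complex is not closed: missing face in dim ",
                            k - 1)
      B[cbind(ridx, seq_len(nk))] <- (-1)^(i - 1)
    }
  }
  structure(list(k = as.integer(k), entries = B,
                 bases = list(rows = row_keys, cols = col_keys)),
            class = "BoundaryMatrix")
}

#' Serialize a complex to plain text
#'
#' One simplex per line: `k v0 .. vk value`.
#'
#' @param cx A `filtration_complex`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(cx, path) {
  lines <- character(0)
  for (k in 0:cx$max_dim) {
    mat <- cx$simplices[[k + 1]]
    if (nrow(mat) == 0) next
    lines <- c(lines, paste(k, apply(mat, 1, paste, collapse = " "),
                            format(cx$values[[k + 1]], digits = 12)))
  }
  writeLines(lines, path)
  invisible(path)
}
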