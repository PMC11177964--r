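# Combinatorial and persistent k-Laplacians and their spectra.
#
# L_k = B_{k+1} B_{k+1}^T + B_k^T B_k, with L_0 = B_1 B_1^T since the
# 0-boundary is the zero map. The multiplicity of the zero eigenvalue equals
# the k-th Betti number (combinatorial Hodge theorem), which betti_by_rank
# recomputes independently through ranks of the boundary matrices.

svd_rank <- function(M) {
  if (nrow(M) == 0 || ncol(M) == 0) return(0L)
  d <- svd(M, nu = 0, nv = 0)$d
  sum(d > max(dim(M)) * .Machine$double.eps * max(d, 1e-300))
}

null_space_basis <- function(M) {
  # orthonormal basis of the null space of M (columns)
  p <- ncol(M)
  if (p == 0) return(matrix(0, nrow = 0, ncol = 0))
  if (nrow(M) == 0) return(diag(p))
  s <- svd(M, nu = 0, nv = p)
  tol <- max(dim(M)) * .Machine$double.eps * max(s$d, 1e-300)
  keep <- c(s$d <= tol, rep(TRUE, p - length(s$d)))
  s$v[, keep, drop = FALSE]
}

#' Combinatorial k-Laplacian of a complex snapshot
#'
#' @param cx A `filtration_complex` snapshot.
#' @param k Dimension, `0 <= k <= max_dim`.
#' @return Symmetric positive semidefinite matrix of size `n_k x n_k`
#'   (possibly `0 x 0` when the snapshot has no k-simplices).
#' @export
combinatorial_laplacian <- function(cx, k) {
  if (k < 0 || k > cx$max_dim) stop("dimension k out of range")
  nk <- n_simplices(cx, k)
  if (nk == 0) return(matrix(0, 0, 0))
  up <- if (k + 1 <= cx$max_dim && n_simplices(cx, k + 1) > 0) {
    B1 <- boundary_matrix(cx, k + 1)$entries
    tcrossprod(B1)
  } else {
    matrix(0, nk, nk)
  }
  down <- if (k == 0) {
    matrix(0, nk, nk)
  } else {
    Bk <- boundary_matrix(cx, k)$entries
    crossprod(Bk)
  }
  up + down
}

assert_nested <- function(cx_t, cx_tp) {
  for (k in 0:cx_t$max_dim) {
    kt <- simplex_keys(cx_t$simplices[[k + 1]])
    if (k > cx_tp$max_dim) {
      if (length(kt) > 0) stop("snapshots are not nested (dim ", k, ")")
      next
    }
    if (!all(kt %in% simplex_keys(cx_tp$simplices[[k + 1]]))) {
      stop("snapshots are not nested (dim ", k, ")")
    }
  }
  invisible(TRUE)
}

#' p-persistent k-Laplacian for a nested pair of snapshots
#'
#' The up-part acts through the (k+1)-chains of the later snapshot whose
#' boundary stays inside the k-chains of the earlier one; that subspace is
#' obtained as the null space of the boundary rows indexed by k-simplices
#' born strictly after `t`, represented in an orthonormal basis. The
#' down-part is the ordinary `B_k^T B_k` of the earlier snapshot. With
#' `p = 0` (identical snapshots) the operator reduces exactly to
#' [combinatorial_laplacian()].
#'
#' @param cx_t Snapshot at scale `t`.
#' @param cx_tp Snapshot at scale `t + p`; must contain `cx_t`.
#' @param k Dimension.
#' @return Symmetric PSD matrix on the k-chains of `cx_t`.
#' @export
persistent_laplacian <- function(cx_t, cx_tp, k) {
  if (k < 0 || k > cx_t$max_dim) stop("dimension k out of range")
  assert_nested(cx_t, cx_tp)
  nk <- n_simplices(cx_t, k)
  if (nk == 0) return(matrix(0, 0, 0))

  keys_t <- simplex_keys(cx_t$simplices[[k + 1]])
  keys_tp <- simplex_keys(cx_tp$simplices[[k + 1]])
  idx <- match(keys_t, keys_tp)

  up <- matrix(0, nk, nk)
  if (k + 1 <= cx_tp$max_dim && n_simplices(cx_tp, k + 1) > 0) {
    B <- boundary_matrix(cx_tp, k + 1)$entries
    outside <- setdiff(seq_len(nrow(B)), idx)
    if (length(outside) == 0) {
      D <- B[idx, , drop = FALSE]
    } else {
      Q <- null_space_basis(B[outside, , drop = FALSE])
      D <- B[idx, , drop = FALSE] %*% Q
    }
    up <- tcrossprod(D)
  }
  down <- if (k == 0) {
    matrix(0, nk, nk)
  } else {
    Bk <- boundary_matrix(cx_t, k)$entries
    crossprod(Bk)
  }
  L <- up + down
  (L + t(L)) / 2
}

#' Sorted spectrum of a (persistent) Laplacian
#'
#' @param m Symmetric matrix.
#' @param k,t,p Dimension, filtration value and persistence offset recorded
#'   with the spectrum.
#' @param zero_tol Threshold below which an eigenvalue counts as harmonic;
#'   default `1e-8 * max(1, largest eigenvalue)`.
#' @return A `LaplacianSpectrum`: ascending eigenvalues (small negatives
#'   within the tolerance clamped to zero), `k`, `t`, `p`, `zero_tol`.
#' @export
spectrum <- function(m, k = NA_integer_, t = NA_real_, p = 0,
                     zero_tol = NULL) {
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (nrow(m) == 0) {
    return(structure(list(k = k, t = t, p = p, eigenvalues = numeric(0),
                          zero_tol = if (is.null(zero_tol)) 1e-8 else
                            zero_tol),
                     class = "LaplacianSpectrum"))
  }
  scale <- max(1, max(abs(m)))
  if (max(abs(m - t(m))) > 1e-8 * scale) {
    stop("matrix is asymmetric beyond tolerance")
  }
  ev <- sort(eigen((m + t(m)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values)
  if (is.null(zero_tol)) zero_tol <- 1e-8 * max(1, ev[length(ev)])
  ev[ev < 0 & ev > -zero_tol] <- 0
  structure(list(k = k, t = t, p = p, eigenvalues = ev, zero_tol = zero_tol),
            class = "LaplacianSpectrum")
}

#' @export
print.LaplacianSpectrum <- function(x, ...) {
  cat("LaplacianSpectrum k=", x$k, " t=", x$t, " p=", x$p, ": ",
      length(x$eigenvalues), " eigenvalues, ", betti_from_spectrum(x),
      " harmonic\n", sep = "")
  invisible(x)
}

#' Betti number as harmonic multiplicity
#'
#' Counts eigenvalues below the spectrum's zero tolerance; by the
#' combinatorial Hodge theorem this is the k-th Betti number of the
#' snapshot (components for k = 0, loops for k = 1, cavities for k = 2).
#'
#' @param spec A `LaplacianSpectrum`.
#' @return Integer count.
#' @export
betti_from_spectrum <- function(spec) {
  sum(spec$eigenvalues < spec$zero_tol)
}

#' Betti number through boundary-matrix ranks
#'
#' Independent of any eigendecomposition:
#' `beta_k = n_k - rank(B_k) - rank(B_(k+1))`.
#'
#' @param cx A `filtration_complex` snapshot.
#' @param k Dimension.
#' @return Integer Betti number.
#' @export
betti_by_rank <- function(cx, k) {
  if (k < 0 || k > cx$max_dim) stop("dimension k out of range")
  nk <- n_simplices(cx, k)
  if (nk == 0) return(0L)
  rk <- if (k == 0) 0L else svd_rank(boundary_matrix(cx, k)$entries)
  rk1 <- if (k + 1 <= cx$max_dim && n_simplices(cx, k + 1) > 0) {
    svd_rank(boundary_matrix(cx, k + 1)$entries)
  } else 0L
  as.integer(nk - rk - rk1)
}
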