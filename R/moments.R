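# Fixed order of the 10 moment indices (j, k) with j + k <= 3 used by every
# moment family; 3 families x 10 = 30 coefficients per matrix.
MOMENT_ORDER <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L), c(0L, 2L),
                     c(2L, 0L), c(1L, 2L), c(2L, 1L), c(0L, 3L), c(3L, 0L))

moment_labels <- function() {
  vapply(MOMENT_ORDER, function(jk) sprintf("%d%d", jk[1], jk[2]), character(1))
}

check_matrix <- function(M) {
  M <- as.matrix(M)
  if (!is.numeric(M) || length(M) == 0L)
    stop("matrix must be numeric and non-empty", call. = FALSE)
  if (any(!is.finite(M))) stop("matrix has non-finite entries", call. = FALSE)
  M
}

# All E_jk (or central n_ij) for j,k in 0..3 at once: with P[c, j+1] = w_r(c)^j
# and Q[d, k+1] = w_c(d)^k, t(P) %*% M %*% Q is the 4 x 4 table of moments.
moment_table <- function(M, row_shift = 0, col_shift = 0) {
  r <- seq_len(nrow(M)) - row_shift
  d <- seq_len(ncol(M)) - col_shift
  P <- outer(r, 0:3, `^`)
  Q <- outer(d, 0:3, `^`)
  crossprod(P, M %*% Q)
}

pick_moments <- function(tab, prefix) {
  out <- vapply(MOMENT_ORDER, function(jk) tab[jk[1] + 1L, jk[2] + 1L],
                numeric(1))
  names(out) <- paste0(prefix, moment_labels())
  out
}

#' Raw geometric moments of a matrix
#'
#' Computes the ten raw moments E_jk = sum_c sum_d c^j d^k M[c, d] for all
#' orders j + k <= 3, with 1-based row coordinate c and column coordinate d.
#'
#' @param M numeric matrix with finite entries.
#' @return Named numeric vector of 10 values, in the fixed index order
#'   (00, 01, 10, 11, 02, 20, 12, 21, 03, 30).
#' @examples
#' raw_moments(matrix(1:4, 2, byrow = TRUE))["raw_00"]  # 10: the matrix sum
#' @export
raw_moments <- function(M) {
  M <- check_matrix(M)
  pick_moments(moment_table(M), "raw_")
}

#' Mass centroid of a matrix
#'
#' @param M numeric matrix with nonzero total mass.
#' @return c(x, y): the mass-weighted mean row and column coordinate
#'   (E10/E00, E01/E00).
#' @export
moment_centroid <- function(M) {
  M <- check_matrix(M)
  e00 <- sum(M)
  if (abs(e00) < .Machine$double.eps * length(M))
    stop("degenerate matrix: zero total mass", call. = FALSE)
  r <- seq_len(nrow(M))
  d <- seq_len(ncol(M))
  c(x = sum(r * rowSums(M)) / e00, y = sum(d * colSums(M)) / e00)
}

#' Central moments of a matrix
#'
#' The ten moments n_ij = sum_b sum_q (b - x)^i (q - y)^j M[b, q] about the
#' mass centroid (x, y), for orders i + j <= 3. The first-order central
#' moments vanish by construction.
#'
#' @inheritParams raw_moments
#' @return Named numeric vector of 10 values in the fixed index order.
#' @export
central_moments <- function(M) {
  M <- check_matrix(M)
  ctr <- moment_centroid(M)
  pick_moments(moment_table(M, row_shift = ctr[["x"]], col_shift = ctr[["y"]]),
               "central_")
}

# ---- Hahn moments -----------------------------------------------------------

pochhammer <- function(a, k) {
  if (k == 0L) return(1)
  prod(a + seq_len(k) - 1)
}

#' Discrete Hahn polynomial
#'
#' Evaluates the order-n Hahn polynomial on the integer support 0..N-1 with
#' shape parameters (u, v): the classical hypergeometric sum
#' Q_n(r; u, v, N-1) scaled by the prefactor (N+v-1)_n (N-1)_n, where (a)_k
#' is the rising factorial. The family is orthogonal on the support under the
#' weight rho(r) = choose(u+r, r) * choose(v+N-1-r, N-1-r); at the default
#' u = v = 0 the weight is uniform.
#'
#' @param n polynomial order, 0 <= n <= N-1.
#' @param r support point, 0 <= r <= N-1 (vectorized).
#' @param N support size.
#' @param u,v shape parameters (> -1).
#' @return Polynomial value(s) at `r`.
#' @examples
#' hahn_polynomial(0, 0:3, N = 4)        # all 1
#' hahn_polynomial(1, 0, N = 4)          # 9
#' @export
hahn_polynomial <- function(n, r, N, u = 0, v = 0) {
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  if (u <= -1 || v <= -1) stop("u and v must exceed -1", call. = FALSE)
  if (n < 0 || n > N - 1) stop("order n out of support", call. = FALSE)
  if (any(r < 0) || any(r > N - 1)) stop("point r out of support", call. = FALSE)
  M <- N - 1
  pre <- pochhammer(N + v - 1, n) * pochhammer(N - 1, n)
  vals <- numeric(length(r))
  for (k in 0:n) {
    coef <- pochhammer(-n, k) * pochhammer(n + u + v + 1, k) /
      (pochhammer(u + 1, k) * pochhammer(-M, k) * factorial(k))
    # (-r)_k rising = (-1)^k * r (r-1) ... (r-k+1)
    vals <- vals + coef * (-1)^k *
      vapply(r, function(ri) falling(ri, k), numeric(1))
  }
  pre * vals
}

falling <- function(a, k) if (k == 0L) 1 else prod(a - seq_len(k) + 1)

#' Hahn weight function
#'
#' @inheritParams hahn_polynomial
#' @return Weight rho(r) on the support.
#' @export
hahn_weight <- function(r, N, u = 0, v = 0) {
  choose(u + r, r) * choose(v + N - 1 - r, N - 1 - r)
}

#' Orthonormal Hahn basis
#'
#' Rows are the weight-absorbed, norm-scaled Hahn polynomials
#' e_n(r) = sqrt(rho(r)) h_n(r) / ||h_n||, so that E %*% t(E) is the
#' identity. Used internally by [hahn_moments()]; exposed so the moment
#' transform can be inverted in full order.
#'
#' @param N support size (matrix side).
#' @param orders polynomial orders to include (default 0..N-1, the full
#'   invertible transform).
#' @param u,v shape parameters.
#' @return length(orders) x N matrix.
#' @export
hahn_basis <- function(N, orders = 0:(N - 1), u = 0, v = 0) {
  r <- 0:(N - 1)
  rho <- hahn_weight(r, N, u, v)
  E <- matrix(0, length(orders), N)
  for (i in seq_along(orders)) {
    h <- hahn_polynomial(orders[i], r, N, u, v)
    E[i, ] <- h * sqrt(rho)
    E[i, ] <- E[i, ] / sqrt(sum(E[i, ]^2))
  }
  E
}

# Cache of low-order Hahn bases keyed by (N, u, v); the encoder reuses sides
# 4, 7, 16, 64 thousands of times.
.hahn_cache <- new.env(parent = emptyenv())

hahn_basis_cached <- function(N, u = 0, v = 0) {
  key <- sprintf("%d_%g_%g", N, u, v)
  if (is.null(.hahn_cache[[key]]))
    .hahn_cache[[key]] <- hahn_basis(N, orders = 0:min(3L, N - 1L), u = u, v = v)
  .hahn_cache[[key]]
}

#' Hahn moments of a matrix
#'
#' Computes the ten Hahn moments H_ij = sum_q sum_p M[q+1, p+1] e_i(q) e_j(p)
#' for orders i + j <= 3, where e_n are the orthonormal Hahn basis functions
#' of [hahn_basis()]. Rectangular input is zero-padded (bottom/right) to the
#' square side N = max(nrow, ncol).
#'
#' @inheritParams raw_moments
#' @param u,v Hahn shape parameters (default 0: uniform weight).
#' @return Named numeric vector of 10 values in the fixed index order.
#' @export
hahn_moments <- function(M, u = 0, v = 0) {
  M <- check_matrix(M)
  N <- max(dim(M))
  if (nrow(M) != N || ncol(M) != N) {
    P <- matrix(0, N, N)
    P[seq_len(nrow(M)), seq_len(ncol(M))] <- M
    M <- P
  }
  E <- hahn_basis_cached(N, u, v)
  H <- E %*% M %*% t(E)  # H[i+1, j+1] = moment of order (i, j)
  out <- vapply(MOMENT_ORDER, function(jk) {
    if (jk[1] + 1L > nrow(H) || jk[2] + 1L > nrow(H)) 0 else
      H[jk[1] + 1L, jk[2] + 1L]
  }, numeric(1))
  names(out) <- paste0("hahn_", moment_labels())
  out
}

#' All 30 moments of a matrix
#'
#' Raw, central and Hahn moments (10 each, orders j + k <= 3) of one matrix.
#' If the matrix has zero total mass the centroid is undefined; the central
#' block is then zero-filled and a warning raised, so that feature assembly
#' never aborts on a degenerate incidence matrix.
#'
#' @inheritParams hahn_moments
#' @return Named numeric vector of 30 values: raw_, central_, hahn_ blocks.
#' @export
moment_set <- function(M, u = 0, v = 0) {
  M <- check_matrix(M)
  central <- tryCatch(central_moments(M), error = function(e) {
    warning("degenerate matrix (zero mass): central moments set to 0",
            call. = FALSE)
    out <- numeric(10)
    names(out) <- paste0("central_", moment_labels())
    out
  })
  c(raw_moments(M), central, hahn_moments(M, u, v))
}
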