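#' Restricted cubic spline basis and its derivative
#'
#' Builds the natural (restricted) cubic spline basis used throughout the
#' package: piecewise cubic between the knots and constrained to be linear
#' beyond the boundary knots. With `K` knots the basis has `K - 1` columns.
#' The first column is `x` itself; for each interior knot `k_j`
#' (`j = 2, ..., K-1`) the next column is
#' `v_j(x) = (x - k_j)^3_+ - lambda_j (x - k_1)^3_+ - (1 - lambda_j) (x - k_K)^3_+`
#' with `lambda_j = (k_K - k_j) / (k_K - k_1)`, which makes the cubic and
#' quadratic terms cancel outside the boundary knots.
#'
#' @param x numeric vector of evaluation points.
#' @param knots strictly increasing numeric vector of at least 2 knots.
#' @return list with `basis` and `deriv`, both matrices of dimension
#'   `length(x) x (length(knots) - 1)`; `deriv` holds elementwise
#'   derivatives with respect to `x`.
#' @examples
#' b <- rcs_basis(seq(0, 2, by = 0.5), knots = c(0, 1, 2))
#' b$basis
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) < 2L) stop("need at least 2 knots")
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  if (any(!is.finite(x))) stop("non-finite values in x")
  K <- length(knots)
  kmin <- knots[1L]
  kmax <- knots[K]
  n <- length(x)
  B <- matrix(0, n, K - 1L)
  D <- matrix(0, n, K - 1L)
  B[, 1L] <- x
  D[, 1L] <- 1
  if (K > 2L) {
    p3 <- function(u) ifelse(u > 0, u^3, 0)
    p2 <- function(u) ifelse(u > 0, 3 * u^2, 0)
    for (j in seq_len(K - 2L)) {
      kj <- knots[j + 1L]
      lam <- (kmax - kj) / (kmax - kmin)
      B[, j + 1L] <- p3(x - kj) - lam * p3(x - kmin) - (1 - lam) * p3(x - kmax)
      D[, j + 1L] <- p2(x - kj) - lam * p2(x - kmin) - (1 - lam) * p2(x - kmax)
    }
  }
  colnames(B) <- colnames(D) <- paste0("s", seq_len(K - 1L))
  list(basis = B, deriv = D)
}

#' Knot vector for a spline of given flexibility
#'
#' Boundary knots at the observed min/max; `df - 1` interior knots at
#' equally spaced centiles (`100 i / df`, `i = 1..df-1`) of the supplied
#' values, the convention used for baseline log-time splines. `df` is the
#' number of basis columns, so `df + 1` knots are returned.
#'
#' @param x numeric values whose distribution places the knots.
#' @param df positive integer; number of basis columns.
#' @return numeric knot vector of length `df + 1`.
#' @export
rcs_knots <- function(x, df) {
  if (df < 1L) stop("df must be >= 1")
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite values to place knots")
  probs <- seq(0, 1, length.out = df + 1L)
  k <- unname(stats::quantile(x, probs, type = 7))
  k <- unique(k)
  if (length(k) < 2L) stop("degenerate values: cannot place distinct knots")
  k
}

# Knots at named centiles (for covariate splines, e.g. 5/35/65/95).
centile_knots <- function(x, centiles) {
  x <- x[is.finite(x)]
  k <- unname(stats::quantile(x, centiles / 100, type = 7))
  unique(k)
}
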