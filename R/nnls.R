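#' Non-negative least squares
#'
#' Solves `min_{x >= 0} 1/2 ||A x - b||^2` by the Lawson-Hanson active-set
#' method. The implementation is deterministic: among candidate variables
#' with equal (within `tol`) most-negative gradient the lowest index enters
#' the passive set first, and inner-loop step lengths break ties the same
#' way, so repeated calls on the same input take the same path.
#'
#' At the solution the Karush-Kuhn-Tucker conditions hold: for passive
#' (positive) components the gradient `t(A) (A x - b)` is zero, for active
#' (zero) components it is non-negative, to within `tol`.
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric right-hand side, length m.
#' @param tol Dual-feasibility tolerance; default `1e-10 * max(|t(A) b|, 1)`.
#' @param max_iter Iteration cap (default `3 * n^2 + 30`).
#' @return List: `x` (solution, all >= 0), `residual_norm` (`||A x - b||`),
#'   `passive` (logical, component free at the solution), `iterations`,
#'   `converged`.
#' @examples
#' A <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
#' nnls_fit(A, c(2, -1, 1))$x
#' @export
nnls_fit <- function(A, b, tol = NULL, max_iter = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(max(abs(crossprod(A, b))), 1)
  if (is.null(max_iter)) max_iter <- 3L * n * n + 30L

  x <- numeric(n)
  passive <- rep(FALSE, n)
  iter <- 0L
  converged <- TRUE

  solve_passive <- function(P) {
    # unconstrained LS on the passive set via QR (rank-revealing pivoting is
    # qr()'s default; deterministic for fixed input)
    Ap <- A[, P, drop = FALSE]
    z <- numeric(n)
    z[P] <- qr.coef(qr(Ap), b)
    z[P][is.na(z[P])] <- 0  # rank-deficient direction: leave at zero
    z
  }

  repeat {
    w <- crossprod(A, b - A %*% x)  # negative gradient
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    # steepest-descent entry rule, lowest index on ties
    wmax <- max(w[cand])
    j <- min(cand[w[cand] >= wmax - tol])
    passive[j] <- TRUE

    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        converged <- FALSE
        break
      }
      z <- solve_passive(passive)
      neg <- which(passive & z <= 0)
      if (!length(neg)) {
        x <- z
        break
      }
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- pmax(x + alpha * (z - x), 0)
      blocked <- which(passive & (z <= 0) &
                         (x <= tol * max(max(x), 1)))
      if (!length(blocked)) blocked <- min(neg)
      x[blocked] <- 0
      passive[blocked] <- FALSE
    }
    if (!converged) break
  }

  x[x < 0] <- 0
  list(
    x = x,
    residual_norm = sqrt(sum((A %*% x - b)^2)),
    passive = passive,
    iterations = iter,
    converged = converged
  )
}
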