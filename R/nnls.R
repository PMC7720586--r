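# Lawson-Hanson active-set solver for min ||A x - b||_2 subject to x >= 0.
# Small dense problems only (96 rows, a handful of signatures), which is
# exactly the signature-refitting regime; no compiled code needed.

#' Non-negative least squares
#'
#' Lawson-Hanson active-set algorithm. At convergence the Karush-Kuhn-Tucker
#' conditions hold: positive coefficients have zero gradient, zero
#' coefficients have non-positive correlation with the residual.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @param tol tolerance on the dual feasibility check.
#' @return list with `x` (coefficients, `>= 0`) and `deviance` (squared
#'   residual norm).
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)[, 1L]
  scale_ <- max(abs(w), 1)
  it <- 0L; max_it <- 30L * n
  while (any(!passive) && max(w[!passive]) > tol * scale_) {
    it <- it + 1L
    if (it > max_it) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- numeric(n)
      z[passive] <- qr.coef(qr(Ap), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) break
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- crossprod(A, b - A %*% x)[, 1L]
  }
  list(x = pmax(x, 0), deviance = sum((b - A %*% pmax(x, 0))^2))
}
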