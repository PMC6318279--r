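#' Knight-Ruiz matrix balancing
#'
#' Computes positive weights `w` such that every row (and, by symmetry,
#' column) of `diag(w) %*% M %*% diag(w)` sums to 1, using the
#' Knight-Ruiz inner-outer Newton iteration (conjugate-gradient inner
#' solves with damping bounds on the step). Bins whose marginal is zero
#' are masked out before balancing and reported with `NA` weights.
#'
#' @param m A [contact_matrix()] or a symmetric non-negative matrix.
#' @param tol Relative tolerance on the row sums of the balanced matrix.
#' @param max_iter Maximum outer iterations before aborting.
#' @param mask Additional bin indices to exclude from balancing.
#' @return The input `contact_matrix` with `$weights` (NA at masked
#'   bins) and `$balanced` (balanced matrix, NA rows/columns at masked
#'   bins) filled in; a plain matrix input is wrapped first.
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 100L, mask = integer(0)) {
  if (is.matrix(m)) m <- contact_matrix(m, bin_size = 1L)
  stopifnot(inherits(m, "contact_matrix"))
  C <- m$counts
  n <- nrow(C)
  keep <- which(rowSums(C) > 0)
  keep <- setdiff(keep, mask)
  if (length(keep) == 0)
    stop("matrix has no unmasked rows with non-zero marginals",
         call. = FALSE)
  A <- C[keep, keep, drop = FALSE]
  x <- kr_bnewt(A, tol = tol, max_outer = max_iter)
  w <- rep(NA_real_, n)
  w[keep] <- x
  B <- matrix(NA_real_, n, n)
  B[keep, keep] <- A * tcrossprod(x)
  m$weights <- w
  m$mask <- setdiff(seq_len(n), keep)
  m$balanced <- B
  m
}

# Knight & Ruiz inner-outer Newton iteration; returns x with
# rowSums(diag(x) A diag(x)) = 1 to within tol (2-norm of the residual).
kr_bnewt <- function(A, tol = 1e-6, delta = 0.1, Delta = 3,
                     max_outer = 100L) {
  n <- nrow(A)
  if (any(A < 0)) stop("matrix must be non-negative", call. = FALSE)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax; stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * drop(A %*% x)
  rk <- 1 - v
  rho_km1 <- drop(crossprod(rk))
  rout <- rho_km1; rold <- rout
  outer_i <- 0L
  while (rout > rt) {
    outer_i <- outer_i + 1L
    if (outer_i > max_outer)
      stop(sprintf(
        "KR balancing did not converge in %d iterations (residual %.3g)",
        max_outer, sqrt(rout)), call. = FALSE)
    k <- 0L; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- NA_real_
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- drop(crossprod(rk, Z))
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * drop(A %*% (x * p)) + v * p
      alpha <- rho_km1 / drop(crossprod(p, w))
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- drop(crossprod(rk, Z))
    }
    x <- x * y
    v <- x * drop(A %*% x)
    rk <- 1 - v
    rho_km1 <- drop(crossprod(rk))
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}
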