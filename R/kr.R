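# Knight-Ruiz balancing: inner-outer Newton iteration with a
# conjugate-gradient inner solve (Knight & Ruiz 2013, IMA J Numer Anal).
# Returns x with rowSums(diag(x) %*% A %*% diag(x)) = 1 to within tol.
kr_weights <- function(A, tol = 1e-8, max_iter = 200,
                       delta = 0.1, Delta = 3) {
  n <- nrow(A)
  stopifnot(n == ncol(A))
  if (n == 0) return(numeric(0))
  # scale so the mean row sum is ~1; improves conditioning, undone below
  s <- Matrix::rowSums(A)
  if (any(s <= 0)) stop("kr_weights: zero row in input")
  sc <- mean(s)
  A <- A / sc
  e <- rep(1, n)
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  x <- e
  rt <- tol^2
  v <- x * as.numeric(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  it <- 0
  while (rout > rt) {
    it <- it + 1
    if (it > max_iter)
      stop(sprintf(
        "Knight-Ruiz balancing did not converge in %d iterations (residual %.3g, target %.3g)",
        max_iter, sqrt(rout), tol))
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.numeric(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
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
      rho_km1 <- sum(rk * Z)
      if (k > 200) break
    }
    x <- x * y
    v <- x * as.numeric(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / (2 * res_norm))
  }
  x / sqrt(sc)
}
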