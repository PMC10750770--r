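# Independent solver for the penalized log-likelihood
#     max  log det(Theta) - tr(S Theta) - lambda * sum_{i!=j} |theta_ij|
# via ADMM (alternating eigen-decomposition step and soft-thresholding),
# a different algorithm from the block coordinate descent used by the
# package. Used as a cross-check oracle only.
admm_glasso <- function(S, lambda, rho = 1, tol = 1e-10, maxit = 20000) {
  p <- nrow(S)
  Theta <- diag(p); Z <- diag(p); U <- matrix(0, p, p)
  for (i in seq_len(maxit)) {
    eg <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    d <- (eg$values + sqrt(eg$values^2 + 4 * rho)) / (2 * rho)
    Theta <- eg$vectors %*% (d * t(eg$vectors))
    Zold <- Z
    A <- Theta + U
    Z <- sign(A) * pmax(abs(A) - lambda / rho, 0)
    diag(Z) <- diag(A)              # diagonal unpenalized
    U <- U + Theta - Z
    r_prim <- max(abs(Theta - Z))
    r_dual <- rho * max(abs(Z - Zold))
    if (r_prim < tol && r_dual < tol) break
  }
  (Z + t(Z)) / 2
}

# Holm step-down adjustment written out from the formula, independent of
# stats::p.adjust: sort ascending, multiply by (m - rank + 1), enforce
# monotonicity with a running maximum, cap at 1.
holm_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
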