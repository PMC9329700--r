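# Matrix-free LSQR (Paige & Saunders 1982) for min ||A x - b||_2.
#
# A is given as a pair of closures: aprod(x) computes A %*% x (length-d
# result) and atprod(y) computes t(A) %*% y (length-p result). For
# rank-deficient systems LSQR converges to the minimum-norm least-squares
# solution when started from zero, which is how the completion step resolves
# the gauge freedom of the factorization — no explicit regularization.
# Damping (Tikhonov) is realized through the standard augmented system
# [A; damp * I], so the core iteration stays the plain one.
#
# atol/btol are the standard relative stopping tolerances; itnlim caps the
# iteration count. Returns list(x, itn, istop, resid_norm).
lsqr_solve <- function(aprod, atprod, b, p,
                       atol = 1e-8, btol = 1e-8, itnlim = 1000L,
                       damp = 0) {
  if (damp > 0) {
    d0 <- length(b)
    ap <- function(x) c(aprod(x), damp * x)
    atp <- function(y) atprod(y[seq_len(d0)]) + damp * y[d0 + seq_len(p)]
    return(lsqr_solve(ap, atp, c(b, numeric(p)), p,
                      atol = atol, btol = btol, itnlim = itnlim, damp = 0))
  }
  x <- numeric(p)
  u <- b
  beta <- sqrt(sum(u^2))
  bnorm <- beta
  if (beta == 0) {
    return(list(x = x, itn = 0L, istop = 0L, resid_norm = 0))
  }
  u <- u / beta
  v <- atprod(u)
  alpha <- sqrt(sum(v^2))
  if (alpha == 0) {
    return(list(x = x, itn = 0L, istop = 0L, resid_norm = beta))
  }
  v <- v / alpha
  w <- v
  phibar <- beta
  rhobar <- alpha
  anorm <- 0
  istop <- 0L
  itn <- 0L
  rnorm <- beta

  while (itn < itnlim) {
    itn <- itn + 1L
    # Golub-Kahan bidiagonalization step
    u <- aprod(v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) {
      u <- u / beta
      anorm <- sqrt(anorm^2 + alpha^2 + beta^2)
      v <- atprod(u) - beta * v
      alpha <- sqrt(sum(v^2))
      if (alpha > 0) v <- v / alpha
    }
    # plane rotation to eliminate the subdiagonal
    rho <- sqrt(rhobar^2 + beta^2)
    cs <- rhobar / rho
    sn <- beta / rho
    theta <- sn * alpha
    rhobar <- -cs * alpha
    phi <- cs * phibar
    phibar <- sn * phibar
    # update solution and search direction
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w

    rnorm <- abs(phibar)
    arnorm <- alpha * abs(sn * phi)
    # stopping tests (consistent system, least-squares, safeguards)
    test1 <- rnorm / bnorm
    test2 <- if (anorm > 0 && rnorm > 0) arnorm / (anorm * rnorm) else 0
    rtol <- btol + atol * anorm * sqrt(sum(x^2)) / bnorm
    if (test1 <= rtol) { istop <- 1L; break }
    if (test2 <= atol) { istop <- 2L; break }
    if (!is.finite(rnorm) || !is.finite(arnorm)) { istop <- 9L; break }
  }
  list(x = x, itn = itn, istop = istop, resid_norm = rnorm)
}
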