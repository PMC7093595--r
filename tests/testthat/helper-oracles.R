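# Independent oracles used across the suite.  These deliberately do not
# call the package's simulation/estimation code paths they are checking.

# Closed-form solution of the linear PK cascade gut -> central -> 6-TGN for
# a single gut bolus `b` at time 0 (Bateman cascade with distinct rates).
pk_bolus_closed_form <- function(t, b, ka, k20, cl, fm3_kme) {
  gut <- b * exp(-ka * t)
  cen <- b * ka / (k20 - ka) * (exp(-ka * t) - exp(-k20 * t))
  tgn <- b * fm3_kme * ka * (
    exp(-ka * t) / ((k20 - ka) * (cl - ka)) +
    exp(-k20 * t) / ((ka - k20) * (cl - k20)) +
    exp(-cl * t) / ((ka - cl) * (k20 - cl)))
  cbind(gut = gut, cen = cen, tgn = tgn)
}

# Exact marginal -2 log-likelihood of a linear-Gaussian mixed model
#   y = a + B eta + e,  eta ~ N(0, diag(omega2_free)),  e ~ N(0, sigma2 I)
lin_gauss_neg2ll <- function(y, a, B, omega2_free, sigma2) {
  V <- B %*% (omega2_free * t(B)) + diag(sigma2, length(y))
  r <- y - a
  length(y) * log(2 * pi) + as.numeric(determinant(V)$modulus) +
    drop(r %*% solve(V, r))
}

# Adaptive Gauss-Hermite -2 log marginal likelihood for one patient with
# free random-effect dimensions `free` (k <= 3 for tractability).
# predfun(eta_full) -> f; proportional or additive error.
agh_neg2ll <- function(y, predfun, omega2, sigma2, error = "proportional",
                       nodes = 32) {
  free <- which(omega2 > 0)
  k <- length(free)
  stopifnot(k >= 1, k <= 3)
  nlj <- function(ef) {                 # negative log joint density
    eta <- numeric(length(omega2)); eta[free] <- ef
    f <- predfun(eta)
    g <- if (error == "proportional") sigma2 * f^2 else rep(sigma2, length(f))
    0.5 * (sum((y - f)^2 / g + log(2 * pi * g)) +
           sum(ef^2 / omega2[free]) + sum(log(2 * pi * omega2[free])))
  }
  mode <- optim(numeric(k), nlj, method = "BFGS",
                control = list(reltol = 1e-14, maxit = 500))$par
  H <- pracma::hessian(nlj, mode)
  Sig <- solve((H + t(H)) / 2)
  E <- eigen(Sig, symmetric = TRUE)
  A <- E$vectors %*% diag(sqrt(pmax(E$values, 0)), k)
  gh <- pracma::gaussHermite(nodes)
  idx <- expand.grid(rep(list(seq_len(nodes)), k))
  z <- as.matrix(idx)
  lw <- rowSums(matrix(log(gh$w[z]), nrow(z), k))
  x <- matrix(gh$x[z], nrow(z), k)
  expo <- vapply(seq_len(nrow(x)), function(i) {
    eta <- mode + sqrt(2) * drop(A %*% x[i, ])
    -nlj(eta) + sum(x[i, ]^2)
  }, numeric(1))
  lt <- lw + expo
  m <- max(lt)
  log_int <- (k / 2) * log(2) + determinant(A)$modulus + m +
    log(sum(exp(lt - m)))
  -2 * as.numeric(log_int)
}
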