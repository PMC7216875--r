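# Shared fixtures and independent oracles for the test suite.

# The simulation reference: WM-like two-pool tissue and the four-weighting
# protocol (15/15/30/30 deg, 256/1024/256/1024 us, TR 7/7.768/7/7.768 ms).
study_tissue <- function() tissue_params()
study_protocol <- function() default_protocol()

# Independent single-pool SSFP oracle in the Freeman-Hill factored form
# (product-minus-product denominator), for the fb -> 0 limit checks.
single_pool_ssfp <- function(m0, t1, t2, alpha, tr, psi, phi_n) {
  e1 <- exp(-tr / t1); e2 <- exp(-tr / t2)
  theta <- psi + phi_n
  d <- (1 - e1 * cos(alpha)) * (1 - e2 * cos(theta)) -
    e2 * (e1 - cos(alpha)) * (e2 - cos(theta))
  m0 * (1 - e1) * sin(alpha) * (1 - e2 * exp(-1i * theta)) / d *
    e2 * exp(1i * psi / 2)
}

# Single-pool ellipse parameters in their classical closed forms.
single_pool_ellipse <- function(m0, t1, t2, alpha, tr) {
  e1 <- exp(-tr / t1); e2 <- exp(-tr / t2)
  den <- 1 - e1 * cos(alpha) - e2^2 * (e1 - cos(alpha))
  list(me = m0 * e2 * (1 - e1) * sin(alpha) / den,
       a = e2,
       b = e2 * (1 - e1) * (1 + cos(alpha)) / den)
}

# Algebraic conic fit: smallest right singular vector of the design matrix
# [x^2 xy y^2 x y 1]; returns the RMS algebraic residual on unit-norm
# coefficients.  Used to certify that the theta-locus is an exact conic.
conic_residual <- function(z) {
  x <- Re(z); y <- Im(z)
  d <- cbind(x^2, x * y, y^2, x, y, 1)
  v <- svd(d)$v[, 6]
  sqrt(mean((d %*% v)^2))
}

# Cache for the expensive acceptance-scale Monte Carlo run (shared by the
# acceptance criteria tests so the 4096-realization study runs once).
.mc_cache <- new.env(parent = emptyenv())
acceptance_mc <- function() {
  if (is.null(.mc_cache$summary)) {
    cfg <- mc_config(n_realizations = 4096, seed = 925)
    .mc_cache$summary <- run_monte_carlo(cfg)
  }
  .mc_cache$summary
}
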