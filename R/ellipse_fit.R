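#' Initial guess for the per-ellipse fit
#'
#' `M_E` is initialized as the magnitude of the complex mean of the samples.
#' `a` and `b` are initialized from the single-pool closed form assuming
#' `T1f/T2f = 1000/50` ms and no bound pool, for the given `TR` and flip
#' angle.  The tightly coupled phases are initialized by trying three
#' candidates for `psi` (-pi, 0, +pi); for each, `phi_rf` is set to the
#' phase of the complex mean minus half the `psi` candidate (the complex
#' mean of a phase-cycled ellipse is close to real before the global
#' `e^{i(psi/2 + phi_rf)}` factor), and the candidate triple with the
#' lowest RMS residual against the data wins.
#'
#' @param samples complex data, one value per phase increment.
#' @param phase_increments RF phase increments, radians.
#' @param tr repetition time, ms.
#' @param alpha nominal flip angle, radians.
#' @return an [ellipse_params()] to start the full nonlinear fit from.
#' @export
ellipse_initial_guess <- function(samples, phase_increments, tr, alpha) {
  if (all(abs(samples) == 0))
    stop_mtellipse("all-zero samples: degenerate input", "degenerate_input")
  mbar <- mean(samples)
  me0 <- abs(mbar)
  ref <- tissue_params(m0f = 1, t1f = 1000, t2f = 50, t1b = 1000,
                       fb = 0, kbf = 0)
  setting <- sequence_setting(alpha, tr, trf = min(0.256, tr / 2),
                              phase_increments = phase_increments)
  g <- ellipse_geometry(ref, setting, alpha)
  best <- NULL
  best_rss <- Inf
  for (psi0 in c(-pi, 0, pi)) {
    # the complex mean of a phase-cycled ellipse is close to real before the
    # global e^{i(psi/2 + phi_rf)} factor, so subtract the candidate's psi/2
    phi0 <- Arg(mbar) - psi0 / 2
    theta <- psi0 + phase_increments
    m <- me0 * (1 - g$a * exp(-1i * theta)) / (1 - g$b * cos(theta)) *
      exp(1i * (psi0 / 2 + phi0))
    rss <- sum(Mod(m - samples)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- ellipse_params(me = me0, a = g$a, b = g$b,
                             psi = psi0, phi_rf = phi0)
    }
  }
  best
}

#' Per-ellipse bounded nonlinear least-squares fit
#'
#' Fits the five ellipse parameters `(M_E, a, b, psi, phi_rf)` to complex
#' phase-increment samples by trust-region least squares on the stacked real
#' and imaginary residuals, with a Huber loss to suppress outliers.  Bounds:
#' `0 < a < exp(-TR/5000)`, `0 < b < 1`, `-2pi < psi < 2pi`,
#' `-2pi < phi_rf < 2pi`, and the ellipse is kept vertical by the exact
#' reparameterization `b = 2a*beta/(1+a^2)` with `0 < beta < 1`.
#'
#' @inheritParams ellipse_initial_guess
#' @param huber apply a Huber loss (threshold `1.345` times the median
#'   absolute deviation of the residuals from a first plain pass)?
#' @param psi_starts off-resonance phase values to start the solver from;
#'   the lowest-cost solution over all starts is kept.  The default spans
#'   `(-pi, pi]` at the 60-degree spacing of the usual phase-increment
#'   scheme, which removes the solver's local minima in the coupled
#'   `(psi, phi_rf)` subspace.
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return an object of class `ellipse_fit` with elements `params`
#'   (an [ellipse_params()] with `psi`, `phi_rf` wrapped to `(-pi, pi]`),
#'   `rmse` (root-mean-square complex residual, un-robustified),
#'   `rel_rmse` (`rmse/me`), `n_points`, and `converged`.
#' @details Internally the solver works in `(M_E, a, beta, psi, chi)` with
#'   `chi = psi/2 + phi_rf` the global signal phase: `psi` then only moves
#'   the sampling angles and `chi` only rotates the data, which conditions
#'   the problem far better than the raw `(psi, phi_rf)` pair.
#' @export
fit_ellipse <- function(samples, phase_increments, tr, alpha,
                        huber = TRUE,
                        psi_starts = seq(-pi, pi, by = pi / 3),
                        control = minpack.lm::nls.lm.control(
                          ftol = 1e-10, ptol = 1e-10, maxiter = 200)) {
  n <- length(samples)
  if (n != length(phase_increments))
    stop_mtellipse("samples and phase_increments differ in length",
                   "invalid_input")
  if (n < 5)
    stop_mtellipse("at least 5 phase increments needed for 5 parameters",
                   "underdetermined")
  if (all(abs(samples) == 0))
    stop_mtellipse("all-zero samples: degenerate input", "degenerate_input")

  sre <- Re(samples); sim <- Im(samples)
  resid_plain <- function(par) {
    b <- 2 * par[2] * par[3] / (1 + par[2]^2)
    theta <- par[4] + phase_increments
    m <- par[1] * (1 - par[2] * exp(-1i * theta)) / (1 - b * cos(theta)) *
      exp(1i * par[5])
    c(Re(m) - sre, Im(m) - sim)
  }

  mbar <- mean(samples)
  st <- sequence_setting(alpha, tr, trf = min(0.256, tr / 2),
                         phase_increments = phase_increments)
  a_hi <- exp(-tr / 5000)
  eps <- 1e-9
  # geometry starts: a tissue-like reference (T1f/T2f = 1000/50 ms), a
  # long-T2 fluid-like one (near-degenerate flat ellipses), and two short-T2
  # fallbacks so arbitrary ellipse shapes are reached
  geo0 <- lapply(c(50, 1000, 10, 3), function(t2) {
    g <- ellipse_geometry(tissue_params(m0f = 1, t1f = 1000, t2f = t2,
                                        t1b = 1000, fb = 0, kbf = 0),
                          st, alpha)
    a0 <- min(max(g$a, eps), a_hi - eps)
    c(a0 = a0, beta0 = min(max(g$b * (1 + a0^2) / (2 * a0), eps), 1 - eps))
  })
  # near the verticality limit (b close to 2a/(1+a^2)) none of the
  # tissue-derived starts is flat enough; add one strongly flattened pair
  geo0 <- c(geo0, list(c(a0 = 0.7, beta0 = 0.95)))
  me0 <- max(abs(mbar), eps)
  chi0 <- Arg(mbar)
  lower <- c(eps, eps, eps, -2 * pi, -3 * pi)
  upper <- c(Inf, a_hi - eps, 1 - eps, 2 * pi, 3 * pi)

  fit <- NULL
  for (g0 in geo0) for (psi0 in psi_starts) {
    f <- minpack.lm::nls.lm(c(me0, g0[["a0"]], g0[["beta0"]], psi0, chi0),
                            lower, upper, fn = resid_plain, control = control)
    if (is.null(fit) || f$deviance < fit$deviance) fit <- f
    if (fit$deviance < 1e-20 * sum(Mod(samples)^2)) break
  }
  par <- fit$par
  converged <- fit$info %in% 1:4

  if (huber) {
    r <- resid_plain(par)
    scale <- stats::mad(r, center = 0)
    if (scale > 0) {
      delta <- 1.345 * scale
      resid_huber <- function(p) {
        r <- resid_plain(p)
        ar <- abs(r)
        rho <- ifelse(ar <= delta, r^2 / 2, delta * (ar - delta / 2))
        sqrt(rho)
      }
      fit <- minpack.lm::nls.lm(par, lower, upper, fn = resid_huber,
                                control = control)
      par <- fit$par
      converged <- converged && fit$info %in% 1:4
    }
  }

  ph <- canonical_phases(par[4], par[5] - par[4] / 2)  # phi_rf = chi - psi/2
  b_hat <- 2 * par[2] * par[3] / (1 + par[2]^2)
  params <- ellipse_params(me = par[1], a = par[2], b = b_hat,
                           psi = ph$psi, phi_rf = ph$phi_rf)
  r <- resid_plain(par)
  rmse <- sqrt(mean(r[1:n]^2 + r[n + 1:n]^2))
  structure(list(params = params, rmse = rmse,
                 rel_rmse = rmse / params$me,
                 n_points = n, converged = converged),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> M_E = %.4g, a = %.4f, b = %.4f, psi = %.3f, phi_rf = %.3f | rmse = %.3g (%.2f%% of M_E), %s\n",
    x$params$me, x$params$a, x$params$b, x$params$psi, x$params$phi_rf,
    x$rmse, 100 * x$rel_rmse,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' RMSE diagnostic maps from a grid of ellipse fits
#'
#' Surfaces model mismatch as per-voxel, per-weighting fit residuals, both
#' absolute and relative to the fitted `M_E`.  Elevated relative residuals
#' flag voxels whose signal departs from a single ellipse (for example a
#' second frequency-shifted water component).
#'
#' @param fits a list (or array-shaped list) of `ellipse_fit` objects, or a
#'   list of lists per weighting.
#' @return a list with numeric vectors/arrays `rmse` and `rel_rmse`
#'   matching the input shape.
#' @export
rmse_map <- function(fits) {
  shape <- dim(fits)
  rmse <- vapply(fits, function(f) f$rmse, numeric(1))
  rel <- vapply(fits, function(f) f$rel_rmse, numeric(1))
  if (!is.null(shape)) {
    dim(rmse) <- shape
    dim(rel) <- shape
  }
  list(rmse = rmse, rel_rmse = rel)
}
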