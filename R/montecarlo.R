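#' Monte Carlo configuration
#'
#' Defaults reproduce the validation study conditions: the white-matter-like
#' tissue (`M0f = 100`, `T1f/T2f = 1100/80` ms, `kbf = 4.45` /s,
#' `fb = 10%`), the four-weighting protocol, complex Gaussian noise with
#' `sigma = M0f/500` (standard deviation of the complex noise; each of the
#' real and imaginary channels receives `sigma/sqrt(2)`), and 4096 noise
#' realizations.
#'
#' @param tissue a [tissue_params()].
#' @param protocol an [mt_protocol()].
#' @param sigma complex noise standard deviation, signal units.
#' @param n_realizations number of noise realizations.
#' @param seed RNG seed used by [run_monte_carlo()].
#' @return an object of class `mc_config`.
#' @export
mc_config <- function(tissue = tissue_params(),
                      protocol = default_protocol(),
                      sigma = tissue$m0f / 500,
                      n_realizations = 4096,
                      seed = 1L) {
  if (sigma < 0) stop_mtellipse("sigma must be non-negative", "invalid_config")
  if (n_realizations < 1)
    stop_mtellipse("need at least one realization", "invalid_config")
  tissue$g0 <- protocol$g0
  structure(list(tissue = tissue, protocol = protocol, sigma = sigma,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "mc_config")
}

#' Draw one noisy multi-ellipse realization
#'
#' Evaluates the noiseless forward model for every setting and phase
#' increment at the given nuisance phases, then adds complex Gaussian noise:
#' independent zero-mean Gaussians of standard deviation `sigma/sqrt(2)` on
#' the real and imaginary channels, so the complex noise has standard
#' deviation `sigma`.
#'
#' @param cfg an [mc_config()].
#' @param psi off-resonance phase per TR, radians (shared by all settings).
#' @param phi_rf transmit RF phase, radians.
#' @param noisy add noise? (`FALSE` returns the noiseless samples).
#' @return a complex matrix, one row per setting, one column per phase
#'   increment (4 x 6 = 24 data points under the default protocol).
#' @export
draw_realization <- function(cfg, psi, phi_rf, noisy = TRUE) {
  settings <- cfg$protocol$settings
  n_inc <- vapply(settings, function(s) length(s$phase_increments), integer(1))
  if (length(unique(n_inc)) != 1)
    stop_mtellipse("all settings must share the phase-increment count",
                   "invalid_config")
  out <- matrix(0i, length(settings), n_inc[1])
  for (i in seq_along(settings)) {
    ep <- ellipse_from_tissue(cfg$tissue, settings[[i]],
                              psi = psi, phi_rf = phi_rf)
    out[i, ] <- ellipse_signal(ep, psi + settings[[i]]$phase_increments)
  }
  if (noisy && cfg$sigma > 0) {
    s <- cfg$sigma / sqrt(2)
    out <- out + matrix(complex(real = rnorm(length(out), sd = s),
                                imaginary = rnorm(length(out), sd = s)),
                        nrow(out), ncol(out))
  }
  out
}

#' Run the Monte Carlo parameter-recovery experiment
#'
#' For each realization, fresh nuisance phases `psi` and `phi_rf` are drawn
#' uniformly on `(-pi, pi)`, a noisy sample set is generated, every ellipse
#' is fitted (stage 1), `T2f` is inverted in closed form, and the MT
#' parameters are fitted (stage 2).  Per-parameter bias and coefficient of
#' variation are summarized over realizations; for the angular parameters
#' the true value modulo `2*pi` is subtracted before summarizing, and
#' `phi_rf` fits that land degenerately at the `+pi/-pi` boundary are
#' excluded from its own statistics but counted.
#'
#' @param cfg an [mc_config()].
#' @param progress print a progress line every 512 realizations?
#' @return an object of class `mc_summary`: data frames `ellipse` (bias and
#'   CoV of `M_E`, `a`, `b` per setting, plus angular errors), `qmt` (bias
#'   and CoV of `M0f`, `fb`, `kbf`, `T1f`, `T2f`), scalars
#'   `phi_boundary_fraction`, `kbf_bound_fraction`, `snr`, and the raw
#'   per-realization estimate tables `draws_ellipse`, `draws_qmt`.
#' @export
run_monte_carlo <- function(cfg, progress = FALSE) {
  set.seed(cfg$seed)
  settings <- cfg$protocol$settings
  m <- length(settings)
  n <- cfg$n_realizations

  truth <- lapply(settings, function(s)
    ellipse_geometry(cfg$tissue, s, s$alpha))
  noiseless_mean <- mean(abs(draw_realization(cfg, 0, 0, noisy = FALSE)))
  snr <- if (cfg$sigma > 0) noiseless_mean / (cfg$sigma / sqrt(2)) else Inf

  de <- vector("list", n)
  dq <- vector("list", n)
  n_fail <- 0L
  for (r in seq_len(n)) {
    psi <- runif(1, -pi, pi)
    phi <- runif(1, -pi, pi)
    samp <- draw_realization(cfg, psi, phi)
    est <- tryCatch({
      fits <- lapply(seq_len(m), function(i)
        fit_ellipse(samp[i, ], settings[[i]]$phase_increments,
                    settings[[i]]$tr, settings[[i]]$alpha))
      me <- vapply(fits, function(f) f$params$me, numeric(1))
      a <- vapply(fits, function(f) f$params$a, numeric(1))
      b <- vapply(fits, function(f) f$params$b, numeric(1))
      psih <- vapply(fits, function(f) f$params$psi, numeric(1))
      phih <- vapply(fits, function(f) f$params$phi_rf, numeric(1))
      t2f <- estimate_t2f(a, vapply(settings, `[[`, numeric(1), "tr"))
      q <- fit_qmt(me, b, settings, t2f, g0 = cfg$protocol$g0)
      list(ellipse = data.frame(
             realization = r, setting = seq_len(m), me = me, a = a, b = b,
             dpsi = wrap_angle(psih - psi), dphi = wrap_angle(phih - phi)),
           qmt = data.frame(realization = r, m0f = q$m0f, fb = q$fb,
                            kbf = q$kbf, t1f = q$t1f, t2f = t2f,
                            kbf_at_bound = q$hit_bounds[["kbf"]]))
    }, error = function(e) NULL)
    if (is.null(est)) n_fail <- n_fail + 1L else {
      de[[r]] <- est$ellipse
      dq[[r]] <- est$qmt
    }
    if (progress && r %% 512 == 0)
      message(sprintf("  realization %d / %d", r, n))
  }
  draws_ellipse <- do.call(rbind, de)
  draws_qmt <- do.call(rbind, dq)
  summarize_mc(cfg, draws_ellipse, draws_qmt, truth, snr, n_fail)
}

# Build the mc_summary from raw draw tables (kept separate so that summary
# statistics are, by construction, invariant to realization order).
summarize_mc <- function(cfg, draws_ellipse, draws_qmt, truth, snr, n_fail) {
  m <- length(cfg$protocol$settings)
  stat <- function(est, tru) {
    mu <- mean(est)
    c(bias_pct = (mu - tru) / tru * 100,
      cov_pct = stats::sd(est) / mu * 100)
  }
  ell <- do.call(rbind, lapply(seq_len(m), function(i) {
    d <- draws_ellipse[draws_ellipse$setting == i, ]
    s_me <- stat(d$me, truth[[i]]$me)
    s_a <- stat(d$a, truth[[i]]$a)
    s_b <- stat(d$b, truth[[i]]$b)
    keep <- abs(d$dphi) <= pi / 2       # drop +pi/-pi degenerate solutions
    data.frame(setting = i,
               me_bias = s_me[1], me_cov = s_me[2],
               a_bias = s_a[1], a_cov = s_a[2],
               b_bias = s_b[1], b_cov = s_b[2],
               dpsi_mean_deg = rad2deg(mean(d$dpsi)),
               dpsi_sd_deg = rad2deg(stats::sd(d$dpsi)),
               dphi_mean_deg = rad2deg(mean(d$dphi[keep])),
               dphi_sd_deg = rad2deg(stats::sd(d$dphi[keep])),
               row.names = NULL)
  }))
  phi_boundary <- mean(abs(draws_ellipse$dphi) > pi / 2)
  tru <- cfg$tissue
  qmt <- data.frame(
    parameter = c("m0f", "fb", "kbf", "t1f", "t2f"),
    truth = c(tru$m0f, tru$fb, tru$kbf, tru$t1f, tru$t2f),
    rbind(stat(draws_qmt$m0f, tru$m0f), stat(draws_qmt$fb, tru$fb),
          stat(draws_qmt$kbf, tru$kbf), stat(draws_qmt$t1f, tru$t1f),
          stat(draws_qmt$t2f, tru$t2f)),
    row.names = NULL)
  structure(list(
    config = cfg, ellipse = ell, qmt = qmt,
    phi_boundary_fraction = phi_boundary,
    kbf_bound_fraction = mean(draws_qmt$kbf_at_bound),
    snr = snr, n_failed = n_fail,
    draws_ellipse = draws_ellipse, draws_qmt = draws_qmt),
    class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<mc_summary> %d realizations, sigma = %.3g, SNR = %.1f\n",
              x$config$n_realizations, x$config$sigma, x$snr))
  cat("Ellipse parameters (bias %, CoV % per setting):\n")
  print(round(x$ellipse[, 1:7], digits))
  cat("MT parameters:\n")
  print(cbind(x$qmt[, 1:2], round(x$qmt[, 3:4], digits)))
  cat(sprintf("phi_rf boundary-degenerate fraction: %.3g%%\n",
              100 * x$phi_boundary_fraction))
  cat(sprintf("kbf upper-bound hits: %.3g%%; failed realizations: %d\n",
              100 * x$kbf_bound_fraction, x$n_failed))
  invisible(x)
}
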