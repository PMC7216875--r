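#' Two-pool tissue parameters
#'
#' Ground-truth or fitted parameters of the binary spin-bath model: a free
#' water pool (directly observed) exchanging with a semi-solid bound pool
#' (observed only through its effect on the free pool).  The bound pool
#' fraction is defined as \eqn{f_b = M_{0b} / (M_{0f} + M_{0b})}, and the
#' reverse (free-to-bound) exchange rate follows from detailed balance at
#' equilibrium, \eqn{k_{fb} = k_{bf} f_b / f_f}.
#'
#' @param m0f free-pool equilibrium magnetization (arbitrary signal units).
#' @param t1f free-pool longitudinal relaxation time, ms.
#' @param t2f free-pool transverse relaxation time, ms.
#' @param t1b bound-pool longitudinal relaxation time, ms (default: `t1f`).
#' @param fb bound-pool fraction, in `[0, 1)`.
#' @param kbf bound-to-free exchange rate, s^-1.
#' @param g0 absorption lineshape value at resonance, microseconds.
#' @return an object of class `tissue_params`.
#' @examples
#' tissue_params()  # the white-matter-like simulation reference
#' @export
tissue_params <- function(m0f = 100, t1f = 1100, t2f = 80, t1b = t1f,
                          fb = 0.10, kbf = 4.45, g0 = 14) {
  if (t1f <= 0 || t2f <= 0 || t1b <= 0)
    stop_mtellipse("relaxation times must be positive", "invalid_tissue")
  if (fb < 0 || fb >= 1)
    stop_mtellipse("bound pool fraction must lie in [0, 1)", "invalid_tissue")
  if (kbf < 0)
    stop_mtellipse("exchange rate must be non-negative", "invalid_tissue")
  structure(list(m0f = m0f, t1f = t1f, t2f = t2f, t1b = t1b,
                 fb = fb, kbf = kbf, g0 = g0),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "<tissue_params> M0f = %g, T1f = %g ms, T2f = %g ms, T1b = %g ms, fb = %.1f%%, kbf = %g /s, G0 = %g us\n",
    x$m0f, x$t1f, x$t2f, x$t1b, 100 * x$fb, x$kbf, x$g0))
  invisible(x)
}

#' Per-voxel nuisance field state
#'
#' @param psi off-resonance phase accrued per TR, `psi = 2*pi*df0*TR`, rad.
#' @param phi_rf transmit (B1+) RF phase, rad.
#' @param b1 relative transmit field amplitude (1 = nominal flip angle).
#' @return an object of class `field_state`.
#' @export
field_state <- function(psi = 0, phi_rf = 0, b1 = 1) {
  if (b1 <= 0)
    stop_mtellipse("b1 scale must be positive", "invalid_field")
  structure(list(psi = psi, phi_rf = phi_rf, b1 = b1), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> psi = %.3f rad, phi_rf = %.3f rad, b1 = %.3f\n",
              x$psi, x$phi_rf, x$b1))
  invisible(x)
}

# Relaxation / exchange / saturation intermediates for one tissue + setting.
#
# All quantities in ms and rad internally; kbf converted from s^-1, g0 from
# microseconds.  Vectorized over alpha_eff so that voxelwise forward
# modelling with a spatially varying B1+ scale stays cheap.  Returns the
# exponential factors and the A, B, C terms of the closed-form solution.
two_pool_terms <- function(tissue, setting, alpha_eff) {
  ff <- 1 - tissue$fb
  kbf <- tissue$kbf / 1000                   # s^-1 -> ms^-1
  kfb <- kbf * tissue$fb / ff                # detailed balance
  tr <- setting$tr
  e1f <- exp(-tr / tissue$t1f)
  e1b <- exp(-tr / tissue$t1b)
  e2f <- exp(-tr / tissue$t2f)
  ek <- exp(-(kbf + kfb) * tr)
  sat <- saturation_rate(alpha_eff, setting, tissue$g0)
  a_ <- 1 - sat$ew * e1b * (tissue$fb + ff * ek)
  b_ <- ff - ek * (sat$ew * e1b - tissue$fb)
  c_ <- tissue$fb * (1 - e1b) * (1 - ek)
  list(ff = ff, kbf = kbf, kfb = kfb,
       e1f = e1f, e1b = e1b, e2f = e2f, ek = ek,
       w = sat$w, ew = sat$ew, A = a_, B = b_, C = c_)
}
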