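#' Bound-pool saturation rate of an on-resonance RF pulse
#'
#' For a shaped pulse of flip angle `alpha_eff` and duration `TRF`, the mean
#' saturation rate experienced by the bound pool is
#' \deqn{W = \pi G_0 (p_2/p_1^2) \alpha^2 / T_{RF}^2,}
#' so a block pulse's saturation scales with flip angle squared and the
#' inverse square of the pulse length.  Flip angle in radians; `G0` is
#' converted from microseconds and `W` returned in ms^-1.
#'
#' @param alpha_eff effective flip angle in radians (nominal angle already
#'   scaled by the relative transmit field).
#' @param setting a [sequence_setting()].
#' @param g0 lineshape value at resonance, microseconds.
#' @return a list with `w` (saturation rate, ms^-1) and
#'   `ew = exp(-w * trf)` (per-pulse bound-pool attenuation).  Vectorized
#'   over `alpha_eff`.
#' @examples
#' saturation_rate(deg2rad(15), sequence_setting(deg2rad(15), 7, 0.256), 14)
#' @export
saturation_rate <- function(alpha_eff, setting, g0) {
  if (setting$trf <= 0)
    stop_mtellipse("TRF must be positive", "invalid_protocol")
  if (any(alpha_eff < 0))
    stop_mtellipse("effective flip angle must be non-negative", "invalid_protocol")
  w <- pi * (g0 * 1e-3) * (setting$p2 / setting$p1^2) *
    alpha_eff^2 / setting$trf^2
  list(w = w, ew = exp(-w * setting$trf))
}

# --- internal matrix builders -------------------------------------------
#
# State vector (Mxf, Myf, Mzf, Mzb).  Precession is counterclockwise,
# m = Mx + i*My -> e^{+i psi} m, so that the accrued off-resonance phase
# enters the echo signal as e^{+i psi/2}.  The RF pulse rotates the phase
# increment into the tip axis: a z-rotation by phi followed by a tip about
# y in the sense that carries +z onto +x (excited magnetization appears
# along +x, making the on-resonance signal real and positive); the bound
# pool is attenuated by ew.  This composition reproduces the closed-form
# two-pool ellipse exactly; see the methods vignette for the convention.

rot_z4 <- function(psi) {
  c_ <- cos(psi); s_ <- sin(psi)
  rbind(c(c_, -s_, 0, 0),
        c(s_,  c_, 0, 0),
        c(0,   0,  1, 0),
        c(0,   0,  0, 1))
}

relax_mat <- function(terms) diag(c(terms$e2f, terms$e2f, terms$e1f, terms$e1b))

exchange_mat <- function(tissue, terms) {
  fb <- tissue$fb; ff <- terms$ff; ek <- terms$ek
  rbind(c(1, 0, 0, 0),
        c(0, 1, 0, 0),
        c(0, 0, ff + fb * ek, ff * (1 - ek)),
        c(0, 0, fb * (1 - ek), fb + ff * ek))
}

pulse_mat <- function(alpha_eff, phi_n, ew) {
  ca <- cos(alpha_eff); sa <- sin(alpha_eff)
  tip <- rbind(c(ca, 0, sa),
               c(0,  1, 0),
               c(-sa, 0, ca))
  cp <- cos(phi_n); sp <- sin(phi_n)
  zrot <- rbind(c(cp, -sp, 0), c(sp, cp, 0), c(0, 0, 1))
  free <- tip %*% zrot
  rbind(cbind(free, 0), c(0, 0, 0, ew))
}

equilibrium_mag <- function(tissue, terms) {
  m0b <- tissue$m0f * tissue$fb / terms$ff
  c(0, 0, tissue$m0f, m0b)
}

regrowth_vec <- function(tissue, terms) {
  m0b <- tissue$m0f * tissue$fb / terms$ff
  c(0, 0, tissue$m0f * (1 - terms$e1f), m0b * (1 - terms$e1b))
}

#' Propagate the two-pool magnetization over one TR
#'
#' Applies one step of the steady-state recursion
#' \eqn{M_{n+1}^- = X (O R P M_n^- + M_0)}: RF pulse (with phase increment
#' and bound-pool saturation), relaxation, off-resonance precession, then
#' exchange with longitudinal regrowth.  The state is the magnetization just
#' before the next RF pulse.
#'
#' @param m_minus numeric 4-vector `(Mxf, Myf, Mzf, Mzb)` before the pulse.
#' @param tissue a [tissue_params()].
#' @param setting a [sequence_setting()].
#' @param field a [field_state()]; the effective flip angle is
#'   `field$b1 * setting$alpha` in both the rotation and the saturation rate.
#' @param phi_n RF phase increment for this acquisition, radians.
#' @return the 4-vector state before the following pulse.
#' @export
propagate_one_tr <- function(m_minus, tissue, setting, field, phi_n) {
  alpha_eff <- field$b1 * setting$alpha
  terms <- two_pool_terms(tissue, setting, alpha_eff)
  p <- pulse_mat(alpha_eff, phi_n, terms$ew)
  orp <- rot_z4(field$psi) %*% relax_mat(terms) %*% p
  as.numeric(exchange_mat(tissue, terms) %*%
               (orp %*% m_minus + regrowth_vec(tissue, terms)))
}

#' Steady-state transverse magnetization at TE via matrix inversion
#'
#' Solves the fixed point of the per-TR recursion by matrix inversion,
#' applies the RF pulse, and evolves to the echo time `TE = TR/2`
#' (transverse decay and precession by `psi/2`, plus the transmit phase).
#' Serves as the oracle for the closed-form expression.
#'
#' @inheritParams propagate_one_tr
#' @return complex transverse magnetization `Mxf + i*Myf` at TE.
#' @export
steady_state_matrix <- function(tissue, setting, field, phi_n) {
  alpha_eff <- field$b1 * setting$alpha
  terms <- two_pool_terms(tissue, setting, alpha_eff)
  p <- pulse_mat(alpha_eff, phi_n, terms$ew)
  x <- exchange_mat(tissue, terms)
  loop <- x %*% rot_z4(field$psi) %*% relax_mat(terms) %*% p
  lhs <- diag(4) - loop
  m_minus <- tryCatch(
    solve(lhs, x %*% regrowth_vec(tissue, terms)),
    error = function(e) stop_mtellipse(
      sprintf("degenerate steady state (singular I - XORP): %s", conditionMessage(e)),
      "degenerate_steady_state"))
  m_plus <- p %*% m_minus
  echo_to_te(complex(real = m_plus[1], imaginary = m_plus[2]), terms$e2f, field)
}

# Evolution from just after the RF pulse to the echo time.  The precession
# contributes e^{+i psi/2}; the amplitude carries the closed form's full-TR
# transverse factor E2f (the model's echo-amplitude convention, absorbed by
# the per-ellipse M_E fit); the transmit phase phi_rf adds as a constant.
echo_to_te <- function(m_plus_xy, e2f, field) {
  m_plus_xy * e2f * exp(1i * (field$psi / 2 + field$phi_rf))
}

#' Closed-form complex steady-state SSFP signal of the two-pool model
#'
#' Evaluates the closed-form solution of the MT-extended SSFP steady state
#' at the echo time, with \eqn{\theta = \psi + \phi_n}:
#' \deqn{M_{xy} = \frac{M_{0f} (B(1-E_{1f}) + C)(1 - E_{2f} e^{-i\theta})
#'   \sin\alpha \; E_{2f} e^{i\psi/2}}
#'   {A - B E_{1f}\cos\alpha - E_{2f}^2 (B E_{1f} - A \cos\alpha)
#'    - E_{2f}(A - B E_{1f})(1 + \cos\alpha)\cos\theta}}
#' multiplied by the transmit phase factor \eqn{e^{i\phi_{RF}}}.
#'
#' @inheritParams propagate_one_tr
#' @return complex signal at TE; vectorized over `phi_n`.
#' @export
mxy_closed_form <- function(tissue, setting, field, phi_n) {
  alpha_eff <- field$b1 * setting$alpha
  terms <- two_pool_terms(tissue, setting, alpha_eff)
  theta <- field$psi + phi_n
  ca <- cos(alpha_eff)
  den <- terms$A - terms$B * terms$e1f * ca -
    terms$e2f^2 * (terms$B * terms$e1f - terms$A * ca) -
    terms$e2f * (terms$A - terms$B * terms$e1f) * (1 + ca) * cos(theta)
  if (any(abs(den) < .Machine$double.eps * 100))
    stop_mtellipse("degenerate closed-form denominator", "degenerate_signal")
  num <- tissue$m0f * (terms$B * (1 - terms$e1f) + terms$C) *
    (1 - terms$e2f * exp(-1i * theta)) * sin(alpha_eff) *
    terms$e2f * exp(1i * field$psi / 2)
  num / den * exp(1i * field$phi_rf)
}

#' Ellipse parameters of a tissue under one MT weighting
#'
#' Converts the closed-form steady state to elliptical form.  `me` is the
#' geometric solution (real, includes the echo-time transverse decay), `a`
#' equals `exp(-TR/T2f)` and carries no MT weighting at all, and `b` is the
#' flattening, which shrinks with increasing saturation:
#' \deqn{M_E = \frac{M_{0f} E_{2f} (B(1-E_{1f})+C)\sin\alpha}
#'   {A - B E_{1f}\cos\alpha - E_{2f}^2(B E_{1f} - A\cos\alpha)}, \quad
#'   a = E_{2f}, \quad
#'   b = \frac{E_{2f}(A - B E_{1f})(\cos\alpha + 1)}
#'   {A - B E_{1f}\cos\alpha - E_{2f}^2(B E_{1f} - A\cos\alpha)}.}
#'
#' @param tissue a [tissue_params()].
#' @param setting a [sequence_setting()].
#' @param alpha_eff effective flip angle in radians (defaults to the nominal
#'   angle of the setting).
#' @param psi,phi_rf nuisance phases stored alongside the geometry (radians).
#' @return an [ellipse_params()] object.
#' @export
ellipse_from_tissue <- function(tissue, setting, alpha_eff = setting$alpha,
                                psi = 0, phi_rf = 0) {
  g <- ellipse_geometry(tissue, setting, alpha_eff)
  ellipse_params(me = g$me, a = g$a, b = g$b, psi = psi, phi_rf = phi_rf)
}

# Vectorized geometry (me, a, b) over alpha_eff; used by the phantom where
# a continuous B1+ field makes the effective flip angle voxel-dependent.
ellipse_geometry <- function(tissue, setting, alpha_eff) {
  terms <- two_pool_terms(tissue, setting, alpha_eff)
  ca <- cos(alpha_eff)
  den <- terms$A - terms$B * terms$e1f * ca -
    terms$e2f^2 * (terms$B * terms$e1f - terms$A * ca)
  me <- tissue$m0f * terms$e2f * (terms$B * (1 - terms$e1f) + terms$C) *
    sin(alpha_eff) / den
  b <- terms$e2f * (terms$A - terms$B * terms$e1f) * (ca + 1) / den
  list(me = me, a = rep_len(terms$e2f, length(me)), b = b)
}

#' Ellipse parameter container
#'
#' @param me geometric-solution magnitude, signal units (non-negative).
#' @param a ellipse size parameter in `(0, 1)`; equals `exp(-TR/T2f)` when
#'   generated from the forward model.
#' @param b ellipse flattening parameter in `[0, 1)`.
#' @param psi off-resonance phase per TR, radians.
#' @param phi_rf transmit RF phase, radians.
#' @return an object of class `ellipse_params`.  Construction checks the
#'   vertical-ellipse condition `b < 2a/(1 + a^2)` (equivalently, the
#'   ellipse does not contain the origin) and flags violations.
#' @export
ellipse_params <- function(me, a, b, psi = 0, phi_rf = 0) {
  if (any(me < 0)) stop_mtellipse("me must be non-negative", "invalid_ellipse")
  if (any(a <= 0) || any(a >= 1))
    stop_mtellipse("a must lie in (0, 1)", "invalid_ellipse")
  if (any(b < 0) || any(b >= 1))
    stop_mtellipse("b must lie in [0, 1)", "invalid_ellipse")
  if (any(b >= 2 * a / (1 + a^2)))
    stop_mtellipse("ellipse is not vertical: b >= 2a/(1+a^2)", "invalid_ellipse")
  structure(list(me = me, a = a, b = b, psi = psi, phi_rf = phi_rf),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(
    "<ellipse_params> M_E = %.4g, a = %.4f, b = %.4f, psi = %.3f rad, phi_rf = %.3f rad\n",
    x$me[1], x$a[1], x$b[1], x$psi[1], x$phi_rf[1]))
  invisible(x)
}

#' Complex SSFP signal of an ellipse at a given precession angle
#'
#' \deqn{M(\theta) = M_E \frac{1 - a e^{-i\theta}}{1 - b\cos\theta}
#'   e^{i(\psi/2 + \phi_{RF})}}
#' where \eqn{\theta = \psi + \phi_n} is the total phase advance per TR.
#' The `e^{-i\theta}` bracket is the handedness consistent with the
#' closed-form steady state and its `e^{+i\psi/2}` echo-time phase.
#'
#' @param ep an [ellipse_params()].
#' @param theta total precession angle(s) per TR, radians.
#' @return complex signal, vectorized over `theta`.
#' @export
ellipse_signal <- function(ep, theta) {
  den <- 1 - ep$b * cos(theta)
  if (any(abs(den) < .Machine$double.eps * 100))
    stop_mtellipse("degenerate ellipse denominator", "degenerate_signal")
  ep$me * (1 - ep$a * exp(-1i * theta)) / den *
    exp(1i * (ep$psi / 2 + ep$phi_rf))
}
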