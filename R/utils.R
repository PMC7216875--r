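#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi))
#' @export
wrap_angle <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Degree/radian conversion
#'
#' @param x numeric vector.
#' @return converted angles.
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

# Canonicalize the (psi, phi_rf) pair of an SSFP ellipse.
#
# The ellipse signal is invariant under psi -> psi + 2*pi*k combined with
# phi_rf -> phi_rf + pi*k (the e^{i psi/2} factor flips sign for odd k).
# Returns the representative with psi in (-pi, pi] and phi_rf in (-pi, pi]
# describing exactly the same signal.
canonical_phases <- function(psi, phi_rf) {
  psi_w <- wrap_angle(psi)
  k <- round((psi - psi_w) / (2 * pi))
  list(psi = psi_w, phi_rf = wrap_angle(phi_rf + pi * k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mtellipse <- function(msg, class) {
  stop(structure(class = c(class, "mtellipse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
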