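#' One SSFP acquisition setting (a single MT weighting)
#'
#' A setting is one combination of flip angle, TR and RF pulse duration,
#' acquired at a list of RF phase increments.  Varying the flip angle or the
#' pulse duration between settings changes the MT weighting: the bound-pool
#' saturation per pulse scales with flip angle squared and inversely with
#' pulse duration.
#'
#' @param alpha nominal flip angle in radians.
#' @param tr repetition time in ms.
#' @param trf RF pulse duration in ms (must satisfy `0 < trf < tr`).
#' @param p1 ratio of the pulse's mean B1 to its maximum B1 (1 = block pulse).
#' @param p2 ratio of the pulse's mean B1 squared to its maximum B1 squared.
#' @param phase_increments RF phase increments in radians; default six
#'   increments at multiples of 60 degrees.
#' @return an object of class `sequence_setting`.  The echo time is fixed at
#'   `TE = TR/2`.
#' @examples
#' sequence_setting(deg2rad(15), tr = 7, trf = 0.256)
#' @export
sequence_setting <- function(alpha, tr, trf, p1 = 1, p2 = 1,
                             phase_increments = (1:6) * pi / 3) {
  if (!is.numeric(tr) || tr <= 0 || !is.numeric(trf) || trf <= 0 || trf >= tr)
    stop_mtellipse("invalid protocol: need TR > TRF > 0", "invalid_protocol")
  if (p1 <= 0 || p1 > 1 || p2 <= 0 || p2 > 1)
    stop_mtellipse("pulse shape factors must lie in (0, 1]", "invalid_protocol")
  if (length(phase_increments) < 1)
    stop_mtellipse("at least one phase increment required", "invalid_protocol")
  structure(list(alpha = alpha, tr = tr, trf = trf, p1 = p1, p2 = p2,
                 phase_increments = as.numeric(phase_increments),
                 te = tr / 2),
            class = "sequence_setting")
}

#' @export
print.sequence_setting <- function(x, ...) {
  cat(sprintf(
    "<sequence_setting> alpha = %.1f deg, TR = %.3f ms, TRF = %.0f us, p1 = %.2f, p2 = %.2f, %d phase increments\n",
    rad2deg(x$alpha), x$tr, x$trf * 1000, x$p1, x$p2,
    length(x$phase_increments)))
  invisible(x)
}

#' Acquisition protocol: a set of MT-weighted SSFP settings
#'
#' @param settings a list of [sequence_setting()] objects.
#' @param g0 on-resonance value of the bound-pool absorption lineshape in
#'   microseconds (Super-Lorentzian extrapolated from 1 kHz to resonance).
#' @return an object of class `mt_protocol`.
#' @export
mt_protocol <- function(settings, g0 = 14) {
  if (!length(settings) || !all(vapply(settings, inherits, TRUE, "sequence_setting")))
    stop_mtellipse("settings must be a list of sequence_setting objects",
                   "invalid_protocol")
  structure(list(settings = settings, g0 = g0), class = "mt_protocol")
}

#' @export
print.mt_protocol <- function(x, ...) {
  cat(sprintf("<mt_protocol> %d settings, G0 = %g us\n", length(x$settings), x$g0))
  for (s in x$settings) print(s)
  invisible(x)
}

#' Default four-weighting 3T protocol
#'
#' Four MT weightings crossing two flip angles (15 and 30 degrees) with two
#' RF pulse durations (256 and 1024 us); the longer pulse forces a slightly
#' longer TR (7.768 vs 7 ms).  Six phase increments at multiples of 60
#' degrees per setting.  Block pulses (`p1 = p2 = 1`) are assumed.
#'
#' @param g0 lineshape value at resonance in microseconds.
#' @return an `mt_protocol` with four settings.
#' @examples
#' default_protocol()
#' @export
default_protocol <- function(g0 = 14) {
  alpha <- deg2rad(c(15, 15, 30, 30))
  trf <- c(256, 1024, 256, 1024) / 1000
  tr <- c(7, 7.768, 7, 7.768)
  mt_protocol(lapply(1:4, function(i)
    sequence_setting(alpha[i], tr[i], trf[i])), g0 = g0)
}

#' Read or write a protocol as JSON
#'
#' The JSON layout uses acquisition-console units: flip angles and phase
#' increments in degrees, TR in ms, RF pulse duration in microseconds, and
#' the lineshape value `g0_us` in microseconds.
#'
#' @param path file path.
#' @return `read_protocol()` returns an `mt_protocol`;
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$settings))
    stop_mtellipse("protocol JSON must contain a 'settings' array",
                   "invalid_protocol")
  sl <- doc$settings
  if (is.data.frame(sl)) sl <- split(sl, seq_len(nrow(sl)))
  settings <- lapply(sl, function(s) {
    s <- as.list(s)
    sequence_setting(
      alpha = deg2rad(s$flip_angle_deg),
      tr = s$tr_ms,
      trf = s$trf_us / 1000,
      p1 = s$p1 %||% 1, p2 = s$p2 %||% 1,
      phase_increments = deg2rad(unlist(s$phase_increments_deg)))
  })
  mt_protocol(unname(settings), g0 = doc$g0_us %||% 14)
}

#' @param protocol an `mt_protocol` object.
#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  doc <- list(
    settings = lapply(protocol$settings, function(s) list(
      flip_angle_deg = rad2deg(s$alpha), tr_ms = s$tr,
      trf_us = s$trf * 1000, p1 = s$p1, p2 = s$p2,
      phase_increments_deg = rad2deg(s$phase_increments))),
    g0_us = protocol$g0)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
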