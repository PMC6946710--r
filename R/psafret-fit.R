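#' Convert an anisotropy change to a drFRET efficiency
#'
#' Converts the anisotropies measured with all fluorophores on (`r_et1`,
#' under homo-FRET) and extrapolated to complete photoswitching (`r_et0`, no
#' energy transfer) into the drFRET efficiency,
#' \deqn{drFRET = \frac{6 (r_{et0} - r_{et1})}
#'                     {1 + 8 r_{et0} - 4 r_{et1} + 4 r_{et0} r_{et1}}}
#' the fractional gain of perpendicular-channel signal caused by energy
#' transfer. Unlike the raw anisotropy change, drFRET is comparable across
#' optical configurations (objective NA, g-factor).
#'
#' @param r_et0 Anisotropy in the absence of energy transfer, in
#'   `[-0.2, 0.4]`.
#' @param r_et1 Anisotropy during energy transfer.
#' @return drFRET (vectorized); 0 when `r_et1 == r_et0`, negative (with a
#'   warning) when `r_et1 > r_et0`.
#' @examples
#' drfret(0.30, 0.25)  # ~0.111
#' @export
drfret <- function(r_et0, r_et1) {
  if (any(r_et0 < -0.2 | r_et0 > 0.4))
    stop("`r_et0` outside the isotropic-population range [-0.2, 0.4]",
         call. = FALSE)
  denom <- 1 + 8 * r_et0 - 4 * r_et1 + 4 * r_et0 * r_et1
  if (any(denom <= 0))
    stop("drFRET undefined: non-positive denominator for (r_et0, r_et1) = (",
         paste(r_et0[denom <= 0], r_et1[denom <= 0], sep = ", ",
               collapse = "; "), ")", call. = FALSE)
  out <- 6 * (r_et0 - r_et1) / denom
  if (any(out < 0))
    warning("negative drFRET (r_et1 > r_et0); reported as-is")
  out
}

#' Anisotropy trace derived from a channel trace
#'
#' Applies background subtraction, the g-factor and (optionally) the high-NA
#' unmixing to a [channel_trace()], yielding per-frame anisotropy `r`, total
#' fluorescence `f_tot`, the fraction photoswitched `fraction_switched` and
#' the fit abscissa `x = 1 - F(t)` (the surviving signal fraction).
#'
#' @param trace A [channel_trace()].
#' @param optics An [optics_config()]; `apply_axelrod` selects corrected
#'   anisotropies.
#' @return A data frame with columns `frame`, `i_par`, `gi_perp`, `f_tot`,
#'   `r`, `fraction_switched`, `x`, and attribute `corrected`.
#' @export
anisotropy_trace <- function(trace, optics = optics_config()) {
  tr <- as_channel_trace(trace)
  stopifnot(inherits(optics, "optics_config"))
  i_par <- tr$mean_par - tr$bg_par
  i_perp <- tr$mean_perp - tr$bg_perp
  if (any(i_par < 0) || any(i_perp < 0))
    warning("negative background-subtracted intensities in ",
            sum(i_par < 0 | i_perp < 0), " frame(s); preserved, not clipped")
  gi_perp <- optics$g_factor * i_perp
  f_tot <- total_fluorescence(i_par, i_perp, optics$g_factor)
  r <- if (optics$apply_axelrod) {
    axelrod_unmix(i_par, gi_perp, optics$theta)$r
  } else {
    anisotropy(i_par, i_perp, optics$g_factor)
  }
  fs <- fraction_switched(f_tot)
  out <- data.frame(frame = tr$frame, i_par = i_par, gi_perp = gi_perp,
                    f_tot = f_tot, r = r, fraction_switched = fs, x = 1 - fs)
  attr(out, "corrected") <- optics$apply_axelrod
  out
}

# ordinary least squares with the regression error statistics used for the
# slope of the anisotropy-vs-x line: residual standard error
# s = sqrt(SSE / (n - 2)), SS_xx = sum(x^2) - (sum x)^2 / n, and the slope
# standard error s_beta1 = s / sqrt(SS_xx)
ols_line <- function(x, y) {
  n <- length(x)
  ss_xx <- sum(x^2) - sum(x)^2 / n
  if (ss_xx <= 0)
    stop("degenerate abscissa: no spread in the fraction photoswitched",
         call. = FALSE)
  b <- (sum(x * y) - sum(x) * sum(y) / n) / ss_xx
  a <- mean(y) - b * mean(x)
  resid <- y - (a + b * x)
  s <- sqrt(sum(resid^2) / (n - 2))
  structure(list(a = a, b = b, s = s, s_beta1 = s / sqrt(ss_xx),
                 ss_xx = ss_xx, n_used = n),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> r = %.5f %+.5f x  (n=%d, s=%.2g, s_beta1=%.2g)\n",
    x$a, x$b, x$n_used, x$s, x$s_beta1))
  invisible(x)
}

#' Fit the anisotropy-vs-fraction-photoswitched line
#'
#' Ordinary least squares of anisotropy `r` on `x = 1 - F(t)` over the
#' frames retained for fitting. Frames beyond the photoswitching `cutoff`
#' are excluded because the anisotropy becomes very noisy once most of the
#' fluorophore is off; frames whose total fluorescence has fallen below
#' `low_signal_frac` of the initial value are excluded for the same reason.
#'
#' @param aniso An anisotropy trace from [anisotropy_trace()] (any data
#'   frame with columns `r`, `x`, `fraction_switched`, `f_tot`).
#' @param cutoff Largest fraction photoswitched retained in the fit
#'   (default 0.8).
#' @param low_signal_frac Frames with `f_tot` below this fraction of the
#'   initial total fluorescence are dropped (default 0.05).
#' @return A `linear_fit`: intercept `a`, slope `b`, residual standard error
#'   `s`, slope standard error `s_beta1`, `ss_xx`, `n_used`.
#' @export
fit_anisotropy_line <- function(aniso, cutoff = 0.8, low_signal_frac = 0.05) {
  stopifnot(all(c("r", "x", "fraction_switched", "f_tot") %in% names(aniso)))
  keep <- aniso$fraction_switched <= cutoff &
    aniso$f_tot >= low_signal_frac * aniso$f_tot[1L]
  n_dropped <- sum(!keep)
  if (sum(keep) < 3L)
    stop("insufficient data: fewer than 3 frames at or below the cutoff",
         call. = FALSE)
  fit <- ols_line(aniso$x[keep], aniso$r[keep])
  fit$n_dropped <- n_dropped
  fit
}

#' Extrapolate the fitted line to the FRET and no-FRET anisotropies
#'
#' On the `x = 1 - F(t)` axis, `x = 1` is the unswitched start of the
#' experiment (all fluorophores on, full homo-FRET) and `x = 0` is complete
#' photoswitching (no acceptors left, no energy transfer). The fitted line
#' therefore gives `r_et1 = a + b` and `r_et0 = a`, and the homo-FRET
#' anisotropy change is `delta_r = r_et0 - r_et1 = -b`.
#'
#' @param fit A `linear_fit` from [fit_anisotropy_line()].
#' @return A list with `r_et1`, `r_et0`, `delta_r`.
#' @export
extrapolate <- function(fit) {
  stopifnot(inherits(fit, "linear_fit"))
  list(r_et1 = fit$a + fit$b, r_et0 = fit$a, delta_r = -fit$b)
}

#' Run the full psAFRET analysis on one channel trace
#'
#' The complete estimator: background subtraction and g-factor, optional
#' high-NA correction, total fluorescence and fraction photoswitched, linear
#' fit of anisotropy against the surviving signal fraction, extrapolation to
#' `r_et1` / `r_et0`, and conversion of the anisotropy change to drFRET.
#'
#' @inheritParams anisotropy_trace
#' @inheritParams fit_anisotropy_line
#' @return An object of class `psafret_result`: `r_et1`, `r_et0`, `delta_r`,
#'   `drfret`, `cutoff_used`, `corrected`, the `fit` (a `linear_fit`), the
#'   per-frame `aniso` table (all frames, with a `used` flag), and `optics`.
#' @examples
#' sim <- simulate_trace(oligomer_model(2, coupling = 1), seed = 7)
#' analyze_trace(sim$trace)
#' @export
analyze_trace <- function(trace, optics = optics_config(), cutoff = 0.8,
                          low_signal_frac = 0.05) {
  aniso <- anisotropy_trace(trace, optics)
  fit <- fit_anisotropy_line(aniso, cutoff, low_signal_frac)
  ex <- extrapolate(fit)
  aniso$used <- aniso$fraction_switched <= cutoff &
    aniso$f_tot >= low_signal_frac * aniso$f_tot[1L]
  structure(list(r_et1 = ex$r_et1, r_et0 = ex$r_et0, delta_r = ex$delta_r,
                 drfret = drfret(ex$r_et0, ex$r_et1), cutoff_used = cutoff,
                 corrected = isTRUE(attr(aniso, "corrected")), fit = fit,
                 aniso = aniso, optics = optics),
            class = "psafret_result")
}

#' @export
print.psafret_result <- function(x, ...) {
  cat("psAFRET result", if (x$corrected) "(high-NA corrected)" else
      "(uncorrected)", "\n")
  cat(sprintf("  r_et1   = %.4f   (anisotropy under homo-FRET)\n", x$r_et1))
  cat(sprintf("  r_et0   = %.4f   (anisotropy, no energy transfer)\n",
              x$r_et0))
  cat(sprintf("  delta r = %.4f\n", x$delta_r))
  cat(sprintf("  drFRET  = %.4f\n", x$drfret))
  cat(sprintf("  fit: n=%d frames (cutoff %.2f), slope SE %.2g\n",
              x$fit$n_used, x$cutoff_used, x$fit$s_beta1))
  invisible(x)
}

#' Flatten a psAFRET result to a one-row data frame
#'
#' @param x A `psafret_result`.
#' @param label Optional ROI/cell label.
#' @param ... Unused.
#' @return A one-row data frame suitable for `rbind`-ing across ROIs and for
#'   the group-statistics functions.
#' @export
as.data.frame.psafret_result <- function(x, label = NA_character_, ...) {
  data.frame(label = label, r_et1 = x$r_et1, r_et0 = x$r_et0,
             delta_r = x$delta_r, drfret = x$drfret, slope = x$fit$b,
             intercept = x$fit$a, s = x$fit$s, s_beta1 = x$fit$s_beta1,
             ss_xx = x$fit$ss_xx, n_used = x$fit$n_used,
             cutoff = x$cutoff_used, corrected = x$corrected,
             na = x$optics$na, refractive_index = x$optics$refractive_index,
             g_factor = x$optics$g_factor)
}
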