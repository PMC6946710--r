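#' Optical configuration for polarization anisotropy imaging
#'
#' Bundles the properties of the detection path that enter the anisotropy
#' calculation: the objective numerical aperture and immersion refractive
#' index (which set the collection half-angle), the instrument g-factor, and
#' whether the high-NA polarization-mixing correction should be applied.
#'
#' @param na Numerical aperture of the objective lens.
#' @param refractive_index Refractive index of the immersion medium;
#'   must satisfy `0 < na <= refractive_index`.
#' @param g_factor Instrument polarization bias correction factor (ratio of
#'   parallel to perpendicular detection efficiency, calibrated on an
#'   isotropic dye solution); must be positive.
#' @param apply_axelrod Logical; if `TRUE`, anisotropies are computed after
#'   linear unmixing of the polarization scrambling caused by wide collection
#'   angles (see [axelrod_unmix()]).
#'
#' @return An object of class `optics_config`: a list with fields `na`,
#'   `refractive_index`, `g_factor`, `apply_axelrod` and the derived
#'   collection half-angle `theta` in degrees.
#' @examples
#' optics_config(na = 1.4, refractive_index = 1.515)
#' @export
optics_config <- function(na = 1.4, refractive_index = 1.515, g_factor = 1,
                          apply_axelrod = FALSE) {
  stopifnot(is.numeric(na), length(na) == 1L, is.numeric(refractive_index),
            length(refractive_index) == 1L, is.numeric(g_factor),
            length(g_factor) == 1L, is.logical(apply_axelrod))
  if (g_factor <= 0) stop("`g_factor` must be positive", call. = FALSE)
  theta <- collection_angle(na, refractive_index)
  structure(list(na = na, refractive_index = refractive_index,
                 g_factor = g_factor,
                 apply_axelrod = isTRUE(apply_axelrod), theta = theta),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf("<optics_config> NA=%.3g n=%.4g theta=%.2f deg g=%.4g %s\n",
              x$na, x$refractive_index, x$theta, x$g_factor,
              if (x$apply_axelrod) "[high-NA correction on]"
              else "[uncorrected]"))
  invisible(x)
}

#' Collection half-angle of an objective lens
#'
#' The half-angle of the collection cone, from `NA = n * sin(theta)`.
#'
#' @param na Numerical aperture.
#' @param refractive_index Immersion refractive index `n`.
#' @return Half-angle `theta` in degrees, in `(0, 90]`.
#' @examples
#' collection_angle(1.4, 1.515)  # ~67.5 degrees
#' @export
collection_angle <- function(na, refractive_index) {
  if (any(na <= 0) || any(na > refractive_index))
    stop("need 0 < na <= refractive_index", call. = FALSE)
  asin(na / refractive_index) * 180 / pi
}

#' Polarization mixing coefficients for a wide collection cone
#'
#' Weighting factors describing how the three orthogonal emission dipole
#' intensity components (I_x, I_y, I_z) mix into the parallel and
#' perpendicular detection channels when emission is collected over a cone
#' of half-angle `theta` (high-NA objective). All three vanish as the cone
#' closes (theta -> 0) and grow monotonically with theta.
#'
#' @param theta Collection half-angle in degrees, in `[0, 90]`.
#' @return A list with numeric fields `k_a`, `k_b`, `k_c` (each the same
#'   length as `theta`).
#' @examples
#' k_factors(67.5)
#' @export
k_factors <- function(theta) {
  if (any(theta < 0 | theta > 90))
    stop("`theta` must lie in [0, 90] degrees", call. = FALSE)
  ct <- cos(theta * pi / 180)
  list(k_a = (2 - 3 * ct + ct^3) / 3,
       k_b = (1 - 3 * ct + 3 * ct^2 - ct^3) / 12,
       k_c = (5 - 3 * ct - ct^2 - ct^3) / 4)
}

#' Fluorescence anisotropy from polarized channel intensities
#'
#' `r = (I_par - g * I_perp) / (I_par + 2 * g * I_perp)`. For an isotropic
#' population excited with polarized light, r is bounded by the
#' photoselection limits \[-0.2, 0.4\].
#'
#' @param i_par Parallel channel intensity (background subtracted).
#' @param i_perp Perpendicular channel intensity (background subtracted).
#' @param g Instrument g-factor (default 1).
#' @return Anisotropy r (vectorized).
#' @examples
#' anisotropy(3, 1)   #  0.4, the parallel photoselection limit
#' anisotropy(1, 2)   # -0.2, the perpendicular limit
#' @export
anisotropy <- function(i_par, i_perp, g = 1) {
  denom <- i_par + 2 * g * i_perp
  if (any(denom == 0))
    stop("anisotropy undefined: I_par + 2 g I_perp is zero", call. = FALSE)
  (i_par - g * i_perp) / denom
}

#' Total fluorescence from polarized channel intensities
#'
#' `F_tot = I_par + 2 * g * I_perp`, the orientation-independent total
#' emission intensity.
#'
#' @inheritParams anisotropy
#' @return Total fluorescence (vectorized).
#' @export
total_fluorescence <- function(i_par, i_perp, g = 1) {
  i_par + 2 * g * i_perp
}

#' Fraction of fluorophore photoswitched (or photobleached)
#'
#' `F(t) = (I(t0) - I(t)) / I(t0)` computed from the total fluorescence
#' trace; 0 at the first frame and approaching 1 as the population switches
#' off. Noise can push individual values slightly negative; these are
#' preserved, not clipped.
#'
#' @param f_tot Numeric vector of per-frame total fluorescence, first element
#'   taken as the pre-switching intensity `I(t0)`.
#' @return Numeric vector of per-frame switched fractions.
#' @export
fraction_switched <- function(f_tot) {
  if (length(f_tot) < 1L || !is.finite(f_tot[1L]) || f_tot[1L] <= 0)
    stop("initial total fluorescence must be positive", call. = FALSE)
  (f_tot[1L] - f_tot) / f_tot[1L]
}

#' Calibrate the instrument g-factor from an isotropic reference
#'
#' The g-factor corrects for unequal transmission/detection of the two
#' polarization channels. It is calibrated by imaging a solution of a small,
#' fast-rotating dye (e.g. fluorescein isothiocyanate), whose rotational
#' depolarization makes the true anisotropy zero, so the ratio of
#' background-subtracted channel means gives g directly:
#' `g = mean(I_par - bg_par) / mean(I_perp - bg_perp)`.
#'
#' @param reference_trace A [channel_trace()] recorded on the isotropic
#'   reference solution.
#' @return A list with `g` (the calibrated factor), `se` (standard error of
#'   the per-frame ratio estimates) and `n_frames`.
#' @export
estimate_g <- function(reference_trace) {
  tr <- as_channel_trace(reference_trace)
  np <- tr$mean_par - tr$bg_par
  ns <- tr$mean_perp - tr$bg_perp
  if (mean(np) <= 0 || mean(ns) <= 0)
    stop("calibration error: non-positive background-subtracted reference ",
         "intensities", call. = FALSE)
  g <- mean(np) / mean(ns)
  ratios <- np / ns
  se <- if (length(ratios) > 1L) stats::sd(ratios) / sqrt(length(ratios))
        else NA_real_
  list(g = g, se = se, n_frames = nrow(tr))
}

#' Recover dipole-frame intensities from high-NA mixed channels
#'
#' With a wide collection cone the measured channels are linear mixtures of
#' the emission dipole intensity components: `I_par = Kc Iz + Kb Iy + Ka Ix`
#' and `g I_perp = Kb Iz + Kc Iy + Ka Ix`. Assuming randomly oriented
#' fluorophores (`Ix = Iy`), the 2x2 system inverts to
#' \deqn{Iy = (I_par Kb - g I_perp Kc) / D}
#' \deqn{Iz = (g I_perp (Kb + Ka) - I_par (Kc + Ka)) / D}
#' with `D = Kb^2 + Ka Kb - Kc^2 - Ka Kc`, and the corrected anisotropy is
#' `r = (Iz - Iy) / (Iz + 2 Iy)`.
#'
#' @param i_par Measured parallel intensity.
#' @param gi_perp Measured perpendicular intensity already scaled by the
#'   g-factor (i.e. `g * I_perp`).
#' @param theta Collection half-angle in degrees, strictly in `(0, 90]`.
#' @return A list with vectors `i_z`, `i_y` and the corrected anisotropy `r`.
#' @examples
#' ch <- project_to_channels(1 / 3, 9, optics_config(1.4, 1.515,
#'                                                   apply_axelrod = TRUE))
#' axelrod_unmix(ch$i_par, ch$gi_perp, collection_angle(1.4, 1.515))
#' @export
axelrod_unmix <- function(i_par, gi_perp, theta) {
  if (theta <= 0 || theta > 90)
    stop("`theta` must lie in (0, 90] degrees", call. = FALSE)
  k <- k_factors(theta)
  d <- k$k_b^2 + k$k_a * k$k_b - k$k_c^2 - k$k_a * k$k_c
  if (abs(d) < 1e-9 * max(k$k_c^2, 1))
    stop("ill-conditioned correction at theta = ", format(theta),
         " degrees; use the uncorrected anisotropy instead", call. = FALSE)
  i_y <- (i_par * k$k_b - gi_perp * k$k_c) / d
  i_z <- (gi_perp * k$k_b + gi_perp * k$k_a - i_par * k$k_c - i_par * k$k_a) / d
  list(i_z = i_z, i_y = i_y, r = (i_z - i_y) / (i_z + 2 * i_y))
}

#' Fit a single exponential with offset to a fluorescence decay
#'
#' Fits `y = a * exp(-b * t) + c` by nonlinear least squares, the standard
#' model for the total-fluorescence decay during a photoswitching cycle
#' (geometric off-switching gives `b = -log(1 - p_off)` per frame).
#'
#' @param time Numeric vector of time points (frames).
#' @param y Numeric vector of fluorescence values, same length as `time`.
#' @param normalize Logical; if `TRUE` (default) `y` is divided by its first
#'   value before fitting, so `a + c ~ 1` at the start of the cycle.
#' @return A list with estimates `a`, `b`, `c`, the `fitted` values (on the
#'   possibly normalized scale), `normalized`, and `degenerate` (`TRUE` when
#'   the data carry no detectable decay and the exponential is unidentified).
#' @export
fit_exponential <- function(time, y, normalize = TRUE) {
  stopifnot(length(time) == length(y))
  if (length(y) < 4L)
    stop("need at least 4 points to fit an exponential with offset",
         call. = FALSE)
  scale <- if (normalize) y[1L] else 1
  if (normalize && (!is.finite(scale) || scale <= 0))
    stop("cannot normalize: first value is not positive", call. = FALSE)
  yn <- y / scale
  rng <- diff(range(yn))
  if (rng < 1e-12 * max(abs(yn), 1)) {
    return(list(a = 0, b = 0, c = mean(yn), fitted = rep(mean(yn), length(yn)),
                normalized = normalize, degenerate = TRUE))
  }
  # log-linear start for the rate, floor offset start at the tail value
  c0 <- min(yn) - 1e-6 * rng
  pos <- yn - c0 > 0
  b0 <- tryCatch({
    cf <- stats::coef(stats::lm(log(yn[pos] - c0) ~ time[pos]))
    max(-cf[[2L]], 1e-6)
  }, error = function(e) 0.1)
  fit <- minpack.lm::nlsLM(yn ~ a * exp(-b * time) + c,
                           start = list(a = yn[1L] - c0, b = b0, c = c0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
       fitted = stats::fitted(fit), normalized = normalize,
       degenerate = abs(unname(cf["b"])) < 1e-10)
}
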