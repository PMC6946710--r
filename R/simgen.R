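#' Oligomer homo-FRET model
#'
#' Parameterizes the steady-state anisotropy of a cluster of `n_subunits`
#' identical fluorophores that exchange excitation energy by homo-FRET.
#' Emission from the directly excited fluorophore carries the monomer
#' anisotropy `r_mono`; emission sensitized through energy transfer carries
#' `r_et` (near zero for immobile fluorophores with uncorrelated dipole
#' orientations). The pairwise `coupling` is the product of the
#' transfer rate and the fluorescence lifetime, which scales with separation
#' as `(d / R0)^-6`.
#'
#' @param n_subunits Integer number of fluorophores in the complex (>= 1).
#' @param r_mono Anisotropy of an isolated on-state fluorophore, in
#'   `(-0.2, 0.4]`.
#' @param r_et Anisotropy of FRET-sensitized emission, in `[-0.2, 0.4]`.
#' @param coupling Dimensionless pairwise transfer-rate x lifetime product
#'   (>= 0). Ignored if `d_over_r0` is supplied.
#' @param d_over_r0 Optional separation in units of the Foerster radius;
#'   sets `coupling = d_over_r0^-6`.
#' @return An object of class `oligomer_model`.
#' @examples
#' oligomer_model(2, coupling = 1)          # strongly coupled dimer
#' oligomer_model(4, d_over_r0 = 0.8)       # tight tetramer
#' @export
oligomer_model <- function(n_subunits = 2L, r_mono = 0.35, r_et = 0,
                           coupling = 1, d_over_r0 = NULL) {
  n_subunits <- as.integer(n_subunits)
  stopifnot(length(n_subunits) == 1L, n_subunits >= 1L)
  if (r_mono <= -0.2 || r_mono > 0.4)
    stop("`r_mono` must lie in (-0.2, 0.4]", call. = FALSE)
  if (r_et < -0.2 || r_et > 0.4)
    stop("`r_et` must lie in [-0.2, 0.4]", call. = FALSE)
  if (!is.null(d_over_r0)) {
    stopifnot(d_over_r0 > 0)
    coupling <- d_over_r0^-6
  }
  if (coupling < 0) stop("`coupling` must be >= 0", call. = FALSE)
  structure(list(n_subunits = n_subunits, r_mono = r_mono, r_et = r_et,
                 coupling = coupling, d_over_r0 = d_over_r0),
            class = "oligomer_model")
}

#' Steady-state anisotropy of a cluster with k fluorophores on
#'
#' For a cluster in which `k_on` of the subunits are in the on state and all
#' on-pairs share the same transfer coupling, the excitation equilibrates
#' over the cluster and the emission anisotropy is
#' \deqn{r(k) = r_{mono} (1 + \omega\tau) / (1 + k \omega\tau) +
#'       r_{et} (k - 1) \omega\tau / (1 + k \omega\tau)}
#' i.e. a weighted mixture of directly excited and sensitized emission. With
#' one fluorophore on, or zero coupling, this reduces to `r_mono`.
#'
#' @param k_on Number of on-state fluorophores, `1 <= k_on <= n_subunits`.
#' @param model An [oligomer_model()].
#' @return Steady-state anisotropy (vectorized over `k_on`).
#' @export
cluster_anisotropy <- function(k_on, model) {
  stopifnot(inherits(model, "oligomer_model"))
  if (any(k_on < 1L) || any(k_on > model$n_subunits))
    stop("`k_on` must lie in [1, n_subunits]", call. = FALSE)
  wt <- model$coupling
  (model$r_mono * (1 + wt) + model$r_et * (k_on - 1) * wt) / (1 + k_on * wt)
}

#' Ensemble anisotropy of partially switched oligomers
#'
#' At on-fraction `p_on`, the number of on-state partners of an emitting
#' fluorophore is binomial over the remaining `N - 1` subunits, so the
#' intensity-weighted ensemble anisotropy is
#' \deqn{r(p) = \sum_{j=0}^{N-1} \binom{N-1}{j} p^j (1-p)^{N-1-j}
#'       \; r_{cluster}(j + 1)}
#' (equal quantum yields assumed). For a dimer this is exactly affine in
#' `p_on`; for larger N with tight coupling (`d/R0 <= ~0.8`) the curve bows
#' upward relative to its chord.
#'
#' @param p_on On-state fraction in `[0, 1]` (vectorized).
#' @param model An [oligomer_model()].
#' @return Ensemble anisotropy at each `p_on`.
#' @export
ensemble_anisotropy <- function(p_on, model) {
  stopifnot(inherits(model, "oligomer_model"))
  if (any(p_on < 0 | p_on > 1))
    stop("`p_on` must lie in [0, 1]", call. = FALSE)
  n <- model$n_subunits
  j <- 0:(n - 1L)
  rk <- cluster_anisotropy(j + 1L, model)
  vapply(p_on, function(p) {
    sum(stats::dbinom(j, size = n - 1L, prob = p) * rk)
  }, numeric(1))
}

#' Project anisotropy and total intensity onto detection channels
#'
#' Decomposes `(r, F_tot)` into the dipole-frame intensity components
#' `Iz = F_tot (1 + 2r) / 3` and `Iy = Ix = F_tot (1 - r) / 3`, then mixes
#' them into the measured channels with the collection-cone weighting
#' factors: `I_par = Kc Iz + Kb Iy + Ka Ix`, `g I_perp = Kb Iz + Kc Iy +
#' Ka Ix`. When `optics$apply_axelrod` is `FALSE` the ideal narrow-cone
#' channels `(Iz, Iy)` are returned unchanged.
#'
#' @param r Anisotropy of the emitting population.
#' @param f_total Total fluorescence intensity (>= 0).
#' @param optics An [optics_config()]; `apply_axelrod` selects whether
#'   polarization mixing is simulated.
#' @return A list with `i_par` and `gi_perp` (the g-scaled perpendicular
#'   channel, i.e. the quantity entering the anisotropy formula).
#' @export
project_to_channels <- function(r, f_total, optics) {
  stopifnot(inherits(optics, "optics_config"))
  if (any(f_total < 0)) stop("`f_total` must be >= 0", call. = FALSE)
  i_z <- f_total * (1 + 2 * r) / 3
  i_y <- f_total * (1 - r) / 3
  if (!optics$apply_axelrod)
    return(list(i_par = i_z, gi_perp = i_y))
  if (optics$theta <= 0)
    stop("degenerate optics: theta = 0 with mixing enabled", call. = FALSE)
  k <- k_factors(optics$theta)
  list(i_par = k$k_c * i_z + k$k_b * i_y + k$k_a * i_y,
       gi_perp = k$k_b * i_z + k$k_c * i_y + k$k_a * i_y)
}

#' Photoswitching kinetics parameters
#'
#' @param p_off_per_frame Probability in `[0, 1]` that an on-state
#'   fluorophore switches off during one frame (geometric decay; independent
#'   of illumination history).
#' @param n_frames Number of frames recorded (>= 2).
#' @return An object of class `switching_params`.
#' @export
switching_params <- function(p_off_per_frame = 0.08, n_frames = 50L) {
  stopifnot(p_off_per_frame >= 0, p_off_per_frame <= 1, n_frames >= 2L)
  structure(list(p_off_per_frame = p_off_per_frame,
                 n_frames = as.integer(n_frames)),
            class = "switching_params")
}

#' Camera noise model
#'
#' Shot noise is Poisson on detected photons; the camera adds Gaussian read
#' noise and a constant baseline offset. Defaults approximate a modern sCMOS
#' detector recording a moderately bright fluorescent-protein signal.
#'
#' @param photons_per_fluor Expected detected photons per on-state
#'   fluorophore per frame.
#' @param read_noise_sd Gaussian read-noise standard deviation, in counts.
#' @param offset Camera baseline, in counts.
#' @param gain Counts per detected photon.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(photons_per_fluor = 100, read_noise_sd = 1.5,
                         offset = 100, gain = 1) {
  stopifnot(photons_per_fluor >= 0, read_noise_sd >= 0, offset >= 0,
            gain >= 0)
  structure(list(photons_per_fluor = photons_per_fluor,
                 read_noise_sd = read_noise_sd, offset = offset, gain = gain),
            class = "camera_model")
}

#' Ground truth of a simulated photoswitching experiment
#'
#' @keywords internal
ground_truth <- function(model, p_trajectory) {
  r_et1 <- ensemble_anisotropy(1, model)
  r_et0 <- model$r_mono
  list(r_et1_true = r_et1, r_et0_true = r_et0,
       drfret_true = drfret(r_et0, r_et1), p_trajectory = p_trajectory)
}

# Simulate per-frame on-state counts and exact channel expectations for a
# population of identical oligomers. Returns photon-level (noise-free)
# channel intensities plus the realized on counts per frame.
simulate_population <- function(model, switching, camera, optics,
                                n_oligomers) {
  n <- model$n_subunits
  nf <- switching$n_frames
  state <- matrix(TRUE, nrow = n_oligomers, ncol = n)
  i_par <- numeric(nf)
  gi_perp <- numeric(nf)
  n_on <- integer(nf)
  j <- 0:(n - 1L)
  rk <- cluster_anisotropy(j + 1L, model)
  for (t in seq_len(nf)) {
    k <- rowSums(state)
    n_on[t] <- sum(k)
    if (n_on[t] > 0L) {
      tab <- tabulate(k, nbins = n)
      # intensity-weighted mixture over realized cluster compositions
      r_t <- sum(tab * seq_len(n) * rk) / n_on[t]
    } else r_t <- model$r_mono
    f_t <- n_on[t] * camera$photons_per_fluor
    ch <- project_to_channels(r_t, f_t, optics)
    i_par[t] <- ch$i_par
    gi_perp[t] <- ch$gi_perp
    if (t < nf && switching$p_off_per_frame > 0) {
      on_idx <- which(state)
      flip <- stats::runif(length(on_idx)) < switching$p_off_per_frame
      state[on_idx[flip]] <- FALSE
    }
  }
  list(i_par = i_par, gi_perp = gi_perp, n_on = n_on,
       p_on = n_on / (n_oligomers * n))
}

#' Simulate a photoswitching anisotropy trace
#'
#' Simulates a population of identical oligomers under polarized illumination
#' being driven to the off state: per frame, on-state fluorophores switch off
#' independently with probability `p_off_per_frame`; the exact ensemble
#' anisotropy and brightness of the realized population are projected onto
#' the detection channels (with optional high-NA polarization mixing and the
#' instrument g-factor); Poisson shot noise, Gaussian read noise and the
#' camera offset are then added.
#'
#' @param model An [oligomer_model()].
#' @param switching A [switching_params()].
#' @param camera A [camera_model()].
#' @param optics An [optics_config()]; its `apply_axelrod` flag controls
#'   whether polarization mixing is simulated, and its `g_factor` is the
#'   polarization bias baked into the recorded perpendicular channel.
#' @param n_oligomers Number of oligomers in the population.
#' @param seed Integer seed; the same seed reproduces the trace exactly.
#' @return A list with `trace` (a [channel_trace()]) and `truth` (the ground
#'   truth: `r_et1_true`, `r_et0_true`, `drfret_true`, `p_trajectory`).
#' @examples
#' sim <- simulate_trace(oligomer_model(2, coupling = 1), seed = 1)
#' sim$truth$drfret_true
#' @export
simulate_trace <- function(model = oligomer_model(),
                           switching = switching_params(),
                           camera = camera_model(),
                           optics = optics_config(apply_axelrod = FALSE),
                           n_oligomers = 10000L, seed = 1L) {
  stopifnot(n_oligomers >= 1L)
  set.seed(seed)
  pop <- simulate_population(model, switching, camera, optics, n_oligomers)
  nf <- switching$n_frames
  # photon-level noise on the raw detected channels; the perpendicular
  # detector sees gi_perp / g photons (bias g is an instrument property)
  par_phot <- stats::rpois(nf, pop$i_par)
  perp_phot <- stats::rpois(nf, pop$gi_perp / optics$g_factor)
  mk_counts <- function(phot)
    camera$gain * phot + stats::rnorm(nf, 0, camera$read_noise_sd) +
      camera$offset
  trace <- channel_trace(mean_par = mk_counts(par_phot),
                         mean_perp = mk_counts(perp_phot),
                         bg_par = rep(camera$offset, nf),
                         bg_perp = rep(camera$offset, nf),
                         n_pixels = rep(1L, nf))
  list(trace = trace, truth = ground_truth(model, pop$p_on))
}

#' Scene geometry for rendered dual-view stacks
#'
#' @param height,width Dimensions of each polarization half, in pixels; the
#'   rendered page is `height x 2 width` with the parallel field on the left.
#' @param cell_vertices Polygon (matrix or list of `(row, col)` pairs,
#'   0-based pixel-edge coordinates) delimiting the signal-carrying region in
#'   the parallel half. Default: a centered rectangle covering ~1/4 of the
#'   field.
#' @param background_vertices Polygon for the background (no-cell) region.
#' @param channel_offset Integer `(rows, cols)` translation of the
#'   perpendicular field relative to the parallel field.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(height = 48L, width = 48L, cell_vertices = NULL,
                         background_vertices = NULL,
                         channel_offset = c(0L, 0L)) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.null(cell_vertices)) {
    r0 <- height %/% 4; r1 <- 3 * height %/% 4
    c0 <- width %/% 4; c1 <- 3 * width %/% 4
    cell_vertices <- rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0))
  }
  if (is.null(background_vertices)) {
    background_vertices <- rbind(c(0, 0), c(0, width %/% 8),
                                 c(height %/% 8, width %/% 8),
                                 c(height %/% 8, 0))
  }
  structure(list(height = height, width = width,
                 cell_vertices = as.matrix(cell_vertices),
                 background_vertices = as.matrix(background_vertices),
                 channel_offset = as.integer(channel_offset)),
            class = "scene_config")
}

#' Render a simulated photoswitching experiment as a dual-view TIFF stack
#'
#' Writes a 16-bit multi-page TIFF in which each page holds the parallel
#' field (left half) and the perpendicular field (right half), emulating a
#' dual-view polarization splitter on a single camera. Pixels inside the
#' cell polygon share the simulated photon flux (per-pixel Poisson noise);
#' all pixels carry camera offset and Gaussian read noise. Companion JSON
#' files record the ROI polygons (with the channel offset) and the
#' simulation ground truth.
#'
#' @inheritParams simulate_trace
#' @param scene A [scene_config()].
#' @param dir Output directory (created if missing).
#' @param basename Stem for the output files (`<stem>.tif`,
#'   `<stem>_roi.json`, `<stem>_truth.json`).
#' @return Invisibly, a list with the written `paths`, the `truth`, and the
#'   per-frame expected channel photon totals.
#' @export
render_stack <- function(model = oligomer_model(),
                         switching = switching_params(),
                         camera = camera_model(),
                         optics = optics_config(apply_axelrod = FALSE),
                         scene = scene_config(),
                         n_oligomers = 10000L, seed = 1L,
                         dir = tempdir(), basename = "psafret_sim") {
  stopifnot(inherits(scene, "scene_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  pop <- simulate_population(model, switching, camera, optics, n_oligomers)
  nf <- switching$n_frames
  h <- scene$height; w <- scene$width
  cell_mask <- rasterize_polygon(scene$cell_vertices, h, w)
  n_cell <- sum(cell_mask)
  if (n_cell == 0L) stop("cell polygon rasterizes to zero pixels",
                         call. = FALSE)
  off <- scene$channel_offset
  pages <- vector("list", nf)
  for (t in seq_len(nf)) {
    lam_par <- pop$i_par[t] / n_cell
    lam_perp <- (pop$gi_perp[t] / optics$g_factor) / n_cell
    half_par <- matrix(0, h, w)
    half_perp <- matrix(0, h, w)
    half_par[cell_mask] <- stats::rpois(n_cell, lam_par)
    # perpendicular cell drawn at the configured translation
    perp_mask <- shift_mask(cell_mask, off[1L], off[2L])
    half_perp[perp_mask] <- stats::rpois(sum(perp_mask), lam_perp)
    page <- cbind(half_par, half_perp) * camera$gain + camera$offset +
      matrix(stats::rnorm(h * 2L * w, 0, camera$read_noise_sd), h, 2L * w)
    pages[[t]] <- pmin(pmax(round(page), 0), 65535) / 65535
  }
  paths <- list(stack = file.path(dir, paste0(basename, ".tif")),
                roi = file.path(dir, paste0(basename, "_roi.json")),
                truth = file.path(dir, paste0(basename, "_truth.json")))
  tiff::writeTIFF(pages, paths$stack, bits.per.sample = 16L,
                  compression = "none")
  rois <- list(
    list(label = "cell", vertices = unname(apply(scene$cell_vertices, 1L,
                                                 as.list, simplify = FALSE)),
         channel_offset = as.list(off)),
    list(label = "background",
         vertices = unname(apply(scene$background_vertices, 1L, as.list,
                                 simplify = FALSE)),
         channel_offset = as.list(off)))
  jsonlite::write_json(rois, paths$roi, auto_unbox = TRUE, digits = NA)
  truth <- ground_truth(model, pop$p_on)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth,
                 expected = list(i_par = pop$i_par, gi_perp = pop$gi_perp)))
}

# integer-pixel translation of a logical mask, zero fill
shift_mask <- function(mask, dr, dc) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  src <- which(mask, arr.ind = TRUE)
  dst_r <- src[, 1L] + dr
  dst_c <- src[, 2L] + dc
  keep <- dst_r >= 1L & dst_r <= h & dst_c >= 1L & dst_c <= w
  out[cbind(dst_r[keep], dst_c[keep])] <- TRUE
  out
}
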