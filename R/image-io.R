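#' Per-frame polarization channel trace
#'
#' The tabular container the whole pipeline operates on: per-frame mean ROI
#' intensities of the parallel and perpendicular channels, the matching
#' background-region means, and the pixel count. Background subtraction is
#' performed downstream ([analyze_trace()], [estimate_g()]) so raw and
#' background values travel together.
#'
#' @param mean_par,mean_perp Per-frame mean ROI intensities (counts).
#' @param bg_par,bg_perp Per-frame background means (counts).
#' @param n_pixels Pixels in the ROI.
#' @return A data frame of class `channel_trace` with one row per frame.
#' @export
channel_trace <- function(mean_par, mean_perp, bg_par = 0, bg_perp = 0,
                          n_pixels = 1L) {
  n <- length(mean_par)
  stopifnot(length(mean_perp) == n, n >= 1L)
  out <- data.frame(frame = seq_len(n) - 1L, mean_par = mean_par,
                    mean_perp = mean_perp, bg_par = rep_len(bg_par, n),
                    bg_perp = rep_len(bg_perp, n),
                    n_pixels = rep_len(as.integer(n_pixels), n))
  class(out) <- c("channel_trace", "data.frame")
  out
}

#' @keywords internal
as_channel_trace <- function(x) {
  if (inherits(x, "channel_trace")) return(x)
  req <- c("mean_par", "mean_perp", "bg_par", "bg_perp")
  if (!is.data.frame(x) || !all(req %in% names(x)))
    stop("expected a channel_trace or a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  channel_trace(x$mean_par, x$mean_perp, x$bg_par, x$bg_perp,
                if ("n_pixels" %in% names(x)) x$n_pixels else 1L)
}

#' Read a dual-view polarization TIFF stack
#'
#' Reads a multi-page grayscale TIFF in which each page carries the parallel
#' and perpendicular polarization fields side by side (parallel left by
#' default), splits the halves, and registers the perpendicular half onto
#' the parallel one by an integer-pixel rigid translation. Two pre-split
#' stacks may be given instead (`path` and `path_perp`).
#'
#' @param path Path to the dual-view stack, or to the parallel stack if
#'   `path_perp` is given.
#' @param path_perp Optional path to a separate perpendicular stack.
#' @param split_col Column (1-based, counted in the full page) at which to
#'   split; default is the page midpoint. Pages of odd width require an
#'   explicit `split_col`.
#' @param offset Integer `(rows, cols)` translation taking the perpendicular
#'   field onto the parallel field's coordinates (i.e. the offset the
#'   acquisition introduced). Applied as a reverse shift during registration.
#' @param refine_offset Logical; if `TRUE`, refines `offset` by maximizing
#'   the integer-pixel cross-correlation of the frame-averaged halves within
#'   `max_shift` pixels.
#' @param max_shift Search radius for `refine_offset`.
#' @return A list with 3-D arrays `par` and `perp` (`height x width x
#'   frames`, registered) and the `offset` actually applied.
#' @export
read_stack <- function(path, path_perp = NULL, split_col = NULL,
                       offset = c(0L, 0L), refine_offset = FALSE,
                       max_shift = 5L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(path_perp)) {
    pages <- read_pages(path)
    w <- ncol(pages[[1L]])
    if (is.null(split_col)) {
      if (w %% 2L != 0L)
        stop("layout error: odd page width (", w, ") needs an explicit ",
             "`split_col`", call. = FALSE)
      split_col <- w %/% 2L
    }
    par <- simplify2array(lapply(pages, function(p) p[, 1:split_col]))
    perp <- simplify2array(lapply(pages, function(p) p[, (split_col + 1L):w]))
  } else {
    par <- simplify2array(read_pages(path))
    perp <- simplify2array(read_pages(path_perp))
    if (dim(par)[3L] != dim(perp)[3L])
      stop("format error: mismatched frame counts (", dim(par)[3L], " vs ",
           dim(perp)[3L], ")", call. = FALSE)
  }
  offset <- as.integer(offset)
  if (refine_offset) {
    offset <- refine_translation(apply(par, c(1L, 2L), mean),
                                 apply(perp, c(1L, 2L), mean),
                                 offset, max_shift)
  }
  if (any(offset != 0L)) {
    for (t in seq_len(dim(perp)[3L]))
      perp[, , t] <- shift_image(perp[, , t], -offset[1L], -offset[2L])
  }
  list(par = par, perp = perp, offset = offset)
}

read_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # ignore extra samples
    p
  })
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("format error: pages differ in size", call. = FALSE)
  if (length(pages) < 2L)
    warning("stack has fewer than 2 frames; analysis needs a time series")
  pages
}

# translate image by integer pixels, filling with the image median so the
# border does not bias ROI means
shift_image <- function(img, dr, dc) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(stats::median(img), h, w)
  sr <- max(1L, 1L - dr):min(h, h - dr)
  sc <- max(1L, 1L - dc):min(w, w - dc)
  if (length(sr) > 0L && length(sc) > 0L)
    out[sr + dr, sc + dc] <- img[sr, sc]
  out
}

# integer-pixel translation maximizing cross-correlation between the mean
# parallel and perpendicular images, searched around `start`
refine_translation <- function(ref, moving, start, max_shift) {
  best <- start; best_cc <- -Inf
  for (dr in (start[1L] - max_shift):(start[1L] + max_shift)) {
    for (dc in (start[2L] - max_shift):(start[2L] + max_shift)) {
      shifted <- shift_image(moving, -dr, -dc)
      cc <- stats::cor(as.vector(ref), as.vector(shifted))
      if (is.finite(cc) && cc > best_cc) {
        best_cc <- cc
        best <- c(dr, dc)
      }
    }
  }
  as.integer(best)
}

#' Region-of-interest specification
#'
#' @param label Name of the region.
#' @param vertices Polygon as an `n x 2` matrix of `(row, col)` pairs in
#'   0-based pixel-edge coordinates (at least 3 vertices).
#' @param channel_offset Integer `(rows, cols)` translation mapping this ROI
#'   from the parallel field to the perpendicular field, when the stacks are
#'   not already registered.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(label, vertices, channel_offset = c(0L, 0L)) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stop("`vertices` must be an n x 2 matrix with n >= 3", call. = FALSE)
  structure(list(label = label, vertices = vertices,
                 channel_offset = as.integer(channel_offset)),
            class = "roi_spec")
}

#' Read ROI definitions from JSON
#'
#' Expects an array of objects with fields `label`, `vertices` (a list of
#' `(row, col)` pairs, 0-based) and optionally `channel_offset`.
#'
#' @param path Path to the ROI JSON file.
#' @return A named list of [roi_spec()] objects keyed by label.
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(r) {
    v <- do.call(rbind, lapply(r$vertices, unlist))
    off <- if (!is.null(r$channel_offset)) unlist(r$channel_offset)
           else c(0L, 0L)
    roi_spec(r$label, v, off)
  })
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}

#' Rasterize a polygon into a pixel mask
#'
#' Pixel-center containment: pixel `(i, j)` (0-based) belongs to the region
#' when its center `(i + 0.5, j + 0.5)` lies inside the polygon (even-odd
#' rule; boundary points count as inside). Integer-vertex axis-aligned
#' rectangles therefore behave half-open: vertices `(r0,c0)...(r1,c1)` cover
#' rows `r0..r1-1` and columns `c0..c1-1`.
#'
#' @param vertices `n x 2` matrix of `(row, col)` polygon vertices, 0-based.
#' @param height,width Raster dimensions.
#' @return A logical `height x width` matrix.
#' @export
rasterize_polygon <- function(vertices, height, width) {
  vertices <- as.matrix(vertices)
  centers_r <- rep(seq_len(height) - 0.5, times = width)
  centers_c <- rep(seq_len(width) - 0.5, each = height)
  inside <- pracma::inpolygon(centers_r, centers_c,
                              vertices[, 1L], vertices[, 2L],
                              boundary = TRUE)
  matrix(inside, nrow = height, ncol = width)
}

#' Extract a per-frame channel trace from registered stacks
#'
#' Computes the per-frame mean over the ROI pixels in each channel together
#' with per-frame background means from a no-cell region. Background is
#' tracked per frame (not as a single constant) so slow baseline drifts are
#' followed. Subtraction happens downstream and negative subtracted values
#' are preserved, never clipped.
#'
#' @param par,perp `height x width x frames` arrays as returned by
#'   [read_stack()].
#' @param roi A [roi_spec()] for the signal region (parallel-field
#'   coordinates; `channel_offset` maps it onto the perpendicular field).
#' @param background_roi A [roi_spec()] for the background region.
#' @return A [channel_trace()].
#' @export
extract_trace <- function(par, perp, roi, background_roi) {
  stopifnot(inherits(roi, "roi_spec"), inherits(background_roi, "roi_spec"))
  h <- dim(par)[1L]; w <- dim(par)[2L]; nf <- dim(par)[3L]
  stopifnot(all(dim(perp) == dim(par)))
  mask_par <- rasterize_polygon(roi$vertices, h, w)
  mask_perp <- shift_mask(mask_par, roi$channel_offset[1L],
                          roi$channel_offset[2L])
  bmask_par <- rasterize_polygon(background_roi$vertices, h, w)
  bmask_perp <- shift_mask(bmask_par, background_roi$channel_offset[1L],
                           background_roi$channel_offset[2L])
  if (!any(mask_par) || !any(bmask_par))
    stop("empty ROI after rasterization", call. = FALSE)
  frame_mean <- function(arr, mask)
    vapply(seq_len(nf), function(t) mean(arr[, , t][mask]), numeric(1))
  channel_trace(mean_par = frame_mean(par, mask_par),
                mean_perp = frame_mean(perp, mask_perp),
                bg_par = frame_mean(par, bmask_par),
                bg_perp = frame_mean(perp, bmask_perp),
                n_pixels = sum(mask_par))
}

#' Write a channel trace as CSV
#'
#' @param trace A [channel_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
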