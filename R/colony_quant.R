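#' Estimate the smooth background of a plate image
#'
#' Builds a low-frequency background surface that is not inflated by
#' colony foreground. The default estimator takes a low quantile
#' (\code{q}, default the 10th percentile) of the pixels in overlapping
#' \code{window}-sized blocks — on a dense colony array the low quantile
#' lands on the inter-colony floor even where colonies cover most of a
#' block — and interpolates the block grid bilinearly back to pixel
#' resolution. A large-window 2D median filter (EBImage) is available as
#' \code{method = "median"}; on high-density arrays the window median
#' sits partly on colony tail light and over-estimates the background.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param window Block/window side in pixels; at least 3x the expected
#'   colony diameter so each block reaches between colonies, and no
#'   larger than the image.
#' @param method \code{"quantile"} (default) or \code{"median"}.
#' @param q Quantile used by the default estimator.
#' @return Background matrix of the same shape as \code{image}.
#' @export
estimate_background <- function(image, window,
                                method = c("quantile", "median"), q = 0.1) {
  stopifnot(is.matrix(image))
  method <- match.arg(method)
  window <- as.integer(window)
  if (window < 3L) stopf("background window must be >= 3 px")
  if (window > min(dim(image)))
    stopf("background window (%d px) exceeds image size (%d x %d)",
          window, nrow(image), ncol(image))
  if (window %% 2L == 0L) window <- window + 1L
  if (method == "median") {
    top <- max(image)
    if (top <= 0) return(matrix(0, nrow(image), ncol(image)))
    # EBImage's constant-time median filter wants intensities in [0, 1]
    bg <- EBImage::medianFilter(image / top, size = (window - 1L) %/% 2L) * top
    return(matrix(as.numeric(bg), nrow(image), ncol(image)))
  }
  nr <- nrow(image); nc <- ncol(image)
  half <- window %/% 2L
  step <- max(1L, half)                       # 50% block overlap
  cy <- unique(c(seq(1L, nr, by = step), nr))
  cx <- unique(c(seq(1L, nc, by = step), nc))
  block <- matrix(NA_real_, length(cy), length(cx))
  for (i in seq_along(cy)) {
    ys <- max(1L, cy[i] - half):min(nr, cy[i] + half)
    for (j in seq_along(cx)) {
      xs <- max(1L, cx[j] - half):min(nc, cx[j] + half)
      block[i, j] <- stats::quantile(image[ys, xs], q, names = FALSE)
    }
  }
  # separable bilinear interpolation of the block grid to pixel resolution
  tmp <- apply(block, 2, function(v)
    stats::approx(cy, v, xout = seq_len(nr), rule = 2)$y)
  t(apply(tmp, 1, function(v)
    stats::approx(cx, v, xout = seq_len(nc), rule = 2)$y))
}

#' Subtract a background surface from an image
#'
#' Elementwise \code{max(image - background, 0)}.
#'
#' @param image,background Numeric matrices of identical shape.
#' @return Background-subtracted matrix, clipped at 0.
#' @export
subtract_background <- function(image, background) {
  if (!identical(dim(image), dim(background)))
    stopf("image (%s) and background (%s) shapes differ",
          paste(dim(image), collapse = "x"),
          paste(dim(background), collapse = "x"))
  pmax(image - background, 0)
}

# Best (offset, pitch) for one axis: maximize the summed projection-profile
# intensity over the comb of n node positions. Two-stage grid search around
# the configured geometry; linear interpolation of the profile.
fit_axis <- function(profile, n_nodes, pitch0, margin0) {
  prof_at <- function(x) {
    x <- pmin(pmax(x, 0), length(profile) - 1)
    i <- floor(x); f <- x - i
    (1 - f) * profile[i + 1] + f * profile[pmin(i + 2, length(profile))]
  }
  score <- function(o, p) sum(prof_at(o + (seq_len(n_nodes) - 1) * p))
  search <- function(os, ps) {
    best <- c(-Inf, NA, NA)
    for (p in ps) for (o in os) {
      s <- score(o, p)
      if (s > best[1]) best <- c(s, o, p)
    }
    best
  }
  b <- search(seq(margin0 - pitch0 / 2, margin0 + pitch0 / 2, by = 0.5),
              seq(pitch0 * 0.96, pitch0 * 1.04, by = 0.1))
  b <- search(seq(b[2] - 0.6, b[2] + 0.6, by = 0.05),
              seq(b[3] - 0.12, b[3] + 0.12, by = 0.01))
  list(origin = b[2], pitch = b[3])
}

#' Fit the rigid colony grid of a plate image
#'
#' Colony arrays pinned by a robot form a rigid lattice, so instead of
#' segmenting colonies individually the grid is fitted globally: the
#' background-subtracted image is projected onto rows and columns, and the
#' (origin, pitch) pair maximizing the summed profile intensity over the
#' comb of expected node positions is found by a two-stage search around
#' the configured geometry.
#'
#' @param image Numeric matrix (background-subtracted or raw white-light
#'   plate image; at least half the expected colonies must be present).
#' @param spec A \code{\link{plate_spec}} giving the expected geometry.
#' @return An object of class \code{colony_grid}: 0-based pixel node
#'   centres (\code{row_centers}, \code{col_centers}), fitted pitches and
#'   origins, and the fraction of nodes with detectable signal.
#' @export
detect_grid <- function(image, spec) {
  stopifnot(is.matrix(image), inherits(spec, "plate_spec"))
  bg <- stats::median(image)
  work <- pmax(image - bg, 0)
  fy <- fit_axis(rowSums(work), spec$n_rows, spec$pitch_px, spec$margin_px)
  fx <- fit_axis(colSums(work), spec$n_cols, spec$pitch_px, spec$margin_px)
  row_centers <- fy$origin + (seq_len(spec$n_rows) - 1) * fy$pitch
  col_centers <- fx$origin + (seq_len(spec$n_cols) - 1) * fx$pitch

  # diagnostic: fraction of nodes whose local mean clears the image's
  # background level by more than twice its robust spread
  floor_level <- stats::median(image) + 2 * stats::mad(image) + 1e-12
  h <- max(2L, floor(spec$pitch_px / 5))
  ry <- round(row_centers) + 1L; rx <- round(col_centers) + 1L
  hit <- outer(ry, rx, Vectorize(function(y, x) {
    ys <- max(1, y - h):min(nrow(image), y + h)
    xs <- max(1, x - h):min(ncol(image), x + h)
    mean(image[ys, xs]) > floor_level
  }))
  frac <- mean(hit)
  if (frac < 0.25)
    stopf(paste0("grid detection failed: only %.0f%% of the %d expected ",
                 "colony positions show signal (fitted pitch %.2f/%.2f px, ",
                 "origin %.1f/%.1f px)"),
          100 * frac, spec$density, fy$pitch, fx$pitch, fy$origin, fx$origin)
  structure(list(row_centers = row_centers, col_centers = col_centers,
                 pitch = c(row = fy$pitch, col = fx$pitch),
                 origin = c(row = fy$origin, col = fx$origin),
                 detected_fraction = frac, spec = spec),
            class = "colony_grid")
}

#' @export
print.colony_grid <- function(x, ...) {
  cat(sprintf("colony_grid: %d x %d nodes, pitch (%.2f, %.2f) px, origin (%.2f, %.2f) px, %.0f%% detected\n",
              length(x$row_centers), length(x$col_centers),
              x$pitch[1], x$pitch[2], x$origin[1], x$origin[2],
              100 * x$detected_fraction))
  invisible(x)
}

#' Integrated intensity of one colony ROI
#'
#' Sums (never averages) the pixel values in a square region of interest
#' centred on a grid node — the screen's observable is the pixel
#' integrated intensity, the sum of the pixel values not divided by their
#' number, so that it scales with both colony brightness and size.
#'
#' @param image Numeric matrix (normally background-subtracted).
#' @param node Length-2 numeric \code{c(y, x)} centre in 0-based pixel
#'   coordinates.
#' @param roi_half_side Half the ROI side in pixels.
#' @return A list: \code{sum}, \code{area} (pixels actually summed) and
#'   \code{clipped} (TRUE if the ROI ran off the image edge).
#' @export
measure_colony <- function(image, node, roi_half_side) {
  cy <- round(node[1]) + 1L; cx <- round(node[2]) + 1L
  h <- as.integer(roi_half_side)
  ys <- (cy - h):(cy + h); xs <- (cx - h):(cx + h)
  clipped <- ys[1] < 1L || xs[1] < 1L || ys[length(ys)] > nrow(image) ||
    xs[length(xs)] > ncol(image)
  ys <- ys[ys >= 1L & ys <= nrow(image)]
  xs <- xs[xs >= 1L & xs <= ncol(image)]
  if (!length(ys) || !length(xs))
    return(list(sum = 0, area = 0L, clipped = TRUE))
  block <- image[ys, xs, drop = FALSE]
  list(sum = sum(block), area = length(block), clipped = clipped)
}

#' Quantify a plate image pair into per-colony measurements
#'
#' The full image stage: per channel, estimate and subtract the
#' background, fit the rigid colony grid on the white-light image, and sum
#' each square ROI in both channels at the same grid nodes. EMPTY map
#' positions are measured too (they quantify residual background) but
#' flagged.
#'
#' @param pair A \code{plate_image_pair} (see
#'   \code{\link{simulate_colony_plates}}), or any list with
#'   \code{biomass_image}, \code{fluor_image} and metadata fields.
#' @param map A \code{\link{generate_plate_map}} result.
#' @param spec A \code{\link{plate_spec}}.
#' @param roi_fraction ROI side as a fraction of the pitch (default 0.8,
#'   non-overlapping).
#' @param background_window Background median-filter window in pixels;
#'   default 3x the nominal colony diameter (1.8x pitch).
#' @return A \code{data.frame} with one row per map position:
#'   \code{plate_id}, \code{replicate_id}, \code{timepoint},
#'   \code{reporter}, \code{row}, \code{col}, \code{strain_id},
#'   \code{biomass_sum}, \code{fluor_sum}, \code{roi_area}, \code{flags}
#'   (comma-separated subset of \code{EMPTY}, \code{EDGE_OF_IMAGE},
#'   \code{SATURATED}).
#' @export
quantify_plate <- function(pair, map, spec, roi_fraction = 0.8,
                           background_window = NULL) {
  stopifnot(inherits(spec, "plate_spec"))
  plate_no <- sub("^plate", "", pair$plate_id %||% "1")
  map_plate <- map[as.character(map$plate) == plate_no, , drop = FALSE]
  if (nrow(map_plate) != spec$density)
    stopf("map plate %s has %d positions, spec expects %d",
          plate_no, nrow(map_plate), spec$density)
  window <- background_window %||% (2 * floor(3 * 0.6 * spec$pitch_px / 2) + 1)

  prep <- function(img) {
    subtract_background(img, estimate_background(img, window))
  }
  bio <- prep(pair$biomass_image)
  flu <- prep(pair$fluor_image)
  grid <- detect_grid(bio, spec)
  h <- floor(roi_fraction * mean(grid$pitch) / 2)
  maxval <- 2^spec$bit_depth - 1

  n <- nrow(map_plate)
  biomass_sum <- fluor_sum <- roi_area <- numeric(n)
  flags <- character(n)
  for (i in seq_len(n)) {
    node <- c(grid$row_centers[map_plate$row[i]],
              grid$col_centers[map_plate$col[i]])
    mb <- measure_colony(bio, node, h)
    mf <- measure_colony(flu, node, h)
    biomass_sum[i] <- mb$sum; fluor_sum[i] <- mf$sum
    roi_area[i] <- mb$area
    fl <- character()
    if (map_plate$strain_id[i] == "EMPTY") fl <- c(fl, "EMPTY")
    if (mb$clipped || mf$clipped) fl <- c(fl, "EDGE_OF_IMAGE")
    # saturation QC: count raw pixels at full scale in the raw ROI
    raw <- measure_colony(pair$biomass_image >= maxval |
                            pair$fluor_image >= maxval, node, h)
    if (raw$area > 0 && raw$sum / raw$area > 0.05) fl <- c(fl, "SATURATED")
    flags[i] <- paste(fl, collapse = ",")
  }
  data.frame(
    plate_id = pair$plate_id %||% paste0("plate", plate_no),
    replicate_id = pair$replicate_id %||% "rep1",
    timepoint = pair$timepoint %||% "24h",
    reporter = pair$reporter %||% "WT",
    row = map_plate$row, col = map_plate$col,
    strain_id = map_plate$strain_id,
    biomass_sum = biomass_sum, fluor_sum = fluor_sum,
    roi_area = roi_area, flags = flags,
    stringsAsFactors = FALSE
  )
}
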