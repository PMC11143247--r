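#' Geometry of a pinned colony-array plate
#'
#' Describes a rectangular colony array as pinned by a high-density robot:
#' the grid dimensions (32 x 48 = 1536 positions by default), the pixel
#' pitch between adjacent grid nodes in the plate images, and the margin
#' from the image edge to the first node. All downstream image operations
#' (grid fitting, ROI measurement) and the synthetic renderer share this
#' description.
#'
#' @param n_rows,n_cols Grid dimensions; their product is the array density
#'   (1536 for the standard high-density format).
#' @param pitch_px Pixel distance between adjacent grid nodes (>= 8).
#' @param margin_px Pixels from the image edge to the first node
#'   (>= pitch_px / 2 so border ROIs fit in the image).
#' @param bit_depth Image bit depth, 8 or 16.
#' @return An object of class \code{plate_spec}.
#' @examples
#' spec <- plate_spec()
#' spec$density   # 1536
#' @export
plate_spec <- function(n_rows = 32L, n_cols = 48L, pitch_px = 20,
                       margin_px = 20, bit_depth = 16L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stopf("grid dimensions must be positive")
  if (pitch_px < 8) stopf("pitch_px must be >= 8 pixels, got %s", pitch_px)
  if (margin_px < pitch_px / 2)
    stopf("margin_px (%s) must be >= pitch_px/2 (%s)", margin_px, pitch_px / 2)
  if (!bit_depth %in% c(8L, 16L)) stopf("bit_depth must be 8 or 16")
  structure(list(
    n_rows = n_rows, n_cols = n_cols,
    pitch_px = pitch_px, margin_px = margin_px,
    bit_depth = as.integer(bit_depth),
    density = n_rows * n_cols,
    image_height = as.integer(round(2 * margin_px + (n_rows - 1) * pitch_px) + 1L),
    image_width  = as.integer(round(2 * margin_px + (n_cols - 1) * pitch_px) + 1L)
  ), class = "plate_spec")
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf("plate_spec: %d x %d grid (%d positions), pitch %g px, margin %g px, %d-bit\n",
              x$n_rows, x$n_cols, x$density, x$pitch_px, x$margin_px, x$bit_depth))
  invisible(x)
}

#' Generate a randomized plate map for a colony-array screen
#'
#' Assigns strains to grid positions across one or more plates, mirroring
#' the layout of an arrayed deletion collection: most strains occupy a
#' single position, a set of internal-control strains is duplicated (402
#' in the standard layout), and the remaining positions are EMPTY. The
#' assignment is a seeded random permutation, so duplicate pairs and empty
#' wells are scattered over the plates.
#'
#' @param spec A \code{\link{plate_spec}}.
#' @param n_strains Number of distinct strains.
#' @param n_duplicates Number of those strains pinned at two positions
#'   (extra positions beyond \code{n_strains}).
#' @param n_empty Number of EMPTY positions. \code{NULL} (default) fills
#'   whatever capacity remains; if given it must make the map tile the
#'   plates exactly.
#' @param n_plates Number of plates the map spans.
#' @param seed Integer seed; identical seeds give identical maps.
#' @param strain_ids Optional character vector of strain names
#'   (length \code{n_strains}); default \code{"strain_0001"} style ids.
#' @return A \code{data.frame} of class \code{plate_map} with columns
#'   \code{plate}, \code{row}, \code{col}, \code{strain_id} (\code{"EMPTY"}
#'   for empty positions); every position of every plate appears exactly
#'   once.
#' @examples
#' map <- generate_plate_map(plate_spec(), n_strains = 1000,
#'                           n_duplicates = 100, seed = 1)
#' sum(map$strain_id == "EMPTY")  # 436
#' @export
generate_plate_map <- function(spec, n_strains, n_duplicates = 0L,
                               n_empty = NULL, n_plates = 1L, seed = 1L,
                               strain_ids = NULL) {
  stopifnot(inherits(spec, "plate_spec"))
  n_strains <- as.integer(n_strains)
  n_duplicates <- as.integer(n_duplicates)
  n_plates <- as.integer(n_plates)
  if (n_duplicates > n_strains)
    stopf("n_duplicates (%d) cannot exceed n_strains (%d)", n_duplicates, n_strains)
  capacity <- n_plates * spec$density
  occupied <- n_strains + n_duplicates
  if (is.null(n_empty)) n_empty <- capacity - occupied
  n_empty <- as.integer(n_empty)
  if (n_empty < 0L || occupied + n_empty > capacity)
    stopf(paste0("map does not fit: %d strains + %d duplicate positions + %d empty ",
                 "= %d positions, but %d plate(s) of density %d hold only %d"),
          n_strains, n_duplicates, max(n_empty, 0L),
          occupied + max(n_empty, 0L), n_plates, spec$density, capacity)
  if (occupied + n_empty < capacity)
    stopf(paste0("map must tile the plates exactly: %d positions requested, ",
                 "%d available; leave n_empty = NULL to fill the remainder"),
          occupied + n_empty, capacity)
  if (is.null(strain_ids)) {
    strain_ids <- sprintf("strain_%05d", seq_len(n_strains))
  } else if (length(strain_ids) != n_strains || anyDuplicated(strain_ids)) {
    stopf("strain_ids must be %d unique names", n_strains)
  }
  if (any(strain_ids == "EMPTY")) stopf("'EMPTY' is a reserved strain id")

  map <- with_seed(seed, {
    dup <- if (n_duplicates > 0) sample(strain_ids, n_duplicates) else character()
    labels <- c(strain_ids, dup, rep("EMPTY", n_empty))
    labels <- sample(labels)          # scatter over positions
    data.frame(
      plate = rep(seq_len(n_plates), each = spec$density),
      row   = rep(rep(seq_len(spec$n_rows), each = spec$n_cols), times = n_plates),
      col   = rep(rep(seq_len(spec$n_cols), times = spec$n_rows), times = n_plates),
      strain_id = labels,
      stringsAsFactors = FALSE
    )
  })
  attr(map, "spec") <- spec
  attr(map, "seed") <- seed
  class(map) <- c("plate_map", "data.frame")
  map
}

#' @export
print.plate_map <- function(x, ...) {
  tab <- table(x$strain_id)
  n_empty <- sum(x$strain_id == "EMPTY")
  n_dup <- sum(tab[names(tab) != "EMPTY"] == 2L)
  cat(sprintf("plate_map: %d plates, %d positions, %d strains (%d duplicated), %d EMPTY\n",
              length(unique(x$plate)), nrow(x),
              length(setdiff(names(tab), "EMPTY")), n_dup, n_empty))
  invisible(x)
}
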