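# File I/O for the standard interchange formats: 16-bit grayscale TIFF
# plate images, plate-map / measurement / curve CSVs.

#' Write a plate image as 16-bit grayscale TIFF
#'
#' @param image Numeric matrix in instrument counts.
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @return Invisibly, \code{path}.
#' @export
write_plate_image <- function(image, path, bit_depth = 16L) {
  maxval <- 2^bit_depth - 1
  tiff::writeTIFF(pmin(pmax(image, 0), maxval) / maxval, path,
                  bits.per.sample = as.integer(bit_depth),
                  compression = "none")
  invisible(path)
}

#' Read a grayscale plate image (TIFF or PNG) into instrument counts
#'
#' @param path Image path.
#' @param bit_depth Bit depth used to rescale to counts (default 16).
#' @return Numeric matrix.
#' @export
read_plate_image <- function(path, bit_depth = 16L) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]   # first channel if not gray
  img * (2^bit_depth - 1)
}

#' Write/read a plate map CSV
#'
#' Columns \code{plate}, \code{row}, \code{col}, \code{strain_id}
#' (\code{"EMPTY"} for empty wells).
#'
#' @param map A \code{plate_map}.
#' @param path CSV path.
#' @return Invisibly \code{path}; \code{read_plate_map} returns the map
#'   \code{data.frame}.
#' @export
write_plate_map <- function(map, path) {
  write_table(as.data.frame(map)[, c("plate", "row", "col", "strain_id")], path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) stopf("plate map file not found: %s", path)
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plate", "row", "col", "strain_id")
  if (!all(req %in% names(map)))
    stopf("plate map %s lacks columns: %s", path,
          paste(setdiff(req, names(map)), collapse = ", "))
  class(map) <- c("plate_map", "data.frame")
  map
}

#' Read a long-format plate-reader curve CSV
#'
#' Expected columns: \code{well}, \code{construct}, \code{condition_molar},
#' \code{time_h}, \code{od600}, \code{fluor} (or \code{fluorescence}),
#' \code{is_blank}.
#'
#' @param path CSV path.
#' @return A \code{growth_curves} data.frame.
#' @export
read_growth_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("fluorescence" %in% names(df) && !"fluor" %in% names(df))
    names(df)[names(df) == "fluorescence"] <- "fluor"
  req <- c("well", "condition_molar", "time_h", "od600", "fluor", "is_blank")
  if (!all(req %in% names(df)))
    stopf("curve file %s lacks columns: %s", path,
          paste(setdiff(req, names(df)), collapse = ", "))
  df$is_blank <- as.logical(df$is_blank)
  df$construct <- df$construct %||% "construct"
  class(df) <- c("growth_curves", "data.frame")
  df
}
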