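#' Fluorescence/biomass ratio with growth filtering
#'
#' The screen's base observable: per-colony integrated fluorescence
#' divided by integrated biomass, which cancels colony-size variation and
#' part of the growth-related edge effect. Empty wells are removed, and
#' colonies whose biomass falls below a fraction of the plate median
#' (failed pinnings) are excluded rather than producing unstable ratios.
#'
#' @param measurements A \code{\link{quantify_plate}}-style table for one
#'   or more plates of one reporter/replicate.
#' @param growth_floor Minimum biomass as a fraction of the per-plate
#'   median biomass of non-empty colonies (default 0.1).
#' @return A \code{data.frame} of normalized records: the measurement
#'   columns plus \code{ratio}, \code{ratio_corrected} (NA until
#'   \code{\link{spatial_normalize}}), \code{excluded} and
#'   \code{exclude_reason} (\code{""}, \code{"EMPTY"} or
#'   \code{"LOW_GROWTH"}). Excluded colonies carry \code{NA} ratios,
#'   never zeros.
#' @export
compute_ratio <- function(measurements, growth_floor = 0.1) {
  req <- c("plate_id", "row", "col", "strain_id", "biomass_sum", "fluor_sum")
  if (!all(req %in% names(measurements)))
    stopf("measurements lack columns: %s",
          paste(setdiff(req, names(measurements)), collapse = ", "))
  m <- measurements
  is_empty <- m$strain_id == "EMPTY" | grepl("EMPTY", m$flags %||% "")
  floor_abs <- stats::ave(m$biomass_sum, m$plate_id, FUN = function(x) NA)
  for (p in unique(m$plate_id)) {
    sel <- m$plate_id == p & !is_empty
    if (!any(sel)) next
    floor_abs[m$plate_id == p] <- growth_floor * stats::median(m$biomass_sum[sel])
  }
  low <- !is_empty & (m$biomass_sum < floor_abs | m$biomass_sum <= 0)
  excluded <- is_empty | low
  if (all(excluded))
    stopf("empty plate: all %d colonies excluded (EMPTY or below growth floor)",
          nrow(m))
  m$ratio <- ifelse(excluded, NA_real_, m$fluor_sum / m$biomass_sum)
  m$ratio_corrected <- NA_real_
  m$excluded <- excluded
  m$exclude_reason <- ifelse(is_empty, "EMPTY", ifelse(low, "LOW_GROWTH", ""))
  m
}

# Running median over a grid with NA holes; window shrinks at the edges.
grid_running_median <- function(mat, half) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ys <- max(1, i - half):min(nr, i + half)
    for (j in seq_len(nc)) {
      xs <- max(1, j - half):min(nc, j + half)
      v <- mat[ys, xs]
      v <- v[!is.na(v)]
      if (length(v)) out[i, j] <- stats::median(v)
    }
  }
  out
}

#' Spatial normalization of colony ratios
#'
#' Removes the border/incubator effect: a robust low-frequency trend
#' surface is estimated per plate over the grid of included log-ratios,
#' each ratio is divided by the local trend, and the result is rescaled
#' so the per-plate median of corrected ratios is exactly 1.
#'
#' The default trend is a robust local-quadratic surface
#' (\code{stats::loess} on \code{log(ratio) ~ row * col} with bisquare
#' reweighting, neighborhood sized to \code{smooth_window^2} grid cells).
#' The local polynomial tracks the steep monotone ramp at the plate
#' border without the boundary bias of a running median, while the
#' bisquare weights keep isolated biological outliers (hits) out of the
#' trend so they survive the correction. A plain 2D running median
#' (window shrinking at the edges) is available as
#' \code{method = "median"}; it is equally robust to hits but
#' under-corrects the outermost rings of a strong border gradient.
#'
#' @param records A \code{\link{compute_ratio}} table (grid positions
#'   required).
#' @param smooth_window Odd trend window side in grid cells (default 9).
#' @param method \code{"loess"} (default) or \code{"median"}.
#' @return The records with \code{ratio_corrected} filled in (per-plate
#'   median exactly 1 over included colonies; NA where excluded).
#' @export
spatial_normalize <- function(records, smooth_window = 9L,
                              method = c("loess", "median")) {
  method <- match.arg(method)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 3L || smooth_window %% 2L == 0L)
    stopf("smooth_window must be an odd integer >= 3, got %d", smooth_window)
  half <- (smooth_window - 1L) %/% 2L
  out <- records
  for (p in unique(records$plate_id)) {
    sel <- which(records$plate_id == p)
    r <- records[sel, ]
    inc <- !r$excluded & is.finite(r$ratio) & r$ratio > 0
    if (!any(inc))
      stopf("plate %s: no usable ratios for spatial normalization", p)
    corr <- rep(NA_real_, nrow(r))
    if (method == "loess") {
      dat <- data.frame(row = r$row[inc], col = r$col[inc],
                        y = log(r$ratio[inc]))
      span <- min(1, 1.5 * smooth_window^2 / nrow(dat))
      # small spans on an integer lattice trip loess's rank warnings;
      # the pseudoinverse fit it falls back to is exactly what we want
      fit <- suppressWarnings(
        stats::loess(y ~ row * col, data = dat, span = span, degree = 2,
                     family = "symmetric", normalize = FALSE,
                     control = stats::loess.control(surface = "direct")))
      surf <- exp(suppressWarnings(
        stats::predict(fit, data.frame(row = r$row, col = r$col))))
      corr[inc] <- r$ratio[inc] / surf[inc]
    } else {
      nr <- max(r$row); nc <- max(r$col)
      mat <- matrix(NA_real_, nr, nc)
      mat[cbind(r$row[inc], r$col[inc])] <- r$ratio[inc]
      surf <- grid_running_median(mat, half)
      corr[inc] <- r$ratio[inc] / surf[cbind(r$row[inc], r$col[inc])]
    }
    med <- stats::median(corr[inc])
    if (!is.finite(med) || med <= 0)
      stopf("plate %s: degenerate corrected-ratio distribution", p)
    out$ratio_corrected[sel] <- corr / med
  }
  out
}

#' Per-plate quality-control summary
#'
#' Counts included/excluded colonies by reason and contrasts the
#' border-ring vs. plate-centre median ratio before and after spatial
#' correction — the border/centre contrast is the direct readout of the
#' edge effect and should be ~1 after correction.
#'
#' @param records A \code{\link{spatial_normalize}} output (one or more
#'   plates).
#' @param center_from Grid distance from the edge at which the "centre"
#'   block starts (default 4, matching the gradient decay length).
#' @return A list of class \code{plate_qc}, one element per plate:
#'   counts, median ratio, \code{border_center_raw},
#'   \code{border_center_corrected}, saturated-colony count.
#' @export
plate_qc <- function(records, center_from = 4L) {
  if (!nrow(records)) stopf("no records to QC")
  out <- list()
  for (p in unique(records$plate_id)) {
    r <- records[records$plate_id == p, ]
    nr <- max(r$row); nc <- max(r$col)
    d <- edge_distance(r$row, r$col, nr, nc)
    inc <- !r$excluded
    bc <- function(v) {
      b <- stats::median(v[inc & d == 0], na.rm = TRUE)
      c0 <- stats::median(v[inc & d >= center_from], na.rm = TRUE)
      b / c0
    }
    out[[p]] <- list(
      plate_id = p,
      n = nrow(r),
      n_included = sum(inc),
      n_excluded = sum(!inc),
      excluded_by_reason = table(r$exclude_reason[!inc]),
      median_ratio = stats::median(r$ratio[inc], na.rm = TRUE),
      border_center_raw = bc(r$ratio),
      border_center_corrected = bc(r$ratio_corrected),
      n_saturated = sum(grepl("SATURATED", r$flags %||% ""))
    )
  }
  structure(out, class = "plate_qc")
}

#' @export
print.plate_qc <- function(x, ...) {
  for (q in x) {
    cat(sprintf("%s: %d colonies, %d included, %d excluded; median ratio %.3f; border/center %.3f -> %.3f; %d saturated\n",
                q$plate_id, q$n, q$n_included, q$n_excluded, q$median_ratio,
                q$border_center_raw, q$border_center_corrected, q$n_saturated))
  }
  invisible(x)
}
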