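#' Per-strain mean corrected ratios within one replicate
#'
#' Averages the spatially corrected ratios of each strain's included
#' positions within a single biological replicate — duplicated strains are
#' collapsed to one value here, before any cross-replicate statistics.
#'
#' @param records A \code{\link{spatial_normalize}} output for one
#'   replicate (one reporter, any number of plates).
#' @return A \code{data.frame}: \code{strain_id}, \code{value},
#'   \code{n_positions}.
#' @export
per_strain_means <- function(records) {
  r <- records[!records$excluded & records$strain_id != "EMPTY", ]
  if (!nrow(r)) stopf("no included colonies in records")
  agg <- stats::aggregate(r$ratio_corrected, list(strain_id = r$strain_id),
                          mean)
  cnt <- stats::aggregate(r$ratio_corrected, list(strain_id = r$strain_id),
                          length)
  data.frame(strain_id = agg$strain_id, value = agg$x,
             n_positions = cnt$x, stringsAsFactors = FALSE)
}

#' Combine biological replicates of one reporter screen
#'
#' Per strain: mean and SD of the corrected ratio across replicates,
#' after duplicated positions have been averaged within each replicate.
#'
#' @param tables A list of per-replicate record tables
#'   (\code{\link{spatial_normalize}} outputs) or per-strain tables
#'   (\code{\link{per_strain_means}} outputs).
#' @return A \code{data.frame}: \code{strain_id}, \code{mean}, \code{sd}
#'   (NA with a warning when fewer than 2 replicates), \code{n}.
#' @export
combine_replicates <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  per_rep <- lapply(tables, function(t) {
    if ("value" %in% names(t)) t else per_strain_means(t)
  })
  if (length(per_rep) < 2)
    warning("fewer than 2 replicates: per-strain SD reported as NA",
            call. = FALSE)
  long <- do.call(rbind, Map(function(t, i)
    data.frame(strain_id = t$strain_id, value = t$value, rep = i),
    per_rep, seq_along(per_rep)))
  m <- stats::aggregate(value ~ strain_id, long, mean)
  s <- stats::aggregate(value ~ strain_id, long,
                        function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  n <- stats::aggregate(value ~ strain_id, long, length)
  data.frame(strain_id = m$strain_id, mean = m$value, sd = s$value,
             n = n$value, stringsAsFactors = FALSE)
}

#' Control-normalized expression index
#'
#' Divides each strain's replicate-mean WT-reporter value by its value in
#' the ligand-blind binding-mutant (G31C) control screen, then recentres
#' the index distribution at a median of 1. The per-strain ratio removes
#' every fluorescence variation the control shares with the WT reporter —
#' reporter artifacts, plasmid copy number, strain-specific expression —
#' leaving only riboswitch-driven (ligand-dependent) signal.
#'
#' @param wt,g31c Per-strain tables from \code{\link{combine_replicates}}
#'   for the WT and control reporter screens.
#' @return A \code{data.frame} of class \code{expression_index}:
#'   \code{strain_id}, \code{wt_mean}, \code{wt_sd}, \code{ctrl_mean},
#'   \code{ctrl_sd}, \code{index} (median 1; NA with \code{reason} when a
#'   strain is missing on either side), \code{n_replicates}.
#' @export
control_normalize <- function(wt, g31c) {
  ids <- union(wt$strain_id, g31c$strain_id)
  if (!length(intersect(wt$strain_id, g31c$strain_id)))
    stopf("WT and control screens share no strains")
  iw <- match(ids, wt$strain_id); ic <- match(ids, g31c$strain_id)
  wt_mean <- wt$mean[iw]; ctrl_mean <- g31c$mean[ic]
  index <- ifelse(!is.na(wt_mean) & !is.na(ctrl_mean) & ctrl_mean > 0,
                  wt_mean / ctrl_mean, NA_real_)
  med <- stats::median(index, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) stopf("index distribution is degenerate")
  out <- data.frame(
    strain_id = ids,
    wt_mean = wt_mean, wt_sd = wt$sd[iw],
    ctrl_mean = ctrl_mean, ctrl_sd = g31c$sd[ic],
    index = index / med,
    n_replicates = pmin(ifelse(is.na(iw), 0L, wt$n[iw]),
                        ifelse(is.na(ic), 0L, g31c$n[ic])),
    reason = ifelse(is.na(wt_mean), "missing in WT",
                    ifelse(is.na(ctrl_mean), "missing in control",
                           ifelse(ctrl_mean <= 0, "non-positive control", ""))),
    stringsAsFactors = FALSE
  )
  class(out) <- c("expression_index", "data.frame")
  out
}

#' Call screen hits beyond 1 +/- k SD
#'
#' Strains whose expression index lies at least \code{threshold_k}
#' population SDs above or below the centre (1) are called. Because the
#' biosensor is an OFF switch, a high-fluorescence index means low
#' intracellular ligand (\code{HIGH_FLUOR}) and a low index means high
#' ligand (\code{LOW_FLUOR}). Ties exactly at the threshold are included.
#'
#' The population scale is estimated robustly by default
#' (median/MAD over the full index distribution), so a handful of strong
#' hits does not inflate the threshold; the classical SD is available via
#' \code{sd_method = "sd"}.
#'
#' @param index_table A \code{\link{control_normalize}} output.
#' @param threshold_k SD multiplier (default 5).
#' @param sd_method \code{"mad"} (default, robust) or \code{"sd"}.
#' @return A \code{data.frame} of class \code{hit_calls}:
#'   \code{strain_id}, \code{index}, \code{sd_distance}
#'   (\code{(index - 1)/SD_pop}), \code{direction} (\code{HIGH_FLUOR} =
#'   low ligand, \code{LOW_FLUOR} = high ligand), \code{threshold_k};
#'   sorted by \code{|sd_distance|} descending. Attributes \code{sd_pop}
#'   and \code{n_scored} record the scale used.
#' @export
call_hits <- function(index_table, threshold_k = 5, sd_method = c("mad", "sd")) {
  sd_method <- match.arg(sd_method)
  if (threshold_k <= 0) stopf("threshold_k must be > 0")
  idx <- index_table$index
  ok <- !is.na(idx)
  if (sum(ok) < 10)
    stopf("only %d defined indices; at least 10 needed for a meaningful SD",
          sum(ok))
  sd_pop <- if (sd_method == "mad") stats::mad(idx[ok]) else stats::sd(idx[ok])
  if (!is.finite(sd_pop) || sd_pop == 0)
    stopf("degenerate index distribution: population SD is 0")
  dist <- (idx - 1) / sd_pop
  hit <- ok & abs(dist) >= threshold_k
  out <- data.frame(
    strain_id = index_table$strain_id[hit],
    index = idx[hit],
    sd_distance = dist[hit],
    direction = ifelse(dist[hit] > 0, "HIGH_FLUOR", "LOW_FLUOR"),
    threshold_k = rep(threshold_k, sum(hit)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-abs(out$sd_distance)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sd_pop") <- sd_pop
  attr(out, "sd_method") <- sd_method
  attr(out, "n_scored") <- sum(ok)
  class(out) <- c("hit_calls", "data.frame")
  out
}

#' @export
print.hit_calls <- function(x, ...) {
  cat(sprintf("hit_calls: %d hits (%d HIGH_FLUOR / %d LOW_FLUOR) at 1 +/- %g x SD (SD_pop = %.4g, %s, n = %d)\n",
              nrow(x), sum(x$direction == "HIGH_FLUOR"),
              sum(x$direction == "LOW_FLUOR"),
              x$threshold_k[1] %||% NA, attr(x, "sd_pop"),
              attr(x, "sd_method"), attr(x, "n_scored")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Concordance of duplicated internal-control strains
#'
#' Strains pinned at two positions act as an internal control of
#' measurement robustness: for each duplicated strain the pair of
#' corrected ratios (un-averaged) is compared via its log2 difference.
#'
#' @param records One replicate's record table, or a list of them (each
#'   analyzed separately).
#' @param map The \code{\link{generate_plate_map}} layout (identifies the
#'   duplicated strains).
#' @return A list of class \code{duplicate_concordance}: \code{pairs}
#'   (replicate, strain, both values, \code{log2_diff}) and
#'   \code{summary} (\code{n_pairs}, \code{median_abs_log2},
#'   \code{frac_within_1.5x}). Zero duplicates yields an empty result
#'   with a warning.
#' @export
duplicate_concordance <- function(records, map) {
  tab <- table(map$strain_id[map$strain_id != "EMPTY"])
  dup_ids <- names(tab)[tab == 2L]
  if (!length(dup_ids)) {
    warning("map contains no duplicated strains", call. = FALSE)
    return(structure(list(pairs = data.frame(), summary = list(n_pairs = 0L)),
                     class = "duplicate_concordance"))
  }
  if (is.data.frame(records)) records <- list(records)
  pairs <- do.call(rbind, lapply(seq_along(records), function(k) {
    r <- records[[k]]
    r <- r[!r$excluded & r$strain_id %in% dup_ids, ]
    ok <- names(which(table(r$strain_id) == 2L))
    if (!length(ok)) return(NULL)
    do.call(rbind, lapply(ok, function(s) {
      v <- r$ratio_corrected[r$strain_id == s]
      data.frame(replicate = k, strain_id = s,
                 value_1 = v[1], value_2 = v[2],
                 log2_diff = log2(v[1] / v[2]), stringsAsFactors = FALSE)
    }))
  }))
  structure(list(
    pairs = pairs,
    summary = list(
      n_pairs = nrow(pairs),
      median_abs_log2 = stats::median(abs(pairs$log2_diff)),
      frac_within_1.5x = mean(abs(pairs$log2_diff) <= log2(1.5))
    )
  ), class = "duplicate_concordance")
}

#' @export
print.duplicate_concordance <- function(x, ...) {
  s <- x$summary
  if (!s$n_pairs) { cat("duplicate_concordance: no pairs\n"); return(invisible(x)) }
  cat(sprintf("duplicate_concordance: %d pairs, median |log2 diff| %.3f, %.1f%% within 1.5-fold\n",
              s$n_pairs, s$median_abs_log2, 100 * s$frac_within_1.5x))
  invisible(x)
}

#' Pearson correlation between replicate screens
#'
#' Pairwise Pearson correlation of per-strain values over the strains
#' shared (and defined) between each pair of replicates — the screen's
#' reproducibility readout.
#'
#' @param tables A list of >= 2 per-strain tables
#'   (\code{\link{per_strain_means}} outputs, or any data.frames with
#'   \code{strain_id} and a \code{value} or \code{mean} column).
#' @return A symmetric correlation matrix.
#' @export
replicate_pearson <- function(tables) {
  if (length(tables) < 2) stopf("need at least 2 replicate tables")
  vals <- lapply(tables, function(t) {
    v <- if ("value" %in% names(t)) t$value else t$mean
    stats::setNames(v, t$strain_id)
  })
  k <- length(vals)
  r <- diag(1, k)
  dimnames(r) <- list(paste0("rep", seq_len(k)), paste0("rep", seq_len(k)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    shared <- intersect(names(vals[[i]]), names(vals[[j]]))
    a <- vals[[i]][shared]; b <- vals[[j]][shared]
    def <- !is.na(a) & !is.na(b)
    if (sum(def) < 3)
      stopf("replicates %d and %d share only %d defined strains (>= 3 needed)",
            i, j, sum(def))
    r[i, j] <- r[j, i] <- stats::cor(a[def], b[def])
  }
  r
}

#' Write screen result artifacts
#'
#' Writes the index table, HIGH/LOW hit lists (sorted by
#' \code{|sd_distance|}), the unscored-strain list, per-plate heatmap
#' matrices (CSV) and heatmap/index-plot PNGs.
#'
#' @param index_table \code{\link{control_normalize}} output.
#' @param hits \code{\link{call_hits}} output.
#' @param records Optional record table (any number of plates) used for
#'   the per-plate heatmaps of corrected ratios.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_outputs <- function(index_table, hits, records = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name); write_table(df, p); files <<- c(files, p); p
  }
  wr(index_table, "index.csv")
  hi <- hits[hits$direction == "HIGH_FLUOR", , drop = FALSE]
  lo <- hits[hits$direction == "LOW_FLUOR", , drop = FALSE]
  wr(hi, "hits_high.csv")
  wr(lo, "hits_low.csv")
  wr(index_table[is.na(index_table$index), , drop = FALSE], "unscored.csv")

  sd_pop <- attr(hits, "sd_pop")
  k <- if (nrow(hits)) hits$threshold_k[1] else 5
  p <- file.path(out_dir, "index_plot.png")
  grDevices::png(p, width = 900, height = 500)
  ok <- !is.na(index_table$index)
  graphics::plot(seq_len(sum(ok)), sort(index_table$index[ok]),
                 pch = 16, cex = 0.4, col = "grey30",
                 xlab = "strain (ordered by index)", ylab = "expression index",
                 main = sprintf("Expression index (1 +/- %g SD)", k))
  graphics::abline(h = c(1 - k * sd_pop, 1, 1 + k * sd_pop),
                   lty = c(2, 1, 2), col = c("red", "grey", "red"))
  grDevices::dev.off()
  files <- c(files, p)

  if (!is.null(records)) {
    for (pl in unique(records$plate_id)) {
      r <- records[records$plate_id == pl, ]
      mat <- matrix(NA_real_, max(r$row), max(r$col))
      mat[cbind(r$row, r$col)] <- r$ratio_corrected
      mdf <- as.data.frame(mat)
      names(mdf) <- paste0("col", seq_len(ncol(mat)))
      files <- c(files, wr(mdf, sprintf("heatmap_%s.csv", pl)))
      png_path <- file.path(out_dir, sprintf("heatmap_%s.png", pl))
      grDevices::png(png_path, width = 720, height = 500)
      graphics::image(t(mat[nrow(mat):1, ]), axes = FALSE, useRaster = TRUE,
                      col = grDevices::hcl.colors(64, "viridis"),
                      main = sprintf("Corrected ratio, %s", pl))
      grDevices::dev.off()
      files <- c(files, png_path)
    }
  }
  invisible(unique(files))
}
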