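#' Blank-correct plate-reader curves
#'
#' Subtracts, at each time point, the median reading of the blank wells
#' from every sample well (OD600 and fluorescence independently), clipping
#' negatives at 0. Blank wells are dropped from the output.
#'
#' @param curves A long-format curve table (see
#'   \code{\link{simulate_growth_curves}} for columns).
#' @return The blank-corrected non-blank wells.
#' @export
blank_correct <- function(curves) {
  if (!any(curves$is_blank))
    stopf("no blank wells in the curve set; blank correction impossible")
  bl <- curves[curves$is_blank, ]
  bo <- stats::aggregate(od600 ~ time_h, bl, stats::median)
  bf <- stats::aggregate(fluor ~ time_h, bl, stats::median)
  out <- curves[!curves$is_blank, , drop = FALSE]
  out$od600 <- pmax(out$od600 - bo$od600[match(out$time_h, bo$time_h)], 0)
  out$fluor <- pmax(out$fluor - bf$fluor[match(out$time_h, bf$time_h)], 0)
  out
}

#' Pointwise fluorescence/OD ratio of one well
#'
#' @param curve Blank-corrected rows of a single well (columns
#'   \code{time_h}, \code{od600}, \code{fluor}).
#' @param od_floor OD below which the ratio is undefined (default 0.02;
#'   avoids blank-noise blow-up early in growth).
#' @return A \code{data.frame}: \code{time_h}, \code{f_over_od} (NA where
#'   OD is below the floor).
#' @export
ratio_curve <- function(curve, od_floor = 0.02) {
  data.frame(
    time_h = curve$time_h,
    f_over_od = ifelse(curve$od600 >= od_floor,
                       curve$fluor / curve$od600, NA_real_)
  )
}

#' Exponential-phase midpoint of a growth curve
#'
#' The time at which the blank-corrected OD first crosses half of its
#' maximal amplitude, \code{(OD_min + OD_max)/2}, with linear
#' interpolation between samples. For a symmetric logistic starting near
#' zero this is the inflection time.
#'
#' @param time_h,od Time (hours) and blank-corrected OD series of one
#'   well; \code{time_h} may be a one-well curve \code{data.frame}.
#' @return Midpoint time in hours.
#' @export
exponential_midpoint <- function(time_h, od = NULL) {
  if (is.data.frame(time_h)) { od <- time_h$od600; time_h <- time_h$time_h }
  stopifnot(length(time_h) == length(od), !is.unsorted(time_h))
  lo <- min(od); hi <- max(od)
  noise <- stats::sd(diff(od)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  # robust amplitude: the 5-95% spread of a pure-noise well stays below
  # 5 x the point noise, while a real growth curve far exceeds it
  amp <- diff(stats::quantile(od, c(0.05, 0.95), names = FALSE))
  if (amp <= 5 * noise)
    stopf(paste0("no growth plateau: OD amplitude %.4g is within noise ",
                 "(%.4g); cannot locate the exponential midpoint"),
          amp, noise)
  half <- (lo + hi) / 2
  above <- which(od >= half)
  i <- above[1]
  if (i == 1) return(time_h[1])
  # linear interpolation on the crossing segment
  t0 <- time_h[i - 1]; t1 <- time_h[i]
  y0 <- od[i - 1]; y1 <- od[i]
  t0 + (half - y0) / (y1 - y0) * (t1 - t0)
}

#' Expression values at the exponential and stationary phase points
#'
#' Interpolates the F/OD series at the exponential midpoint and at the
#' stationary time (16 h of growth by default).
#'
#' @param ratio_series A \code{\link{ratio_curve}} output.
#' @param midpoint Exponential midpoint in hours
#'   (\code{\link{exponential_midpoint}}).
#' @param stationary_t Stationary readout time in hours (default 16).
#' @return Named numeric: \code{exponential}, \code{stationary}.
#' @export
phase_values <- function(ratio_series, midpoint, stationary_t = 16) {
  tmax <- max(ratio_series$time_h)
  if (tmax < stationary_t)
    stopf("series ends at %.2f h but the stationary readout is at %g h",
          tmax, stationary_t)
  ok <- !is.na(ratio_series$f_over_od)
  at <- function(t) stats::approx(ratio_series$time_h[ok],
                                  ratio_series$f_over_od[ok], xout = t,
                                  rule = 2)$y
  c(exponential = at(midpoint), stationary = at(stationary_t))
}

#' Fold regulation against the no-ligand reference
#'
#' Normalizes each condition's F/OD value to the no-ligand reference
#' (normalized expression; reference is exactly 1) and reports the
#' reciprocal as fold regulation — larger values mean stronger
#' repression of the OFF switch.
#'
#' @param values A \code{data.frame} with columns \code{condition_molar},
#'   \code{phase} (\code{"EXPONENTIAL"}/\code{"STATIONARY"}) and
#'   \code{f_over_od} (optionally \code{construct}).
#' @param reference Reference ligand concentration (default 0, no ligand).
#' @return The input of class \code{regulation_result} with
#'   \code{normalized_expression} and \code{fold_regulation} columns.
#' @export
fold_regulation <- function(values, reference = 0) {
  req <- c("condition_molar", "phase", "f_over_od")
  if (!all(req %in% names(values)))
    stopf("values lack columns: %s",
          paste(setdiff(req, names(values)), collapse = ", "))
  values$construct <- values$construct %||% "construct"
  out <- values
  out$normalized_expression <- NA_real_
  for (con in unique(values$construct)) for (ph in unique(values$phase)) {
    sel <- values$construct == con & values$phase == ph
    ref <- values$f_over_od[sel & values$condition_molar == reference]
    if (!length(ref))
      stopf("no reference condition (%g M) for construct %s, phase %s",
            reference, con, ph)
    ref <- mean(ref)
    if (!is.finite(ref) || ref == 0)
      stopf("reference F/OD is 0 for construct %s, phase %s", con, ph)
    out$normalized_expression[sel] <- values$f_over_od[sel] / ref
  }
  out$fold_regulation <- 1 / out$normalized_expression
  class(out) <- c("regulation_result", "data.frame")
  out
}

#' Dose-response summary of a ligand titration
#'
#' Orders the normalized expression of one phase by ligand concentration
#' and summarizes the titration: maximal repression, the lowest
#' concentration reaching >= 90\% of it (saturation onset), an estimate
#' of the half-repression concentration (log-linear interpolation), and
#' the number of isotonic violations (increases of expression with
#' concentration, which a pure OFF switch should not show).
#'
#' @param results A \code{\link{fold_regulation}} output (or a data.frame
#'   with \code{condition_molar} and \code{normalized_expression}).
#' @param phase Which phase to summarize when a \code{phase} column is
#'   present (default \code{"STATIONARY"}).
#' @param flat_tol Repression below which the response is considered flat
#'   and the saturation/half-repression flags are undefined (default
#'   0.05).
#' @return A list of class \code{dose_response}: \code{table} (one row
#'   per concentration), \code{max_repression},
#'   \code{saturating_conc} (NA when flat), \code{half_repression_conc}
#'   (NA when flat), \code{isotonic_violations}.
#' @export
dose_response <- function(results, phase = "STATIONARY", flat_tol = 0.05) {
  r <- results
  if ("phase" %in% names(r)) r <- r[r$phase == phase, , drop = FALSE]
  agg <- stats::aggregate(normalized_expression ~ condition_molar, r, mean)
  agg <- agg[order(agg$condition_molar), , drop = FALSE]
  if (nrow(agg) < 3) stopf("dose-response needs >= 3 concentrations, got %d",
                           nrow(agg))
  agg$repression <- 1 - agg$normalized_expression
  max_rep <- max(agg$repression)
  flat <- max_rep < flat_tol
  sat <- if (flat) NA_real_ else
    min(agg$condition_molar[agg$repression >= 0.9 * max_rep])
  half <- NA_real_
  if (!flat) {
    # first crossing of half-maximal repression, interpolated in log10(c)
    pos <- agg[agg$condition_molar > 0, , drop = FALSE]
    target <- max_rep / 2
    ix <- which(pos$repression >= target)[1]
    if (!is.na(ix)) {
      if (ix == 1) half <- pos$condition_molar[1]
      else {
        l0 <- log10(pos$condition_molar[ix - 1]); l1 <- log10(pos$condition_molar[ix])
        y0 <- pos$repression[ix - 1]; y1 <- pos$repression[ix]
        half <- 10^(l0 + (target - y0) / (y1 - y0) * (l1 - l0))
      }
    }
  }
  structure(list(
    table = agg,
    max_repression = max_rep,
    saturating_conc = sat,
    half_repression_conc = half,
    isotonic_violations = sum(diff(agg$normalized_expression) > 0)
  ), class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("dose_response: max repression %.2f, 90%%-saturation at %s M, half-repression ~%s M, %d isotonic violations\n",
              x$max_repression,
              format(x$saturating_conc), format(x$half_repression_conc),
              x$isotonic_violations))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Full kinetics analysis of one curve set
#'
#' Convenience wrapper: blank-correct, compute per-well F/OD, locate each
#' well's exponential midpoint, read phase values, average technical
#' wells per condition, and compute fold regulation for both phases.
#'
#' @param curves A raw curve table with blanks.
#' @param reference Reference concentration (default 0).
#' @param stationary_t Stationary readout time (default 16 h).
#' @param od_floor OD floor for the ratio (default 0.02).
#' @return A \code{\link{fold_regulation}} table with one row per
#'   construct x condition x phase.
#' @export
analyze_kinetics <- function(curves, reference = 0, stationary_t = 16,
                             od_floor = 0.02) {
  cc <- blank_correct(curves)
  per_well <- do.call(rbind, lapply(split(cc, cc$well), function(w) {
    w <- w[order(w$time_h), ]
    mid <- exponential_midpoint(w$time_h, w$od600)
    pv <- phase_values(ratio_curve(w, od_floor), mid, stationary_t)
    data.frame(construct = w$construct[1],
               condition_molar = w$condition_molar[1],
               well = w$well[1], midpoint_h = mid,
               EXPONENTIAL = pv[["exponential"]],
               STATIONARY = pv[["stationary"]], stringsAsFactors = FALSE)
  }))
  long <- rbind(
    data.frame(construct = per_well$construct,
               condition_molar = per_well$condition_molar,
               phase = "EXPONENTIAL", f_over_od = per_well$EXPONENTIAL),
    data.frame(construct = per_well$construct,
               condition_molar = per_well$condition_molar,
               phase = "STATIONARY", f_over_od = per_well$STATIONARY)
  )
  agg <- stats::aggregate(f_over_od ~ construct + condition_molar + phase,
                          long, mean)
  fold_regulation(agg, reference = reference)
}
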