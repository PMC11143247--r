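#' Planted ground truth for a synthetic colony-array screen
#'
#' Defines the generative model for a two-reporter (wild-type riboswitch
#' vs. ligand-blind binding-mutant control) colony screen with planted
#' effects:
#' \itemize{
#'   \item \emph{riboswitch effects}: multiplicative fluorescence factors
#'     applied to the WT reporter only. Because the sensor is an OFF
#'     switch, a factor > 1 emulates a strain with low intracellular
#'     ligand (de-repressed reporter) and a factor < 1 a strain with high
#'     ligand.
#'   \item \emph{artifact effects}: multiplicative fluorescence factors
#'     applied to BOTH reporters (e.g. reporter-plasmid copy-number
#'     perturbations); these must cancel in the control-normalized index.
#'   \item a per-strain \emph{baseline} expression factor shared by both
#'     reporters (strain-to-strain reporter heterogeneity).
#'   \item a multiplicative spatial \emph{edge gradient} (border /
#'     incubator effect) and lognormal colony-to-colony noise.
#' }
#' The biomass channel carries a growth gradient of amplitude
#' \code{gradient_amplitude_biomass}; the fluorescence channel carries that
#' same growth gradient multiplied by an extra edge gradient of amplitude
#' \code{edge_amplitude}, so the planted fluorescence/biomass ratio carries
#' a net border gradient of exactly \code{edge_amplitude}.
#'
#' @param map A \code{\link{generate_plate_map}} result naming the strains.
#' @param n_high,n_low Number of strains planted with fluorescence-up
#'   (low-ligand) and fluorescence-down (high-ligand) riboswitch effects.
#' @param n_artifact Number of strains planted with reporter artifacts.
#' @param high_range,low_range Ranges the riboswitch effect factors are
#'   drawn from (uniform).
#' @param edge_amplitude Net border-ring gradient of the
#'   fluorescence/biomass ratio (1 = no edge effect).
#' @param gradient_amplitude_biomass Border gradient of colony biomass.
#' @param noise_cv Lognormal coefficient of variation of per-colony
#'   biomass and fluorescence totals (technical/pinning noise).
#' @param strain_cv Lognormal CV of the per-strain baseline expression
#'   factor shared by both reporters.
#' @param read_noise_sd Additive Gaussian pixel read noise used when
#'   rendering images (instrument counts).
#' @param seed Integer seed for the planted-effect draws.
#' @return An object of class \code{screen_truth}: a list with a
#'   \code{strains} data.frame (\code{strain_id}, \code{riboswitch_effect},
#'   \code{artifact_effect}, \code{baseline_effect}) and the generative
#'   parameters.
#' @export
screen_truth <- function(map, n_high = 22L, n_low = 4L, n_artifact = 10L,
                         high_range = c(3, 6), low_range = c(0.2, 0.4),
                         edge_amplitude = 1.5,
                         gradient_amplitude_biomass = 1.2,
                         noise_cv = 0.1, strain_cv = 0.35,
                         read_noise_sd = 2, seed = 1L) {
  stopifnot(inherits(map, "plate_map"))
  ids <- setdiff(unique(map$strain_id), "EMPTY")
  if (n_high + n_low + n_artifact > length(ids))
    stopf("more planted strains (%d) than strains in the map (%d)",
          n_high + n_low + n_artifact, length(ids))
  if (edge_amplitude <= 0 || gradient_amplitude_biomass <= 0)
    stopf("gradient amplitudes must be > 0")
  if (noise_cv < 0 || strain_cv < 0) stopf("CVs must be >= 0")

  strains <- with_seed(seed, {
    picked <- sample(ids, n_high + n_low + n_artifact)
    high_ids <- picked[seq_len(n_high)]
    low_ids  <- picked[n_high + seq_len(n_low)]
    art_ids  <- picked[n_high + n_low + seq_len(n_artifact)]
    ribo <- stats::setNames(rep(1, length(ids)), ids)
    ribo[high_ids] <- stats::runif(n_high, high_range[1], high_range[2])
    ribo[low_ids]  <- stats::runif(n_low, low_range[1], low_range[2])
    art <- stats::setNames(rep(1, length(ids)), ids)
    if (n_artifact > 0) {
      up <- stats::runif(n_artifact) < 0.5
      art[art_ids] <- ifelse(up, stats::runif(n_artifact, 3, 6),
                             stats::runif(n_artifact, 0.15, 0.4))
    }
    data.frame(
      strain_id = ids,
      riboswitch_effect = unname(ribo),
      artifact_effect = unname(art),
      baseline_effect = rlnorm_cv(length(ids), strain_cv),
      stringsAsFactors = FALSE
    )
  })
  structure(list(
    strains = strains,
    high_strains = strains$strain_id[strains$riboswitch_effect > 1],
    low_strains  = strains$strain_id[strains$riboswitch_effect < 1],
    artifact_strains = strains$strain_id[strains$artifact_effect != 1],
    edge_amplitude = edge_amplitude,
    gradient_amplitude_biomass = gradient_amplitude_biomass,
    noise_cv = noise_cv, strain_cv = strain_cv,
    base_biomass = 3e4, base_fluor = 2e4,
    background_level = 200, read_noise_sd = read_noise_sd,
    seed = seed
  ), class = "screen_truth")
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf(paste0("screen_truth: %d strains; planted %d fluorescence-up, ",
                     "%d fluorescence-down, %d artifact; edge gradient %.2fx; ",
                     "noise CV %.2f (seed %d)\n"),
              nrow(x$strains), length(x$high_strains), length(x$low_strains),
              length(x$artifact_strains), x$edge_amplitude, x$noise_cv, x$seed))
  invisible(x)
}

# Multiplicative border gradient over the grid: amplitude at the border
# ring, cosine-decaying to 1 at >= decay_cells rows/cols inward.
edge_gradient_factor <- function(row, col, n_rows, n_cols, amplitude,
                                 decay_cells = 4) {
  d <- pmin(edge_distance(row, col, n_rows, n_cols), decay_cells)
  1 + (amplitude - 1) * (cos(pi * d / decay_cells) + 1) / 2
}

#' Border-gradient matrix for a plate grid
#'
#' The multiplicative edge-effect surface used by the synthetic screen:
#' \code{amplitude} at the border ring, smoothly (half-cosine) decaying to
#' 1 at \code{decay_cells} rows/columns inward.
#'
#' @param spec A \code{\link{plate_spec}}.
#' @param amplitude Multiplier at the border ring.
#' @param decay_cells Rows/columns over which the gradient decays to 1.
#' @return An \code{n_rows x n_cols} matrix.
#' @export
edge_gradient <- function(spec, amplitude, decay_cells = 4) {
  outer(seq_len(spec$n_rows), seq_len(spec$n_cols), function(r, c)
    edge_gradient_factor(r, c, spec$n_rows, spec$n_cols, amplitude, decay_cells))
}

# Planted per-colony totals for one plate of one reporter at one timepoint.
# This is the shared generative core: the image renderer draws colonies at
# exactly these totals, and the measurement-level simulator returns them
# directly.
planted_colony_totals <- function(map_plate, spec, truth, reporter, timepoint,
                                  seed) {
  reporter <- match.arg(reporter, c("WT", "G31C"))
  timepoint <- match.arg(timepoint, c("24h", "4h"))
  st <- truth$strains
  idx <- match(map_plate$strain_id, st$strain_id)
  is_empty <- map_plate$strain_id == "EMPTY"
  ribo <- ifelse(is_empty, 0, st$riboswitch_effect[idx])
  if (reporter == "G31C") ribo[!is_empty] <- 1   # ligand-blind control
  art  <- ifelse(is_empty, 0, st$artifact_effect[idx])
  base <- ifelse(is_empty, 0, st$baseline_effect[idx])

  g_bio <- edge_gradient_factor(map_plate$row, map_plate$col,
                                spec$n_rows, spec$n_cols,
                                truth$gradient_amplitude_biomass)
  g_edge <- edge_gradient_factor(map_plate$row, map_plate$col,
                                 spec$n_rows, spec$n_cols,
                                 truth$edge_amplitude)
  scale_t <- if (timepoint == "4h") 0.15 else 1

  with_seed(seed, {
    n <- nrow(map_plate)
    # pinning/colony-size noise is shared between channels: the colony's
    # integrated fluorescence scales with its biomass, and cancelling that
    # shared part is precisely what the fluorescence/biomass ratio is for;
    # expression noise is fluorescence-specific
    noise_b <- rlnorm_cv(n, truth$noise_cv)
    noise_e <- rlnorm_cv(n, truth$noise_cv)
    data.frame(
      plate = map_plate$plate, row = map_plate$row, col = map_plate$col,
      strain_id = map_plate$strain_id,
      planted_biomass = ifelse(is_empty, 0,
        truth$base_biomass * scale_t * g_bio * noise_b),
      planted_fluor = ifelse(is_empty, 0,
        truth$base_fluor * scale_t * ribo * art * base * g_bio * g_edge *
          noise_b * noise_e),
      planted_ratio_gradient = g_edge,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate paired colony-array images with planted truth
#'
#' Renders one plate of a synthetic screen as a registered white-light
#' (biomass) / fluorescence image pair. Colonies are Gaussian-profile
#' disks centred on the grid nodes whose \emph{integrated} intensity
#' equals the planted per-colony total exactly; radius scales with the
#' square root of biomass. A flat background level (optionally tilted by
#' \code{background_tilt}) and Gaussian pixel read noise are added, and
#' pixels are quantized and clipped to the bit depth.
#'
#' @param map A \code{\link{generate_plate_map}} result (one plate of it
#'   is rendered, see \code{plate}).
#' @param spec A \code{\link{plate_spec}}.
#' @param truth A \code{\link{screen_truth}}.
#' @param reporter \code{"WT"} or \code{"G31C"} (the control reporter
#'   ignores planted riboswitch effects but keeps artifacts).
#' @param timepoint \code{"24h"} (screen readout) or \code{"4h"} (early
#'   growth QC).
#' @param plate Which plate of the map to render.
#' @param seed Integer seed (colonies and pixels).
#' @param replicate_id Label stored on the image pair.
#' @param background_tilt Length-2 fractional gradient of the background
#'   level across image height and width (planted planar background).
#' @param offset_px Length-2 (y, x) pixel translation of the whole grid,
#'   for testing grid-detection robustness.
#' @return A list of class \code{plate_image_pair}: \code{biomass_image}
#'   and \code{fluor_image} (matrices in instrument counts), metadata, and
#'   \code{truth} — the per-colony planted totals table.
#' @export
simulate_colony_plates <- function(map, spec, truth, reporter = "WT",
                                   timepoint = "24h", plate = 1L, seed = 1L,
                                   replicate_id = "rep1",
                                   background_tilt = c(0, 0),
                                   offset_px = c(0, 0)) {
  stopifnot(inherits(map, "plate_map"), inherits(spec, "plate_spec"),
            inherits(truth, "screen_truth"))
  map_plate <- map[map$plate == plate, , drop = FALSE]
  if (nrow(map_plate) != spec$density)
    stopf("plate %s of the map has %d positions, spec expects %d",
          plate, nrow(map_plate), spec$density)
  totals <- planted_colony_totals(map_plate, spec, truth, reporter, timepoint,
                                  seed = child_seed(seed, 1))
  maxval <- 2^spec$bit_depth - 1

  render_channel <- function(colony_totals, pix_seed) {
    img <- matrix(0, spec$image_height, spec$image_width)
    # background level with optional planar tilt
    bg <- truth$background_level *
      (1 + background_tilt[1] * (row(img) - 1) / (nrow(img) - 1) +
           background_tilt[2] * (col(img) - 1) / (ncol(img) - 1))
    # tight profile: 3.5 sigma stays inside the half-pitch so neighboring
    # ROIs see essentially no cross-talk and the inter-colony floor stays
    # at the true background
    sigma0 <- 0.14 * spec$pitch_px
    cy <- spec$margin_px + (map_plate$row - 1) * spec$pitch_px + offset_px[1]
    cx <- spec$margin_px + (map_plate$col - 1) * spec$pitch_px + offset_px[2]
    bio <- totals$planted_biomass
    for (i in seq_len(nrow(map_plate))) {
      tot <- colony_totals[i]
      if (tot <= 0) next
      # radius tracks biomass so integrated intensity scales with colony size
      sigma <- sigma0 * sqrt(max(bio[i], 1e-9) / truth$base_biomass)
      h <- min(ceiling(3.5 * sigma), floor(spec$pitch_px / 2))
      ys <- max(1, round(cy[i]) + 1 - h):min(nrow(img), round(cy[i]) + 1 + h)
      xs <- max(1, round(cx[i]) + 1 - h):min(ncol(img), round(cx[i]) + 1 + h)
      ky <- exp(-((ys - 1 - cy[i])^2) / (2 * sigma^2))
      kx <- exp(-((xs - 1 - cx[i])^2) / (2 * sigma^2))
      kern <- outer(ky, kx)
      img[ys, xs] <- img[ys, xs] + kern * (tot / sum(kern))
    }
    with_seed(pix_seed, {
      img <- img + bg +
        matrix(stats::rnorm(length(img), 0, truth$read_noise_sd),
               nrow(img), ncol(img))
    })
    matrix(pmin(pmax(round(img), 0), maxval), nrow(img), ncol(img))
  }

  structure(list(
    biomass_image = render_channel(totals$planted_biomass, child_seed(seed, 2)),
    fluor_image = render_channel(totals$planted_fluor, child_seed(seed, 3)),
    plate_id = sprintf("plate%s", plate),
    replicate_id = replicate_id, timepoint = timepoint, reporter = reporter,
    spec = spec, truth = totals
  ), class = "plate_image_pair")
}

#' @export
print.plate_image_pair <- function(x, ...) {
  cat(sprintf("plate_image_pair: %s %s %s %s, %d x %d px\n",
              x$plate_id, x$replicate_id, x$reporter, x$timepoint,
              nrow(x$biomass_image), ncol(x$biomass_image)))
  invisible(x)
}

#' Simulate a full multi-replicate two-reporter screen
#'
#' Generates the complete measurement layer of a synthetic screen: for
#' each biological replicate and each reporter (WT and G31C), per-colony
#' integrated biomass and fluorescence totals for every plate of the map,
#' drawn from the \code{\link{screen_truth}} generative model. With
#' \code{render = TRUE} the plates are additionally rendered to image
#' pairs and re-quantified through the image pipeline
#' (\code{\link{quantify_plate}}); with the default \code{render = FALSE}
#' the planted totals are returned directly as measurements, which is
#' statistically identical and fast enough for screen-scale simulation.
#'
#' @param map,spec,truth As in \code{\link{simulate_colony_plates}}.
#' @param n_replicates Biological replicates per reporter.
#' @param timepoint Screen readout timepoint.
#' @param seed Integer master seed.
#' @param render Render images and quantify them instead of emitting the
#'   planted totals directly.
#' @return A list of class \code{screen_sim} with elements \code{WT} and
#'   \code{G31C}, each a list of per-replicate measurement tables (see
#'   \code{\link{quantify_plate}} for columns), plus \code{map} and
#'   \code{truth}.
#' @export
simulate_screen <- function(map, spec, truth, n_replicates = 3L,
                            timepoint = "24h", seed = 1L, render = FALSE) {
  plates <- unique(map$plate)
  out <- list()
  for (rep_i in seq_len(n_replicates)) {
    for (reporter in c("WT", "G31C")) {
      tabs <- lapply(plates, function(p) {
        s <- child_seed(seed, 1000 * rep_i + 10 * p +
                          (if (reporter == "WT") 0 else 5))
        if (render) {
          pair <- simulate_colony_plates(map, spec, truth, reporter, timepoint,
                                         plate = p, seed = s,
                                         replicate_id = sprintf("rep%d", rep_i))
          quantify_plate(pair, map, spec)
        } else {
          tot <- planted_colony_totals(map[map$plate == p, , drop = FALSE],
                                       spec, truth, reporter, timepoint, s)
          data.frame(
            plate_id = sprintf("plate%d", p),
            replicate_id = sprintf("rep%d", rep_i),
            timepoint = timepoint, reporter = reporter,
            row = tot$row, col = tot$col, strain_id = tot$strain_id,
            biomass_sum = tot$planted_biomass,
            fluor_sum = tot$planted_fluor,
            roi_area = NA_real_,
            flags = ifelse(tot$strain_id == "EMPTY", "EMPTY", ""),
            stringsAsFactors = FALSE
          )
        }
      })
      out[[reporter]][[sprintf("rep%d", rep_i)]] <- do.call(rbind, tabs)
    }
  }
  structure(list(WT = out$WT, G31C = out$G31C, map = map, truth = truth,
                 seed = seed, timepoint = timepoint),
            class = "screen_sim")
}
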