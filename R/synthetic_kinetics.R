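#' Planted ground truth for plate-reader reporter kinetics
#'
#' Generative model for fluorescent-reporter growth curves under an
#' OFF-switch riboswitch: logistic growth
#' \deqn{OD(t) = K / (1 + ((K - od0)/od0) e^{-rt})}
#' and fluorescence accumulating proportionally to instantaneous biomass
#' under Hill-type ligand repression,
#' \deqn{dF/dt = \alpha \, OD(t) \left[leak + (1 - leak)\left(1 -
#'   E_{max} \frac{c^{n}}{K_{half}^{n} + c^{n}}\right)\right].}
#' At a fixed ligand concentration the repression term is constant, so the
#' asymptotic fold regulation (reference / condition of stationary F/OD)
#' is \eqn{1 / (1 - E_{max}(1 - leak) \cdot c^n/(K_{half}^n + c^n))}
#' — 2-fold at saturating ligand for the default
#' \code{E_max = 0.5, leak = 0}, matching a ~2-fold OFF switch.
#'
#' @param od0 Initial OD600 (default 0.02).
#' @param K Carrying-capacity OD (default 0.8).
#' @param r Growth rate per hour (default 0.9); the logistic inflection
#'   time \code{t_m = log((K - od0)/od0)/r} is derived, not free.
#' @param alpha Fluorescence production rate (AU per OD per hour).
#' @param E_max Maximal fractional repression at saturating ligand (0-1);
#'   0 emulates the ligand-blind G31C control.
#' @param K_half Ligand concentration of half repression (molar).
#' @param hill_n Hill coefficient.
#' @param leak Ligand-independent fraction of reporter output.
#' @param od_noise_sd,fluor_noise_sd Additive Gaussian measurement noise.
#' @param blank_od,blank_fluor Media blank offsets added to every reading.
#' @param seed Integer seed.
#' @return An object of class \code{kinetics_truth}.
#' @export
kinetics_truth <- function(od0 = 0.02, K = 0.8, r = 0.9, alpha = 1000,
                           E_max = 0.5, K_half = 1e-7, hill_n = 1,
                           leak = 0, od_noise_sd = 0.005,
                           fluor_noise_sd = 5, blank_od = 0.04,
                           blank_fluor = 50, seed = 1L) {
  if (E_max < 0 || E_max > 1) stopf("E_max must be in [0, 1]")
  if (!(K > od0 && od0 > 0)) stopf("need K > od0 > 0")
  if (r <= 0) stopf("growth rate r must be > 0")
  if (K_half <= 0) stopf("K_half must be > 0")
  if (leak < 0 || leak > 1) stopf("leak must be in [0, 1]")
  structure(list(od0 = od0, K = K, r = r,
                 t_m = log((K - od0) / od0) / r,
                 alpha = alpha, E_max = E_max, K_half = K_half,
                 hill_n = hill_n, leak = leak,
                 od_noise_sd = od_noise_sd, fluor_noise_sd = fluor_noise_sd,
                 blank_od = blank_od, blank_fluor = blank_fluor,
                 seed = seed),
            class = "kinetics_truth")
}

#' @export
print.kinetics_truth <- function(x, ...) {
  cat(sprintf(paste0("kinetics_truth: logistic OD (od0 %.3g, K %.3g, r %.3g/h, ",
                     "t_m %.2f h); Hill repression E_max %.2f, K_half %.3g M, ",
                     "n %.2f, leak %.2f\n"),
              x$od0, x$K, x$r, x$t_m, x$E_max, x$K_half, x$hill_n, x$leak))
  invisible(x)
}

# Noise-free model curves: OD(t) and accumulated fluorescence F(t) at
# ligand concentration c (closed-form integral of the logistic).
kinetics_model <- function(truth, time_h, conc) {
  C <- (truth$K - truth$od0) / truth$od0
  od <- truth$K / (1 + C * exp(-truth$r * time_h))
  hill <- if (conc > 0)
    conc^truth$hill_n / (truth$K_half^truth$hill_n + conc^truth$hill_n) else 0
  g <- truth$leak + (1 - truth$leak) * (1 - truth$E_max * hill)
  int_od <- (truth$K / truth$r) * (log(exp(truth$r * time_h) + C) - log(1 + C))
  list(od = od, fluor = truth$alpha * g * int_od, repression_factor = g)
}

#' Simulate plate-reader growth/fluorescence curves
#'
#' Emits a long-format well table emulating a kinetic plate-reader run
#' across a ligand titration: logistic OD600 and Hill-repressed reporter
#' fluorescence from \code{\link{kinetics_truth}}, plus media-blank
#' offsets, additive Gaussian measurement noise, and dedicated blank
#' wells.
#'
#' @param truth A \code{\link{kinetics_truth}}.
#' @param tpp_concs Ligand concentrations in molar (include 0 for the
#'   no-ligand reference).
#' @param t_end End of the run in hours (>= 16 for a stationary readout).
#' @param dt Sampling interval in hours (default 1/6 h = 10 min).
#' @param n_wells Technical-replicate wells per concentration.
#' @param n_blanks Number of blank wells.
#' @param construct Label stored on the wells.
#' @param seed Integer seed.
#' @return A \code{data.frame} of class \code{growth_curves}: \code{well},
#'   \code{construct}, \code{condition_molar}, \code{time_h},
#'   \code{od600}, \code{fluor}, \code{is_blank}.
#' @export
simulate_growth_curves <- function(truth,
                                   tpp_concs = c(0, 1e-8, 1e-7, 1e-6, 1e-5, 1e-3),
                                   t_end = 16, dt = 1/6, n_wells = 3L,
                                   n_blanks = 3L, construct = "thiC-gfp",
                                   seed = NULL) {
  stopifnot(inherits(truth, "kinetics_truth"))
  if (dt <= 0) stopf("sampling interval dt must be > 0, got %s", dt)
  seed <- seed %||% truth$seed
  time_h <- seq(0, t_end, by = dt)
  nt <- length(time_h)
  with_seed(seed, {
    rows <- list()
    wi <- 0L
    for (conc in tpp_concs) {
      mod <- kinetics_model(truth, time_h, conc)
      for (w in seq_len(n_wells)) {
        wi <- wi + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          well = sprintf("W%02d", wi), construct = construct,
          condition_molar = conc, time_h = time_h,
          od600 = mod$od + truth$blank_od +
            stats::rnorm(nt, 0, truth$od_noise_sd),
          fluor = mod$fluor + truth$blank_fluor +
            stats::rnorm(nt, 0, truth$fluor_noise_sd),
          is_blank = FALSE, stringsAsFactors = FALSE
        )
      }
    }
    for (b in seq_len(n_blanks)) {
      wi <- wi + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        well = sprintf("W%02d", wi), construct = "BLANK",
        condition_molar = NA_real_, time_h = time_h,
        od600 = truth$blank_od + stats::rnorm(nt, 0, truth$od_noise_sd),
        fluor = truth$blank_fluor + stats::rnorm(nt, 0, truth$fluor_noise_sd),
        is_blank = TRUE, stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- truth
    class(out) <- c("growth_curves", "data.frame")
    out
  })
}
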