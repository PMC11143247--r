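# Independent oracle for the reporter-accumulation model: numerically
# integrate dF/dt = alpha * OD(t) * g(c) with the trapezoid rule on a fine
# grid, never using the package's closed-form integral.
oracle_curves <- function(od0, K, r, alpha, g, t_end, dt) {
  tt <- seq(0, t_end, by = dt)
  C <- (K - od0) / od0
  od <- K / (1 + C * exp(-r * tt))
  f <- c(0, cumsum((od[-1] + od[-length(od)]) / 2 * diff(tt))) * alpha * g
  data.frame(time_h = tt, od600 = od, fluor = f)
}

test_that("simulated curves match the numerically integrated reporter model", {
  tr <- kinetics_truth(od_noise_sd = 0, fluor_noise_sd = 0,
                       blank_od = 0, blank_fluor = 0, seed = 41)
  cv <- simulate_growth_curves(tr, tpp_concs = c(0, 1e-3), n_wells = 1,
                               n_blanks = 1, seed = 41)
  for (conc in c(0, 1e-3)) {
    w <- cv[cv$condition_molar %in% conc & !cv$is_blank, ]
    g <- if (conc == 0) 1 else
      1 - tr$E_max * conc / (tr$K_half + conc)   # hill_n = 1
    orc <- oracle_curves(tr$od0, tr$K, tr$r, tr$alpha, g, 16, 0.002)
    expect_equal(w$od600,
                 stats::approx(orc$time_h, orc$od600, w$time_h)$y,
                 tolerance = 1e-5)
    expect_equal(w$fluor,
                 stats::approx(orc$time_h, orc$fluor, w$time_h)$y,
                 tolerance = 1e-4)
  }
  # stationary F/OD fold approaches 1/(1 - E_max) at saturating ligand
  f_od <- function(conc) {
    w <- cv[cv$condition_molar %in% conc & !cv$is_blank, ]
    tail(w$fluor / w$od600, 1)
  }
  expect_equal(f_od(0) / f_od(1e-3), 2.0, tolerance = 0.02)
})

test_that("sampling grid and determinism match the run design", {
  tr <- kinetics_truth(seed = 42)
  cv <- simulate_growth_curves(tr, t_end = 16, dt = 1/6, seed = 42)
  expect_equal(sum(cv$well == "W01"), 97L)        # 16 h at 10 min intervals
  cv2 <- simulate_growth_curves(tr, t_end = 16, dt = 1/6, seed = 42)
  expect_identical(cv, cv2)
  expect_error(simulate_growth_curves(tr, dt = 0), "dt")
  # ligand-blind truth: stationary F/OD flat in concentration up to noise
  tr0 <- kinetics_truth(E_max = 0, seed = 43)
  r0 <- analyze_kinetics(simulate_growth_curves(tr0, seed = 43))
  st <- r0[r0$phase == "STATIONARY", ]
  expect_lt(max(abs(st$fold_regulation - 1)), 0.05)
})

test_that("blank correction subtracts the time-matched blank median", {
  cv <- data.frame(
    well = rep(c("A", "BLK"), each = 3), construct = "x",
    condition_molar = c(0, 0, 0, NA, NA, NA), time_h = rep(0:2, 2),
    od600 = c(0.15, 0.2, 0.25, 0.05, 0.05, 0.05),
    fluor = c(100, 120, 150, 100, 120, 150),
    is_blank = rep(c(FALSE, TRUE), each = 3)
  )
  cc <- blank_correct(cv)
  expect_equal(cc$od600, c(0.10, 0.15, 0.20))
  expect_equal(cc$fluor, c(0, 0, 0))              # blank equals reading
  expect_false(any(cc$is_blank))
  expect_error(blank_correct(cv[!cv$is_blank, ]), "no blank")
  # planted blank offset is recovered within noise
  tr <- kinetics_truth(seed = 44)
  sim <- blank_correct(simulate_growth_curves(tr, tpp_concs = 0, seed = 44))
  w <- sim[sim$well == "W01", ]
  C <- (tr$K - tr$od0) / tr$od0
  planted <- tr$K / (1 + C * exp(-tr$r * w$time_h))
  expect_lt(stats::median(abs(w$od600 - planted)), 3 * tr$od_noise_sd)
})

test_that("the F/OD ratio is floored, linear in gain, and phase-readable", {
  w <- data.frame(time_h = 0:4, od600 = c(0.01, 0.02, 0.5, 1, 1),
                  fluor = c(5, 10, 500, 1000, 1500))
  rc <- ratio_curve(w, od_floor = 0.02)
  expect_true(is.na(rc$f_over_od[1]))             # below the OD floor
  expect_equal(rc$f_over_od[3], 1000)
  w2 <- w; w2$fluor <- w2$fluor * 2
  expect_equal(ratio_curve(w2)$f_over_od, rc$f_over_od * 2)
  # constant ratio reads the same value at both phase points
  flat <- data.frame(time_h = seq(0, 16, 0.5), f_over_od = 2)
  pv <- phase_values(flat, midpoint = 4)
  expect_equal(unname(pv), c(2, 2))
  expect_error(phase_values(flat[flat$time_h < 10, ], 4), "16")
})

test_that("the exponential midpoint is the half-amplitude crossing", {
  # ideal logistic starting near zero crosses half-amplitude at t_m
  tt <- seq(0, 16, 1/6)
  od0 <- 8e-4; K <- 0.8; r <- 0.9
  t_m <- log((K - od0) / od0) / r
  od <- K / (1 + ((K - od0) / od0) * exp(-r * tt))
  expect_equal(exponential_midpoint(tt, od), t_m, tolerance = 0.02)
  # monotone ramp 0 -> 1 over 10 h crosses at 5 h
  expect_equal(exponential_midpoint(seq(0, 10, 0.1), seq(0, 1, 0.01)), 5)
  # a flat well has no detectable plateau
  set.seed(45)
  expect_error(exponential_midpoint(tt, rnorm(length(tt), 0.05, 0.005)),
               "plateau")
  # noisy planted logistic: recovered within 0.25 h over 50 seeds
  tr <- kinetics_truth(od0 = 0.02, K = 0.8, r = log((0.8 - 0.02) / 0.02) / 4,
                       seed = 1)
  err <- vapply(1:50, function(s) {
    cc <- blank_correct(simulate_growth_curves(tr, tpp_concs = 0,
                                               n_wells = 1, seed = s))
    abs(exponential_midpoint(cc$time_h, cc$od600) - 4)
  }, numeric(1))
  expect_lt(max(err), 0.25)
})

test_that("fold regulation normalizes to the no-ligand reference", {
  v <- data.frame(condition_molar = c(0, 1e-3), phase = "STATIONARY",
                  f_over_od = c(1000, 500))
  fr <- fold_regulation(v)
  expect_equal(fr$normalized_expression, c(1, 0.5))
  expect_equal(fr$fold_regulation, c(1, 2))
  expect_equal(fr$fold_regulation, 1 / fr$normalized_expression)
  expect_error(fold_regulation(v[2, , drop = FALSE]), "no reference")
  expect_error(fold_regulation(transform(v, f_over_od = c(0, 1))), "0")
  # gain invariance: scaling all fluorescence leaves the fold unchanged
  tr <- kinetics_truth(seed = 46)
  cv <- simulate_growth_curves(tr, seed = 46)
  cv2 <- cv; cv2$fluor <- cv2$fluor * 3.7
  r1 <- analyze_kinetics(cv); r2 <- analyze_kinetics(cv2)
  expect_equal(r2$fold_regulation, r1$fold_regulation, tolerance = 1e-9)
})

test_that("dose-response summarizes saturation, EC50 and monotonicity", {
  tr <- kinetics_truth(K_half = 1e-7, seed = 47)
  reg <- analyze_kinetics(simulate_growth_curves(
    tr, tpp_concs = c(0, 1e-8, 3e-8, 1e-7, 1e-6, 1e-5), seed = 47))
  dr <- dose_response(reg)
  expect_lt(abs(log2(dr$half_repression_conc / 1e-7)), 1)   # within 2x
  expect_true(dr$saturating_conc %in% c(1e-6, 1e-5))
  # noise-free monotone response has zero isotonic violations
  clean <- data.frame(condition_molar = c(0, 1e-8, 1e-7, 1e-6),
                      phase = "STATIONARY",
                      normalized_expression = c(1, 0.9, 0.6, 0.5))
  dr2 <- dose_response(clean)
  expect_equal(dr2$isotonic_violations, 0L)
  # constant response: saturation undefined, reported as such
  flat <- data.frame(condition_molar = c(0, 1e-8, 1e-7),
                     phase = "STATIONARY",
                     normalized_expression = c(1, 1.001, 0.999))
  dr3 <- dose_response(flat)
  expect_true(is.na(dr3$saturating_conc))
  expect_true(is.na(dr3$half_repression_conc))
  expect_error(dose_response(clean[1:2, ]), ">= 3")
})

test_that("maximal fold regulation is recovered across an (E_max, K_half) grid", {
  for (em in c(0.3, 0.5, 0.8)) for (kh in c(5e-8, 1e-7, 1e-6)) {
    tr <- kinetics_truth(E_max = em, K_half = kh,
                         seed = round(1e4 * em + 1e8 * kh))
    reg <- analyze_kinetics(simulate_growth_curves(
      tr, tpp_concs = c(0, 1e-4, 1e-3), n_wells = 2, seed = tr$seed))
    st <- reg[reg$phase == "STATIONARY" & reg$condition_molar == 1e-3, ]
    want <- 1 / (1 - em * (1 - tr$leak))
    expect_equal(st$fold_regulation, want, tolerance = 0.15)
  }
})
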