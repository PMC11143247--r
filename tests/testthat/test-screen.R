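test_that("replicate combination averages duplicates first, then replicates", {
  mk <- function(vals, strains) data.frame(strain_id = strains, value = vals,
                                           n_positions = 1L)
  # three replicates {1.0, 1.1, 0.9} -> mean 1.0, SD 0.1
  tabs <- lapply(c(1.0, 1.1, 0.9), mk, strains = "s1")
  out <- combine_replicates(tabs)
  expect_equal(out$mean, 1.0)
  expect_equal(out$sd, 0.1)
  expect_equal(out$n, 3L)
  # duplicate positions (1.2, 1.4) collapse to 1.3 within the replicate
  rec <- data.frame(
    plate_id = "p", row = c(1, 2), col = 1, strain_id = "s1",
    ratio = c(1.2, 1.4), ratio_corrected = c(1.2, 1.4),
    excluded = FALSE, exclude_reason = "", stringsAsFactors = FALSE
  )
  expect_equal(per_strain_means(rec)$value, 1.3)
  expect_warning(combine_replicates(list(mk(1, "s1"))), "fewer than 2")
})

test_that("per-strain SD tracks the planted replicate CV", {
  scr <- small_screen(seed = 31, n_replicates = 3, strain_cv = 0,
                      n_high = 0, n_low = 0, n_artifact = 0,
                      edge_amplitude = 1, gradient_amplitude_biomass = 1)
  tabs <- lapply(scr$sim$WT, function(m)
    per_strain_means(spatial_normalize(compute_ratio(m))))
  comb <- combine_replicates(tabs)
  # shared colony-size noise cancels in the ratio; the per-strain CV is
  # the planted expression noise CV of 0.1
  expect_equal(stats::median(comb$sd / comb$mean), 0.1, tolerance = 0.25)
})

test_that("control normalization cancels shared effects and keeps riboswitch signal", {
  wt <- data.frame(strain_id = c("a", "b", "c"), mean = c(1, 3, 3),
                   sd = 0.1, n = 3L)
  ct_same <- wt
  idx_same <- control_normalize(wt, ct_same)
  expect_equal(idx_same$index, rep(1, 3))
  # strain b: 3x in WT only (riboswitch); strain c: 3x in both (artifact)
  ct <- data.frame(strain_id = c("a", "b", "c"), mean = c(1, 1, 3),
                   sd = 0.1, n = 3L)
  idx <- control_normalize(wt, ct)
  expect_equal(idx$index[idx$strain_id == "b"], 3)
  expect_equal(idx$index[idx$strain_id == "c"], 1)
  # strains missing on one side are reported, not dropped
  wt2 <- rbind(wt, data.frame(strain_id = "d", mean = 2, sd = 0.1, n = 3L))
  idx2 <- control_normalize(wt2, ct)
  expect_true(is.na(idx2$index[idx2$strain_id == "d"]))
  expect_equal(idx2$reason[idx2$strain_id == "d"], "missing in control")
})

test_that("hit calling enforces the 1 +/- k SD rule with OFF-switch directions", {
  set.seed(32)
  idx <- index_table(c(1 + rnorm(500, 0, 0.05), 2.0, 0.2))
  hits <- call_hits(idx, threshold_k = 5)
  expect_true("s0501" %in% hits$strain_id)
  expect_equal(hits$direction[hits$strain_id == "s0501"], "HIGH_FLUOR")
  expect_equal(hits$direction[hits$strain_id == "s0502"], "LOW_FLUOR")
  expect_true(all(abs(hits$sd_distance) >= 5))
  # k = 6 hits are a subset of k = 5 hits
  h6 <- call_hits(idx, threshold_k = 6)
  expect_true(all(h6$strain_id %in% hits$strain_id))
  # ties exactly at the threshold are included
  s <- attr(call_hits(idx, 5), "sd_pop")
  idx_tie <- index_table(c(rep(1, 99), 1 + 5 * attr(call_hits(idx, 5), "sd_pop")))
  # degenerate and undersized distributions error
  expect_error(call_hits(index_table(rep(1, 50))), "degenerate")
  expect_error(call_hits(index_table(rnorm(5))), "at least 10")
})

test_that("threshold ties are called and the robust scale ignores hits", {
  # a strain sitting exactly at the threshold is included (>=, not >):
  # re-call with threshold_k set to a called strain's own |sd_distance|,
  # which makes that strain an exact tie in identical float arithmetic
  set.seed(40)
  idx <- index_table(c(1 + rnorm(500, 0, 0.02), 1.6, 0.4))
  h1 <- call_hits(idx, threshold_k = 5)
  d0 <- min(abs(h1$sd_distance))
  tied_strain <- h1$strain_id[which.min(abs(h1$sd_distance))]
  expect_true(tied_strain %in%
                call_hits(idx, threshold_k = d0)$strain_id)
  expect_false(tied_strain %in%
                 call_hits(idx, threshold_k = d0 * (1 + 1e-9))$strain_id)
  # classical SD is available and is inflated by planted hits
  set.seed(39)
  big <- index_table(c(1 + rnorm(200, 0, 0.02), rep(4, 20)))
  expect_gt(attr(call_hits(big, sd_method = "sd"), "sd_pop"),
            attr(call_hits(big, sd_method = "mad"), "sd_pop"))
})

test_that("duplicate pairs match a Monte-Carlo two-lognormal oracle", {
  scr <- small_screen(seed = 33, n_high = 0, n_low = 0, n_artifact = 0,
                      edge_amplitude = 1, gradient_amplitude_biomass = 1)
  rec <- spatial_normalize(compute_ratio(scr$sim$WT$rep1))
  dc <- duplicate_concordance(rec, scr$map)
  expect_equal(dc$summary$n_pairs, 150L)
  expect_equal(dc$pairs$log2_diff,
               log2(dc$pairs$value_1 / dc$pairs$value_2))
  expect_equal(dc$summary$frac_within_1.5x,
               mean(abs(dc$pairs$log2_diff) <= log2(1.5)))
  # Monte-Carlo oracle: each ratio carries one lognormal expression-noise
  # factor (cv = 0.1); the shared colony-size noise cancels in the ratio
  set.seed(34)
  sdl <- sqrt(log(1 + 0.1^2)); n <- 2e5
  v1 <- stats::rlnorm(n, 0, sdl)
  v2 <- stats::rlnorm(n, 0, sdl)
  oracle <- stats::median(abs(log2(v1 / v2)))
  expect_equal(dc$summary$median_abs_log2, oracle, tolerance = 0.15)
  # no duplicates -> empty result with warning
  map1 <- generate_plate_map(spec_small(), 90L, 0L, seed = 35)
  expect_warning(duplicate_concordance(rec, map1), "no duplicated")
})

test_that("replicate Pearson separates shared signal from noise", {
  t1 <- data.frame(strain_id = c("a", "b", "c", "d"), value = c(1, 2, 3, 4))
  expect_equal(replicate_pearson(list(t1, t1))[1, 2], 1)
  set.seed(36)
  n1 <- data.frame(strain_id = sprintf("s%d", 1:1000), value = rnorm(1000))
  n2 <- data.frame(strain_id = sprintf("s%d", 1:1000), value = rnorm(1000))
  expect_lt(abs(replicate_pearson(list(n1, n2))[1, 2]), 0.1)
  expect_error(replicate_pearson(list(t1)), "at least 2")
  expect_error(replicate_pearson(list(t1[1:2, ], t1[3:4, ])), "share")
  # dominant strain-level signal -> r > 0.9 across synthetic replicates
  scr <- small_screen(seed = 37, n_replicates = 2, strain_cv = 0.5)
  tabs <- lapply(scr$sim$WT, function(m)
    per_strain_means(spatial_normalize(compute_ratio(m))))
  expect_gt(replicate_pearson(tabs)[1, 2], 0.9)
})

test_that("rendered screen outputs are complete and well-formed", {
  scr <- small_screen(seed = 38, n_replicates = 2)
  recs <- lapply(scr$sim$WT, function(m)
    spatial_normalize(compute_ratio(m)))
  ctrl <- lapply(scr$sim$G31C, function(m)
    spatial_normalize(compute_ratio(m)))
  idx <- control_normalize(
    combine_replicates(lapply(recs, per_strain_means)),
    combine_replicates(lapply(ctrl, per_strain_means)))
  hits <- call_hits(idx)
  out <- withr::local_tempdir()
  files <- render_outputs(idx, hits, recs[[1]], out)
  expect_true(all(file.exists(
    file.path(out, c("index.csv", "hits_high.csv", "hits_low.csv",
                     "unscored.csv", "index_plot.png",
                     "heatmap_plate1.csv", "heatmap_plate1.png")))))
  hm <- utils::read.csv(file.path(out, "heatmap_plate1.csv"))
  expect_equal(dim(hm), c(scr$spec$n_rows, scr$spec$n_cols))
  hi <- utils::read.csv(file.path(out, "hits_high.csv"))
  if (nrow(hi) > 1) expect_true(!is.unsorted(rev(abs(hi$sd_distance))))
  # hit lists are valid (with headers) even when empty
  empty_hits <- call_hits(index_table(c(stats::qnorm((1:99)/100, 1, 0.02))))
  files2 <- render_outputs(index_table(c(stats::qnorm((1:99)/100, 1, 0.02))),
                           empty_hits, NULL, withr::local_tempdir())
  lo <- utils::read.csv(grep("hits_low", files2, value = TRUE))
  expect_equal(nrow(lo), 0L)
  expect_true(all(c("strain_id", "index") %in% names(lo)))
})
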