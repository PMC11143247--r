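# End-to-end orchestration: configuration, staged execution with
# stage-tagged errors, and a hashed run manifest.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage %s failed: %s", stage, conditionMessage(e)))
}

write_manifest <- function(out_dir, files, params) {
  files <- sort(unique(files[file.exists(files)]))
  manifest <- list(
    package_version = as.character(utils::packageVersion("riboscreen")),
    parameters = params,
    outputs = lapply(files, function(f) {
      np <- normalizePath(f)
      prefix <- paste0(normalizePath(out_dir), "/")
      list(path = if (startsWith(np, prefix))
             substring(np, nchar(prefix) + 1) else basename(np),
           md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; keys are the arguments of
#'   \code{\link{run_screen}} / \code{\link{run_kinetics}}.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

#' Run the full screen pipeline
#'
#' Executes quantification, ratio computation, spatial normalization,
#' replicate combination, control normalization, hit calling and QC, and
#' writes every artifact plus a machine-readable manifest (parameters,
#' seed, file hashes). Any stage error aborts with the stage name.
#'
#' The configuration is a named list (or YAML via
#' \code{\link{read_run_config}}) with either
#' \itemize{
#'   \item \code{mode = "synthetic"}: a seeded synthetic screen is
#'     generated (\code{seed}, \code{n_strains}, \code{n_duplicates},
#'     \code{n_plates}, \code{n_replicates}, plate-spec and truth
#'     parameters, optional \code{render}); or
#'   \item \code{mode = "images"}: \code{wt_images} and \code{ctrl_images}
#'     lists (one element per replicate, each a named list of
#'     biomass/fluorescence TIFF path pairs per plate) and a
#'     \code{map} CSV path.
#' }
#' Common keys: \code{threshold_k} (default 5), \code{smooth_window} (9),
#' \code{growth_floor} (0.1), \code{out_dir}.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with the index table, hits, QC, Pearson
#'   matrix, duplicate concordance and the manifest path.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||% stopf("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  k <- config$threshold_k %||% 5
  win <- config$smooth_window %||% 9L
  floor_f <- config$growth_floor %||% 0.1
  mode <- config$mode %||% "synthetic"

  if (mode == "synthetic") {
    spec <- run_stage("configure", plate_spec(
      n_rows = config$n_rows %||% 32L, n_cols = config$n_cols %||% 48L,
      pitch_px = config$pitch_px %||% 20, margin_px = config$margin_px %||% 20))
    seed <- config$seed %||% 1L
    map <- run_stage("plate_map", generate_plate_map(
      spec, n_strains = config$n_strains %||% 3800L,
      n_duplicates = config$n_duplicates %||% 402L,
      n_plates = config$n_plates %||% 3L, seed = seed))
    truth <- run_stage("screen_truth", screen_truth(
      map, n_high = config$n_high %||% 22L, n_low = config$n_low %||% 4L,
      n_artifact = config$n_artifact %||% 10L,
      edge_amplitude = config$edge_amplitude %||% 1.5,
      noise_cv = config$noise_cv %||% 0.1, seed = seed))
    sim <- run_stage("simulate", simulate_screen(
      map, spec, truth, n_replicates = config$n_replicates %||% 3L,
      seed = seed, render = isTRUE(config$render)))
    wt_meas <- sim$WT; ctrl_meas <- sim$G31C
  } else {
    spec <- run_stage("configure", plate_spec(
      n_rows = config$n_rows %||% 32L, n_cols = config$n_cols %||% 48L,
      pitch_px = config$pitch_px %||% 20, margin_px = config$margin_px %||% 20))
    map <- run_stage("plate_map", read_plate_map(
      config$map %||% stopf("image mode needs a map path")))
    read_rep <- function(rep_cfg, reporter, rep_i) {
      do.call(rbind, lapply(seq_along(rep_cfg), function(p) {
        pair <- list(
          biomass_image = read_plate_image(rep_cfg[[p]]$biomass),
          fluor_image = read_plate_image(rep_cfg[[p]]$fluor),
          plate_id = sprintf("plate%d", p),
          replicate_id = sprintf("rep%d", rep_i),
          timepoint = config$timepoint %||% "24h", reporter = reporter)
        quantify_plate(pair, map, spec)
      }))
    }
    wt_meas <- run_stage("quantify", lapply(seq_along(config$wt_images),
      function(i) read_rep(config$wt_images[[i]], "WT", i)))
    if (is.null(config$ctrl_images) || !length(config$ctrl_images))
      stopf("stage control_normalize failed: no G31C control inputs configured")
    ctrl_meas <- run_stage("quantify", lapply(seq_along(config$ctrl_images),
      function(i) read_rep(config$ctrl_images[[i]], "G31C", i)))
  }

  normalize_all <- function(meas_list)
    lapply(meas_list, function(m) run_stage("spatial_normalize",
      spatial_normalize(run_stage("compute_ratio",
        compute_ratio(m, growth_floor = floor_f)), smooth_window = win)))
  wt_rec <- normalize_all(wt_meas)
  ctrl_rec <- normalize_all(ctrl_meas)

  wt_strain <- run_stage("combine_replicates",
                         combine_replicates(lapply(wt_rec, per_strain_means)))
  ctrl_strain <- run_stage("combine_replicates",
                           combine_replicates(lapply(ctrl_rec, per_strain_means)))
  index <- run_stage("control_normalize", control_normalize(wt_strain, ctrl_strain))
  hits <- run_stage("call_hits", call_hits(index, threshold_k = k))
  qc <- run_stage("plate_qc", plate_qc(do.call(rbind, wt_rec)))
  pear <- run_stage("replicate_pearson",
                    replicate_pearson(lapply(wt_rec, per_strain_means)))
  dup <- run_stage("duplicate_concordance", duplicate_concordance(wt_rec[[1]], map))

  files <- run_stage("render_outputs",
                     render_outputs(index, hits, wt_rec[[1]], out_dir))
  pear_df <- as.data.frame(pear)
  pear_df <- cbind(replicate = rownames(pear_df), pear_df)
  files <- c(files, write_table(pear_df, file.path(out_dir, "pearson.csv")))
  if (nrow(dup$pairs))
    files <- c(files, write_table(dup$pairs, file.path(out_dir, "duplicates.csv")))
  qc_path <- file.path(out_dir, "qc.json")
  jsonlite::write_json(lapply(unclass(qc), function(q) {
    q$excluded_by_reason <- as.list(q$excluded_by_reason); q
  }), qc_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, qc_path)
  manifest <- write_manifest(out_dir, files,
                             params = config[setdiff(names(config), "out_dir")])
  invisible(list(index = index, hits = hits, qc = qc, pearson = pear,
                 duplicates = dup, files = files, manifest = manifest))
}

#' Run the kinetics pipeline
#'
#' Blank correction, per-well F/OD, phase detection, fold regulation and
#' dose-response summary, with artifacts and a hashed manifest.
#'
#' Config keys: \code{curves} (CSV path) or \code{mode = "synthetic"}
#' (with \code{seed} and optional \code{\link{kinetics_truth}}
#' parameters), \code{reference} (default 0), \code{stationary_t} (16),
#' \code{out_dir}.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with the regulation table, dose-response
#'   summary and manifest path.
#' @export
run_kinetics <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||% stopf("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- if ((config$mode %||% "file") == "synthetic") {
    truth <- run_stage("configure", kinetics_truth(
      E_max = config$E_max %||% 0.5, K_half = config$K_half %||% 1e-7,
      seed = config$seed %||% 1L))
    run_stage("simulate", simulate_growth_curves(truth))
  } else {
    run_stage("read_curves", read_growth_curves(
      config$curves %||% stopf("config needs a curves path")))
  }
  if (!any(curves$is_blank))
    stopf("stage blank_correct failed: no blank wells in input")
  reg <- run_stage("fold_regulation", analyze_kinetics(
    curves, reference = config$reference %||% 0,
    stationary_t = config$stationary_t %||% 16))
  dr <- run_stage("dose_response", dose_response(reg))
  files <- c(
    write_table(reg, file.path(out_dir, "regulation.csv")),
    write_table(dr$table, file.path(out_dir, "dose_response.csv"))
  )
  manifest <- write_manifest(out_dir, files,
                             params = config[setdiff(names(config), "out_dir")])
  invisible(list(regulation = reg, dose_response = dr, files = files,
                 manifest = manifest))
}

#' Deterministic end-to-end demo run
#'
#' Runs a small seeded synthetic screen (one 1536 plate, 3 replicates)
#' and a synthetic ligand titration, writing both output bundles under
#' \code{out_dir}. Rerunning with the same seed reproduces the bundle.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (default 7).
#' @return Invisibly, a list with both pipeline results.
#' @export
riboscreen_demo <- function(out_dir, seed = 7L) {
  screen <- run_screen(list(
    mode = "synthetic", seed = seed,
    n_strains = 1200L, n_duplicates = 100L, n_plates = 1L,
    n_high = 6L, n_low = 2L, n_artifact = 3L,
    out_dir = file.path(out_dir, "screen")))
  kin <- run_kinetics(list(
    mode = "synthetic", seed = seed,
    out_dir = file.path(out_dir, "kinetics")))
  invisible(list(screen = screen, kinetics = kin))
}
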