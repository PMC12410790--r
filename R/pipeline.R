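#' Default demonstration run configuration
#'
#' A complete small-sensor configuration exercising every stage: read-noise
#' frames, a dark-current exposure series, a photon-transfer shot series, a
#' gain series, and a synthetic cell scene with stray-light background.
#'
#' @param masterSeed integer master seed.
#' @param sensorShape sensor size for the demo (small by default so the
#'   full pipeline runs in seconds).
#' @return a config list accepted by \code{\link{runPipeline}}.
#' @export
demoRunConfig <- function(masterSeed = 1L, sensorShape = c(192L, 160L)) {
  list(
    camera_spec = .specToList(demoCameraSpec(sensorShape = sensorShape)),
    master_seed = as.integer(masterSeed),
    excess_noise = "sqrt2",
    suites = list(
      read_noise = list(n_frames = 5L),
      dark_series = list(exposures = c(120, 240, 360, 480, 600),
                         n_frames = 3L),
      shot_series = list(exposures = c(0.02, 0.04, 0.06, 0.08),
                         n_frames = 3L),
      gain_series = list(gains = list(g1 = 2.40, g2 = 9.03, g3 = 103.5),
                         exposure = 0.05, n_frames = 3L),
      cell_scene = list(n_cells = 6L, background_flux = 2000,
                        cell_flux = 20000, excess_background_flux = 2000,
                        exposure = 0.05, n_frames = 3L)
    )
  )
}

.readConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config
}

#' Long-format parameter table of a calibration report
#'
#' @param report a \linkS4class{CalibrationReport}.
#' @return data.frame(parameter, value, unit, uncertainty, evidence) in
#'   tidy long format.
#' @export
reportTable <- function(report) {
  rows <- list()
  add <- function(parameter, value, unit, uncertainty = NA_real_,
                  evidence = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = parameter, value = value, unit = unit,
      uncertainty = uncertainty, evidence = evidence)
  }
  if (length(report@readNoise))
    add("read_noise", report@readNoise$value_e, "e-", report@readNoise$sd_e,
        sprintf("%d zero-exposure dark frames",
                length(report@readNoise$per_frame_gv)))
  if (length(report@kRatio))
    add("k_ratio", report@kRatio$value, "GV/e-",
        stats::sd(report@kRatio$per_pair, na.rm = TRUE),
        "photon-transfer mean-variance at unity gain")
  if (length(report@darkCurrent)) {
    if (isTRUE(report@darkCurrent$detected))
      add("dark_current", report@darkCurrent$value, "e-/s/px",
          evidence = sprintf("variance fit over %d exposures",
                             report@darkCurrent$fit$n_used))
    else
      add("dark_current_upper_bound", report@darkCurrent$upper_bound_e_per_s,
          "e-/s/px", evidence = "not detected at any exposure")
  }
  for (lab in names(report@emGain))
    add(paste0("em_gain_", lab), report@emGain[[lab]], "dimensionless",
        evidence = "intensity ratio of steady source")
  if (length(report@cic)) {
    for (lab in names(report@cic$per_gain))
      add(paste0("cic_", lab), report@cic$per_gain[[lab]], "e-",
          evidence = "gained vs ungained dark-frame variance")
    add("cic_average", report@cic$average, "e-")
  }
  if (length(report@pixelIndependence))
    add("pixel_independence_similarity",
        report@pixelIndependence$similarity, "fraction",
        evidence = "consecutive difference images")
  do.call(rbind, rows)
}

#' Run the end-to-end simulate/calibrate/SNR pipeline
#'
#' Generates (or loads) every suite named in the configuration, runs the
#' calibration estimators, and, when a cell scene is configured, the SNR
#' analysis. With an \code{outputDir}, writes \code{report.json} and
#' \code{report.csv} (long format) plus an SNR table. Identical
#' configurations produce identical results.
#'
#' @param config a config list (see \code{\link{demoRunConfig}}) or a path
#'   to a YAML/JSON config file.
#' @param outputDir optional directory for report artifacts.
#' @return list(calibration, report_table, background, snr, config).
#' @export
runPipeline <- function(config = demoRunConfig(), outputDir = NULL) {
  config <- .readConfig(config)
  spec <- if (is(config$camera_spec, "CameraSpec")) config$camera_spec
  else .specFromList(config$camera_spec)
  ms <- as.integer(config$master_seed %||% 1L)
  en <- config$excess_noise %||% sqrt(2)
  # "sqrt2" stays symbolic so serialized configs lose no precision
  if (is.character(en)) en <- if (en == "sqrt2") sqrt(2) else as.numeric(en)
  sc <- config$suites
  suites <- list()
  if (!is.null(sc$read_noise))
    suites$read_noise <- generateSuite(SuiteRecipe(
      "read_noise", spec, nFrames = sc$read_noise$n_frames %||% 5L,
      masterSeed = deriveSeed(ms, 1)))$read_noise
  if (!is.null(sc$dark_series))
    suites$dark_series <- generateSuite(SuiteRecipe(
      "dark_series", spec, exposures = unlist(sc$dark_series$exposures),
      nFrames = sc$dark_series$n_frames %||% 3L,
      masterSeed = deriveSeed(ms, 2)))
  if (!is.null(sc$shot_series))
    suites$shot_series <- generateSuite(SuiteRecipe(
      "shot_series", spec, exposures = unlist(sc$shot_series$exposures),
      nFrames = sc$shot_series$n_frames %||% 3L,
      masterSeed = deriveSeed(ms, 3)))
  if (!is.null(sc$gain_series))
    suites$gain_series <- generateSuite(SuiteRecipe(
      "gain_series", spec, gains = unlist(sc$gain_series$gains),
      exposures = sc$gain_series$exposure %||% 0.05,
      nFrames = sc$gain_series$n_frames %||% 3L,
      masterSeed = deriveSeed(ms, 4)))
  report <- calibrate(suites, excessNoise = en)
  background <- NULL
  snr <- NULL
  if (!is.null(sc$cell_scene)) {
    cs <- sc$cell_scene
    scene <- generateCellScene(
      nCells = cs$n_cells %||% 6L, shape = spec@sensorShape,
      backgroundFlux = cs$background_flux %||% 2000,
      cellFlux = cs$cell_flux %||% 20000,
      excessBackgroundFlux = cs$excess_background_flux %||% 0,
      seed = deriveSeed(ms, 5))
    cellSuite <- generateSuite(SuiteRecipe(
      "cell_scene", spec, exposures = cs$exposure %||% 0.05,
      nFrames = cs$n_frames %||% 3L, masterSeed = deriveSeed(ms, 6),
      scene = scene))
    cicE <- if (length(report@cic)) report@cic$average else NA_real_
    background <- excessBackgroundNoise(cellSuite$cells, cellSuite$dark,
                                        excessNoise = en, cicE = cicE)
    snr <- cameraIndependentSnr(cellSuite$cells, cellSuite$dark,
                                cellRegions(scene))
  } else {
    message("no cell scene configured; SNR stage skipped")
  }
  tab <- reportTable(report)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(outputDir, "report.csv"),
                     row.names = FALSE)
    out <- list(master_seed = ms,
                parameters = stats::setNames(as.list(tab$value),
                                             tab$parameter))
    if (!is.null(background))
      out$background <- list(
        bg_mean_gv = background@bgMeanGv, bg_sd_gv = background@bgSdGv,
        dark_sd_gv = background@darkSdGv,
        excess_sd_gv = background@excessSdGv,
        relative_excess = background@relativeExcess,
        excess_e_per_gain = background@excessEPerGain)
    jsonlite::write_json(out, file.path(outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(snr))
      utils::write.csv(snr, file.path(outputDir, "snr.csv"),
                       row.names = FALSE)
  }
  list(calibration = report, report_table = tab, background = background,
       snr = snr, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
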