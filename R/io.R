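.specToList <- function(spec) {
  list(quantum_efficiency = spec@quantumEfficiency,
       dark_current = spec@darkCurrent,
       cic = spec@cic,
       read_noise = spec@readNoise,
       k_ratio = spec@kRatio,
       bias = spec@bias,
       bit_depth = spec@bitDepth,
       sensor_shape = as.integer(spec@sensorShape),
       en_model = spec@enModel,
       n_stages = spec@nStages)
}

.specFromList <- function(x) {
  CameraSpec(quantumEfficiency = x$quantum_efficiency,
             darkCurrent = x$dark_current, cic = x$cic,
             readNoise = x$read_noise, kRatio = x$k_ratio, bias = x$bias,
             bitDepth = x$bit_depth, sensorShape = unlist(x$sensor_shape),
             enModel = x$en_model,
             nStages = if (is.null(x$n_stages)) 500L else x$n_stages)
}

#' Write a CameraSpec to a YAML or JSON config file
#'
#' @param spec a \linkS4class{CameraSpec}.
#' @param path output path; format chosen by extension (.yaml/.yml or
#'   .json).
#' @return the path, invisibly.
#' @export
writeCameraSpec <- function(spec, path) {
  stopifnot(is(spec, "CameraSpec"))
  x <- .specToList(spec)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a CameraSpec from a YAML or JSON config file
#'
#' @param path config file path.
#' @return a \linkS4class{CameraSpec}.
#' @export
readCameraSpec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  .specFromList(x)
}

#' Write a FrameStack as 16-bit multi-page TIFF plus sidecar JSON
#'
#' Pixels go to a 16-bit grayscale multi-page TIFF; acquisition metadata
#' (exposure_s, em_gain, gain_setting, shutter_open, seed) and, for
#' simulated stacks, the full generating camera spec go to
#' \code{paste0(path, ".json")}.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param path TIFF output path.
#' @return the path, invisibly.
#' @export
writeFrameStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  if (any(stack@pixels > 65535))
    stop("pixels exceed the 16-bit TIFF container")
  pages <- lapply(seq_len(nFrames(stack)), function(i)
    framePixels(stack, i) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  s <- stack@settings
  side <- list(exposure_s = s@exposureTime, em_gain = s@emGain,
               gain_setting = s@gainLabel, shutter_open = s@shutterOpen,
               seed = as.integer(stack@seeds),
               spec_id = if (is.null(stack@spec)) NULL else "embedded",
               camera_spec = if (is.null(stack@spec)) NULL
                             else .specToList(stack@spec),
               metadata = stack@metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a FrameStack from a 16-bit multi-page TIFF plus sidecar JSON
#'
#' @param path TIFF path; the sidecar is expected at
#'   \code{paste0(path, ".json")}. With no sidecar, frames are loaded with
#'   default settings and \code{metadata$settings_unknown = TRUE}.
#' @return a \linkS4class{FrameStack}.
#' @export
readFrameStack <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("not a readable TIFF file: ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2L)
      stop("format error: non-grayscale TIFF page")
    if (!identical(dim(p), dim(pages[[1]])))
      stop("format error: mixed page shapes")
  }
  px <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages))
    px[, , i] <- as.integer(round(pages[[i]] * 65535))
  sidePath <- paste0(path, ".json")
  if (file.exists(sidePath)) {
    side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
    settings <- AcquisitionSettings(side$exposure_s, side$em_gain,
                                    side$gain_setting, side$shutter_open)
    spec <- if (!is.null(side$camera_spec)) .specFromList(side$camera_spec)
    seeds <- if (length(side$seed)) as.integer(side$seed) else integer()
    meta <- if (is.null(side$metadata)) list() else as.list(side$metadata)
    FrameStack(px, settings, spec = spec, seeds = seeds, metadata = meta)
  } else {
    FrameStack(px, AcquisitionSettings(),
               metadata = list(settings_unknown = TRUE))
  }
}

#' Write a suite of FrameStacks with a manifest
#'
#' @param suite named list of \linkS4class{FrameStack}s (as from
#'   \code{\link{generateSuite}}).
#' @param dir output directory (created if needed).
#' @return path of the manifest JSON, invisibly.
#' @export
writeSuite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(suite)) {
    f <- file.path(dir, paste0(nm, ".tif"))
    writeFrameStack(suite[[nm]], f)
    files[nm] <- basename(f)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(stacks = as.list(files)), manifest,
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a suite written by \code{\link{writeSuite}}
#'
#' @param dir suite directory containing \code{manifest.json}.
#' @return named list of \linkS4class{FrameStack}s.
#' @export
readSuite <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- lapply(manifest$stacks, function(f)
    readFrameStack(file.path(dir, f)))
  names(out) <- names(manifest$stacks)
  out
}
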