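#' @import methods
NULL

.EN_MODELS <- c("none", "sqrt2", "branching")

#' CameraSpec: physical parameters of a scientific camera
#'
#' Container for the ground-truth (or estimated) parameters that drive the
#' image-formation noise chain: quantum efficiency, dark current,
#' clock-induced charge (CIC), read noise, the gray-value/electron conversion
#' ratio K, the ADC bias offset and bit depth, the sensor geometry, and the
#' excess-noise model used for electron multiplication.
#'
#' @slot quantumEfficiency fraction of incident photons converted to
#'   photoelectrons, in \[0, 1\].
#' @slot darkCurrent thermally generated electrons per second per pixel.
#' @slot cic clock-induced charge, spurious electrons per pixel per frame
#'   (injected before the gain register; zero effect at unity gain).
#' @slot readNoise RMS read noise in electrons.
#' @slot kRatio gray values produced per electron (K, GV/e-).
#' @slot bias constant ADC offset in gray values.
#' @slot bitDepth ADC bit depth; pixels saturate at 2^bitDepth - 1.
#' @slot sensorShape integer c(rows, cols).
#' @slot enModel one of "none", "sqrt2", "branching": how the stochastic
#'   electron-multiplication cascade is modelled.
#' @slot nStages number of gain-register stages for the branching model.
#' @export
setClass("CameraSpec",
  representation(
    quantumEfficiency = "numeric",
    darkCurrent = "numeric",
    cic = "numeric",
    readNoise = "numeric",
    kRatio = "numeric",
    bias = "numeric",
    bitDepth = "integer",
    sensorShape = "integer",
    enModel = "character",
    nStages = "integer"
  )
)

setValidity("CameraSpec", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@quantumEfficiency) ||
      object@quantumEfficiency < 0 || object@quantumEfficiency > 1)
    msg <- c(msg, "quantumEfficiency must be a single value in [0, 1]")
  for (s in c("darkCurrent", "cic", "readNoise", "bias")) {
    v <- slot(object, s)
    if (!num1(v) || v < 0) msg <- c(msg, paste(s, "must be a single value >= 0"))
  }
  if (!num1(object@kRatio) || object@kRatio <= 0)
    msg <- c(msg, "kRatio must be > 0")
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L)
    msg <- c(msg, "bitDepth must be a positive integer")
  if (length(object@sensorShape) != 2L || any(object@sensorShape < 1L))
    msg <- c(msg, "sensorShape must be two positive integers (rows, cols)")
  if (length(object@enModel) != 1L || !object@enModel %in% .EN_MODELS)
    msg <- c(msg, sprintf("enModel must be one of %s",
                          paste(.EN_MODELS, collapse = ", ")))
  if (length(object@nStages) != 1L || object@nStages < 1L)
    msg <- c(msg, "nStages must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a CameraSpec
#'
#' @param quantumEfficiency photon-to-electron conversion fraction. Defaults
#'   to 1 so that scene flux reads directly as detected photons; the
#'   estimators never separate QE from flux (they always appear as a product).
#' @param darkCurrent electrons/second/pixel.
#' @param cic clock-induced charge, electrons/pixel/frame.
#' @param readNoise RMS read noise, electrons.
#' @param kRatio gray values per electron (K).
#' @param bias ADC offset, gray values.
#' @param bitDepth ADC bit depth (saturation at 2^bitDepth - 1).
#' @param sensorShape integer c(rows, cols) of the sensor.
#' @param enModel "sqrt2" (default), "branching", or "none".
#' @param nStages gain-register stages for the branching cascade.
#' @return A \linkS4class{CameraSpec}.
#' @examples
#' spec <- CameraSpec(readNoise = 25.3, kRatio = 1.2)
#' @export
CameraSpec <- function(quantumEfficiency = 1, darkCurrent = 0, cic = 0,
                       readNoise = 0, kRatio = 1, bias = 100,
                       bitDepth = 16L, sensorShape = c(653L, 492L),
                       enModel = "sqrt2", nStages = 500L) {
  new("CameraSpec",
      quantumEfficiency = as.numeric(quantumEfficiency),
      darkCurrent = as.numeric(darkCurrent),
      cic = as.numeric(cic),
      readNoise = as.numeric(readNoise),
      kRatio = as.numeric(kRatio),
      bias = as.numeric(bias),
      bitDepth = as.integer(bitDepth),
      sensorShape = as.integer(sensorShape),
      enModel = as.character(enModel),
      nStages = as.integer(nStages))
}

#' AcquisitionSettings: how one frame stack was acquired
#'
#' @slot exposureTime commanded exposure in seconds (t).
#' @slot emGain calculated electron-multiplication gain (>= 1); 1 means no
#'   multiplication. This is the physical gain, not the software setting.
#' @slot gainLabel opaque software gain-setting identifier (e.g. "g0", "g3");
#'   carries no numeric meaning.
#' @slot shutterOpen logical; FALSE for dark frames.
#' @export
setClass("AcquisitionSettings",
  representation(
    exposureTime = "numeric",
    emGain = "numeric",
    gainLabel = "character",
    shutterOpen = "logical"
  )
)

setValidity("AcquisitionSettings", function(object) {
  msg <- character()
  if (length(object@exposureTime) != 1L || !is.finite(object@exposureTime) ||
      object@exposureTime < 0)
    msg <- c(msg, "exposureTime must be a single value >= 0 seconds")
  if (length(object@emGain) != 1L || !is.finite(object@emGain) ||
      object@emGain < 1)
    msg <- c(msg, "emGain must be a single value >= 1")
  if (length(object@gainLabel) != 1L)
    msg <- c(msg, "gainLabel must be a single string")
  if (identical(object@gainLabel, "g0") && object@emGain != 1)
    msg <- c(msg, "gainLabel \"g0\" denotes no gain and requires emGain == 1")
  if (length(object@shutterOpen) != 1L || is.na(object@shutterOpen))
    msg <- c(msg, "shutterOpen must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct AcquisitionSettings
#'
#' @param exposureTime seconds (>= 0).
#' @param emGain electron-multiplication gain (>= 1).
#' @param gainLabel software gain setting label; "g0" must have emGain 1.
#' @param shutterOpen logical, FALSE for dark frames.
#' @return An \linkS4class{AcquisitionSettings}.
#' @export
AcquisitionSettings <- function(exposureTime = 0, emGain = 1,
                                gainLabel = if (emGain == 1) "g0" else "gi",
                                shutterOpen = FALSE) {
  new("AcquisitionSettings",
      exposureTime = as.numeric(exposureTime),
      emGain = as.numeric(emGain),
      gainLabel = as.character(gainLabel),
      shutterOpen = as.logical(shutterOpen))
}

#' PhotonScene: per-pixel mean photon arrival rate
#'
#' @slot flux matrix of mean photon rates (photons/second/pixel), all >= 0,
#'   with dimensions equal to the sensor shape.
#' @export
setClass("PhotonScene", representation(flux = "matrix"))

setValidity("PhotonScene", function(object) {
  if (!is.numeric(object@flux) || any(!is.finite(object@flux)) ||
      any(object@flux < 0))
    return("flux must be a numeric matrix with all values finite and >= 0")
  TRUE
})

#' Construct a PhotonScene
#'
#' @param flux either a single non-negative rate (expanded to a uniform
#'   scene over `shape`) or a matrix of rates.
#' @param shape integer c(rows, cols); required when `flux` is scalar.
#' @return A \linkS4class{PhotonScene}.
#' @examples
#' PhotonScene(500, shape = c(64, 64))
#' @export
PhotonScene <- function(flux, shape = NULL) {
  if (is.matrix(flux)) {
    m <- flux
  } else {
    stopifnot(length(flux) == 1L, !is.null(shape))
    m <- matrix(as.numeric(flux), nrow = shape[1], ncol = shape[2])
  }
  new("PhotonScene", flux = m)
}

#' FrameStack: ordered raw frames sharing one acquisition setting
#'
#' Pixels are integer gray values in a rows x cols x n array. Frames
#' produced by the simulator carry their generating \linkS4class{CameraSpec}
#' and per-frame seeds; frames read from disk may carry neither.
#'
#' @slot pixels integer array (rows, cols, n).
#' @slot settings the shared \linkS4class{AcquisitionSettings}.
#' @slot spec the generating CameraSpec, or NULL for frames of unknown origin.
#' @slot seeds integer vector of per-frame RNG seeds (length n), or
#'   length 0 for real frames.
#' @slot metadata list of free-form provenance entries.
#' @export
setClass("FrameStack",
  representation(
    pixels = "array",
    settings = "AcquisitionSettings",
    spec = "ANY",
    seeds = "integer",
    metadata = "list"
  )
)

setValidity("FrameStack", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L)
    msg <- c(msg, "pixels must be a 3-D array (rows, cols, frames)")
  if (any(object@pixels < 0))
    msg <- c(msg, "pixel gray values must be >= 0")
  if (!is.null(object@spec)) {
    if (!is(object@spec, "CameraSpec"))
      msg <- c(msg, "spec must be a CameraSpec or NULL")
    else {
      if (!identical(d[1:2], as.integer(object@spec@sensorShape)))
        msg <- c(msg, "frame dimensions must equal the sensor shape")
      if (any(object@pixels > 2^object@spec@bitDepth - 1))
        msg <- c(msg, "pixel gray values exceed ADC saturation")
    }
  }
  if (length(object@seeds) && length(object@seeds) != d[3])
    msg <- c(msg, "seeds must be empty or one per frame")
  if (length(msg)) msg else TRUE
})

#' Construct a FrameStack
#'
#' @param pixels integer array (rows, cols, n) or a single matrix.
#' @param settings shared \linkS4class{AcquisitionSettings}.
#' @param spec generating \linkS4class{CameraSpec} or NULL.
#' @param seeds per-frame RNG seeds (optional).
#' @param metadata list of provenance entries.
#' @return A \linkS4class{FrameStack}.
#' @export
FrameStack <- function(pixels, settings, spec = NULL, seeds = integer(),
                       metadata = list()) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  storage.mode(pixels) <- "integer"
  new("FrameStack", pixels = pixels, settings = settings, spec = spec,
      seeds = as.integer(seeds), metadata = metadata)
}

#' NoiseBudget: theoretical per-source noise decomposition
#'
#' Mean signal and per-source standard deviations, each expressed both in
#' electrons and in gray values. The total satisfies
#' sd_total^2 = sd_photon^2 + sd_dark^2 + sd_cic^2 + sd_read^2 exactly,
#' by construction.
#'
#' @slot electrons named numeric: mean_signal, sd_photon, sd_dark, sd_cic,
#'   sd_read, sd_total, in electrons.
#' @slot grayValues the same quantities in gray values (electrons times K).
#' @export
setClass("NoiseBudget",
  representation(electrons = "numeric", grayValues = "numeric"))

.BUDGET_FIELDS <- c("mean_signal", "sd_photon", "sd_dark", "sd_cic",
                    "sd_read", "sd_total")

setValidity("NoiseBudget", function(object) {
  for (s in c("electrons", "grayValues")) {
    v <- slot(object, s)
    if (!identical(names(v), .BUDGET_FIELDS))
      return(sprintf("%s must be named %s", s,
                     paste(.BUDGET_FIELDS, collapse = ", ")))
    if (any(v[-1] < 0)) return("standard deviations must be >= 0")
  }
  TRUE
})

#' ROI: rectangular region of interest
#'
#' 0-based, half-open rectangle: rows \[rowStart, rowStart + height),
#' columns \[colStart, colStart + width).
#'
#' @slot rowStart,colStart 0-based offsets of the top-left corner.
#' @slot height,width extent in pixels.
#' @export
setClass("ROI",
  representation(rowStart = "integer", colStart = "integer",
                 height = "integer", width = "integer"))

setValidity("ROI", function(object) {
  if (object@rowStart < 0L || object@colStart < 0L ||
      object@height < 1L || object@width < 1L)
    return("ROI must have non-negative offsets and positive extent")
  TRUE
})

#' Construct an ROI
#'
#' @param rowStart,colStart 0-based offsets.
#' @param height,width extent in pixels (>= 1).
#' @return An \linkS4class{ROI}.
#' @export
ROI <- function(rowStart, colStart, height, width) {
  new("ROI", rowStart = as.integer(rowStart), colStart = as.integer(colStart),
      height = as.integer(height), width = as.integer(width))
}

#' Default centered ROI covering ~20% of each image dimension
#'
#' @param shape integer c(rows, cols) of the frame.
#' @param fraction linear fraction of each dimension to cover (default 0.2).
#' @return An \linkS4class{ROI} centered in the frame.
#' @export
defaultRoi <- function(shape, fraction = 0.2) {
  h <- max(1L, as.integer(round(shape[1] * fraction)))
  w <- max(1L, as.integer(round(shape[2] * fraction)))
  ROI(rowStart = (shape[1] - h) %/% 2, colStart = (shape[2] - w) %/% 2,
      height = h, width = w)
}

#' SuiteRecipe: a calibration frame-suite design
#'
#' Describes one of the standard calibration experiments: read-noise
#' zero-exposure dark frames, a dark-current exposure series, a photon-shot
#' exposure series with matched darks, a gain series (light/dark pairs at
#' each gain), or a synthetic cell scene with matched darks.
#'
#' @slot kind one of "read_noise", "dark_series", "shot_series",
#'   "gain_series", "cell_scene".
#' @slot spec ground-truth \linkS4class{CameraSpec}.
#' @slot exposures seconds, strictly increasing (where applicable).
#' @slot gains named numeric: gain-setting label -> EM gain.
#' @slot nFrames frames per condition (>= 1).
#' @slot masterSeed integer master seed; per-frame seeds derive from it.
#' @slot flux photons/s/px of the steady light source (where applicable).
#' @slot scene optional \linkS4class{CellScene} for kind "cell_scene".
#' @export
setClass("SuiteRecipe",
  representation(
    kind = "character",
    spec = "CameraSpec",
    exposures = "numeric",
    gains = "numeric",
    nFrames = "integer",
    masterSeed = "integer",
    flux = "numeric",
    scene = "ANY"
  )
)

.SUITE_KINDS <- c("read_noise", "dark_series", "shot_series", "gain_series",
                  "cell_scene")

setValidity("SuiteRecipe", function(object) {
  msg <- character()
  if (!object@kind %in% .SUITE_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.SUITE_KINDS, collapse = ", ")))
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (length(object@exposures)) {
    if (any(object@exposures < 0))
      msg <- c(msg, "exposures must be non-negative")
    if (length(object@exposures) > 1 && any(diff(object@exposures) <= 0))
      msg <- c(msg, "exposures must be strictly increasing")
  }
  if (length(object@gains) && any(object@gains < 1))
    msg <- c(msg, "gains must all be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SuiteRecipe
#'
#' @param kind suite kind; see \linkS4class{SuiteRecipe}.
#' @param spec ground-truth \linkS4class{CameraSpec}.
#' @param exposures seconds (dark_series / shot_series).
#' @param gains named numeric mapping gain labels to EM gains (gain_series).
#' @param nFrames frames per condition.
#' @param masterSeed integer master seed.
#' @param flux steady-source flux in photons/s/px; NA asks the generator to
#'   size it automatically (see \code{\link{generateSuite}}).
#' @param scene optional \linkS4class{CellScene} (cell_scene).
#' @return A \linkS4class{SuiteRecipe}.
#' @export
SuiteRecipe <- function(kind, spec, exposures = numeric(), gains = numeric(),
                        nFrames = 5L, masterSeed = 1L, flux = NA_real_,
                        scene = NULL) {
  new("SuiteRecipe", kind = kind, spec = spec,
      exposures = as.numeric(exposures), gains = gains,
      nFrames = as.integer(nFrames), masterSeed = as.integer(masterSeed),
      flux = as.numeric(flux), scene = scene)
}

#' CellScene: synthetic field of disk-shaped cells on a uniform background
#'
#' A stand-in for fluorescence images of cells on a pad: disk cells of
#' constant flux on a uniform background, plus an optional uniform
#' excess-background flux modelling stray or leaked light. Only the contrast
#' statistics matter to the SNR metrics; no morphology or PSF is modelled.
#'
#' @slot backgroundFlux photons/s/px of the cell-free background.
#' @slot cellFlux photons/s/px inside cells (>= backgroundFlux).
#' @slot excessBackgroundFlux photons/s/px added uniformly (stray light).
#' @slot centers n x 2 matrix of (row, col) cell centers (1-based).
#' @slot radii numeric vector of cell radii in pixels.
#' @slot shape integer c(rows, cols) of the sensor.
#' @export
setClass("CellScene",
  representation(
    backgroundFlux = "numeric",
    cellFlux = "numeric",
    excessBackgroundFlux = "numeric",
    centers = "matrix",
    radii = "numeric",
    shape = "integer"
  )
)

setValidity("CellScene", function(object) {
  msg <- character()
  if (object@backgroundFlux < 0 || object@excessBackgroundFlux < 0)
    msg <- c(msg, "fluxes must be >= 0")
  if (object@cellFlux < object@backgroundFlux)
    msg <- c(msg, "cellFlux must be >= backgroundFlux")
  if (nrow(object@centers) != length(object@radii))
    msg <- c(msg, "one radius per cell center required")
  if (length(msg)) msg else TRUE
})

#' CalibrationReport: estimated camera parameters with evidence
#'
#' Aggregates the outputs of the calibration estimators. Components that
#' could not be measured are flagged "not detected" rather than zero-filled.
#'
#' @slot readNoise list(value_e, sd_e, per_frame_gv, k_ratio_used).
#' @slot kRatio list(value, per_pair).
#' @slot darkCurrent list(value, detected, per_exposure, fit).
#' @slot emGain named numeric, gain label -> estimated gain.
#' @slot cic list(per_gain, average, detected).
#' @slot pixelIndependence list(observed_sd, expected_sd, similarity).
#' @slot enFactor the excess-noise factor used in gained-frame estimators.
#' @export
setClass("CalibrationReport",
  representation(
    readNoise = "list",
    kRatio = "list",
    darkCurrent = "list",
    emGain = "numeric",
    cic = "list",
    pixelIndependence = "list",
    enFactor = "numeric"
  )
)

#' BackgroundReport: background vs matched-dark noise decomposition
#'
#' @slot bgMeanGv,bgSdGv mean/SD of the image background ROI (gray values).
#' @slot darkMeanGv,darkSdGv mean/SD of the matched dark ROI (gray values).
#' @slot excessSdGv excess background noise sigma_EBG (gray values).
#' @slot relativeExcess sigma_EBG / sigma_DarkImage.
#' @slot excessEPerGain gain-normalized excess background in electrons (NA
#'   when no CIC floor was supplied).
#' @slot normalization "cic_floor" when excessEPerGain used the
#'   CIC-dominated dark-frame normalization, else "none".
#' @slot detected FALSE when the background variance did not exceed the
#'   dark variance (excess clamped to zero).
#' @export
setClass("BackgroundReport",
  representation(
    bgMeanGv = "numeric", bgSdGv = "numeric",
    darkMeanGv = "numeric", darkSdGv = "numeric",
    excessSdGv = "numeric", relativeExcess = "numeric",
    excessEPerGain = "numeric", normalization = "character",
    detected = "logical"
  )
)
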