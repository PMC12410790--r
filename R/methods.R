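#' @describeIn nFrames frame count of a FrameStack
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@pixels)[3L])

#' @describeIn acquisition settings of a FrameStack
#' @export
setMethod("acquisition", "FrameStack", function(x) x@settings)

#' @describeIn framePixels pixels of a FrameStack
#' @export
setMethod("framePixels", "FrameStack", function(x, i) {
  if (missing(i)) return(x@pixels)
  x@pixels[, , i, drop = TRUE]
})

#' @describeIn cameraSpec generating spec of a FrameStack
#' @export
setMethod("cameraSpec", "FrameStack", function(x) x@spec)

#' @describeIn cropRoi crop a single frame matrix
#' @export
setMethod("cropRoi", "matrix", function(x, roi) {
  rows <- (roi@rowStart + 1L):(roi@rowStart + roi@height)
  cols <- (roi@colStart + 1L):(roi@colStart + roi@width)
  if (max(rows) > nrow(x) || max(cols) > ncol(x))
    stop("ROI extends outside the frame")
  x[rows, cols, drop = FALSE]
})

#' @describeIn cropRoi crop every frame of a stack
#' @export
setMethod("cropRoi", "FrameStack", function(x, roi) {
  rows <- (roi@rowStart + 1L):(roi@rowStart + roi@height)
  cols <- (roi@colStart + 1L):(roi@colStart + roi@width)
  d <- dim(x@pixels)
  if (max(rows) > d[1] || max(cols) > d[2])
    stop("ROI extends outside the frame")
  x@pixels[rows, cols, , drop = FALSE]
})

setMethod("show", "CameraSpec", function(object) {
  cat("CameraSpec\n")
  cat(sprintf("  sensor          : %d x %d px, %d-bit ADC, bias %g GV\n",
              object@sensorShape[1], object@sensorShape[2],
              object@bitDepth, object@bias))
  cat(sprintf("  QE              : %g\n", object@quantumEfficiency))
  cat(sprintf("  dark current    : %g e-/s/px\n", object@darkCurrent))
  cat(sprintf("  CIC             : %g e-/frame\n", object@cic))
  cat(sprintf("  read noise      : %g e- RMS\n", object@readNoise))
  cat(sprintf("  K (GV/e-)       : %g\n", object@kRatio))
  cat(sprintf("  EM noise model  : %s\n", object@enModel))
})

setMethod("show", "AcquisitionSettings", function(object) {
  cat(sprintf(
    "AcquisitionSettings: t = %g s, EM gain = %g (%s), shutter %s\n",
    object@exposureTime, object@emGain, object@gainLabel,
    if (object@shutterOpen) "open" else "closed"))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FrameStack: %d frame(s) of %d x %d px\n", d[3], d[1], d[2]))
  show(object@settings)
  if (!is.null(object@spec)) cat("  simulated (spec attached)\n")
})

setMethod("show", "NoiseBudget", function(object) {
  cat("NoiseBudget (SD per source)\n")
  tab <- rbind(electrons = object@electrons, gray_values = object@grayValues)
  print(round(t(tab), 4))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI: rows [%d, %d), cols [%d, %d)\n",
              object@rowStart, object@rowStart + object@height,
              object@colStart, object@colStart + object@width))
})

setMethod("show", "CalibrationReport", function(object) {
  cat("CalibrationReport\n")
  if (length(object@readNoise))
    cat(sprintf("  read noise   : %.3g e- (SD over frames %.2g)\n",
                object@readNoise$value_e, object@readNoise$sd_e))
  if (length(object@kRatio))
    cat(sprintf("  K            : %.4g GV/e-\n", object@kRatio$value))
  if (length(object@darkCurrent)) {
    if (isTRUE(object@darkCurrent$detected))
      cat(sprintf("  dark current : %.3g e-/s/px\n", object@darkCurrent$value))
    else
      cat("  dark current : not detected\n")
  }
  if (length(object@emGain))
    cat(sprintf("  EM gain      : %s\n",
                paste(sprintf("%s=%.4g", names(object@emGain), object@emGain),
                      collapse = ", ")))
  if (length(object@cic)) {
    if (isTRUE(object@cic$detected))
      cat(sprintf("  CIC          : %.3g e- (average over gains)\n",
                  object@cic$average))
    else
      cat("  CIC          : not detected\n")
  }
  if (length(object@pixelIndependence))
    cat(sprintf("  pixel independence: %.1f%% similarity\n",
                100 * object@pixelIndependence$similarity))
})

setMethod("show", "BackgroundReport", function(object) {
  cat("BackgroundReport\n")
  cat(sprintf("  background   : mean %.4g GV, SD %.4g GV\n",
              object@bgMeanGv, object@bgSdGv))
  cat(sprintf("  matched dark : mean %.4g GV, SD %.4g GV\n",
              object@darkMeanGv, object@darkSdGv))
  if (object@detected)
    cat(sprintf("  excess noise : %.4g GV (%.3g x dark)\n",
                object@excessSdGv, object@relativeExcess))
  else
    cat("  excess noise : not detected\n")
  if (is.finite(object@excessEPerGain))
    cat(sprintf("  gain-normalized excess: %.3g e-\n", object@excessEPerGain))
})
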