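#' Mean and SD of an ROI
#'
#' @param frame a matrix or single-frame \linkS4class{FrameStack}.
#' @param roi an \linkS4class{ROI}; default centered 20%.
#' @return list(mean, sd): arithmetic mean and population SD of the ROI
#'   pixels, in gray values.
#' @export
roiStats <- function(frame, roi = NULL) {
  m <- if (is(frame, "FrameStack")) framePixels(frame, 1) else frame
  if (is.null(roi)) roi <- defaultRoi(dim(m))
  px <- cropRoi(m, roi)
  if (length(px) == 0) stop("ROI is empty")
  list(mean = mean(px), sd = .popSd(px))
}

#' Excess background noise relative to a matched dark frame
#'
#' Decomposes the background noise of an image into the matched dark
#' frame's camera noise and the excess:
#' sigma_EBG = sqrt(max(0, sigma_BG^2 - sigma_DarkImage^2)). The relative
#' excess sigma_EBG / sigma_DarkImage is camera-setting-free; when the dark
#' frame's noise is dominated by amplified clock-induced charge, the
#' gain-normalized excess in photoelectrons is
#' relative_excess * EN * sqrt(CIC).
#'
#' @param imageFrame the image (stack or matrix).
#' @param darkFrame matched dark frame: identical exposure and gain, closed
#'   shutter.
#' @param roi an \linkS4class{ROI}; default centered 20%.
#' @param excessNoise EN factor for the gain normalization.
#' @param cicE clock-induced charge in electrons; NA skips the
#'   normalization.
#' @return a \linkS4class{BackgroundReport}.
#' @export
excessBackgroundNoise <- function(imageFrame, darkFrame, roi = NULL,
                                  excessNoise = sqrt(2), cicE = NA_real_) {
  img <- .asStack(imageFrame); drk <- .asStack(darkFrame)
  if (!.sameSettings(img@settings, drk@settings, ignoreShutter = TRUE))
    stop("image and dark frame must share exposure and gain")
  if (drk@settings@shutterOpen)
    stop("the matched dark frame must have a closed shutter")
  bg <- darkImageStats(img, roi)
  dk <- darkImageStats(drk, roi)
  vExcess <- bg$sd_gv^2 - dk$sd_gv^2
  detected <- vExcess > 0
  excess <- sqrt(max(0, vExcess))
  rel <- if (dk$sd_gv > 0) excess / dk$sd_gv else NA_real_
  if (is.finite(cicE) && is.finite(rel)) {
    ePerGain <- rel * excessNoise * sqrt(cicE)
    norm <- "cic_floor"
  } else {
    ePerGain <- NA_real_
    norm <- "none"
  }
  new("BackgroundReport",
      bgMeanGv = bg$mean_gv, bgSdGv = bg$sd_gv,
      darkMeanGv = dk$mean_gv, darkSdGv = dk$sd_gv,
      excessSdGv = excess, relativeExcess = rel,
      excessEPerGain = ePerGain, normalization = norm,
      detected = detected)
}

#' Gain-normalized dark-image noise floor
#'
#' The sensitivity floor of an EM camera in photoelectrons: the
#' amplification-deducted dark-image noise EN * sqrt(CIC). With EN = 1.41
#' and CIC = 24 e- this is about 6.91 e-.
#'
#' @param excessNoise EN factor.
#' @param cicE clock-induced charge in electrons (>= 0).
#' @return electrons.
#' @examples
#' gainNormalizedDarkNoise(1.41, 24)  # ~6.91
#' @export
gainNormalizedDarkNoise <- function(excessNoise, cicE) {
  stopifnot(cicE >= 0, excessNoise >= 0)
  excessNoise * sqrt(cicE)
}

#' Fraction of total background variance from excess background noise
#'
#' For relative excess r = sigma_EBG / sigma_DarkImage, the excess
#' contributes r^2 / (1 + r^2) of the total background variance: excess
#' below half the dark noise contributes less than 20%.
#'
#' @param relativeExcess r >= 0.
#' @return fraction in \[0, 1).
#' @examples
#' excessVarianceFraction(0.5)  # 0.2
#' @export
excessVarianceFraction <- function(relativeExcess) {
  stopifnot(all(relativeExcess >= 0))
  relativeExcess^2 / (1 + relativeExcess^2)
}

.regionMask <- function(region, shape) {
  if (is.matrix(region) && is.logical(region)) {
    stopifnot(identical(dim(region), as.integer(shape)))
    return(region)
  }
  if (is.list(region) && !is.null(region$center) && !is.null(region$radius)) {
    rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    return((rows - region$center[1])^2 + (cols - region$center[2])^2 <=
             region$radius^2)
  }
  stop("cell region must be a logical mask or list(center=, radius=)")
}

#' Cell regions of a CellScene
#'
#' @param scene a \linkS4class{CellScene}.
#' @return list of list(center, radius) regions, one per cell, usable with
#'   \code{\link{cameraIndependentSnr}}.
#' @export
cellRegions <- function(scene) {
  stopifnot(is(scene, "CellScene"))
  lapply(seq_len(nrow(scene@centers)), function(i)
    list(center = scene@centers[i, ], radius = scene@radii[i]))
}

#' Camera-independent SNR of cell regions
#'
#' Per cell: background-subtracted cell intensity (mean cell gray value
#' minus the mean of an adjacent cell-free background ROI) divided by the
#' photon shot noise of the background region, the latter obtained by
#' subtracting the matched dark image's ROI variance from the background
#' ROI variance and taking the square root. When the background variance
#' does not exceed the dark variance the SNR is reported as NA
#' (not computable), never infinity.
#'
#' @param cellFrames image stack containing the cells.
#' @param darkFrames matched closed-shutter stack.
#' @param regions list of cell regions: logical masks or
#'   list(center, radius) circles (see \code{\link{cellRegions}}).
#' @param bgRoi background \linkS4class{ROI} adjacent to but not
#'   overlapping any cell; default centered 20%.
#' @return data.frame with one row per cell: cell_mean_gv, bg_mean_gv,
#'   bg_subtracted_gv, photon_noise_gv, snr, computable.
#' @export
cameraIndependentSnr <- function(cellFrames, darkFrames, regions,
                                 bgRoi = NULL) {
  img <- .asStack(cellFrames); drk <- .asStack(darkFrames)
  shape <- dim(img@pixels)[1:2]
  if (is.null(bgRoi)) bgRoi <- defaultRoi(shape)
  masks <- lapply(regions, .regionMask, shape = shape)
  bgMask <- matrix(FALSE, shape[1], shape[2])
  bgMask[(bgRoi@rowStart + 1):(bgRoi@rowStart + bgRoi@height),
         (bgRoi@colStart + 1):(bgRoi@colStart + bgRoi@width)] <- TRUE
  for (m in masks)
    if (any(m & bgMask))
      stop("background ROI must not overlap any cell region")
  bg <- darkImageStats(img, bgRoi)
  dk <- darkImageStats(drk, bgRoi)
  vPhoton <- bg$sd_gv^2 - dk$sd_gv^2
  computable <- vPhoton > 0
  noise <- sqrt(max(0, vPhoton))
  nFr <- nFrames(img)
  out <- do.call(rbind, lapply(seq_along(masks), function(i) {
    cellMean <- mean(vapply(seq_len(nFr), function(f)
      mean(img@pixels[, , f][masks[[i]]]), numeric(1)))
    sub <- cellMean - bg$mean_gv
    data.frame(cell = i, cell_mean_gv = cellMean, bg_mean_gv = bg$mean_gv,
               bg_subtracted_gv = sub,
               photon_noise_gv = noise,
               snr = if (computable) sub / noise else NA_real_,
               computable = computable)
  }))
  out
}

#' Theoretical signal-to-noise ratio of a uniform scene
#'
#' Mean signal over total noise from the additive budget: numerator
#' Gain * QE * P * t electrons, denominator the quadrature total of photon,
#' dark, CIC and read SDs (gain and excess noise applied consistently).
#' In the shot-noise-limited regime at unity gain this reduces to
#' sqrt(QE * P * t).
#'
#' @param spec a \linkS4class{CameraSpec}.
#' @param settings an \linkS4class{AcquisitionSettings}.
#' @param sceneFlux photons/s/px.
#' @return dimensionless SNR.
#' @export
theoreticalSnr <- function(spec, settings, sceneFlux) {
  b <- theoreticalNoiseBudget(spec, settings, sceneFlux)
  if (b@electrons[["mean_signal"]] == 0) return(0)
  b@electrons[["mean_signal"]] / b@electrons[["sd_total"]]
}
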