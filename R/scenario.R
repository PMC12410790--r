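#' Size a steady-source flux for a gain series
#'
#' Targets a mean above-dark signal of about \code{targetGv} gray values at
#' unity gain, but caps the flux so that at the highest gain in the recipe
#' the mean plus six standard deviations stays below ADC saturation (the
#' EM-amplified intensity distribution is right-skewed, so a generous
#' margin is needed).
#' A saturated steady source would violate the brightness validity
#' conditions of the intensity-ratio gain estimator.
#'
#' @param spec a \linkS4class{CameraSpec}.
#' @param maxGain the largest EM gain the source will be imaged at.
#' @param exposure exposure time in seconds.
#' @param targetGv desired above-dark mean in GV at unity gain.
#' @return flux in photons/s/px.
#' @export
steadySourceFlux <- function(spec, maxGain, exposure, targetGv = 1000) {
  satAt <- 2^spec@bitDepth - 1
  en <- .enFromModel(maxGain, spec@enModel, spec@nStages)
  headroom <- function(lam) {
    meanGv <- spec@kRatio * maxGain * lam + spec@bias
    sdGv <- spec@kRatio * sqrt(en^2 * maxGain^2 * lam + spec@readNoise^2)
    satAt - (meanGv + 6 * sdGv)
  }
  lamTarget <- targetGv / spec@kRatio
  lam <- lamTarget
  if (headroom(lamTarget) < 0) {
    upper <- (satAt - spec@bias) / (spec@kRatio * maxGain)
    lam <- stats::uniroot(headroom, c(0, upper))$root
  }
  lam / (spec@quantumEfficiency * exposure)
}

.cellSceneFlux <- function(scene) {
  flux <- matrix(scene@backgroundFlux + scene@excessBackgroundFlux,
                 scene@shape[1], scene@shape[2])
  if (nrow(scene@centers)) {
    rows <- matrix(seq_len(scene@shape[1]), scene@shape[1], scene@shape[2])
    cols <- matrix(seq_len(scene@shape[2]), scene@shape[1], scene@shape[2],
                   byrow = TRUE)
    for (i in seq_len(nrow(scene@centers))) {
      inside <- (rows - scene@centers[i, 1])^2 +
        (cols - scene@centers[i, 2])^2 <= scene@radii[i]^2
      flux[inside] <- scene@cellFlux + scene@excessBackgroundFlux
    }
  }
  PhotonScene(flux)
}

#' Photon scene of a CellScene
#'
#' @param scene a \linkS4class{CellScene}.
#' @return a \linkS4class{PhotonScene}: background + excess-background flux
#'   everywhere, cell flux (+ excess) inside cell disks.
#' @export
cellSceneFlux <- function(scene) {
  stopifnot(is(scene, "CellScene"))
  .cellSceneFlux(scene)
}

#' Generate a synthetic cell scene
#'
#' Places \code{nCells} non-overlapping disk-shaped cells uniformly at
#' random inside the sensor bounds, optionally keeping a centered rectangle
#' cell-free so a background ROI is guaranteed. Only the contrast statistics
#' of the scene matter to the SNR metrics; no morphology is modelled.
#'
#' @param nCells number of cells (>= 0).
#' @param shape integer c(rows, cols) of the sensor.
#' @param radiusRange c(min, max) cell radius in pixels.
#' @param backgroundFlux photons/s/px of the cell-free background.
#' @param cellFlux photons/s/px inside cells (>= backgroundFlux).
#' @param excessBackgroundFlux uniform stray-light flux, photons/s/px.
#' @param keepClearCenter keep the default centered ROI free of cells.
#' @param seed integer RNG seed.
#' @param maxTries placement attempts per cell before giving up.
#' @return a \linkS4class{CellScene}.
#' @export
generateCellScene <- function(nCells, shape = c(653L, 492L),
                              radiusRange = c(5, 15),
                              backgroundFlux = 100, cellFlux = 400,
                              excessBackgroundFlux = 0,
                              keepClearCenter = TRUE, seed = 1L,
                              maxTries = 200L) {
  stopifnot(nCells >= 0)
  clear <- if (keepClearCenter) defaultRoi(shape) else NULL
  place <- function() {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    for (i in seq_len(nCells)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        r <- stats::runif(1, radiusRange[1], radiusRange[2])
        cy <- stats::runif(1, r + 1, shape[1] - r)
        cx <- stats::runif(1, r + 1, shape[2] - r)
        overlaps <- nrow(centers) > 0 &&
          any(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) <
                radii + r + 2)
        inClear <- !is.null(clear) &&
          cy + r >= clear@rowStart && cy - r < clear@rowStart + clear@height &&
          cx + r >= clear@colStart && cx - r < clear@colStart + clear@width
        if (!overlaps && !inClear) {
          centers <- rbind(centers, c(cy, cx))
          radii <- c(radii, r)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could not place cell %d without overlap after %d tries",
                     i, maxTries))
    }
    list(centers = centers, radii = radii)
  }
  pl <- withr::with_seed(as.integer(seed), place())
  new("CellScene", backgroundFlux = as.numeric(backgroundFlux),
      cellFlux = as.numeric(cellFlux),
      excessBackgroundFlux = as.numeric(excessBackgroundFlux),
      centers = pl$centers, radii = pl$radii, shape = as.integer(shape))
}

#' Generate a calibration frame suite
#'
#' Produces the standard frame suites each calibration estimator expects,
#' with all other noise sources suppressed by design:
#' \describe{
#'   \item{read_noise}{n closed-shutter, 0-s, unity-gain frames (the
#'     "0G-0E" dark frames).}
#'   \item{dark_series}{closed-shutter unity-gain stacks at 0 s and at each
#'     recipe exposure.}
#'   \item{shot_series}{open-shutter uniform-flux stacks at each exposure,
#'     plus matched dark stacks.}
#'   \item{gain_series}{closed- and open-shutter stack pairs at unity gain
#'     and at each recipe gain, same exposure and steady source.}
#'   \item{cell_scene}{open-shutter stacks of a \linkS4class{CellScene}
#'     plus matched darks.}
#' }
#' Identical recipes (same master seed) yield bit-identical frames. Every
#' stack embeds the ground-truth spec and condition metadata.
#'
#' @param recipe a \linkS4class{SuiteRecipe}.
#' @return named list of \linkS4class{FrameStack}s.
#' @examples
#' spec <- CameraSpec(readNoise = 10, kRatio = 2, sensorShape = c(64, 64))
#' suite <- generateSuite(SuiteRecipe("read_noise", spec, nFrames = 3))
#' @export
generateSuite <- function(recipe) {
  stopifnot(is(recipe, "SuiteRecipe"))
  spec <- recipe@spec
  n <- recipe@nFrames
  ms <- recipe@masterSeed
  stackAt <- function(settings, scene, condIdx, label) {
    st <- simulateStack(spec, settings, n, scene, masterSeed = ms,
                        indexOffset = condIdx * 1000L)
    st@metadata <- list(condition = label, master_seed = ms)
    st
  }
  kind <- recipe@kind
  if (kind == "read_noise") {
    s <- AcquisitionSettings(0, 1, "g0", FALSE)
    return(list(read_noise = stackAt(s, NULL, 0L, "read_noise")))
  }
  if (kind == "dark_series") {
    if (length(recipe@exposures) < 1)
      stop("dark_series requires exposures")
    exps <- unique(c(0, recipe@exposures))
    out <- list()
    for (i in seq_along(exps)) {
      s <- AcquisitionSettings(exps[i], 1, "g0", FALSE)
      out[[sprintf("dark_t%g", exps[i])]] <-
        stackAt(s, NULL, i, sprintf("dark_t%g", exps[i]))
    }
    return(out)
  }
  if (kind == "shot_series") {
    if (length(recipe@exposures) < 2)
      stop("shot_series requires at least two exposures")
    flux <- recipe@flux
    if (is.na(flux))
      flux <- steadySourceFlux(spec, 1, min(recipe@exposures))
    scene <- PhotonScene(flux, spec@sensorShape)
    out <- list()
    for (i in seq_along(recipe@exposures)) {
      t <- recipe@exposures[i]
      sl <- AcquisitionSettings(t, 1, "g0", TRUE)
      sd <- AcquisitionSettings(t, 1, "g0", FALSE)
      out[[sprintf("light_t%g", t)]] <-
        stackAt(sl, scene, 2L * i, sprintf("light_t%g", t))
      out[[sprintf("dark_t%g", t)]] <-
        stackAt(sd, NULL, 2L * i + 1L, sprintf("dark_t%g", t))
    }
    return(out)
  }
  if (kind == "gain_series") {
    if (!length(recipe@gains) || is.null(names(recipe@gains)))
      stop("gain_series requires named gains (label -> EM gain)")
    t <- if (length(recipe@exposures)) recipe@exposures[1] else 0.05
    flux <- recipe@flux
    if (is.na(flux))
      flux <- steadySourceFlux(spec, max(recipe@gains), t)
    scene <- PhotonScene(flux, spec@sensorShape)
    out <- list()
    sl0 <- AcquisitionSettings(t, 1, "g0", TRUE)
    sd0 <- AcquisitionSettings(t, 1, "g0", FALSE)
    out[["light_g0"]] <- stackAt(sl0, scene, 0L, "light_g0")
    out[["dark_g0"]] <- stackAt(sd0, NULL, 1L, "dark_g0")
    for (i in seq_along(recipe@gains)) {
      lab <- names(recipe@gains)[i]
      g <- recipe@gains[[i]]
      sl <- AcquisitionSettings(t, g, lab, TRUE)
      sd <- AcquisitionSettings(t, g, lab, FALSE)
      out[[paste0("light_", lab)]] <-
        stackAt(sl, scene, 2L * i, paste0("light_", lab))
      out[[paste0("dark_", lab)]] <-
        stackAt(sd, NULL, 2L * i + 1L, paste0("dark_", lab))
    }
    return(out)
  }
  if (kind == "cell_scene") {
    if (is.null(recipe@scene))
      stop("cell_scene requires a CellScene in the recipe")
    t <- if (length(recipe@exposures)) recipe@exposures[1] else 0.05
    g <- if (length(recipe@gains)) recipe@gains[[1]] else 1
    lab <- if (g == 1) "g0" else names(recipe@gains)[1]
    scene <- .cellSceneFlux(recipe@scene)
    sl <- AcquisitionSettings(t, g, lab, TRUE)
    sd <- AcquisitionSettings(t, g, lab, FALSE)
    return(list(
      cells = stackAt(sl, scene, 0L, "cells"),
      dark = stackAt(sd, NULL, 1L, "dark")))
  }
  stop("unknown suite kind: ", kind)
}

#' Example camera matching the calibrated EMCCD of the package vignette
#'
#' Read noise 25.3 e-, K = 1.20 GV/e-, dark current 2.5 e-/s/px, CIC 25
#' e-/frame, 653 x 492 sensor, 16-bit ADC, sqrt(2) excess-noise model.
#'
#' @param ... overrides passed to \code{\link{CameraSpec}}.
#' @return a \linkS4class{CameraSpec}.
#' @export
demoCameraSpec <- function(...) {
  args <- list(readNoise = 25.3, kRatio = 1.2, darkCurrent = 2.5, cic = 25,
               sensorShape = c(653L, 492L))
  args[names(list(...))] <- list(...)
  do.call(CameraSpec, args)
}
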