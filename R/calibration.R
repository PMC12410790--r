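.popVar <- function(x) {
  x <- as.numeric(x)
  mean((x - mean(x))^2)
}
.popSd <- function(x) sqrt(.popVar(x))

# stop with a dedicated condition class so "signal too weak to measure"
# outcomes are distinguishable from programming errors
.notDetected <- function(msg) {
  stop(errorCondition(msg, class = c("camsnr_not_detected", "camsnrError")))
}

.asStack <- function(x) {
  if (is(x, "FrameStack")) return(x)
  if (is.matrix(x)) return(FrameStack(x, AcquisitionSettings()))
  stop("expected a FrameStack or a matrix")
}

.stackRoiStats <- function(stack, roi = NULL) {
  px <- stack@pixels
  if (is.null(roi)) roi <- defaultRoi(dim(px)[1:2])
  cropped <- cropRoi(stack, roi)
  n <- dim(cropped)[3]
  means <- vapply(seq_len(n), function(i) mean(cropped[, , i]), numeric(1))
  sds <- vapply(seq_len(n), function(i) .popSd(cropped[, , i]), numeric(1))
  data.frame(frame = seq_len(n), mean_gv = means, sd_gv = sds)
}

#' Per-frame ROI statistics of a dark (or any) frame stack
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param roi an \linkS4class{ROI}; default is the centered 20% region.
#' @return list(mean_gv, sd_gv, per_frame, settings): stack-level mean of
#'   the per-frame ROI means and SDs, plus the per-frame table.
#' @export
darkImageStats <- function(stack, roi = NULL) {
  stack <- .asStack(stack)
  tab <- .stackRoiStats(stack, roi)
  list(mean_gv = mean(tab$mean_gv), sd_gv = mean(tab$sd_gv),
       per_frame = tab, settings = stack@settings)
}

.sameSettings <- function(a, b, ignoreShutter = FALSE) {
  ok <- a@exposureTime == b@exposureTime && a@emGain == b@emGain
  if (!ignoreShutter) ok <- ok && a@shutterOpen == b@shutterOpen
  ok
}

#' Signed difference image with an additive bias
#'
#' Returns (a + bias) - b with no truncation of negative values. On real
#' 8/16-bit pipelines a difference clips negatives to zero; adding a bias
#' large enough first keeps every difference positive, so the result here is
#' always the exact integer difference shifted by the bias.
#'
#' @param a,b frames (matrices or single-frame \linkS4class{FrameStack}s)
#'   of identical shape.
#' @param bias gray values added to \code{a} before subtracting.
#' @return numeric matrix \code{a + bias - b}.
#' @export
differenceImage <- function(a, b, bias = 0) {
  am <- if (is(a, "FrameStack")) framePixels(a, 1) else a
  bm <- if (is(b, "FrameStack")) framePixels(b, 1) else b
  if (!identical(dim(am), dim(bm)))
    stop("frames must have identical shape")
  am + bias - bm
}

#' Check pixel independence via consecutive difference images
#'
#' If pixels have no fixed pattern and identical variance, the variance of a
#' difference of two frames equals the sum of the two frame variances.
#' Consecutive difference images (frame i+1 minus frame i) are computed in
#' the ROI; the observed value is the mean SD of those differences, the
#' expected value is the mean over pairs of sqrt(sd_i^2 + sd_(i+1)^2), and
#' similarity is the ratio min/max of the two means.
#'
#' @param frames a \linkS4class{FrameStack} with at least 2 frames.
#' @param roi an \linkS4class{ROI}; default centered 20%.
#' @return list(observed_sd, expected_sd, similarity, per_pair).
#' @export
checkPixelIndependence <- function(frames, roi = NULL) {
  frames <- .asStack(frames)
  n <- nFrames(frames)
  if (n < 2) stop("at least 2 frames are required")
  if (is.null(roi)) roi <- defaultRoi(dim(frames@pixels)[1:2])
  cropped <- cropRoi(frames, roi)
  sds <- vapply(seq_len(n), function(i) .popSd(cropped[, , i]), numeric(1))
  obs <- vapply(seq_len(n - 1), function(i)
    .popSd(cropped[, , i + 1] - cropped[, , i]), numeric(1))
  expd <- sqrt(sds[-n]^2 + sds[-1]^2)
  per <- data.frame(pair = seq_len(n - 1), observed_sd = obs,
                    expected_sd = expd)
  o <- mean(obs); e <- mean(expd)
  list(observed_sd = o, expected_sd = e,
       similarity = if (max(o, e) == 0) 1 else min(o, e) / max(o, e),
       per_pair = per)
}

#' Estimate read noise from zero-gain, zero-exposure dark frames
#'
#' With the shutter closed, zero exposure and no EM gain, the only noise
#' left is the read noise, so the mean ROI standard deviation in gray
#' values divided by K is the read noise in electrons.
#'
#' @param frames closed-shutter, 0-s, unity-gain \linkS4class{FrameStack}.
#' @param roi an \linkS4class{ROI}; default centered 20%.
#' @param kRatio gray values per electron.
#' @return list(value_e, sd_e, per_frame_gv, k_ratio_used).
#' @examples
#' # mean SD 30.3 GV at K = 1.20 gives 25.25 e-
#' @export
estimateReadNoise <- function(frames, roi = NULL, kRatio = 1) {
  frames <- .asStack(frames)
  s <- frames@settings
  if (s@shutterOpen || s@exposureTime != 0 || s@emGain != 1)
    stop("read-noise frames must be closed-shutter, 0-s exposure, unity gain")
  tab <- .stackRoiStats(frames, roi)
  list(value_e = mean(tab$sd_gv) / kRatio,
       sd_e = stats::sd(tab$sd_gv) / kRatio,
       per_frame_gv = tab$sd_gv,
       k_ratio_used = kRatio)
}

#' Estimate the gray-value/electron ratio K by the photon-transfer method
#'
#' For Poisson photoelectrons at unity gain, the photon-induced variance in
#' gray values equals K times the mean above-dark signal:
#' K = sigma_photon(GV)^2 / S(GV), with sigma_photon(GV)^2 the light-frame
#' ROI variance minus the matched dark-frame ROI variance and S(GV) the
#' above-dark mean. Gained stacks are rejected: with EM gain the
#' mean-variance ratio would include EN^2 * Gain.
#'
#' @param lightStack open-shutter \linkS4class{FrameStack} at unity gain.
#' @param darkStack matched closed-shutter stack (same exposure and gain).
#' @param roi an \linkS4class{ROI}; default centered 20%.
#' @return list(value, signal_gv, photon_var_gv, per_pair).
#' @export
estimateKRatio <- function(lightStack, darkStack, roi = NULL) {
  lightStack <- .asStack(lightStack); darkStack <- .asStack(darkStack)
  if (!.sameSettings(lightStack@settings, darkStack@settings,
                     ignoreShutter = TRUE))
    stop("light and dark stacks must share exposure and gain")
  if (lightStack@settings@emGain != 1)
    stop("K estimation is defined at unity gain only")
  lt <- .stackRoiStats(lightStack, roi)
  dk <- .stackRoiStats(darkStack, roi)
  s <- mean(lt$mean_gv) - mean(dk$mean_gv)
  vPhoton <- mean(lt$sd_gv^2) - mean(dk$sd_gv^2)
  if (s <= 0 || vPhoton <= 0)
    .notDetected("signal too weak: light variance or mean does not exceed dark")
  nPairs <- min(nrow(lt), nrow(dk))
  perPair <- vapply(seq_len(nPairs), function(i) {
    si <- lt$mean_gv[i] - dk$mean_gv[i]
    vi <- lt$sd_gv[i]^2 - dk$sd_gv[i]^2
    if (si > 0 && vi > 0) vi / si else NA_real_
  }, numeric(1))
  list(value = vPhoton / s, signal_gv = s, photon_var_gv = vPhoton,
       per_pair = perPair)
}

#' Largest exposure with negligible dark-current noise
#'
#' The dark-current SD stays below half the read noise as long as
#' t < 0.25 * readNoise^2 / darkCurrent.
#'
#' @param readNoiseE read noise in electrons.
#' @param darkCurrent dark current in electrons/s/px.
#' @return seconds; \code{Inf} when darkCurrent is 0.
#' @examples
#' maxNegligibleExposure(1, 0.1)    # 2.5 s
#' maxNegligibleExposure(1, 0.001)  # 250 s
#' @export
maxNegligibleExposure <- function(readNoiseE, darkCurrent) {
  stopifnot(readNoiseE >= 0, darkCurrent >= 0)
  if (darkCurrent == 0) return(Inf)
  0.25 * readNoiseE^2 / darkCurrent
}

#' Fit the dark current from a closed-shutter exposure series
#'
#' Per exposure, the dark-current variance is isolated by subtracting the
#' zero-exposure (read-noise-only) variance; exposures where the observed
#' variance does not exceed the zero-exposure variance are flagged
#' not-detected and excluded (never zero-filled into the fit). The dark
#' current is the slope of an unweighted least-squares fit of isolated
#' variance (in electrons^2) against exposure time through the origin.
#'
#' @param darkStacks list of closed-shutter unity-gain
#'   \linkS4class{FrameStack}s; must include a 0-s stack (or pass
#'   \code{zeroExposureStats}).
#' @param roi an \linkS4class{ROI}; default centered 20%.
#' @param kRatio gray values per electron.
#' @param zeroExposureStats optional \code{\link{darkImageStats}} of the
#'   0-s stack, if not part of \code{darkStacks}.
#' @return list(value, detected, per_exposure, fit, upper_bound_e_per_s).
#'   When dark current is undetected at every exposure, \code{value} is NA,
#'   \code{detected} FALSE, and \code{upper_bound_e_per_s} carries the bound
#'   0.25 * readNoise^2 / max(t) implied by the detection failure.
#' @export
fitDarkCurrent <- function(darkStacks, roi = NULL, kRatio = 1,
                           zeroExposureStats = NULL) {
  stacks <- lapply(darkStacks, .asStack)
  for (st in stacks) {
    s <- st@settings
    if (s@shutterOpen || s@emGain != 1)
      stop("dark-current stacks must be closed-shutter at unity gain")
  }
  exps <- vapply(stacks, function(s) s@settings@exposureTime, numeric(1))
  if (is.null(zeroExposureStats)) {
    if (!any(exps == 0))
      stop("a 0-s exposure stack (or zeroExposureStats) is required")
    zeroExposureStats <- darkImageStats(stacks[[which(exps == 0)[1]]], roi)
  }
  v0 <- zeroExposureStats$sd_gv^2
  keep <- exps > 0
  if (sum(keep) < 2)
    stop("at least 2 nonzero exposures are required")
  stacks <- stacks[keep]; exps <- exps[keep]
  ord <- order(exps)
  stacks <- stacks[ord]; exps <- exps[ord]
  tab <- do.call(rbind, lapply(seq_along(stacks), function(i) {
    st <- darkImageStats(stacks[[i]], roi)
    vt <- st$sd_gv^2
    detected <- vt > v0
    isoVarE <- if (detected) (vt - v0) / kRatio^2 else 0
    data.frame(exposure_s = exps[i], var_gv = vt,
               isolated_var_e2 = isoVarE,
               isolated_sd_e = sqrt(isoVarE), detected = detected)
  }))
  readE <- sqrt(v0) / kRatio
  if (!any(tab$detected)) {
    return(list(value = NA_real_, detected = FALSE, per_exposure = tab,
                fit = NULL,
                upper_bound_e_per_s = 0.25 * readE^2 / max(exps)))
  }
  det <- tab[tab$detected, ]
  fit <- stats::lm(isolated_var_e2 ~ 0 + exposure_s, data = det)
  list(value = unname(stats::coef(fit)[1]), detected = TRUE,
       per_exposure = tab,
       fit = list(residuals = stats::residuals(fit),
                  fitted = stats::fitted(fit),
                  n_used = nrow(det)),
       upper_bound_e_per_s = NA_real_)
}

#' Verify square-root-of-time scaling of photon shot noise
#'
#' Photon shot noise at each exposure is isolated by subtracting the
#' matched dark-image variance (clamped at zero when undetected). Since
#' the photoelectron count is Poisson with mean proportional to t, the
#' photon SD at exposure t_i is predicted from the shortest exposure t_1 as
#' observed(t_1) * sqrt(t_i / t_1).
#'
#' @param lightStacks list of open-shutter stacks at increasing exposures,
#'   identical flux and gain.
#' @param darkStacks matched closed-shutter stacks, same exposures.
#' @param roi an \linkS4class{ROI}; default centered 20%.
#' @return list(per_exposure, max_rel_deviation).
#' @export
verifyShotNoiseScaling <- function(lightStacks, darkStacks, roi = NULL) {
  lightStacks <- lapply(lightStacks, .asStack)
  darkStacks <- lapply(darkStacks, .asStack)
  if (length(lightStacks) < 2)
    stop("at least 2 exposures are required")
  if (length(lightStacks) != length(darkStacks))
    stop("one matched dark stack per light stack is required")
  exps <- vapply(lightStacks, function(s) s@settings@exposureTime, numeric(1))
  ord <- order(exps)
  lightStacks <- lightStacks[ord]; darkStacks <- darkStacks[ord]
  exps <- exps[ord]
  obs <- vapply(seq_along(exps), function(i) {
    if (!.sameSettings(lightStacks[[i]]@settings, darkStacks[[i]]@settings,
                       ignoreShutter = TRUE))
      stop("light and dark stacks must share exposure and gain")
    lt <- darkImageStats(lightStacks[[i]], roi)
    dk <- darkImageStats(darkStacks[[i]], roi)
    sqrt(max(0, lt$sd_gv^2 - dk$sd_gv^2))
  }, numeric(1))
  if (obs[1] == 0)
    .notDetected("photon noise undetected at the shortest exposure")
  pred <- obs[1] * sqrt(exps / exps[1])
  tab <- data.frame(exposure_s = exps, observed_sd_gv = obs,
                    predicted_sd_gv = pred)
  list(per_exposure = tab,
       max_rel_deviation = max(abs(obs - pred) / pred))
}

#' Estimate EM gain from intensity ratios of a steady source
#'
#' Gain = (mean light at gain g_i minus its matched dark) over (mean light
#' at unity gain minus its matched dark), for the same steady scene and
#' exposure. Diagnostics report the above-dark relative SD at each gain
#' (the source must be bright and steady) and, when a half-exposure stack
#' at g_i is supplied, the ratio of its above-dark intensity to half the
#' full-exposure intensity (should be near 1).
#'
#' @param lightG0,darkG0 stacks at unity gain (open / closed shutter).
#' @param lightGi,darkGi stacks at the gained setting.
#' @param roi an \linkS4class{ROI}; default centered 20%.
#' @param halfExposureLightGi optional open-shutter stack at g_i and half
#'   the exposure, for the validity check.
#' @param halfExposureDarkGi optional matched dark for the half-exposure
#'   check.
#' @return list(value, diagnostics).
#' @export
estimateEmGain <- function(lightG0, darkG0, lightGi, darkGi, roi = NULL,
                           halfExposureLightGi = NULL,
                           halfExposureDarkGi = NULL) {
  lightG0 <- .asStack(lightG0); darkG0 <- .asStack(darkG0)
  lightGi <- .asStack(lightGi); darkGi <- .asStack(darkGi)
  if (lightG0@settings@emGain != 1)
    stop("the g0 stacks must be at unity gain")
  if (lightG0@settings@exposureTime != lightGi@settings@exposureTime)
    stop("all four stacks must share one exposure time")
  l0 <- darkImageStats(lightG0, roi); d0 <- darkImageStats(darkG0, roi)
  li <- darkImageStats(lightGi, roi); di <- darkImageStats(darkGi, roi)
  s0 <- l0$mean_gv - d0$mean_gv
  si <- li$mean_gv - di$mean_gv
  if (s0 <= 0)
    stop("denominator (above-dark signal at unity gain) must be positive")
  diagnostics <- list(
    rel_sd_g0 = l0$sd_gv / s0,
    rel_sd_gi = li$sd_gv / si,
    half_exposure_ratio = NA_real_)
  if (!is.null(halfExposureLightGi) && !is.null(halfExposureDarkGi)) {
    lh <- darkImageStats(.asStack(halfExposureLightGi), roi)
    dh <- darkImageStats(.asStack(halfExposureDarkGi), roi)
    diagnostics$half_exposure_ratio <- (lh$mean_gv - dh$mean_gv) / (si / 2)
  }
  list(value = si / s0, diagnostics = diagnostics)
}

#' Estimate clock-induced charge from gained vs ungained dark frames
#'
#' The variance of a short-exposure dark frame at gain g_i exceeds that of
#' the unity-gain dark frame by the amplified CIC plus the amplification of
#' the dark-current noise:
#' CIC = (var_e(g_i) - var_e(g0) - (EN^2 Gain^2 - 1) * Dark * t) /
#' (EN^2 Gain^2), with the gray-value variances converted to electrons^2
#' via K. Negative results clamp to 0 with \code{detected = FALSE}.
#'
#' @param darkG0Stats \code{\link{darkImageStats}} of the unity-gain dark
#'   stack (or the stack itself).
#' @param darkGiStats stats (or stack) of the gained dark stack.
#' @param emGain the calculated EM gain of the gained stack (> 1).
#' @param excessNoise EN factor to use; default sqrt(2).
#' @param darkCurrent e-/s/px; 0 when negligible/undetected.
#' @param exposure exposure time in seconds (identical for both stacks).
#' @param kRatio gray values per electron.
#' @return list(value, detected, var_g0_e2, var_gi_e2).
#' @export
estimateCic <- function(darkG0Stats, darkGiStats, emGain,
                        excessNoise = sqrt(2), darkCurrent = 0,
                        exposure = 0, kRatio = 1) {
  if (emGain <= 1) stop("CIC estimation requires emGain > 1")
  if (is(darkG0Stats, "FrameStack") || is.matrix(darkG0Stats))
    darkG0Stats <- darkImageStats(darkG0Stats)
  if (is(darkGiStats, "FrameStack") || is.matrix(darkGiStats))
    darkGiStats <- darkImageStats(darkGiStats)
  v0 <- darkG0Stats$sd_gv^2 / kRatio^2
  vi <- darkGiStats$sd_gv^2 / kRatio^2
  eg2 <- excessNoise^2 * emGain^2
  cic <- (vi - v0 - (eg2 - 1) * darkCurrent * exposure) / eg2
  list(value = max(0, cic), detected = cic > 0,
       var_g0_e2 = v0, var_gi_e2 = vi)
}

#' Run the full calibration pipeline over generated (or loaded) suites
#'
#' Applies each estimator to its frame suite: pixel independence and read
#' noise from the zero-exposure dark frames, K from the unity-gain
#' light/dark pair of the gain series (or the shortest shot-series
#' exposure), dark current from the exposure series, then EM gain and CIC
#' per gained setting (CIC averaged over gains with equal weight).
#'
#' @param suites named list with any of: \code{read_noise} (a stack),
#'   \code{dark_series}, \code{shot_series}, \code{gain_series} (lists of
#'   stacks as produced by \code{\link{generateSuite}}).
#' @param roi an \linkS4class{ROI}; default centered 20%.
#' @param excessNoise EN factor for gained-frame estimators (default
#'   sqrt(2)).
#' @return a \linkS4class{CalibrationReport}.
#' @export
calibrate <- function(suites, roi = NULL, excessNoise = sqrt(2)) {
  rep <- new("CalibrationReport", readNoise = list(), kRatio = list(),
             darkCurrent = list(), emGain = numeric(), cic = list(),
             pixelIndependence = list(), enFactor = excessNoise)
  k <- 1
  if (!is.null(suites$read_noise)) {
    rn <- suites$read_noise
    rep@pixelIndependence <- checkPixelIndependence(rn, roi)
    rep@readNoise <- estimateReadNoise(rn, roi, kRatio = 1)
  }
  gs <- suites$gain_series
  # prefer the brightest unity-gain light/dark pair for K: its precision
  # propagates as K^2 into the dark-current and CIC unit conversions
  if (!is.null(suites$shot_series)) {
    ss <- suites$shot_series
    ln <- grep("^light_", names(ss), value = TRUE)
    if (length(ln)) {
      exps <- vapply(ss[ln], function(s) s@settings@exposureTime, numeric(1))
      lab <- sub("^light_", "", ln[which.max(exps)])
      rep@kRatio <- estimateKRatio(ss[[paste0("light_", lab)]],
                                   ss[[paste0("dark_", lab)]], roi)
      k <- rep@kRatio$value
    }
  }
  if (!length(rep@kRatio) && !is.null(gs) && !is.null(gs$light_g0) &&
      !is.null(gs$dark_g0)) {
    rep@kRatio <- estimateKRatio(gs$light_g0, gs$dark_g0, roi)
    k <- rep@kRatio$value
  }
  if (length(rep@readNoise)) {
    rep@readNoise$value_e <- rep@readNoise$value_e / k
    rep@readNoise$sd_e <- rep@readNoise$sd_e / k
    rep@readNoise$k_ratio_used <- k
  }
  if (!is.null(suites$dark_series))
    rep@darkCurrent <- fitDarkCurrent(suites$dark_series, roi, kRatio = k)
  darkRate <- if (isTRUE(rep@darkCurrent$detected)) rep@darkCurrent$value else 0
  if (!is.null(gs)) {
    gained <- setdiff(unique(sub("^(light|dark)_", "", names(gs))), "g0")
    gains <- numeric(); cics <- list()
    for (lab in gained) {
      lg <- gs[[paste0("light_", lab)]]; dg <- gs[[paste0("dark_", lab)]]
      if (is.null(lg) || is.null(dg)) next
      gains[lab] <- estimateEmGain(gs$light_g0, gs$dark_g0, lg, dg,
                                   roi)$value
      if (gains[lab] <= 1) next  # no multiplication, no CIC to isolate
      cics[[lab]] <- estimateCic(
        darkImageStats(gs$dark_g0, roi), darkImageStats(dg, roi),
        emGain = gains[lab], excessNoise = excessNoise,
        darkCurrent = darkRate, exposure = dg@settings@exposureTime,
        kRatio = k)
    }
    rep@emGain <- gains
    if (length(cics)) {
      per <- vapply(cics, `[[`, numeric(1), "value")
      rep@cic <- list(per_gain = per, average = mean(per),
                      detected = any(vapply(cics, `[[`, logical(1),
                                            "detected")))
    }
  }
  rep
}
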