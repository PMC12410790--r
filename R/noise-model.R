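#' Derive a per-frame seed from a master seed
#'
#' Deterministic derivation so that suites are reproducible frame-by-frame:
#' seed_i = (48271 * master + 1009 * index) mod (2^31 - 1), mapped away from
#' zero. Indices may encode (condition, frame) positions.
#'
#' @param masterSeed integer master seed.
#' @param index non-negative integer stream index.
#' @return a single integer seed in \[1, 2^31 - 2\].
#' @export
deriveSeed <- function(masterSeed, index) {
  m <- 2147483647
  s <- (48271 * (as.double(masterSeed) %% m) + 1009 * as.double(index)) %% m
  as.integer(s) + 1L
}

.enFromModel <- function(emGain, enModel, nStages = 500L) {
  if (enModel == "none" || emGain == 1) return(1)
  if (enModel == "sqrt2") return(sqrt(2))
  # branching cascade: nStages stages, per-stage duplication probability p,
  # offspring mean m = 1 + p with m^nStages = emGain.  For a Galton-Watson
  # cascade started from one electron the output variance is
  # sigma2 * m^(N-1) * (m^N - 1)/(m - 1) with per-stage offspring variance
  # sigma2 = p(1-p); for Poisson input the squared excess-noise factor is
  # 1 + Var_single / Gain^2.
  p <- emGain^(1 / nStages) - 1
  m <- 1 + p
  varSingle <- p * (1 - p) * m^(nStages - 1) * (m^nStages - 1) / (m - 1)
  sqrt(1 + varSingle / emGain^2)
}

#' Excess-noise factor of the electron-multiplication cascade
#'
#' The EM gain register amplifies stochastically, inflating the standard
#' deviation of any Poisson-distributed electron input by the excess-noise
#' factor EN (about sqrt(2) at high gain). \code{enModel = "none"} or unity
#' gain give 1; \code{"sqrt2"} gives exactly sqrt(2); \code{"branching"}
#' returns the closed-form factor of the Bernoulli-duplication cascade used
#' by \code{\link{applyEmGain}}, which tends to sqrt(2) as gain grows.
#'
#' @param emGain electron-multiplication gain (>= 1).
#' @param enModel "none", "sqrt2", or "branching".
#' @param nStages gain-register stages for the branching model.
#' @return the dimensionless excess-noise factor.
#' @examples
#' excessNoiseFactor(103.5, "sqrt2")   # sqrt(2)
#' excessNoiseFactor(103.5, "branching")
#' @export
excessNoiseFactor <- function(emGain, enModel = "sqrt2", nStages = 500L) {
  if (!is.numeric(emGain) || length(emGain) != 1L || !is.finite(emGain) ||
      emGain < 1)
    stop("emGain must be a single value >= 1")
  enModel <- match.arg(enModel, .EN_MODELS)
  .enFromModel(emGain, enModel, nStages)
}

.amplify <- function(electrons, emGain, enModel, nStages = 500L) {
  n <- as.numeric(electrons)
  if (emGain == 1) return(n)
  if (enModel == "none") return(n * emGain)
  if (enModel == "sqrt2") {
    # Conditional output law n -> Gamma(shape = n, scale = Gain): mean
    # Gain*n, variance n*Gain^2, so Poisson(lambda) input comes out with
    # variance 2*Gain^2*lambda = EN^2*Gain^2*lambda, EN = sqrt(2).
    out <- numeric(length(n))
    pos <- n > 0
    if (any(pos)) out[pos] <- stats::rgamma(sum(pos), shape = n[pos],
                                            scale = emGain)
    return(out)
  }
  # branching: each stage duplicates every electron independently with
  # probability p; after nStages stages the mean multiplication is
  # (1+p)^nStages = emGain.
  p <- emGain^(1 / nStages) - 1
  out <- n
  for (s in seq_len(nStages)) {
    active <- out > 0
    if (!any(active)) break
    out[active] <- out[active] + stats::rbinom(sum(active), out[active], p)
  }
  out
}

#' Apply stochastic electron-multiplication gain to an electron field
#'
#' Per pixel, the input electron count is amplified so that the output mean
#' is exactly \code{emGain} times the input and the output variance for
#' Poisson(lambda) input equals EN^2 * Gain^2 * lambda. The "sqrt2" model
#' draws from a Gamma law with that mean and variance; "branching" simulates
#' the per-stage Bernoulli duplication cascade; "none" multiplies
#' deterministically.
#'
#' @param electrons matrix/vector of non-negative integer electron counts.
#' @param emGain electron-multiplication gain (>= 1).
#' @param enModel "none", "sqrt2", or "branching".
#' @param seed optional integer seed for reproducibility.
#' @param nStages stages for the branching cascade.
#' @return amplified electron field, same shape as the input.
#' @export
applyEmGain <- function(electrons, emGain, enModel = "sqrt2", seed = NULL,
                        nStages = 500L) {
  if (any(electrons < 0)) stop("electron counts must be >= 0")
  if (any(electrons != round(electrons)))
    stop("electron counts must be integers")
  if (!is.numeric(emGain) || emGain < 1)
    stop("emGain must be >= 1")
  enModel <- match.arg(enModel, .EN_MODELS)
  run <- function() .amplify(electrons, emGain, enModel, nStages)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (is.matrix(electrons)) out <- matrix(out, nrow = nrow(electrons))
  out
}

#' Simulate one raw camera frame
#'
#' Full image-formation chain: photoelectrons ~ Poisson(QE * flux * t) when
#' the shutter is open, plus dark electrons ~ Poisson(Dark * t), plus
#' clock-induced charge ~ Poisson(CIC) when the gain register is active
#' (emGain > 1); the sum passes through the stochastic EM gain; Gaussian read
#' noise (SD readNoise electrons) is added; gray value =
#' round(K * electrons + bias) clipped to the ADC range.
#'
#' @param spec a \linkS4class{CameraSpec}.
#' @param settings an \linkS4class{AcquisitionSettings}.
#' @param scene a \linkS4class{PhotonScene}; ignored (may be NULL) when the
#'   shutter is closed.
#' @param seed integer RNG seed for the frame.
#' @return a \linkS4class{FrameStack} with one frame. A warning is issued
#'   (frame still returned) if more than 1% of pixels saturate.
#' @examples
#' spec <- CameraSpec(readNoise = 25.3, kRatio = 1.2, sensorShape = c(64, 64))
#' fr <- simulateFrame(spec, AcquisitionSettings(), seed = 1)
#' @export
simulateFrame <- function(spec, settings, scene = NULL, seed = 1L) {
  stopifnot(is(spec, "CameraSpec"), is(settings, "AcquisitionSettings"))
  shape <- spec@sensorShape
  npx <- prod(shape)
  if (settings@shutterOpen) {
    if (is.null(scene)) stop("an open shutter requires a PhotonScene")
    if (!identical(dim(scene@flux), as.integer(shape)))
      stop("scene shape must match the sensor shape")
    lambdaSignal <- spec@quantumEfficiency * scene@flux * settings@exposureTime
  } else {
    lambdaSignal <- matrix(0, shape[1], shape[2])
  }
  lambdaDark <- spec@darkCurrent * settings@exposureTime
  lambdaCic <- if (settings@emGain > 1) spec@cic else 0

  gv <- withr::with_seed(as.integer(seed), {
    n <- stats::rpois(npx, as.numeric(lambdaSignal)) +
      stats::rpois(npx, lambdaDark) +
      stats::rpois(npx, lambdaCic)
    e <- .amplify(n, settings@emGain, spec@enModel, spec@nStages)
    e <- e + stats::rnorm(npx, 0, spec@readNoise)
    round(spec@kRatio * e + spec@bias)
  })
  satAt <- 2^spec@bitDepth - 1
  nSat <- sum(gv > satAt)
  if (nSat > 0.01 * npx)
    warning(sprintf("%.1f%% of pixels saturated at %d GV",
                    100 * nSat / npx, satAt))
  gv <- pmin(pmax(gv, 0), satAt)
  FrameStack(matrix(as.integer(gv), shape[1], shape[2]), settings,
             spec = spec, seeds = as.integer(seed))
}

#' Simulate a stack of frames sharing one setting
#'
#' @param spec a \linkS4class{CameraSpec}.
#' @param settings an \linkS4class{AcquisitionSettings}.
#' @param n number of frames.
#' @param scene optional \linkS4class{PhotonScene}.
#' @param masterSeed integer; per-frame seeds derive via
#'   \code{\link{deriveSeed}}.
#' @param indexOffset stream offset so different stacks of one suite use
#'   disjoint seed streams.
#' @return a \linkS4class{FrameStack} with \code{n} frames.
#' @export
simulateStack <- function(spec, settings, n, scene = NULL, masterSeed = 1L,
                          indexOffset = 0L) {
  seeds <- vapply(seq_len(n) + indexOffset, function(i)
    deriveSeed(masterSeed, i), integer(1))
  shape <- spec@sensorShape
  px <- array(0L, dim = c(shape[1], shape[2], n))
  for (i in seq_len(n))
    px[, , i] <- framePixels(simulateFrame(spec, settings, scene, seeds[i]), 1)
  FrameStack(px, settings, spec = spec, seeds = seeds)
}

#' Theoretical per-source noise budget
#'
#' Computes the additive noise decomposition for a uniform scene: mean
#' signal Gain * QE * P * t electrons; photon shot SD EN * Gain *
#' sqrt(QE * P * t); dark SD EN * Gain * sqrt(Dark * t); CIC SD
#' EN * Gain * sqrt(CIC) (zero at unity gain); read SD readNoise. The total
#' is the quadrature sum, so total variance equals the sum of component
#' variances exactly by construction. Gray-value entries are the electron
#' entries multiplied by K.
#'
#' @param spec a \linkS4class{CameraSpec}.
#' @param settings an \linkS4class{AcquisitionSettings}.
#' @param sceneFlux uniform scene flux in photons/s/px (0 for dark frames);
#'   ignored (treated as 0) when the shutter is closed.
#' @return a \linkS4class{NoiseBudget}.
#' @examples
#' spec <- CameraSpec(cic = 4, readNoise = 25.25, kRatio = 1.2)
#' budget <- theoreticalNoiseBudget(spec, AcquisitionSettings(emGain = 103.5))
#' @export
theoreticalNoiseBudget <- function(spec, settings, sceneFlux = 0) {
  stopifnot(is(spec, "CameraSpec"), is(settings, "AcquisitionSettings"))
  g <- settings@emGain
  en <- .enFromModel(g, spec@enModel, spec@nStages)
  t <- settings@exposureTime
  p <- if (settings@shutterOpen) sceneFlux else 0
  nSignal <- spec@quantumEfficiency * p * t
  e <- c(
    mean_signal = g * nSignal,
    sd_photon = en * g * sqrt(nSignal),
    sd_dark = en * g * sqrt(spec@darkCurrent * t),
    sd_cic = if (g > 1) en * g * sqrt(spec@cic) else 0,
    sd_read = spec@readNoise,
    sd_total = NA_real_
  )
  e["sd_total"] <- sqrt(sum(e[c("sd_photon", "sd_dark", "sd_cic",
                                "sd_read")]^2))
  new("NoiseBudget", electrons = e, grayValues = e * spec@kRatio)
}
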