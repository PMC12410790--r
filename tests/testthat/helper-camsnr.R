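# shared fixture builders: everything is generated in code at test time

# the camera whose fitted parameters anchor the recovery tests
paperSpec <- function(...) {
  camsnr::demoCameraSpec(...)
}

# small sensor for fast statistical tests (still >= 3e4 pixels)
smallSpec <- function(...) {
  args <- list(sensorShape = c(220L, 180L))
  args[names(list(...))] <- list(...)
  do.call(camsnr::CameraSpec, args)
}

# population SD (the package measures ROI noise as population SD)
popSd <- function(x) sqrt(mean((x - mean(x))^2))

darkSettings <- function(t = 0, gain = 1) {
  camsnr::AcquisitionSettings(t, gain,
                              if (gain == 1) "g0" else "gi", FALSE)
}

lightSettings <- function(t, gain = 1) {
  camsnr::AcquisitionSettings(t, gain,
                              if (gain == 1) "g0" else "gi", TRUE)
}
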