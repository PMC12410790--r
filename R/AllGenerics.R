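#' Number of frames in a stack
#' @param x a \linkS4class{FrameStack}
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Acquisition settings of an object
#' @param x a \linkS4class{FrameStack}
#' @return an \linkS4class{AcquisitionSettings}
#' @export
setGeneric("acquisition", function(x) standardGeneric("acquisition"))

#' Pixel data of an object
#' @param x a \linkS4class{FrameStack}
#' @param i optional frame index; when given, a single matrix is returned
#' @return integer array (rows, cols, n) or a matrix
#' @export
setGeneric("framePixels", function(x, i) standardGeneric("framePixels"))

#' Generating camera spec of an object (NULL when unknown)
#' @param x a \linkS4class{FrameStack}
#' @return a \linkS4class{CameraSpec} or NULL
#' @export
setGeneric("cameraSpec", function(x) standardGeneric("cameraSpec"))

#' Extract an ROI as a pixel matrix (or array over frames)
#' @param x a matrix or \linkS4class{FrameStack}
#' @param roi an \linkS4class{ROI}
#' @return cropped pixels
#' @export
setGeneric("cropRoi", function(x, roi) standardGeneric("cropRoi"))
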