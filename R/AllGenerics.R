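#' @include fft-utils.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the package classes: `gammas()` returns
#' per-capture intensity factors, `defocus()` the defocus distance in
#' micrometres, `lossHistory()` the per-epoch objective trace,
#' `nFrames()` the number of low-resolution captures, `pixelSize()` the
#' object-plane pixel pitch in micrometres, and `wavevectors()` the per-LED
#' spectral shifts in 1/um.
#'
#' @param x An object of one of the package classes.
#' @return The slot value documented above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gammas", function(x) standardGeneric("gammas"))

#' @rdname accessors
#' @export
setGeneric("defocus", function(x) standardGeneric("defocus"))

#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("wavevectors", function(x) standardGeneric("wavevectors"))

#' @rdname accessors
#' @export
setGeneric("phaseMap", function(x) standardGeneric("phaseMap"))

#' @rdname accessors
#' @export
setGeneric("absorptionMap", function(x) standardGeneric("absorptionMap"))
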