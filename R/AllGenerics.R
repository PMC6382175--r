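#' @include AllClasses.R
NULL

#' Number of saved frames
#' @param x a [Chronogram-class].
#' @return integer.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame times
#' @param x a [Chronogram-class].
#' @return numeric vector.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Domain length (in length units) per frame
#' @param x a [Chronogram-class].
#' @return numeric vector.
#' @export
setGeneric("domainLengths", function(x) standardGeneric("domainLengths"))

#' Extract one frame as a data frame
#' @param x a [Chronogram-class].
#' @param j frame index (negative counts from the end; default last frame).
#' @return data.frame with columns `x`, `activator`, `inhibitor`,
#'   `maturation`, `density`, `regime`.
#' @export
setGeneric("getFrame", function(x, j = -1L) standardGeneric("getFrame"))

#' Extract a full field matrix (frames x nodes, NA padded)
#' @param x a [Chronogram-class].
#' @param field one of "activator", "inhibitor", "maturation", "density",
#'   "regime".
#' @return numeric matrix.
#' @export
setGeneric("fieldMatrix", function(x, field = "activator")
  standardGeneric("fieldMatrix"))

#' Event table of an EventLog
#' @param x an [EventLog-class].
#' @param type optional filter on event type(s).
#' @return data.frame of events.
#' @export
setGeneric("events", function(x, type = NULL) standardGeneric("events"))

#' Fastest-growing wavenumber
#' @param x a [DispersionResult-class].
#' @return numeric scalar.
#' @export
setGeneric("kMax", function(x) standardGeneric("kMax"))

#' Regime classification label
#' @param x a [DispersionResult-class].
#' @return character scalar.
#' @export
setGeneric("regimeLabel", function(x) standardGeneric("regimeLabel"))
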