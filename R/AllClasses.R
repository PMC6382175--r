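#' @import methods
NULL

#' Space-time record of a simulation (kymograph container)
#'
#' A `Chronogram` stores every saved frame of a simulation on the (possibly
#' growing) one-dimensional grid: the activator, inhibitor, maturation and
#' cell-density fields, the mesenchyme activity, and the per-cell regime
#' flag, together with the fully resolved configuration and seed that
#' produced it. Field matrices are frames x grid nodes, right-padded with
#' `NA` while the domain is still short of its final length. The anterior
#' end is at `x = 0`; node `j` sits at `x = (j-1) * dx`.
#'
#' @slot times numeric, time of each saved frame.
#' @slot lengths integer, number of active grid nodes per frame
#'   (non-decreasing).
#' @slot dx grid spacing.
#' @slot activator,inhibitor,maturation,density numeric matrices
#'   (frames x max nodes, `NA`-padded).
#' @slot regime integer matrix, 0 = bistable, 1 = turing, `NA`-padded.
#' @slot mesenchyme numeric, posterior mesenchyme activity per frame.
#' @slot config fully resolved configuration list.
#' @slot seed integer seed used for the initial perturbation.
#' @slot clipped number of field values clipped to zero during the run.
#' @export
setClass("Chronogram",
  representation(
    times = "numeric", lengths = "integer", dx = "numeric",
    activator = "matrix", inhibitor = "matrix", maturation = "matrix",
    density = "matrix", regime = "matrix", mesenchyme = "numeric",
    config = "list", seed = "integer", clipped = "numeric"
  )
)

setValidity("Chronogram", function(object) {
  nf <- length(object@times)
  msgs <- character()
  if (length(object@lengths) != nf) {
    msgs <- c(msgs, "lengths and times must have equal length")
  }
  if (nf > 1 && any(diff(object@lengths) < 0)) {
    msgs <- c(msgs, "grid length must be non-decreasing in time")
  }
  for (nm in c("activator", "inhibitor", "maturation", "density", "regime")) {
    m <- slot(object, nm)
    if (nrow(m) != nf) msgs <- c(msgs, paste0(nm, " must have one row per frame"))
  }
  act <- object@activator
  for (j in seq_len(nf)) {
    n <- object@lengths[j]
    vals <- act[j, seq_len(n)]
    if (any(!is.finite(vals))) {
      msgs <- c(msgs, sprintf("non-finite activator values in frame %d", j))
      break
    }
    if (any(vals < 0)) {
      msgs <- c(msgs, sprintf("negative activator values in frame %d", j))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Typed pattern events extracted from a chronogram
#'
#' Ordered, timestamped events of the patterning phenomenology: peak
#' `birth`, `erasure`, `recovery` (a birth overlapping a prior erasure
#' site), `fusion` (two peaks merging into one that persists) and
#' `front_passage` (a broad activation front sweeping over a peak, with
#' fitted speed).
#'
#' @slot events data.frame with columns `type`, `time`, `x`, `peak_id`,
#'   `parents`, `speed`.
#' @slot parameters list of the detection parameters used (`theta_peak`,
#'   `w_min`, `persistence_min`, ...).
#' @export
setClass("EventLog",
  representation(events = "data.frame", parameters = "list")
)

setValidity("EventLog", function(object) {
  need <- c("type", "time", "x", "peak_id", "parents", "speed")
  if (!all(need %in% names(object@events))) {
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  }
  ok_types <- c("birth", "erasure", "recovery", "fusion", "front_passage")
  if (nrow(object@events) && !all(object@events$type %in% ok_types)) {
    return("unknown event type")
  }
  ev <- object@events
  if (nrow(ev) > 1 && is.unsorted(ev$time)) return("events must be time-ordered")
  TRUE
})

#' Linear dispersion analysis result
#'
#' Growth rate of spatial modes around a homogeneous reference state, the
#' fastest-growing wavenumber, and the regime classification of the
#' parameter set.
#'
#' @slot k wavenumber grid (includes 0).
#' @slot lambda maximal real eigenvalue part of `J - D k^2` per wavenumber.
#' @slot k_max fastest-growing wavenumber (over `k > 0`).
#' @slot state reference homogeneous state `c(a, i)`.
#' @slot jacobian 2x2 reaction Jacobian at the reference state.
#' @slot regime classification label: "bistable", "turing" or "other".
#' @slot steady_states the homogeneous steady-state table used.
#' @export
setClass("DispersionResult",
  representation(
    k = "numeric", lambda = "numeric", k_max = "numeric", state = "numeric",
    jacobian = "matrix", regime = "character", steady_states = "data.frame"
  )
)

setValidity("DispersionResult", function(object) {
  if (length(object@k) != length(object@lambda)) {
    return("k and lambda must have equal length")
  }
  if (!any(object@k == 0)) return("k grid must include k = 0")
  TRUE
})

#' @keywords internal
newDispersionResult <- function(k, lambda, k_max, state, jacobian, regime,
                                steady_states) {
  new("DispersionResult", k = k, lambda = lambda, k_max = k_max,
      state = state, jacobian = jacobian, regime = regime,
      steady_states = as.data.frame(steady_states))
}

#' @keywords internal
newEventLog <- function(events, parameters = list()) {
  if (is.null(events) || !nrow(events)) {
    events <- data.frame(type = character(), time = numeric(), x = numeric(),
                         peak_id = integer(), parents = character(),
                         speed = numeric(), stringsAsFactors = FALSE)
  }
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  new("EventLog", events = events, parameters = parameters)
}
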