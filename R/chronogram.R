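#' @include AllClasses.R AllGenerics.R
NULL

#' @keywords internal
newChronogram <- function(times, lengths, dx, activator, inhibitor,
                          maturation, density, regime, mesenchyme, config,
                          seed, clipped = 0) {
  new("Chronogram",
      times = as.numeric(times), lengths = as.integer(lengths), dx = dx,
      activator = activator, inhibitor = inhibitor, maturation = maturation,
      density = density, regime = regime, mesenchyme = as.numeric(mesenchyme),
      config = config, seed = as.integer(seed), clipped = clipped)
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "Chronogram", function(x) length(x@times))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Chronogram", function(x) x@times)

#' @rdname domainLengths
#' @export
setMethod("domainLengths", "Chronogram", function(x) (x@lengths - 1L) * x@dx)

#' @rdname getFrame
#' @export
setMethod("getFrame", "Chronogram", function(x, j = -1L) {
  nf <- nFrames(x)
  if (j < 0) j <- nf + 1L + j
  if (j < 1 || j > nf) stop("frame index out of range", call. = FALSE)
  n <- x@lengths[j]
  idx <- seq_len(n)
  data.frame(
    x = (idx - 1) * x@dx,
    activator = x@activator[j, idx],
    inhibitor = x@inhibitor[j, idx],
    maturation = x@maturation[j, idx],
    density = x@density[j, idx],
    regime = x@regime[j, idx]
  )
})

#' @rdname fieldMatrix
#' @export
setMethod("fieldMatrix", "Chronogram", function(x, field = "activator") {
  field <- match.arg(field, c("activator", "inhibitor", "maturation",
                              "density", "regime"))
  slot(x, field)
})

#' @export
setMethod("show", "Chronogram", function(object) {
  nf <- nFrames(object)
  cat("Chronogram:", nf, "frames, t in [",
      format(min(object@times), digits = 4), ",",
      format(max(object@times), digits = 4), "]\n")
  cat("  domain: length", format(domainLengths(object)[nf], digits = 4),
      "(", object@lengths[nf], "nodes, dx =",
      format(object@dx, digits = 4), ")\n")
  cat("  fields: activator, inhibitor, maturation, density, regime\n")
  if (object@clipped > 0) {
    cat("  note:", object@clipped, "values clipped to zero\n")
  }
  invisible(object)
})

#' Long-format data frame of a chronogram
#'
#' @param x a [Chronogram-class].
#' @param ... unused.
#' @return data.frame with columns `time`, `x`, `field`, `value`.
#' @export
#' @method as.data.frame Chronogram
as.data.frame.Chronogram <- function(x, ...) {
  frames <- lapply(seq_len(nFrames(x)), function(j) {
    fr <- getFrame(x, j)
    n <- nrow(fr)
    data.frame(
      time = rep(x@times[j], 5L * n),
      x = rep(fr$x, 5L),
      field = rep(c("activator", "inhibitor", "maturation", "density",
                    "regime"), each = n),
      value = c(fr$activator, fr$inhibitor, fr$maturation, fr$density,
                as.numeric(fr$regime))
    )
  })
  do.call(rbind, frames)
}

setMethod("as.data.frame", "Chronogram",
          function(x, ...) as.data.frame.Chronogram(x, ...))

#' Write a chronogram as long-format CSV
#'
#' Columns `time`, `x`, `field`, `value`; a self-describing plain-text
#' interchange format. Metadata (dx, seed, config) is written to a JSON
#' sidecar file `<path>.meta.json`.
#'
#' @param x a [Chronogram-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeChronogramCSV <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(dx = x@dx, seed = x@seed, clipped = x@clipped,
               mesenchyme = x@mesenchyme, config = x@config)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a chronogram from long-format CSV
#'
#' Inverse of [writeChronogramCSV()] (requires the JSON sidecar).
#'
#' @param path CSV path written by [writeChronogramCSV()].
#' @return a [Chronogram-class].
#' @export
readChronogramCSV <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  times <- sort(unique(df$time))
  dx <- meta$dx
  lengths <- vapply(times, function(t) {
    length(unique(df$x[df$time == t]))
  }, integer(1))
  maxN <- max(lengths)
  mk <- function(field) {
    m <- matrix(NA_real_, length(times), maxN)
    for (j in seq_along(times)) {
      sub <- df[df$time == times[j] & df$field == field, ]
      sub <- sub[order(sub$x), ]
      m[j, seq_len(nrow(sub))] <- sub$value
    }
    m
  }
  cfg <- meta$config
  newChronogram(times, lengths, dx,
                activator = mk("activator"), inhibitor = mk("inhibitor"),
                maturation = mk("maturation"), density = mk("density"),
                regime = mk("regime"),
                mesenchyme = as.numeric(meta$mesenchyme),
                config = if (is.null(cfg)) list() else cfg,
                seed = meta$seed %||% NA_integer_,
                clipped = meta$clipped %||% 0)
}

#' @rdname events
#' @export
setMethod("events", "EventLog", function(x, type = NULL) {
  ev <- x@events
  if (!is.null(type)) ev <- ev[ev$type %in% type, , drop = FALSE]
  rownames(ev) <- NULL
  ev
})

#' @export
setMethod("show", "EventLog", function(object) {
  ev <- object@events
  cat("EventLog:", nrow(ev), "events\n")
  if (nrow(ev)) {
    tab <- table(ev$type)
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
  invisible(object)
})

#' Number of events (optionally of one type)
#' @param x an [EventLog-class].
#' @param type optional event type filter.
#' @return integer.
#' @export
eventCount <- function(x, type = NULL) nrow(events(x, type))

#' Write an event log as JSON
#'
#' @param x an [EventLog-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEventsJSON <- function(x, path) {
  jsonlite::write_json(
    list(events = events(x), parameters = x@parameters),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}

#' @rdname kMax
#' @export
setMethod("kMax", "DispersionResult", function(x) x@k_max)

#' @rdname regimeLabel
#' @export
setMethod("regimeLabel", "DispersionResult", function(x) x@regime)

#' @export
setMethod("show", "DispersionResult", function(object) {
  cat("DispersionResult: regime =", object@regime, "\n")
  cat("  reference state: a* =", format(object@state[1], digits = 5),
      ", i* =", format(object@state[2], digits = 5), "\n")
  lam_pos <- object@lambda[object@k > 0]
  cat("  lambda(0) =", format(object@lambda[object@k == 0][1], digits = 4),
      "; max lambda(k>0) =", format(max(lam_pos), digits = 4),
      "at k =", format(object@k_max, digits = 4), "\n")
  invisible(object)
})

#' Dispersion curve as a data frame
#' @param x a [DispersionResult-class].
#' @param ... unused.
#' @return data.frame with columns `k`, `lambda`.
#' @export
#' @method as.data.frame DispersionResult
as.data.frame.DispersionResult <- function(x, ...) {
  data.frame(k = x@k, lambda = x@lambda)
}

setMethod("as.data.frame", "DispersionResult",
          function(x, ...) as.data.frame.DispersionResult(x, ...))
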