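#' @include AllClasses.R
NULL

#' Detect activator peaks in a single profile
#'
#' A peak is a connected super-threshold region (activator > `theta_peak`)
#' of width at least `w_min` that contains a local maximum. Position is the
#' location of the highest node in the region.
#'
#' @param a activator profile.
#' @param x grid positions (same length as `a`).
#' @param theta_peak detection threshold; by default the midpoint between
#'   the low and high homogeneous activator states (0.5).
#' @param w_min minimal width of the super-threshold support (length
#'   units); regions narrower than this are ignored.
#' @return data.frame with one row per peak: `x` (position of maximum),
#'   `height`, `left`, `right` (support bounds), `ileft`, `iright`
#'   (support node indices).
#' @export
#' @examples
#' x <- seq(0, 2.6, by = 0.01)
#' a <- exp(-((x - 0.65) / 0.2)^2) + exp(-((x - 1.95) / 0.2)^2)
#' detectPeaks(a, x)
detectPeaks <- function(a, x, theta_peak = 0.5, w_min = 4 * diff(x[1:2])) {
  stopifnot(length(a) == length(x))
  above <- a > theta_peak
  out <- data.frame(x = numeric(), height = numeric(), left = numeric(),
                    right = numeric(), ileft = integer(), iright = integer())
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (seg in which(r$values)) {
    i0 <- starts[seg]; i1 <- ends[seg]
    if (x[i1] - x[i0] < w_min) next
    idx <- i0:i1
    # require an interior local maximum (or a boundary-touching plateau)
    imax <- idx[which.max(a[idx])]
    out <- rbind(out, data.frame(
      x = x[imax], height = a[imax], left = x[i0], right = x[i1],
      ileft = i0, iright = i1))
  }
  rownames(out) <- NULL
  out
}

#' Brute-force peak oracle
#'
#' Independent re-implementation of the peak definition by exhaustive node
#' scanning (no run-length encoding); used to cross-check [detectPeaks()].
#'
#' @inheritParams detectPeaks
#' @return integer count and positions, as a list.
#' @keywords internal
detectPeaksBruteForce <- function(a, x, theta_peak = 0.5,
                                  w_min = 4 * diff(x[1:2])) {
  n <- length(a)
  comps <- list()
  j <- 1L
  while (j <= n) {
    if (a[j] > theta_peak) {
      k <- j
      while (k < n && a[k + 1L] > theta_peak) k <- k + 1L
      if (x[k] - x[j] >= w_min) comps[[length(comps) + 1L]] <- j:k
      j <- k + 1L
    } else j <- j + 1L
  }
  list(count = length(comps),
       x = vapply(comps, function(ix) x[ix[which.max(a[ix])]], numeric(1)))
}

#' Track peaks through a chronogram and log typed events
#'
#' Links peaks frame-to-frame by support overlap and emits the pattern
#' events of the phenomenology:
#' \describe{
#'   \item{birth}{a new track that persists at least `persistence_min`
#'     frames (time stamped at first appearance).}
#'   \item{recovery}{a birth whose support overlaps the site of a previous
#'     erasure.}
#'   \item{erasure}{a confirmed track whose height falls below
#'     `theta_peak` (it disappears); when a merged object dies before
#'     confirming, one erasure is logged per confirmed constituent.}
#'   \item{fusion}{two peak-like tracks merging into one that persists at
#'     least `persistence_min` frames after the merge.}
#'   \item{front_passage}{a merge in which one partner is a broad
#'     activation object (support wider than `broad_width`): the front has
#'     swept over the peak. The speed is fitted from the broad object's
#'     anterior edge over the preceding frames (positive = moving
#'     anteriorly).}
#' }
#' A merge is logged either as a fusion or as erasure(s), never both; the
#' persistence criterion decides.
#'
#' @param cg a [Chronogram-class] with at least 2 frames.
#' @param theta_peak detection threshold (default 0.5).
#' @param w_min minimal peak width (default `4 * dx`).
#' @param persistence_min minimal persistence in frames (default 20).
#' @param broad_width support width (length units) above which an object
#'   counts as a broad activation front rather than a peak (default 1.3,
#'   comfortably above one pattern wavelength).
#' @param site_tolerance positional tolerance (length units) when matching
#'   a birth against earlier erasure sites: centers closer than about half
#'   the pattern wavelength occupy the same pattern slot, so a birth within
#'   this distance of an erased support counts as a recovery.
#' @return an [EventLog-class].
#' @export
trackEvents <- function(cg, theta_peak = 0.5, w_min = 4 * cg@dx,
                        persistence_min = 20L, broad_width = 1.3,
                        site_tolerance = 0.5) {
  nf <- nFrames(cg)
  if (nf < 2) stop("chronogram must have at least 2 frames", call. = FALSE)
  times <- frameTimes(cg)
  dx <- cg@dx

  tracks <- list()
  next_id <- 1L
  erasures <- list()   # support intervals (x units) of erased peaks
  ev <- list()
  emit <- function(type, time, x, id, parents = "", speed = NA_real_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      type = type, time = time, x = x, peak_id = id,
      parents = parents, speed = speed, stringsAsFactors = FALSE)
  }
  overlaps_erasure <- function(left, right) {
    for (er in erasures) {
      if (left <= er[2] + site_tolerance && right >= er[1] - site_tolerance) {
        return(TRUE)
      }
    }
    FALSE
  }
  confirm <- function(tr) {
    if (tr$origin == "new" && tr$start == 1L) {
      # present from the first frame: an initial condition, not a birth
      tr$confirmed <- TRUE
      return(tr)
    }
    if (tr$origin == "merge") {
      emit("fusion", tr$merge_time, tr$x, tr$id,
           parents = paste(vapply(tr$constituents, function(cst) cst$id,
                                  integer(1)), collapse = ","))
    } else {
      rec <- overlaps_erasure(tr$birth_left, tr$birth_right)
      emit(if (rec) "recovery" else "birth", tr$start_time, tr$birth_x, tr$id)
    }
    tr$confirmed <- TRUE
    tr
  }
  register_erasure <- function(tr, time) {
    emit("erasure", time, tr$x, tr$id)
    erasures[[length(erasures) + 1L]] <<- c(tr$left, tr$right)
  }
  kill <- function(tr, time) {
    # lineage ends below threshold; merged-but-unconfirmed objects erase
    # their confirmed constituents instead (a merge is never double-logged)
    if (tr$confirmed && tr$origin != "merge") {
      register_erasure(tr, time)
    } else if (tr$origin == "merge") {
      if (tr$confirmed) {
        register_erasure(tr, time)
      } else {
        for (cst in tr$constituents) {
          if (cst$confirmed) {
            emit("erasure", time, cst$x, cst$id)
            erasures[[length(erasures) + 1L]] <<- c(cst$left, cst$right)
          }
        }
      }
    }
    invisible(NULL)
  }
  new_track <- function(pk, p, j, origin = "new", constituents = list(),
                        merge_time = NA_real_) {
    nt <- list(id = next_id, start = j, start_time = times[j],
               ileft = pk$ileft[p], iright = pk$iright[p],
               left = pk$left[p], right = pk$right[p],
               birth_left = pk$left[p], birth_right = pk$right[p],
               birth_x = pk$x[p],
               x = pk$x[p], height = pk$height[p], last = j,
               alive = TRUE, confirmed = FALSE, origin = origin,
               constituents = constituents, merge_time = merge_time,
               prev_width = pk$right[p] - pk$left[p],
               edge_hist = matrix(c(times[j], pk$left[p]), 1))
    next_id <<- next_id + 1L
    nt
  }

  act <- fieldMatrix(cg, "activator")
  for (j in seq_len(nf)) {
    n <- cg@lengths[j]
    a <- act[j, seq_len(n)]
    x <- (seq_len(n) - 1) * dx
    pk <- detectPeaks(a, x, theta_peak, w_min)
    npk <- nrow(pk)
    live <- which(vapply(tracks, function(tr) tr$alive, logical(1)))
    # overlap sets between live tracks (previous supports) and current peaks
    parents <- vector("list", npk)
    if (npk && length(live)) {
      for (p in seq_len(npk)) {
        ov <- live[vapply(live, function(tix) {
          tr <- tracks[[tix]]
          min(tr$iright, pk$iright[p]) - max(tr$ileft, pk$ileft[p]) >= 0
        }, logical(1))]
        parents[[p]] <- ov
      }
    }
    consumed <- rep(FALSE, npk)   # peaks taken over by a merge track
    absorbed <- integer()         # tracks ended by a merge this frame
    new_tracks <- list()

    # ---- merges: a peak overlapping several live lineages ----
    if (npk) for (p in seq_len(npk)) {
      par <- setdiff(parents[[p]], absorbed)
      if (length(par) < 2) { parents[p] <- list(par); next }
      widths <- vapply(par, function(tix) tracks[[tix]]$prev_width, numeric(1))
      broad <- widths >= broad_width
      if (any(broad)) {
        # front passage: the broad activation object overruns the peak(s);
        # the overrun pattern is erased
        btix <- par[which(broad)[1]]
        eh <- tracks[[btix]]$edge_hist
        spd <- NA_real_
        if (nrow(eh) >= 3) {
          tail_eh <- eh[max(1, nrow(eh) - 10):nrow(eh), , drop = FALSE]
          spd <- -unname(coef(stats::lm(tail_eh[, 2] ~ tail_eh[, 1]))[2])
        }
        others <- setdiff(par, btix)
        px <- if (length(others)) tracks[[others[1]]]$x else tracks[[btix]]$x
        emit("front_passage", times[j], px, tracks[[btix]]$id, speed = spd)
        for (tix in others) {
          tr <- tracks[[tix]]
          if (tr$confirmed) register_erasure(tr, times[j])
          tr$alive <- FALSE
          tracks[[tix]] <- tr
          absorbed <- c(absorbed, tix)
        }
        parents[p] <- list(btix)
      } else {
        # peak-peak merge: candidate fusion carried by a fresh lineage
        csts <- lapply(par, function(tix) {
          tr <- tracks[[tix]]
          list(id = tr$id, x = tr$x, left = tr$left, right = tr$right,
               confirmed = tr$confirmed)
        })
        for (tix in par) {
          tracks[[tix]]$alive <- FALSE
          absorbed <- c(absorbed, tix)
        }
        new_tracks[[length(new_tracks) + 1L]] <-
          new_track(pk, p, j, origin = "merge", constituents = csts,
                    merge_time = times[j])
        consumed[p] <- TRUE
        parents[p] <- list(integer())
      }
    }

    # ---- continuation and splits ----
    live <- setdiff(which(vapply(tracks, function(tr) tr$alive, logical(1))),
                    absorbed)
    for (tix in live) {
      kids <- which(!consumed & vapply(seq_len(npk), function(p) {
        length(parents[[p]]) == 1 && parents[[p]] == tix
      }, logical(1)))
      tr <- tracks[[tix]]
      if (!length(kids)) {
        tr$alive <- FALSE
        tracks[[tix]] <- tr
        kill(tr, times[j])
        next
      }
      main <- kids[which.max(pk$height[kids])]
      tr$ileft <- pk$ileft[main]; tr$iright <- pk$iright[main]
      tr$left <- pk$left[main]; tr$right <- pk$right[main]
      tr$x <- pk$x[main]; tr$height <- pk$height[main]
      tr$last <- j
      tr$edge_hist <- rbind(tr$edge_hist, c(times[j], pk$left[main]))
      if (!tr$confirmed && j - tr$start + 1L >= persistence_min) {
        tr <- confirm(tr)
      }
      tracks[[tix]] <- tr
      consumed[main] <- TRUE
      for (p in setdiff(kids, main)) {
        new_tracks[[length(new_tracks) + 1L]] <- new_track(pk, p, j, "split")
        consumed[p] <- TRUE
      }
    }

    # ---- brand-new peaks ----
    if (npk) for (p in which(!consumed)) {
      if (!length(parents[[p]])) {
        new_tracks[[length(new_tracks) + 1L]] <- new_track(pk, p, j)
      }
    }
    tracks <- c(tracks, new_tracks)
    for (tix in seq_along(tracks)) {
      if (tracks[[tix]]$alive && tracks[[tix]]$last == j) {
        tracks[[tix]]$prev_width <- tracks[[tix]]$right - tracks[[tix]]$left
      }
    }
  }
  # confirm still-alive tracks that reached persistence by the last frame
  for (tix in seq_along(tracks)) {
    tr <- tracks[[tix]]
    if (tr$alive && !tr$confirmed && nf - tr$start + 1L >= persistence_min) {
      tracks[[tix]] <- confirm(tr)
    }
  }
  evdf <- if (length(ev)) do.call(rbind, ev) else NULL
  newEventLog(evdf, parameters = list(
    theta_peak = theta_peak, w_min = w_min,
    persistence_min = persistence_min, broad_width = broad_width))
}

#' Peak count in the final frame of a chronogram
#'
#' @param cg a [Chronogram-class].
#' @inheritParams detectPeaks
#' @return integer.
#' @export
finalPeakCount <- function(cg, theta_peak = 0.5, w_min = 4 * cg@dx) {
  fr <- getFrame(cg, -1L)
  nrow(detectPeaks(fr$activator, fr$x, theta_peak, w_min))
}

#' Traveling-front speed from a chronogram
#'
#' Finds the level crossing of the activator in every frame of the fit
#' window and fits a least-squares line to crossing position versus time.
#' Positive speed means the front moves anteriorly (toward `x = 0`).
#'
#' @param cg a [Chronogram-class].
#' @param level crossing level (default 0.5).
#' @param t_window length-2 time window used for the fit (default all).
#' @param x_window optional length-2 spatial window to search for the
#'   crossing.
#' @param edge `"rising"` for the anterior edge of a posterior activated
#'   region (activator increasing with x at the crossing), `"falling"` for
#'   the posterior edge of an anterior activated region.
#' @return list of class `"FrontFit"` with `speed`, `residual` (RMS of the
#'   linear fit), `times`, `positions`, `level`.
#' @export
frontSpeed <- function(cg, level = 0.5, t_window = NULL, x_window = NULL,
                       edge = c("rising", "falling")) {
  edge <- match.arg(edge)
  times <- frameTimes(cg)
  if (is.null(t_window)) t_window <- range(times)
  sel <- which(times >= t_window[1] & times <= t_window[2])
  if (length(sel) < 5) stop("front fit needs at least 5 frames", call. = FALSE)
  act <- fieldMatrix(cg, "activator")
  pos <- rep(NA_real_, length(sel))
  for (jj in seq_along(sel)) {
    j <- sel[jj]
    n <- cg@lengths[j]
    a <- act[j, seq_len(n)]
    x <- (seq_len(n) - 1) * cg@dx
    if (!is.null(x_window)) {
      keep <- x >= x_window[1] & x <= x_window[2]
      a <- a[keep]; x <- x[keep]
    }
    d <- a - level
    prod <- d[-length(d)] * d[-1]
    # include exact-zero touches (the level can sit on a grid node)
    cross <- which(prod < 0 | (prod == 0 & (d[-length(d)] != 0 | d[-1] != 0)))
    if (edge == "rising") cross <- cross[d[cross + 1] > d[cross]]
    else cross <- cross[d[cross + 1] < d[cross]]
    if (!length(cross)) next
    ci <- cross[1]
    da <- a[ci + 1] - a[ci]
    pos[jj] <- if (da == 0) x[ci] else {
      x[ci] + (x[ci + 1] - x[ci]) * (level - a[ci]) / da
    }
  }
  ok <- !is.na(pos)
  if (sum(ok) < length(sel) / 2) {
    stop("no level crossing found in at least half of the frames", call. = FALSE)
  }
  fit <- stats::lm(pos[ok] ~ times[sel][ok])
  structure(list(
    speed = -unname(coef(fit)[2]),
    residual = sqrt(mean(stats::residuals(fit)^2)),
    times = times[sel][ok], positions = pos[ok], level = level
  ), class = "FrontFit")
}

#' @export
print.FrontFit <- function(x, ...) {
  cat("FrontFit: speed =", format(x$speed, digits = 5),
      "(positive = anterior), residual =", format(x$residual, digits = 3),
      "over", length(x$times), "frames\n")
  invisible(x)
}

#' Posterior broad-activation episodes
#'
#' Detects episodes in which the mean activator over the posterior window
#' stays above the threshold for a minimal number of consecutive frames:
#' the periodic posterior activation phases of the growing-domain
#' phenomenology.
#'
#' @param cg a [Chronogram-class].
#' @param window_frac posterior fraction of the domain (default the
#'   mesenchyme spatial window of the run's config, or 0.15).
#' @param theta_peak activation threshold (default 0.5).
#' @param min_frames minimal episode length in frames (default 20).
#' @return data.frame with columns `start`, `end` (times).
#' @export
broadActivationEpisodes <- function(cg, window_frac = NULL, theta_peak = 0.5,
                                    min_frames = 20L) {
  if (is.null(window_frac)) {
    window_frac <- tryCatch(cg@config$mesenchyme$spatial_window,
                            error = function(e) NULL) %||% 0.15
  }
  act <- fieldMatrix(cg, "activator")
  nf <- nFrames(cg)
  wmean <- vapply(seq_len(nf), function(j) {
    n <- cg@lengths[j]
    wlen <- max(1L, as.integer(round(window_frac * n)))
    mean(act[j, seq.int(n - wlen + 1L, n)])
  }, numeric(1))
  above <- wmean > theta_peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_frames)
  times <- frameTimes(cg)
  data.frame(start = times[starts[keep]], end = times[ends[keep]])
}
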