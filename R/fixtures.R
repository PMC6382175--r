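#' Synthetic activator profile with Gaussian bumps
#'
#' Deterministic test fixture for the peak-detection analytics: a baseline
#' profile with Gaussian bumps of known centers and widths (ground truth by
#' construction), optionally with seeded uniform noise.
#'
#' @param L domain length.
#' @param dx grid spacing.
#' @param centers bump centers (length units).
#' @param amplitude bump amplitude(s), recycled.
#' @param width bump standard width(s), recycled.
#' @param baseline constant baseline level.
#' @param noise_sd amplitude of added uniform noise (0 = none).
#' @param seed RNG seed for the noise.
#' @param disjoint if `TRUE`, error when bump supports (3 widths around
#'   each center) overlap.
#' @return list with `x`, `a`, and the ground truth `centers`.
#' @export
#' @examples
#' f <- makeProfileFixture(centers = c(0.65, 1.95))
#' detectPeaks(f$a, f$x)
makeProfileFixture <- function(L = 2.6, dx = 0.01, centers = c(0.65, 1.95),
                               amplitude = 1, width = 0.2, baseline = 0,
                               noise_sd = 0, seed = 1L, disjoint = TRUE) {
  stopifnot(L > 0, dx > 0, all(centers >= 0 & centers <= L))
  amplitude <- rep_len(amplitude, length(centers))
  width <- rep_len(width, length(centers))
  if (disjoint && length(centers) > 1) {
    o <- order(centers)
    cs <- centers[o]; ws <- width[o]
    gaps <- diff(cs) - 3 * (ws[-length(ws)] + ws[-1]) / 2
    if (any(gaps < 0)) {
      stop("bump supports overlap; centers too close for the given widths",
           call. = FALSE)
    }
  }
  x <- seq(0, L, by = dx)
  a <- rep(baseline, length(x))
  for (j in seq_along(centers)) {
    a <- a + amplitude[j] * exp(-((x - centers[j]) / width[j])^2)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    a <- pmax(a + stats::runif(length(x), -noise_sd, noise_sd), 0)
  }
  list(x = x, a = a, centers = sort(centers))
}

#' Synthetic chronogram with an imposed front or drifting bumps
#'
#' Builds a [Chronogram-class] directly from closed-form profiles, without
#' running the solver: either a sigmoidal front whose level set moves at a
#' constant imposed speed (ground truth for [frontSpeed()]) or a set of
#' stationary bumps. Deterministic given the seed.
#'
#' @param type `"front"` (posterior activated region whose anterior edge
#'   moves anteriorly at `speed`) or `"bumps"` (stationary profile from
#'   [makeProfileFixture()] repeated over time).
#' @param L,dx domain geometry.
#' @param t_end,dt_frame time span and frame cadence.
#' @param speed imposed front speed (positive = toward `x = 0`).
#' @param x0 initial front position.
#' @param front_width front interface width.
#' @param centers,amplitude,width bump parameters for `type = "bumps"`.
#' @param seed seed recorded in the chronogram.
#' @return a [Chronogram-class] (fields other than the activator are zero).
#' @export
makeChronogramFixture <- function(type = c("front", "bumps"), L = 4,
                                  dx = 0.01, t_end = 50, dt_frame = 1,
                                  speed = 0.02, x0 = 3, front_width = 0.1,
                                  centers = c(0.65, 1.95), amplitude = 1,
                                  width = 0.2, seed = 1L) {
  type <- match.arg(type)
  x <- seq(0, L, by = dx)
  n <- length(x)
  times <- seq(0, t_end, by = dt_frame)
  nf <- length(times)
  A <- matrix(NA_real_, nf, n)
  if (type == "front") {
    for (j in seq_len(nf)) {
      pos <- x0 - speed * times[j]
      A[j, ] <- 1 / (1 + exp(-(x - pos) / front_width))
    }
  } else {
    prof <- makeProfileFixture(L = L, dx = dx, centers = centers,
                               amplitude = amplitude, width = width,
                               seed = seed)
    for (j in seq_len(nf)) A[j, ] <- prof$a
  }
  zero <- matrix(0, nf, n)
  newChronogram(times = times, lengths = rep(n, nf), dx = dx,
                activator = A, inhibitor = zero, maturation = zero,
                density = zero, regime = matrix(0L, nf, n),
                mesenchyme = rep(0, nf),
                config = list(fixture = type, speed = speed),
                seed = seed)
}
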