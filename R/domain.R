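#' Create a simulation state
#'
#' Builds the initial [state] list for a configuration: grid, fields
#' (activator `a`, inhibitor `i`, maturation `m`, cell density `rho`),
#' mesenchyme activity `s`, per-cell regime flags, time and growth
#' accumulator. The initial condition is selected by `cfg$init$mode`:
#' \describe{
#'   \item{flat_low}{everything at the low (inactivated) state.}
#'   \item{two_bump}{Gaussian activator bumps at
#'     `bump_centers_frac * L` (the two-peak seeding used by the fixed
#'     mature-domain scenarios).}
#'   \item{front}{activated state posterior of `front_position_frac * L`,
#'     inactivated anterior of it, inhibitor at its local equilibrium.}
#'   \item{turing_homogeneous}{the Turing-capable interior homogeneous
#'     state plus a seeded multiplicative perturbation of relative
#'     amplitude `numerics$perturbation_amplitude`.}
#' }
#'
#' @param cfg configuration list.
#' @return state list with elements `x`, `dx`, `a`, `i`, `m`, `rho`, `s`,
#'   `flag` (0 bistable / 1 turing), `t`, `acc`.
#' @export
makeState <- function(cfg) {
  g <- cfg$growth
  n <- max(2L, as.integer(round(g$L0 / g$dx)) + 1L)
  x <- (seq_len(n) - 1) * g$dx
  L <- x[n]
  a <- numeric(n)
  i <- numeric(n)
  init <- cfg$init
  if (init$mode == "two_bump") {
    for (cfrac in init$bump_centers_frac) {
      a <- a + init$bump_amplitude * exp(-((x - cfrac * L) / init$bump_width)^2)
    }
  } else if (init$mode == "anterior_peak") {
    # an established, matured signaling center near the anterior end;
    # the rest of the domain is immature and inactivated
    ctr <- init$anterior_peak_center
    a <- init$bump_amplitude * exp(-((x - ctr) / init$bump_width)^2)
    mature_zone <- abs(x - ctr) < init$anterior_peak_mature_halfwidth
    mt0 <- cfg$maturation
    m0 <- rep(mt0$seed_value, n)
    m0[mature_zone] <- mt0$switch_threshold
    flag0 <- as.integer(mature_zone)
    return(list(
      x = x, dx = g$dx, a = a, i = i,
      m = m0, rho = rep(cfg$chemotaxis$rho_ref, n), s = 0,
      flag = flag0, t = 0, acc = 0
    ))
  } else if (init$mode == "front") {
    # activated posterior region, inactivated anterior region: the front
    # interface sits at front_position_frac * L and (when the activated
    # state is the more stable one) invades anteriorly
    act <- x >= init$front_position_frac * L
    a[act] <- 1
    regime0 <- if (isTRUE(init$all_mature)) "turing" else "bistable"
    ss <- homogeneousSteadyStates(cfg, regime0)
    hi <- ss[ss$a > 0.9, , drop = FALSE]
    if (nrow(hi)) i[act] <- hi$i[1]
  } else if (init$mode == "turing_homogeneous") {
    d <- dispersionRelation(cfg, "turing")
    set.seed(cfg$numerics$seed)
    amp <- cfg$numerics$perturbation_amplitude
    a <- d@state[1] * (1 + amp * stats::runif(n, -1, 1))
    i <- rep(d@state[2], n)
  }
  mt <- cfg$maturation
  mature <- isTRUE(init$all_mature) || init$mode == "turing_homogeneous"
  list(
    x = x, dx = g$dx, a = a, i = i,
    m = rep(if (mature) mt$switch_threshold else mt$seed_value, n),
    rho = rep(cfg$chemotaxis$rho_ref, n),
    s = 0,
    flag = rep(if (mature) 1L else 0L, n),
    t = 0, acc = 0
  )
}

#' Grow the domain at its posterior end
#'
#' Advances a fractional growth accumulator by `growth_speed * dt`; each
#' time it exceeds one grid spacing, a new cell is appended at the
#' posterior end, initialized at the low stable state with seed maturation
#' and a bistable regime flag. The domain saturates at `max_length`.
#'
#' @param state state list (see [makeState()]).
#' @param dt time increment.
#' @param cfg configuration list.
#' @return updated state.
#' @export
growDomain <- function(state, dt, cfg) {
  g <- cfg$growth
  state$acc <- state$acc + g$growth_speed * dt
  max_n <- as.integer(round(g$max_length / g$dx)) + 1L
  while (state$acc >= state$dx && length(state$a) < max_n) {
    state$acc <- state$acc - state$dx
    n <- length(state$a) + 1L
    state$x <- c(state$x, state$x[n - 1L] + state$dx)
    state$a <- c(state$a, 0)
    state$i <- c(state$i, 0)
    state$m <- c(state$m, cfg$maturation$seed_value)
    state$rho <- c(state$rho, cfg$chemotaxis$rho_ref)
    state$flag <- c(state$flag, 0L)
  }
  if (state$acc >= state$dx) state$acc <- state$dx
  state
}

#' Update the maturation field
#'
#' Exponential maturation `dm/dt = (alpha + beta * H(a_delayed -
#' theta_m)) * m` with a smooth step `H`: slow baseline growth everywhere,
#' boosted where the activator exceeded the activation threshold a delay
#' `tau` earlier. `m` is non-decreasing and capped at
#' `cap_factor * switch_threshold`.
#'
#' @param state state list.
#' @param dt time increment.
#' @param cfg configuration list.
#' @param a_delayed activator field at the same positions `delay` time
#'   units earlier (defaults to the current activator, i.e. zero delay).
#' @return updated state.
#' @export
updateMaturation <- function(state, dt, cfg, a_delayed = state$a) {
  mt <- cfg$maturation
  if (length(a_delayed) != length(state$a)) {
    stop("a_delayed must match the current grid length", call. = FALSE)
  }
  rate <- mt$baseline_rate +
    mt$activator_boost * smoothStep(a_delayed - mt$activation_threshold, mt$eps)
  state$m <- pmin(state$m + dt * rate * state$m,
                  mt$cap_factor * mt$switch_threshold)
  state
}

#' Update the per-cell regime flags
#'
#' A cell switches irreversibly from the bistable (0) to the Turing (1)
#' regime when its maturation reaches the switch threshold; the update is
#' idempotent and never reverses a switch.
#'
#' @param state state list.
#' @param cfg configuration list.
#' @return updated state.
#' @export
updateRegimeFlags <- function(state, cfg) {
  state$flag <- as.integer(state$flag | (state$m >= cfg$maturation$switch_threshold))
  state
}

#' Mesenchymal forcing at the posterior end
#'
#' The extrinsic component standing in for epithelium-mesenchyme
#' interaction. Within the posterior window (fraction `spatial_window` of
#' the domain), a stored activity `s` is released as a positive activator
#' source wherever local activation is below `low_threshold`, and a mild
#' direct sink (`negative_gain`) applies wherever activation exceeds
#' `high_threshold`. `s` recharges at `positive_gain` while the window is
#' quiet and relaxes at `relaxation_rate`. Together with the
#' maturation-triggered regime switch this yields oscillatory posterior
#' activation.
#'
#' @param state state list.
#' @param dt time increment.
#' @param cfg configuration list.
#' @return list with elements `source` (activator source term field, zero
#'   outside the window) and `state` (with updated `s`).
#' @export
mesenchymeForcing <- function(state, dt, cfg) {
  ms <- cfg$mesenchyme
  n <- length(state$a)
  source <- numeric(n)
  if (isTRUE(ms$enabled)) {
    wlen <- max(1L, as.integer(round(ms$spatial_window * n)))
    idx <- seq.int(n - wlen + 1L, n)
    aw <- state$a[idx]
    source[idx] <- state$s * smoothStep(ms$low_threshold - aw, ms$eps) -
      ms$negative_gain * aw * smoothStep(aw - ms$high_threshold, ms$eps)
    abar <- mean(aw)
    state$s <- max(0, state$s + dt * (
      ms$positive_gain * smoothStep(ms$low_threshold - abar, ms$eps) -
        ms$relaxation_rate * state$s))
  }
  list(source = source, state = state)
}

#' Chemotactic flux of cells up the activator gradient
#'
#' Advective flux `chi * rho * da/dx` discretized conservatively at cell
#' faces (length `n - 1`), with zero flux through the domain ends.
#'
#' @param rho cell density field.
#' @param a activator field.
#' @param chi chemotactic coefficient (>= 0).
#' @param dx grid spacing.
#' @return numeric vector of face fluxes (`length(rho) - 1`); positive
#'   values transport cells toward larger `x`.
#' @export
chemotacticFlux <- function(rho, a, chi, dx) {
  stopifnot(chi >= 0, length(rho) == length(a))
  n <- length(rho)
  if (n < 2) return(numeric(0))
  grad <- diff(a) / dx
  v <- chi * grad
  upw <- ifelse(v > 0, rho[-n], rho[-1])
  v * upw
}

#' Density feedback on inhibitor production
#'
#' Multiplier on the inhibitor production rate, strictly decreasing in the
#' cell density and equal to 1 at the reference density. Above the
#' reference the suppression acts at the full feedback strength,
#' `exp(-feedback_strength * (rho/rho_ref - 1))`; below it the release is
#' ten-fold weaker (saturating response). Higher cell density
#' down-regulates the inhibitor, the coupling through which chemotactic
#' aggregation feeds back on the pattern.
#'
#' @param rho cell density (vectorized).
#' @param cfg configuration list.
#' @return numeric multiplier(s) in (0, Inf).
#' @export
densityFeedback <- function(rho, cfg) {
  ch <- cfg$chemotaxis
  z <- rho / ch$rho_ref - 1
  # saturating response: cell crowding suppresses inhibitor production at
  # the full feedback strength, while depletion below the reference only
  # weakly releases it (a cell-mediated effect cannot exceed its baseline
  # much when the cells are gone)
  exp(-ch$feedback_strength * ifelse(z >= 0, z, z / 10))
}
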