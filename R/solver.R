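#' One explicit time step (reference implementation)
#'
#' Advances a state by one explicit-Euler step, applying in order:
#' reaction (regime-flag dependent), mesenchymal forcing, diffusion of
#' activator and inhibitor (zero-flux boundaries), conservative cell
#' density diffusion/chemotaxis, maturation, regime flags, domain growth.
#' This is the readable R mirror of the compiled stepper used by
#' [simulate()]; the two are tested for agreement.
#'
#' @param state state list (see [makeState()]).
#' @param dt time step; must satisfy the explicit stability bound.
#' @param cfg configuration list.
#' @param a_delayed delayed activator field for the maturation update
#'   (defaults to the post-diffusion activator, i.e. zero delay).
#' @param growth,maturation,mesenchyme,chemotaxis logical switches for the
#'   corresponding processes.
#' @return updated state.
#' @export
stepState <- function(state, dt, cfg, a_delayed = NULL,
                      growth = TRUE, maturation = TRUE,
                      mesenchyme = isTRUE(cfg$mesenchyme$enabled),
                      chemotaxis = isTRUE(cfg$chemotaxis$enabled)) {
  k <- cfg$kinetics
  n <- length(state$a)
  dx <- state$dx

  # reaction
  phi <- if (chemotaxis) densityFeedback(state$rho, cfg) else 1
  q <- ifelse(state$flag == 1L, regimeQ(cfg, "turing"), regimeQ(cfg, "bistable"))
  Q <- k$Q_l + (k$Q_h - k$Q_l) * smoothStep(state$a - k$a_switch, k$eps_Q)
  da <- Q * state$a * (1 - state$a) * (state$a - k$theta0 - k$gamma * state$i / (1 + k$i_sat * state$i))
  ap <- pmax(state$a, 0)^k$p_i
  di <- phi * k$b * ap / ((k$K_i^k$p_i + ap) * (1 + q * state$i)) - k$d_i * state$i
  state$a <- state$a + dt * da
  state$i <- state$i + dt * di

  # mesenchymal forcing
  if (mesenchyme) {
    mf <- mesenchymeForcing(state, dt, cfg)
    state <- mf$state
    state$a <- state$a + dt * mf$source
  }

  # diffusion (explicit, ghost-node no-flux)
  lap <- function(u) {
    if (length(u) == 1) return(0)
    c(u[2] - u[1], diff(u, differences = 2), u[length(u) - 1] - u[length(u)]) ## nolint
  }
  state$a <- state$a + k$D_a * dt / dx^2 * lap(state$a)
  state$i <- state$i + k$D_i * dt / dx^2 * lap(state$i)

  # cell density: conservative diffusion + chemotaxis
  if (chemotaxis && n > 1) {
    ch <- cfg$chemotaxis
    Fface <- -ch$D_rho * diff(state$rho) / dx +
      chemotacticFlux(state$rho, state$a, ch$chi, dx)
    state$rho <- state$rho - dt / dx * diff(c(0, Fface, 0))
  }

  # maturation + regime flags
  if (maturation) {
    if (is.null(a_delayed)) a_delayed <- state$a
    state <- updateMaturation(state, dt, cfg, a_delayed)
    state <- updateRegimeFlags(state, cfg)
  }

  # growth
  if (growth) state <- growDomain(state, dt, cfg)

  # positivity contract
  for (f in c("a", "i", "rho")) {
    v <- state[[f]]
    if (any(!is.finite(v))) {
      stop("non-finite field value in '", f, "' at t = ", state$t + dt,
           ": numerical stability violated", call. = FALSE)
    }
    if (any(v < -1e-12)) {
      stop("field '", f, "' fell below -1e-12 at t = ", state$t + dt,
           call. = FALSE)
    }
    state[[f]] <- pmax(v, 0)
  }
  state$t <- state$t + dt
  state
}

#' @keywords internal
enginePar <- function(cfg, growth, maturation, mesenchyme, chemotaxis) {
  k <- cfg$kinetics; g <- cfg$growth; mt <- cfg$maturation
  ms <- cfg$mesenchyme; ch <- cfg$chemotaxis; nu <- cfg$numerics
  list(
    dx = g$dx, dt = nu$dt,
    D_a = k$D_a, D_i = k$D_i, Q_h = k$Q_h, Q_l = k$Q_l,
    theta0 = k$theta0, gamma = k$gamma, i_sat = k$i_sat, a_switch = k$a_switch,
    eps_Q = k$eps_Q, b = k$b, d_i = k$d_i, p_i = k$p_i, K_i = k$K_i,
    q_bistable = regimeQ(cfg, "bistable"), q_turing = regimeQ(cfg, "turing"),
    growth_speed = g$growth_speed, growth_on = as.integer(growth),
    maturation_on = as.integer(maturation),
    mat_alpha = mt$baseline_rate, mat_beta = mt$activator_boost,
    mat_thresh = mt$activation_threshold, mat_tau = mt$delay,
    m_star = mt$switch_threshold, m_seed = mt$seed_value,
    m_cap = mt$cap_factor, mat_eps = mt$eps,
    mes_on = as.integer(mesenchyme),
    th_low = ms$low_threshold, th_high = ms$high_threshold,
    k_pos = ms$positive_gain, k_neg = ms$negative_gain,
    k_relax = ms$relaxation_rate, window_frac = ms$spatial_window,
    mes_eps = ms$eps,
    chem_on = as.integer(chemotaxis), chi = ch$chi, D_rho = ch$D_rho,
    rho_ref = ch$rho_ref, fb_strength = ch$feedback_strength,
    imex = as.integer(nu$scheme == "imex")
  )
}

#' @keywords internal
checkStability <- function(cfg) {
  k <- cfg$kinetics; nu <- cfg$numerics; g <- cfg$growth; ch <- cfg$chemotaxis
  dx <- g$dx; dt <- nu$dt
  if (nu$scheme == "explicit") {
    lim <- dx^2 / (2 * max(k$D_a, k$D_i))
    if (dt > lim) {
      stop("numerics.dt = ", dt, " violates the explicit diffusion ",
           "stability bound dx^2/(2 max(D)) = ", signif(lim, 4), call. = FALSE)
    }
  }
  if (isTRUE(ch$enabled)) {
    if (nu$scheme == "explicit" && ch$D_rho > 0) {
      lim <- dx^2 / (2 * ch$D_rho)
      if (dt > lim) {
        stop("numerics.dt = ", dt, " violates the cell-density diffusion ",
             "bound dx^2/(2 D_rho) = ", signif(lim, 4), call. = FALSE)
      }
    }
    if (ch$chi > 0) {
      # rough advection CFL: activator gradients are steepest across the
      # front interface, of order 1/(20 dx) concentration per node scale
      lim <- dx / (20 * ch$chi)
      if (dt > lim) {
        stop("numerics.dt = ", dt, " violates the chemotactic advection ",
             "bound ~", signif(lim, 4), call. = FALSE)
      }
    }
  }
  # crude explicit-reaction bound: fastest linear rate in the kinetics
  rate <- max(k$Q_h, k$Q_l) * (1 + k$theta0) + k$d_i
  if (dt * rate > 1) {
    stop("numerics.dt = ", dt, " exceeds the explicit reaction bound 1/",
         signif(rate, 4), call. = FALSE)
  }
  invisible(TRUE)
}

#' Run a full simulation
#'
#' Integrates the coupled activator/inhibitor/maturation/density system on
#' the (optionally growing) grid from the configured initial condition to
#' `t_end`, saving every `output_stride` steps, and returns the space-time
#' record as a [Chronogram-class]. Deterministic given the configuration
#' (the seeded initial perturbation is the only source of randomness).
#'
#' @param cfg configuration list (see [modelConfig()]).
#' @param growth,maturation,mesenchyme,chemotaxis logical switches;
#'   defaults follow the configuration (`growth` on iff `growth_speed > 0`).
#' @return a [Chronogram-class].
#' @export
#' @examples
#' cfg <- modelConfig(list(
#'   numerics = list(t_end = 5),
#'   init = list(mode = "two_bump", all_mature = TRUE),
#'   growth = list(growth_speed = 0)))
#' simulate(cfg, mesenchyme = FALSE)
simulate <- function(cfg,
                     growth = cfg$growth$growth_speed > 0,
                     maturation = !isTRUE(cfg$init$all_mature),
                     mesenchyme = isTRUE(cfg$mesenchyme$enabled),
                     chemotaxis = isTRUE(cfg$chemotaxis$enabled)) {
  validateConfig(cfg)
  checkStability(cfg)
  nu <- cfg$numerics
  state <- makeState(cfg)
  n_steps <- as.integer(ceiling(nu$t_end / nu$dt))
  max_n <- if (growth) {
    as.integer(round(cfg$growth$max_length / cfg$growth$dx)) + 1L
  } else {
    length(state$a)
  }
  out <- engine_run(state$a, state$i, state$m, state$rho, state$flag,
                    state$s,
                    enginePar(cfg, growth, maturation, mesenchyme, chemotaxis),
                    state$t, state$acc, n_steps, as.integer(nu$output_stride),
                    max_n)
  nmax <- max(out$lengths)
  trim <- function(M) M[, seq_len(nmax), drop = FALSE]
  newChronogram(
    times = out$times, lengths = out$lengths, dx = cfg$growth$dx,
    activator = trim(out$activator), inhibitor = trim(out$inhibitor),
    maturation = trim(out$maturation), density = trim(out$density),
    regime = trim(out$regime), mesenchyme = out$s,
    config = cfg, seed = nu$seed, clipped = out$clipped
  )
}
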