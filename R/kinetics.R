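#' Effective auto-inhibition rate for a regime
#'
#' The single parameter whose value differs between the immature (bistable)
#' and mature (Turing) tissue, optionally rescaled by the mutant factor
#' (values < 1 model lowered auto-inhibition, i.e. stronger inhibition).
#'
#' @param cfg configuration list (uses sections `regimes`).
#' @param regime `"bistable"` or `"turing"`.
#' @return scalar `q_auto`.
#' @export
regimeQ <- function(cfg, regime = c("bistable", "turing")) {
  regime <- match.arg(regime)
  r <- cfg$regimes
  q <- if (regime == "bistable") r$q_bistable else r$q_turing
  q * r$mutant_scale
}

#' Activator-inhibitor reaction terms
#'
#' Instantaneous kinetic rates of the activator/inhibitor pair:
#' \deqn{f(a,i) = Q(a)\, a (1-a) (a - \theta_0 - \gamma i)}
#' \deqn{g(a,i) = \phi\, b\, a^2 / ((K_i^2 + a^2)(1 + q_{auto} i)) - d_i\, i}
#' where \eqn{Q(a)} interpolates smoothly between `Q_l` (below the
#' intermediate state) and `Q_h` (above it), the inhibitor raises the
#' activation threshold (repression), the activator drives inhibitor
#' production (activation), and \eqn{q_{auto}} — the inhibitor's negative
#' feedback on its own production — is the only coefficient that differs
#' between the two regimes. `phi` is an optional multiplier on inhibitor
#' production (density feedback, see [densityFeedback()]).
#'
#' @param a,i activator and inhibitor concentrations (vectors of equal
#'   length, non-negative).
#' @param regime `"bistable"` or `"turing"`.
#' @param cfg configuration list.
#' @param phi inhibitor production multiplier (default 1).
#' @return list with components `da`, `di`.
#' @export
#' @examples
#' cfg <- modelConfig()
#' reactionTerms(0.5, 0.1, "bistable", cfg)
reactionTerms <- function(a, i, regime = c("bistable", "turing"), cfg,
                          phi = 1) {
  regime <- match.arg(regime)
  if (any(!is.finite(a)) || any(!is.finite(i))) {
    stop("non-finite concentration passed to reactionTerms", call. = FALSE)
  }
  if (any(a < 0) || any(i < 0)) {
    stop("negative concentration passed to reactionTerms", call. = FALSE)
  }
  reactionTermsRaw(a, i, regime, cfg, phi)
}

#' Reaction terms without domain checks
#'
#' Same formulas as [reactionTerms()] but admits small negative arguments;
#' used internally by finite-difference stencils and Newton iterations
#' whose intermediate points may leave the physical domain.
#' @inheritParams reactionTerms
#' @keywords internal
reactionTermsRaw <- function(a, i, regime, cfg, phi = 1) {
  k <- cfg$kinetics
  q <- regimeQ(cfg, regime)
  Q <- k$Q_l + (k$Q_h - k$Q_l) * smoothStep(a - k$a_switch, k$eps_Q)
  da <- Q * a * (1 - a) * (a - k$theta0 - k$gamma * i / (1 + k$i_sat * i))
  ap <- pmax(a, 0)^k$p_i
  di <- phi * k$b * ap / ((k$K_i^k$p_i + ap) * (1 + q * i)) - k$d_i * i
  list(da = da, di = di)
}

#' Jacobian of the reaction terms at a point
#'
#' Central finite differences of [reactionTerms()]; used by the steady-state
#' and dispersion analyses.
#'
#' @inheritParams reactionTerms
#' @param h finite-difference step.
#' @return 2x2 matrix `d(da,di)/d(a,i)`.
#' @export
reactionJacobian <- function(a, i, regime, cfg, h = 1e-6) {
  f <- function(a, i) {
    # raw evaluation: FD stencil may step slightly outside the physical domain
    r <- reactionTermsRaw(a, i, regime, cfg)
    c(r$da, r$di)
  }
  J <- matrix(NA_real_, 2, 2)
  J[, 1] <- (f(a + h, i) - f(a - h, i)) / (2 * h)
  J[, 2] <- (f(a, i + h) - f(a, i - h)) / (2 * h)
  J
}

#' Homogeneous steady states of the kinetics
#'
#' Multi-start damped Newton search for the roots of the reaction terms on a
#' rectangle, with deduplication, followed by linear stability analysis of
#' each root.
#'
#' @inheritParams reactionTerms
#' @param a_max,i_max upper corners of the search box (lower corner is 0).
#' @param n_seed seeds per axis of the starting grid.
#' @param tol root tolerance on the max-norm of the reaction terms.
#' @param marginal_tol eigenvalue real parts within this distance of zero
#'   are classified marginal (`stable = NA`).
#' @return data frame of class `"SteadyStateSet"` with columns `a`, `i`,
#'   `eig1`, `eig2` (real parts, `eig1` the leading one) and `stable`
#'   (logical, `NA` when marginal).
#' @export
homogeneousSteadyStates <- function(cfg, regime = c("bistable", "turing"),
                                    a_max = 1.5, i_max = NULL, n_seed = 20,
                                    tol = 1e-10, marginal_tol = 1e-9) {
  regime <- match.arg(regime)
  k <- cfg$kinetics
  q <- regimeQ(cfg, regime)
  if (is.null(i_max)) {
    # inhibitor cannot exceed its equilibrium at full activation
    imax_eq <- k$b * a_max^3 / k$d_i
    i_max <- max(1.5 * imax_eq / (1 + q * min(imax_eq, 1)), 0.5)
  }
  fvec <- function(p) {
    r <- reactionTermsRaw(p[1], p[2], regime, cfg)
    c(r$da, r$di)
  }
  roots <- list()
  seeds_a <- seq(0, a_max, length.out = n_seed)
  seeds_i <- seq(0, i_max, length.out = n_seed)
  for (sa in seeds_a) for (si in seeds_i) {
    p <- c(sa, si)
    ok <- FALSE
    for (iter in 1:60) {
      fv <- fvec(p)
      if (max(abs(fv)) < tol) { ok <- TRUE; break }
      J <- reactionJacobian(p[1], p[2], regime, cfg)
      step <- tryCatch(solve(J, fv), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      # damping: keep iterates inside a slightly padded box
      lam <- 1
      repeat {
        pn <- p - lam * step
        if (all(pn > c(-0.05, -0.05)) && all(pn < c(a_max + 0.5, i_max * 2 + 1))) break
        lam <- lam / 2
        if (lam < 1e-4) break
      }
      if (max(abs(pn - p)) < 1e-14) { ok <- max(abs(fv)) < 1e2 * tol; break }
      p <- pn
    }
    if (ok && all(p > -1e-8)) {
      p <- pmax(p, 0)
      dup <- any(vapply(roots, function(r) max(abs(r - p)) < 1e-6, logical(1)))
      if (!dup) roots[[length(roots) + 1]] <- p
    }
  }
  if (!length(roots)) {
    stop("no homogeneous steady state found in the search box", call. = FALSE)
  }
  res <- do.call(rbind, lapply(roots, function(p) {
    J <- reactionJacobian(p[1], p[2], regime, cfg)
    ev <- sort(Re(eigen(J, only.values = TRUE)$values), decreasing = TRUE)
    stable <- if (any(abs(ev) < marginal_tol)) NA else all(ev < 0)
    data.frame(a = p[1], i = p[2], eig1 = ev[1], eig2 = ev[2], stable = stable)
  }))
  res <- res[order(res$a), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("SteadyStateSet", "data.frame")
  res
}

#' Default wavenumber grid for dispersion analysis
#'
#' 200 log-spaced wavenumbers in `[1e-3, 50]` plus `k = 0`.
#' @return numeric vector.
#' @export
defaultKGrid <- function() c(0, logSpace(1e-3, 50, 200))

#' Closed-form growth rate of spatial mode k
#'
#' Largest real part of the eigenvalues of `J - diag(D_a, D_i) k^2` from the
#' 2x2 trace/determinant formula.
#'
#' @param J 2x2 Jacobian at the reference state.
#' @param D_a,D_i diffusivities.
#' @param k wavenumber (vectorized).
#' @return numeric vector `lambda(k)`.
#' @export
growthRate <- function(J, D_a, D_i, k) {
  k2 <- k^2
  tr <- (J[1, 1] - D_a * k2) + (J[2, 2] - D_i * k2)
  det <- (J[1, 1] - D_a * k2) * (J[2, 2] - D_i * k2) - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * det
  ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
}

#' Linear dispersion relation around a homogeneous state
#'
#' Computes \eqn{\lambda(k)}, the maximal real part of the eigenvalues of
#' `J - diag(D_a, D_i) k^2`, around a reference homogeneous state, and
#' classifies the parameter set. When `state` is not given, the reference is
#' chosen among the homogeneous steady states that are stable to uniform
#' perturbations (\eqn{\lambda(0) < 0}) as the one with the largest maximal
#' growth rate over `k > 0` (i.e. the Turing-capable state when one exists).
#'
#' @inheritParams reactionTerms
#' @param k wavenumber grid; must include `k = 0`.
#' @param state optional c(a, i) reference state.
#' @return a [DispersionResult-class] object.
#' @export
#' @examples
#' cfg <- modelConfig()
#' d <- dispersionRelation(cfg, "turing")
#' regimeLabel(d); kMax(d)
dispersionRelation <- function(cfg, regime = c("bistable", "turing"),
                               k = defaultKGrid(), state = NULL) {
  regime <- match.arg(regime)
  if (!any(k == 0)) stop("the wavenumber grid must include k = 0", call. = FALSE)
  ss <- homogeneousSteadyStates(cfg, regime)
  if (is.null(state)) {
    cand <- ss[!is.na(ss$stable) & ss$eig1 < 0, , drop = FALSE]
    if (!nrow(cand)) {
      stop("no homogeneous state stable to uniform perturbations; ",
           "dispersion reference state undefined", call. = FALSE)
    }
    best <- vapply(seq_len(nrow(cand)), function(j) {
      J <- reactionJacobian(cand$a[j], cand$i[j], regime, cfg)
      max(growthRate(J, cfg$kinetics$D_a, cfg$kinetics$D_i, k[k > 0]))
    }, numeric(1))
    state <- c(cand$a[which.max(best)], cand$i[which.max(best)])
  }
  J <- reactionJacobian(state[1], state[2], regime, cfg)
  lam <- growthRate(J, cfg$kinetics$D_a, cfg$kinetics$D_i, k)
  lam0 <- lam[which(k == 0)[1]]
  pos <- k > 0
  turing <- lam0 < 0 && any(lam[pos] > 0)
  kmax <- if (any(pos)) k[pos][which.max(lam[pos])] else NA_real_
  label <- if (turing) {
    "turing"
  } else {
    nstab <- sum(!is.na(ss$stable) & ss$stable)
    if (nstab >= 2) "bistable" else "other"
  }
  newDispersionResult(k = k, lambda = lam, k_max = kmax, state = state,
                      jacobian = J, regime = label, steady_states = ss)
}

#' Classify a parameter set
#'
#' `"turing"` when some homogeneous state is stable to uniform perturbations
#' but unstable to a band of finite wavenumbers; otherwise `"bistable"` when
#' at least two homogeneous states are strictly stable (and neither is
#' Turing-unstable); `"other"` otherwise (including marginal eigenvalues).
#'
#' @inheritParams reactionTerms
#' @param k wavenumber grid.
#' @return `"bistable"`, `"turing"` or `"other"`.
#' @export
classifyRegime <- function(cfg, regime = c("bistable", "turing"),
                           k = defaultKGrid()) {
  regime <- match.arg(regime)
  ss <- homogeneousSteadyStates(cfg, regime)
  kin <- cfg$kinetics
  pos <- k[k > 0]
  for (j in seq_len(nrow(ss))) {
    J <- reactionJacobian(ss$a[j], ss$i[j], regime, cfg)
    lam0 <- growthRate(J, kin$D_a, kin$D_i, 0)
    if (lam0 < 0 && max(growthRate(J, kin$D_a, kin$D_i, pos)) > 0) {
      return("turing")
    }
  }
  nstab <- sum(!is.na(ss$stable) & ss$stable)
  if (nstab >= 2) "bistable" else "other"
}
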