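#' Scenario presets
#'
#' Named configuration overlays reproducing the model's canonical
#' simulations: sequential peak formation on the growing domain
#' (`fig2_sequential`), the traveling-wave palimpsest
#' (`fig3_palimpsest`), its suppression under increased inhibition
#' (`fig4_mutant`, which differs from the palimpsest preset in the
#' auto-inhibition scaling only), the fixed matured-domain chemotaxis
#' suite (`fig6_nochemo`, `fig6_chemo_low`, `fig6_chemo`,
#' `fig6_large_domain`), and the single-species traveling-wave oracle
#' (`nagumo_wave_oracle`, whose front speed has the closed form
#' `sqrt(2 D) (1/2 - alpha_c)`).
#'
#' @param name preset name; see Details.
#' @return list with elements `config` (fully resolved), `overlay` (the
#'   patch over the defaults), `description`, and `expected` (character
#'   tags of the qualitative signature, used by [runScenario()]).
#' @export
scenarioConfig <- function(name) {
  presets <- scenarioPresets()
  if (!name %in% names(presets)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  list(name = name, config = modelConfig(p$overlay), overlay = p$overlay,
       description = p$description, expected = p$expected,
       switches = p$switches)
}

#' @keywords internal
scenarioPresets <- function() {
  grow_num <- list(dt = 0.005, output_stride = 200)  # frame every 1 time unit
  fig6_base <- function(L, chi) {
    list(
      growth = list(L0 = L, growth_speed = 0, max_length = L),
      numerics = list(t_end = 450, dt = 5e-4, output_stride = 4000),
      init = list(mode = "two_bump", all_mature = TRUE),
      chemotaxis = list(enabled = TRUE, chi = chi),
      mesenchyme = list(enabled = FALSE)
    )
  }
  list(
    fig2_sequential = list(
      overlay = list(
        numerics = c(grow_num, list(t_end = 400)),
        growth = list(L0 = 1.0, growth_speed = 0.02, max_length = 4.6)
      ),
      switches = list(),
      description = paste(
        "Posteriorly growing domain with symmetric bistable kinetics:",
        "periodic posterior activation episodes each maturing into a new",
        "Turing peak; no erasures."),
      expected = c("births >= 2", "erasures == 0", "episodes precede births")
    ),
    fig3_palimpsest = list(
      overlay = list(
        kinetics = list(Q_h = 3.2),
        regimes = list(q_bistable = 8),
        maturation = list(activator_boost = 0.1, delay = 15),
        init = list(mode = "anterior_peak", anterior_peak_center = 0.4,
                    anterior_peak_mature_halfwidth = 0.3),
        numerics = c(grow_num, list(t_end = 400)),
        growth = list(L0 = 1.6, growth_speed = 0.02, max_length = 3.4)
      ),
      switches = list(),
      description = paste(
        "Asymmetric self-regulation (Q_h > Q_l) makes the activated state",
        "more stable: a posterior activation wave invades the domain,",
        "erases the established anterior peak, which then recovers next to",
        "a newly formed posterior peak (developmental palimpsest)."),
      expected = c("front_passage >= 1", "erasure >= 1", "recovery >= 1",
                   "final peaks >= 2")
    ),
    fig4_mutant = list(
      overlay = list(
        kinetics = list(Q_h = 3.2),
        regimes = list(q_bistable = 8, mutant_scale = 0.5),
        maturation = list(activator_boost = 0.1, delay = 15),
        init = list(mode = "anterior_peak", anterior_peak_center = 0.4,
                    anterior_peak_mature_halfwidth = 0.3),
        numerics = c(grow_num, list(t_end = 400)),
        growth = list(L0 = 1.6, growth_speed = 0.02, max_length = 3.4)
      ),
      switches = list(),
      description = paste(
        "Same configuration as the palimpsest run except that the",
        "auto-inhibition rates are scaled down (stronger inhibition, the",
        "Edar loss-of-function analogue): the wave is suppressed, no",
        "erasure occurs, and the first peak forms later and more",
        "posteriorly."),
      expected = c("erasures == 0", "births >= 1")
    ),
    fig6_nochemo = list(
      overlay = fig6_base(2.6, 0),
      switches = list(maturation = FALSE),
      description = "Fixed matured domain L = 2.6 without chemotaxis: two Turing peaks.",
      expected = c("final peaks == 2", "fusions == 0")
    ),
    fig6_chemo_low = list(
      overlay = fig6_base(2.6, 0.1),
      switches = list(maturation = FALSE),
      description = "Weak chemotaxis (chi = 0.1): the two peaks do not fuse.",
      expected = c("fusions == 0")
    ),
    fig6_chemo = list(
      overlay = fig6_base(2.6, 0.5),
      switches = list(maturation = FALSE),
      description = "Chemotaxis chi = 0.5 fuses the two peaks into one large peak.",
      expected = c("fusions == 1", "final peaks == 1")
    ),
    fig6_large_domain = list(
      overlay = fig6_base(3.0, 0.5),
      switches = list(maturation = FALSE),
      description = paste(
        "Larger domain (L = 3) with the wider-spaced two-peak mode:",
        "the same chemotaxis level no longer fuses the peaks."),
      expected = c("fusions == 0")
    ),
    nagumo_wave_oracle = list(
      overlay = list(
        kinetics = list(gamma = 0, Q_h = 1, Q_l = 1, theta0 = 0.3,
                        D_a = 0.01, D_i = 0.05, b = 0),
        growth = list(L0 = 6, growth_speed = 0, max_length = 6, dx = 0.01),
        numerics = list(t_end = 100, dt = 0.005, output_stride = 200),
        init = list(mode = "front", front_position_frac = 0.5),
        mesenchyme = list(enabled = FALSE)
      ),
      switches = list(maturation = FALSE),
      description = paste(
        "Single-species reduction (inhibitor decoupled): the reaction is",
        "the exact Nagumo cubic a(1-a)(a-0.3); the bistable front speed",
        "has the closed form sqrt(2 D)(1/2 - alpha_c)."),
      expected = c("front speed within 3% of closed form")
    )
  )
}

#' Run a scenario preset
#'
#' Resolves the preset configuration, runs the simulation, extracts the
#' event log, and checks the scenario's expected qualitative signature.
#'
#' @param name preset name (see [scenarioConfig()]).
#' @param overrides optional extra configuration overlay.
#' @return list with `chronogram`, `events` ([EventLog-class]), `checks`
#'   (named logical vector), `pass` (all checks true), `name`.
#' @export
runScenario <- function(name, overrides = NULL) {
  sc <- scenarioConfig(name)
  cfg <- if (is.null(overrides)) sc$config else {
    modelConfig(mergeConfig(sc$overlay, overrides))
  }
  args <- c(list(cfg), sc$switches)
  cg <- do.call(simulate, args)
  ev <- trackEvents(cg)
  checks <- checkSignature(name, cg, ev)
  list(name = name, chronogram = cg, events = ev, checks = checks,
       pass = all(checks))
}

#' @keywords internal
checkSignature <- function(name, cg, ev) {
  n_birth <- eventCount(ev, "birth")
  n_rec <- eventCount(ev, "recovery")
  n_eras <- eventCount(ev, "erasure")
  n_fus <- eventCount(ev, "fusion")
  n_front <- eventCount(ev, "front_passage")
  final_pk <- finalPeakCount(cg)
  switch(name,
    fig2_sequential = {
      eps <- broadActivationEpisodes(cg)
      births <- events(ev, c("birth", "recovery"))
      preceded <- nrow(births) > 0 && all(vapply(births$time, function(tb) {
        any(eps$start <= tb & tb <= eps$end + 30)
      }, logical(1)))
      c(two_births = n_birth + n_rec >= 2, no_erasure = n_eras == 0,
        episodes_precede = preceded)
    },
    fig3_palimpsest = {
      evd <- events(ev)
      t_front <- if (n_front) min(evd$time[evd$type == "front_passage"]) else NA
      t_eras <- if (n_eras) min(evd$time[evd$type == "erasure"]) else NA
      t_rec <- if (n_rec) min(evd$time[evd$type == "recovery"]) else NA
      c(front = n_front >= 1, erasure = n_eras >= 1, recovery = n_rec >= 1,
        ordered = !is.na(t_front) && !is.na(t_eras) && !is.na(t_rec) &&
          t_front <= t_eras && t_eras < t_rec,
        coexist = final_pk >= 2)
    },
    fig4_mutant = c(no_erasure = n_eras == 0, some_birth = n_birth >= 1),
    fig6_nochemo = c(two_peaks = final_pk == 2, no_fusion = n_fus == 0),
    fig6_chemo_low = c(no_fusion = n_fus == 0),
    fig6_chemo = c(one_fusion = n_fus == 1, one_peak = final_pk == 1),
    fig6_large_domain = c(no_fusion = n_fus == 0),
    nagumo_wave_oracle = {
      k <- cg@config$kinetics
      ff <- frontSpeed(cg, level = 0.5, t_window = c(20, 90))
      ref <- sqrt(2 * k$D_a) * (0.5 - k$theta0)
      c(speed_3pct = abs(ff$speed - ref) / ref < 0.03)
    },
    stop("no signature defined for scenario ", name, call. = FALSE)
  )
}

#' Domain-size sweep for chemotaxis-driven fusion
#'
#' Reruns the fused two-peak scenario on progressively longer fixed
#' domains (the seeded two-bump spacing scales with the domain) at a given
#' chemotaxis level, recording whether the peaks fuse, and reports the
#' smallest length increase that prevents fusion.
#'
#' @param chi chemotaxis coefficient (default 0.5).
#' @param base_length reference length (default 2.6).
#' @param increments percentage length increases to test.
#' @return list with `table` (data.frame increment/length/fused) and
#'   `threshold` (smallest non-fusing increment, `NA` if all fuse). Errors
#'   if the base case does not fuse.
#' @export
domainSizeSweep <- function(chi = 0.5, base_length = 2.6,
                            increments = c(0, 5, 10, 15, 20)) {
  increments <- sort(increments)
  fused <- logical(length(increments))
  for (j in seq_along(increments)) {
    L <- base_length * (1 + increments[j] / 100)
    res <- runScenario("fig6_chemo", overrides = list(
      growth = list(L0 = L, max_length = L)))
    fused[j] <- eventCount(res$events, "fusion") >= 1
    if (increments[j] == 0 && !fused[j]) {
      stop("base configuration does not fuse; the sweep is meaningless",
           call. = FALSE)
    }
  }
  tab <- data.frame(increment_pct = increments,
                    length = base_length * (1 + increments / 100),
                    fused = fused)
  thr <- increments[!fused]
  list(table = tab, threshold = if (length(thr)) min(thr) else NA_real_)
}

#' Single-parameter robustness sweep
#'
#' Reruns a scenario with one configuration value scaled by each factor in
#' `relative_changes` and records whether the qualitative signature is
#' preserved.
#'
#' @param scenario preset name.
#' @param parameter dotted configuration key (e.g. `"kinetics.D_a"`).
#' @param relative_changes multiplicative factors (1 = unchanged).
#' @return data.frame with columns `factor`, `value`, `preserved`.
#' @export
robustnessSweep <- function(scenario, parameter,
                            relative_changes = c(0.9, 1, 1.1)) {
  sc <- scenarioConfig(scenario)
  path <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  base_val <- sc$config[[path]]
  if (is.null(base_val)) stop("unknown parameter: ", parameter, call. = FALSE)
  out <- data.frame(factor = relative_changes,
                    value = base_val * relative_changes,
                    preserved = NA)
  for (j in seq_along(relative_changes)) {
    ov <- list()
    ov[[path[1]]] <- stats::setNames(list(base_val * relative_changes[j]),
                                     path[2])
    res <- tryCatch(runScenario(scenario, overrides = ov),
                    error = function(e) NULL)
    out$preserved[j] <- !is.null(res) && res$pass
  }
  out
}
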