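#' Default model configuration
#'
#' Returns the canonical configuration of the patterning model as a nested
#' named list. Every simulation, scenario preset and analysis starts from
#' these values; presets are expressed as small overlay patches on top of
#' them (see [scenarioConfig()]).
#'
#' Sections:
#' \describe{
#'   \item{kinetics}{activator/inhibitor reaction constants. `D_a`, `D_i`:
#'     diffusivities (nondimensional length^2/time, `D_i > D_a`). `Q_h`,
#'     `Q_l`: activator self-regulation strength above/below the unstable
#'     intermediate state (`Q_h > Q_l` makes the high-activation state more
#'     stable and drives an invading wave). `b`, `d_i`: inhibitor production
#'     and decay rates. `theta0`: activation threshold of the cubic
#'     autocatalysis at zero inhibitor; `gamma`: how strongly the inhibitor
#'     raises that threshold (`i_sat` optionally saturates the coupling;
#'     0 = linear). `p_i`, `K_i`: exponent and half-saturation of the Hill
#'     drive of inhibitor production. `a_switch`, `eps_Q`: centre and width
#'     of the smooth switch between `Q_l` and `Q_h`.}
#'   \item{regimes}{`q_bistable`, `q_turing`: the inhibitor auto-inhibition
#'     rate `q_auto` in immature and mature tissue; this single parameter is
#'     what the maturation switch changes. `mutant_scale`: multiplier
#'     applied to both (values < 1 lower auto-inhibition, i.e. strengthen
#'     inhibition, as in the Edar loss-of-function scenario).}
#'   \item{growth}{posterior tissue growth: initial length `L0`, speed
#'     `growth_speed`, saturation `max_length`, grid spacing `dx`.}
#'   \item{maturation}{exponential tissue maturation: baseline rate
#'     `baseline_rate`, activator-stimulated boost `activator_boost` applied
#'     when the delayed activator exceeds `activation_threshold` (delay
#'     `delay`), irreversible regime switch at `switch_threshold`, new-cell
#'     seed `seed_value`, cap at `cap_factor * switch_threshold`.}
#'   \item{mesenchyme}{posterior priming component: below `low_threshold`
#'     the stored activity `s` is released as a positive activator source,
#'     above `high_threshold` a mild direct sink (`negative_gain`) applies;
#'     `positive_gain` and `relaxation_rate` set the charging dynamics,
#'     `spatial_window` the posterior fraction of the domain affected.}
#'   \item{chemotaxis}{cell-density layer: chemotactic coefficient `chi`,
#'     cell diffusivity `D_rho`, reference density `rho_ref`, and
#'     `feedback_strength` of the density-dependent down-regulation of
#'     inhibitor production.}
#'   \item{numerics}{time step `dt`, horizon `t_end`, frame saving stride
#'     `output_stride`, `scheme` ("imex" or "explicit"),
#'     `perturbation_amplitude` and `seed` for symmetry breaking.}
#'   \item{init}{initial condition: `mode` one of "flat_low", "two_bump",
#'     "front", "turing_homogeneous"; bump/front geometry; `all_mature`
#'     starts the whole domain in the mature (Turing) regime.}
#' }
#'
#' @param overlay optional nested list patched over the defaults.
#' @return a validated configuration list (see [validateConfig()]).
#' @export
#' @examples
#' cfg <- modelConfig(list(numerics = list(t_end = 10)))
#' cfg$numerics$t_end
modelConfig <- function(overlay = NULL) {
  cfg <- list(
    kinetics = list(
      D_a = 0.0034, D_i = 0.4,
      Q_h = 1.9, Q_l = 1.9,
      b = 8.44956836, d_i = 4,
      theta0 = 0.1, gamma = 1.2, i_sat = 0, p_i = 2, K_i = 1.0547,
      a_switch = 0.15, eps_Q = 0.05
    ),
    regimes = list(
      q_bistable = 0.75, q_turing = 0.1, mutant_scale = 1
    ),
    growth = list(
      L0 = 1.0, growth_speed = 0.02, max_length = 3.4, dx = 2.6 / 300
    ),
    maturation = list(
      baseline_rate = 0.002, activator_boost = 0.25,
      activation_threshold = 0.7, delay = 8,
      switch_threshold = 1, seed_value = 0.1,
      cap_factor = 10, eps = 0.05
    ),
    mesenchyme = list(
      enabled = TRUE,
      low_threshold = 0.55, high_threshold = 0.85,
      positive_gain = 0.05, negative_gain = 0.2,
      relaxation_rate = 0.05, spatial_window = 0.15,
      eps = 0.02
    ),
    chemotaxis = list(
      enabled = FALSE, chi = 0, D_rho = 0.4, rho_ref = 1,
      feedback_strength = 6
    ),
    numerics = list(
      dt = 0.005, t_end = 300, output_stride = 200,
      scheme = "imex", perturbation_amplitude = 1e-3, seed = 1
    ),
    init = list(
      mode = "flat_low",
      bump_centers_frac = c(0.25, 0.75),
      bump_amplitude = 0.6, bump_width = 0.15,
      front_position_frac = 0.5,
      anterior_peak_center = 0.4,
      anterior_peak_mature_halfwidth = 0.35,
      all_mature = FALSE
    )
  )
  cfg <- mergeConfig(cfg, overlay)
  validateConfig(cfg)
}

#' Validate a configuration list
#'
#' Checks the schema (unknown keys are rejected), value domains, and the
#' cross-field constraints of the model. Returns the config invisibly
#' unchanged on success; stops with a message naming the offending key
#' otherwise.
#'
#' @param cfg nested configuration list as returned by [modelConfig()].
#' @return the validated config (invisibly the same object).
#' @export
validateConfig <- function(cfg) {
  known <- modelConfigSchema()
  for (sec in names(cfg)) {
    if (!sec %in% names(known)) {
      stop("unknown config section: ", sec, call. = FALSE)
    }
    extra <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(extra)) {
      stop("unknown config key: ", sec, ".", extra[1], call. = FALSE)
    }
  }
  k <- cfg$kinetics
  if (!(k$D_a > 0 && k$D_i > k$D_a)) {
    stop("kinetics.D_i must exceed kinetics.D_a > 0 ",
         "(differential diffusion is required for a Turing instability)",
         call. = FALSE)
  }
  for (nm in c("Q_h", "Q_l", "b", "d_i", "gamma", "eps_Q")) {
    if (k[[nm]] < 0) stop("kinetics.", nm, " must be >= 0", call. = FALSE)
  }
  r <- cfg$regimes
  if (r$q_bistable < 0 || r$q_turing < 0 || r$mutant_scale <= 0) {
    stop("regimes values must be non-negative (mutant_scale > 0)", call. = FALSE)
  }
  if (r$q_bistable == r$q_turing) {
    stop("regimes.q_bistable must differ from regimes.q_turing ",
         "(the maturation switch changes exactly this parameter)",
         call. = FALSE)
  }
  g <- cfg$growth
  if (g$L0 <= 0) stop("growth.L0 must be > 0", call. = FALSE)
  if (g$growth_speed < 0) stop("growth.growth_speed must be >= 0", call. = FALSE)
  if (g$dx <= 0) stop("growth.dx must be > 0", call. = FALSE)
  if (g$max_length < g$L0) stop("growth.max_length must be >= growth.L0", call. = FALSE)
  m <- cfg$maturation
  if (m$baseline_rate <= 0) stop("maturation.baseline_rate must be > 0", call. = FALSE)
  if (m$delay < 0) stop("maturation.delay must be >= 0", call. = FALSE)
  if (!(m$seed_value > 0 && m$seed_value < m$switch_threshold)) {
    stop("maturation.seed_value must lie in (0, switch_threshold)", call. = FALSE)
  }
  ms <- cfg$mesenchyme
  if (ms$low_threshold >= ms$high_threshold) {
    stop("mesenchyme.low_threshold must be < mesenchyme.high_threshold", call. = FALSE)
  }
  if (ms$positive_gain < 0 || ms$negative_gain < 0 || ms$relaxation_rate < 0) {
    stop("mesenchyme gains and relaxation_rate must be >= 0", call. = FALSE)
  }
  ch <- cfg$chemotaxis
  if (ch$chi < 0) stop("chemotaxis.chi must be >= 0", call. = FALSE)
  if (ch$D_rho < 0) stop("chemotaxis.D_rho must be >= 0", call. = FALSE)
  if (ch$rho_ref <= 0) stop("chemotaxis.rho_ref must be > 0", call. = FALSE)
  n <- cfg$numerics
  if (n$dt <= 0) stop("numerics.dt must be > 0", call. = FALSE)
  if (n$t_end <= 0) stop("numerics.t_end must be > 0", call. = FALSE)
  if (!(n$output_stride >= 1)) stop("numerics.output_stride must be >= 1", call. = FALSE)
  if (!n$scheme %in% c("imex", "explicit")) {
    stop("numerics.scheme must be 'imex' or 'explicit'", call. = FALSE)
  }
  if (!cfg$init$mode %in% c("flat_low", "two_bump", "front", "anterior_peak", "turing_homogeneous")) {
    stop("init.mode must be one of flat_low, two_bump, front, anterior_peak, turing_homogeneous",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @keywords internal
modelConfigSchema <- function() {
  list(
    kinetics = c("D_a", "D_i", "Q_h", "Q_l", "b", "d_i", "theta0", "gamma",
                 "a_switch", "eps_Q", "i_sat", "p_i", "K_i"),
    regimes = c("q_bistable", "q_turing", "mutant_scale"),
    growth = c("L0", "growth_speed", "max_length", "dx"),
    maturation = c("baseline_rate", "activator_boost", "activation_threshold",
                   "delay", "switch_threshold", "seed_value", "cap_factor", "eps"),
    mesenchyme = c("enabled", "low_threshold", "high_threshold", "positive_gain",
                   "negative_gain", "relaxation_rate", "spatial_window", "eps"),
    chemotaxis = c("enabled", "chi", "D_rho", "rho_ref", "feedback_strength"),
    numerics = c("dt", "t_end", "output_stride", "scheme",
                 "perturbation_amplitude", "seed"),
    init = c("mode", "bump_centers_frac", "bump_amplitude", "bump_width",
             "front_position_frac", "anterior_peak_center",
             "anterior_peak_mature_halfwidth", "all_mature")
  )
}

#' Load a configuration file
#'
#' Reads a YAML or JSON configuration (chosen by file extension), patches it
#' over the defaults, validates the result, and records provenance (path and
#' md5) as attributes.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file containing any
#'   subset of the configuration sections.
#' @return a validated configuration list with attributes `source_path` and
#'   `source_md5`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  overlay <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON, got extension: ", ext, call. = FALSE)
  )
  cfg <- modelConfig(overlay)
  attr(cfg, "source_path") <- normalizePath(path)
  attr(cfg, "source_md5") <- unname(tools::md5sum(path))
  cfg
}

#' Write a configuration to file
#'
#' @param cfg configuration list.
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
writeConfig <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  x <- cfg
  attributes(x) <- list(names = names(x))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(x, path, precision = 15),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("config must be YAML or JSON, got extension: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' Differences between two configurations
#'
#' Flattens both configs to dotted keys and reports keys whose values
#' differ. Used e.g. to verify that the mutant scenario differs from the
#' wild type in the auto-inhibition values only.
#'
#' @param a,b configuration lists.
#' @return character vector of dotted key names that differ.
#' @export
configDiff <- function(a, b) {
  fa <- flattenConfig(a)
  fb <- flattenConfig(b)
  keys <- union(names(fa), names(fb))
  differs <- vapply(keys, function(k) {
    !identical(fa[[k]], fb[[k]])
  }, logical(1))
  sort(keys[differs])
}
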