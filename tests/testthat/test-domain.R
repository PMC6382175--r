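test_that("growth appends cells at the accumulator rate and saturates", {
  cfg <- modelConfig(list(growth = list(L0 = 1, growth_speed = 0.05,
                                        max_length = 2)))
  st <- makeState(cfg)
  n0 <- length(st$a)
  # no growth: bit-identical state
  st0 <- growDomain(st, 1, modelConfig(list(growth = list(growth_speed = 0))))
  expect_identical(st0$a, st$a)
  expect_identical(st0$x, st$x)
  # accumulate to time T: length within one dx of L0 + c_g T
  dt <- 0.05
  L0_actual <- max(st$x)
  for (k in seq_len(200)) st <- growDomain(st, dt, cfg)  # T = 10
  L_T <- max(st$x)
  # grown length equals c_g * T to within one appended cell
  expect_lt(abs((L_T - L0_actual) - 0.05 * 10), cfg$growth$dx + 1e-12)
  # appended cells start inactivated, immature, bistable
  new_idx <- seq.int(n0 + 1L, length(st$a))
  expect_true(all(st$a[new_idx] == 0))
  expect_true(all(st$m[new_idx] == cfg$maturation$seed_value))
  expect_true(all(st$flag[new_idx] == 0L))
  # saturation at max_length
  for (k in seq_len(1000)) st <- growDomain(st, dt, cfg)
  expect_lte(max(st$x), cfg$growth$max_length + cfg$growth$dx)
})

test_that("maturation without activation follows the exponential closed form", {
  cfg <- modelConfig(list(
    growth = list(L0 = 0.5, growth_speed = 0),
    numerics = list(t_end = 50, dt = 0.005, output_stride = 2000),
    mesenchyme = list(enabled = FALSE)
  ))
  cg <- simulate(cfg)   # a stays 0 everywhere: only baseline maturation
  alpha <- cfg$maturation$baseline_rate
  m0 <- cfg$maturation$seed_value
  for (j in seq_len(nFrames(cg))) {
    t <- frameTimes(cg)[j]
    m <- getFrame(cg, j)$maturation
    expect_equal(m, rep(m0 * exp(alpha * t), length(m)), tolerance = 1e-4)
  }
})

test_that("maturation is non-decreasing at every node of a full simulation", {
  r <- cachedScenario("fig2_sequential")
  M <- fieldMatrix(r$chronogram, "maturation")
  lens <- r$chronogram@lengths
  for (j in 2:nFrames(r$chronogram)) {
    n <- lens[j - 1]
    expect_true(all(M[j, seq_len(n)] >= M[j - 1, seq_len(n)] - 1e-12))
  }
})

test_that("activator stimulation of maturation acts only after the delay", {
  # the posterior window ignites at some time t0 (observable from the
  # chronogram); the maturation boost must follow only at t0 + tau
  tau <- 15
  cfg <- modelConfig(list(
    growth = list(L0 = 1, growth_speed = 0),
    maturation = list(delay = tau, activator_boost = 0.25,
                      switch_threshold = 30, cap_factor = 2),
    mesenchyme = list(positive_gain = 0.3, relaxation_rate = 0.05),
    numerics = list(t_end = 40, dt = 0.005, output_stride = 40)
  ))
  cg <- simulate(cfg)
  times <- frameTimes(cg)
  n <- cg@lengths[1]
  node <- n - 2L   # inside the posterior window
  a_node <- fieldMatrix(cg, "activator")[, node]
  m_node <- fieldMatrix(cg, "maturation")[, node]
  th <- cfg$maturation$activation_threshold
  t0 <- times[which(a_node > th)[1]]
  expect_false(is.na(t0))
  rate <- diff(log(m_node)) / diff(times)
  alpha <- cfg$maturation$baseline_rate
  beta <- cfg$maturation$activator_boost
  early <- rate[times[-1] < t0 + tau - 3]
  late <- rate[times[-1] > t0 + tau + 3]
  expect_lt(max(early), alpha + beta / 4)    # before t0 + tau: near baseline
  expect_gt(min(late), (alpha + beta) * 0.8) # afterwards: boosted
})

test_that("regime flags are irreversible and idempotent", {
  cfg <- modelConfig()
  st <- makeState(cfg)
  st$m[5] <- cfg$maturation$switch_threshold
  st1 <- updateRegimeFlags(st, cfg)
  expect_identical(st1$flag[5], 1L)
  expect_true(all(st1$flag[-5] == 0L))
  # lowering m afterwards must not revert the flag
  st1$m[5] <- 0.1
  st2 <- updateRegimeFlags(st1, cfg)
  expect_identical(st2$flag[5], 1L)
  # idempotent on an already-mature state
  st3 <- updateRegimeFlags(st2, cfg)
  expect_identical(st3$flag, st2$flag)
})

test_that("regime flags never revert during a full simulation", {
  r <- cachedScenario("fig3_palimpsest")
  FL <- fieldMatrix(r$chronogram, "regime")
  lens <- r$chronogram@lengths
  for (j in 2:nFrames(r$chronogram)) {
    n <- lens[j - 1]
    expect_true(all(FL[j, seq_len(n)] >= FL[j - 1, seq_len(n)]))
  }
})

test_that("mesenchymal source is positive below the low threshold and non-positive above the high one", {
  cfg <- modelConfig(list(mesenchyme = list(spatial_window = 1)))
  st <- makeState(cfg)
  st$s <- 0.5
  # quiescent window: priming source only
  mf <- mesenchymeForcing(st, 0.01, cfg)
  expect_true(all(mf$source >= 0))
  expect_gt(max(mf$source), 0)
  # strongly activated window: sink only
  st$a <- rep(1, length(st$a))
  mf2 <- mesenchymeForcing(st, 0.01, cfg)
  expect_true(all(mf2$source <= 1e-10))
  expect_lt(min(mf2$source), 0)
  # outside the window the source vanishes
  cfg3 <- modelConfig(list(mesenchyme = list(spatial_window = 0.2)))
  st3 <- makeState(cfg3)
  st3$s <- 0.5
  mf3 <- mesenchymeForcing(st3, 0.01, cfg3)
  n <- length(st3$a)
  expect_true(all(mf3$source[seq_len(floor(0.7 * n))] == 0))
})

test_that("the mesenchyme reservoir cycles through discharge and recharge", {
  # the posterior oscillation of this model is spatial: each growth-spaced
  # activation episode discharges the reservoir s, which then recharges
  # while the fresh posterior tissue is still locked. The s trace of the
  # growing-domain run must show repeated discharge/recharge cycles.
  r <- cachedScenario("fig2_sequential")
  s <- r$chronogram@mesenchyme
  up <- sum(diff(s > 0.15) == 1)
  expect_gte(up, 2)
  # and the priming is what ignites activation at all: a single quiescent
  # posterior node with priming crosses the ignition threshold
  cfg0 <- modelConfig(list(
    growth = list(L0 = 2 * (2.6 / 300), growth_speed = 0),
    mesenchyme = list(spatial_window = 1),
    numerics = list(t_end = 50, dt = 0.005, output_stride = 40)
  ))
  cg0 <- simulate(cfg0, maturation = FALSE)
  a_node <- fieldMatrix(cg0, "activator")[, 2]
  expect_gt(max(a_node), cfg0$mesenchyme$low_threshold)
})

test_that("inhibitory lock: tissue next to a mature peak stays inactivated without forcing", {
  # grow fresh bistable tissue next to an established mature peak with the
  # mesenchyme disabled: the new segment must relax to the low state and
  # stay below the unstable intermediate state
  cfg <- modelConfig(list(
    init = list(mode = "anterior_peak", anterior_peak_center = 0.4,
                anterior_peak_mature_halfwidth = 1.0),
    growth = list(L0 = 1.2, growth_speed = 0.02, max_length = 2.2),
    mesenchyme = list(enabled = FALSE),
    numerics = list(t_end = 250, dt = 0.005, output_stride = 1000)
  ))
  cg <- simulate(cfg)
  ss <- homogeneousSteadyStates(cfg, "bistable")
  a_unstable <- ss$a[ss$stable %in% FALSE][1]
  fr <- getFrame(cg, -1)
  grown <- fr$x > 1.2
  expect_true(any(grown))
  expect_lt(max(fr$activator[grown]), a_unstable)
})

test_that("without mesenchymal priming no new peak ever forms in the grown domain", {
  cfg <- modelConfig(list(mesenchyme = list(positive_gain = 0),
                          growth = list(max_length = 4.6),
                          numerics = list(t_end = 300, dt = 0.005,
                                          output_stride = 1000)))
  cg <- simulate(cfg)
  counts <- vapply(seq_len(nFrames(cg)), function(j) {
    fr <- getFrame(cg, j)
    nrow(detectPeaks(fr$activator, fr$x))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))   # peak count never increases
})
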