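test_that("a uniform stable homogeneous state is a fixed point of the stepper", {
  cfg <- modelConfig(list(growth = list(L0 = 1, growth_speed = 0),
                          numerics = list(t_end = 0.05, dt = 0.005,
                                          output_stride = 1)))
  ss <- homogeneousSteadyStates(cfg, "bistable")
  hi <- ss[ss$stable %in% TRUE & ss$a > 0.9, ]
  for (state0 in list(c(0, 0), c(hi$a[1], hi$i[1]))) {
    st <- makeState(cfg)
    st$a <- rep(state0[1], length(st$a))
    st$i <- rep(state0[2], length(st$i))
    out <- toothwave:::engine_run(
      st$a, st$i, st$m, st$rho, st$flag, 0,
      toothwave:::enginePar(cfg, FALSE, FALSE, FALSE, FALSE),
      0, 0, 10L, 1L, length(st$a))
    expect_lt(max(abs(out$final$a - state0[1])), 1e-10)
    expect_lt(max(abs(out$final$i - state0[2])), 1e-10)
  }
})

test_that("the R reference step and the compiled explicit step agree", {
  cfg <- modelConfig(list(
    growth = list(L0 = 1.2, growth_speed = 0.05),
    numerics = list(dt = 5e-5, scheme = "explicit"),
    maturation = list(delay = 0),
    mesenchyme = list(enabled = TRUE, spatial_window = 0.3),
    chemotaxis = list(enabled = TRUE, chi = 0.3),
    init = list(mode = "two_bump", bump_amplitude = 0.8, bump_width = 0.2)
  ))
  st <- makeState(cfg)
  st$s <- 0.2
  st$rho <- st$rho * (1 + 0.1 * sin(seq_along(st$rho)))
  dt <- cfg$numerics$dt
  n_steps <- 25L
  max_n <- as.integer(round(cfg$growth$max_length / cfg$growth$dx)) + 1L
  out <- toothwave:::engine_run(
    st$a, st$i, st$m, st$rho, st$flag, st$s,
    toothwave:::enginePar(cfg, TRUE, TRUE, TRUE, TRUE),
    0, 0, n_steps, n_steps, max_n)
  st_r <- st
  for (k in seq_len(n_steps)) st_r <- stepState(st_r, dt, cfg)
  n <- length(st_r$a)
  expect_identical(length(out$final$a), n)
  expect_lt(max(abs(out$final$a - st_r$a)), 1e-12)
  expect_lt(max(abs(out$final$i - st_r$i)), 1e-12)
  expect_lt(max(abs(out$final$m - st_r$m)), 1e-12)
  expect_lt(max(abs(out$final$rho - st_r$rho)), 1e-12)
  expect_equal(out$final$s, st_r$s, tolerance = 1e-12)
})

test_that("total cell mass is conserved under no-flux chemotaxis", {
  r <- cachedScenario("fig6_chemo")
  cg <- r$chronogram
  mass <- vapply(seq_len(nFrames(cg)), function(j) {
    sum(getFrame(cg, j)$density)
  }, numeric(1))
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-8)
})

test_that("all saved fields stay non-negative", {
  for (nm in c("fig3_palimpsest", "fig6_chemo")) {
    cg <- cachedScenario(nm)$chronogram
    for (f in c("activator", "inhibitor", "density")) {
      M <- fieldMatrix(cg, f)
      expect_true(all(M[!is.na(M)] >= 0))
    }
  }
})

test_that("chemotactic flux has the Keller-Segel structure", {
  dx <- 0.01
  x <- seq(0, 2, by = dx)
  rho <- rep(1, length(x))
  a <- exp(-((x - 1) / 0.2)^2)
  expect_true(all(chemotacticFlux(rho, a, 0, dx) == 0))
  expect_true(all(chemotacticFlux(rho, rep(0.4, length(x)), 0.5, dx) == 0))
  fl <- chemotacticFlux(rho, a, 0.5, dx)
  xf <- (x[-1] + x[-length(x)]) / 2
  expect_true(all(fl[xf < 0.95] >= 0))   # drift toward the peak from the left
  expect_true(all(fl[xf > 1.05] <= 0))   # and from the right
})

test_that("density feedback is 1 at the reference density and monotone non-increasing", {
  cfg <- modelConfig()
  expect_equal(densityFeedback(cfg$chemotaxis$rho_ref, cfg), 1)
  grid <- seq(0, 4, by = 0.01)
  phi <- densityFeedback(grid, cfg)
  expect_true(all(diff(phi) <= 0))
  expect_true(all(phi[grid > 1] < 1))
  expect_true(all(phi > 0))
})

test_that("identical configuration and seed give identical chronograms", {
  cfg <- modelConfig(list(
    growth = list(L0 = 2.6, growth_speed = 0, dx = 0.01),
    numerics = list(t_end = 30, dt = 0.005, output_stride = 500, seed = 7),
    init = list(mode = "turing_homogeneous")
  ))
  cg1 <- simulate(cfg, mesenchyme = FALSE, maturation = FALSE)
  cg2 <- simulate(cfg, mesenchyme = FALSE, maturation = FALSE)
  expect_identical(fieldMatrix(cg1, "activator"), fieldMatrix(cg2, "activator"))
  expect_identical(fieldMatrix(cg1, "inhibitor"), fieldMatrix(cg2, "inhibitor"))
  expect_identical(cg1@mesenchyme, cg2@mesenchyme)
  # a different seed perturbs differently
  cfg3 <- modelConfig(toothwave:::mergeConfig(cfg,
                                              list(numerics = list(seed = 8))))
  cg3 <- simulate(cfg3, mesenchyme = FALSE, maturation = FALSE)
  expect_false(identical(fieldMatrix(cg1, "activator")[1, ],
                         fieldMatrix(cg3, "activator")[1, ]))
})

test_that("stability violations are reported with the configured bound", {
  expect_error(simulate(modelConfig(list(numerics = list(dt = 0.5)))),
               "reaction bound")
  expect_error(
    simulate(modelConfig(list(numerics = list(dt = 0.005, scheme = "explicit"),
                              growth = list(dx = 0.005)))),
    "diffusion")
  expect_error(
    simulate(modelConfig(list(chemotaxis = list(enabled = TRUE, chi = 0.5),
                              numerics = list(dt = 0.005)))),
    "advection")
})

test_that("chronogram CSV round-trips through the long format", {
  cfg <- modelConfig(list(growth = list(L0 = 0.5, growth_speed = 0),
                          numerics = list(t_end = 2, dt = 0.005,
                                          output_stride = 200),
                          mesenchyme = list(enabled = FALSE)))
  cg <- simulate(cfg)
  path <- tempfile(fileext = ".csv")
  writeChronogramCSV(cg, path)
  cg2 <- readChronogramCSV(path)
  expect_equal(frameTimes(cg2), frameTimes(cg))
  expect_equal(cg2@lengths, cg@lengths)
  expect_equal(fieldMatrix(cg2, "activator"), fieldMatrix(cg, "activator"),
               tolerance = 1e-6)
})
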