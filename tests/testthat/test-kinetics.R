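test_that("reaction terms vanish at every reported steady state", {
  cfg <- modelConfig()
  for (regime in c("bistable", "turing")) {
    ss <- homogeneousSteadyStates(cfg, regime)
    for (j in seq_len(nrow(ss))) {
      r <- reactionTerms(ss$a[j], ss$i[j], regime, cfg)
      expect_lt(max(abs(c(r$da, r$di))), 1e-8)
    }
  }
})

test_that("steady states match a brute-force nullcline grid scan", {
  cfg <- modelConfig()
  ss <- homogeneousSteadyStates(cfg, "bistable")
  # oracle: sign changes of both reaction terms over a 400 x 400 grid
  na <- 400; ni <- 400
  av <- seq(0, 1.4, length.out = na)
  iv <- seq(0, 1.0, length.out = ni)
  FA <- outer(av, iv, function(a, i) reactionTerms(a, i, "bistable", cfg)$da)
  FI <- outer(av, iv, function(a, i) reactionTerms(a, i, "bistable", cfg)$di)
  hit <- matrix(FALSE, na - 1, ni - 1)
  for (j in seq_len(na - 1)) for (k in seq_len(ni - 1)) {
    ca <- FA[j:(j + 1), k:(k + 1)]; ci <- FI[j:(j + 1), k:(k + 1)]
    hit[j, k] <- min(ca) <= 0 && max(ca) >= 0 && min(ci) <= 0 && max(ci) >= 0
  }
  # every Newton root lies in (or adjacent to) a sign-change cell, and every
  # connected cluster of sign-change cells contains a Newton root.
  # note: f = a(1-a)(...) vanishes identically on the a = 0 and a = 1 grid
  # lines, so restrict the comparison to cells where the inhibitor nullcline
  # also crosses.
  cells <- which(hit, arr.ind = TRUE)
  cellpos <- cbind(av[cells[, 1]] + diff(av[1:2]) / 2,
                   iv[cells[, 2]] + diff(iv[1:2]) / 2)
  for (j in seq_len(nrow(ss))) {
    d <- sqrt((cellpos[, 1] - ss$a[j])^2 + (cellpos[, 2] - ss$i[j])^2)
    expect_lt(min(d), 0.01)   # within ~2 grid cells
  }
  # cluster the oracle cells by distance to the nearest reported root: each
  # cell must be near some root (no extra intersections missed by Newton)
  for (r in seq_len(nrow(cellpos))) {
    d <- sqrt((ss$a - cellpos[r, 1])^2 + (ss$i - cellpos[r, 2])^2)
    expect_lt(min(d), 0.02)
  }
})

test_that("the bistable regime has two stable states and one saddle", {
  cfg <- modelConfig()
  ss <- homogeneousSteadyStates(cfg, "bistable")
  expect_gte(nrow(ss), 3)
  expect_identical(sum(ss$stable %in% TRUE), 2L)
  stable <- ss[ss$stable %in% TRUE, ]
  expect_lt(min(stable$a), 0.1)   # low state at a = 0
  expect_gt(max(stable$a), 0.9)   # high state at a = 1
})

test_that("symmetric configuration: equal leading eigenvalues at both stable states", {
  cfg <- modelConfig()
  expect_identical(cfg$kinetics$Q_h, cfg$kinetics$Q_l)
  ss <- homogeneousSteadyStates(cfg, "bistable")
  stable <- ss[ss$stable %in% TRUE, ]
  expect_lt(abs(stable$eig1[1] - stable$eig1[2]), 1e-8)
})

test_that("Jacobian sign pattern: inhibitor represses activator, activator drives inhibitor", {
  cfg <- modelConfig()
  d <- dispersionRelation(cfg, "turing")
  J <- reactionJacobian(d@state[1], d@state[2], "turing", cfg)
  expect_gt(J[1, 1], 0)   # self-activation at the patterning state
  expect_lt(J[1, 2], 0)   # inhibitor represses activator
  expect_gt(J[2, 1], 0)   # activator drives inhibitor production
  expect_lt(J[2, 2], 0)
  # at the outer stable states the activator is self-restoring
  ssb <- homogeneousSteadyStates(cfg, "bistable")
  low <- reactionJacobian(0, 0, "bistable", cfg)
  expect_lt(low[1, 1], 0)
})

test_that("closed-form dispersion agrees with direct eigendecomposition to 1e-10", {
  cfg <- modelConfig()
  d <- dispersionRelation(cfg, "turing")
  J <- d@jacobian
  k_grid <- logSpace <- exp(seq(log(1e-3), log(50), length.out = 50))
  lam_closed <- growthRate(J, cfg$kinetics$D_a, cfg$kinetics$D_i, k_grid)
  lam_eigen <- vapply(k_grid, function(k) {
    M <- J - diag(c(cfg$kinetics$D_a, cfg$kinetics$D_i)) * k^2
    max(Re(eigen(M, only.values = TRUE)$values))
  }, numeric(1))
  expect_lt(max(abs(lam_closed - lam_eigen)), 1e-10)
})

test_that("Turing regime: stable to uniform perturbations, unstable in a finite-k band", {
  cfg <- modelConfig()
  d <- dispersionRelation(cfg, "turing")
  expect_identical(regimeLabel(d), "turing")
  lam0 <- d@lambda[d@k == 0]
  expect_lt(lam0, 0)
  expect_gt(max(d@lambda[d@k > 0]), 0)
  expect_gt(kMax(d), 0)
})

test_that("equal diffusivities admit no diffusion-driven instability", {
  # classical Turing requirement: differential diffusion. Equal D violates
  # the config contract, so probe the dispersion formula directly.
  cfg <- modelConfig()
  d <- dispersionRelation(cfg, "turing")
  J <- d@jacobian
  D <- cfg$kinetics$D_a
  lam <- growthRate(J, D, D, c(0, logSpace(1e-3, 50, 100)))
  expect_true(all(lam <= lam[1] + 1e-12))
  expect_true(all(lam < 0))
})

test_that("regime dichotomy: changing q_auto alone flips the classification", {
  cfg <- modelConfig()
  expect_identical(classifyRegime(cfg, "bistable"), "bistable")
  expect_identical(classifyRegime(cfg, "turing"), "turing")
  # the two calls differ in the single parameter q_auto
  expect_false(regimeQ(cfg, "bistable") == regimeQ(cfg, "turing"))
})

test_that("degenerate kinetics classify as 'other'", {
  cfg <- modelConfig(list(kinetics = list(Q_h = 0, Q_l = 0, b = 0)))
  expect_identical(classifyRegime(cfg, "bistable"), "other")
})

test_that("invalid inputs are rejected", {
  cfg <- modelConfig()
  expect_error(reactionTerms(-0.1, 0.2, "bistable", cfg), "negative")
  expect_error(reactionTerms(0.5, NaN, "bistable", cfg), "non-finite")
  expect_error(dispersionRelation(cfg, "turing", k = c(1, 2)), "k = 0")
})
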