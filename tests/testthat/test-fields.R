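test_that("expansion of the identity deformation is zero", {
  f <- make_scaling_field(rep(0, 2))
  e <- compute_expansion(f)
  expect_true(all(e$values == 0))
})

test_that("uniform 10% dilatation gives the closed-form expansion 0.331", {
  f <- make_scaling_field(c(0.05, 0.1))
  e <- compute_expansion(f, 2)
  # linear displacement: differences are exact on every voxel
  expect_equal(max(abs(e$values - (1.1^3 - 1))), 0, tolerance = 1e-12)
  e1 <- compute_expansion(f, 1)
  expect_equal(max(abs(e1$values - (1.05^3 - 1))), 0, tolerance = 1e-12)
})

test_that("expansion matches the brute-force Jacobian oracle", {
  for (seed in 1:3) {
    f <- make_smooth_field(seed = seed)
    e <- compute_expansion(f, 2)
    ref <- oracle_expansion(f, 2)
    expect_lt(max(abs(e$values - ref[e$support])), 1e-10)
  }
})

test_that("expansion is invariant to rigid translation of the field", {
  f <- make_smooth_field(seed = 4)
  e0 <- compute_expansion(f, 2)
  u2 <- f$u
  for (ax in 1:3) u2[, , , ax, 2:3] <- u2[, , , ax, 2:3] + c(0.7, -1.3, 2.1)[ax]
  # translating breaks the phase-0 zero contract, so rebuild around it
  f2 <- f; f2$u <- u2
  e1 <- compute_expansion(f2, 2)
  expect_lt(max(abs(e0$values - e1$values)), 1e-12)
})

test_that("mask thinner than the difference stencil is rejected", {
  sh <- c(8L, 8L, 8L)
  mask <- array(FALSE, sh)
  mask[, , 4:5] <- TRUE # only 2 voxels thick along z
  u <- array(0, c(sh, 3, 2))
  f <- displacement_field(u, mask)
  expect_error(compute_expansion(f), "thinner")
})

test_that("flow is zero for static fields and recovers a linear slope", {
  f0 <- make_scaling_field(rep(0, 6))
  iv <- interval_specs(7)
  expect_equal(nrow(iv), 9L)
  expect_identical(iv$phase_lo, c(0L, 1L, 2L, 3L, 4L, 5L, 0L, 3L, 0L))
  expect_identical(iv$phase_hi, c(1L, 2L, 3L, 4L, 5L, 6L, 3L, 6L, 6L))
  for (r in c(1, 5, 9)) {
    expect_true(all(compute_flow(f0, iv[r, ])$values == 0))
  }
  # u chosen so that e(p) = slope * p exactly: flow = slope on all intervals
  slope <- 0.04
  coefs <- (1 + slope * (1:6))^(1 / 3) - 1
  fl <- make_scaling_field(coefs)
  for (r in seq_len(9)) {
    fv <- compute_flow(fl, iv[r, ])
    expect_equal(max(abs(fv$values - slope)), 0, tolerance = 1e-12)
  }
  expect_error(compute_flow(fl, list(id = 1, phase_lo = 3, phase_hi = 3)),
               "invalid interval")
})

test_that("flow telescopes: consecutive intervals sum to the expansion change", {
  cfg <- default_phenotypes()$copd_gold34
  cfg$seed <- 31L
  s <- simulate_subject(cfg, shape = c(16L, 16L, 16L))
  iv <- interval_specs(7)
  fsum <- 0
  for (r in 1:6) {
    ivr <- iv[r, ]
    fsum <- fsum + compute_flow(s$field, ivr)$values * (ivr$phase_hi - ivr$phase_lo)
  }
  e6 <- compute_expansion(s$field, 6)
  e0 <- compute_expansion(s$field, 0)
  expect_lt(max(abs(fsum - (e6$values - e0$values))), 1e-10)
})

test_that("oscillation is 0 for monotone inflation and 1 for alternation", {
  f <- make_scaling_field(seq(0.01, 0.06, by = 0.01))
  for (v in 1:4) expect_true(all(compute_oscillation(f, v)$values == 0))
  # increments alternating +v, -v over 6 steps: every pair reverses
  coefs <- rep(c(0.05, 0), 3)
  fa <- make_scaling_field(coefs)
  for (v in 1:4) expect_true(all(compute_oscillation(fa, v)$values == 1))
  u3 <- array(0, c(4, 4, 4, 3, 2))
  expect_error(
    compute_oscillation(displacement_field(u3, array(TRUE, c(4, 4, 4))), 1),
    "3 phases"
  )
})

test_that("oscillation matches direct enumeration for all variants", {
  withr::with_seed(55, {
    sh <- c(4L, 4L, 4L)
    u <- array(rnorm(prod(sh) * 3 * 7, sd = 0.5), c(sh, 3, 7))
    u[, , , , 1] <- 0
    f <- displacement_field(u, array(TRUE, sh))
  })
  for (v in 1:4) {
    o <- compute_oscillation(f, v)
    expect_equal(o$values, oracle_oscillation(f, v))
    expect_true(all(o$values >= 0 & o$values <= 1))
  }
})

test_that("oscillation is invariant to uniform positive rescaling", {
  cfg <- default_phenotypes()$drcb
  cfg$seed <- 12L
  s <- simulate_subject(cfg, shape = c(16L, 16L, 16L))
  f2 <- s$field
  f2$u <- f2$u * 3.7
  for (v in 1:4) {
    expect_identical(compute_oscillation(s$field, v)$values,
                     compute_oscillation(f2, v)$values)
  }
})

test_that("derive_all returns the full field set with finite values", {
  cfg <- default_phenotypes()$control
  cfg$seed <- 9L
  s <- simulate_subject(cfg, shape = c(16L, 16L, 16L))
  fs <- derive_all(s$field)
  expect_length(fs, 14L) # 1 expansion + 9 flow + 4 oscillation
  expect_true(all(vapply(fs, function(f) all(is.finite(f$values)), TRUE)))
  # reduced configuration: 3 phases, consecutive intervals only
  f3 <- make_scaling_field(c(0.03, 0.06), shape = c(8L, 8L, 8L))
  fs3 <- derive_all(f3, intervals = interval_specs(3, consecutive_only = TRUE))
  expect_length(fs3, 1L + 2L + 4L)
})
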