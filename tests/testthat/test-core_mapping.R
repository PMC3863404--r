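ref48 <- generate_reference(paper_te, w = 100, t2star_ms = 48)

test_that("a pixel equal to the reference maps to lambda = 1, xi = 0", {
  stk <- affine_stack(ref48, a = 1, b = 0)
  fit <- fit_ssm_fmm(stk, ref48)
  expect_equal(as.vector(fit$ssm), rep(1, 9), tolerance = 1e-12)
  expect_equal(as.vector(fit$fmm), rep(0, 9), tolerance = 1e-12)
  expect_identical(map_kind(fit$ssm), "SSM")
  expect_identical(map_kind(fit$fmm), "FMM")
})

test_that("affine pixels V = a*R + b are recovered exactly for several (a, b)", {
  for (ab in list(c(2, 3), c(0.5, 10), c(0.02, 120), c(3, 0))) {
    fit <- fit_ssm_fmm(affine_stack(ref48, ab[1], ab[2]), ref48)
    expect_equal(fit$ssm[2, 2], ab[1], tolerance = 1e-10)
    expect_equal(fit$fmm[2, 2], ab[2], tolerance = 1e-10)
  }
})

test_that("closed-form fit matches an independent lm() oracle on random stacks", {
  for (seed in 1:3) {
    stk <- random_stack(4, 4, seed = seed)
    fit <- fit_ssm_fmm(stk, ref48)
    orc <- oracle_lm_fit(stk, ref48)
    expect_equal(unclass(fit$ssm), orc$lambda, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(unclass(fit$fmm), orc$xi, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("fits are equivariant under intensity and reference rescaling", {
  stk <- random_stack(3, 5, seed = 9)
  fit <- fit_ssm_fmm(stk, ref48)
  # scaling the stack by c scales both lambda and xi by c
  stk2 <- echo_stack(stk$intensities * 2.5, stk$te_ms)
  fit2 <- fit_ssm_fmm(stk2, ref48)
  expect_equal(unclass(fit2$ssm), unclass(fit$ssm) * 2.5, tolerance = 1e-12)
  expect_equal(unclass(fit2$fmm), unclass(fit$fmm) * 2.5, tolerance = 1e-12)
  # scaling the reference by c divides lambda by c, leaves xi unchanged
  ref2 <- generate_reference(paper_te, w = 100 * 4, t2star_ms = 48)
  fit3 <- fit_ssm_fmm(stk, ref2)
  expect_equal(unclass(fit3$ssm), unclass(fit$ssm) / 4, tolerance = 1e-12)
  expect_equal(unclass(fit3$fmm), unclass(fit$fmm), tolerance = 1e-12)
})

test_that("SCM is the no-intercept least-squares scale", {
  stk <- affine_stack(ref48, a = 1, b = 0)
  expect_equal(as.vector(fit_scm(stk, ref48)), rep(1, 9), tolerance = 1e-12)
  zero <- echo_stack(array(0, dim = c(2, 2, 12)), paper_te)
  expect_equal(as.vector(fit_scm(zero, ref48)), rep(0, 4))
  # random pixels match the closed-form 1D least squares done independently
  stk <- random_stack(3, 3, seed = 4)
  scm <- fit_scm(stk, ref48)
  for (i in 1:3) for (j in 1:3) {
    co <- stats::coef(stats::lm(stk$intensities[i, j, ] ~ 0 + ref48$values))
    expect_equal(scm[i, j], unname(co), tolerance = 1e-8)
  }
})

test_that("degenerate and mismatched references are rejected", {
  expect_error(reference_signal(rep(5, 12)), "zero variance")
  expect_error(reference_signal(c(1, -1, 2)), "nonnegative")
  short <- reference_signal(exp(-(1:6) / 3))
  expect_error(fit_ssm_fmm(random_stack(2, 2), short), "does not match")
  expect_error(fit_scm(random_stack(2, 2), short), "does not match")
})

test_that("T2* map inverts the decay model and flags degenerate pixels", {
  # noiseless model pixels on the 12-echo schedule: exact recovery
  ph <- generate_phantom(vein_phantom_spec(shape = c(24, 24),
                                           noise_model = "none", seed = 3))
  est <- fit_t2star_map(ph$stack)
  tissue <- ph$truth$region_labels > 0
  expect_equal(est$t2star[tissue], ph$truth$t2star_map[tissue],
               tolerance = 1e-9)
  expect_equal(est$w[tissue], ph$truth$w_map[tissue], tolerance = 1e-9)
  # air pixels (all-zero decay) are invalid
  expect_true(all(is.na(est$t2star[!tissue])))
  # constant positive pixel: slope 0, infinite T2* -> invalid
  const <- echo_stack(array(7, dim = c(1, 1, 12)), paper_te)
  expect_true(is.na(fit_t2star_map(const)$t2star[1, 1]))
})

test_that("noisy T2* estimates match a log-domain lm() oracle", {
  set.seed(42)
  v <- 100 * exp(-paper_te / 48) + rnorm(12, sd = 0.5)
  stk <- echo_stack(array(v, dim = c(1, 1, 12)), paper_te)
  est <- fit_t2star_map(stk)
  co <- stats::coef(stats::lm(log(v) ~ paper_te))
  expect_equal(est$t2star[1, 1], -1 / unname(co[2]), tolerance = 1e-6)
  expect_equal(est$w[1, 1], exp(unname(co[1])), tolerance = 1e-6)
})

test_that("residual MSE is zero for exact fits and minimal at the optimum", {
  stk <- affine_stack(ref48, a = 2, b = 3)
  fit <- fit_ssm_fmm(stk, ref48)
  mse <- residual_mse(stk, ref48, fit$ssm, fit$fmm)
  expect_equal(as.vector(mse), rep(0, 9), tolerance = 1e-18)
  # perturbing the optimum can only increase MSE
  stk <- random_stack(3, 3, seed = 11)
  fit <- fit_ssm_fmm(stk, ref48)
  base <- residual_mse(stk, ref48, fit$ssm, fit$fmm)
  for (delta in c(-0.05, 0.01, 0.2)) {
    bumped <- residual_mse(stk, ref48, unclass(fit$ssm) + delta, fit$fmm)
    expect_true(all(bumped >= base))
  }
})

test_that("two-parameter fit never loses to the nested SCM fit", {
  for (seed in c(2, 7)) {
    stk <- random_stack(5, 5, seed = seed)
    fit <- fit_ssm_fmm(stk, ref48)
    scm <- fit_scm(stk, ref48)
    mse2 <- residual_mse(stk, ref48, fit$ssm, fit$fmm)
    mse1 <- residual_mse(stk, ref48, scm, NULL)
    expect_true(all(mse2 <= mse1 + 1e-12))
  }
})

test_that("echo_stack validates its invariants", {
  arr <- array(1, dim = c(2, 2, 3))
  expect_error(echo_stack(arr, c(1, 2)), "does not match")
  expect_error(echo_stack(arr, c(3, 2, 1)), "ascending")
  expect_error(echo_stack(arr, c(0, 1, 2)), "positive")
  arr[1, 1, 1] <- -1
  expect_error(echo_stack(arr, c(1, 2, 3)), "nonnegative")
})
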