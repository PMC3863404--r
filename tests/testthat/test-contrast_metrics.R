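test_that("CI of a constant image is zero and the single-window toy gives 0.5", {
  expect_equal(local_contrast_index(matrix(5, 10, 12)), 0)
  img <- matrix(1, 7, 7)
  img[4, 4] <- 3
  expect_equal(local_contrast_index(img), 0.5)
})

test_that("CI matches the naive two-loop oracle on random images", {
  for (seed in 1:3) {
    set.seed(seed)
    img <- matrix(runif(16 * 16, 0, 10), 16, 16)
    expect_equal(local_contrast_index(img), oracle_ci(img), tolerance = 1e-10)
  }
  # and with invalid pixels scattered in
  set.seed(99)
  img <- matrix(runif(20 * 20, 0, 5), 20, 20)
  img[sample(400, 12)] <- NA
  expect_equal(local_contrast_index(img), oracle_ci(img), tolerance = 1e-10)
})

test_that("CI is scale-invariant, bounded in [0, 1], and offset-sensitive", {
  set.seed(5)
  img <- matrix(rexp(15 * 15), 15, 15)
  ci <- local_contrast_index(img)
  expect_gte(ci, 0); expect_lte(ci, 1)
  for (c in c(0.01, 3, 1e6))
    expect_equal(local_contrast_index(img * c), ci, tolerance = 1e-10)
  # a positive offset grows every denominator, so CI strictly drops
  expect_lt(local_contrast_index(img + 2), ci)
})

test_that("CI rejects undersized, negative and all-skipped inputs", {
  expect_error(local_contrast_index(matrix(1, 5, 9)), "smaller than")
  expect_error(local_contrast_index(matrix(-1, 9, 9)), "nonnegative")
  expect_error(local_contrast_index(matrix(0, 9, 9)), "undefined")
  expect_error(local_contrast_index(matrix(1, 9, 9), window = 4), "odd")
})

test_that("CII is the plain ratio and rejects zero-contrast originals", {
  expect_equal(contrast_improvement_index(0.5, 0.25), 2)
  expect_equal(contrast_improvement_index(0.3, 0.3), 1)
  expect_equal(contrast_improvement_index(0, 0.2), 0)
  expect_error(contrast_improvement_index(0.5, 0), "positive")
})

test_that("map_for_contrast clamps slopes, folds intercepts, keeps NA", {
  m <- matrix(c(-1, 0.5, 2, -0.25), 2, 2)
  expect_equal(map_for_contrast(parametric_map(m, "SSM")),
               pmax(m, 0), ignore_attr = TRUE)
  expect_equal(map_for_contrast(parametric_map(m, "SCM")),
               pmax(m, 0), ignore_attr = TRUE)
  expect_equal(map_for_contrast(parametric_map(m, "FMM")),
               abs(m), ignore_attr = TRUE)
  m[1, 1] <- NA
  expect_true(is.na(map_for_contrast(parametric_map(m, "T2STAR"))[1, 1]))
})

test_that("contrast_report assembles CI and CII tables consistently", {
  ph <- generate_phantom(vein_phantom_spec(shape = c(24, 24), seed = 2))
  ref <- generate_reference(ph$stack$te_ms, 80, 48)
  fit <- fit_ssm_fmm(ph$stack, ref)
  rep <- contrast_report(ph$stack, list(SSM = fit$ssm, FMM = fit$fmm))
  expect_equal(nrow(rep$ci), 12 + 2)
  expect_equal(nrow(rep$cii), 12 * 2)
  # CII rows are exactly CI_map / CI_ori for the recorded pair
  ci <- setNames(rep$ci$ci, rep$ci$label)
  expect_equal(rep$cii$cii,
               ci[rep$cii$map] / ci[rep$cii$original],
               ignore_attr = TRUE, tolerance = 1e-14)
  expect_equal(unname(rep$mean_cii["SSM"]),
               mean(rep$cii$cii[rep$cii$map == "SSM"]))
})

test_that("the optional air mask drops background windows from CI", {
  ph <- generate_phantom(vein_phantom_spec(shape = c(32, 32), seed = 13))
  ref <- generate_reference(ph$stack$te_ms, 80, 48)
  fit <- fit_ssm_fmm(ph$stack, ref)
  plain <- contrast_report(ph$stack, list(SSM = fit$ssm))
  masked <- contrast_report(ph$stack, list(SSM = fit$ssm),
                            mask_threshold = 5)
  expect_false(isTRUE(all.equal(plain$ci$ci, masked$ci$ci)))
  # masking must reproduce CI computed on explicitly NA-ed images
  air <- matrix(rowMeans(matrix(ph$stack$intensities, 32 * 32, 12)) < 5,
                32, 32)
  img <- ph$stack$intensities[, , 1]
  img[air] <- NA
  expect_equal(masked$ci$ci[1], local_contrast_index(img))
})
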