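test_that("the power transform obeys its closed-form identities", {
  p <- seq(0.5, 4, length.out = 12)

  # lambda = 1 is affine: p + A - 1 + B
  pt1 <- power_transform(1, A = 2, B = 0.5)
  expect_equal(transform_phenotypes(p, pt1), p + 2 - 1 + 0.5)

  # continuity at the removable singularity lambda -> 0
  pt_eps <- power_transform(1e-8, A = 1, B = 0, GM = 2)
  pt_log <- power_transform(0, A = 1, B = 0, GM = 2)
  a <- transform_phenotypes(p, pt_eps)
  b <- transform_phenotypes(p, pt_log)
  expect_lt(max(abs(a - b)) / diff(range(b)), 1e-6)

  # p + A = 1 maps to B for any lambda
  for (lam in c(-2, -0.5, 0, 0.7, 3)) {
    pt <- power_transform(lam, A = 0.25, B = -1.4, GM = 1.7)
    expect_equal(transform_phenotypes(0.75, pt), -1.4)
  }

  # strictly monotone increasing on its domain
  for (lam in c(-1.5, 0, 0.4, 1, 2.5)) {
    pt <- power_transform(lam, A = 0.5, B = 0, GM = 1.3, amplitude = 2)
    expect_true(all(diff(transform_phenotypes(p, pt)) > 0))
  }

  # domain violations error
  expect_error(transform_phenotypes(-3, power_transform(0.5, A = 1, B = 0)),
               "domain")
})

test_that("linearize is the exact inverse of the transform", {
  set.seed(42)
  for (rep in 1:20) {
    lam <- runif(1, 0.2, 3) * sample(c(-1, 1), 1)
    if (rep <= 4) lam <- 0  # exercise the log branch too
    A <- runif(1, 0.5, 3)
    B <- runif(1, -2, 2)
    amp <- runif(1, 0.3, 3)
    GM <- runif(1, 0.5, 2)
    pt <- power_transform(lam, A, B, GM, amp)
    p <- runif(16, -A + 0.05, -A + 6)
    back <- linearize(transform_phenotypes(p, pt), pt)
    expect_lt(max(abs(back - p)) / diff(range(p)), 1e-9)
  }

  # out-of-range phenotypes are reported, and clipping maps them to -A
  pt <- power_transform(2, A = 1, B = 0, GM = 1)
  bad <- transform_phenotypes(0.2, pt) - 10
  expect_error(linearize(c(bad, 1, 2), pt), "position")
  expect_equal(linearize(bad, pt, clip = TRUE), -1)
})

test_that("fitting recovers curves from its own family and the identity", {
  # identity data: fitted curve is the identity pointwise
  p <- seq(0.2, 5, length.out = 32)
  ptI <- fit_power_transform(p, p)
  expect_false(ptI$curved)
  expect_lt(max(abs(ptI$fitted - p)), 1e-8)
  expect_lt(max(abs(linearize(p, ptI) - p)), 1e-8)

  # data generated by a member of the family is matched pointwise
  gen <- power_transform(0.5, A = 1, B = 0,
                         GM = exp(mean(log(p + 1))))
  pobs <- transform_phenotypes(p, gen)
  fit <- fit_power_transform(p, pobs)
  expect_true(fit$curved)
  expect_lt(max(abs(fit$fitted - pobs)) / diff(range(pobs)), 1e-6)
  # and the back-transform returns the additive inputs
  expect_lt(max(abs(linearize(pobs, fit) - p)) / diff(range(p)), 1e-5)

  expect_error(fit_power_transform(1:3, 1:3), "at least 4")
})

test_that("the fitted scale of a saturating additive map is monotone concave", {
  sim <- build_map(random_coefficients(5, order = 1, seed = 3),
                   scale_saturating(K = 2))
  tb <- padd_vs_pobs_table(sim)
  pt <- fit_power_transform(tb$p_add, tb$p_obs)
  expect_true(pt$curved)
  # monotone increasing and concave over the data range
  grid <- seq(min(tb$p_add), max(tb$p_add), length.out = 50)
  f <- transform_phenotypes(grid, pt)
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(diff(f)) < 1e-8))
  # the curve tracks the data closely relative to the phenotype range
  expect_lt(max(abs(pt$residuals)) / diff(range(tb$p_obs)), 0.1)
  expect_gt(pt$r2, 0.95)
})

test_that("a scale drawn from the power family is removed to solver tolerance", {
  # additive truth passed through an interpolable (power-family) scale
  m <- additive_map(c(1, -0.6, 0.8, 0.5))
  p_lin <- m$data$phenotype
  gen <- power_transform(0.4, A = -min(p_lin) + 1, B = 0.2)
  p_obs <- transform_phenotypes(p_lin, gen)
  design <- walsh_encode(m)
  hi <- design$orders >= 2

  # fitted against the true additive phenotypes the curve interpolates, so
  # the linearized decomposition has no epistasis beyond solver tolerance
  pt <- fit_power_transform(p_lin, p_obs)
  b_exact <- decompose(linearize(p_obs, pt), design)
  lead <- max(abs(b_exact$beta[design$orders == 1]))
  expect_lt(max(abs(b_exact$beta[hi])) / lead, 1e-6)

  # the full pipeline must estimate the additive phenotypes from the curved
  # map, which leaves a small estimation residue -- far below the spurious
  # epistasis of the raw analysis
  m_obs <- gpmap(data.frame(genotype = m$data$genotype, phenotype = p_obs))
  fit <- fit_epistasis(m_obs, scale = "power")
  expect_lt(max(abs(fit$coefficients$beta[hi])) / lead, 1e-2)
  fit0 <- fit_epistasis(m_obs, scale = "none")
  expect_gt(max(abs(fit0$coefficients$beta[hi])) / lead, 0.01)
})

test_that("scatter without curvature is left untransformed", {
  # pure high-order epistasis, no scale: no systematic curvature, so the
  # scale fit must not warp the phenotypes (lambda stays at the affine 1)
  co <- random_coefficients(5, seed = 13,
                            magnitudes = c(1e-12, 1e-12, 0.35, 0.35, 0.35))
  sim <- build_map(co, scale_none())
  tb <- padd_vs_pobs_table(sim)
  pt <- fit_power_transform(tb$p_add, tb$p_obs)
  expect_false(pt$curved)
  expect_equal(pt$lambda, 1)
  expect_gt(recovery_r2(sim, "power"), 0.99)
})

test_that("saturating scale fixed points and special values hold", {
  expect_equal(saturating_scale(0, 5), 0)
  expect_equal(saturating_scale(1, 5), 1)
  expect_equal(saturating_scale(0.5, 2), 0.75)
  expect_equal(saturating_scale(c(0.3, 0.9), 0), c(0.3, 0.9))  # identity
  expect_error(saturating_scale(-0.5, 2), "pole")
  expect_error(saturating_scale(0.5, -1))
})

test_that("scale reports serialize the fitted parameters", {
  sim <- build_map(random_coefficients(4, order = 1, seed = 5),
                   scale_saturating(2))
  tb <- padd_vs_pobs_table(sim)
  pt <- fit_power_transform(tb$p_add, tb$p_obs)
  td <- withr::local_tempdir()
  scale_report(pt, file.path(td, "scale.json"))
  got <- jsonlite::fromJSON(file.path(td, "scale.json"))
  expect_equal(got$lambda, pt$lambda)
  expect_equal(got$n_points, 16)
  expect_equal(got$pearson_r2_fit, pt$r2)
})
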