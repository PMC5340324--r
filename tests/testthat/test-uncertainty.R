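test_that("zero measurement noise collapses the bootstrap immediately", {
  m <- toy_map()  # stdev defaults to 0
  bs <- bootstrap_coefficients(m, scale = "none", seed = 1)
  expect_true(attr(bs, "converged"))
  expect_equal(attr(bs, "n_pseudoreplicates"), 100)  # two batches of 50
  expect_equal(bs$beta_sd, rep(0, 4))
  expect_equal(bs$beta, c(1.25, 0.25, 0.75, -0.25))
})

test_that("bootstraps are bit-reproducible for a fixed seed", {
  sim <- build_map(random_coefficients(3, order = 1, seed = 2),
                   scale_saturating(2), noise_sd = 0.01, n_replicates = 3,
                   seed = 3)
  b1 <- suppressWarnings(bootstrap_coefficients(sim$map, scale = "power",
                                                max_reps = 200, seed = 7))
  b2 <- suppressWarnings(bootstrap_coefficients(sim$map, scale = "power",
                                                max_reps = 200, seed = 7))
  expect_identical(b1, b2)
  b3 <- suppressWarnings(bootstrap_coefficients(sim$map, scale = "power",
                                                max_reps = 200, seed = 8))
  expect_false(identical(b1$beta, b3$beta))
})

test_that("significance arithmetic follows the z / Bonferroni rules", {
  mk <- function(beta, sd, order) {
    s <- data.frame(sites = as.character(seq_along(beta)), order = order,
                    beta = beta, beta_sd = sd)
    class(s) <- c("bootstrap_summary", "data.frame")
    s
  }
  # zero mean: z = 0, p = 1, not significant
  s <- significance(mk(c(1, 0), c(0.5, 0.3), c(0, 1)), alpha = 0.05)
  expect_equal(s$z[2], 0)
  expect_equal(s$p_raw[2], 1)
  expect_false(s$significant[2])
  # the constant term is never tested
  expect_true(is.na(s$z[1]))

  # z = 1.96 with a single tested coefficient sits at the 5% boundary
  s2 <- significance(mk(c(0, 1.96), c(1, 1), c(0, 1)))
  expect_equal(s2$p_raw[2], 0.05, tolerance = 1e-3)

  # Bonferroni multiplies by the number of tested coefficients
  beta <- c(0, rep(1, 31)); sd <- c(1, rep(1, 31))
  s3 <- significance(mk(beta, sd, c(0, rep(1, 31))))
  z <- 1
  expect_equal(s3$p_bonferroni[2], min(1, 31 * 2 * pnorm(-z)))
  # p_raw = 0.01 with m = 31 -> 0.31, not significant at 0.05
  zz <- qnorm(1 - 0.005)
  s4 <- significance(mk(c(0, zz, rep(0, 30)), rep(1, 32),
                        c(0, rep(1, 31))))
  expect_equal(s4$p_bonferroni[2], 0.31, tolerance = 1e-3)
  expect_false(s4$significant[2])

  # degenerate: sd = 0 with nonzero mean -> p_raw = 0 by convention
  s5 <- significance(mk(c(0, 0.5), c(1, 0), c(0, 1)))
  expect_equal(s5$p_raw[2], 0)
  expect_equal(s5$stars[2], "***")
})

test_that("coefficient uncertainty grows monotonically with phenotype noise", {
  base <- build_map(random_coefficients(4, order = 1, seed = 4),
                    scale_none(), noise_sd = 0.01, n_replicates = 3,
                    seed = 5)
  m_small <- base$map
  m_large <- m_small
  m_large$data$stdev <- m_small$data$stdev * 5
  b_small <- suppressWarnings(bootstrap_coefficients(
    m_small, scale = "none", max_reps = 1000, seed = 11))
  b_large <- suppressWarnings(bootstrap_coefficients(
    m_large, scale = "none", max_reps = 1000, seed = 11))
  # same seed: draws are proportional, so every coefficient sd is larger
  expect_true(all(b_large$beta_sd >= b_small$beta_sd))
  expect_gt(mean(b_large$beta_sd / pmax(b_small$beta_sd, 1e-300)), 4.5)
})

test_that("bootstrap intervals cover the generating coefficients at ~95%", {
  # n_replicates = 1 with the generating sd recorded: the pseudoreplicate
  # distribution then matches the sampling distribution of the recorded
  # means, so mean +/- 1.96 sd should cover the truth for ~95% of
  # coefficients pooled over maps
  nmap <- 100
  covered <- 0; total <- 0
  for (s in seq_len(nmap)) {
    co <- random_coefficients(4, order = 2, seed = 1000 + s)
    sim <- build_map(co, scale_none(), noise_sd = 0.05, n_replicates = 1,
                     seed = 2000 + s)
    bs <- suppressWarnings(bootstrap_coefficients(
      sim$map, scale = "none", max_reps = 1500, seed = 3000 + s))
    keep <- bs$order > 0
    lo <- bs$beta[keep] - 1.96 * bs$beta_sd[keep]
    hi <- bs$beta[keep] + 1.96 * bs$beta_sd[keep]
    truth <- co$beta[keep]
    covered <- covered + sum(truth >= lo & truth <= hi)
    total <- total + sum(keep)
  }
  expect_gt(covered / total, 0.92)
  expect_lt(covered / total, 0.98)
})

test_that("unconverged runs warn but still return results", {
  sim <- build_map(random_coefficients(3, order = 1, seed = 6),
                   scale_none(), noise_sd = 0.05, n_replicates = 3, seed = 7)
  expect_warning(
    bs <- bootstrap_coefficients(sim$map, scale = "none", max_reps = 150,
                                 seed = 8),
    "max_reps")
  expect_false(attr(bs, "converged"))
  expect_equal(attr(bs, "n_pseudoreplicates"), 150)
  expect_true(all(is.finite(bs$beta)))
})

test_that("scale-fit uncertainty can be propagated or frozen", {
  sim <- build_map(random_coefficients(3, order = 1, seed = 9),
                   scale_saturating(2), noise_sd = 0.01, n_replicates = 3,
                   seed = 10)
  b_refit <- suppressWarnings(bootstrap_coefficients(
    sim$map, scale = "power", refit_transform = TRUE, max_reps = 150,
    seed = 12))
  b_frozen <- suppressWarnings(bootstrap_coefficients(
    sim$map, scale = "power", refit_transform = FALSE, max_reps = 150,
    seed = 12))
  expect_false(identical(b_refit$beta_sd, b_frozen$beta_sd))
  expect_true(all(is.finite(b_refit$beta_sd)))
})
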