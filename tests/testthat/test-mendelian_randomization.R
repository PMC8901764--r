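test_that("wald ratio and its delta-method SE behave as expected", {
  w <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(w$estimate, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(1, 0.1, 0, 0.1)$estimate, 0)
  expect_error(wald_ratio(0, 0.1, 0.1, 0.1), "zero exposure")

  # Monte-Carlo oracle for the first-order SE (strong instrument)
  set.seed(99)
  bx <- 0.2; sx <- 0.005; by <- 0.1; sy <- 0.01
  draws <- rnorm(1e5, by, sy) / rnorm(1e5, bx, sx)
  expect_lt(abs(sd(draws) - wald_ratio(bx, sx, by, sy)$se) / sd(draws),
            0.05)
})

test_that("IVW equals the zero-intercept weighted least-squares slope", {
  # two instruments with identical ratios give that ratio
  ins <- inst_set(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.10),
                  c(0.01, 0.02))
  expect_equal(ivw(ins)$estimate, 0.5)

  set.seed(5)
  ins2 <- inst_set(runif(20, 0.05, 0.2), runif(20, 0.003, 0.01),
                   rnorm(20, 0.03, 0.02), runif(20, 0.003, 0.01))
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = ins2,
            weights = 1 / ins2$se_outcome^2)
  res <- ivw(ins2)
  expect_equal(res$estimate, unname(coef(fit)), tolerance = 1e-12)
  # fixed-effect SE from the weighted information
  expect_equal(res$se, 1 / sqrt(sum(ins2$beta_exposure^2 /
                                      ins2$se_outcome^2)))
  expect_gte(ivw(ins2, random_effects = TRUE)$se, res$se)
  expect_error(ivw(ins2[1, , drop = FALSE]), "at least 2")
})

test_that("Egger recovers an exact line and matches the WLS oracle", {
  ins <- inst_set(c(0.1, 0.2, 0.3), rep(0.01, 3),
                  0.1 + 0.5 * c(0.1, 0.2, 0.3), rep(0.01, 3))
  e <- suppressWarnings(egger(ins))  # exact fit: lm flags zero residuals
  expect_equal(e$estimate, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept, 0.1, tolerance = 1e-10)

  set.seed(6)
  ins2 <- inst_set(runif(15, 0.05, 0.25), runif(15, 0.003, 0.01),
                   rnorm(15, 0.04, 0.03), runif(15, 0.003, 0.01))
  w <- 1 / ins2$se_outcome^2
  fit <- lm(beta_outcome ~ beta_exposure, data = ins2, weights = w)
  e2 <- egger(ins2)
  expect_equal(e2$estimate, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(e2$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
  expect_error(egger(ins2[1:2, ]), "at least 3")
})

test_that("Egger slope equals IVW when the fitted intercept is zero", {
  # symmetric construction forcing the WLS intercept through the origin
  ins <- inst_set(c(0.1, 0.2, 0.3), rep(0.01, 3),
                  0.5 * c(0.1, 0.2, 0.3), rep(0.01, 3))
  # lm warns about the deliberately perfect fit; only the point
  # estimates matter here
  e <- suppressWarnings(egger(ins))
  expect_equal(e$estimate, ivw(ins)$estimate, tolerance = 1e-10)
  expect_equal(e$intercept, 0, tolerance = 1e-12)
})

test_that("Egger bootstrap is seed-reproducible with a percentile CI", {
  set.seed(7)
  ins <- inst_set(runif(12, 0.05, 0.25), runif(12, 0.003, 0.01),
                  rnorm(12, 0.04, 0.03), runif(12, 0.003, 0.01))
  b1 <- egger(ins, bootstrap_reps = 200, seed = 42)
  b2 <- egger(ins, bootstrap_reps = 200, seed = 42)
  expect_identical(b1, b2)
  expect_equal(b1$method, "egger_bootstrap")
  expect_lte(b1$ci_low, b1$ci_high)
})

test_that("weighted median interpolates the 50% weight point", {
  # negligible exposure SE: ratio variances (hence weights) are equal
  ins <- inst_set(rep(1, 3), rep(1e-12, 3), c(0.4, 0.5, 0.9), rep(0.1, 3))
  wm <- weighted_median(ins, boot_reps = 50, seed = 1)
  expect_equal(wm$estimate, 0.5, tolerance = 1e-10)

  # a dominant weight pulls the estimate to its ratio
  ins2 <- inst_set(rep(1, 3), rep(0.01, 3), c(0.2, 0.9, 1.0),
                   c(0.01, 0.6, 0.6))
  wm2 <- weighted_median(ins2, boot_reps = 50, seed = 1)
  expect_equal(wm2$estimate, 0.2, tolerance = 0.05)
  expect_error(weighted_median(ins2[1:2, ]), "at least 3")
})

test_that("weighted median resists 50% invalid instruments", {
  # oracle: generator truth tau = 0.2 with half the SNPs pleiotropic
  set.seed(31)
  n_seeds <- 60
  wm_err <- numeric(n_seeds)
  ivw_err <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    L <- 20
    bx <- abs(rnorm(L, 0.15, 0.03))
    sx <- rep(0.005, L)
    sy <- rep(0.005, L)
    alpha <- c(rep(0, L / 2), abs(rnorm(L / 2, 0.02, 0.005)))
    by <- 0.2 * bx + alpha + rnorm(L, 0, sy)
    ins <- inst_set(bx, sx, by, sy)
    wm_err[s] <- weighted_median(ins, boot_reps = 20, seed = 1)$estimate -
      0.2
    ivw_err[s] <- ivw(ins)$estimate - 0.2
  }
  expect_lt(mean(abs(wm_err)), mean(abs(ivw_err)))
})

test_that("weighted mode finds the dominant ratio cluster", {
  ins <- inst_set(rep(1, 5), rep(0.01, 5), rep(0.3, 5), rep(0.05, 5))
  expect_equal(weighted_mode(ins, boot_reps = 20, seed = 1)$estimate, 0.3)

  # 7 ratios at 0.2, 3 outliers at 1.0, equal weights
  ins2 <- inst_set(rep(1, 10), rep(0.01, 10),
                   c(rep(0.2, 7), rep(1.0, 3)), rep(0.05, 10))
  est <- weighted_mode(ins2, boot_reps = 20, seed = 1)$estimate
  # oracle: grid maximization of the weighted kernel density
  r <- c(rep(0.2, 7), rep(1.0, 3))
  h <- 0.9 * sd(r) * 10^(-1 / 5)  # mad is 0 here, sd fallback
  grid <- seq(-0.5, 1.5, length.out = 4001)
  dens <- sapply(grid, function(x) sum(dnorm((x - r) / h)))
  expect_lt(abs(est - grid[which.max(dens)]), 0.02)
  expect_lt(abs(est - 0.2), 0.1)

  # NOME differs only through weights; tiny exposure SE converges
  ins3 <- inst_set(runif(6, 0.1, 0.3), rep(1e-10, 6),
                   rnorm(6, 0.05, 0.02), runif(6, 0.01, 0.02))
  m1 <- weighted_mode(ins3, nome = FALSE, boot_reps = 20, seed = 1)
  m2 <- weighted_mode(ins3, nome = TRUE, boot_reps = 20, seed = 1)
  expect_equal(m1$estimate, m2$estimate, tolerance = 1e-6)
})

test_that("I2-GX matches its formula and limiting regimes", {
  ins <- inst_set(rep(0.2, 5), rep(0.01, 5), rnorm(5), rep(0.01, 5))
  expect_equal(i2_gx(ins), 0)  # zero dispersion

  set.seed(8)
  ins2 <- inst_set(runif(10, 0.05, 0.3), runif(10, 0.001, 0.01),
                   rnorm(10), rep(0.01, 10))
  bx <- abs(ins2$beta_exposure)
  w <- 1 / ins2$se_exposure^2
  q <- sum(w * (bx - sum(w * bx) / sum(w))^2)
  expect_equal(i2_gx(ins2), max(0, (q - 9) / q))

  # vanishing exposure SE with dispersed bx drives I2-GX to 1
  ins3 <- ins2
  ins3$se_exposure <- rep(1e-8, 10)
  expect_gt(i2_gx(ins3), 0.999999)
})

test_that("estimators are invariant to re-orienting a single SNP", {
  set.seed(9)
  ins <- inst_set(runif(8, 0.05, 0.25), runif(8, 0.003, 0.01),
                  rnorm(8, 0.04, 0.03), runif(8, 0.003, 0.01))
  flipped <- ins
  flipped$beta_exposure[3] <- -flipped$beta_exposure[3]
  flipped$beta_outcome[3] <- -flipped$beta_outcome[3]
  expect_equal(ivw(flipped)$estimate, ivw(ins)$estimate)
  expect_equal(egger(flipped)$estimate, egger(ins)$estimate)
  expect_equal(weighted_median(flipped, boot_reps = 20, seed = 1)$estimate,
               weighted_median(ins, boot_reps = 20, seed = 1)$estimate)
  expect_equal(i2_gx(flipped), i2_gx(ins))
})

test_that("instrument building aligns, infers SEs and filters direction", {
  co <- simulate_cohort(simulation_config(n_snps = 40, tau = 0.2,
                                          seed = 13))
  exp_nose <- co$exposure
  exp_nose$se <- NA_real_
  out_nose <- co$outcome
  out_nose$se <- NA_real_
  ins <- build_instruments(exp_nose, out_nose)
  expect_true(all(ins$beta_exposure > 0))
  expect_true(all(ins$se_exposure > 0))
  # inferred SEs reproduce the analytic generator SEs
  truth_se <- co$truth$se_exposure[match(ins$snp_id, co$truth$snp_id)]
  expect_equal(ins$se_exposure, truth_se, tolerance = 1e-6)

  # direction filtering drops discordant pairs
  ins_dir <- build_instruments(co$exposure, co$outcome,
                               direction_rule = "require_concordant")
  expect_true(all(ins_dir$beta_outcome > 0))

  # palindromic SNP with MAF above 0.3 is excluded
  a <- rbind(rec("rs_pal", ref = "A", alt = "T", freq = 0.45,
                 beta = 0.1, se = 0.01),
             rec("rs_ok", ref = "A", alt = "G", freq = 0.2,
                 beta = 0.1, se = 0.01))
  b <- a
  b$beta <- 0.05
  ins_pal <- build_instruments(a, b)
  expect_false("rs_pal" %in% ins_pal$snp_id)
  expect_true("rs_ok" %in% ins_pal$snp_id)
})

test_that("the suite dispatches by instrument count", {
  co <- simulate_cohort(simulation_config(n_snps = 10, tau = 0.2,
                                          seed = 14))
  ins <- build_instruments(co$exposure, co$outcome)
  res <- mr_suite(ins, seed = 1, boot_reps = 50)
  expect_setequal(res$method,
                  c("ivw", "egger", "egger_bootstrap", "weighted_median",
                    "weighted_mode", "weighted_mode_nome"))
  expect_true(all(res$ci_low <= res$estimate & res$estimate <= res$ci_high))
  one <- mr_suite(ins[1, , drop = FALSE])
  expect_equal(one$method, "wald")
})
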