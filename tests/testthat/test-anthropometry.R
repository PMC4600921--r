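test_that("age sampling honours defaults, exact values and intervals", {
  set.seed(11)
  a <- sample_age(1e5)
  expect_true(all(a >= 16 & a <= 65))
  expect_equal(mean(a), 40.5, tolerance = 0.15 / 40.5)

  expect_equal(sample_age(5, constraints(age = 49)), rep(49, 5))
  b <- sample_age(1e4, constraints(age = c(50, 55)))
  expect_true(all(b >= 50 & b <= 55))
  expect_error(constraints(age = c(50, 70)), "within")
  expect_error(constraints(age = c(55, 50)), "lo < hi")
})

test_that("location functions evaluate the printed polynomial forms", {
  expect_equal(height_location(30, uk_male_white), 177.8)
  expect_equal(logbm_location(16, us_female_hisp), 4.05624,
               tolerance = 1e-6)
  ## polynomial identity at A = 0 (outside the supported range; location
  ## function only)
  expect_equal(height_location(0, uk_male_white),
               uk_male_white$anthro$height_alpha)

  ## male logistic and female cubic cardiac-output forms
  expect_equal(cardiac_output_location(49, 163.06, us_female_white),
               1.854 + 0.0248 * 163.06 + 0.0127 * 49 -
                 0.000956 * 49^2 + 0.00000739 * 49^3)
  expect_equal(cardiac_output_location(30, 176, uk_male_white),
               2.755 + 0.025 * 176 - 0.030 * 30 -
                 0.707 / (1 + exp(0.626 * 12)))
  expect_equal(cardiac_output_location(30, 176, uk_male_white), 6.255,
               tolerance = 1e-3)
})

test_that("the standardised-width rule decides the sampling order", {
  ## known intervals: height in [171, 175] cm, mass in [75, 80] kg
  con <- constraints(height = c(171, 175), body_mass = c(75, 80))
  w_h <- (175 - 171) / 6.9
  w_m <- log(80 / 75) / 0.17
  expect_lt(w_m, w_h)   # 0.380 < 0.580, so log body mass goes first
  expect_equal(physpop:::.anthro_order(con, uk_male_white), "mass_first")
  ## unconstrained: both widths are 6; ties resolve to height
  expect_equal(physpop:::.anthro_order(constraints(), uk_male_white),
               "height_first")
  ## narrow height interval flips the order
  expect_equal(physpop:::.anthro_order(constraints(height = c(175, 177)),
                                       uk_male_white), "height_first")
})

test_that("joint height/log-mass draws recover the generating moments", {
  set.seed(21)
  n <- 1e5
  hm <- sample_height_mass(n, age = 40, params = uk_male_white,
                           bmi_limits = NULL)
  a <- uk_male_white$anthro
  ## marginal SDs against the closed-form +-3 sigma truncated oracle
  expect_equal(sd(hm$height), trunc_sd_oracle(a$height_sigma, 3),
               tolerance = 0.01)
  expect_equal(sd(log(hm$body_mass)), trunc_sd_oracle(a$logbm_sigma, 3),
               tolerance = 0.01)
  expect_equal(mean(hm$height), height_location(40, uk_male_white),
               tolerance = 1e-3)
  expect_equal(cor(hm$height, log(hm$body_mass)), a$rho_height_logbm,
               tolerance = 0.01 / a$rho_height_logbm)
})

test_that("exact and interval constraints are honoured", {
  set.seed(22)
  con <- constraints(height = c(171, 175), body_mass = c(75, 80))
  hm <- sample_height_mass(5000, age = 52.5, constr = con,
                           params = uk_male_white, bmi_limits = NULL)
  expect_true(all(hm$height >= 171 & hm$height <= 175))
  expect_true(all(hm$body_mass >= 75 & hm$body_mass <= 80))

  hm2 <- sample_height_mass(100, age = 30, constr = constraints(height = 180),
                            params = uk_male_white, bmi_limits = NULL)
  expect_equal(hm2$height, rep(180, 100))
  expect_gt(sd(hm2$body_mass), 0)

  ## zero-probability interval far outside the marginal
  expect_error(
    sample_height_mass(10, age = 30,
                       constr = constraints(height = c(300, 301)),
                       params = uk_male_white, bmi_limits = NULL),
    "probability mass")
})

test_that("the joint distribution does not depend on the sampling order", {
  ## fixed age so locations are common; a mass interval fractionally
  ## narrower than the default +-3 sigma band flips the order while leaving
  ## the truncation essentially unchanged
  a <- uk_male_white$anthro
  mu_l <- logbm_location(40, uk_male_white)
  con_flip <- constraints(body_mass = exp(mu_l + c(-1, 1) * 2.995 *
                                            a$logbm_sigma))
  expect_equal(physpop:::.anthro_order(con_flip, uk_male_white), "mass_first")
  for (seed in c(31, 32)) {
    set.seed(seed)
    h1 <- sample_height_mass(1e4, 40, params = uk_male_white,
                             bmi_limits = NULL)
    h2 <- sample_height_mass(1e4, 40, constr = con_flip,
                             params = uk_male_white, bmi_limits = NULL)
    expect_gt(ks.test(h1$height, h2$height)$p.value, 0.01)
    expect_gt(ks.test(log(h1$body_mass), log(h2$body_mass))$p.value, 0.01)
  }
})

test_that("interval conditioning converges to the exact conditional", {
  ## E[log BM | H = h] = mu_L + (sigma_L / sigma_H) rho (h - mu_H)
  a <- uk_male_white$anthro
  h <- 180
  exact <- logbm_location(40, uk_male_white) +
    (a$logbm_sigma / a$height_sigma) * a$rho_height_logbm *
      (h - height_location(40, uk_male_white))
  set.seed(33)
  hm <- sample_height_mass(2e4, 40,
                           constr = constraints(height = c(h - 0.01, h + 0.01)),
                           params = uk_male_white, bmi_limits = NULL)
  se <- sd(log(hm$body_mass)) / sqrt(length(hm$body_mass))
  expect_equal(mean(log(hm$body_mass)), exact, tolerance = 4 * se / exact)
})

test_that("the BMI filter leaves only individuals inside the window", {
  set.seed(34)
  hm <- sample_height_mass(5000, sample_age(5000), params = uk_male_white,
                           bmi_limits = c(17.5, 32.5))
  bmi <- hm$body_mass / (hm$height / 100)^2
  expect_true(all(bmi >= 17.5 & bmi <= 32.5))
  ## jointly infeasible constraints error out rather than loop forever
  expect_error(
    sample_height_mass(5, 30,
                       constr = constraints(height = 200, body_mass = 50),
                       params = uk_male_white, bmi_limits = c(17.5, 32.5),
                       max_tries = 50),
    "incompatible")
})

test_that("cardiac output sampling is a truncated normal around the form", {
  set.seed(35)
  co <- sample_cardiac_output(1e5, 30, 176, uk_male_white)
  expect_equal(sd(co), uk_male_white$co$sigma, tolerance = 0.02)
  expect_equal(mean(co), cardiac_output_location(30, 176, uk_male_white),
               tolerance = 1e-3)
  expect_true(all(co > 0))
  p0 <- uk_male_white
  p0$co$sigma <- 0
  expect_equal(sample_cardiac_output(3, 30, 176, p0),
               rep(cardiac_output_location(30, 176, p0), 3))
})
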