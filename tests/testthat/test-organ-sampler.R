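test_that("organ mass locations evaluate the printed forms", {
  ind <- list(age = 30, height = 176, body_mass = 76, bmi = 24.5)
  expect_equal(organ_mass_location(uk_male_white$organs$liver, ind), 2.449)
  ## spleen is lognormal: the location is on the log scale
  expect_equal(organ_mass_location(uk_male_white$organs$spleen, ind),
               -2.272 + 0.0047 * 176)
  expect_equal(exp(organ_mass_location(uk_male_white$organs$spleen, ind)),
               0.236, tolerance = 1e-3)
  ## sexual organs: constant form
  uk_female_white <- load_parameters("UK", "female", "White")
  expect_equal(organ_mass_location(uk_female_white$organs$sexual_organs, ind),
               0.012)
  ## adipose form with age, height and BMI terms
  ind2 <- list(age = 30, height = 177, body_mass = 25 * 1.77^2, bmi = 25)
  expect_equal(organ_mass_location(uk_male_white$organs$adipose, ind2),
               -3.51 - 0.0115 * 30 + 0.00016 * 900 + 0.023 * 177 +
                 0.105 * 25)
  expect_equal(organ_mass_location(uk_male_white$organs$adipose, ind2),
               2.985, tolerance = 1e-3)
  ## male bone: logistic ramp on the h2 term
  bone <- uk_male_white$organs$bone
  expect_equal(organ_mass_location(bone, ind),
               3.187 + 0.044 * 176 +
                 0.0098 * 176 / (1 + exp(-0.379 * 12)))
})

test_that("organ masses respect the central-90% truncation bands", {
  set.seed(41)
  n <- 2e4
  ind <- data.frame(age = rep(30, n), height = 176, body_mass = 76,
                    bmi = 24.5)
  m <- sample_organ_masses(ind, uk_male_white)
  z <- qnorm(0.95)
  liv <- uk_male_white$organs$liver
  loc <- 2.449
  expect_true(all(m[, "liver"] >= loc - z * liv$mass_sigma))
  expect_true(all(m[, "liver"] <= loc + z * liv$mass_sigma))
  ## symmetric truncation leaves the mean at the location
  expect_equal(mean(m[, "liver"]), loc, tolerance = 0.005)
  expect_equal(sd(m[, "liver"]), trunc_sd_oracle(liv$mass_sigma, z),
               tolerance = 0.02)
  ## lognormal organ: band on the log scale
  spl <- uk_male_white$organs$spleen
  lloc <- organ_mass_location(spl, ind[1, ])
  expect_true(all(log(m[, "spleen"]) >= lloc - z * spl$mass_sigma - 1e-12))
  expect_true(all(log(m[, "spleen"]) <= lloc + z * spl$mass_sigma + 1e-12))
  expect_true(all(m > 0))
})

test_that("adipose and muscle logs carry the table correlation", {
  set.seed(42)
  n <- 5e4
  ind <- data.frame(age = rep(40, n), height = 176,
                    body_mass = 25 * 1.76^2, bmi = 25)
  m <- sample_organ_masses(ind, uk_male_white)
  got <- cor(log(m[, "adipose"]), log(m[, "muscle"]))
  ## the joint rectangle truncation shrinks |rho| slightly; the quadrature
  ## oracle gives the post-truncation value
  oracle <- bivar_trunc_cor_oracle(-0.90, qnorm(0.95))
  expect_equal(got, oracle, tolerance = abs(0.02 / oracle))
  expect_lt(abs(oracle), 0.90)   # sanity on the oracle itself
})

test_that("flow fractions are truncated at two standard deviations", {
  set.seed(43)
  fr <- sample_flow_fractions(2e4, uk_male_white)
  for (o in organ_names()) {
    mod <- uk_male_white$organs[[o]]
    expect_true(all(fr[, o] >= mod$flow_c1 - 2 * mod$flow_sigma - 1e-12),
                info = o)
    expect_true(all(fr[, o] <= mod$flow_c1 + 2 * mod$flow_sigma + 1e-12),
                info = o)
  }
  expect_true(all(fr > 0))
  ## female kidney: the printed band 0.204 +- 0.092
  set.seed(44)
  frf <- sample_flow_fractions(2e4, us_female_hisp)
  expect_true(all(frf[, "kidneys"] >= 0.204 - 0.092 - 1e-12))
  expect_true(all(frf[, "kidneys"] <= 0.204 + 0.092 + 1e-12))
  ## female reference fractions sum near 1.023
  c1f <- sum(sapply(us_female_hisp$organs, function(m) m$flow_c1))
  expect_equal(c1f, 1.0232, tolerance = 1e-6)
})

test_that("flow rebalancing scales to cardiac output exactly", {
  fr <- matrix(c(0.5, 0.5, 0.25, 0.75), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))
  fl <- rebalance_flows(fr, c(6, 8))
  expect_equal(unname(rowSums(fl)), c(6, 8))
  expect_equal(fl[1, ], c(a = 3, b = 3))
  expect_equal(fl[2, ], c(a = 2, b = 6))
  expect_error(rebalance_flows(matrix(0, 1, 2), 5), "positive sum")

  set.seed(45)
  fr2 <- sample_flow_fractions(1000, uk_male_white)
  fl2 <- rebalance_flows(fr2, rep(6.2, 1000))
  expect_equal(unname(rowSums(fl2)), rep(6.2, 1000), tolerance = 1e-12)
})

test_that("mass rebalancing scales adipose and muscle by a common factor", {
  raw <- matrix(1, 1, 15, dimnames = list(NULL, organ_names()))
  raw[1, setdiff(organ_names(), c("adipose", "muscle"))] <- 20 / 13
  raw[1, "adipose"] <- 15
  raw[1, "muscle"] <- 25
  bal <- rebalance_masses(raw, 70)
  expect_equal(unname(bal$lambda), 1.25)
  expect_equal(unname(bal$masses[1, "adipose"]), 18.75)
  expect_equal(unname(bal$masses[1, "muscle"]), 31.25)
  expect_equal(unname(rowSums(bal$masses)), 70)
  ## ratio preserved
  expect_equal(unname(bal$masses[1, "adipose"] / bal$masses[1, "muscle"]),
               15 / 25)
})

test_that("zero-variance pipeline equals the closed-form oracle", {
  p0 <- zero_sigma_params(uk_male_white)
  ind <- simulate_population(p0, n = 1, constr = constraints(age = 40),
                             bmi_limits = NULL, seed = 46)
  oracle <- deterministic_oracle(p0, 40)
  expect_equal(ind$height_cm, oracle$height)
  expect_equal(ind$body_mass_kg, oracle$body_mass)
  expect_equal(ind$cardiac_output_l_min, oracle$cardiac_output)
  for (o in organ_names()) {
    expect_equal(ind[[paste0("mass_", o, "_kg")]],
                 unname(oracle$masses[o]), info = o)
    expect_equal(ind[[paste0("flow_", o, "_l_min")]],
                 unname(oracle$flows[o]), info = o)
  }
})

test_that("simulated populations balance mass and flow for every individual", {
  pop <- simulate_population(us_female_hisp, n = 2000, seed = 47)
  mass_cols <- grep("^mass_.*_kg$", names(pop), value = TRUE)
  flow_cols <- grep("^flow_.*_l_min$", names(pop), value = TRUE)
  expect_equal(unname(rowSums(pop[mass_cols])), pop$body_mass_kg,
               tolerance = 1e-9)
  expect_equal(unname(rowSums(pop[flow_cols])), pop$cardiac_output_l_min,
               tolerance = 1e-9)
  expect_true(all(as.matrix(pop[mass_cols]) > 0))
  expect_true(all(as.matrix(pop[flow_cols]) > 0))
  expect_equal(pop$bmi, pop$body_mass_kg / (pop$height_cm / 100)^2)
  expect_true(all(pop$bmi >= 17.5 & pop$bmi <= 32.5))
  expect_true(all(pop$age >= 16 & pop$age <= 65))
})

test_that("seeded simulation is bit-reproducible", {
  a <- simulate_population(uk_male_white, n = 200, seed = 48)
  b <- simulate_population(uk_male_white, n = 200, seed = 48)
  expect_identical(a, b)
  c <- simulate_population(uk_male_white, n = 200, seed = 49)
  expect_false(identical(a$body_mass_kg, c$body_mass_kg))
})

test_that("infeasible body mass triggers rejection then error", {
  ## a 40 kg body cannot hold UK-male organ masses: lambda <= 0 every draw
  expect_error(
    simulate_population(uk_male_white, n = 5,
                        constr = constraints(age = 40, height = 190,
                                             body_mass = 25),
                        bmi_limits = NULL, seed = 50),
    "mass balance|infeasible")
})
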