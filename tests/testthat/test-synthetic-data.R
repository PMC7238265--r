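test_that("the default design reproduces the trial sampling layout", {
  design <- trial_design()
  expect_equal(design$n_subjects, 53)
  # 14 scheduled samples on each of Days 1 and 7 plus 3 troughs
  expect_length(design$pk_times, 2 * 14 + 3)
  d <- generate_trial(trial_design(n_subjects = 4), default_parameters(),
                      default_population(), seed = 2)
  one <- d[d$ID == 1 & d$EVID == 0, ]
  expect_equal(sum(one$DVID == "conc_BUD"), 31)
  expect_equal(sum(one$DVID == "conc_FMT"), 31)
  expect_equal(sum(one$DVID == "FEV1"), 6)   # includes week -2 run-in
  expect_equal(sum(one$DVID == "ECP"), 5)
  expect_equal(sum(one$DVID == "ACT"), 5)
  expect_equal(min(one$TIME), -2 * 168)
  # only concentrations are ever LLOQ-censored
  expect_true(all(d$BLQ[d$DVID %in% c("ECP", "FEV1", "ACT")] == 0))
})

test_that("zero variability collapses the cohort onto the typical subject", {
  d <- generate_trial(trial_design(n_subjects = 3), default_parameters(),
                      zero_population(), seed = 5)
  obs <- d[d$EVID == 0, ]
  for (ep in c("conc_BUD", "ACT", "FEV1")) {
    m <- matrix(obs$DV[obs$DVID == ep], ncol = 3)
    expect_equal(m[, 1], m[, 2], label = ep)
    expect_equal(m[, 1], m[, 3], label = ep)
  }
  # ACT at week 0 equals the typical baseline exactly
  expect_equal(obs$DV[obs$DVID == "ACT" & obs$TIME == 0], rep(19.7, 3))
})

test_that("generation is deterministic and BLQ-heavy for formoterol", {
  a <- generate_trial(trial_design(n_subjects = 10), default_parameters(),
                      default_population(), seed = 77)
  b <- generate_trial(trial_design(n_subjects = 10), default_parameters(),
                      default_population(), seed = 77)
  expect_identical(a, b)
  expect_gt(mean(a$BLQ[a$DVID == "conc_FMT"]), 0.3)
})

test_that("generated baseline ACT draws are centred on the typical value", {
  ind <- sample_population(default_parameters(), default_population(),
                          n = 10000, seed = 8)
  # SE of the median of a log-normal sample, via the asymptotic formula
  se_med <- 1.2533 * 0.149 * 19.7 / sqrt(10000)
  expect_lt(abs(median(ind$co.BASE_ACT) - 19.7), 3 * se_med)
})

test_that("generated datasets pass the reader's schema silently", {
  d <- generate_trial(trial_design(n_subjects = 3), default_parameters(),
                      default_population(), seed = 9)
  expect_no_warning(validate_dataset(d))
  path <- tempfile(fileext = ".csv")
  expect_no_warning(write_dataset(d, path))
  expect_no_warning(read_dataset(path))
})

test_that("round-tripping a generated dataset preserves it", {
  d <- generate_trial(trial_design(n_subjects = 3), default_parameters(),
                      default_population(), seed = 10)
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- read_dataset(path)
  expect_equal(d2$DV, d$DV, tolerance = 1e-8)
  expect_equal(d2$TIME, d$TIME)
  expect_identical(d2$DVID, d$DVID)
  expect_identical(d2$ID, d$ID)
})

test_that("covariates are independent of parameters unless an effect is planted", {
  p <- default_parameters()
  pop <- default_population()
  demo <- sample_demographics(500, seed = 11)
  ind <- sample_population(p, pop, 500, covariates = demo, seed = 12)
  # no planted effect: log CL uncorrelated with log weight
  expect_gt(cor.test(log(ind$fmt.CL), log(ind$weight))$p.value, 0.001)
  # strong planted weight-power effect on clearance
  pop$covariates <- covariate_model(list(list(
    parameter = "fmt.CL", covariate = "weight", relation = "power",
    coefficient = 3.5, ref = 70)))
  demo2 <- sample_demographics(200, seed = 13)
  ind2 <- sample_population(p, pop, 200, covariates = demo2, seed = 14)
  expect_gt(cor(log(ind2$fmt.CL), log(ind2$weight)), 0.5)
})

test_that("covariate-effect datasets are deterministic and single-endpoint", {
  d0 <- generate_covariate_data("fmt.CL", "weight", 0, n = 8, seed = 3)
  expect_equal(length(unique(d0$ID)), 8)
  expect_equal(unique(d0$DVID[d0$EVID == 0]), "conc_FMT")
  expect_no_warning(validate_dataset(d0))
  expect_identical(d0, generate_covariate_data("fmt.CL", "weight", 0,
                                               n = 8, seed = 3))
  # planting an effect changes the observations
  d1 <- generate_covariate_data("fmt.CL", "weight", 1.5, n = 8, seed = 3)
  expect_false(identical(d0$DV, d1$DV))
})

test_that("demographics match the study population", {
  demo <- sample_demographics(5000, seed = 15)
  expect_true(all(demo$age >= 20 & demo$age <= 70))
  expect_true(all(demo$duration > 0))
  expect_equal(mean(demo$sex == "M"), 33 / 53, tolerance = 0.05)
  expect_equal(unname(table(demo$genotype)["AG"] / 5000), 25 / 53,
               tolerance = 0.05)
  expect_equal(mean(demo$weight), 70, tolerance = 0.02)
})
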