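test_that("noise-free simulation reproduces the closed-form curves", {
  grid <- c(10, 20, 30, 45, 60, 120)
  spec <- dissolution_sim_spec("first_order", k = 0.03)
  p <- simulate_dissolution(spec)
  expect_equal(p$dissolved, 100 * (1 - exp(-0.03 * grid)),
               tolerance = 1e-12)
  z <- simulate_dissolution(dissolution_sim_spec("zero_order", k = 0.5))
  expect_equal(z$dissolved, 0.5 * grid)
  h <- simulate_dissolution(dissolution_sim_spec("higuchi", k = 9))
  expect_equal(h$dissolved, pmin(9 * sqrt(grid), 100))
})

test_that("simulation is bit-identical under the same seed", {
  spec <- dissolution_sim_spec("higuchi", k = 8, noise_sd = 2,
                               n_vessels = 6, seed = 123)
  expect_identical(simulate_dissolution(spec), simulate_dissolution(spec))
  spec2 <- dissolution_sim_spec("higuchi", k = 8, noise_sd = 2,
                                n_vessels = 6, seed = 124)
  expect_false(identical(simulate_dissolution(spec)$dissolved,
                         simulate_dissolution(spec2)$dissolved))

  pkspec <- pk_sim_spec(seed = 77)
  a <- simulate_plasma(pkspec)
  b <- simulate_plasma(pkspec)
  expect_identical(a, b)
})

test_that("seeded simulation does not disturb the caller's random stream", {
  set.seed(2024)
  before <- runif(1)
  set.seed(2024)
  invisible(simulate_dissolution(
    dissolution_sim_spec("zero_order", 0.5, noise_sd = 1, seed = 9)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("zero-noise simulate-then-select round trip recovers each model", {
  for (m in c("zero_order", "first_order", "higuchi", "hixson_crowell")) {
    k <- switch(m, zero_order = 0.8, first_order = 0.03, higuchi = 8,
                hixson_crowell = 0.03)
    p <- simulate_dissolution(dissolution_sim_spec(m, k))
    sel <- suppressWarnings(select_model(p))
    expect_identical(sel$best, m)
    expect_equal(sel$table$r_squared[1], 1, tolerance = 1e-9)
    fit <- suppressWarnings(fit_kinetic_model(p, m))
    expect_equal(fit$rate_constant, k, tolerance = 1e-9)
  }
})

test_that("simulated vessels respect profile invariants for random specs", {
  set.seed(31)
  for (i in 1:40) {
    m <- sample(c("zero_order", "first_order", "higuchi",
                  "hixson_crowell"), 1)
    spec <- dissolution_sim_spec(m, k = runif(1, 0.01, 5),
                                 noise_sd = runif(1, 0, 5),
                                 n_vessels = sample(1:6, 1),
                                 seed = sample.int(1e6, 1))
    p <- simulate_dissolution(spec)
    expect_s3_class(p, "dissolution_profile")
    expect_true(all(p$dissolved >= 0 & p$dissolved <= 100))
    expect_true(all(p$replicates >= 0 & p$replicates <= 100))
    expect_equal(rowMeans(p$replicates), p$dissolved, tolerance = 1e-12)
  }
})

test_that("fitted k is unbiased at 2% vessel noise over 200 seeds", {
  # study conditions: 6-vessel runs, fits on the vessel-mean profile
  grid_fits <- function(model, k) {
    vapply(1:200, function(s) {
      p <- simulate_dissolution(dissolution_sim_spec(
        model, k, noise_sd = 2, n_vessels = 6, seed = s))
      suppressWarnings(fit_kinetic_model(p, model))$rate_constant
    }, numeric(1))
  }
  for (case in list(list("zero_order", 0.8), list("higuchi", 8),
                    list("first_order", 0.02),
                    list("hixson_crowell", 0.02))) {
    ks <- grid_fits(case[[1]], case[[2]])
    se <- sd(ks) / sqrt(length(ks))
    expect_lt(abs(mean(ks) - case[[2]]), 2 * se)
    # individual recoveries stay within 10% of the generating constant
    expect_gt(mean(abs(ks - case[[2]]) / case[[2]] < 0.10), 0.95)
  }
})

test_that("Bateman curves have the analytic peak and scale linearly", {
  ka <- 1.5; ke <- 0.2
  tmax_analytic <- log(ka / ke) / (ka - ke)
  tt <- seq(0.01, 24, by = 0.01)
  p <- simulate_plasma(pk_sim_spec(ka = ka, ke = ke, cv = 0,
                                   times = tt, n_subjects = 1))[[1]]
  expect_equal(nca(p)$tmax, tmax_analytic, tolerance = 0.01)

  p1 <- simulate_plasma(pk_sim_spec(scale = 1, cv = 0, seed = 3))[[1]]
  p2 <- simulate_plasma(pk_sim_spec(scale = 2, cv = 0, seed = 3))[[1]]
  expect_equal(nca(p2)$auc_0_t, 2 * nca(p1)$auc_0_t, tolerance = 1e-12)

  expect_error(pk_sim_spec(ka = 0.2, ke = 0.2), "differ")
  expect_error(bateman(1, 0.2, 0.2), "degenerate")
})

test_that("generated plasma cohorts satisfy container invariants", {
  set.seed(7)
  for (i in 1:20) {
    spec <- pk_sim_spec(ka = runif(1, 0.5, 3), ke = runif(1, 0.05, 0.45),
                        scale = runif(1, 0.5, 5), cv = runif(1, 0, 0.3),
                        n_subjects = sample(1:6, 1),
                        seed = sample.int(1e6, 1))
    cohort <- simulate_plasma(spec)
    expect_length(cohort, spec$n_subjects)
    for (p in cohort) {
      expect_s3_class(p, "plasma_profile")
      expect_true(all(p$concentrations >= 0))
      expect_false(is.unsorted(p$times, strictly = TRUE))
    }
  }
})

test_that("the study bundle has the expected arms and passes invariants", {
  st <- make_study(seed = 42)
  expect_named(st$dissolution, c("slow", "moderate", "fast_a", "fast_b"))
  expect_named(st$plasma, c("reference", "test_low", "test_mid",
                            "test_high"))
  expect_true(all(vapply(st$plasma, length, integer(1)) == 5))
  # slow arm stays incomplete at 120 min; fast arms finish early
  expect_lt(st$dissolution$slow$dissolved[6], 60)
  expect_gt(st$dissolution$fast_b$dissolved[1], 85)
  expect_identical(make_study(seed = 42)$dissolution$slow$dissolved,
                   st$dissolution$slow$dissolved)

  # single-subject cohorts exercise the SD-undefined path
  tiny <- make_study(seed = 1, n_subjects = 1)
  g <- group_summary(tiny$plasma$reference)
  expect_true(all(is.na(g$summary$sd)))
})

test_that("configured exposure ratios propagate through the pipeline", {
  st <- make_study(seed = 11, auc_ratios = c(ref = 1, double = 2), cv = 0)
  g <- lapply(st$plasma, group_summary)
  f <- relative_bioavailability(g$double, g$ref)$f_percent
  expect_equal(f, 200, tolerance = 1e-9) # exact with no between-subject CV
})
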