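grid6 <- c(10, 20, 30, 45, 60, 120)

test_that("dissolution profiles validate their structure", {
  expect_error(dissolution_profile("x", c(10, 5), c(1, 2)),
               "strictly increasing")
  expect_error(dissolution_profile("x", c(10, 20), c(1, 120)),
               "\\[0, 110\\]")
  expect_error(dissolution_profile("x", c(10, 20), c(1, 2, 3)),
               "same length")
  mat <- cbind(c(10, 20), c(20, 40))
  p <- dissolution_profile("x", c(10, 20), c(15, 30), replicates = mat)
  expect_equal(p$n_vessels, 2)
  expect_error(dissolution_profile("x", c(10, 20), c(16, 30),
                                   replicates = mat), "row means")
})

test_that("f2 matches its closed-form oracles", {
  q <- c(40, 55, 65, 75, 85, 99)
  a <- dissolution_profile("a", grid6, q)
  expect_equal(f2_similarity(a, a), 100)

  b <- dissolution_profile("b", grid6, q - 10)
  expect_equal(f2_similarity(a, b), 50 * log10(100 / sqrt(101)),
               tolerance = 1e-12)

  s1 <- dissolution_profile("s1", c(10, 20, 30), c(50, 60, 70))
  s2 <- dissolution_profile("s2", c(10, 20, 30), c(50, 60, 75))
  # single differing point of 5 over n = 3
  expect_equal(f2_similarity(s1, s2),
               50 * log10(100 / sqrt(1 + 25 / 3)), tolerance = 1e-12)
})

test_that("f2 equals an independent recomputation and is symmetric", {
  set.seed(99)
  for (i in 1:50) {
    r <- sort(runif(6, 0, 100))
    t_ <- pmin(pmax(r + rnorm(6, 0, 15), 0), 100)
    a <- dissolution_profile("a", grid6, r)
    b <- dissolution_profile("b", grid6, t_)
    expect_equal(f2_similarity(a, b), f2_oracle(r, t_), tolerance = 1e-12)
    expect_equal(f2_similarity(a, b), f2_similarity(b, a))
  }
})

test_that("f2 strictly decreases as a uniform offset grows", {
  q <- c(30, 50, 65, 80, 90, 95)
  a <- dissolution_profile("a", grid6, q)
  f2s <- vapply(seq(0.5, 15, by = 0.5), function(off) {
    f2_similarity(a, dissolution_profile("b", grid6, q - off))
  }, numeric(1))
  expect_true(all(diff(f2s) < 0))
})

test_that("f2 refuses mismatched grids instead of interpolating", {
  a <- dissolution_profile("a", c(10, 20, 30), c(10, 20, 30))
  b <- dissolution_profile("b", c(10, 20, 45), c(10, 20, 30))
  expect_error(f2_similarity(a, b), "time grids")
  c_ <- dissolution_profile("c", c(10, 20), c(10, 20))
  expect_error(f2_similarity(a, c_), "time grids")
})

test_that("optional truncation keeps at most one point past 85% for both", {
  r <- c(40, 70, 90, 95, 99, 100)
  t_ <- c(35, 66, 88, 94, 99, 100)
  a <- dissolution_profile("a", grid6, r)
  b <- dissolution_profile("b", grid6, t_)
  # default uses the full profile
  expect_equal(f2_similarity(a, b), f2_oracle(r, t_))
  # truncated: both cross 85% at point 3, so points 1..3 remain
  expect_equal(f2_similarity(a, b, truncate_85 = TRUE),
               f2_oracle(r[1:3], t_[1:3]))
})

test_that("similarity decision uses the rapid-dissolution exemption", {
  fast1 <- dissolution_profile("f1", grid6, c(99, 99.5, 100, 100, 100, 100))
  fast2 <- dissolution_profile("f2", grid6, c(97, 99, 100, 100, 100, 100))
  d <- similarity_decision(fast1, fast2)
  expect_identical(d$rule, "rapid_dissolution_exemption")
  expect_true(d$similar)
  expect_true(is.na(d$f2))
})

test_that("similarity decision interpolates the 15-min point on the 6-point grid", {
  # 80% at 10 min, 96% at 20 min -> 88% at 15 min by linear interpolation
  edge <- dissolution_profile("e", grid6, c(80, 96, 100, 100, 100, 100))
  d <- similarity_decision(edge, edge)
  expect_identical(d$rule, "rapid_dissolution_exemption")
  # 70% at 10, 90% at 20 -> 80% at 15: below the 85% cutoff, f2 branch
  slowish <- dissolution_profile("s", grid6, c(70, 90, 100, 100, 100, 100))
  d2 <- similarity_decision(slowish, slowish)
  expect_identical(d2$rule, "f2_test")
  expect_equal(d2$f2, 100)
  expect_true(d2$similar)
})

test_that("f2 branch declares similarity strictly above 50", {
  ref <- dissolution_profile("r", grid6, c(20, 35, 48, 60, 70, 85))
  near <- dissolution_profile("n", grid6, c(20, 35, 48, 60, 70, 85) - 8)
  far <- dissolution_profile("f", grid6,
                             pmin(c(20, 35, 48, 60, 70, 85) + 40, 100))
  d_near <- similarity_decision(ref, near)
  expect_identical(d_near$rule, "f2_test")
  expect_true(d_near$f2 > 50 && d_near$similar)
  d_far <- similarity_decision(ref, far)
  expect_true(d_far$f2 < 50)
  expect_false(d_far$similar)
})

test_that("noise-free curves return their generating constants with R^2 = 1", {
  t5 <- c(10, 20, 30, 45, 60)
  cases <- list(
    list(model = "zero_order", k = 1.5, q = 1.5 * t5),
    list(model = "first_order", k = 0.03, q = 100 * (1 - exp(-0.03 * t5))),
    list(model = "higuchi", k = 9, q = 9 * sqrt(t5)),
    list(model = "hixson_crowell", k = 0.04,
         q = 100 - (100^(1 / 3) - 0.04 * t5)^3)
  )
  for (cs in cases) {
    p <- dissolution_profile(cs$model, t5, cs$q)
    fit <- fit_kinetic_model(p, cs$model)
    expect_equal(fit$rate_constant, cs$k, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("saturated points are excluded from log/cube-root transforms", {
  q <- c(80, 95, 99, 100, 100, 100)
  p <- dissolution_profile("sat", grid6, q)
  expect_warning(fit <- fit_kinetic_model(p, "first_order"), "excluded")
  expect_equal(fit$n_points, 3)
  # with fewer than 3 usable points the fit refuses
  p2 <- dissolution_profile("sat2", grid6, c(90, 100, 100, 100, 100, 100))
  expect_warning(expect_error(fit_kinetic_model(p2, "first_order"),
                              "fewer than 3"), "excluded")
})

test_that("through-origin option pins the Higuchi intercept", {
  t5 <- c(10, 20, 30, 45, 60)
  p <- dissolution_profile("h", t5, 9 * sqrt(t5) + 3)
  free <- fit_kinetic_model(p, "higuchi")
  expect_equal(free$intercept, 3, tolerance = 1e-9)
  pinned <- fit_kinetic_model(p, "higuchi", through_origin = TRUE)
  expect_equal(pinned$intercept, 0)
})

test_that("model selection ranks the generating model first", {
  for (case in list(c("first_order", 0.03), c("higuchi", 8),
                    c("zero_order", 0.8))) {
    spec <- dissolution_sim_spec(case[1], as.numeric(case[2]),
                                 noise_sd = 0.5, n_vessels = 3, seed = 5)
    sel <- select_model(simulate_dissolution(spec))
    expect_identical(sel$best, case[1])
    expect_equal(nrow(sel$table), 4)
    expect_true(all(diff(sel$table$r_squared) <= 0))
  }
})

test_that("exact ties break deterministically by fixed model order", {
  # a flat profile is fitted exactly (residual-free) by every
  # linearisation, so all four R^2 tie at 1
  p <- dissolution_profile("tie", c(10, 20, 30), c(50, 50, 50))
  expect_warning(fits <- select_model(p), "tie")
  expect_identical(fits$best, "zero_order")
  expect_equal(fits$table$r_squared, rep(1, 4))
})

test_that("profiles round-trip through long-format delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  spec <- dissolution_sim_spec("first_order", 0.05, noise_sd = 1,
                               n_vessels = 3, seed = 8,
                               formulation = "armA")
  p <- simulate_dissolution(spec)
  write_dissolution(p, path)
  back <- read_dissolution(path)
  expect_equal(back$armA$dissolved, p$dissolved, tolerance = 1e-12)
  expect_equal(back$armA$n_vessels, 3)
  expect_equal(back$armA$replicates, p$replicates,
               ignore_attr = TRUE, tolerance = 1e-12)
})
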