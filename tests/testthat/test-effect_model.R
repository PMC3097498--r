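test_that("saturated fit reproduces the published equation from the 8 runs", {
  m <- estimate_coefficients(alkali_design())
  expect_equal(unname(m$coefficients), alkali_beta_exact())
  # two-decimal display (round half to even) gives the printed equation
  expect_equal(unname(round(m$coefficients, 2)),
               c(13.62, 1.88, 4.12, 11.12, 0.88, 0.38, 1.62, -0.62))
  expect_equal(
    model_equation(m),
    "Y = 13.62 + 1.88 X1 + 4.12 X2 + 11.12 X3 + 0.88 X1X2 + 0.38 X1X3 + 1.62 X2X3 - 0.62 X1X2X3")
})

test_that("constant responses give a pure-intercept model", {
  d <- attach_responses(build_full_factorial(alkali_factors()), rep(7.5, 8))
  m <- estimate_coefficients(d)
  expect_equal(unname(m$coefficients), c(7.5, rep(0, 7)))
})

test_that("contrast estimates equal the dense least-squares solution", {
  d <- build_full_factorial(alkali_factors())
  set.seed(101)
  for (rep in 1:20) {
    y <- rnorm(8, mean = 15, sd = 6)
    m <- estimate_coefficients(attach_responses(d, y))
    oracle <- lm_oracle_coefs(d$runs, y)
    expect_equal(m$coefficients[names(oracle)], oracle, tolerance = 1e-10)
  }
})

test_that("Yates algorithm agrees with contrasts across k = 2..5", {
  # published example: contrast totals / 2^k are the equation coefficients
  contrasts <- yates_algorithm(alkali_responses())
  beta <- estimate_coefficients(alkali_design())$coefficients
  expect_equal(contrasts[names(beta)] / 8, beta, tolerance = 1e-12)

  expect_equal(unname(yates_algorithm(rep(0, 16))), rep(0, 16))
  expect_error(yates_algorithm(rep(1, 6)), "power of two")

  set.seed(7)
  for (k in 2:5) {
    fs <- lapply(seq_len(k), function(i) fd_factor(paste0("f", i), 0, 1))
    d <- build_full_factorial(fs)
    y <- rnorm(2^k)
    yt <- yates_algorithm(y) / 2^k
    beta <- estimate_coefficients(attach_responses(d, y))$coefficients
    expect_equal(yt[names(beta)], beta, tolerance = 1e-10)
  }
})

test_that("effect screen on the alkali runs ranks power above time", {
  s <- screen_effects(alkali_design(), pool = c("X1X2", "X1X3", "X1X2X3"))
  expect_s3_class(s, "effect_screen")
  expect_equal(attr(s, "pool_df"), 3L)
  expect_equal(attr(s, "pooled_error_ms"), (6.125 + 1.125 + 3.125) / 3)
  f <- setNames(s$f_statistic, s$term)
  # significance ordering: microwave power dominates, then time
  expect_true(f[["X3"]] > f[["X2"]])
  expect_true(f[["X2"]] > max(f[c("X1", "X2X3")]))
  expect_true(all(s$significant[s$term %in% c("X2", "X3")]))
  expect_false(any(s$significant[s$pooled]))
  expect_true(all(is.na(s$f_statistic[s$pooled])))
})

test_that("default pool rule keeps only small high-order interactions", {
  s <- screen_effects(alkali_design())
  pooled <- s$term[s$pooled]
  expect_gt(length(pooled), 0)
  # pooled terms are interactions only, and exclude the top-half effects
  expect_true(all(nchar(pooled) > 2))
  top <- s$term[order(-abs(s$effect))][1:3]
  expect_length(intersect(pooled, top), 0)
})

test_that("screen guards: empty pool, exhaustive pool, zero error MS", {
  d <- alkali_design()
  expect_error(screen_effects(d, pool = character(0)), "pool is empty")
  expect_error(
    screen_effects(d, pool = c("X1", "X2", "X3", "X1X2", "X1X3", "X2X3",
                               "X1X2X3")),
    "exhausts")
  expect_error(screen_effects(d, pool = "X9"), "not in design")
  # surface exactly Y = 10 + 5*X3: pooled interactions have zero SS
  d0 <- attach_responses(build_full_factorial(alkali_factors()),
                         10 + 5 * build_full_factorial(alkali_factors())$runs[, 3])
  expect_warning(s0 <- screen_effects(d0, pool = c("X1X2", "X1X3", "X1X2X3")),
                 "zero")
  ss <- setNames(s0$sum_sq, s0$term)
  expect_equal(unname(ss[["X3"]]), 8 * 25)
  expect_equal(sum(ss[s0$term != "X3"]), 0)
})

test_that("sum-of-squares decomposition is exact on random responses", {
  d <- build_full_factorial(alkali_factors())
  set.seed(11)
  for (rep in 1:50) {
    y <- rnorm(8, 10, 4)
    s <- screen_effects(attach_responses(d, y),
                        pool = c("X1X2", "X1X3", "X1X2X3"))
    expect_equal(sum(s$sum_sq), sum((y - mean(y))^2), tolerance = 1e-10)
  }
})

test_that("effect SS ignore a constant shift; intercept absorbs it", {
  d <- build_full_factorial(alkali_factors())
  y <- alkali_responses()
  s1 <- screen_effects(attach_responses(d, y), pool = "X1X2X3")
  s2 <- screen_effects(attach_responses(d, y + 100), pool = "X1X2X3")
  expect_equal(s1$sum_sq, s2$sum_sq, tolerance = 1e-9)
})

test_that("dropping a factor keeps remaining coefficients (orthogonality)", {
  m <- estimate_coefficients(alkali_design())
  m2 <- reduce_model(m, "naoh")
  expect_equal(names(m2$coefficients), c("1", "X2", "X3", "X2X3"))
  expect_equal(unname(m2$coefficients), c(109, 33, 89, 13) / 8)
  expect_equal(unname(round(m2$coefficients, 2)),
               c(13.62, 4.12, 11.12, 1.62))
  # identical model back when nothing dropped
  expect_equal(reduce_model(m, character(0)), m)
  # least-squares refit of the reduced term set agrees exactly
  d <- alkali_design()
  X <- fdopt:::design_model_matrix(d$runs, m2$terms)
  refit <- qr.solve(X, d$responses)
  expect_equal(unname(m2$coefficients), unname(refit), tolerance = 1e-12)
  expect_error(reduce_model(m, c("naoh", "time", "power")), "every factor")
})

test_that("prediction interpolates the saturated fit and handles points", {
  d <- alkali_design()
  m <- estimate_coefficients(d)
  for (i in 1:8) {
    expect_equal(predict(m, d$runs[i, ]), d$responses[i], tolerance = 1e-12)
  }
  expect_equal(predict(m, c(0, 0, 0)), mean(d$responses))
  # published reduced equation at the all-high corner: 13.62+4.12+11.12+1.62
  expect_equal(predict(reduced_printed_model(), c(time = 1, power = 1)),
               30.48)
  expect_warning(predict(m, c(2, 0, 0)), "extrapolating")
  expect_error(predict(m, c(0, 0)), "length 3")
  expect_error(predict(m, c(bogus = 1)), "unknown factor")
})

test_that("coefficients are recovered from noisy simulations (4 SE bound)", {
  d <- build_full_factorial(alkali_factors())
  truth <- setNames(alkali_beta_exact(),
                    c("1", "X1", "X2", "X3", "X1X2", "X1X3", "X2X3", "X1X2X3"))
  sigma <- 1
  bound <- 4 * sigma / sqrt(8)
  inside <- 0L
  total <- 0L
  for (s in 1:500) {
    y <- simulate_factorial_responses(d, truth, noise_sd = sigma, seed = s)
    est <- estimate_coefficients(attach_responses(d, y))$coefficients
    err <- abs(est[names(truth)] - truth)
    inside <- inside + sum(err <= bound)
    total <- total + length(err)
  }
  expect_gte(inside / total, 0.99)
})
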