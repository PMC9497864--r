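test_that("goodness-of-fit matches hand arithmetic and edge cases", {
  g <- goodness_of_fit(c(1, 0.5, 0.25), c(0.9, 0.55, 0.2), n_params = 1)
  expect_equal(g$rmse, sqrt(0.005), tolerance = 1e-12)
  expect_equal(g$rmse, 0.07071, tolerance = 1e-4)
  expect_equal(g$chi2_reduced, 0.0075, tolerance = 1e-12)

  obs <- c(1, 0.6, 0.3, 0.1)
  perfect <- goodness_of_fit(obs, obs, 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$chi2_reduced, 0)

  at_mean <- goodness_of_fit(obs, rep(mean(obs), 4), 1)
  expect_equal(at_mean$r2, 0)

  flat <- goodness_of_fit(rep(0.5, 4), rep(0.4, 4), 1)
  expect_false(flat$r2_defined)
  expect_true(is.na(flat$r2))

  expect_error(goodness_of_fit(1:3 / 3, 1:3 / 3, 3), "more observations")
})

test_that("goodness-of-fit agrees with brute-force loop sums on random vectors", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    obs <- runif(n)
    pred <- obs + rnorm(n, 0, 0.1)
    z <- sample(1:3, 1)
    g <- goodness_of_fit(obs, pred, z)
    ss_res <- 0
    ss_tot <- 0
    m <- sum(obs) / n
    for (j in seq_len(n)) {
      ss_res <- ss_res + (obs[j] - pred[j])^2
      ss_tot <- ss_tot + (obs[j] - m)^2
    }
    expect_equal(g$r2, 1 - ss_res / ss_tot, tolerance = 1e-12)
    expect_equal(g$rmse, sqrt(ss_res / n), tolerance = 1e-12)
    expect_equal(g$chi2_reduced, ss_res / (n - z), tolerance = 1e-12)
  }
})

test_that("noiseless single-parameter data refits exactly", {
  t <- sampling_schedule(360)
  mr <- evaluate_model("newton", c(k = 0.0341), t)
  f <- fit_model("newton", t, mr)
  expect_true(f$converged)
  expect_equal(f$estimate[["k"]], 0.0341, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-12)
})

test_that("noiseless diffusion-approach data recovers the generating triple", {
  truth <- c(a = 0.88, k = 0.03, b = 0.01)
  run <- generate_run(synthetic_config(50, 2, noise_sd = 0))
  mr <- moisture_ratio(moisture_from_weights(run))
  f <- fit_model("diffusion_approach", mr$time_min, mr$mr)
  expect_true(f$converged)
  expect_true(all(abs(f$estimate[names(truth)] - truth) < 1e-4))
  expect_gte(f$r2, 0.999999)
})

test_that("fit_model validates its inputs", {
  expect_error(fit_model("logarithmic", c(0, 10), c(1, 0.9)), "observations")
  expect_error(fit_model("newton", c(0, 10, 10), c(1, 0.9, 0.8)), "strictly increasing")
  expect_error(fit_model("newton", c(0, 10, 20), c(1, 0.9, 1.2)), "mr")
})

test_that("fits are deterministic for a fixed seed", {
  run <- generate_run(synthetic_config(70, 6, seed = 5))
  mr <- moisture_ratio(moisture_from_weights(run))
  f1 <- fit_model("diffusion_approach", mr$time_min, mr$mr, seed = 99)
  f2 <- fit_model("diffusion_approach", mr$time_min, mr$mr, seed = 99)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$sse, f2$sse)
})

test_that("nested models never increase the residual sum of squares", {
  # newton ⊆ henderson_pabis ⊆ diffusion_approach
  run <- generate_run(synthetic_config(60, 4, seed = 3))
  mr <- moisture_ratio(moisture_from_weights(run))
  sse <- vapply(
    c("newton", "henderson_pabis", "diffusion_approach"),
    function(id) fit_model(id, mr$time_min, mr$mr)$sse,
    numeric(1)
  )
  expect_true(sse[2] <= sse[1] + 1e-10)
  expect_true(sse[3] <= sse[2] + 1e-10)
})

test_that("ranking is deterministic, complete and prefers parsimony on ties", {
  t <- sampling_schedule(360)
  mr <- evaluate_model("newton", c(k = 0.03), t)
  rk1 <- rank_models(t, mr)
  rk2 <- rank_models(t, mr)
  expect_equal(rk1$model_id, rk2$model_id)
  expect_equal(nrow(rk1), 7)
  # every superset of newton reaches SSE ~ 0; the one-parameter form wins
  expect_identical(attr(rk1, "best"), "newton")
})

test_that("ranking flags degenerate data instead of aborting", {
  t <- sampling_schedule(120)
  rk <- rank_models(t, rep(1, length(t)))
  expect_equal(nrow(rk), 7)
  expect_true(all(is.na(rk$r2)))
})

test_that("bounded multi-start agrees with an independent optimizer route", {
  run <- generate_run(synthetic_config(60, 4, noise_sd = 0))
  mr <- moisture_ratio(moisture_from_weights(run))
  f <- fit_model("diffusion_approach", mr$time_min, mr$mr)
  alt <- stats::nls(
    mr ~ a * exp(-k * t) + (1 - a) * exp(-k * b * t),
    data = list(t = mr$time_min, mr = mr$mr),
    start = list(a = 0.9, k = 0.03, b = 0.05),
    algorithm = "port",
    lower = c(a = 1e-6, k = 1e-6, b = 1e-6), upper = c(a = 2, k = 10, b = 10)
  )
  expect_equal(f$estimate[c("a", "k", "b")], coef(alt)[c("a", "k", "b")],
    tolerance = 1e-5
  )
})
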