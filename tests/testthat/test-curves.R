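test_that("moisture content is the dry-basis water fraction of the weight", {
  run <- toy_run()
  m <- moisture_from_weights(run)
  expect_equal(m$moisture_db, c(4, 3, 2.2, 1.6, 1.2))
  # inverse map reproduces weights to machine precision
  expect_equal(run$dry_mass * (1 + m$moisture_db), run$weights, tolerance = 1e-15)

  # boundary cases: weight at dry mass is zero moisture, double is 1 kg/kg
  run2 <- drying_run("b", 60, 0.004, 1.5,
    initial_load = 0.4, dry_mass = 0.2,
    times = c(0, 10, 20), weights = c(0.4, 0.3, 0.2),
    initial_moisture_db = 1
  )
  expect_equal(moisture_from_weights(run2)$moisture_db, c(1, 0.5, 0))
})

test_that("fresh plantain load reproduces the 598.12% d.b. initial moisture", {
  dry <- 0.88 / (1 + 5.9812)
  run <- drying_run("init", 50, 0.002, 1.5,
    initial_load = 0.88, dry_mass = dry,
    times = c(0, 10), weights = c(0.88, 0.8),
    initial_moisture_db = 5.9812
  )
  expect_equal(moisture_from_weights(run)$moisture_db[1], 5.9812, tolerance = 1e-12)
})

test_that("weights below the dry mass are rejected with the offending index", {
  expect_error(
    drying_run("bad", 60, 0.004, 1.5,
      initial_load = 0.4, dry_mass = 0.2,
      times = c(0, 10), weights = c(0.4, 0.19),
      initial_moisture_db = 1
    ),
    "index 2"
  )
})

test_that("run construction enforces a strictly increasing schedule from zero", {
  expect_error(
    drying_run("t", 60, 0.004, 1.5, 0.4, 0.2,
      times = c(0, 10, 10), weights = c(0.4, 0.3, 0.3), initial_moisture_db = 1
    ),
    "strictly increasing"
  )
  expect_error(
    drying_run("t", 60, 0.004, 1.5, 0.4, 0.2,
      times = c(5, 10), weights = c(0.4, 0.3), initial_moisture_db = 1
    ),
    "start at 0"
  )
})

test_that("moisture ratio normalizes to 1 at time zero, with or without Me", {
  m <- moisture_from_weights(toy_run())
  mr0 <- moisture_ratio(m)
  expect_equal(mr0$mr[1], 1)
  expect_equal(mr0$mr, m$moisture_db / m$moisture_db[1])

  mr_me <- moisture_ratio(m, equilibrium = 1.2)
  expect_equal(mr_me$mr[1], 1)
  expect_equal(mr_me$mr[5], 0) # Mt = Me
  expect_error(moisture_ratio(m, equilibrium = 4), "equilibrium")
})

test_that("dividing printed initial and final moisture gives the expected ratio", {
  # 12% d.b. final over 598.12% d.b. initial
  series <- tibble::tibble(time_min = c(0, 100), moisture_db = c(5.9812, 0.12))
  expect_equal(moisture_ratio(series)$mr[2], 0.12 / 5.9812)
  expect_equal(moisture_ratio(series)$mr[2], 0.02006, tolerance = 1e-3)
})

test_that("moisture ratio is scale invariant in the Me = 0 mode", {
  m <- moisture_from_weights(toy_run())
  scaled <- m
  scaled$moisture_db <- scaled$moisture_db * 3.7
  expect_equal(moisture_ratio(m)$mr, moisture_ratio(scaled)$mr, tolerance = 1e-14)
})

test_that("drying rate is per hour, positive for loss, and telescopes", {
  m <- moisture_from_weights(toy_run())
  dr <- drying_rate(m)
  expect_equal(nrow(dr), nrow(m) - 1)
  expect_equal(dr$mid_time_min, c(15, 45, 75, 105))
  # 0.8 kg/kg lost over half an hour in the second interval -> 1.6 per hour
  expect_equal(dr$rate_per_h[2], 1.6)
  # a drop of 0.24 kg/kg over one hour is a rate of 0.24 kg/kg/h
  s <- tibble::tibble(time_min = c(0, 60), moisture_db = c(5.98, 5.74))
  expect_equal(drying_rate(s)$rate_per_h, 0.24)
  # telescoping conservation: sum(rate * dt) = M0 - Mlast
  expect_equal(sum(dr$rate_per_h * dr$dt_min / 60),
    m$moisture_db[1] - tail(m$moisture_db, 1),
    tolerance = 1e-14
  )
  # constant moisture -> zero rate
  flat <- tibble::tibble(time_min = c(0, 10, 20), moisture_db = c(1, 1, 1))
  expect_equal(drying_rate(flat)$rate_per_h, c(0, 0))
  # duplicated timestamps -> error
  dup <- tibble::tibble(time_min = c(0, 10, 10), moisture_db = c(1, 0.9, 0.8))
  expect_error(drying_rate(dup), "zero interval|duplicated")
})
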