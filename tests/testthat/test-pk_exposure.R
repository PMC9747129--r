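test_that("schedule construction enforces its invariants", {
  expect_error(dose_schedule(c(0, 0), 100), "strictly increasing")
  expect_error(dose_schedule(c(24, 0), 100), "strictly increasing")
  expect_error(dose_schedule(0, -1), ">= 0")
  sched <- regimen_schedule(100, "qd", 3)
  expect_equal(sched$time, c(0, 24, 48))
  expect_equal(nrow(regimen_schedule(100, "bid", 2)), 4)
  dropped <- drop_dose(sched, day = 1)
  expect_equal(dropped$time, c(0, 48))
  expect_error(drop_dose(dropped, day = 1), "no dose event")
})

test_that("PK parameter validation rejects non-positive values", {
  expect_error(pk_params(ka = 0), "> 0")
  expect_error(pk_params(v_central = -1), "> 0")
  expect_error(pk_params(lag = -1), ">= 0")
})

test_that("empty schedule yields identically zero exposure", {
  ex <- simulate_exposure(dose_schedule(numeric(0), numeric(0)),
                          pk_params(), time_grid(0, 24, 0.5))
  expect_true(all(ex$a_systemic == 0))
  expect_true(all(ex$a_portal == 0))
})

test_that("concentrations are zero through the absorption lag", {
  ex <- simulate_exposure(dose_schedule(0, 100), pk_params(lag = 4),
                          time_grid(0, 24, 0.1))
  expect_true(all(ex$a_systemic[ex$time_h <= 4] == 0))
  expect_true(all(ex$a_portal[ex$time_h <= 4] == 0))
  expect_gt(ex$a_systemic[ex$time_h == 5], 0)
  expect_true(all(ex$a_systemic >= 0) && all(ex$a_portal >= 0))
})

test_that("dose events outside the grid are rejected", {
  expect_error(simulate_exposure(dose_schedule(30, 100), pk_params(),
                                 time_grid(0, 24, 0.5)),
               "outside the simulation grid")
})

test_that("exposure is linear in dose and superposes over events", {
  grid <- time_grid(0, 72, 0.1)
  pk <- pk_params()
  one <- simulate_exposure(dose_schedule(0, 100), pk, grid)
  two_shifted <- simulate_exposure(dose_schedule(24, 100), pk, grid)
  both <- simulate_exposure(dose_schedule(c(0, 24), 100), pk, grid)
  expect_equal(both$a_systemic, one$a_systemic + two_shifted$a_systemic,
               tolerance = 1e-10)
  expect_equal(both$a_portal, one$a_portal + two_shifted$a_portal,
               tolerance = 1e-10)
  scaled <- simulate_exposure(dose_schedule(c(0, 24), 250), pk, grid)
  dev <- abs(scaled$a_systemic - 2.5 * both$a_systemic)
  expect_lt(max(dev) / max(scaled$a_systemic), 1e-6)
})

test_that("concentrations decay toward zero after the last dose", {
  ex <- simulate_exposure(dose_schedule(0, 100), pk_params(),
                          time_grid(0, 96, 0.5))
  expect_lt(ex$a_systemic[ex$time_h == 96], 1e-4 * max(ex$a_systemic))
})

test_that("chronic q.d. dosing reaches a periodic steady state", {
  pk <- pk_params()
  grid <- time_grid(0, 16 * 24, 0.1)
  ex <- simulate_exposure(regimen_schedule(100, "qd", 16), pk, grid)
  peak <- max(ex$a_systemic)
  t1 <- ex$time_h >= 12 * 24 & ex$time_h < 13 * 24   # after >= 10 intervals
  t2 <- ex$time_h >= 13 * 24 & ex$time_h < 14 * 24
  expect_lt(max(abs(ex$a_systemic[t2] - ex$a_systemic[t1])), 1e-6 * peak)

  # closed-form periodic solution agrees with long superposition
  t_day <- ex$time_h[t2] - 13 * 24
  per <- aspirinpd:::pk_periodic(t_day, 0, 100, 24, pk)
  expect_lt(max(abs(per$a_systemic - ex$a_systemic[t2])), 1e-5 * peak)
})

test_that("analytic solution matches a fine-step Euler oracle", {
  pk <- pk_params()
  sched <- dose_schedule(0, 100)
  oracle <- euler_pk(sched, pk, t_end = 12, h = 1e-4)
  ana <- simulate_exposure(sched, pk, time_grid(0, 12, 0.25))
  idx <- match(round(ana$time_h, 6), round(oracle$time_h, 6))
  peak <- max(oracle$a_systemic)
  expect_lt(max(abs(ana$a_systemic - oracle$a_systemic[idx])), 1e-3 * peak)
  expect_lt(max(abs(ana$a_portal - oracle$a_portal[idx])),
            1e-3 * max(oracle$a_portal))
})
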