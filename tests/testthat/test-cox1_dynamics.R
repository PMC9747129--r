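test_that("acetylation flux follows the threshold-saturation form", {
  pd <- acetylation_params(lambda = 120, km = 50, n = 2)
  expect_equal(acetylation_flux(100, 0, pd), 0)
  expect_equal(acetylation_flux(0, 3, pd), 0)
  expect_equal(acetylation_flux(50, 1, pd), 60)        # product = km
  expect_equal(acetylation_flux(25, 2, pd), 60)        # depends on product
  expect_lt(abs(acetylation_flux(5e4, 10, pd) - 120), 120 * 1e-6)  # -> lambda
  s <- seq(0.1, 500, length.out = 50)
  fl <- acetylation_flux(s, 1, pd)
  expect_true(all(diff(fl) > 0))
  expect_true(all(fl < pd$lambda))
  expect_error(acetylation_flux(-1, 1, pd), ">= 0")
  expect_error(acetylation_flux(1, -1, pd), ">= 0")
  expect_error(acetylation_params(n = 0.5), ">= 1")
  expect_error(acetylation_params(lambda = -1), "> 0")
})

test_that("aspirin-free MK unit approaches the p/kd fixed point", {
  mk <- small_mk(p_peak_fold = 0, kd = 0.25)  # kd*t1 = 6: well converged
  tr <- mk_cox1_trajectory(0, mk, acetylation_params(), NULL,
                           plt = small_plt())
  plateau <- mk$f1 * mk$count_fold * mk$p0 / mk$kd
  at_t1 <- tr$x_amount_ng[tr$age_h == mk$t1]
  expect_lt(abs(at_t1 - plateau) / plateau, 0.01)
  expect_true(all(tr$x_amount_ng >= 0))
  expect_equal(unique(tr$phase[tr$age_h < mk$t1]), "maturation")
  expect_equal(unique(tr$phase[tr$age_h >= mk$t1]), "generation")
})

test_that("aspirin-free MK dynamics are linear in the biosynthesis fold", {
  base <- mk_cox1_trajectory(0, small_mk(f1 = 1), acetylation_params(),
                             NULL, plt = small_plt())
  doubled <- mk_cox1_trajectory(0, small_mk(f1 = 2), acetylation_params(),
                                NULL, plt = small_plt())
  expect_equal(doubled$x_amount_ng, 2 * base$x_amount_ng,
               tolerance = 1e-10)
})

test_that("MK and platelet trajectories match the fine-step Euler oracle", {
  pd <- acetylation_params(lambda = 200, km = 60, n = 1)
  h <- 0.025  # resolves the platelet-birth boundary layer
  grid <- time_grid(0, 70, h / 2)
  ex <- simulate_exposure(regimen_schedule(100, "qd", 3), pk_params(), grid)
  a_sys <- stats::approxfun(ex$time_h, ex$a_systemic, rule = 2)
  a_por <- stats::approxfun(ex$time_h, ex$a_portal, rule = 2)
  for (f1 in c(1, 3.2)) {
    mk <- small_mk(f1 = f1, aspirin_frac = 0.5)
    plt <- small_plt()
    # Richardson-extrapolated Euler: second-order-accurate brute force
    e1 <- euler_cohort(0, mk, plt, pd, a_sys, a_por, h = 1e-3)
    e2 <- euler_cohort(0, mk, plt, pd, a_sys, a_por, h = 5e-4)
    oracle <- e1
    oracle$xm <- 2 * e2$xm - e1$xm
    oracle$xp <- 2 * e2$xp - e1$xp
    tr_mk <- mk_cox1_trajectory(0, mk, pd, ex, plt = plt, h = h)
    tr_p <- platelet_cox1_trajectory(tr_mk, plt, pd, ex, h = h)
    idx <- match(round(oracle$age_h[oracle$age_h <= mk$t1 + mk$t2], 6),
                 round(tr_mk$age_h, 6))
    dev_m <- abs(tr_mk$x_amount_ng[idx] -
                   oracle$xm[oracle$age_h <= mk$t1 + mk$t2])
    expect_lt(max(dev_m), 1e-3 * max(oracle$xm))
    idx_p <- match(round(oracle$age_h, 6), round(tr_p$age_h, 6))
    dev_p <- abs(tr_p$x_amount_ng[idx_p] - oracle$xp)
    expect_lt(max(dev_p), 1e-3 * max(oracle$xp))
  }
})

test_that("platelet COX-1 is constant through activity without aspirin", {
  mk <- small_mk()
  plt <- small_plt()
  tr_mk <- mk_cox1_trajectory(0, mk, acetylation_params(), NULL, plt = plt)
  tr_p <- platelet_cox1_trajectory(tr_mk, plt, acetylation_params(), NULL)
  act <- tr_p$phase == "activity"
  expect_gt(sum(act), 10)
  expect_lt(diff(range(tr_p$x_amount_ng[act])),
            1e-9 * max(tr_p$x_amount_ng))
  # phase boundaries: no platelet COX-1 before generation starts
  expect_true(all(tr_p$x_amount_ng[tr_p$age_h < mk$t1] == 0))
  expect_gt(max(tr_p$x_amount_ng), 0)
})

test_that("platelet acetylation is driven by the 75/25 weighted signal", {
  grid <- time_grid(0, 70, 0.025)
  ex <- simulate_exposure(regimen_schedule(100, "qd", 3), pk_params(), grid)
  mixed <- ex
  mixed$a_systemic <- mixed$a_portal <-
    0.75 * ex$a_systemic + 0.25 * ex$a_portal
  pd <- acetylation_params(lambda = 150, km = 60, n = 1)
  mk <- small_mk(aspirin_frac = 0)  # isolate the platelet-phase signal
  tr1 <- platelet_cox1_trajectory(
    mk_cox1_trajectory(0, mk, pd, ex, plt = small_plt()),
    small_plt(), pd, ex)
  tr2 <- platelet_cox1_trajectory(
    mk_cox1_trajectory(0, mk, pd, mixed, plt = small_plt()),
    small_plt(), pd, mixed)
  expect_equal(tr1$x_amount_ng, tr2$x_amount_ng, tolerance = 1e-10)
})

test_that("COX-1 transferred to platelets equals the k5 flux quadrature", {
  mk <- small_mk()
  plt <- small_plt()
  tr_mk <- mk_cox1_trajectory(0, mk, acetylation_params(), NULL, plt = plt,
                              h = 0.02)
  tr_p <- platelet_cox1_trajectory(tr_mk, plt, acetylation_params(), NULL)
  gen <- tr_mk$age_h >= mk$t1
  u <- tr_mk$age_h[gen]
  x <- tr_mk$x_amount_ng[gen]
  flux <- mk$k5 * x
  quad <- sum((flux[-1] + flux[-length(flux)]) / 2 * diff(u))
  gained <- max(tr_p$x_amount_ng)
  expect_lt(abs(quad - gained) / gained, 1e-3)
})

test_that("mass balance holds with acetylation and death switched off", {
  # no aspirin, (near-)zero degradation: COX-1 leaving the MK during
  # generation (content drop plus synthesis) must all appear in platelets
  mk <- small_mk(kd = 1e-12)
  pd <- acetylation_params()
  tr_mk <- mk_cox1_trajectory(0, mk, pd, NULL, plt = small_plt(), h = 0.02)
  tr_p <- platelet_cox1_trajectory(tr_mk, small_plt(), pd, NULL)
  gen <- tr_mk$age_h >= mk$t1
  p_gen <- mk$f1 * mk$count_fold * mk$p0 *
    (1 + mk$p_peak_fold * exp(-tr_mk$age_h[gen] / mk$p_peak_tau))
  synth_in_gen <- sum((p_gen[-1] + p_gen[-length(p_gen)]) / 2) *
    attr(tr_mk, "h")
  mk_loss <- tr_mk$x_amount_ng[match(mk$t1, tr_mk$age_h)] -
    tr_mk$x_amount_ng[nrow(tr_mk)] + synth_in_gen
  gain <- max(tr_p$x_amount_ng)
  expect_lt(abs(mk_loss - gain) / gain, 1e-3)
})

test_that("raising the acetylation capacity never raises platelet COX-1", {
  grid <- time_grid(0, 70, 0.025)
  ex <- simulate_exposure(regimen_schedule(100, "qd", 3), pk_params(), grid)
  mk <- small_mk()
  plt <- small_plt()
  lam <- c(50, 200, 800)
  trajs <- lapply(lam, function(l) {
    pd <- acetylation_params(lambda = l, km = 60, n = 1)
    platelet_cox1_trajectory(mk_cox1_trajectory(0, mk, pd, ex, plt = plt),
                             plt, pd, ex)$x_amount_ng
  })
  expect_true(all(trajs[[2]] <= trajs[[1]] + 1e-9))
  expect_true(all(trajs[[3]] <= trajs[[2]] + 1e-9))
})
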