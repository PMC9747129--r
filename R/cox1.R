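#' Acetylation (pharmacodynamic) parameters
#'
#' Aspirin acetylates COX-1 irreversibly. The acetylation flux is a
#' sigmoidal (Hill) function of the product of COX-1 concentration and
#' aspirin concentration, reflecting a threshold-saturation mechanism:
#' `phi(x, a) = lambda * (a*x)^n / (km^n + (a*x)^n)`.
#'
#' The same parameter set drives acetylation in megakaryocytes and in
#' platelets by default.
#'
#' @param lambda Maximal acetylation flux (ng COX-1 per hour, per cohort).
#'   The shipped default is the value anchored so that the healthy
#'   scenario's steady trough under chronic 100 mg q.d. equals 3% of basal
#'   serum TXB2 (see [anchor_healthy()]).
#' @param km Half-saturation constant, in units of the concentration
#'   product (ng/ml COX-1 times ug/ml aspirin).
#' @param n Hill exponent, `>= 1`.
#' @return An object of class `acetylation_params`.
#' @export
acetylation_params <- function(lambda = .anchored_lambda_default,
                               km = 100, n = 1) {
  if (lambda <= 0 || km <= 0) stop("`lambda` and `km` must be > 0")
  if (n < 1) stop("Hill exponent `n` must be >= 1")
  structure(list(lambda = lambda, km = km, n = n),
            class = "acetylation_params")
}

#' Sigmoidal COX-1 acetylation flux
#'
#' @param cox1_conc COX-1 concentration (ng/ml), `>= 0`.
#' @param aspirin_conc Aspirin concentration (ug/ml), `>= 0`.
#' @param pd An [acetylation_params()].
#' @return Flux (ng/h), in `[0, lambda)`, strictly increasing in the
#'   product of the two concentrations.
#' @examples
#' pd <- acetylation_params(lambda = 100, km = 50, n = 2)
#' acetylation_flux(50, 1, pd)  # product at km: half-saturation, = 50
#' @export
acetylation_flux <- function(cox1_conc, aspirin_conc, pd) {
  if (any(cox1_conc < 0) || any(aspirin_conc < 0)) {
    stop("concentrations must be >= 0")
  }
  s <- (cox1_conc * aspirin_conc)^pd$n
  pd$lambda * s / (pd$km^pd$n + s)
}

# Internal, clamped and validation-free flux used inside the integrator.
phi_flux <- function(x, v, a, lambda, kmn, n) {
  s <- (pmax(x, 0) / v * a)^n
  lambda * s / (kmn + s)
}

#' Megakaryocyte (MK) unit parameters
#'
#' One MK unit is a cohort of megakaryocytes born at the same time,
#' modeled as a single compartment. During maturation (duration `t1`)
#' COX-1 amount balances de novo synthesis against degradation and
#' acetylation; during platelet generation (duration `t2`) an additional
#' output transfers COX-1 to the platelet progeny at rate `k5`, equal to
#' the relative rate of MK volume decay.
#'
#' Synthesis declines from a fast early expression to a constant level:
#' `p(age) = f1 * count_fold * p0 * (1 + p_peak_fold * exp(-age/p_peak_tau))`.
#' MK volume grows exponentially during maturation (endomitosis) by
#' `v_growth_fold` and decays exponentially at rate `k5` during platelet
#' generation.
#'
#' @param t1 Maturation duration = MK lifespan (h).
#' @param t2 Platelet generation duration (h).
#' @param p0 Plateau COX-1 synthesis rate (ng/h) for the healthy reference
#'   unit.
#' @param p_peak_fold,p_peak_tau Early-expression excess (fold over the
#'   plateau) and its decay time constant (h).
#' @param kd COX-1 degradation rate constant (1/h).
#' @param k5 COX-1 transfer rate to platelets during generation (1/h).
#' @param v0 MK unit volume at birth (ml) for the healthy reference unit.
#' @param v_growth_fold Volume fold growth over maturation.
#' @param f1 COX-1 biosynthesis fold vs. healthy: the single parameter
#'   re-fitted per clinical subgroup (multiplies `p0` only).
#' @param count_fold Platelet-count fold vs. healthy: scales the platelet
#'   pool (synthesis and volumes jointly, preserving concentrations), so
#'   that a larger platelet mass shares the same saturable acetylation
#'   capacity.
#' @param aspirin_frac Fraction of the systemic aspirin concentration that
#'   reaches marrow megakaryocytes (the MK acetylation driver is
#'   `aspirin_frac * A_B(t)`). Marrow exposure to aspirin is lower than
#'   circulating-platelet exposure; this partitioning factor controls how
#'   much of each day's COX-1 synthesis is already acetylated before
#'   platelet release.
#' @return An object of class `mk_unit_params`.
#' @export
mk_unit_params <- function(t1 = 96, t2 = 12, p0 = 10,
                           p_peak_fold = 4, p_peak_tau = 24,
                           kd = 0.05, k5 = 0.3,
                           v0 = 0.08, v_growth_fold = 6,
                           f1 = 1, count_fold = 1, aspirin_frac = 0.1) {
  if (t1 <= 0 || t2 <= 0) stop("`t1` and `t2` must be > 0")
  if (min(p0, kd, k5, v0, v_growth_fold, f1, count_fold) <= 0) {
    stop("rates, volumes and folds must be > 0")
  }
  if (p_peak_fold < 0 || p_peak_tau <= 0) {
    stop("`p_peak_fold` must be >= 0 and `p_peak_tau` > 0")
  }
  if (aspirin_frac < 0 || aspirin_frac > 1) {
    stop("`aspirin_frac` must be in [0, 1]")
  }
  structure(list(t1 = t1, t2 = t2, p0 = p0,
                 p_peak_fold = p_peak_fold, p_peak_tau = p_peak_tau,
                 kd = kd, k5 = k5, v0 = v0, v_growth_fold = v_growth_fold,
                 f1 = f1, count_fold = count_fold,
                 aspirin_frac = aspirin_frac),
            class = "mk_unit_params")
}

#' Platelet cohort parameters
#'
#' Platelets produced by one MK unit. They receive COX-1 during the
#' generation phase, lose it only to acetylation during the activity phase
#' (platelets are anucleate: no synthesis), and are destroyed at rate `k6`
#' during the death phase. Acetylation is driven by the weighted aspirin
#' signal `w_sys * A_B(t) + w_portal * A_S(t)` (75/25 systemic/portal
#' blood volume ratio).
#'
#' @param t3a Platelet activity duration (h).
#' @param t3b Platelet death-phase duration (h).
#' @param k6 Death rate constant (1/h), constant over the death phase.
#' @param w_sys,w_portal Systemic and portal weights; must sum to 1.
#' @return An object of class `platelet_params`.
#' @export
platelet_params <- function(t3a = 192, t3b = 48, k6 = 0.1,
                            w_sys = 0.75, w_portal = 0.25) {
  if (t3a <= 0 || t3b <= 0) stop("`t3a` and `t3b` must be > 0")
  if (k6 < 0) stop("`k6` must be >= 0")
  if (abs(w_sys + w_portal - 1) > 1e-12) {
    stop("systemic and portal weights must sum to 1")
  }
  structure(list(t3a = t3a, t3b = t3b, k6 = k6,
                 w_sys = w_sys, w_portal = w_portal),
            class = "platelet_params")
}

# Age-phase coefficient profiles on the half-step grid (step h/2) over
# [0, t1 + t2 + t3a + t3b]. The volume floor avoids division blowup at the
# end of the decay phases.
.v_floor <- 1e-12

cohort_profiles <- function(mk, plt, h) {
  L <- mk$t1 + mk$t2 + plt$t3a + plt$t3b
  he <- h / 2
  stopifnot(abs(L / h - round(L / h)) < 1e-9,
            abs(mk$t1 / h - round(mk$t1 / h)) < 1e-9,
            abs(mk$t2 / h - round(mk$t2 / h)) < 1e-9)
  u <- seq(0, L, by = he)
  in_mat <- u < mk$t1
  in_gen <- u >= mk$t1 & u < mk$t1 + mk$t2
  in_act <- u >= mk$t1 + mk$t2 & u < mk$t1 + mk$t2 + plt$t3a
  in_dth <- u >= mk$t1 + mk$t2 + plt$t3a

  # smooth (continuous) profiles over the whole age grid; the phase
  # on/off switches are applied per integration step from the step
  # midpoint, so every RK4 step sees a smooth vector field and the phase
  # boundaries (which lie on full steps) stay exact
  p <- mk$f1 * mk$count_fold * mk$p0 *
    (1 + mk$p_peak_fold * exp(-u / mk$p_peak_tau))
  g <- log(mk$v_growth_fold) / mk$t1
  v_top <- mk$count_fold * mk$v0 * mk$v_growth_fold
  vmk <- ifelse(u < mk$t1, mk$count_fold * mk$v0 * exp(g * u),
                v_top * exp(-mk$k5 * pmax(u - mk$t1, 0)))
  v_act <- v_top * (1 - exp(-mk$k5 * mk$t2))
  vp <- numeric(length(u))
  vp[in_gen] <- v_top * (1 - exp(-mk$k5 * (u[in_gen] - mk$t1)))
  vp[in_act] <- v_act
  vp[in_dth] <- v_act * exp(-plt$k6 * (u[in_dth] - (mk$t1 + mk$t2 + plt$t3a)))

  list(L = L, he = he, u = u, p = p,
       mk_on = in_mat | in_gen, gen_on = in_gen, dth_on = in_dth,
       kd = mk$kd, k5 = mk$k5, k6 = plt$k6,
       vmk = pmax(vmk, .v_floor), vp = pmax(vp, .v_floor),
       phase = ifelse(in_mat, "maturation",
                      ifelse(in_gen, "generation",
                             ifelse(in_act, "activity", "death"))))
}

# Vectorized-over-cohorts RK4 integration of the MK + platelet COX-1
# amounts against an exposure lookup table (`etab`, step h/2; periodic
# tables are indexed modulo one dosing period).
#
# tau: vector of cohort birth times (h); must lie on the table grid.
# Returns platelet amounts at ages seq(0, L, by = h * keep_every) as a
# matrix [cohort, age], and optionally the MK amounts at step resolution.
integrate_cohorts <- function(tau, mk, plt, pd, etab, h = 0.05,
                              keep_every = 1L, keep_mk = FALSE,
                              ages_to = NULL) {
  pr <- cohort_profiles(mk, plt, h)
  if (abs(etab$he - h / 2) > 1e-12) {
    stop("exposure table step must equal h/2")
  }
  K <- round((if (is.null(ages_to)) pr$L else ages_to) / h)
  n <- length(tau)
  i_tau <- round((tau - etab$t0) / etab$he)
  if (max(abs((tau - etab$t0) / etab$he - i_tau)) > 1e-6) {
    stop("cohort birth times must lie on the exposure grid")
  }
  if (!etab$periodic && (min(i_tau) < 0 || max(i_tau) + 2 * K > etab$n - 1)) {
    stop("exposure grid does not cover the full cohort lifespan")
  }

  lambda <- pd$lambda
  kmn <- pd$km^pd$n
  nh <- pd$n
  ws <- plt$w_sys
  wp <- plt$w_portal
  fmk <- mk$aspirin_frac

  deriv <- function(xm, xp, j, idx, g_mk, g_gen, g_dth) {
    aB <- etab$a_sys[idx]
    aS <- etab$a_por[idx]
    dm <- g_mk * (pr$p[j] - pr$kd * xm -
                    phi_flux(xm, pr$vmk[j], fmk * aB, lambda, kmn, nh)) -
      g_gen * pr$k5 * xm
    dp <- g_gen * pr$k5 * xm - g_dth * pr$k6 * xp -
      phi_flux(xp, pr$vp[j], ws * aB + wp * aS, lambda, kmn, nh)
    list(m = dm, p = dp)
  }

  kk <- as.integer(keep_every)
  n_keep <- K %/% kk + 1L
  xp_store <- matrix(0, n, n_keep)
  age_end <- K * h
  xm_store <- if (keep_mk) matrix(0, n, K + 1L) else NULL

  xm <- numeric(n)
  xp <- numeric(n)
  h2 <- h / 2
  for (k in seq_len(K)) {
    j0 <- 2L * k - 1L
    j1 <- 2L * k
    j2 <- 2L * k + 1L
    if (etab$periodic) {
      i0 <- (i_tau + (j0 - 1L)) %% etab$n + 1L
      i1 <- (i_tau + (j1 - 1L)) %% etab$n + 1L
      i2 <- (i_tau + (j2 - 1L)) %% etab$n + 1L
    } else {
      i0 <- i_tau + j0
      i1 <- i_tau + j1
      i2 <- i_tau + j2
    }
    g_mk <- pr$mk_on[j1]
    g_gen <- pr$gen_on[j1]
    g_dth <- pr$dth_on[j1]
    d1 <- deriv(xm, xp, j0, i0, g_mk, g_gen, g_dth)
    d2 <- deriv(xm + h2 * d1$m, xp + h2 * d1$p, j1, i1, g_mk, g_gen, g_dth)
    d3 <- deriv(xm + h2 * d2$m, xp + h2 * d2$p, j1, i1, g_mk, g_gen, g_dth)
    d4 <- deriv(xm + h * d3$m, xp + h * d3$p, j2, i2, g_mk, g_gen, g_dth)
    xm <- pmax(xm + h / 6 * (d1$m + 2 * d2$m + 2 * d3$m + d4$m), 0)
    xp <- pmax(xp + h / 6 * (d1$p + 2 * d2$p + 2 * d3$p + d4$p), 0)
    if (k %% kk == 0L) xp_store[, k %/% kk + 1L] <- xp
    if (keep_mk) xm_store[, k + 1L] <- xm
  }
  list(ages = seq(0, age_end, by = h * kk), xp = xp_store,
       ages_mk = if (keep_mk) seq(0, age_end, by = h),
       xm = xm_store, profiles = pr)
}

# Interpolate a user-supplied exposure object onto the half-step lookup
# grid required by the integrator. Errors if the exposure does not cover
# [t0, t1].
exposure_table_interp <- function(exposure, t0, t1, he) {
  if (is.null(exposure)) {
    n <- length(seq(t0, t1, by = he))
    return(list(periodic = FALSE, he = he, t0 = t0, n = n,
                a_sys = numeric(n), a_por = numeric(n)))
  }
  stopifnot(inherits(exposure, "aspirin_exposure"))
  if (min(exposure$time_h) > t0 + 1e-9 || max(exposure$time_h) < t1 - 1e-9) {
    stop("exposure grid does not cover the required window [",
         t0, ", ", t1, "] h")
  }
  t <- seq(t0, t1, by = he)
  list(periodic = FALSE, he = he, t0 = t0, n = length(t),
       a_sys = stats::approx(exposure$time_h, exposure$a_systemic, t,
                             rule = 2)$y,
       a_por = stats::approx(exposure$time_h, exposure$a_portal, t,
                             rule = 2)$y)
}

#' COX-1 trajectory of a single megakaryocyte unit
#'
#' Integrates the MK COX-1 amount from birth at `tau` through maturation
#' and platelet generation, with de novo synthesis, degradation, transfer
#' to platelets and saturable acetylation driven by the systemic aspirin
#' concentration.
#'
#' @param tau Birth time of the MK unit (h).
#' @param mk An [mk_unit_params()].
#' @param pd An [acetylation_params()].
#' @param exposure An `aspirin_exposure` covering `[tau, tau + t1 + t2]`,
#'   or `NULL` for the aspirin-free trajectory.
#' @param plt A [platelet_params()] (only used to define the full age
#'   grid; defaults suffice).
#' @param h Integration step (h).
#' @return An object of class `mk_trajectory`: data frame with columns
#'   `age_h`, `x_amount_ng`, `x_conc_ng_per_ml`, `phase`.
#' @export
mk_cox1_trajectory <- function(tau, mk, pd, exposure = NULL,
                               plt = platelet_params(), h = 0.05) {
  etab <- exposure_table_interp(exposure, tau, tau + mk$t1 + mk$t2, h / 2)
  res <- integrate_cohorts(tau, mk, plt, pd, etab, h = h, keep_mk = TRUE,
                           ages_to = mk$t1 + mk$t2)
  keep <- res$ages_mk <= mk$t1 + mk$t2
  out <- data.frame(age_h = res$ages_mk[keep],
                    x_amount_ng = res$xm[1, keep],
                    x_conc_ng_per_ml = res$xm[1, keep] /
                      res$profiles$vmk[2 * seq_len(sum(keep)) - 1L],
                    phase = ifelse(res$ages_mk[keep] < mk$t1,
                                   "maturation", "generation"))
  structure(out, tau = tau, mk = mk, pd = pd, h = h,
            class = c("mk_trajectory", class(out)))
}

#' COX-1 trajectory of the platelet progeny of one MK unit
#'
#' Integrates platelet COX-1 through the generation, activity and death
#' phases. The only input flux is the transfer `k5 * x_MK` during
#' generation; platelets are anucleate so no synthesis occurs in any
#' platelet phase. Acetylation is driven by the 75/25-weighted systemic
#' and portal aspirin concentrations.
#'
#' @param mk_traj An [mk_cox1_trajectory()] result (its MK parameters and
#'   birth time are reused).
#' @param plt A [platelet_params()].
#' @param pd An [acetylation_params()].
#' @param exposure An `aspirin_exposure` covering
#'   `[tau + t1, tau + t1 + t2 + t3a + t3b]`, or `NULL` for aspirin-free.
#' @param h Integration step (h).
#' @return An object of class `platelet_trajectory`: data frame with
#'   columns `age_h`, `x_amount_ng`, `x_conc_ng_per_ml`, `phase`, covering
#'   ages `[0, t1 + t2 + t3a + t3b]`; the amount is zero before age `t1`.
#' @export
platelet_cox1_trajectory <- function(mk_traj, plt, pd, exposure = NULL,
                                     h = attr(mk_traj, "h")) {
  stopifnot(inherits(mk_traj, "mk_trajectory"))
  tau <- attr(mk_traj, "tau")
  mk <- attr(mk_traj, "mk")
  L <- mk$t1 + mk$t2 + plt$t3a + plt$t3b
  etab <- exposure_table_interp(exposure, tau, tau + L, h / 2)
  res <- integrate_cohorts(tau, mk, plt, pd, etab, h = h)
  jj <- 2 * seq_along(res$ages) - 1L
  out <- data.frame(age_h = res$ages,
                    x_amount_ng = res$xp[1, ],
                    x_conc_ng_per_ml = res$xp[1, ] / res$profiles$vp[jj],
                    phase = res$profiles$phase[jj])
  out$x_conc_ng_per_ml[out$x_amount_ng == 0] <- 0
  structure(out, tau = tau, mk = mk, plt = plt, pd = pd, h = h,
            class = c("platelet_trajectory", class(out)))
}
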