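# Anchored default for the maximal acetylation flux lambda (ng/h): the
# value at which the healthy scenario's steady trough under chronic
# 100 mg q.d. equals 3.0% of basal serum TXB2 with all other defaults.
# Recompute with anchor_healthy(); a regression test guards the anchor.
.anchored_lambda_default <- 403.6055

#' Full model parameter set
#'
#' Bundles the PK, acetylation, MK-unit and platelet parameter sets with
#' the whole-body aggregation settings. Scenario presets modify `f1`,
#' `count_fold` and the MK lifespan on top of this set (see
#' [make_scenario()]).
#'
#' @param pk A [pk_params()].
#' @param pd An [acetylation_params()].
#' @param mk An [mk_unit_params()].
#' @param plt A [platelet_params()].
#' @param gamma_g Exponent of the capacity-to-TXB2 map
#'   `g(X) = 100 * (X / X_ref)^gamma_g` (percent of basal), `>= 1`.
#' @param basal_ng_ml Mean pre-aspirin serum TXB2 (ng/ml) used to convert
#'   percent of basal to ng/ml; 575 ng/ml in aspirin-naive PV.
#' @param delta_tau Birth spacing of MK cohorts (h); one cohort per hour
#'   by default.
#' @param h ODE integration step (h).
#' @param dt_eval Evaluation resolution of the whole-body time course (h).
#' @return An object of class `model_params`.
#' @export
model_params <- function(pk = pk_params(), pd = acetylation_params(),
                         mk = mk_unit_params(), plt = platelet_params(),
                         gamma_g = 1, basal_ng_ml = 575,
                         delta_tau = 1, h = 0.05, dt_eval = 0.25) {
  if (gamma_g < 1) stop("`gamma_g` must be >= 1")
  if (basal_ng_ml <= 0) stop("`basal_ng_ml` must be > 0")
  stopifnot(abs(delta_tau / dt_eval - round(delta_tau / dt_eval)) < 1e-9,
            abs(dt_eval / h - round(dt_eval / h)) < 1e-9)
  structure(list(pk = pk, pd = pd, mk = mk, plt = plt,
                 gamma_g = gamma_g, basal_ng_ml = basal_ng_ml,
                 delta_tau = delta_tau, h = h, dt_eval = dt_eval),
            class = "model_params")
}

#' Map whole-body COX-1 capacity to serum TXB2
#'
#' `txb2_map()` calibrates the monotone map `g` against the aspirin-free
#' steady-state capacity `x_ref` of the active scenario, so that
#' `g(0) = 0` and `g(x_ref) = 100%` of basal. `cox1_to_txb2()` applies
#' it, returning percent of basal and ng/ml (`ng/ml = % x basal / 100`).
#'
#' @param x_ref Aspirin-free steady-state whole-body COX-1 (ng).
#' @param basal_ng_ml Pre-aspirin basal serum TXB2 (ng/ml).
#' @param gamma_g Map exponent (`>= 1`).
#' @return For `txb2_map()`, an object of class `txb2_map`; for
#'   `cox1_to_txb2()`, a data frame with columns `pct_basal`, `ng_ml`.
#' @examples
#' m <- txb2_map(x_ref = 1000)
#' cox1_to_txb2(c(0, 30, 1000), m)
#' @export
txb2_map <- function(x_ref, basal_ng_ml = 575, gamma_g = 1) {
  if (!is.finite(x_ref) || x_ref <= 0) {
    stop("`x_ref` must be a positive aspirin-free steady-state capacity; ",
         "calibrate the map before use")
  }
  structure(list(x_ref = x_ref, basal_ng_ml = basal_ng_ml,
                 gamma_g = gamma_g),
            class = "txb2_map")
}

#' @param X Whole-body COX-1 capacity values (ng), `>= 0`.
#' @param map A calibrated [txb2_map()].
#' @rdname txb2_map
#' @export
cox1_to_txb2 <- function(X, map) {
  if (!inherits(map, "txb2_map")) stop("`map` must be a calibrated txb2_map")
  if (any(X < 0)) stop("`X` must be >= 0")
  pct <- 100 * (X / map$x_ref)^map$gamma_g
  data.frame(pct_basal = pct, ng_ml = pct * map$basal_ng_ml / 100)
}

#' Aggregate platelet COX-1 over an ensemble of birth cohorts
#'
#' Whole-body COX-1 capacity at time `t` is the sum of the platelet COX-1
#' amounts of all cohorts alive at `t`, i.e. cohorts born between
#' `t - t1 - t3` and `t - t1`.
#'
#' @param ensemble A list of [platelet_cox1_trajectory()] results with
#'   uniformly spaced birth times.
#' @param t Evaluation time(s) (h).
#' @param check Verify that the ensemble's birth times span the full
#'   contributing window for every `t`.
#' @return Numeric vector of capacities `X(t)` (ng).
#' @export
aggregate_cox1 <- function(ensemble, t, check = TRUE) {
  stopifnot(length(ensemble) > 0)
  taus <- vapply(ensemble, attr, numeric(1), "tau")
  mk <- attr(ensemble[[1]], "mk")
  plt <- attr(ensemble[[1]], "plt")
  L <- mk$t1 + mk$t2 + plt$t3a + plt$t3b
  if (check && length(ensemble) > 1) {
    if (length(taus) > 2 && max(abs(diff(diff(sort(taus))))) > 1e-9) {
      stop("cohort birth times must be uniformly spaced")
    }
    if (any(t - L < min(taus) - 1e-9) || any(t - mk$t1 > max(taus) + 1e-9)) {
      stop("ensemble does not cover the contributing birth window ",
           "[t - t1 - t3, t - t1] for every evaluation time")
    }
  }
  vapply(t, function(ti) {
    sum(vapply(ensemble, function(tr) {
      age <- ti - attr(tr, "tau")
      if (age < 0 || age > L) return(0)
      stats::approx(tr$age_h, tr$x_amount_ng, age, rule = 2)$y
    }, numeric(1)))
  }, numeric(1))
}

# ---- internal whole-body engines ------------------------------------------

# Sum stored cohort platelet amounts into X(t). `xp` is [cohort, age]
# with ages seq(0, L, dt); `tau_of_row(tau)` maps a birth time to its row.
aggregate_store <- function(t_vec, xp, ages, dt, dtau, t1, L, tau_row) {
  vapply(t_vec, function(t) {
    j_lo <- ceiling((t - L) / dtau - 1e-9)
    j_hi <- floor((t - t1) / dtau + 1e-9)
    taus <- seq(j_lo, j_hi) * dtau
    age_idx <- round((t - taus) / dt) + 1L
    sum(xp[cbind(tau_row(taus), age_idx)])
  }, numeric(1))
}

# Aspirin-free reference capacity on the same age-sampling convention as
# the forced run, as a function of the fractional birth-phase offset of
# the evaluation time. Keeps g(X)/g(X_ref) exactly 1 under zero dosing.
# The single aspirin-free cohort trajectory is memoised per parameter set.
.ref_cache <- new.env(parent = emptyenv())

reference_capacity <- function(t_vec, mp) {
  mk <- mp$mk
  L <- mk$t1 + mk$t2 + mp$plt$t3a + mp$plt$t3b
  key <- paste(c(unlist(mk), unlist(mp$plt), unlist(mp$pd),
                 mp$h, mp$dt_eval), collapse = "|")
  xp0 <- .ref_cache[[key]]
  if (is.null(xp0)) {
    etab0 <- exposure_table_interp(NULL, 0, L, mp$h / 2)
    res0 <- integrate_cohorts(0, mk, mp$plt, mp$pd, etab0, h = mp$h,
                              keep_every = round(mp$dt_eval / mp$h))
    xp0 <- res0$xp[1, ]
    .ref_cache[[key]] <- xp0
  }
  dt <- mp$dt_eval
  vapply(t_vec, function(t) {
    j_lo <- ceiling((t - L) / mp$delta_tau - 1e-9)
    j_hi <- floor((t - mk$t1) / mp$delta_tau + 1e-9)
    ages <- t - seq(j_lo, j_hi) * mp$delta_tau
    sum(xp0[round(ages / dt) + 1L])
  }, numeric(1))
}

# Periodic steady-state whole-body TXB2 under a chronic regimen.
# Returns the time course over one dosing day (t in [0, 24), pre-dose
# instant at t = 0) plus scalar summaries.
steady_engine <- function(mp, dose_mg, regimen) {
  period <- dosing_interval(regimen)
  mk <- mp$mk
  L <- mk$t1 + mk$t2 + mp$plt$t3a + mp$plt$t3b
  etab <- exposure_table_periodic(0, dose_mg, period, mp$pk, mp$h / 2)
  phases <- seq(0, period - mp$delta_tau, by = mp$delta_tau)
  res <- integrate_cohorts(phases, mk, mp$plt, mp$pd, etab, h = mp$h,
                           keep_every = round(mp$dt_eval / mp$h))
  t_eval <- seq(0, 24 - mp$dt_eval, by = mp$dt_eval)
  tau_row <- function(taus) round((taus %% period) / mp$delta_tau) + 1L
  X <- aggregate_store(t_eval, res$xp, res$ages, mp$dt_eval, mp$delta_tau,
                       mk$t1, L, tau_row)
  Xref <- reference_capacity(t_eval, mp)
  pct <- 100 * (X / Xref)^mp$gamma_g
  list(time_h = t_eval, X = X, x_ref = Xref, pct_basal = pct,
       trough_pct = pct[1], max_pct = max(pct),
       trough_ng_ml = pct[1] * mp$basal_ng_ml / 100)
}

# Transient engine: whole-body TXB2 at `t_eval` under an arbitrary
# exposure table (already covering all needed cohort lifespans).
transient_engine <- function(mp, etab, t_eval) {
  mk <- mp$mk
  L <- mk$t1 + mk$t2 + mp$plt$t3a + mp$plt$t3b
  j_lo <- ceiling((min(t_eval) - L) / mp$delta_tau - 1e-9)
  j_hi <- floor((max(t_eval) - mk$t1) / mp$delta_tau + 1e-9)
  taus <- seq(j_lo, j_hi) * mp$delta_tau
  res <- integrate_cohorts(taus, mk, mp$plt, mp$pd, etab, h = mp$h,
                           keep_every = round(mp$dt_eval / mp$h))
  tau_row <- function(tt) round((tt - taus[1]) / mp$delta_tau) + 1L
  X <- aggregate_store(t_eval, res$xp, res$ages, mp$dt_eval, mp$delta_tau,
                       mk$t1, L, tau_row)
  Xref <- reference_capacity(t_eval, mp)
  pct <- 100 * (X / Xref)^mp$gamma_g
  list(time_h = t_eval, X = X, x_ref = Xref, pct_basal = pct)
}

#' Whole-body serum TXB2 time course for a scenario and schedule
#'
#' Simulates the whole-body COX-1 capacity under the given dosing
#' schedule, starting aspirin-free, and maps it to serum TXB2. The
#' simulation must be long enough for the periodic steady state to be
#' reached (default 45 days); the final 3 days are reported.
#'
#' @param scenario A scenario name or [make_scenario()] preset.
#' @param schedule A [dose_schedule()] (use [regimen_schedule()] for
#'   chronic regimens; an empty schedule gives 100% of basal throughout).
#' @param days Total simulated days (burn-in included), `>= 40`
#'   recommended for steady state.
#' @param params A [model_params()] set (anchored defaults).
#' @param report_days Number of final days reported.
#' @return An object of class `txb2_time_course`: data frame with columns
#'   `time_h`, `X_ng`, `pct_basal`, `txb2_ng_ml`, with summary attributes
#'   `trough_pct`, `trough_ng_ml`, `max_pct` over the final dosing day.
#' @export
run_whole_body <- function(scenario, schedule, days = 45,
                           params = model_params(), report_days = 3) {
  mp <- apply_scenario(params, scenario)
  mk <- mp$mk
  L <- mk$t1 + mk$t2 + mp$plt$t3a + mp$plt$t3b
  t_end <- days * 24
  t_eval <- seq(t_end - report_days * 24, t_end, by = mp$dt_eval)
  t0 <- min(t_eval) - L - mk$t1 - mp$h
  t0 <- floor(t0 / mp$delta_tau) * mp$delta_tau
  if (nrow(schedule) && max(schedule$time) > t_end) {
    stop("dose events must not lie beyond the simulated end (", t_end,
         " h)")
  }
  etab <- exposure_table_transient(t0, t_end + mk$t1 + L, mp$h / 2,
                                   base = NULL, extra_doses = schedule,
                                   pk = mp$pk)
  res <- transient_engine(mp, etab, t_eval)
  last_day <- res$time_h >= t_end - 24
  out <- data.frame(time_h = res$time_h, X_ng = res$X,
                    pct_basal = res$pct_basal,
                    txb2_ng_ml = res$pct_basal * mp$basal_ng_ml / 100)
  structure(out,
            scenario = scenario_name(scenario),
            regimen = attr(schedule, "label"),
            trough_pct = res$pct_basal[length(res$pct_basal)],
            trough_ng_ml = res$pct_basal[length(res$pct_basal)] *
              mp$basal_ng_ml / 100,
            max_pct = max(res$pct_basal[last_day]),
            class = c("txb2_time_course", "data.frame"))
}

#' @export
print.txb2_time_course <- function(x, ...) {
  cat("<txb2_time_course> scenario: ", attr(x, "scenario"),
      ", regimen: ", attr(x, "regimen"), "\n",
      "  trough ", signif(attr(x, "trough_pct"), 4), "% of basal (",
      signif(attr(x, "trough_ng_ml"), 4), " ng/ml), interval max ",
      signif(attr(x, "max_pct"), 4), "%\n", sep = "")
  invisible(x)
}
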