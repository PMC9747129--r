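# Shared fixtures: a fast small-lifespan model for property/oracle tests,
# independent brute-force Euler oracles, and a cache for the expensive
# full-scale runs shared between acceptance and property tests.

small_mk <- function(...) {
  mk_unit_params(t1 = 24, t2 = 6, ...)
}

small_plt <- function(...) {
  platelet_params(t3a = 24, t3b = 12, ...)
}

small_params <- function(...) {
  model_params(mk = small_mk(), plt = small_plt(), ...)
}

# A small-lifespan scenario preset so regimen experiments can run on the
# fast model (apply_scenario would otherwise restore full lifespans).
small_scenario <- function(base = "pv_poor") {
  sc <- make_scenario(base)
  sc$mk_lifespan_days <- 1
  sc$plt_lifespan_days <- c(t3a = 1, t3b = 0.5)
  sc
}

# Brute-force explicit-Euler oracle for the PK system (independent of the
# analytic eigen-decomposition path).
euler_pk <- function(schedule, pk, t_end, h = 1e-3) {
  nt <- floor(t_end / h) + 1L
  times <- (seq_len(nt) - 1) * h
  x <- c(0, 0, 0, 0)  # gut, portal, central, peripheral
  ab <- as <- numeric(nt)
  doses <- schedule$time + pk$lag
  for (i in seq_len(nt - 1L)) {
    t <- times[i]
    hit <- which(doses > t - 1e-12 & doses <= t + h - 1e-12)
    dx <- c(-pk$ka * x[1],
            pk$ka * x[1] - pk$k_pc * x[2] + pk$k_cp * x[3],
            pk$k_pc * x[2] - (pk$k_cp + pk$k_ct + pk$ke) * x[3] +
              pk$k_tc * x[4],
            pk$k_ct * x[3] - pk$k_tc * x[4])
    x <- x + h * dx
    if (length(hit)) x[1] <- x[1] + sum(schedule$dose[hit])
    ab[i + 1L] <- x[3] / pk$v_central
    as[i + 1L] <- x[2] / pk$v_portal
  }
  data.frame(time_h = times, a_systemic = ab, a_portal = as)
}

# Brute-force Euler oracle for one MK unit + its platelet progeny. The
# coefficient profiles are re-derived here from the parameter definitions,
# independently of cohort_profiles(); exposure is supplied as two functions
# of time.
euler_cohort <- function(tau, mk, plt, pd, a_sys = function(t) 0,
                         a_por = function(t) 0, h = 1e-3) {
  L <- mk$t1 + mk$t2 + plt$t3a + plt$t3b
  g <- log(mk$v_growth_fold) / mk$t1
  v_top <- mk$count_fold * mk$v0 * mk$v_growth_fold
  v_act <- v_top * (1 - exp(-mk$k5 * mk$t2))
  phi <- function(x, v, a) {
    s <- (max(x, 0) / v * a)^pd$n
    pd$lambda * s / (pd$km^pd$n + s)
  }
  nt <- floor(L / h) + 1L
  xm <- xp <- 0
  out_u <- seq(0, L, by = 0.25)
  out_m <- out_p <- numeric(length(out_u))
  nxt <- 1L
  for (i in seq_len(nt)) {
    u <- (i - 1) * h
    if (nxt <= length(out_u) && u >= out_u[nxt] - h / 2) {
      out_m[nxt] <- xm
      out_p[nxt] <- xp
      nxt <- nxt + 1L
    }
    aB <- a_sys(tau + u)
    aS <- a_por(tau + u)
    if (u < mk$t1 + mk$t2) {
      p <- mk$f1 * mk$count_fold * mk$p0 *
        (1 + mk$p_peak_fold * exp(-u / mk$p_peak_tau))
      k5u <- if (u >= mk$t1) mk$k5 else 0
      vmk <- if (u < mk$t1) mk$count_fold * mk$v0 * exp(g * u)
      else v_top * exp(-mk$k5 * (u - mk$t1))
      dm <- p - mk$kd * xm - k5u * xm - phi(xm, vmk, mk$aspirin_frac * aB)
    } else {
      k5u <- 0
      dm <- 0
      xm <- 0
    }
    vp <- if (u < mk$t1) NA
    else if (u < mk$t1 + mk$t2) v_top * (1 - exp(-mk$k5 * (u - mk$t1)))
    else if (u < mk$t1 + mk$t2 + plt$t3a) v_act
    else v_act * exp(-plt$k6 * (u - mk$t1 - mk$t2 - plt$t3a))
    k6u <- if (u >= mk$t1 + mk$t2 + plt$t3a) plt$k6 else 0
    dp <- if (u < mk$t1) 0
    else k5u * xm - k6u * xp -
      phi(xp, max(vp, 1e-12), plt$w_sys * aB + plt$w_portal * aS)
    xm <- max(xm + h * dm, 0)
    xp <- max(xp + h * dp, 0)
  }
  data.frame(age_h = out_u, xm = out_m, xp = out_p)
}

# Cache for expensive full-scale runs shared across test files.
.acc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.acc_cache[[key]])) .acc_cache[[key]] <- force(expr)
  .acc_cache[[key]]
}

cached_steady <- function(scenario, dose_mg, regimen) {
  key <- paste("steady", scenario, dose_mg, regimen, sep = "_")
  cached(key, steady_state_profile(scenario, dose_mg, regimen,
                                   params = model_params()))
}

cached_missed <- function(regimen, dose_mg = 100, scenario = "pv_poor") {
  key <- paste("miss", scenario, dose_mg, regimen, sep = "_")
  cached(key, missed_dose_experiment(scenario, dose_mg, regimen,
                                     params = model_params(),
                                     horizon_days = 10))
}

withr_like_tempdir <- function() {
  d <- tempfile("aspirinpd")
  dir.create(d)
  d
}

# Full-lifespan parameter set with a coarser integration/evaluation grid,
# for smoke tests that must go through the scenario presets.
small_params_for_preset <- function() {
  model_params(h = 0.1, dt_eval = 0.2)
}
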