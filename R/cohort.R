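#' Virtual PV cohort generator parameters
#'
#' Parameters of the seeded generator that emulates the study cohort's
#' marginal distributions and rank-correlation structure: 49 aspirin-treated
#' PV patients with median platelet count 344 x10^3/ul, median serum TXB2
#' 8.2 ng/ml, median urinary TX metabolite (TXM) ~509 pg/mg creatinine, and
#' positive rank correlations platelets-TXB2 (0.39), TXM-TXB2 (0.52) and
#' TXM-8-iso-PGF2a (0.44).
#'
#' The structural model is a log-normal chain:
#' `log platelet_count ~ N(log(344), sdlog_platelets^2)` (truncated at the
#' 150 x10^3/ul eligibility floor);
#' `log serum_txb2 = log(8.2) + b_count_txb2 * (log count - log 344) + z`,
#' `z ~ N(0, sdlog_per_platelet^2)` — at `b_count_txb2 = 1` this is exactly
#' per-platelet TXB2 times the platelet count;
#' `log txm = log(509) + b_txb2_txm * (log txb2 - log 8.2) +`
#' `b_iso_txm * (log iso - log 960) + e`, `e ~ N(0, sdlog_txm_resid^2)`.
#'
#' Default dispersions and dependence coefficients were derived in closed
#' form from the printed statistics (Pearson-on-logs coefficients converted
#' from the target Spearman values via the bivariate-normal relation
#' `rho_p = 2 sin(pi rho_s / 6)`) and then frozen.
#'
#' @param n Cohort size.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param med_platelets,sdlog_platelets Median (x10^3/ul) and log-sd of the
#'   platelet count.
#' @param min_platelets Eligibility floor (x10^3/ul); values below are
#'   resampled.
#' @param med_txb2 Median serum TXB2 (ng/ml).
#' @param sdlog_per_platelet Log-sd of the per-platelet TXB2 dial.
#' @param b_count_txb2 Coupling of serum TXB2 to the platelet count
#'   (1 = strict proportionality to platelet mass; 0 = independent).
#' @param med_txm,med_iso Medians of urinary TXM and 8-iso-PGF2a (pg/mg
#'   creatinine).
#' @param sdlog_iso Log-sd of 8-iso-PGF2a.
#' @param b_txb2_txm,b_iso_txm,sdlog_txm_resid TXM link coefficients and
#'   residual log-sd.
#' @param p_hu,p_thrombosis,p_female Prevalences of hydroxyurea use, prior
#'   thrombosis and female sex (inert covariates).
#' @param threshold_ng_ml Adequacy threshold on serum TXB2 (ng/ml).
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n = 49, seed = 1,
                          med_platelets = 344, sdlog_platelets = 0.40,
                          min_platelets = 150,
                          med_txb2 = 8.2, sdlog_per_platelet = 0.9015,
                          b_count_txb2 = 1,
                          med_txm = 509, med_iso = 960, sdlog_iso = 0.50,
                          b_txb2_txm = 0.26176, b_iso_txm = 0.43843,
                          sdlog_txm_resid = 0.34014,
                          p_hu = 0.77, p_thrombosis = 13 / 49,
                          p_female = 16 / 49,
                          threshold_ng_ml = 10) {
  if (n < 2) stop("`n` must be >= 2")
  if (min(sdlog_platelets, sdlog_per_platelet, sdlog_iso,
          sdlog_txm_resid) <= 0) {
    stop("dispersions must be > 0")
  }
  structure(as.list(environment()), class = "cohort_params")
}

#' Generate a seeded virtual PV cohort
#'
#' Draws `params$n` patient records from the log-normal chain described in
#' [cohort_params()]. Identical parameters and seed give an identical
#' cohort; the global RNG state is left untouched.
#'
#' @param params A [cohort_params()].
#' @return A data frame of class `synthetic_cohort` with one row per
#'   patient: `id`, `age`, `sex`, `platelet_count` (x10^3/ul),
#'   `serum_txb2` (ng/ml), `per_platelet_txb2` (pg per 10^6 platelets, the
#'   printed "pg/platelet" scale), `urinary_txm`, `iso_pgf2a` (pg/mg
#'   creatinine), `on_hydroxyurea`, `prior_thrombosis`.
#' @examples
#' coh <- generate_cohort(cohort_params(seed = 42))
#' median(coh$serum_txb2)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(p$seed)

  count <- exp(stats::rnorm(p$n, log(p$med_platelets), p$sdlog_platelets))
  for (it in 1:100) {
    low <- count < p$min_platelets
    if (!any(low)) break
    count[low] <- exp(stats::rnorm(sum(low), log(p$med_platelets),
                                   p$sdlog_platelets))
  }
  serum <- exp(log(p$med_txb2) +
                 p$b_count_txb2 * (log(count) - log(p$med_platelets)) +
                 stats::rnorm(p$n, 0, p$sdlog_per_platelet))
  iso <- exp(stats::rnorm(p$n, log(p$med_iso), p$sdlog_iso))
  txm <- exp(log(p$med_txm) +
               p$b_txb2_txm * (log(serum) - log(p$med_txb2)) +
               p$b_iso_txm * (log(iso) - log(p$med_iso)) +
               stats::rnorm(p$n, 0, p$sdlog_txm_resid))
  age <- pmin(pmax(round(stats::rnorm(p$n, 67, 9)), 40), 92)
  sex <- ifelse(stats::runif(p$n) < p$p_female, "F", "M")
  hu <- stats::runif(p$n) < p$p_hu
  thr <- stats::runif(p$n) < p$p_thrombosis

  out <- data.frame(id = sprintf("PV%03d", seq_len(p$n)),
                    age = age, sex = sex,
                    platelet_count = count,
                    serum_txb2 = serum,
                    per_platelet_txb2 = per_platelet_txb2(serum, count),
                    urinary_txm = txm,
                    iso_pgf2a = iso,
                    on_hydroxyurea = hu,
                    prior_thrombosis = thr)
  structure(out, params = params,
            class = c("synthetic_cohort", "data.frame"))
}

#' Platelet-count-corrected serum TXB2
#'
#' Expresses serum TXB2 per platelet on the printed "pg/platelet" scale,
#' numerically pg per 10^6 platelets:
#' `serum_txb2 (ng/ml) / platelet_count (x10^3/ul) x 1000`.
#' E.g. 8.2 ng/ml at 344 x10^3/ul gives 23.8 (~ printed 24).
#'
#' @param serum_txb2 Serum TXB2 (ng/ml), `>= 0`.
#' @param platelet_count Platelet count (x10^3/ul), `> 0`.
#' @return Per-platelet TXB2 (pg per 10^6 platelets).
#' @export
per_platelet_txb2 <- function(serum_txb2, platelet_count) {
  if (any(platelet_count <= 0)) stop("`platelet_count` must be > 0")
  if (any(serum_txb2 < 0)) stop("`serum_txb2` must be >= 0")
  serum_txb2 / platelet_count * 1000
}

#' Classify a cohort by the serum TXB2 adequacy threshold
#'
#' Serum TXB2 at or below 10 ng/ml, 24 h after dosing, marks adequate
#' (optimal) platelet COX-1 inhibition; the boundary value belongs to the
#' adequate group.
#'
#' @param cohort A [generate_cohort()] result (or any data frame with a
#'   `serum_txb2` column).
#' @param threshold_ng_ml Threshold (ng/ml).
#' @return The cohort with an added factor column `inhibition` with
#'   levels `adequate` / `inadequate`.
#' @export
classify_threshold <- function(cohort, threshold_ng_ml = 10) {
  if (nrow(cohort) == 0) stop("empty cohort")
  cohort$inhibition <- factor(ifelse(cohort$serum_txb2 <= threshold_ng_ml,
                                     "adequate", "inadequate"),
                              levels = c("adequate", "inadequate"))
  cohort
}

.cor_vars <- c("platelet_count", "serum_txb2", "per_platelet_txb2",
               "urinary_txm", "iso_pgf2a")

#' Spearman correlation matrix of the cohort biomarkers
#'
#' @param cohort A cohort data frame with the biomarker columns.
#' @param vars Columns to correlate.
#' @return Symmetric Spearman correlation matrix with unit diagonal;
#'   correlations involving a constant column are `NA` (with a warning).
#' @export
cohort_correlations <- function(cohort, vars = .cor_vars) {
  if (nrow(cohort) < 3) stop("need at least 3 patients")
  m <- as.matrix(cohort[, vars])
  const <- apply(m, 2, function(x) max(x) - min(x) < .Machine$double.eps)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (any(const)) {
    warning("constant column(s): ", paste(vars[const], collapse = ", "),
            "; their correlations are undefined and reported as NA")
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- 1
  rho
}

#' Summarize a virtual cohort
#'
#' Medians with 2.5-97.5 percentile intervals per biomarker, counts and
#' per-group medians for the 10 ng/ml threshold grouping, and the
#' Spearman correlation matrix.
#'
#' @param cohort A [generate_cohort()] result.
#' @param threshold_ng_ml Adequacy threshold (ng/ml).
#' @return An object of class `cohort_summary`.
#' @export
cohort_summary <- function(cohort, threshold_ng_ml = 10) {
  cls <- classify_threshold(cohort, threshold_ng_ml)
  qfun <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  marg <- t(vapply(.cor_vars, function(v) qfun(cohort[[v]]), numeric(3)))
  colnames(marg) <- c("median", "p2.5", "p97.5")
  counts <- table(cls$inhibition)
  grp_med <- t(vapply(.cor_vars, function(v) {
    tapply(cls[[v]], cls$inhibition, stats::median)
  }, numeric(2)))
  structure(list(n = nrow(cohort),
                 marginals = marg,
                 group_counts = counts,
                 group_medians = grp_med,
                 spearman = cohort_correlations(cohort),
                 threshold_ng_ml = threshold_ng_ml),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n = ", x$n, "\n", sep = "")
  print(round(x$marginals, 2))
  cat("inhibition (threshold ", x$threshold_ng_ml, " ng/ml): adequate ",
      x$group_counts[["adequate"]], ", inadequate ",
      x$group_counts[["inadequate"]], "\n", sep = "")
  cat("Spearman correlations:\n")
  print(round(x$spearman, 2))
  invisible(x)
}
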