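#' Linear trapezoidal AUC over an observed window
#'
#' @param profile a [conc_profile()] (or anything with `times`/`values`).
#' @param t_start,t_end window limits, h; only observed points inside the
#'   closed window are used (no interpolation at the boundaries).
#' @return area in ng*h/mL.
#' @examples
#' auc_trapezoid(conc_profile(c(0, 1, 2), c(100, 50, 25))) # 112.5
#' @export
auc_trapezoid <- function(profile, t_start = -Inf, t_end = Inf) {
  t <- profile$times; v <- profile$values
  keep <- t >= t_start & t <= t_end
  t <- t[keep]; v <- v[keep]
  if (length(t) < 2) stop("need at least 2 points inside the window")
  sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
}

# AUMC (first-moment area) by the same linear trapezoid on t*C
.aumc_trapezoid <- function(t, v) sum(diff(t) * (t[-1] * v[-1] + t[-length(t)] * v[-length(v)]) / 2)

#' Terminal log-linear slope (lambda_z)
#'
#' Log-linear least squares on the terminal points. The point set is chosen
#' by the usual automatic rule: among all suffixes of at least 3 strictly
#' post-Cmax positive observations (Cmax itself excluded), take the fit with
#' the best adjusted r-squared; ties go to the larger point set. A fit is
#' only accepted with a negative slope; otherwise the result is flagged
#' (`lambda_z = NA`) and downstream extrapolated quantities are omitted.
#'
#' @param profile a [conc_profile()].
#' @return list with `lambda_z` (1/h), `t_half`, `r2_adj`, `points_used`
#'   (indices into the profile), `n_points`.
#' @export
fit_lambda_z <- function(profile) {
  t <- profile$times; v <- profile$values
  imax <- which.max(v)
  cand <- which(seq_along(t) > imax & v > 0)
  flagged <- list(lambda_z = NA_real_, t_half = NA_real_, r2_adj = NA_real_,
                  points_used = integer(0), n_points = 0L)
  if (length(cand) < 3) return(flagged)
  best <- NULL
  for (start in seq_len(length(cand) - 2)) {
    idx <- cand[start:length(cand)]
    x <- t[idx]; y <- log(v[idx])
    n <- length(idx)
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) next
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    r2a <- 1 - (1 - r2) * (n - 1) / (n - 2)
    # strict improvement beats; ties (within 1e-10) keep the earlier, larger set
    if (is.null(best) || r2a > best$r2_adj + 1e-10)
      best <- list(lambda_z = -unname(slope), r2_adj = r2a, points_used = idx,
                   n_points = n)
  }
  if (is.null(best)) return(flagged)
  best$t_half <- log(2) / best$lambda_z
  best[c("lambda_z", "t_half", "r2_adj", "points_used", "n_points")]
}

# apply the BLQ policy: leading BLQ -> 0; embedded/trailing BLQ -> dropped
.quantifiable_profile <- function(subject) {
  t <- subject$times; dv <- subject$dv; blq <- subject$blq
  iq <- which(!blq)
  if (!length(iq)) return(NULL)
  first_q <- min(iq)
  keep_zero <- which(blq & seq_along(t) < first_q)
  keep <- sort(c(keep_zero, iq))
  list(times = t[keep], values = ifelse(blq[keep], 0, dv[keep]),
       first_q = first_q)
}

#' Per-subject non-compartmental analysis
#'
#' Linear trapezoidal AUC to the last quantifiable point with log-linear tail
#' extrapolation (`AUC0_INF = AUC0_last + C_last / lambda_z`), first-moment
#' area with the matching tail (`C_last (t_last/lambda_z + 1/lambda_z^2)`),
#' MRT = AUMC/AUC, clearance `Cl = 1000 dose / AUC0_INF` (apparent `Cl/F`
#' after oral dosing), `Vdz = Cl / lambda_z`, and for intravenous subjects
#' `Vdss = Cl * MRT`. Cmax/Tmax are the global maximum (double peaks
#' allowed). BLQ records before the first quantifiable point enter as zero;
#' embedded and trailing BLQ records are excluded.
#'
#' @param subject a `pk_subject` (see [simulate_study()]), needing >= 3
#'   quantifiable observations.
#' @return object of class `nca_result`: named list of the NCA parameters,
#'   including `pct_extrapolated` (flagged via `extrapolation_flag` when
#'   > 20%), `AUC_over_dose`, `n_lambda_points` and `r2_adj`.
#' @export
nca_subject <- function(subject) {
  if (is.null(subject$dose) || !is.finite(subject$dose) || subject$dose <= 0)
    stop("subject needs a positive dose")
  if (any(!is.na(subject$dv) & subject$dv < 0))
    stop("negative unflagged concentrations in subject ", subject$id)
  qp <- .quantifiable_profile(subject)
  if (is.null(qp) || sum(qp$values > 0) < 3)
    stop("subject ", subject$id, " has fewer than 3 quantifiable observations")
  prof <- conc_profile(qp$times, qp$values)
  lam <- fit_lambda_z(prof)
  auc_last <- auc_trapezoid(prof)
  aumc_last <- .aumc_trapezoid(prof$times, prof$values)
  n <- length(prof$times)
  c_last <- prof$values[n]; t_last <- prof$times[n]
  imax <- which.max(prof$values)
  iv <- subject$route == "iv"
  if (is.na(lam$lambda_z)) {
    auc_inf <- aumc_inf <- mrt <- cl <- vdz <- vdss <- NA_real_
    pct <- NA_real_
  } else {
    auc_inf <- auc_last + c_last / lam$lambda_z
    aumc_inf <- aumc_last + c_last * (t_last / lam$lambda_z + 1 / lam$lambda_z^2)
    mrt <- aumc_inf / auc_inf
    cl <- 1000 * subject$dose / auc_inf
    vdz <- cl / lam$lambda_z
    vdss <- if (iv) cl * mrt else NA_real_
    pct <- 100 * (auc_inf - auc_last) / auc_inf
  }
  structure(list(
    id = subject$id, group = subject$group, route = subject$route,
    dose = subject$dose,
    AUC0_last = auc_last, AUC0_INF = auc_inf, pct_extrapolated = pct,
    extrapolation_flag = isTRUE(pct > 20),
    lambda_z = lam$lambda_z, t_half = lam$t_half,
    Cmax = prof$values[imax], Tmax = prof$times[imax],
    MRT = mrt, Cl = cl, Vdss = vdss, Vdz = vdz,
    AUC_over_dose = auc_inf / subject$dose,
    n_lambda_points = lam$n_points, r2_adj = lam$r2_adj),
    class = "nca_result")
}

#' NCA over a whole study
#'
#' @param study a `pk_study`.
#' @return data frame with one row per subject (see [nca_subject()] fields).
#' @export
nca_study <- function(study) {
  stopifnot(inherits(study, "pk_study"))
  rows <- lapply(study, function(s) as.data.frame(unclass(nca_subject(s))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level mean +/- SD summary of NCA parameters
#'
#' Arithmetic mean and sample SD per group for every numeric NCA parameter
#' (dose-normalised AUC is computed per subject before averaging). Groups of
#' one subject report SD = 0 with `n = 1`.
#'
#' @param results data frame from [nca_study()] (or rbound `nca_result`s).
#' @return data frame: one row per (group, parameter) with mean, sd, n.
#' @export
nca_group_summary <- function(results) {
  stopifnot(nrow(results) >= 1)
  params <- setdiff(names(results)[vapply(results, is.numeric, TRUE)],
                    c("id", "group", "n_lambda_points"))
  out <- do.call(rbind, lapply(split(results, results$group), function(d) {
    do.call(rbind, lapply(params, function(p) {
      x <- d[[p]][is.finite(d[[p]])]
      data.frame(group = d$group[1], parameter = p,
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1) stats::sd(x) else 0,
                 n = length(x))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Relative bioavailability (dose-normalised AUC ratio)
#'
#' `Frel = (AUC_test / AUC_ref) * (dose_ref / dose_test)`, with extract doses
#' expressed as rutin equivalents.
#'
#' @param auc_test,auc_ref AUC0-INF of the test and reference treatments,
#'   ng*h/mL.
#' @param dose_test,dose_ref doses, mg/kg (rutin equivalent).
#' @return Frel (fold).
#' @examples
#' relative_bioavailability(3197.85, 7.4, 4095.34, 75) # ~7.9
#' @export
relative_bioavailability <- function(auc_test, dose_test, auc_ref, dose_ref) {
  x <- c(auc_test, dose_test, auc_ref, dose_ref)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all AUCs and doses must be finite and > 0")
  (auc_test / auc_ref) * (dose_ref / dose_test)
}
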