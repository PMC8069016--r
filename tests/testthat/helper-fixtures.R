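# Shared fixtures: published parameter values, independent closed forms and
# small hand-built datasets. Everything here is an oracle or a constructor,
# independent of the package internals it is used to check.

published_iv <- list(V = 0.0646, k = 1.47, k12 = 2.6, k21 = 13.6,
                     beta_V = 0.478, beta_k = 0.395,
                     omega_V = 0.306, omega_k = 0.147, corr = -0.701,
                     a = 38.9, b = 0.128)

published_oral <- list(ka1 = 0.104, ka2 = 0.411, F1 = 0.565, Tlag2 = 3.91,
                       V = 13.2, k = 1.42, k12 = 0.279, k21 = 0.268,
                       a = 8.87, b = 0.0457)

# independent bi-exponential solution of the two-compartment iv bolus model
biexp_oracle <- function(V, k, k12, k21, dose, t) {
  s <- k + k12 + k21
  r <- sqrt(s^2 - 4 * k21 * k)
  al <- (s + r) / 2
  be <- (s - r) / 2
  C0 <- 1000 * dose / V
  A <- C0 * (al - k21) / (al - be)
  B <- C0 * (k21 - be) / (al - be)
  A * exp(-al * t) + B * exp(-be * t)
}

# build a pk_study through the public CSV reader (no reaching into internals)
study_from_rows <- function(rows, lloq = 100) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("ID,TIME,DV,BLQ,AMT,ROUTE,SOURCE,DOSEGRP,GROUP", rows), path)
  read_pk_dataset(path, lloq = lloq)
}

# brute-force marginal likelihood for one subject with a single random
# effect on V (iv model): trapezoid integration over a dense eta grid
grid_loglik_oracle <- function(pop, subject, lloq = 100, step = 2e-3) {
  om <- pop$omega[["V"]]
  etas <- seq(-6 * om, 6 * om, by = step)
  psiV <- log(pop$fixed[["V"]] / (1 - pop$fixed[["V"]]))
  keep <- !subject$blq
  tt <- subject$times[keep]
  yy <- subject$dv[keep]
  dens <- vapply(etas, function(e) {
    Vi <- plogis(psiV + e)
    f <- biexp_oracle(Vi, pop$fixed[["k"]], pop$fixed[["k12"]],
                      pop$fixed[["k21"]], subject$dose, tt)
    sd <- pop$error[["a"]] + pop$error[["b"]] * f
    exp(sum(dnorm(yy, f, sd, log = TRUE)) + dnorm(e, 0, om, log = TRUE))
  }, numeric(1))
  log(sum((dens[-1] + dens[-length(dens)]) / 2 * step))
}
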