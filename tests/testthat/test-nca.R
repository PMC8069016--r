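test_that("trapezoidal AUC matches hand calculations and is additive", {
  p <- conc_profile(c(0, 1, 2), c(100, 50, 25))
  expect_equal(auc_trapezoid(p), (100 + 50) / 2 + (50 + 25) / 2)
  expect_equal(auc_trapezoid(conc_profile(c(0, 4), c(7, 7))), 28) # constant
  expect_equal(auc_trapezoid(conc_profile(c(0, 2), c(10, 0))), 10) # half-rect
  set.seed(2)
  t <- sort(runif(20, 0, 10))
  v <- runif(20, 0, 50)
  pr <- conc_profile(t, v)
  a <- t[8]
  expect_equal(auc_trapezoid(pr, t[1], a) + auc_trapezoid(pr, a, t[20]),
               auc_trapezoid(pr), tolerance = 1e-12)
  expect_error(auc_trapezoid(conc_profile(c(0, 1), c(1, 1)), 5, 6), "2 points")
})

test_that("terminal slope is exact on log-linear data", {
  t <- c(0.5, 1, 2, 4, 6, 8)
  pr <- conc_profile(t, 100 * exp(-0.5 * t))
  fit <- fit_lambda_z(pr)
  expect_equal(fit$lambda_z, 0.5, tolerance = 1e-10)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-10)
  expect_equal(fit$t_half, log(2) / 0.5, tolerance = 1e-10)
})

test_that("terminal point selection equals the exhaustive suffix search", {
  set.seed(7)
  for (rep in 1:5) {
    t <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12)
    v <- 50 * exp(1.5 * t) * exp(-2 * t) + 200 * exp(-0.6 * t)
    v <- v * exp(rnorm(length(t), 0, 0.15))
    pr <- conc_profile(t, v)
    got <- fit_lambda_z(pr)
    # oracle: brute force over all suffixes of >= 3 strictly post-Cmax points
    imax <- which.max(v)
    cand <- which(seq_along(t) > imax & v > 0)
    best <- NULL
    for (s in seq_len(length(cand) - 2)) {
      idx <- cand[s:length(cand)]
      fit <- lm(log(v[idx]) ~ t[idx])
      if (coef(fit)[2] >= 0) next
      r2a <- summary(fit)$adj.r.squared
      if (is.null(best) || r2a > best$r2a + 1e-10)
        best <- list(lambda = -unname(coef(fit)[2]), r2a = r2a, idx = idx)
    }
    expect_equal(got$lambda_z, best$lambda, tolerance = 1e-9)
    expect_identical(got$points_used, best$idx)
  }
  # no decreasing terminal phase -> flagged result
  flat <- fit_lambda_z(conc_profile(1:6, c(1, 5, 6, 7, 8, 9)))
  expect_true(is.na(flat$lambda_z))
})

test_that("NCA on a noise-free dense intravenous profile closes on the model", {
  # dense noise-free profile from the published fixed effects via the
  # public reader (dose 1.45 mg/kg, reference rat)
  p <- do.call(iv_params, published_iv[c("V", "k", "k12", "k21")])
  tg <- seq(0.001, 14, by = 0.01)
  prof <- simulate_iv(p, dose_event("iv_bolus", 1.45), tg)
  rows <- c("1,0,,0,1.45,iv,RU,D1.45,1",
            sprintf("1,%g,%g,0,,iv,RU,D1.45,1", tg, prof$values))
  st <- study_from_rows(rows, lloq = 0)
  r <- nca_subject(st[[1]])
  expect_equal(r$Cl, 0.0646 * 1.47, tolerance = 0.05)     # Cl -> V k = 0.095
  expect_equal(r$Cl, 0.095, tolerance = 0.05)
  expect_equal(r$MRT, (1 + 2.6 / 13.6) / 1.47, tolerance = 0.05)
  expect_equal(r$lambda_z, macro_constants(p)$beta, tolerance = 0.01)
  expect_equal(r$Vdss, r$Cl * r$MRT, tolerance = 1e-10)
  expect_lt(r$pct_extrapolated, 1)
})

test_that("one-compartment NCA identities hold", {
  t <- seq(0.01, 30, by = 0.05)
  C0 <- 5000
  rows <- c("1,0,,0,2,iv,RU,D2,1",
            sprintf("1,%g,%g,0,,iv,RU,D2,1", t, C0 * exp(-0.4 * t)))
  st <- study_from_rows(rows, lloq = 0)
  r <- nca_subject(st[[1]])
  expect_equal(r$Vdss, 1000 * 2 / C0, tolerance = 0.01)
  expect_equal(r$Vdz, 1000 * 2 / C0, tolerance = 0.01)
  expect_equal(r$t_half, log(2) / 0.4, tolerance = 0.01)
})

test_that("Cmax/Tmax take the global maximum of a double-peaked profile", {
  rows <- c("1,0,,0,10,oral,RU,D10,1",
            "1,1,300,0,,oral,RU,D10,1",
            "1,2,250,0,,oral,RU,D10,1",
            "1,4,180,0,,oral,RU,D10,1",
            "1,6,420,0,,oral,RU,D10,1",
            "1,8,260,0,,oral,RU,D10,1",
            "1,12,120,0,,oral,RU,D10,1")
  r <- nca_subject(study_from_rows(rows)[[1]])
  expect_equal(r$Tmax, 6)
  expect_equal(r$Cmax, 420)
})

test_that("extrapolated fraction shrinks as the sampling window extends", {
  p <- do.call(iv_params, published_iv[c("V", "k", "k12", "k21")])
  pct <- vapply(c(2, 4, 8), function(tend) {
    tg <- seq(0.01, tend, by = 0.01)
    prof <- simulate_iv(p, dose_event("iv_bolus", 1.45), tg)
    rows <- c("1,0,,0,1.45,iv,RU,D1.45,1",
              sprintf("1,%g,%g,0,,iv,RU,D1.45,1", tg, prof$values))
    nca_subject(study_from_rows(rows, lloq = 0)[[1]])$pct_extrapolated
  }, numeric(1))
  expect_true(all(diff(pct) < 0))
})

test_that("relative bioavailability reproduces the published fold changes", {
  # extract groups versus the 75 mg/kg pure-rutin reference, group means
  expect_equal(round(relative_bioavailability(3197.85, 7.4, 4095.34, 75), 1),
               7.9)
  expect_equal(round(relative_bioavailability(9074.85, 14.8, 4095.34, 75), 1),
               11.2)
  expect_equal(relative_bioavailability(1234, 5, 1234, 5), 1)
  # dataset against itself is 1 for every dose pairing after normalisation
  set.seed(1)
  for (i in 1:4) {
    auc <- runif(1, 100, 9000); d1 <- runif(1, 1, 100); d2 <- runif(1, 1, 100)
    expect_equal(relative_bioavailability(auc * d2 / d1, d2, auc, d1), 1,
                 tolerance = 1e-12)
  }
  expect_error(relative_bioavailability(-1, 1, 1, 1), "> 0")
})

test_that("group summaries agree with direct recomputation", {
  st <- simulate_study(design_route(default_design(), "iv"),
                       pop_iv = pop_model_iv(), seed = 33)
  res <- nca_study(st)
  sm <- nca_group_summary(res)
  g1 <- res[res$group == 1, ]
  expect_equal(sm$mean[sm$group == 1 & sm$parameter == "AUC0_INF"],
               mean(g1$AUC0_INF))
  expect_equal(sm$sd[sm$group == 1 & sm$parameter == "Cl"], sd(g1$Cl))
  # identical subjects -> zero SD; single subject -> SD 0 with n = 1
  two <- res[c(1, 1), ]
  sm2 <- nca_group_summary(two)
  expect_true(all(sm2$sd == 0))
  one <- nca_group_summary(res[1, , drop = FALSE])
  expect_true(all(one$n[one$parameter == "Cl"] == 1) &&
                all(one$sd == 0, na.rm = TRUE))
})

test_that("BLQ policy: leading zeros in, embedded and trailing out", {
  rows <- c("1,0,,0,5,iv,RU,D5,1",
            "1,0.25,,1,,iv,RU,D5,1",   # leading BLQ -> zero
            "1,0.5,4000,0,,iv,RU,D5,1",
            "1,1,2000,0,,iv,RU,D5,1",
            "1,2,,1,,iv,RU,D5,1",      # embedded BLQ -> excluded
            "1,3,500,0,,iv,RU,D5,1",
            "1,4,250,0,,iv,RU,D5,1",
            "1,6,,1,,iv,RU,D5,1")      # trailing BLQ -> excluded
  r <- nca_subject(study_from_rows(rows)[[1]])
  # AUC0-last on (0.25->0, 0.5, 1, 3, 4) with the embedded/trailing points gone
  tt <- c(0.25, 0.5, 1, 3, 4)
  vv <- c(0, 4000, 2000, 500, 250)
  expect_equal(r$AUC0_last, sum(diff(tt) * (vv[-1] + vv[-5]) / 2))
})
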