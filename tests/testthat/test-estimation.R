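# shared small intravenous study + fit used by several blocks below; the
# dataset is one where the fit lands at an interior optimum (away from the
# k12-collapse ridge), so the observed information is well conditioned
est_study <- simulate_study(design_route(default_design(), "iv"),
                            pop_iv = pop_model_iv(), seed = 101)
est_fit <- saem_fit(est_study, nca_informed_init(est_study, "iv"),
                    saem_control(seed = 9, se = TRUE, se_M = 300))

test_that("near-noise-free data without variability is recovered exactly", {
  gen <- pop_model("iv", c(V = 0.0646, k = 1.47, k12 = 2.6, k21 = 13.6),
                   error = c(a = 1, b = 0), levels = c("RU", "GEXT"),
                   reference = "RU", error_form = "additive")
  des <- design_route(default_design(), "iv")
  des$groups <- des$groups[des$groups$source == "RU", , drop = FALSE]
  st <- simulate_study(des, pop_iv = gen, seed = 3)
  init <- gen
  init$fixed[] <- init$fixed * 1.3
  init$fixed[["V"]] <- 0.08
  init$error[["a"]] <- 10
  fit <- saem_fit(st, init, saem_control(n_burn = 200, n_smooth = 100,
                                         seed = 8))
  fx <- unlist(fit$model$fixed)
  expect_equal(fx[["V"]], 0.0646, tolerance = 0.02)
  expect_equal(fx[["k"]], 1.47, tolerance = 0.02)
  expect_equal(fx[["k12"]], 2.6, tolerance = 0.10)
  expect_equal(fx[["k21"]], 13.6, tolerance = 0.10)
  # holding the distribution constants at their (true) initial values
  # leaves only V and k free and keeps the fixed ones untouched
  init2 <- init
  init2$fixed[c("k12", "k21")] <- c(2.6, 13.6)
  fit2 <- saem_fit(st, init2,
                   saem_control(n_burn = 150, n_smooth = 80, seed = 8,
                                fix = c("k12", "k21", "a"), ll_M = 300))
  fx2 <- unlist(fit2$model$fixed)
  expect_equal(fx2[["k12"]], 2.6, tolerance = 1e-12)
  expect_equal(fx2[["k21"]], 13.6, tolerance = 1e-12)
  expect_equal(fit2$model$error[["a"]], 10, tolerance = 1e-12)
  expect_equal(fx2[["V"]], 0.0646, tolerance = 0.02)
  expect_equal(fx2[["k"]], 1.47, tolerance = 0.02)
  expect_equal(fit2$npar, 4 + 1 - 3) # 4 fixed effects + a, minus 3 held
})

test_that("marginal likelihood agrees with quadrature and a grid oracle", {
  pop <- pop_model("iv", c(V = 0.1, k = 0.8, k12 = 0.3, k21 = 0.5),
                   omega = c(V = 0.3), error = c(a = 60, b = 0),
                   levels = "RU", reference = "RU")
  set.seed(12)
  rows <- character(0)
  for (i in 1:2) {
    eta <- rnorm(1, 0, 0.3)
    Vi <- plogis(qlogis(0.1) + eta)
    tt <- c(0.5, 2, 6)
    f <- biexp_oracle(Vi, 0.8, 0.3, 0.5, 2, tt)
    y <- round(f + rnorm(3, 0, 60), 3)
    rows <- c(rows, sprintf("%d,0,,0,2,iv,RU,D2,1", i),
              sprintf("%d,%g,%g,0,,iv,RU,D2,1", i, tt, y))
  }
  st <- study_from_rows(rows, lloq = 0)
  oracle <- sum(vapply(st, function(s) grid_loglik_oracle(pop, s), numeric(1)))
  agq <- marginal_loglik(pop, st, "agq", nodes = 41)
  is_ll <- marginal_loglik(pop, st, "is", M = 4000, seed = 2)
  expect_equal(agq, oracle, tolerance = 1e-3)
  expect_lt(abs(is_ll - oracle), 0.5)
})

test_that("Wald statistics reproduce the published covariate tests", {
  w <- wald_test(list(estimates = c(beta_V_GEXT = 0.478),
                      se = c(beta_V_GEXT = 0.128)), "beta_V_GEXT")
  expect_equal(w$z, 0.478 / 0.128, tolerance = 1e-12)
  expect_equal(round(w$z, 2), 3.73)
  expect_true(w$p < 0.05 && w$significant)
  w2 <- wald_test(list(estimates = c(beta_Tlag2_D500 = 0.149),
                       se = c(beta_Tlag2_D500 = 0.0936)), "beta_Tlag2_D500")
  expect_equal(round(w2$z, 2), 1.59)
  expect_false(w2$significant)
  w0 <- wald_test(list(estimates = c(x = 0), se = c(x = 1)), "x")
  expect_equal(w0$p, 1)
  expect_error(wald_test(list(estimates = c(x = 1), se = c(x = 0)), "x"),
               "positive")
})

test_that("Fisher SEs are finite and the Wald route works on a real fit", {
  expect_true(all(is.finite(est_fit$se)))
  expect_true(all(est_fit$se > 0))
  # the extract effects were simulated in: both should test significant
  expect_true(wald_test(est_fit, "beta_V_GEXT")$significant)
  expect_true(wald_test(est_fit, "beta_k_GEXT")$significant)
  # distribution rate constants are the weakly identified ones, as in the
  # published table (their RSEs were 42% and 32%)
  expect_gt(est_fit$rse[["k12"]], est_fit$rse[["k"]])
})

test_that("Fisher SEs sit within a factor of three of a subject bootstrap", {
  set.seed(77)
  # draw all resamples first: saem_fit seeds the RNG internally
  idxs <- replicate(8, sample(length(est_study), replace = TRUE),
                    simplify = FALSE)
  boots <- vapply(seq_along(idxs), function(b) {
    stb <- structure(est_study[idxs[[b]]], class = "pk_study",
                     lloq = attr(est_study, "lloq"))
    for (i in seq_along(stb)) stb[[i]]$id <- i
    fb <- saem_fit(stb, nca_informed_init(stb, "iv"),
                   saem_control(n_burn = 120, n_smooth = 60, seed = 5 + b,
                                ll_M = 300))
    c(V = fb$estimates[["V"]], k = fb$estimates[["k"]])
  }, numeric(2))
  for (p in c("V", "k")) {
    ratio <- est_fit$se[[p]] / sd(boots[p, ])
    expect_gt(ratio, 1 / 3)
    expect_lt(ratio, 3)
  }
})

test_that("IWRES from a self-simulated fit behave like standard normals", {
  iw <- compute_iwres(est_fit)
  expect_equal(nrow(iw), est_fit$n_obs)
  expect_lt(abs(mean(iw$iwres)), 0.15)          # symmetric around zero
  expect_gt(ks.test(iw$iwres, "pnorm")$p.value, 0.01)
})

test_that("model ranking by AIC is definitionally consistent", {
  expect_equal(est_fit$AIC, -2 * est_fit$logLik + 2 * est_fit$npar)
  cmp <- compare_models(list(a = est_fit, b = est_fit))
  expect_equal(cmp$dAIC, c(0, 0))
  other <- est_fit
  other$fingerprint <- c(n = 1, obs = 1, sumdv = 1)
  expect_error(compare_models(list(est_fit, other)), "identical data")
})

test_that("the combined error model wins on combined-error data", {
  des <- design_route(default_design(), "iv")
  ctl <- function(fs) saem_control(n_burn = 150, n_smooth = 80, seed = fs,
                                   ll_M = 500)
  wins <- 0
  for (s in 1:3) {
    st <- simulate_study(des, pop_iv = pop_model_iv(), seed = 300 + s)
    init <- nca_informed_init(st, "iv")
    f_comb <- saem_fit(st, init, ctl(11))
    init_a <- init
    init_a$error_form <- "additive"; init_a$error[["b"]] <- 0
    f_add <- saem_fit(st, init_a, ctl(12))
    init_p <- init
    init_p$error_form <- "proportional"
    init_p$error[["a"]] <- 0; init_p$error[["b"]] <- 0.2
    f_prop <- saem_fit(st, init_p, ctl(13))
    cmp <- compare_models(list(combined = f_comb, additive = f_add,
                               proportional = f_prop))
    wins <- wins + (cmp$model[1] == "combined")
  }
  expect_gte(wins, 2)
})

test_that("re-parameterising the reference level leaves the likelihood alone", {
  # same population distribution written with GEXT as the reference
  a <- pop_model_iv()
  b <- a
  b$reference <- "GEXT"
  b$fixed[["V"]] <- plogis(qlogis(a$fixed[["V"]]) + a$beta$V[["GEXT"]])
  b$fixed[["k"]] <- a$fixed[["k"]] * exp(a$beta$k[["GEXT"]])
  b$beta <- list(V = c(RU = -a$beta$V[["GEXT"]]),
                 k = c(RU = -a$beta$k[["GEXT"]]))
  des <- design_route(default_design(), "iv")
  des$groups <- des$groups[des$groups$group %in% c(1, 5), , drop = FALSE]
  des$groups$n <- 3
  st <- simulate_study(des, pop_iv = a, seed = 6)
  lla <- marginal_loglik(a, st, "agq", nodes = 21)
  llb <- marginal_loglik(b, st, "agq", nodes = 21)
  expect_equal(lla, llb, tolerance = 1e-6)
})

test_that("misspecified fits are refused up front", {
  st <- simulate_study(design_route(default_design(), "iv"),
                       pop_iv = pop_model_iv(), seed = 1)
  init <- nca_informed_init(st, "iv")
  init$beta$V <- c(GEXT = 0, BAD = 1) # level not even declared
  expect_error(pop_model("iv", unlist(init$fixed), init$beta, init$omega,
                         init$corr, init$error, init$levels, init$reference),
               "undeclared")
  # declared level absent from the data -> non-identifiable coefficient
  init2 <- pop_model("iv", c(V = 0.08, k = 1, k12 = 1, k21 = 5),
                     beta = list(V = c(GEXT = 0, X2 = 0)),
                     omega = c(V = 0.3, k = 0.3),
                     error = c(a = 20, b = 0.1),
                     levels = c("RU", "GEXT", "X2"), reference = "RU")
  expect_error(saem_fit(st, init2, saem_control()), "absent from the data")
})
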