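test_that("the default design matches the published trial layout", {
  d <- default_design()
  g <- d$groups
  expect_equal(nrow(g), 10)
  expect_true(all(g$n == 5))
  # group 7: extract, i.v., 1000 mg/kg -> 14.8 mg/kg rutin equivalent
  expect_equal(g$route[g$group == 7], "iv")
  expect_equal(g$dose_admin[g$group == 7], 1000)
  expect_equal(g$dose_ruteq[g$group == 7], 14.8)
  # group 3: pure rutin, p.o., 75 mg/kg
  expect_equal(g[g$group == 3, c("route", "dose_admin")],
               data.frame(route = "oral", dose_admin = 75, row.names = "3"),
               ignore_attr = TRUE)
  # extract 500 -> 7.4 rutin equivalent (content 14.8 ug/mg)
  expect_equal(g$dose_ruteq[g$group == 6], 7.4)
  expect_equal(g$dose_ruteq, ifelse(g$source == "HEE",
                                    g$dose_admin * 0.0148, g$dose_admin))
  expect_equal(d$iv_times,
               c(0, 0.05, 0.166, 0.333, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12))
  expect_equal(d$oral_times,
               c(0, 0.083, 0.25, 0.30, 0.75, 1, 2, 3, 4, 6, 8, 10, 12, 24))
  expect_equal(d$lloq, 100)
})

test_that("study simulation is deterministic, censored and design-faithful", {
  st1 <- simulate_study(default_design(), pop_model_iv(), pop_model_oral(),
                        seed = 5)
  st2 <- simulate_study(default_design(), pop_model_iv(), pop_model_oral(),
                        seed = 5)
  expect_identical(st1, st2)
  expect_equal(length(st1), 50)
  for (s in st1) {
    sched <- if (s$route == "iv") default_design()$iv_times else
      default_design()$oral_times
    expect_identical(s$times, sched)
    # no quantifiable value below the LLOQ, BLQ records carry no value
    expect_true(all(s$dv[!s$blq] >= 100))
    expect_true(all(is.na(s$dv[s$blq])))
    expect_true(s$blq[s$times == 0])
  }
})

test_that("zero variability collapses a group onto one profile", {
  pop <- pop_model_iv()
  pop$omega[] <- 0
  pop$error[] <- 0
  st <- simulate_study(design_route(default_design(), "iv"), pop_iv = pop,
                       seed = 1)
  g1 <- Filter(function(s) s$group == 1, st)
  for (s in g1[-1]) expect_identical(s$dv, g1[[1]]$dv)
})

test_that("noise-free intravenous concentrations are unquantifiable after 4 h", {
  pop <- pop_model_iv()
  pop$omega[] <- 0
  pop$error[] <- 0
  st <- simulate_study(design_route(default_design(), "iv"), pop_iv = pop,
                       seed = 1)
  s <- Filter(function(x) x$group == 1, st)[[1]] # pure rutin 1.45 mg/kg
  expect_true(all(s$blq[s$times > 4]))
  # the 4 h sample itself sits just above the quantification limit
  expect_false(s$blq[s$times == 4])
  expect_equal(s$dv[s$times == 4],
               biexp_oracle(0.0646, 1.47, 2.6, 13.6, 1.45, 4),
               tolerance = 1e-9)
})

test_that("noise-free simulated exposure is dose-proportional within a source", {
  pop <- pop_model_iv()
  pop$omega[] <- 0
  pop$error[] <- 0
  des <- design_route(default_design(), "iv")
  des$lloq <- 0 # uncensored so the full curve is integrable
  st <- simulate_study(des, pop_iv = pop, seed = 1, censor = FALSE)
  nca <- nca_study(st)
  ru <- nca[nca$group %in% c(1, 2), ]
  expect_equal(sd(ru$AUC_over_dose) / mean(ru$AUC_over_dose), 0,
               tolerance = 0.02)
  ext <- nca[nca$group %in% c(5, 6, 7), ]
  expect_equal(sd(ext$AUC_over_dose) / mean(ext$AUC_over_dose), 0,
               tolerance = 0.02)
})

test_that("route/model mismatches are refused", {
  expect_error(simulate_study(default_design(), pop_iv = pop_model_iv(),
                              seed = 1), "oral")
  expect_error(simulate_study(design_route(default_design(), "iv"),
                              pop_iv = pop_model_oral(), seed = 1),
               "iv-route")
})
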