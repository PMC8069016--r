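#' SAEM estimation settings
#'
#' Tuning parameters of the stochastic approximation EM estimator. Defaults
#' are sized for cohorts of a few dozen rats with rich sampling: an
#' exploration (burn-in) phase with step size 1, then a smoothing phase with
#' step size `1/t^step_power`. During burn-in, structural parameters that
#' carry no inter-individual variability are given an artificial random
#' effect whose SD is annealed from `aux_sd0` down to ~5e-3, so that all
#' fixed effects are updated by the same closed-form pooled regression and
#' the MCMC can explore them per subject; in the smoothing phase the
#' artificial variability is removed and those fixed effects are polished by
#' a damped warm-started quasi-Newton step.
#'
#' @param n_burn iterations of the exploration phase.
#' @param n_smooth iterations of the smoothing phase.
#' @param n_kernels MCMC kernel sweeps per iteration (each sweep = one
#'   independent prior proposal plus one componentwise random walk).
#' @param step_power exponent of the smoothing-phase step size.
#' @param blq below-quantification policy: `"exclude"` drops BLQ records from
#'   the likelihood (default); `"censored"` integrates the Gaussian mass
#'   below the LLOQ.
#' @param optim_maxit BFGS iterations per smoothing cycle for the fixed
#'   effects without random effects.
#' @param aux_sd0 initial SD of the annealed artificial variability.
#' @param err_step damping factor of the residual-error update during
#'   burn-in (the smoothing phase uses the SAEM step size).
#' @param ll_M importance-sampling draws per subject for the final
#'   log-likelihood.
#' @param se compute standard errors (finite-difference Fisher information on
#'   the importance-sampled likelihood with common random numbers).
#' @param se_M importance-sampling draws per subject during the SE step.
#' @param restarts number of independent SAEM runs; the first starts at the
#'   supplied initial model, later ones jitter its fixed effects on the
#'   transformed scale (SD 0.4), and the run with the best
#'   importance-sampled marginal log-likelihood is returned. Multi-start is
#'   the standard guard against the absorption/elimination flip-flop and
#'   other local modes of rich structural models.
#' @param fix character vector of quantities to hold at their initial
#'   values instead of estimating them: structural parameter names (`"k12"`),
#'   covariate coefficients (`"beta_k_D500"`), random-effect SDs
#'   (`"omega_V"`), or error components (`"a"`, `"b"`).
#' @param seed RNG seed for the whole fit (mandatory for reproducibility).
#' @return list of class `saem_control`.
#' @export
saem_control <- function(n_burn = 250, n_smooth = 150, n_kernels = 2,
                         step_power = 0.65, blq = c("exclude", "censored"),
                         optim_maxit = 2, aux_sd0 = 0.3, err_step = 0.3,
                         ll_M = 1000, se = FALSE, se_M = 500, restarts = 1,
                         fix = character(), seed = 1) {
  structure(list(n_burn = n_burn, n_smooth = n_smooth, n_kernels = n_kernels,
                 step_power = step_power, blq = match.arg(blq),
                 optim_maxit = optim_maxit, aux_sd0 = aux_sd0,
                 err_step = err_step, ll_M = ll_M, se = se,
                 se_M = se_M, restarts = restarts, fix = fix, seed = seed),
            class = "saem_control")
}

# ---- internal model plumbing ------------------------------------------------

# covariate-shift matrix (n x p, transformed scale) for given beta values
.shift_matrix <- function(beta, covariate, pnames) {
  n <- length(covariate)
  S <- matrix(0, n, length(pnames), dimnames = list(NULL, pnames))
  for (j in names(beta)) {
    b <- beta[[j]]
    for (l in names(b)) S[covariate == l, j] <- S[covariate == l, j] + b[[l]]
  }
  S
}

# individual transformed parameters (n x p)
.build_phi <- function(mu, shift, eta) {
  Phi <- sweep(shift, 2, mu, "+")
  if (ncol(eta)) Phi[, colnames(eta)] <- Phi[, colnames(eta)] + eta
  Phi
}

.natural <- function(Phi, tmap) {
  P <- Phi
  for (j in colnames(Phi))
    P[, j] <- par_backtransform(Phi[, j], tmap[[j]])
  P
}

.predict_matrix <- function(route, P, dose, times) {
  if (route == "iv") {
    .conc_iv_matrix(P[, "V"], P[, "k"], P[, "k12"], P[, "k21"], dose, times)
  } else {
    .conc_oral_matrix(P[, "ka1"], P[, "ka2"], P[, "F1"], P[, "Tlag2"],
                      P[, "V"], P[, "k"], P[, "k12"], P[, "k21"], dose, times)
  }
}

# residual SD under the declared error form
.sd_model <- function(err, f, form) {
  switch(form,
         combined = err[1] + err[2] * f,
         combined2 = sqrt(err[1]^2 + (err[2] * f)^2),
         additive = 0 * f + err[1],
         proportional = err[2] * f)
}

# rowwise observation log-likelihood; Y has NA at non-modelled records,
# `cens` (same shape) is TRUE where a censored-likelihood term applies
.ll_rows <- function(Y, f, err, form, cens = NULL, lloq = NULL) {
  f[!is.finite(f)] <- 1e12 # degenerate parameter proposals: vanishing density
  f <- pmax(f, 0)
  sd <- pmax(.sd_model(err, f, form), 1e-8)
  ll <- stats::dnorm(Y, f, sd, log = TRUE)
  out <- rowSums(ll, na.rm = TRUE)
  if (!is.null(cens) && any(cens))
    out <- out + rowSums(ifelse(cens, stats::pnorm(lloq, f, sd, log.p = TRUE), 0))
  out
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# single-subject log-likelihood as a function of an M x q eta matrix
.subject_ll_fun <- function(st, i) {
  force(i)
  function(E, mu = st$mu, beta_shift = st$shift[i, ], err = st$err) {
    M <- nrow(E)
    Phi <- matrix(rep(mu + beta_shift, each = M), M,
                  dimnames = list(NULL, names(mu)))
    if (ncol(E)) Phi[, colnames(E)] <- Phi[, colnames(E)] + E
    P <- .natural(Phi, st$tmap)
    f <- .predict_matrix(st$route, P, rep(st$dose[i], M), st$times)
    Yi <- matrix(rep(st$Y[i, ], each = M), M)
    ci <- if (is.null(st$cens)) NULL else
      matrix(rep(st$cens[i, ], each = M), M)
    .ll_rows(Yi, f, err, st$form, ci, st$lloq)
  }
}

# ---- the SAEM estimator -----------------------------------------------------

#' Fit a population model by stochastic approximation EM
#'
#' Maximises the marginal mixed-effects likelihood by SAEM: Markov-chain
#' Monte Carlo sampling of the individual random effects (an independent
#' proposal from their prior plus adaptive componentwise random walks),
#' stochastic-approximation smoothing of the sufficient statistics of the
#' Gaussian individual-parameter model, closed-form pooled-regression
#' updates of all fixed effects and covariate coefficients (parameters
#' without inter-individual variability receive an annealed artificial
#' random effect during burn-in, then a damped quasi-Newton polish), and a
#' damped update of the combined-error components. The marginal
#' log-likelihood is then estimated by importance sampling around the
#' individual conditional modes, and AIC as `-2 logLik + 2 npar` with
#' `npar` counting every estimated quantity (fixed effects, covariate
#' coefficients, random-effect SDs, correlations, error components).
#'
#' @param study a `pk_study` (subjects of other routes are ignored).
#' @param init a [pop_model()] providing the model structure (which
#'   covariate coefficients exist, which parameters carry random effects,
#'   which correlations are estimated) and the initial values.
#' @param control a [saem_control()].
#' @return object of class `pk_fit` with elements `model` (fitted
#'   [pop_model()]), `estimates` / `se` / `rse` (flat named vectors over all
#'   estimated quantities), `logLik`, `AIC`, `npar`, `eta` (conditional
#'   modes), `iwres` (per-observation data frame), `trajectory` (iteration
#'   history), and `convergence` (final mean step norms).
#' @export
saem_fit <- function(study, init, control = saem_control()) {
  stopifnot(inherits(study, "pk_study"), inherits(init, "pop_model"),
            inherits(control, "saem_control"))
  if (control$restarts > 1) {
    best <- NULL
    for (r in seq_len(control$restarts)) {
      init_r <- if (r == 1) init else {
        set.seed(control$seed + 7777 * r)
        jit <- init
        for (j in names(jit$fixed)) {
          psi <- par_transform(jit$fixed[[j]], jit$transforms[[j]]) +
            stats::rnorm(1, 0, 0.4)
          jit$fixed[[j]] <- par_backtransform(psi, jit$transforms[[j]])
        }
        jit
      }
      ctl_r <- control
      ctl_r$restarts <- 1L
      ctl_r$seed <- control$seed + 1000L * (r - 1L)
      cand <- saem_fit(study, init_r, ctl_r)
      if (is.null(best) || cand$logLik > best$logLik) best <- cand
    }
    # warm-started polish from the winning run
    ctl_p <- control
    ctl_p$restarts <- 1L
    ctl_p$seed <- control$seed + 1000L * control$restarts
    ctl_p$n_burn <- max(50L, ceiling(control$n_burn / 3))
    polish <- saem_fit(study, best$model, ctl_p)
    if (polish$logLik > best$logLik) best <- polish
    return(best)
  }
  set.seed(control$seed)
  mats <- .study_matrices(study, init$route)
  n <- nrow(mats$Y)
  if (n < 2) stop("need at least 2 subjects")
  lv_data <- unique(mats$covariate)
  bad <- setdiff(lv_data, init$levels)
  if (length(bad))
    stop("covariate level(s) in data not declared in the model: ",
         paste(bad, collapse = ", "))
  for (j in names(init$beta)) {
    absent <- setdiff(names(init$beta[[j]]), lv_data)
    if (length(absent))
      stop("beta[", j, "] for level(s) absent from the data: ",
           paste(absent, collapse = ", "), " (non-identifiable)")
  }
  tmap <- init$transforms
  pnames <- names(tmap)
  iiv <- names(init$omega)
  q <- length(iiv)
  noiiv <- setdiff(pnames, iiv)
  qa <- length(noiiv)

  # observation matrices; t = 0 pre-dose records never enter the likelihood
  Y <- mats$Y
  Y[, mats$times == 0] <- NA
  cens <- NULL
  if (control$blq == "censored") {
    cens <- mats$BLQ & matrix(mats$times > 0, n, length(mats$times), byrow = TRUE)
    Y[cens] <- NA
  } else {
    Y[mats$BLQ] <- NA
  }
  lloq <- attr(study, "lloq")
  if (is.null(lloq)) lloq <- 100
  n_obs <- sum(!is.na(Y)) + if (is.null(cens)) 0 else sum(cens)

  # state
  mu <- vapply(pnames, function(j) par_transform(init$fixed[[j]], tmap[[j]]),
               numeric(1))
  beta <- init$beta
  shift <- .shift_matrix(beta, mats$covariate, pnames)
  Om0 <- .omega_matrix(init)
  Om <- Om0
  if (q) diag(Om) <- pmax(diag(Om), 1e-4)
  err <- pmax(init$error, c(a = 1e-3, b = 0))
  form <- init$error_form
  # eta over all parameters; the `noiiv` block is the annealed artificial one
  ecols <- c(iiv, noiiv)
  eta <- matrix(0, n, length(ecols), dimnames = list(NULL, ecols))
  aux_sd_min <- 5e-3
  aux_decay <- (aux_sd_min / control$aux_sd0)^(1 / max(control$n_burn, 1))
  aux_sd <- if (qa) control$aux_sd0 else numeric(0)

  st <- list(mu = mu, shift = shift, err = err, tmap = tmap, form = form,
             route = init$route, dose = mats$dose, times = mats$times,
             Y = Y, cens = cens, lloq = lloq)

  # quantities held at their initial values (free/fixed flags)
  fix <- control$fix
  valid_fix <- c(pnames,
                 unlist(lapply(names(beta), function(j)
                   paste0("beta_", j, "_", names(beta[[j]])))),
                 paste0("omega_", iiv), "a", "b")
  if (length(bad_fix <- setdiff(fix, valid_fix)))
    stop("unknown fixed quantity: ", paste(bad_fix, collapse = ", "))
  mu_init <- mu; beta_init <- beta; err_init <- err; Om_init <- Om
  apply_fix <- function() {
    if (!length(fix)) return(invisible())
    for (nm in fix) {
      if (nm %in% pnames) {
        mu[[nm]] <<- mu_init[[nm]]
      } else if (startsWith(nm, "beta_")) {
        parts <- strsplit(sub("^beta_", "", nm), "_")[[1]]
        beta[[parts[1]]][[parts[2]]] <<- beta_init[[parts[1]]][[parts[2]]]
      } else if (startsWith(nm, "omega_")) {
        j <- sub("^omega_", "", nm)
        old_sd <- sqrt(Om[j, j]); new_sd <- sqrt(Om_init[j, j])
        if (old_sd > 0) { # rescale, preserving estimated correlations
          Om[j, ] <<- Om[j, ] * new_sd / old_sd
          Om[, j] <<- Om[, j] * new_sd / old_sd
        }
        Om[j, j] <<- max(Om_init[j, j], 1e-10)
      } else {
        err[[nm]] <<- err_init[[nm]]
      }
    }
    shift <<- .shift_matrix(beta, mats$covariate, pnames)
    if (q) omI <<- solve(Om + diag(1e-10, q))
    invisible()
  }

  # pooled-regression designs, one per structural parameter
  Xj <- lapply(pnames, function(j) {
    lv <- names(beta[[j]])
    X <- cbind(1, vapply(lv, function(l) as.numeric(mats$covariate == l),
                         numeric(n)))
    colnames(X) <- c("mu", lv)
    X
  })
  names(Xj) <- pnames
  XtXinv <- lapply(Xj, function(X) solve(crossprod(X)))

  # free fixed effects without random effects, flattened
  thF_names <- unlist(lapply(noiiv, function(j)
    c(j, if (length(beta[[j]])) paste0("beta_", j, "_", names(beta[[j]])))))
  pack_F <- function() {
    v <- numeric(0)
    for (j in noiiv) v <- c(v, mu[[j]], unlist(beta[[j]]))
    setNames(v, thF_names)
  }
  unpack_F <- function(v) {
    k <- 1L
    for (j in noiiv) {
      mu[[j]] <<- v[[k]]; k <- k + 1L
      if (length(beta[[j]])) {
        beta[[j]][] <<- v[k:(k + length(beta[[j]]) - 1L)]
        k <- k + length(beta[[j]])
      }
    }
    shift <<- .shift_matrix(beta, mats$covariate, pnames)
  }

  loglik_rows_current <- function() {
    Phi <- .build_phi(mu, shift, eta)
    f <- .predict_matrix(init$route, .natural(Phi, tmap), mats$dose, mats$times)
    .ll_rows(Y, f, err, form, cens, lloq)
  }

  omI <- if (q) solve(Om + diag(1e-10, q)) else matrix(numeric(0), 0, 0)
  lprior <- function(E, aux_active) {
    lp <- numeric(nrow(E))
    if (q) {
      Er <- E[, iiv, drop = FALSE]
      lp <- lp - 0.5 * rowSums((Er %*% omI) * Er)
    }
    if (qa && aux_active) {
      Ea <- E[, noiiv, drop = FALSE]
      lp <- lp - 0.5 * rowSums(Ea^2) / aux_sd^2
    }
    lp
  }

  ll_cur <- loglik_rows_current()
  lp_cur <- lprior(eta, TRUE)

  s_rw <- rep(0.4, length(ecols)) # RW scales, adapted during burn-in
  names(s_rw) <- ecols
  s_joint <- 1 # scale of the joint adaptive kernel
  S1 <- matrix(0, n, length(ecols), dimnames = list(NULL, ecols))
  S2 <- matrix(0, q, q, dimnames = list(iiv, iiv))
  n_iter <- control$n_burn + control$n_smooth
  traj <- matrix(NA_real_, n_iter, length(pnames) + length(thF_names) + q + 2)
  thF <- pack_F()

  # a declared correlation matrix means all its off-diagonals are estimated
  corr_pairs <- if (is.null(init$corr)) NULL else
    which(upper.tri(init$corr), arr.ind = TRUE)

  for (it in seq_len(n_iter)) {
    burn <- it <= control$n_burn
    gamma <- if (burn) 1 else 1 / (it - control$n_burn)^control$step_power
    if (qa && burn) aux_sd <- control$aux_sd0 * aux_decay^(it - 1)
    active <- if (burn) ecols else iiv

    # --- simulation step: MH kernels on eta, vectorised across subjects
    for (kk in seq_len(control$n_kernels)) {
      if (length(active)) {
        # kernel A: independent proposal from the prior
        etap <- eta
        if (q) etap[, iiv] <- .rmvnorm0(n, Om)
        if (qa && burn)
          etap[, noiiv] <- matrix(stats::rnorm(n * qa, sd = aux_sd), n, qa)
        eta_old <- eta; eta <- etap
        llp <- loglik_rows_current()
        acc <- log(stats::runif(n)) < (llp - ll_cur)
        eta[!acc, ] <- eta_old[!acc, ]
        ll_cur[acc] <- llp[acc]
        lp_cur <- lprior(eta, burn)
        # kernel C: joint adaptive random walk along the empirical
        # eta covariance (coordinated moves across correlated parameters)
        d <- length(active)
        if (it > 5 && d > 1) {
          Ce <- stats::cov(eta[, active, drop = FALSE]) + diag(1e-8, d)
          Lc <- tryCatch(t(chol(Ce)), error = function(e) diag(sqrt(diag(Ce))))
          etap <- eta
          etap[, active] <- etap[, active] +
            s_joint * matrix(stats::rnorm(n * d), n, d) %*% t(Lc)
          eta_old <- eta; eta <- etap
          llp <- loglik_rows_current()
          lpp <- lprior(eta, burn)
          acc <- log(stats::runif(n)) < (llp + lpp - ll_cur - lp_cur)
          eta[!acc, ] <- eta_old[!acc, ]
          ll_cur[acc] <- llp[acc]; lp_cur[acc] <- lpp[acc]
          if (burn) s_joint <- s_joint * exp(0.2 * (mean(acc) - 0.3))
        }
        # kernel B: componentwise random walk
        for (jq in active) {
          etap <- eta
          sc <- if (jq %in% noiiv) min(s_rw[jq], 3 * aux_sd) else s_rw[jq]
          etap[, jq] <- etap[, jq] + sc * stats::rnorm(n)
          eta_old <- eta; eta <- etap
          llp <- loglik_rows_current()
          lpp <- lprior(eta, burn)
          acc <- log(stats::runif(n)) < (llp + lpp - ll_cur - lp_cur)
          eta[!acc, ] <- eta_old[!acc, ]
          ll_cur[acc] <- llp[acc]; lp_cur[acc] <- lpp[acc]
          if (burn) s_rw[jq] <- s_rw[jq] * exp(0.2 * (mean(acc) - 0.4))
        }
      }
    }

    # --- stochastic approximation of sufficient statistics
    Phi <- .build_phi(mu, shift, eta)
    S1 <- S1 + gamma * (Phi[, ecols, drop = FALSE] - S1)
    if (q) {
      Phi_iiv <- Phi[, iiv, drop = FALSE]
      S2 <- S2 + gamma * (crossprod(Phi_iiv) - S2)
    }

    # --- M-step: fixed effects + covariate coefficients, pooled regression
    upd <- if (burn) ecols else iiv
    for (j in upd) {
      th <- XtXinv[[j]] %*% crossprod(Xj[[j]], S1[, j])
      mu[[j]] <- th[1]
      if (length(beta[[j]])) beta[[j]][] <- th[-1]
    }
    shift <- .shift_matrix(beta, mats$covariate, pnames)
    if (q) {
      M <- vapply(iiv, function(j)
        drop(Xj[[j]] %*% c(mu[[j]], beta[[j]])), numeric(n))
      M <- matrix(M, n, q, dimnames = list(NULL, iiv))
      # Omega from the smoothed second moments
      S1r <- S1[, iiv, drop = FALSE]
      Omh <- (S2 - crossprod(S1r, M) - crossprod(M, S1r) + crossprod(M)) / n
      Omh <- (Omh + t(Omh)) / 2
      Omn <- diag(pmax(diag(Omh), 1e-6), q)
      dimnames(Omn) <- dimnames(Omh)
      if (!is.null(corr_pairs) && nrow(corr_pairs)) {
        for (rr in seq_len(nrow(corr_pairs))) {
          a_ <- corr_pairs[rr, 1]; b_ <- corr_pairs[rr, 2]
          rho <- Omh[a_, b_] / sqrt(Omn[a_, a_] * Omn[b_, b_])
          rho <- max(min(rho, 0.99), -0.99)
          Omn[a_, b_] <- Omn[b_, a_] <- rho * sqrt(Omn[a_, a_] * Omn[b_, b_])
        }
      }
      if (burn) # annealing floor against early shrinkage collapse
        diag(Omn) <- pmax(diag(Omn), diag(Om0) * 0.95^(it / 5))
      Om <- Omn
      omI <- solve(Om + diag(1e-10, q))
    }
    thF <- pack_F()

    # --- smoothing phase: polish the no-variability fixed effects
    if (!burn && qa) {
      negll_F <- function(v) {
        v <- pmin(pmax(v, -30), 30)
        mu2 <- mu; beta2 <- beta; k <- 1L
        for (j in noiiv) {
          mu2[[j]] <- v[[k]]; k <- k + 1L
          if (length(beta2[[j]])) {
            beta2[[j]][] <- v[k:(k + length(beta2[[j]]) - 1L)]
            k <- k + length(beta2[[j]])
          }
        }
        sh2 <- .shift_matrix(beta2, mats$covariate, pnames)
        Phi2 <- .build_phi(mu2, sh2, eta)
        f2 <- .predict_matrix(init$route, .natural(Phi2, tmap),
                              mats$dose, mats$times)
        out <- -sum(.ll_rows(Y, f2, err, form, cens, lloq))
        if (!is.finite(out)) 1e10 else out
      }
      opt <- stats::optim(thF, negll_F, method = "BFGS",
                          control = list(maxit = control$optim_maxit))
      thF <- thF + gamma * (pmin(pmax(opt$par, -30), 30) - thF)
      unpack_F(thF)
    }

    # --- residual-error update (damped direct maximisation)
    Phi <- .build_phi(mu, shift, eta)
    f <- pmax(.predict_matrix(init$route, .natural(Phi, tmap),
                              mats$dose, mats$times), 0)
    r2mat <- (Y - f)^2
    obs <- !is.na(Y) & is.finite(f)
    fo <- f[obs]; r2o <- r2mat[obs]
    err_free <- switch(form, additive = 1L, proportional = 2L, c(1L, 2L))
    err_obj <- function(lab) {
      e2 <- err
      e2[err_free] <- exp(lab)
      sd <- pmax(.sd_model(e2, fo, form), 1e-8)
      sum(log(sd) + r2o / (2 * sd^2))
    }
    # frozen at the start so early misfit loads on the annealed random
    # effects instead of inflating the error components
    if (it > min(50, control$n_burn / 4)) {
      epar <- if (length(err_free) == 1L) {
        stats::optimize(err_obj, c(-12, 15))$minimum
      } else {
        stats::optim(log(pmax(err[err_free], 1e-6)), err_obj,
                     method = "Nelder-Mead",
                     control = list(maxit = 60))$par
      }
      err_star <- err
      err_star[err_free] <- exp(epar)
      err <- err + min(gamma, control$err_step) * (err_star - err)
      names(err) <- c("a", "b")
    }

    # end of burn-in: remove the artificial variability
    if (qa && it == control$n_burn) eta[, noiiv] <- 0

    apply_fix()
    thF <- pack_F()
    st$mu <- mu; st$shift <- shift; st$err <- err
    ll_cur <- loglik_rows_current()
    lp_cur <- lprior(eta, it < control$n_burn)

    traj[it, ] <- c(mu, thF, if (q) sqrt(diag(Om)), err)
  }
  colnames(traj) <- c(names(mu), paste0("F_", thF_names),
                      if (q) paste0("omega_", iiv), c("a", "b"))

  # --- assemble the fitted population model (natural scale)
  fixed_nat <- vapply(pnames, function(j)
    par_backtransform(mu[[j]], tmap[[j]]), numeric(1))
  om_sd <- if (q) sqrt(diag(Om)) else numeric(0)
  names(om_sd) <- iiv
  corr_hat <- NULL
  if (!is.null(init$corr)) {
    corr_hat <- diag(q)
    dimnames(corr_hat) <- dimnames(Om)
    for (rr in seq_len(nrow(corr_pairs))) {
      a_ <- corr_pairs[rr, 1]; b_ <- corr_pairs[rr, 2]
      corr_hat[a_, b_] <- corr_hat[b_, a_] <-
        Om[a_, b_] / sqrt(Om[a_, a_] * Om[b_, b_])
    }
  }
  fitted_model <- pop_model(init$route, fixed_nat, beta, om_sd, corr_hat,
                            err, init$levels, init$reference, form)

  # --- conditional modes of the random effects
  st$mu <- mu; st$shift <- shift; st$err <- err
  eta_modes <- matrix(0, n, q, dimnames = list(NULL, iiv))
  if (q) {
    for (i in seq_len(n)) {
      lli <- .subject_ll_fun(st, i)
      post <- function(e) -(lli(matrix(e, 1, q, dimnames = list(NULL, iiv))) -
                              0.5 * drop(e %*% omI %*% e))
      o <- stats::optim(eta[i, iiv], post, method = "BFGS")
      eta_modes[i, ] <- o$par
    }
  }

  # --- importance-sampling marginal log-likelihood
  ll_total <- .is_loglik(st, eta_modes, Om, M = control$ll_M)

  npar <- length(pnames) + length(unlist(beta)) + q +
    (if (is.null(corr_pairs)) 0 else nrow(corr_pairs)) +
    (if (form %in% c("combined", "combined2")) 2 else 1) - length(fix)
  aic <- -2 * ll_total + 2 * npar

  # --- IWRES at the conditional modes
  Phi <- .build_phi(mu, shift, eta_modes)
  f_ind <- pmax(.predict_matrix(init$route, .natural(Phi, tmap),
                                mats$dose, mats$times), 0)
  sd_ind <- .sd_model(err, f_ind, form)
  obs <- !is.na(Y)
  iwres <- data.frame(
    id = rep(mats$id, ncol(Y))[obs],
    time = rep(mats$times, each = n)[obs],
    dv = Y[obs], f_ind = f_ind[obs],
    iwres = ((Y - f_ind) / pmax(sd_ind, 1e-8))[obs])
  iwres <- iwres[order(iwres$id, iwres$time), ]
  rownames(iwres) <- NULL

  # flat estimate vector over everything counted in npar
  est <- c(setNames(as.numeric(mu), pnames),
           if (length(unlist(beta)))
             setNames(unlist(lapply(names(beta), function(j)
               setNames(beta[[j]], paste0("beta_", j, "_", names(beta[[j]]))))),
               unlist(lapply(names(beta), function(j)
                 paste0("beta_", j, "_", names(beta[[j]]))))),
           if (q) setNames(log(om_sd), paste0("log_omega_", iiv)),
           if (!is.null(corr_pairs) && nrow(corr_pairs))
             setNames(atanh(vapply(seq_len(nrow(corr_pairs)), function(rr)
               corr_hat[corr_pairs[rr, 1], corr_pairs[rr, 2]], numeric(1))),
               apply(corr_pairs, 1, function(z)
                 paste0("atanh_corr_", iiv[z[1]], "_", iiv[z[2]]))),
           log_a = log(unname(err[["a"]])), log_b = log(unname(err[["b"]])))

  conv <- apply(traj[max(1, n_iter - 9):n_iter, , drop = FALSE], 2,
                function(x) mean(abs(diff(x))))
  fit <- structure(list(
    model = fitted_model, estimates = est, se = NULL, rse = NULL,
    logLik = ll_total, AIC = aic, npar = npar,
    eta = eta_modes, iwres = iwres, trajectory = traj,
    convergence = conv, control = control,
    fingerprint = .data_fingerprint(study, init$route),
    n_subjects = n, n_obs = n_obs), class = "pk_fit")

  if (control$se) {
    fit <- add_fisher_se(fit, study, M = control$se_M)
  }
  fit
}

.data_fingerprint <- function(study, route) {
  subs <- Filter(function(s) s$route == route, study)
  c(n = length(subs),
    obs = sum(vapply(subs, function(s) sum(!s$blq), numeric(1))),
    sumdv = sum(vapply(subs, function(s) sum(s$dv, na.rm = TRUE), numeric(1))))
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("SAEM fit (", x$model$route, " model): ", x$n_subjects, " subjects, ",
      x$n_obs, " observations\n", sep = "")
  cat("logLik", format(x$logLik, digits = 6), " AIC",
      format(x$AIC, digits = 6), " npar", x$npar, "\n")
  print(signif(unlist(x$model$fixed), 3))
  invisible(x)
}
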