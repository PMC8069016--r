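# internal state (same layout as inside saem_fit) from a pop_model + data
.state_from_pop <- function(pop, mats, blq = "exclude", lloq = 100) {
  tmap <- pop$transforms
  pnames <- names(tmap)
  mu <- vapply(pnames, function(j) par_transform(pop$fixed[[j]], tmap[[j]]),
               numeric(1))
  n <- nrow(mats$Y)
  Y <- mats$Y
  Y[, mats$times == 0] <- NA
  cens <- NULL
  if (blq == "censored") {
    cens <- mats$BLQ & matrix(mats$times > 0, n, length(mats$times), byrow = TRUE)
    Y[cens] <- NA
  } else {
    Y[mats$BLQ] <- NA
  }
  list(mu = mu, shift = .shift_matrix(pop$beta, mats$covariate, pnames),
       err = pmax(pop$error, c(a = 1e-8, b = 0)), tmap = tmap,
       form = pop$error_form, route = pop$route, dose = mats$dose,
       times = mats$times, Y = Y, cens = cens, lloq = lloq)
}

# numeric Hessian of a scalar function at x (central differences)
.fd_hessian <- function(fn, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-3 * pmax(abs(x), 1)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

# clip a symmetric matrix to be positive definite
.make_pd <- function(H, floor = 1e-6) {
  e <- eigen(H, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, floor), length(e$values)) %*% t(e$vectors)
}

# conditional modes of eta for every subject under state st
.eta_modes <- function(st, Om, start = NULL) {
  q <- ncol(Om)
  n <- length(st$dose)
  omI <- solve(Om + diag(1e-10, q))
  modes <- if (is.null(start)) matrix(0, n, q) else start
  colnames(modes) <- colnames(Om)
  for (i in seq_len(n)) {
    lli <- .subject_ll_fun(st, i)
    post <- function(e) -(lli(matrix(e, 1, q, dimnames = list(NULL, colnames(Om)))) -
                            0.5 * drop(e %*% omI %*% e))
    modes[i, ] <- stats::optim(modes[i, ], post, method = "BFGS")$par
  }
  modes
}

# importance-sampling marginal log-likelihood given modes
.is_loglik <- function(st, modes, Om, M = 1000, inflate = 1.2, Z = NULL) {
  q <- ncol(Om)
  n <- length(st$dose)
  if (q == 0) {
    E <- matrix(numeric(0), 1, 0)
    return(sum(vapply(seq_len(n), function(i) .subject_ll_fun(st, i)(E),
                      numeric(1))))
  }
  omI <- solve(Om + diag(1e-10, q))
  ldetOm <- determinant(Om, logarithm = TRUE)$modulus
  total <- 0
  for (i in seq_len(n)) {
    lli <- .subject_ll_fun(st, i)
    post <- function(e) -(lli(matrix(e, 1, q, dimnames = list(NULL, colnames(Om)))) -
                            0.5 * drop(e %*% omI %*% e))
    H <- .make_pd(.fd_hessian(post, modes[i, ]))
    Sig <- .make_pd(inflate * solve(H))
    L <- t(chol(Sig))
    Zi <- if (is.null(Z)) matrix(stats::rnorm(M * q), M, q) else Z[[i]]
    E <- sweep(Zi %*% t(L), 2, modes[i, ], "+")
    colnames(E) <- colnames(Om)
    ll_obs <- lli(E)
    lp <- -0.5 * rowSums((E %*% omI) * E) - 0.5 * (ldetOm + q * log(2 * pi))
    lq <- -0.5 * rowSums(Zi^2) - 0.5 * (2 * sum(log(diag(L))) + q * log(2 * pi))
    total <- total + (.logsumexp(ll_obs + lp - lq) - log(nrow(E)))
  }
  unname(total)
}

# adaptive Gauss-Hermite marginal log-likelihood (q <= 2)
.agq_loglik <- function(st, modes, Om, nodes = 31) {
  q <- ncol(Om)
  if (q > 2) stop("adaptive Gauss-Hermite is implemented for q <= 2 only")
  gh <- pracma::gaussHermite(nodes)
  omI <- solve(Om + diag(1e-10, q))
  ldetOm <- determinant(Om, logarithm = TRUE)$modulus
  n <- length(st$dose)
  if (q == 1) {
    zg <- matrix(gh$x, ncol = 1); lw <- log(gh$w)
  } else {
    zg <- as.matrix(expand.grid(gh$x, gh$x))
    lw <- log(outer(gh$w, gh$w))[cbind(rep(seq_len(nodes), nodes),
                                       rep(seq_len(nodes), each = nodes))]
  }
  total <- 0
  for (i in seq_len(n)) {
    lli <- .subject_ll_fun(st, i)
    post <- function(e) -(lli(matrix(e, 1, q, dimnames = list(NULL, colnames(Om)))) -
                            0.5 * drop(e %*% omI %*% e))
    H <- .make_pd(.fd_hessian(post, modes[i, ]))
    L <- t(chol(solve(H)))
    E <- sweep(sqrt(2) * zg %*% t(L), 2, modes[i, ], "+")
    colnames(E) <- colnames(Om)
    ll_obs <- lli(E)
    lp <- -0.5 * rowSums((E %*% omI) * E) - 0.5 * (ldetOm + q * log(2 * pi))
    # int g(e) de = sqrt(2)^q |L| sum_j w_j exp(z_j^2) g(e_j)
    lcorr <- rowSums(zg^2) + lw
    total <- total + .logsumexp(ll_obs + lp + lcorr) +
      q / 2 * log(2) + sum(log(diag(L)))
  }
  unname(total)
}

#' Marginal log-likelihood of a population model on a dataset
#'
#' Integrates the individual random effects out of the mixed-effects
#' likelihood, either by importance sampling around the conditional modes
#' (`"is"`, any number of random effects) or by adaptive Gauss-Hermite
#' quadrature (`"agq"`, up to two random effects).
#'
#' @param pop a [pop_model()].
#' @param study a `pk_study`; only subjects matching `pop$route` are used.
#' @param method `"is"` or `"agq"`.
#' @param M importance-sampling draws per subject.
#' @param nodes Gauss-Hermite nodes per dimension.
#' @param seed RNG seed for the importance draws.
#' @param blq `"exclude"` or `"censored"` (see [saem_control()]).
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(pop, study, method = c("is", "agq"), M = 1000,
                            nodes = 31, seed = 1,
                            blq = c("exclude", "censored")) {
  method <- match.arg(method)
  blq <- match.arg(blq)
  stopifnot(inherits(pop, "pop_model"), inherits(study, "pk_study"))
  mats <- .study_matrices(study, pop$route)
  lloq <- attr(study, "lloq"); if (is.null(lloq)) lloq <- 100
  st <- .state_from_pop(pop, mats, blq, lloq)
  Om <- .omega_matrix(pop)
  diag(Om) <- pmax(diag(Om), 1e-10)
  set.seed(seed)
  modes <- .eta_modes(st, Om)
  if (method == "is") .is_loglik(st, modes, Om, M = M)
  else .agq_loglik(st, modes, Om, nodes = nodes)
}

#' Fisher-information standard errors for a SAEM fit
#'
#' Approximates the observed Fisher information as minus the
#' finite-difference Hessian of the importance-sampled marginal
#' log-likelihood, evaluated with common random numbers and a proposal
#' frozen at the fitted conditional modes. Estimates and SEs are on the
#' estimation scale (transformed fixed effects, log random-effect SDs,
#' atanh correlations, log error components); covariate coefficients are
#' already on their natural additive scale. RSE is reported on the
#' natural scale for fixed effects (SEs mapped through the inverse
#' transform by the delta method).
#'
#' @param fit a `pk_fit`.
#' @param study the `pk_study` the fit was computed from.
#' @param M importance-sampling draws per subject.
#' @return the fit with `se`, `rse` (percent) and `wald` columns filled in.
#' @export
add_fisher_se <- function(fit, study, M = 500) {
  pop <- fit$model
  mats <- .study_matrices(study, pop$route)
  lloq <- attr(study, "lloq"); if (is.null(lloq)) lloq <- 100
  st <- .state_from_pop(pop, mats, fit$control$blq, lloq)
  q <- length(pop$omega)
  iiv <- names(pop$omega)
  est <- fit$estimates
  n <- length(st$dose)
  Om_hat <- .omega_matrix(pop)
  set.seed(fit$control$seed + 1L)
  modes <- .eta_modes(st, Om_hat, start = fit$eta)
  Z <- lapply(seq_len(n), function(i) matrix(stats::rnorm(M * q), M, q))
  # freeze per-subject proposals at the fitted model
  omI_hat <- solve(Om_hat + diag(1e-10, q))
  props <- lapply(seq_len(n), function(i) {
    lli <- .subject_ll_fun(st, i)
    post <- function(e) -(lli(matrix(e, 1, q, dimnames = list(NULL, iiv))) -
                            0.5 * drop(e %*% omI_hat %*% e))
    H <- .make_pd(.fd_hessian(post, modes[i, ]))
    Sig <- .make_pd(1.2 * solve(H))
    L <- t(chol(Sig))
    E <- sweep(Z[[i]] %*% t(L), 2, modes[i, ], "+")
    colnames(E) <- iiv
    lq <- -0.5 * rowSums(Z[[i]]^2) -
      0.5 * (2 * sum(log(diag(L))) + q * log(2 * pi))
    list(E = E, lq = lq)
  })

  pnames <- names(pop$fixed)
  beta_names <- names(est)[startsWith(names(est), "beta_")]
  ll_theta <- function(v) {
    mu <- v[pnames]
    beta <- pop$beta
    for (j in names(beta))
      beta[[j]][] <- v[paste0("beta_", j, "_", names(beta[[j]]))]
    om_sd <- exp(v[paste0("log_omega_", iiv)])
    Om <- diag(om_sd, q) %*%
      (if (is.null(pop$corr)) diag(q) else {
        R <- diag(q)
        dimnames(R) <- dimnames(pop$corr)
        cp <- which(upper.tri(pop$corr), arr.ind = TRUE)
        for (rr in seq_len(nrow(cp))) {
          nm <- paste0("atanh_corr_", iiv[cp[rr, 1]], "_", iiv[cp[rr, 2]])
          R[cp[rr, 1], cp[rr, 2]] <- R[cp[rr, 2], cp[rr, 1]] <- tanh(v[nm])
        }
        R
      }) %*% diag(om_sd, q)
    err <- c(a = exp(unname(v["log_a"])), b = exp(unname(v["log_b"])))
    sh <- .shift_matrix(beta, mats$covariate, pnames)
    omI <- solve(Om + diag(1e-10, q))
    ldetOm <- determinant(Om, logarithm = TRUE)$modulus
    total <- 0
    for (i in seq_len(n)) {
      lli <- .subject_ll_fun(st, i)
      E <- props[[i]]$E
      ll_obs <- lli(E, mu = mu, beta_shift = sh[i, ], err = err)
      lp <- -0.5 * rowSums((E %*% omI) * E) - 0.5 * (ldetOm + q * log(2 * pi))
      total <- total + (.logsumexp(ll_obs + lp - props[[i]]$lq) - log(nrow(E)))
    }
    total
  }
  H <- .fd_hessian(ll_theta, est, h = 0.01 * pmax(abs(est), 0.1))
  # flat or non-concave directions (boundary ridges of weakly identified
  # models) are clipped relative to the leading curvature, so their huge
  # variances cannot contaminate the well-determined directions
  ev <- eigen(-(H + t(H)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-6 * max(ev$values))
  V <- ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(est)
  # natural-scale RSE for structural fixed effects (delta method)
  rse <- 100 * se / pmax(abs(est), 1e-12)
  for (j in pnames) {
    nat <- pop$fixed[[j]]
    dnat <- if (pop$transforms[[j]] == "log") nat else nat * (1 - nat)
    rse[j] <- 100 * se[j] * abs(dnat) / abs(nat)
  }
  fit$se <- se
  fit$rse <- rse
  fit
}
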