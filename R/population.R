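#' Population pharmacokinetic model specification
#'
#' A `pop_model` bundles everything needed to map population quantities to
#' individual structural parameters: natural-scale population fixed effects,
#' additive covariate coefficients (beta) on the transformed scale, standard
#' deviations of the inter-individual random effects (Omega, transformed
#' scale) with optional correlations, and a combined residual-error model
#' with additive component `a` (ng/mL) and proportional component `b`.
#'
#' The individual model on the transformed scale is
#' \deqn{h(P_i) = h(P_{pop}) + \beta_{level(i)} + \eta_i,}
#' with `h` the log (rates, volumes) or logit (fractions; the intravenous
#' central volume) transform, and \eqn{\eta_i \sim N(0, \Omega)}. The
#' observation model is \eqn{y = f + (a + b f)\,\varepsilon},
#' \eqn{\varepsilon \sim N(0,1)} ("combined" error; the alternative
#' \eqn{\sqrt{a^2 + b^2 f^2}} form is available via `error_form`).
#'
#' @param route `"iv"` or `"oral"`; selects the structural model and the
#'   per-parameter transforms.
#' @param fixed named numeric vector of natural-scale population values; must
#'   cover the full structural parameter set of the route.
#' @param beta named list: per structural parameter, a named vector of
#'   covariate coefficients (transformed scale), one per non-reference level.
#' @param omega named numeric vector of random-effect SDs (transformed scale),
#'   a subset of the structural parameters. Parameters absent here carry no
#'   random effect.
#' @param corr optional correlation matrix over `names(omega)` (unit diagonal,
#'   symmetric, positive semi-definite). `NULL` means independence.
#' @param error numeric `c(a =, b =)`, both >= 0.
#' @param levels character vector of all covariate levels of the single
#'   categorical covariate axis (study source for iv, dose group for oral).
#' @param reference the reference level; its beta is identically 0.
#' @param error_form `"combined"` (SD = a + b f, default),
#'   `"combined2"` (SD = sqrt(a^2 + b^2 f^2)), `"additive"` (SD = a) or
#'   `"proportional"` (SD = b f).
#' @return an object of class `pop_model`.
#' @seealso [pop_model_iv()], [pop_model_oral()] for the published models.
#' @export
pop_model <- function(route = c("iv", "oral"), fixed, beta = list(),
                      omega = numeric(), corr = NULL,
                      error = c(a = 0, b = 0),
                      levels, reference,
                      error_form = c("combined", "combined2", "additive",
                                     "proportional")) {
  route <- match.arg(route)
  error_form <- match.arg(error_form)
  if (error_form == "additive") error[["b"]] <- 0
  if (error_form == "proportional") error[["a"]] <- 0
  tmap <- .transform_map(route)
  pnames <- names(tmap)
  if (!setequal(names(fixed), pnames))
    stop("fixed effects must name exactly: ", paste(pnames, collapse = ", "))
  fixed <- fixed[pnames]
  for (j in pnames) par_transform(fixed[[j]], tmap[[j]]) # validates ranges
  if (!reference %in% levels) stop("reference level must be one of `levels`")
  if (length(beta)) {
    if (!all(names(beta) %in% pnames))
      stop("beta refers to unknown parameter(s): ",
           paste(setdiff(names(beta), pnames), collapse = ", "))
    for (j in names(beta)) {
      bad <- setdiff(names(beta[[j]]), setdiff(levels, reference))
      if (length(bad))
        stop("beta[", j, "] refers to undeclared level(s): ",
             paste(bad, collapse = ", "),
             " (declared: ", paste(levels, collapse = ", "), ")")
    }
  }
  if (length(omega)) {
    if (!all(names(omega) %in% pnames))
      stop("omega refers to unknown parameter(s)")
    if (any(omega < 0)) stop("omega SDs must be >= 0")
  }
  if (!is.null(corr)) {
    q <- length(omega)
    if (!is.matrix(corr) || any(dim(corr) != q))
      stop("corr must be a ", q, "x", q, " matrix over names(omega)")
    if (max(abs(corr - t(corr))) > 1e-12 || any(abs(diag(corr) - 1) > 1e-12))
      stop("corr must be symmetric with unit diagonal")
    if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("corr must be positive semi-definite")
    dimnames(corr) <- list(names(omega), names(omega))
  }
  if (any(error < 0)) stop("error components a, b must be >= 0")
  structure(list(route = route, fixed = fixed, beta = beta, omega = omega,
                 corr = corr, error = c(a = unname(error[["a"]]),
                                        b = unname(error[["b"]])),
                 levels = levels, reference = reference,
                 transforms = tmap, error_form = error_form),
            class = "pop_model")
}

#' Published population models
#'
#' `pop_model_iv()` returns the final intravenous rutin model: two-compartment
#' disposition, extract source (GEXT) as covariate on V (logit scale) and k
#' (log scale), correlated random effects on V and k, combined residual error.
#' `pop_model_oral()` returns the final oral quercetin-conjugate model:
#' double-site delayed absorption with two-compartment disposition, dose group
#' as covariate on ka1, Tlag2, V and k (100 mg/kg pure rutin as reference),
#' independent random effects on ka1, ka2, F1 and V.
#'
#' @return a [pop_model()].
#' @export
pop_model_iv <- function() {
  corr <- matrix(c(1, -0.701, -0.701, 1), 2,
                 dimnames = list(c("V", "k"), c("V", "k")))
  pop_model(
    route = "iv",
    fixed = c(V = 0.0646, k = 1.47, k12 = 2.6, k21 = 13.6),
    beta = list(V = c(GEXT = 0.478), k = c(GEXT = 0.395)),
    omega = c(V = 0.306, k = 0.147),
    corr = corr,
    error = c(a = 38.9, b = 0.128),
    levels = c("RU", "GEXT"), reference = "RU"
  )
}

#' @rdname pop_model_iv
#' @export
pop_model_oral <- function() {
  pop_model(
    route = "oral",
    fixed = c(ka1 = 0.104, ka2 = 0.411, F1 = 0.565, Tlag2 = 3.91,
              V = 13.2, k = 1.42, k12 = 0.279, k21 = 0.268),
    beta = list(
      ka1   = c(D75 = 0.281,  D500 = 1.94,   D750 = 3.15,   D1000 = 3.77),
      Tlag2 = c(D75 = -0.0177, D500 = 0.149, D750 = -0.695, D1000 = -1.17),
      V     = c(D75 = 0.251,  D500 = -0.645, D750 = 0.245,  D1000 = 1.09),
      k     = c(D75 = -0.225, D500 = -1.3,   D750 = -2.13,  D1000 = -3.57)),
    omega = c(ka1 = 0.189, ka2 = 0.236, F1 = 0.214, V = 0.0819),
    error = c(a = 8.87, b = 0.0457),
    levels = c("D100", "D75", "D500", "D750", "D1000"), reference = "D100"
  )
}

# transformed-scale population value of parameter j at covariate level
.psi_level <- function(pop, j, level) {
  psi <- par_transform(pop$fixed[[j]], pop$transforms[[j]])
  b <- pop$beta[[j]]
  if (!is.null(b) && level %in% names(b)) psi <- psi + b[[level]]
  psi
}

#' Individual structural parameters from the population model
#'
#' Applies the covariate shift and the individual random effect on the
#' transformed scale, then back-transforms. With the reference level and
#' `eta = 0` the population values are returned exactly.
#'
#' @param pop a [pop_model()].
#' @param level covariate level label of the individual.
#' @param eta named numeric vector of random effects over `names(pop$omega)`
#'   (transformed scale); missing entries default to 0.
#' @return named numeric vector of natural-scale structural parameters.
#' @examples
#' individual_parameters(pop_model_iv(), "GEXT")[["V"]] # ~0.100 L/kg
#' @export
individual_parameters <- function(pop, level, eta = NULL) {
  stopifnot(inherits(pop, "pop_model"))
  if (!level %in% pop$levels)
    stop("unknown covariate level '", level, "'; declared levels: ",
         paste(pop$levels, collapse = ", "))
  full_eta <- setNames(numeric(length(pop$omega)), names(pop$omega))
  if (!is.null(eta)) {
    bad <- setdiff(names(eta), names(pop$omega))
    if (length(bad))
      stop("eta names not among random-effect parameters: ",
           paste(bad, collapse = ", "))
    full_eta[names(eta)] <- eta
  }
  out <- vapply(names(pop$fixed), function(j) {
    psi <- .psi_level(pop, j, level)
    if (j %in% names(full_eta)) psi <- psi + full_eta[[j]]
    par_backtransform(psi, pop$transforms[[j]])
  }, numeric(1))
  out
}

# random-effect covariance matrix (q x q over names(omega))
.omega_matrix <- function(pop) {
  q <- length(pop$omega)
  R <- if (is.null(pop$corr)) diag(q) else pop$corr
  if (q == 0) return(matrix(numeric(0), 0, 0))
  S <- diag(pop$omega, q) %*% R %*% diag(pop$omega, q)
  dimnames(S) <- list(names(pop$omega), names(pop$omega))
  S
}

# draw from N(0, Sigma) via eigen decomposition (handles singular Sigma)
.rmvnorm0 <- function(n, Sigma) {
  q <- ncol(Sigma)
  if (q == 0) return(matrix(numeric(0), n, 0))
  e <- eigen(Sigma, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), q)
  Z <- matrix(stats::rnorm(n * q), n, q)
  out <- Z %*% t(L)
  colnames(out) <- colnames(Sigma)
  out
}

#' Sample individual random effects
#'
#' Draws zero-mean multivariate normal random effects on the transformed
#' scale with covariance built from the Omega SDs and the declared
#' correlations. Reproducible under a fixed seed.
#'
#' @param pop a [pop_model()].
#' @param n number of individuals.
#' @param seed optional integer seed (set locally, not leaking to the caller's
#'   RNG stream when supplied).
#' @return n x q matrix with columns `names(pop$omega)`.
#' @export
sample_etas <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "pop_model"), n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  .rmvnorm0(n, .omega_matrix(pop))
}

#' Residual-error standard deviation
#'
#' Combined residual error: SD = a + b f (default); alternatives are the
#' root-sum-of-squares form sqrt(a^2 + b^2 f^2) and the pure additive or
#' proportional reductions.
#'
#' @param error numeric `c(a =, b =)`.
#' @param f predicted concentration(s), ng/mL, >= 0.
#' @param form `"combined"`, `"combined2"`, `"additive"` or
#'   `"proportional"`.
#' @return SD in ng/mL, same length as `f`.
#' @export
residual_sd <- function(error, f, form = c("combined", "combined2",
                                           "additive", "proportional")) {
  form <- match.arg(form)
  if (any(f < 0)) stop("predicted concentrations must be >= 0")
  a <- unname(error[["a"]]); b <- unname(error[["b"]])
  if (a < 0 || b < 0) stop("error components must be >= 0")
  unname(.sd_model(c(a, b), f, form))
}
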