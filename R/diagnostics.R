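#' Wald test of an estimated quantity
#'
#' `z = estimate / SE` with a two-sided normal p-value; the usual decision
#' rule for keeping a covariate coefficient in the model (significant at
#' p < 0.05).
#'
#' @param fit either a `pk_fit` with standard errors (see [add_fisher_se()])
#'   or a list with numeric vectors `estimates` and `se`.
#' @param name name of the quantity (e.g. `"beta_V_GEXT"`).
#' @return list with `estimate`, `se`, `z`, `p`, `significant` (p < 0.05).
#' @examples
#' wald_test(list(estimates = c(beta_V_GEXT = 0.478),
#'                se = c(beta_V_GEXT = 0.128)), "beta_V_GEXT")
#' @export
wald_test <- function(fit, name) {
  if (is.null(fit$se))
    stop("fit carries no standard errors; run add_fisher_se() first")
  if (!name %in% names(fit$estimates) || !name %in% names(fit$se))
    stop("no estimate/SE named '", name, "'")
  est <- unname(fit$estimates[[name]])
  se <- unname(fit$se[[name]])
  if (!is.finite(se) || se <= 0) stop("SE for '", name, "' is not positive")
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  list(estimate = est, se = se, z = z, p = p, significant = p < 0.05)
}

#' Individual weighted residuals
#'
#' `IWRES = (y - f_ind) / (a + b f_ind)` with the individual prediction
#' `f_ind` evaluated at the conditional modes of the random effects. For a
#' well-specified model these are approximately standard normal.
#'
#' @param fit a `pk_fit`.
#' @return data frame with `id`, `time`, `dv`, `f_ind`, `iwres`.
#' @export
compute_iwres <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  fit$iwres
}

#' Rank fits of the same data by AIC
#'
#' @param fits named list of `pk_fit` objects fitted on identical data.
#' @return data frame sorted by ascending AIC with `dAIC` relative to the
#'   best model.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  fps <- lapply(fits, `[[`, "fingerprint")
  for (i in seq_along(fps))
    if (!isTRUE(all.equal(fps[[1]], fps[[i]], tolerance = 1e-8)))
      stop("fits were not computed on identical data")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  out <- data.frame(model = nm,
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    npar = vapply(fits, `[[`, numeric(1), "npar"),
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  out <- out[order(out$AIC), ]
  out$dAIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}
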