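#' Parameter table of a fit, in the published layout
#'
#' Flattens a `pk_fit` into a Value / S.E. / R.S.E.(%) table: natural-scale
#' population fixed effects, covariate coefficients (transformed-scale
#' shifts), random-effect SDs, correlations, and the residual-error
#' components. Standard errors of log-/logit-/atanh-parameterised quantities
#' are mapped to the reported scale by the delta method. Without a prior
#' [add_fisher_se()] step the SE and RSE columns are `NA`.
#'
#' @param fit a `pk_fit`.
#' @return data frame with columns `name`, `value`, `se`, `rse`.
#' @export
fit_parameter_table <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  pop <- fit$model
  est <- fit$estimates
  se <- if (is.null(fit$se)) setNames(rep(NA_real_, length(est)),
                                      names(est)) else fit$se
  rows <- list()
  add <- function(name, value, se_val) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, value = value, se = se_val,
      rse = if (is.finite(se_val) && abs(value) > 0)
        100 * se_val / abs(value) else NA_real_)
  }
  for (j in names(pop$fixed)) {
    v <- pop$fixed[[j]]
    dnat <- if (pop$transforms[[j]] == "log") v else v * (1 - v)
    add(paste0(j, "_pop"), v, se[[j]] * abs(dnat))
  }
  for (j in names(pop$beta)) for (l in names(pop$beta[[j]])) {
    nm <- paste0("beta_", j, "_", l)
    add(nm, pop$beta[[j]][[l]], se[[nm]])
  }
  for (j in names(pop$omega)) {
    nm <- paste0("log_omega_", j)
    add(paste0("omega_", j), pop$omega[[j]], se[[nm]] * pop$omega[[j]])
  }
  if (!is.null(pop$corr)) {
    cp <- which(upper.tri(pop$corr), arr.ind = TRUE)
    for (rr in seq_len(nrow(cp))) {
      i <- cp[rr, 1]; jj <- cp[rr, 2]
      rho <- pop$corr[i, jj]
      nm <- paste0("atanh_corr_", rownames(pop$corr)[i], "_",
                   colnames(pop$corr)[jj])
      add(paste0("corr_", rownames(pop$corr)[i], "_",
                 colnames(pop$corr)[jj]), rho,
          if (nm %in% names(se)) se[[nm]] * (1 - rho^2) else NA_real_)
    }
  }
  add("a", pop$error[["a"]], se[["log_a"]] * pop$error[["a"]])
  add("b", pop$error[["b"]], se[["log_b"]] * pop$error[["b"]])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rebuild a population model from a parameter table
#'
#' Inverse of [fit_parameter_table()]: reconstructs a [pop_model()] from the
#' flat `name`/`value` table plus the fixed structural facts of the route
#' (transforms, covariate levels, reference, error form).
#'
#' @param tab data frame with `name` and `value` (extra columns ignored).
#' @param route `"iv"` or `"oral"`.
#' @param levels,reference covariate axis; defaults to the published axes.
#' @param error_form residual-error form.
#' @return a [pop_model()].
#' @export
model_from_parameter_table <- function(tab, route = c("iv", "oral"),
                                       levels = NULL, reference = NULL,
                                       error_form = "combined") {
  route <- match.arg(route)
  if (is.null(levels))
    levels <- if (route == "iv") c("RU", "GEXT") else
      c("D100", "D75", "D500", "D750", "D1000")
  if (is.null(reference)) reference <- levels[1]
  val <- setNames(tab$value, tab$name)
  pnames <- names(.transform_map(route))
  fixed <- setNames(val[paste0(pnames, "_pop")], pnames)
  beta <- list()
  bn <- grep("^beta_", tab$name, value = TRUE)
  for (nm in bn) {
    parts <- strsplit(sub("^beta_", "", nm), "_")[[1]]
    beta[[parts[1]]][[parts[2]]] <- unname(val[[nm]])
  }
  beta <- lapply(beta, unlist)
  on <- grep("^omega_", tab$name, value = TRUE)
  omega <- setNames(val[on], sub("^omega_", "", on))
  corr <- NULL
  cn <- grep("^corr_", tab$name, value = TRUE)
  if (length(cn) && length(omega)) {
    corr <- diag(length(omega))
    dimnames(corr) <- list(names(omega), names(omega))
    for (nm in cn) {
      parts <- strsplit(sub("^corr_", "", nm), "_")[[1]]
      corr[parts[1], parts[2]] <- corr[parts[2], parts[1]] <- val[[nm]]
    }
  }
  pop_model(route, fixed, beta, omega, corr,
            error = c(a = unname(val[["a"]]), b = unname(val[["b"]])),
            levels = levels, reference = reference, error_form = error_form)
}
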