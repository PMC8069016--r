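#' Simulate a complete synthetic rat study
#'
#' For every rat in the design: draw its random effects from the population
#' model of its route, derive individual structural parameters with the
#' group's covariate level, evaluate the structural model at the scheduled
#' sampling times, add combined residual noise, and censor values below the
#' quantification limit as BLQ. The pre-dose t = 0 record is always emitted
#' as BLQ. Fully reproducible under a fixed seed.
#'
#' @param design a [default_design()]-style `study_design`.
#' @param pop_iv,pop_oral [pop_model()]s for the routes present in the design
#'   (either may be `NULL` if its route is absent).
#' @param seed integer seed.
#' @param noise if `FALSE`, residual noise and random effects are still drawn
#'   per the models (set Omega/a/b to zero in the model to remove them).
#' @param censor if `FALSE`, no LLOQ censoring is applied (used for
#'   calibration checks); the t = 0 pre-dose record is still BLQ.
#' @return object of class `pk_study`: a list of `pk_subject` records, each
#'   with `id`, `group`, `route`, `source`, `covariate`, `dose` (mg/kg rutin
#'   equivalent), `dose_admin`, `times`, `dv` (ng/mL, `NA` when BLQ), `blq`
#'   (logical), plus attributes `design` and `seed`.
#' @examples
#' st <- simulate_study(default_design(), pop_model_iv(), pop_model_oral(), seed = 1)
#' length(st) # 50 rats
#' @export
simulate_study <- function(design, pop_iv = NULL, pop_oral = NULL, seed,
                           noise = TRUE, censor = TRUE) {
  stopifnot(inherits(design, "study_design"))
  g <- design$groups
  if (any(g$route == "iv") && is.null(pop_iv))
    stop("design contains iv groups but no iv population model was given")
  if (any(g$route == "oral") && is.null(pop_oral))
    stop("design contains oral groups but no oral population model was given")
  if (!is.null(pop_iv) && pop_iv$route != "iv")
    stop("pop_iv must be an iv-route model")
  if (!is.null(pop_oral) && pop_oral$route != "oral")
    stop("pop_oral must be an oral-route model")
  for (i in seq_len(nrow(g))) {
    pop <- if (g$route[i] == "iv") pop_iv else pop_oral
    if (!g$covariate[i] %in% pop$levels)
      stop("group ", g$group[i], " covariate level '", g$covariate[i],
           "' is not declared in the ", g$route[i], " model")
  }
  set.seed(seed)
  subjects <- list()
  id <- 0L
  for (i in seq_len(nrow(g))) {
    route <- g$route[i]
    pop <- if (route == "iv") pop_iv else pop_oral
    times <- if (route == "iv") design$iv_times else design$oral_times
    etas <- .rmvnorm0(g$n[i], .omega_matrix(pop))
    for (r in seq_len(g$n[i])) {
      id <- id + 1L
      eta <- if (ncol(etas)) etas[r, ] else NULL
      th <- individual_parameters(pop, g$covariate[i], eta)
      f0 <- if (route == "iv") {
        drop(.conc_iv_matrix(th[["V"]], th[["k"]], th[["k12"]], th[["k21"]],
                             g$dose_ruteq[i], times))
      } else {
        drop(.conc_oral_matrix(th[["ka1"]], th[["ka2"]], th[["F1"]],
                               th[["Tlag2"]], th[["V"]], th[["k"]],
                               th[["k12"]], th[["k21"]],
                               g$dose_ruteq[i], times))
      }
      f <- pmax(f0, 0) # guard tiny negative round-off from the closed form
      y <- if (noise) {
        f + residual_sd(pop$error, f, pop$error_form) * stats::rnorm(length(f))
      } else f
      blq <- times == 0 | (if (censor) y < design$lloq else !is.finite(y))
      dv <- ifelse(blq, NA_real_, y)
      subjects[[id]] <- structure(list(
        id = id, group = g$group[i], route = route, source = g$source[i],
        covariate = g$covariate[i], dose = g$dose_ruteq[i],
        dose_admin = g$dose_admin[i], times = times, dv = dv, blq = blq),
        class = "pk_subject")
    }
  }
  structure(subjects, class = "pk_study", design = design, seed = seed,
            lloq = design$lloq)
}

#' @export
print.pk_study <- function(x, ...) {
  routes <- table(vapply(x, `[[`, "", "route"))
  cat("pk_study:", length(x), "subjects (",
      paste(names(routes), routes, sep = ": ", collapse = ", "), ")\n")
  invisible(x)
}

#' Flatten a study to the NONMEM-style dataset table
#'
#' One dose row per subject at TIME 0 (AMT set, DV empty), then one row per
#' scheduled observation with DV xor BLQ = 1.
#'
#' @param x a `pk_study`.
#' @param ... unused.
#' @return data frame with columns ID, TIME, DV, BLQ, AMT, ROUTE, SOURCE,
#'   DOSEGRP, GROUP.
#' @export
as.data.frame.pk_study <- function(x, ...) {
  rows <- lapply(x, function(s) {
    dosegrp <- paste0("D", s$dose_admin)
    rbind(
      data.frame(ID = s$id, TIME = 0, DV = NA_real_, BLQ = NA_integer_,
                 AMT = s$dose, ROUTE = s$route, SOURCE = s$source,
                 DOSEGRP = dosegrp, GROUP = s$group),
      data.frame(ID = s$id, TIME = s$times, DV = s$dv,
                 BLQ = as.integer(s$blq), AMT = NA_real_, ROUTE = s$route,
                 SOURCE = s$source, DOSEGRP = dosegrp, GROUP = s$group))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# subjects of one route, as matrices used by the estimation code:
# list(times, Y (n x T, NA where not quantifiable), BLQ mask, dose, covariate)
.study_matrices <- function(study, route) {
  subs <- Filter(function(s) s$route == route, study)
  if (!length(subs)) stop("no subjects with route '", route, "' in the data")
  times <- subs[[1]]$times
  for (s in subs) if (!identical(s$times, times))
    stop("all subjects of one route must share a sampling schedule")
  Y <- t(vapply(subs, `[[`, numeric(length(times)), "dv"))
  B <- t(vapply(subs, `[[`, logical(length(times)), "blq"))
  list(subjects = subs, times = times, Y = Y, BLQ = B,
       dose = vapply(subs, `[[`, numeric(1), "dose"),
       covariate = vapply(subs, `[[`, "", "covariate"),
       id = vapply(subs, `[[`, integer(1), "id"))
}
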