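#' Trial design of the rat pharmacokinetic study
#'
#' `default_design()` reproduces the published design: 10 groups of 5 Wistar
#' rats. Pure rutin: 1.45 and 2.9 mg/kg i.v., 75 and 100 mg/kg p.o.
#' Calyx extract: 250, 500 and 1000 mg/kg i.v. and 500, 750 and 1000 mg/kg
#' p.o., dosed in the models as the rutin-equivalent amount (extract dose x
#' 0.0148, from a rutin content of 14.8 ug/mg). Sampling: 14 times per route
#' (i.v. up to 12 h, p.o. up to 24 h, including the printed 0.30 h point);
#' quantification limit 100 ng/mL.
#'
#' Covariate levels attached to each group are the ones used by the final
#' population models: study source (`RU` reference / `GEXT`) for the
#' intravenous model and dose group (`D100` reference, `D75`, `D500`, `D750`,
#' `D1000`) for the oral model.
#'
#' @param n_per_group rats per group (default 5).
#' @return object of class `study_design`: a list with `groups` (data frame),
#'   `iv_times`, `oral_times`, `lloq`.
#' @examples
#' default_design()$groups
#' @export
default_design <- function(n_per_group = 5) {
  stopifnot(n_per_group >= 1)
  groups <- data.frame(
    group = 1:10,
    intervention = rep(c("pure rutin", "extract"), c(4, 6)),
    source = rep(c("RU", "HEE"), c(4, 6)),
    route = c("iv", "iv", "oral", "oral", "iv", "iv", "iv",
              "oral", "oral", "oral"),
    dose_admin = c(1.45, 2.9, 75, 100, 250, 500, 1000, 500, 750, 1000),
    stringsAsFactors = FALSE
  )
  rutin_content <- 0.0148 # mg rutin per mg extract
  groups$dose_ruteq <- ifelse(groups$source == "HEE",
                              groups$dose_admin * rutin_content,
                              groups$dose_admin)
  groups$covariate <- ifelse(
    groups$route == "iv",
    ifelse(groups$source == "RU", "RU", "GEXT"),
    paste0("D", groups$dose_admin))
  groups$n <- n_per_group
  structure(list(
    groups = groups,
    iv_times = c(0, 0.05, 0.166, 0.333, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12),
    oral_times = c(0, 0.083, 0.25, 0.30, 0.75, 1, 2, 3, 4, 6, 8, 10, 12, 24),
    lloq = 100
  ), class = "study_design")
}

#' Restrict a design to one administration route
#'
#' @param design a `study_design`.
#' @param route `"iv"` or `"oral"`.
#' @return the design with only the matching groups.
#' @export
design_route <- function(design, route = c("iv", "oral")) {
  route <- match.arg(route)
  stopifnot(inherits(design, "study_design"))
  design$groups <- design$groups[design$groups$route == route, , drop = FALSE]
  design
}
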