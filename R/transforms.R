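#' Parameter-scale transforms
#'
#' Structural PK parameters are estimated on a transformed scale: `log` for
#' strictly positive rate constants and volumes, `logit` for quantities
#' constrained to (0, 1) (the absorbed fraction F1, and the central volume in
#' the intravenous model, whose population value of 0.0646 L/kg lies inside
#' the unit interval). `par_transform` maps unit scale -> transformed scale;
#' `par_backtransform` inverts it.
#'
#' @param x numeric vector on the unit (natural) scale.
#' @param kind `"log"` or `"logit"`.
#' @return numeric vector on the transformed scale (or back).
#' @examples
#' par_backtransform(par_transform(0.0646, "logit"), "logit")
#' @export
par_transform <- function(x, kind = c("log", "logit")) {
  kind <- match.arg(kind)
  if (kind == "log") {
    if (any(x <= 0)) stop("log transform requires strictly positive values")
    log(x)
  } else {
    if (any(x <= 0 | x >= 1))
      stop("logit transform requires values strictly inside (0, 1); got ",
           paste(signif(x[x <= 0 | x >= 1], 4), collapse = ", "))
    log(x / (1 - x))
  }
}

#' @rdname par_transform
#' @export
par_backtransform <- function(x, kind = c("log", "logit")) {
  kind <- match.arg(kind)
  if (kind == "log") exp(x) else 1 / (1 + exp(-x))
}

# transform kind per structural parameter, by route
.transform_map <- function(route) {
  if (route == "iv") {
    c(V = "logit", k = "log", k12 = "log", k21 = "log")
  } else {
    c(ka1 = "log", ka2 = "log", F1 = "logit", Tlag2 = "log",
      V = "log", k = "log", k12 = "log", k21 = "log")
  }
}
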