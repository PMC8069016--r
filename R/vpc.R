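#' Visual predictive check
#'
#' Simulates `n_sim` replicate studies under a population model and the
#' study design, and summarises, per dose group and scheduled sampling time,
#' the 5th/50th/95th percentile prediction bands together with the empirical
#' percentiles of the observed data. The coverage fraction is the proportion
#' of quantifiable observations (t > 0) falling inside the 90% band of
#' their group and time.
#'
#' @param pop a [pop_model()] (typically the fitted model of a `pk_fit`).
#' @param design a `study_design` restricted to `pop$route` groups (other
#'   groups are ignored).
#' @param data a `pk_study` with the observations being checked.
#' @param n_sim number of replicate studies (>= 2).
#' @param seed RNG seed.
#' @return object of class `pk_vpc`: list with `bands` (data frame: group,
#'   time, lo, med, hi, obs_lo, obs_med, obs_hi, n_obs), `coverage`
#'   (fraction inside the 90% band) and `n_obs`.
#' @export
vpc <- function(pop, design, data, n_sim = 1000, seed = 1) {
  stopifnot(inherits(pop, "pop_model"), inherits(design, "study_design"),
            inherits(data, "pk_study"))
  if (n_sim < 2) stop("n_sim must be >= 2")
  set.seed(seed)
  g <- design$groups[design$groups$route == pop$route, , drop = FALSE]
  if (!nrow(g)) stop("design has no groups with route '", pop$route, "'")
  times <- if (pop$route == "iv") design$iv_times else design$oral_times
  Om <- .omega_matrix(pop)
  tmap <- pop$transforms
  pnames <- names(pop$fixed)
  mu <- vapply(pnames, function(j) par_transform(pop$fixed[[j]], tmap[[j]]),
               numeric(1))
  bands <- list()
  for (i in seq_len(nrow(g))) {
    nr <- n_sim * g$n[i]
    eta <- .rmvnorm0(nr, Om)
    shift <- .shift_matrix(pop$beta, rep(g$covariate[i], nr), pnames)
    Phi <- .build_phi(mu, shift, eta)
    f <- pmax(.predict_matrix(pop$route, .natural(Phi, tmap),
                              rep(g$dose_ruteq[i], nr), times), 0)
    sdm <- .sd_model(pop$error, f, pop$error_form)
    y <- f + sdm * matrix(stats::rnorm(length(f)), nrow(f))
    qs <- apply(y, 2, stats::quantile, probs = c(0.05, 0.5, 0.95))
    bands[[i]] <- data.frame(group = g$group[i], time = times,
                             lo = qs[1, ], med = qs[2, ], hi = qs[3, ])
  }
  bands <- do.call(rbind, bands)
  rownames(bands) <- NULL
  # empirical percentiles of the observed data, and coverage
  obs <- do.call(rbind, lapply(Filter(function(s) s$route == pop$route, data),
                               function(s) data.frame(group = s$group,
                                                      time = s$times,
                                                      dv = s$dv)[!s$blq, ]))
  bands$obs_lo <- bands$obs_med <- bands$obs_hi <- NA_real_
  bands$n_obs <- 0L
  inside <- logical(0)
  for (r in seq_len(nrow(bands))) {
    sel <- obs$group == bands$group[r] & obs$time == bands$time[r]
    v <- obs$dv[sel]
    if (length(v)) {
      bands$obs_lo[r] <- unname(stats::quantile(v, 0.05))
      bands$obs_med[r] <- unname(stats::quantile(v, 0.5))
      bands$obs_hi[r] <- unname(stats::quantile(v, 0.95))
      bands$n_obs[r] <- length(v)
      inside <- c(inside, v >= bands$lo[r] & v <= bands$hi[r])
    }
  }
  stopifnot(all(bands$lo <= bands$med & bands$med <= bands$hi))
  structure(list(bands = bands,
                 coverage = if (length(inside)) mean(inside) else NA_real_,
                 n_obs = length(inside)),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat("VPC:", x$n_obs, "observations, coverage of the 90% band:",
      format(x$coverage, digits = 3), "\n")
  invisible(x)
}
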