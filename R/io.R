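#' Read and write the longitudinal dataset CSV
#'
#' The dataset dialect is a comma-separated, UTF-8, '.'-decimal table with
#' exactly the columns `ID, TIME, DV, BLQ, AMT, ROUTE, SOURCE, DOSEGRP,
#' GROUP`. Each subject has one dose row at TIME 0 (AMT set, DV and BLQ
#' empty) and one row per scheduled observation carrying either a numeric DV
#' (BLQ = 0) or BLQ = 1 with an empty DV. Files written by
#' `write_pk_dataset()` parse back to an equal in-memory study.
#'
#' @param path file path.
#' @param lloq quantification limit attached to the study on read, ng/mL.
#' @return `read_pk_dataset()` returns a `pk_study`; `write_pk_dataset()`
#'   returns `path` invisibly.
#' @export
read_pk_dataset <- function(path, lloq = 100) {
  if (!file.exists(path)) stop("no such file: ", path)
  expected <- c("ID", "TIME", "DV", "BLQ", "AMT", "ROUTE", "SOURCE",
                "DOSEGRP", "GROUP")
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  unknown <- setdiff(hdr, expected)
  if (length(unknown))
    stop("unknown column(s) in dataset: ", paste(unknown, collapse = ", "))
  missing <- setdiff(expected, hdr)
  if (length(missing))
    stop("missing column(s) in dataset: ", paste(missing, collapse = ", "))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ID = "integer", TIME = "numeric",
                                       DV = "numeric", BLQ = "integer",
                                       AMT = "numeric", ROUTE = "character",
                                       SOURCE = "character",
                                       DOSEGRP = "character",
                                       GROUP = "integer")[expected])
  bad <- which(!is.na(df$DV) & !is.na(df$BLQ) & df$BLQ == 1)
  if (length(bad))
    stop("DV and BLQ both set on line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  subjects <- list()
  for (sid in unique(df$ID)) {
    d <- df[df$ID == sid, , drop = FALSE]
    dose_rows <- d[!is.na(d$AMT), , drop = FALSE]
    if (nrow(dose_rows) != 1L || dose_rows$TIME[1] != 0)
      stop("subject ", sid, " must have exactly one dose row at TIME 0")
    obs <- d[is.na(d$AMT), , drop = FALSE]
    if (!nrow(obs)) stop("subject ", sid, " has no observation rows")
    badrow <- which(is.na(obs$DV) & (is.na(obs$BLQ) | obs$BLQ != 1))
    if (length(badrow))
      stop("subject ", sid, ": observation rows need DV or BLQ = 1")
    obs <- obs[order(obs$TIME), , drop = FALSE]
    dosegrp <- obs$DOSEGRP[1]
    route <- obs$ROUTE[1]
    covariate <- if (route == "iv") {
      if (obs$SOURCE[1] == "RU") "RU" else "GEXT"
    } else {
      dosegrp
    }
    subjects[[length(subjects) + 1L]] <- structure(list(
      id = sid, group = obs$GROUP[1], route = route, source = obs$SOURCE[1],
      covariate = covariate, dose = dose_rows$AMT[1],
      dose_admin = as.numeric(sub("^D", "", dosegrp)),
      times = obs$TIME, dv = obs$DV, blq = obs$BLQ == 1),
      class = "pk_subject")
  }
  structure(subjects, class = "pk_study", lloq = lloq)
}

#' @param study a `pk_study`.
#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(study, path) {
  stopifnot(inherits(study, "pk_study"))
  df <- as.data.frame(study)
  num <- function(v) ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  out <- data.frame(ID = df$ID, TIME = num(df$TIME), DV = num(df$DV),
                    BLQ = ifelse(is.na(df$BLQ), "", df$BLQ),
                    AMT = num(df$AMT), ROUTE = df$ROUTE, SOURCE = df$SOURCE,
                    DOSEGRP = df$DOSEGRP, GROUP = df$GROUP)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
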