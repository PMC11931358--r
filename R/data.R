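#' Validate a subject-level survival data frame
#'
#' Checks the schema used throughout the package: one row per subject with a
#' nonnegative follow-up `time`, a binary `event` indicator (1 = event
#' observed, 0 = censored), optionally a binary `arm` indicator
#' (1 = treatment, 0 = control) and numeric baseline covariates free of
#' missing values.
#'
#' @param data A data frame.
#' @param covariates Character vector of covariate column names to validate
#'   (may be `NULL`).
#' @param require_arm Require a valid `arm` column?
#' @return `data` as a tibble, invisibly validated.
#' @export
check_survival_data <- function(data, covariates = NULL, require_arm = TRUE) {
  data <- as_tibble(data)
  for (col in c("time", "event")) {
    if (!col %in% names(data)) abort(sprintf("missing required column '%s'", col))
  }
  if (nrow(data) < 2L) abort("need at least 2 subjects")
  if (anyNA(data$time) || any(data$time < 0)) {
    bad <- which(is.na(data$time) | data$time < 0)[1]
    abort(sprintf("negative or missing time in row %d", bad))
  }
  if (!all(data$event %in% c(0, 1))) {
    abort("event must be coded 0 (censored) / 1 (event)")
  }
  if (require_arm) {
    if (!"arm" %in% names(data)) abort("missing required column 'arm'")
    if (!all(data$arm %in% c(0, 1))) abort("arm must be coded 0 (control) / 1 (treatment)")
  }
  for (v in covariates) {
    if (!v %in% names(data)) abort(sprintf("covariate column '%s' not found", v))
    if (!is.numeric(data[[v]])) abort(sprintf("covariate '%s' must be numeric", v))
    if (anyNA(data[[v]])) abort(sprintf("covariate '%s' contains missing values", v))
  }
  data
}

#' Read subject-level survival data from delimited text
#'
#' Reads a CSV/TSV file with one row per subject, maps the named columns onto
#' the canonical schema (`time`, `event`, `arm`, covariates) and validates it.
#' Rows with missing covariate values are dropped with a message, mirroring
#' the usual complete-case handling of baseline covariates.
#'
#' @param path Path to a delimited text file.
#' @param time,event,arm Names of the corresponding columns in the file
#'   (`arm = NULL` for single-group data such as reference or blinded sets).
#' @param covariates Covariate column names; `NULL` selects every remaining
#'   numeric column.
#' @param delim Field delimiter; guessed from the file extension when `NULL`.
#' @return A validated tibble with columns `time`, `event`, optionally `arm`,
#'   and the covariates.
#' @export
read_survival_data <- function(path, time = "time", event = "event",
                               arm = "arm", covariates = NULL, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c(time, event)) {
    if (!col %in% names(raw)) abort(sprintf("missing required column '%s'", col))
  }
  has_arm <- !is.null(arm) && arm %in% names(raw)
  out <- tibble(time = as.numeric(raw[[time]]), event = as.numeric(raw[[event]]))
  if (has_arm) out$arm <- as.numeric(raw[[arm]])
  if (is.null(covariates)) {
    rest <- setdiff(names(raw), c(time, event, arm, "id"))
    covariates <- rest[vapply(raw[rest], is.numeric, logical(1))]
  }
  for (v in covariates) {
    if (!v %in% names(raw)) abort(sprintf("covariate column '%s' not found", v))
    out[[v]] <- as.numeric(raw[[v]])
  }
  if (length(covariates)) {
    cc <- stats::complete.cases(out[covariates])
    if (any(!cc)) {
      inform(sprintf("dropped %d row(s) with missing covariate values", sum(!cc)))
      out <- out[cc, ]
    }
  }
  check_survival_data(out, covariates = covariates, require_arm = has_arm)
}

#' Write subject-level survival data to delimited text
#'
#' @param data A survival data frame.
#' @param path Output path; extension `.tsv` selects tab delimiting.
#' @return `data`, invisibly.
#' @export
write_survival_data <- function(data, path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(data, path, delim = delim)
  invisible(data)
}

# covariate matrix helper: returns NULL when no covariates requested
.cov_matrix <- function(data, covariates) {
  if (is.null(covariates) || !length(covariates)) return(NULL)
  data <- check_survival_data(data, covariates = covariates, require_arm = FALSE)
  as.matrix(data[covariates])
}

# default covariate set: every numeric column outside the core schema
.default_covariates <- function(data) {
  rest <- setdiff(names(data), c("time", "event", "arm", "id"))
  rest[vapply(data[rest], is.numeric, logical(1))]
}
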