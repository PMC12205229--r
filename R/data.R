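#' Joint longitudinal/survival dataset
#'
#' Bundles a long-format table of repeated marker measurements with a
#' one-row-per-subject survival table and validates their consistency.
#'
#' Required longitudinal columns: `id`, `trial`, `time`, `value`. Required
#' survival columns: `id`, `trial`, `time` (follow-up), `event` (0/1),
#' `treatment` (0/1); any further numeric columns are treated as baseline
#' covariates. Indicators must be literally 0/1 — no factor recoding, so an
#' arm swap cannot happen silently. Measurements recorded after a subject's
#' follow-up time are rejected (not dropped): the likelihood conditions on
#' measurements up to the event/censoring time, and silent truncation would
#' hide data errors.
#'
#' @param longitudinal Data frame of repeated measurements.
#' @param survival Data frame with one row per subject.
#' @param tau Study horizon; defaults to the maximum follow-up time.
#' @return An object of class `"joint_dataset"` with elements
#'   `longitudinal`, `survival`, `tau`, `trials`.
#' @export
joint_dataset <- function(longitudinal, survival, tau = NULL) {
  need_l <- c("id", "trial", "time", "value")
  need_s <- c("id", "trial", "time", "event", "treatment")
  miss <- setdiff(need_l, names(longitudinal))
  if (length(miss))
    stop("longitudinal table lacks column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_s, names(survival))
  if (length(miss))
    stop("survival table lacks column(s): ", paste(miss, collapse = ", "))
  longitudinal <- as.data.frame(longitudinal)
  survival <- as.data.frame(survival)

  if (anyDuplicated(survival$id)) {
    dup <- survival$id[duplicated(survival$id)][1]
    stop("survival table must have exactly one row per subject; subject '",
         dup, "' appears more than once")
  }
  only_l <- setdiff(unique(longitudinal$id), survival$id)
  if (length(only_l))
    stop("subject '", only_l[1], "' has longitudinal records but no ",
         "survival record")
  only_s <- setdiff(survival$id, unique(longitudinal$id))
  if (length(only_s))
    stop("subject '", only_s[1], "' has a survival record but no ",
         "longitudinal records")

  if (any(!is.finite(longitudinal$value))) {
    bad <- longitudinal$id[!is.finite(longitudinal$value)][1]
    stop("non-finite marker value for subject '", bad, "'")
  }
  if (any(!is.finite(longitudinal$time)) || any(longitudinal$time < 0)) {
    bad <- longitudinal$id[!is.finite(longitudinal$time) |
                             longitudinal$time < 0][1]
    stop("measurement times must be finite and nonnegative; offending ",
         "subject '", bad, "'")
  }
  if (any(!is.finite(survival$time)) || any(survival$time <= 0)) {
    bad <- survival$id[!is.finite(survival$time) | survival$time <= 0][1]
    stop("follow-up times must be finite and positive; offending subject '",
         bad, "'")
  }
  for (col in c("event", "treatment")) {
    v <- survival[[col]]
    if (!is.numeric(v) || !all(v %in% c(0, 1)))
      stop("column '", col, "' must contain literal 0/1 values")
  }

  if (is.null(tau)) tau <- max(survival$time)
  if (any(survival$time > tau)) {
    bad <- survival$id[survival$time > tau][1]
    stop("follow-up exceeds the study horizon tau for subject '", bad, "'")
  }
  if (any(longitudinal$time > tau)) {
    bad <- longitudinal$id[longitudinal$time > tau][1]
    stop("measurement time exceeds the study horizon tau for subject '",
         bad, "'")
  }
  fup <- survival$time[match(longitudinal$id, survival$id)]
  late <- longitudinal$time > fup
  if (any(late)) {
    bad <- longitudinal$id[late][1]
    stop("subject '", bad, "' has a measurement after the follow-up time; ",
         "measurements beyond follow-up are rejected, not dropped")
  }

  tr_l <- longitudinal$trial[match(survival$id, longitudinal$id)]
  if (any(tr_l != survival$trial)) {
    bad <- survival$id[which(tr_l != survival$trial)][1]
    stop("subject '", bad, "' has inconsistent trial labels between tables")
  }

  trials <- sort(unique(survival$trial))
  structure(list(longitudinal = longitudinal[order(longitudinal$id,
                                                   longitudinal$time), ,
                                             drop = FALSE],
                 survival = survival[order(survival$id), , drop = FALSE],
                 tau = tau, trials = trials),
            class = "joint_dataset")
}

#' Covariate columns of a joint dataset
#' @param dataset A [joint_dataset()].
#' @return Character vector of covariate column names in the survival table.
#' @export
dataset_covariates <- function(dataset) {
  setdiff(names(dataset$survival), c("id", "trial", "time", "event",
                                     "treatment"))
}

#' Read a joint dataset from delimited text tables
#'
#' @param longitudinal_path,survival_path Paths to CSV files.
#' @param column_map Named list mapping the canonical names (`id`, `trial`,
#'   `time`, `value`, `event`, `treatment`) to the column names used in the
#'   files; entries may be omitted when the file already uses canonical
#'   names. `time` may be given separately for each table via `time_long` /
#'   `time_surv`.
#' @param tau Optional study horizon override.
#' @return A validated [joint_dataset()].
#' @export
read_joint_dataset <- function(longitudinal_path, survival_path,
                               column_map = list(), tau = NULL) {
  lt <- read.csv(longitudinal_path, check.names = FALSE)
  st <- read.csv(survival_path, check.names = FALSE)
  ren <- function(df, map) {
    for (canon in names(map)) {
      src <- map[[canon]]
      if (!src %in% names(df))
        stop("configured column '", src, "' not found in table (wanted for '",
             canon, "')")
      names(df)[names(df) == src] <- canon
    }
    df
  }
  ml <- column_map[intersect(names(column_map),
                             c("id", "trial", "time", "value"))]
  if (!is.null(column_map$time_long)) ml$time <- column_map$time_long
  ms <- column_map[intersect(names(column_map),
                             c("id", "trial", "time", "event", "treatment"))]
  if (!is.null(column_map$time_surv)) ms$time <- column_map$time_surv
  joint_dataset(ren(lt, ml), ren(st, ms), tau = tau)
}

#' Write a joint dataset to CSV tables
#'
#' The written tables round-trip through [read_joint_dataset()] to full
#' double precision.
#'
#' @param dataset A [joint_dataset()].
#' @param longitudinal_path,survival_path Output paths.
#' @export
write_joint_dataset <- function(dataset, longitudinal_path, survival_path) {
  stopifnot(inherits(dataset, "joint_dataset"))
  fmt <- function(df) {
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    df
  }
  write.csv(fmt(dataset$longitudinal), longitudinal_path, row.names = FALSE,
            quote = FALSE)
  write.csv(fmt(dataset$survival), survival_path, row.names = FALSE,
            quote = FALSE)
  invisible(c(longitudinal_path, survival_path))
}

#' Summary statistics of a joint dataset
#'
#' @param dataset A [joint_dataset()].
#' @return A list with `n_subjects`, `n_trials`, `n_measurements`,
#'   `mean_measurements` (per subject), `events` (total and per arm),
#'   `censoring_fraction` (= 1 - sum(event)/n) and `tau`.
#' @export
summarize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "joint_dataset"))
  sv <- dataset$survival
  n <- nrow(sv)
  nm <- table(factor(dataset$longitudinal$id, levels = sv$id))
  list(n_subjects = n,
       n_trials = length(dataset$trials),
       n_measurements = nrow(dataset$longitudinal),
       mean_measurements = nrow(dataset$longitudinal) / n,
       events = sum(sv$event),
       events_treated = sum(sv$event[sv$treatment == 1]),
       events_control = sum(sv$event[sv$treatment == 0]),
       censoring_fraction = 1 - sum(sv$event) / n,
       tau = dataset$tau)
}

#' @export
print.joint_dataset <- function(x, ...) {
  s <- summarize_dataset(x)
  cat(sprintf(paste0("joint dataset: %d subjects in %d trial(s), ",
                     "%d measurements (%.2f per subject)\n"),
              s$n_subjects, s$n_trials, s$n_measurements,
              s$mean_measurements))
  cat(sprintf("  events: %d (censoring %.1f%%), horizon tau = %g\n",
              s$events, 100 * s$censoring_fraction, s$tau))
  invisible(x)
}
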