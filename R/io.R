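# Reading and writing observed-trial summary tables.
#
# Schema (CSV columns / JSON record fields): arm_id, stage1_estimate,
# stage1_se, stage2_estimate, stage2_se.  Exactly one arm (the selected one)
# carries stage-2 data; the others leave those fields blank/NA.  Arm ids are
# 1-based in all user-facing I/O.

.trial_cols <- c("arm_id", "stage1_estimate", "stage1_se",
                 "stage2_estimate", "stage2_se")

#' Represent a trial as an observed-summary table
#'
#' @param outcome A [dtl_outcome()].
#' @param design A [dtl_design()].
#' @return A data frame in the observed-trial schema, one row per arm, with
#'   stage-2 fields `NA` for the dropped arms.
#' @export
as_trial_table <- function(outcome, design) {
  stopifnot(inherits(outcome, "dtl_outcome"), inherits(design, "dtl_design"))
  k <- design$k
  d <- data.frame(arm_id = seq_len(k),
                  stage1_estimate = outcome$x,
                  stage1_se = rep(design$sigma1, k),
                  stage2_estimate = rep(NA_real_, k),
                  stage2_se = rep(NA_real_, k))
  d$stage2_estimate[outcome$s] <- outcome$y_s
  d$stage2_se[outcome$s] <- design$sigma2
  d
}

#' Write a trial to CSV or JSON
#'
#' The format is chosen by the file extension (`.csv` or `.json`).  Numeric
#' fields are written at full precision so that a write/read round trip
#' reproduces the trial exactly.
#'
#' @inheritParams as_trial_table
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(outcome, design, path) {
  d <- as_trial_table(outcome, design)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(d, path, digits = NA, na = "null")
  } else {
    num <- vapply(d, is.numeric, logical(1)) &
      names(d) != "arm_id"
    d[num] <- lapply(d[num], function(v)
      ifelse(is.na(v), "", sprintf("%.17g", v)))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an observed trial from CSV or JSON
#'
#' Validates the schema: a common stage-1 standard error across arms, and
#' exactly one arm carrying stage-2 data.  If the continued arm is not the
#' stage-1 maximum (selection by other criteria), the trial is accepted with
#' a warning, but the selection-bias corrections implemented by this package
#' are then void.
#'
#' @param path Path to a `.csv` or `.json` file in the observed-trial
#'   schema.
#' @param small_k_fix Passed through to [dtl_design()].
#' @return A list with components `design` ([dtl_design()]) and `outcome`
#'   ([dtl_outcome()]).
#' @export
read_trial <- function(path, small_k_fix = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(.trial_cols, names(d))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  for (cc in setdiff(.trial_cols, "arm_id")) d[[cc]] <- as.numeric(d[[cc]])
  k <- nrow(d)
  if (k < 2L) stop("need at least 2 arms")
  if (anyNA(d$stage1_estimate) || anyNA(d$stage1_se))
    stop("stage-1 estimate and SE are required for every arm")
  se1 <- unique(d$stage1_se)
  if (length(se1) > 1L)
    stop("a common stage-1 SE across arms is required; got: ",
         paste(se1, collapse = ", "))
  has2 <- !is.na(d$stage2_estimate)
  if (sum(has2) != 1L)
    stop("exactly one arm must carry a stage-2 estimate; found ", sum(has2))
  s <- which(has2)
  if (is.na(d$stage2_se[s])) stop("stage-2 SE missing for the selected arm")
  x <- d$stage1_estimate
  strict <- x[s] >= max(x)
  if (!strict)
    warning("the continued arm does not carry the largest stage-1 ",
            "estimate; accepting, but bias-correction guarantees are void")
  r <- which.max(replace(x, s, -Inf))
  design <- dtl_design(k, se1, d$stage2_se[s], small_k_fix = small_k_fix)
  outcome <- dtl_outcome(x, d$stage2_estimate[s], s = s, r = r,
                         strict = strict)
  list(design = design, outcome = outcome)
}
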