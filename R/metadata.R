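#' Validate a sample metadata table
#'
#' The metadata table carries the clinical and technical annotations that
#' drive every grouping in the pipeline: subject, cohort (control or SALS),
#' fluid (serum or CSF), sampling week, treatment arm (ROPI, placebo, or
#' none for controls), measurement batch, and whether the subject had
#' received drug by the draw (`ropi_exposed`). The trial design implies the
#' exposure flag: ROPI-arm subjects are exposed from the first on-drug draw
#' (week > 0), and placebo-arm subjects become exposed after week 24 when
#' the open-label extension starts. Controls are never exposed and are a
#' single point-in-time draw recorded as week 0.
#'
#' @param info data.frame with columns `sample_id`, `subject_id`, `cohort`,
#'   `fluid`, `week`, `arm`, `batch`, and optionally `ropi_exposed` (filled
#'   in from the design if absent).
#' @return the validated data.frame, with `ropi_exposed` guaranteed present.
#' @export
validate_sample_info <- function(info) {
  required <- c("sample_id", "subject_id", "cohort", "fluid", "week", "arm", "batch")
  miss <- setdiff(required, names(info))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(info$sample_id))
    stop("duplicated sample id(s): ",
         paste(unique(info$sample_id[duplicated(info$sample_id)]), collapse = ", "))
  chk <- function(col, allowed) {
    bad <- setdiff(unique(info[[col]]), allowed)
    if (length(bad))
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "))
  }
  chk("cohort", c("control", "SALS"))
  chk("fluid", c("serum", "CSF"))
  chk("arm", c("ROPI", "placebo", "none"))
  if (!all(info$batch %in% c(1L, 2L)))
    stop("batch must be 1 or 2")
  if (!is.numeric(info$week) || any(info$week < 0))
    stop("week must be a non-negative number")
  if (is.null(info$ropi_exposed))
    info$ropi_exposed <- ropi_exposure(info$arm, info$week)
  ctrl <- info$cohort == "control"
  if (any(info$arm[ctrl] != "none"))
    stop("controls must have arm = none")
  if (any(info$ropi_exposed[ctrl]))
    stop("controls must have ropi_exposed = FALSE")
  if (any(info$arm[!ctrl] == "none"))
    stop("SALS samples must have arm ROPI or placebo")
  expect <- ropi_exposure(info$arm, info$week)
  if (any(info$ropi_exposed != expect))
    stop("ropi_exposed inconsistent with trial design (ROPI arm exposed for ",
         "week > 0; placebo arm exposed for week > 24)")
  info
}

#' Drug-exposure flag implied by the trial design
#'
#' @param arm character vector of arms (`"ROPI"`, `"placebo"`, `"none"`).
#' @param week numeric vector of sampling weeks.
#' @return logical vector: `TRUE` iff the subject had received ropinirole by
#'   the draw. The double-blind period runs to week 24; placebo subjects
#'   cross over to drug in the open-label extension afterwards.
#' @export
ropi_exposure <- function(arm, week) {
  (arm == "ROPI" & week > 0) | (arm == "placebo" & week > 24)
}

#' Read sample metadata from delimited text
#' @param path TSV/CSV with the columns listed in [validate_sample_info()].
#' @return validated data.frame.
#' @export
read_sample_info <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  info <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(info$ropi_exposed))
    info$ropi_exposed <- as.logical(info$ropi_exposed)
  validate_sample_info(info)
}

#' Write sample metadata
#' @param info validated metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_info <- function(info, path) {
  utils::write.table(info, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate ALSFRS-R score series
#'
#' @param scores data.frame with columns `subject_id`, `week`,
#'   `alsfrs_r` (integer scores in 0..48). Weeks must be strictly
#'   increasing within each subject.
#' @return the validated data.frame, ordered by subject and week.
#' @export
validate_alsfrs <- function(scores) {
  required <- c("subject_id", "week", "alsfrs_r")
  miss <- setdiff(required, names(scores))
  if (length(miss))
    stop("ALSFRS-R table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(scores$alsfrs_r < 0 | scores$alsfrs_r > 48))
    stop("ALSFRS-R scores must lie in [0, 48]")
  scores <- scores[order(scores$subject_id, scores$week), , drop = FALSE]
  dup <- stats::aggregate(week ~ subject_id, scores,
                          function(w) anyDuplicated(w) > 0L)
  if (any(dup$week))
    stop("duplicated week(s) for subject(s): ",
         paste(dup$subject_id[dup$week], collapse = ", "))
  rownames(scores) <- NULL
  scores
}

#' Read ALSFRS-R series from delimited text
#' @param path TSV/CSV with columns `subject_id`, `week`, `alsfrs_r`.
#' @return validated data.frame.
#' @export
read_alsfrs <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  validate_alsfrs(utils::read.table(path, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE))
}
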