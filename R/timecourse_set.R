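#' Multi-subject component time courses
#'
#' Container for per-subject component time-course matrices sharing a
#' component set and TR, together with subject metadata and (optionally)
#' motion traces.
#'
#' @param timecourses list of T x C numeric matrices (rows = time points,
#'   columns = components), one per subject; all must share dimensions.
#' @param tr repetition time in seconds.
#' @param subjects data.frame with at least `subject_id` and `group`
#'   columns; one row per subject, in the order of `timecourses`.
#' @param motion optional list of [motion_trace] objects (one per subject).
#' @return object of class `timecourse_set`.
#' @export
timecourse_set <- function(timecourses, tr, subjects, motion = NULL) {
  stopifnot(is.list(timecourses), length(timecourses) >= 1, tr > 0)
  timecourses <- lapply(timecourses, as.matrix)
  dims <- vapply(timecourses, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all subjects must share time-point and component counts")
  if (dims[1, 1] < 2) stop("need at least 2 time points")
  if (any(vapply(timecourses, function(m) anyNA(m) || any(!is.finite(m)),
                 logical(1))))
    stop("time courses contain missing or non-finite values")
  if (!is.data.frame(subjects) ||
      !all(c("subject_id", "group") %in% names(subjects)))
    stop("subjects must be a data.frame with subject_id and group columns")
  if (nrow(subjects) != length(timecourses))
    stop("subject table rows must match the number of time-course matrices")
  if (!is.null(motion)) {
    if (length(motion) != length(timecourses))
      stop("motion traces must match the number of subjects")
    ok <- vapply(motion, function(m) inherits(m, "motion_trace") &&
                   nrow(m$params) == dims[1, 1], logical(1))
    if (!all(ok)) stop("each motion trace must be a motion_trace covering all TRs")
  }
  comp <- colnames(timecourses[[1]])
  if (is.null(comp)) comp <- paste0("IC", seq_len(dims[2, 1]))
  timecourses <- lapply(timecourses, function(m) {
    colnames(m) <- comp
    m
  })
  structure(list(timecourses = timecourses, tr = tr,
                 components = comp, subjects = subjects, motion = motion),
            class = "timecourse_set")
}

#' @export
print.timecourse_set <- function(x, ...) {
  cat(sprintf("timecourse_set: %d subjects, %d time points x %d components, TR = %g s\n",
              length(x$timecourses), nrow(x$timecourses[[1]]),
              length(x$components), x$tr))
  if (!is.null(x$subjects$group))
    print(table(x$subjects$group))
  invisible(x)
}

#' Number of subjects in a timecourse_set
#' @param set a `timecourse_set`.
#' @export
n_subjects <- function(set) length(set$timecourses)

# subset a timecourse_set by subject index
subset_subjects <- function(set, idx) {
  timecourse_set(set$timecourses[idx], tr = set$tr,
                 subjects = set$subjects[idx, , drop = FALSE],
                 motion = if (!is.null(set$motion)) set$motion[idx])
}
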