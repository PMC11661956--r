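#' Write a timecourse_set to a directory of delimited text files
#'
#' One TSV per subject (`<subject_id>_timecourse.tsv`, rows = TRs,
#' columns = components), optional motion TSVs
#' (`<subject_id>_motion.tsv`), a `subjects.tsv` table, and a `meta.json`
#' sidecar carrying the TR and component labels. Values are written with
#' full double precision so a write/read round trip is bitwise exact.
#'
#' @param set `timecourse_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_timecourse_set <- function(set, dir) {
  stopifnot(inherits(set, "timecourse_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(m) {
    out <- apply(m, 2, function(col) sprintf("%.17g", col))
    colnames(out) <- colnames(m)
    out
  }
  for (i in seq_len(n_subjects(set))) {
    sid <- set$subjects$subject_id[i]
    write.table(fmt(set$timecourses[[i]]),
                file.path(dir, paste0(sid, "_timecourse.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(set$motion))
      write.table(fmt(set$motion[[i]]$params),
                  file.path(dir, paste0(sid, "_motion.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(set$subjects, file.path(dir, "subjects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr = set$tr, components = set$components),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a timecourse_set from a directory
#'
#' Expects the layout written by [write_timecourse_set]. Every subject in
#' the table must have a time-course file (and vice versa); all matrices
#' must share dimensions, and a file whose row count disagrees is named
#' in the error.
#'
#' @param dir directory containing `subjects.tsv`, per-subject
#'   `<subject_id>_timecourse.tsv` files, and optionally motion files and
#'   a `meta.json` sidecar.
#' @param tr repetition time (s); read from `meta.json` when NULL.
#' @return `timecourse_set`.
#' @export
load_timecourses <- function(dir, tr = NULL) {
  subj_path <- file.path(dir, "subjects.tsv")
  if (!file.exists(subj_path)) stop("missing subject table: ", subj_path)
  subjects <- read.delim(subj_path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(subjects)))
    stop("subject table must have subject_id and group columns")
  meta_path <- file.path(dir, "meta.json")
  if (is.null(tr)) {
    if (!file.exists(meta_path))
      stop("tr not given and no meta.json sidecar present")
    tr <- jsonlite::read_json(meta_path)$tr
  }
  files <- file.path(dir, paste0(subjects$subject_id, "_timecourse.tsv"))
  missing <- !file.exists(files)
  if (any(missing))
    stop("subject(s) in table without a time-course file: ",
         paste(subjects$subject_id[missing], collapse = ", "))
  extra <- setdiff(list.files(dir, pattern = "_timecourse\\.tsv$"),
                   basename(files))
  if (length(extra))
    stop("time-course file(s) without a subject-table row: ",
         paste(extra, collapse = ", "))
  tcs <- lapply(files, function(f) as.matrix(read.delim(f, check.names = FALSE)))
  dims <- vapply(tcs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]))
    stop(sprintf("file %s has %d rows; expected %d",
                 basename(files[which(dims[1, ] != dims[1, 1])[1]]),
                 dims[1, which(dims[1, ] != dims[1, 1])[1]], dims[1, 1]))
  mot_files <- file.path(dir, paste0(subjects$subject_id, "_motion.tsv"))
  motion <- NULL
  if (all(file.exists(mot_files)))
    motion <- lapply(mot_files, function(f)
      motion_trace(as.matrix(read.delim(f, check.names = FALSE))))
  timecourse_set(tcs, tr = tr, subjects = subjects, motion = motion)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters with documented defaults plus a
#' master seed from which each stochastic stage derives its own stream.
#' Can be read from / written to YAML.
#'
#' @param preprocess `preprocess_params`.
#' @param window `window_params`.
#' @param glasso `glasso_params`.
#' @param cluster `cluster_params`.
#' @param meta `meta_params`.
#' @param sweep_ks state counts for the sensitivity sweep.
#' @param alpha significance level used by the statistics stage.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_params(),
                            window = window_params(),
                            glasso = glasso_params(),
                            cluster = cluster_params(),
                            meta = meta_params(),
                            sweep_ks = c(4, 5, 6),
                            alpha = 0.05, seed = 1L) {
  structure(list(preprocess = preprocess, window = window,
                 glasso = glasso, cluster = cluster, meta = meta,
                 sweep_ks = sweep_ks, alpha = alpha, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to the documented defaults.
#'
#' @param path YAML file with (optionally nested) parameter fields named
#'   as in [pipeline_config].
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  fill <- function(ctor, vals) do.call(ctor, vals[names(vals) %in%
                                                    names(formals(ctor))])
  pipeline_config(
    preprocess = fill(preprocess_params, y$preprocess %||% list()),
    window = fill(window_params, y$window %||% list()),
    glasso = fill(glasso_params, y$glasso %||% list()),
    cluster = fill(cluster_params, y$cluster %||% list()),
    meta = fill(meta_params, y$meta %||% list()),
    sweep_ks = y$sweep_ks %||% c(4, 5, 6),
    alpha = y$alpha %||% 0.05,
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full connectivity pipeline
#'
#' Chains QC -> conditioning -> static FNC -> windowed glasso FNC ->
#' cluster states (with k sweep) -> meta-states -> group statistics, and
#' writes each stage's tables to `out_dir` alongside a JSON copy of the
#' resolved configuration and seeds. Running twice with the same inputs
#' and configuration reproduces every table exactly.
#'
#' @param set input `timecourse_set` (e.g. from [load_timecourses] or
#'   [simulate_cohort]).
#' @param config `pipeline_config`.
#' @param out_dir output directory; NULL to skip writing.
#' @return list with the stage results: `qc`, `sfnc` (selection +
#'   univariate), `wfnc`, `states` (sweep incl. the headline k),
#'   `state_metrics`, `meta`, `meta_metrics`, `group_tests`,
#'   `brain_behavior`.
#' @export
run_pipeline <- function(set, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(set, "timecourse_set"),
            inherits(config, "pipeline_config"))
  qc <- qc_exclude(set, config$preprocess)
  cond <- preprocess_timecourses(qc$kept, config$preprocess)

  feats <- fnc_feature_matrix(cond)
  subj <- cond$subjects
  case_level <- if ("EP" %in% subj$group) "EP" else subj$group[1]
  design <- data.frame(diagnosis = as.integer(subj$group == case_level))
  for (cn in c("age", "mean_fd", "rms_motion"))
    if (!is.null(subj[[cn]])) design[[cn]] <- subj[[cn]]
  sel <- mancova_backward_select(feats, design, alpha = config$alpha)
  uni <- if ("diagnosis" %in% sel$retained)
    univariate_effects(feats, design[, sel$retained, drop = FALSE],
                       "diagnosis", config$alpha) else NULL

  wfnc <- windowed_fnc(cond, config$window, config$glasso,
                       seed = config$seed)
  wfnc <- regress_motion_from_windows(wfnc, cond)

  ks <- sort(unique(c(config$cluster$k, config$sweep_ks)))
  sweep <- sweep_k(wfnc, ks, n_replicates = config$cluster$n_replicates,
                   seed = config$cluster$seed)
  model <- sweep$models[[paste0("k", config$cluster$k)]]
  smetrics <- cohort_state_metrics(model)

  meta <- fit_meta_states(wfnc, config$meta)
  traj <- discretize_weights(meta)
  mmetrics <- cohort_meta_metrics(traj)

  metric_tab <- merge(smetrics, mmetrics)
  grp_cols <- setdiff(names(metric_tab), c("subject_id", "group"))
  groups <- factor(metric_tab$group)
  tests <- do.call(rbind, lapply(grp_cols, function(cn) {
    xa <- metric_tab[[cn]][groups == levels(groups)[1]]
    xb <- metric_tab[[cn]][groups == levels(groups)[2]]
    if (sd(xa) == 0 && sd(xb) == 0) return(NULL)   # degenerate metric
    cbind(variable = cn, choose_and_run_test(xa, xb))
  }))

  # brain-behavior stage: score vs meta-state dynamism in the EP group
  bb <- NULL
  ep <- if (is.null(subj$score)) logical(nrow(subj))
        else subj$group == "EP" & !is.na(subj$score)
  if (sum(ep) > 8) {
    mm <- mmetrics[ep, c("n_meta_states", "n_changes", "span",
                         "total_distance")]
    bb <- brain_behavior_correlations(subj$score[ep], mm,
                                      nuisance = subj$cpz_equiv[ep])
  }

  out <- list(qc = qc$report, sfnc = list(selection = sel, univariate = uni),
              wfnc = wfnc, states = sweep, model = model,
              state_metrics = smetrics, meta = meta,
              meta_metrics = mmetrics, group_tests = tests,
              brain_behavior = bb)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(qc$report, "qc_report.tsv")
    wt(sel$steps, "sfnc_selection_steps.tsv")
    if (!is.null(uni)) wt(uni, "sfnc_univariate_diagnosis.tsv")
    wt(smetrics, "state_metrics.tsv")
    wt(mmetrics, "meta_state_metrics.tsv")
    wt(tests, "group_tests.tsv")
    if (!is.null(bb)) wt(bb, "brain_behavior.tsv")
    wt(sweep$cost, "sweep_cost.tsv")
    for (kn in names(sweep$models))
      jsonlite::write_json(list(k = sweep$models[[kn]]$k,
                                centroids = sweep$models[[kn]]$centroids,
                                cost = sweep$models[[kn]]$cost),
                           file.path(out_dir, paste0("states_", kn, ".json")),
                           digits = NA, matrix = "rowmajor")
    jsonlite::write_json(list(seed = config$seed, alpha = config$alpha,
                              k = config$cluster$k,
                              sweep_ks = config$sweep_ks,
                              penalty = wfnc$penalty),
                         file.path(out_dir, "pipeline_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
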