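# End-to-end experiment: fit class-conditional densities on a
# construction cohort, evaluate on a held-out test cohort, emit
# per-measure reports (binormal Az, empirical ROC/AUC with CI, y = 0
# confusion summary) plus the hippocampal asymmetry table.

#' Run the full construction -> test experiment
#'
#' For each requested measure: fits the likelihood-ratio observer on
#' the training cohort, computes the binormal detectability index Az
#' (Gaussian backend), scores the test cohort, and reports the
#' empirical ROC, its AUC with Hanley-McNeil confidence interval, and
#' the sensitivity/specificity/balanced-accuracy summary at the y = 0
#' criterion. A hippocampal left/right asymmetry table of the training
#' cohort is included. Every report field is recomputable from the
#' written model JSON plus the test CSV alone.
#'
#' @param config A list (or path to a YAML/JSON file holding one) with
#'   elements:
#'   \describe{
#'     \item{train}{a [cohort_table()], or a path to a cohort CSV, or
#'       the string `"simulate:adni_like"`.}
#'     \item{test}{likewise; `"simulate:miriad_like"` for a synthetic
#'       held-out cohort.}
#'     \item{measures}{list of [measure_spec()]s, or character names
#'       among `"mtl"`, `"hippocampus"`, `"amygdala"`, `"entorhinal"`,
#'       `"parahippocampal"`; default `c("mtl", "hippocampus")`.}
#'     \item{density_backend}{`"gaussian"` (default) or `"kde"`.}
#'     \item{seed}{integer; seeds simulated cohorts (train uses `seed`,
#'       test `seed + 1`).}
#'     \item{output_dir}{optional; when given, model JSONs, ROC CSVs
#'       and the report JSON are written there.}
#'   }
#' @param quiet Suppress the per-stage log lines.
#' @return An `experiment_report`: list with `schema_version`, `seed`,
#'   `backend`, `cohorts` (sizes), `measures` (per-measure results) and
#'   `morphometry`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  seed <- as.integer(config$seed %||% 42L)
  backend <- config$density_backend %||% "gaussian"
  say <- function(...) if (!quiet) message(...)

  train <- resolve_cohort(config$train, "adni_like", seed)
  test <- resolve_cohort(config$test, "miriad_like", seed + 1L)
  say("train: ", n_subjects(train), " subjects [",
      attr(train, "provenance"), "]; test: ", n_subjects(test),
      " subjects [", attr(test, "provenance"), "]; backend=", backend,
      "; seed=", seed)

  measures <- config$measures %||% c("mtl", "hippocampus")
  measures <- lapply(measures, function(m) {
    if (inherits(m, "measure_spec")) m
    else if (identical(tolower(m), "mtl")) mtl_measure()
    else region_measure(m)
  })

  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  results <- lapply(measures, function(ms) {
    model <- lr_observer(train, ms, backend = backend)
    pred <- predict(model, test)
    roc <- empirical_roc(pred$log_lr, pred$group)
    ci <- auc_confidence_interval(roc)
    rep <- evaluate_at_zero_threshold(model, test)
    say("measure=", ms$name, ": Az(binormal)=",
        if (backend == "gaussian")
          sprintf("%.3f", binormal_az(model)) else "NA",
        " AUC(test)=", sprintf("%.3f", roc$auc),
        " sens=", sprintf("%.3f", rep$sensitivity),
        " spec=", sprintf("%.3f", rep$specificity))
    slug <- gsub("[^a-z0-9]+", "_", tolower(ms$name))
    if (!is.null(out_dir)) {
      if (backend == "gaussian") {
        write_density_json(model$normal,
                           file.path(out_dir, paste0(slug, "_nc.json")),
                           measure = ms$name, group = "NC",
                           provenance = attr(train, "provenance"))
        write_density_json(model$diseased,
                           file.path(out_dir, paste0(slug, "_ad.json")),
                           measure = ms$name, group = "AD",
                           provenance = attr(train, "provenance"))
      }
      utils::write.csv(roc$points,
                       file.path(out_dir, paste0(slug, "_roc.csv")),
                       row.names = FALSE)
    }
    list(measure = ms$name,
         mu_nc = model$normal$mu, sigma_nc = model$normal$sigma,
         mu_ad = model$diseased$mu, sigma_ad = model$diseased$sigma,
         az_binormal = if (backend == "gaussian")
           binormal_az(model) else NA_real_,
         auc_empirical = roc$auc,
         auc_ci_lower = ci[["lower"]], auc_ci_upper = ci[["upper"]],
         tp = rep$tp, fp = rep$fp, tn = rep$tn, fn = rep$fn,
         sensitivity = rep$sensitivity, specificity = rep$specificity,
         balanced_accuracy = rep$balanced_accuracy)
  })
  names(results) <- vapply(results, `[[`, "", "measure")

  report <- list(
    schema_version = 1L, seed = seed, backend = backend,
    cohorts = list(
      train = list(provenance = attr(train, "provenance"),
                   n_ad = n_subjects(cohort_group(train, "AD")),
                   n_nc = n_subjects(cohort_group(train, "NC"))),
      test = list(provenance = attr(test, "provenance"),
                  n_ad = n_subjects(cohort_group(test, "AD")),
                  n_nc = n_subjects(cohort_group(test, "NC")))),
    measures = results,
    morphometry = asymmetry_summary(train, "hippocampus"))
  class(report) <- "experiment_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}

resolve_cohort <- function(x, default_source, seed) {
  if (inherits(x, "cohort_table")) return(x)
  if (is.null(x)) x <- paste0("simulate:", default_source)
  if (is.character(x) && grepl("^simulate:", x)) {
    src <- sub("^simulate:", "", x)
    return(generate_cohort(default_recipe(src, seed = seed)))
  }
  if (is.character(x)) {
    if (!file.exists(x))
      stop("config error: cohort path not found: ", x, call. = FALSE)
    return(load_cohort_csv(x))
  }
  stop("config error: cannot interpret cohort specification", call. = FALSE)
}

#' @rdname run_experiment
#' @param path YAML or JSON config file (YAML requires the `yaml`
#'   package).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report (seed ", x$seed, ", ", x$backend,
      " backend)\n", sep = "")
  cat(sprintf("  train: %d AD / %d NC   test: %d AD / %d NC\n",
              x$cohorts$train$n_ad, x$cohorts$train$n_nc,
              x$cohorts$test$n_ad, x$cohorts$test$n_nc))
  for (m in x$measures)
    cat(sprintf(
      "  %-18s Az=%.3f AUC=%.3f (CI %.3f-%.3f) sens=%.1f%% spec=%.1f%%\n",
      m$measure, m$az_binormal, m$auc_empirical, m$auc_ci_lower,
      m$auc_ci_upper, 100 * m$sensitivity, 100 * m$specificity))
  invisible(x)
}

#' Balanced-accuracy improvement between two operating points
#'
#' Difference of balanced accuracies in percentage points:
#' 100 * (BA_a - BA_b), i.e. the mean of the sensitivity and
#' specificity gains. Positive when `report_a` outperforms `report_b`.
#'
#' @param report_a,report_b `classification_report`s evaluated on the
#'   same test cohort.
#' @return Percentage points (may be negative).
#' @export
improvement_over_baseline <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "classification_report"),
            inherits(report_b, "classification_report"))
  if (report_a$tp + report_a$fn != report_b$tp + report_b$fn ||
      report_a$tn + report_a$fp != report_b$tn + report_b$fp)
    stop("reports are not comparable: different test cohort sizes",
         call. = FALSE)
  100 * (report_a$balanced_accuracy - report_b$balanced_accuracy)
}
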