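# Artifact I/O: stimulus JSON round-trip, fixed-dialect CSV tables, and
# the simulate/analyze run orchestration with a reproducibility manifest.

#' Write a stimulus to JSON
#'
#' Schema: `{space: {width, height, radius, grid_step}, dots: [{x, y,
#' label}], true_center: [x, y]}` (true centre optional). Deterministic
#' round-trip with [read_stimulus_json()].
#'
#' @param stimulus A `cq_stimulus` or a list with `dots` (data.frame) and
#'   optionally `true_center`.
#' @param space A `cq_space`.
#' @param path Output file.
#' @export
write_stimulus_json <- function(stimulus, space, path) {
  obj <- list(space = list(width = space$width, height = space$height,
                           radius = space$circle_radius,
                           grid_step = space$grid_step),
              dots = stimulus$dots[, c("x", "y", "label")])
  if (!is.null(stimulus$true_center))
    obj$true_center <- as.numeric(stimulus$true_center)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stimulus JSON file
#'
#' @param path File written by [write_stimulus_json()] or conforming.
#' @return A list with `space` (a `cq_space`), `dots`, and `true_center`
#'   (NULL if absent).
#' @export
read_stimulus_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- search_space(width = obj$space$width, height = obj$space$height,
                     circle_radius = obj$space$radius,
                     grid_step = if (is.null(obj$space$grid_step)) 4
                                 else obj$space$grid_step)
  list(space = sp, dots = as.data.frame(obj$dots),
       true_center = obj$true_center)
}

#' Write a table in the package's fixed CSV dialect
#'
#' UTF-8, comma-separated, header row, `.` decimal separator, no row
#' names and no quoting changes across runs, so identical tables diff
#' byte-identically.
#'
#' @param x A data.frame.
#' @param path Output file.
#' @export
write_cq_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a table written by [write_cq_csv()]
#'
#' @param path CSV file.
#' @return A data.frame.
#' @export
read_cq_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

# Stable content hash of a list of data.frames (column-wise, rounded
# serialization via deparsed text) without external digest dependencies.
.manifest_hash <- function(tables) {
  txt <- paste(vapply(tables, function(t) {
    paste(utils::capture.output(utils::write.csv(t, row.names = FALSE)),
          collapse = "\n")
  }, character(1)), collapse = "\f")
  raw <- utf8ToInt(txt)
  h <- 5381
  for (chunk in split(raw, ceiling(seq_along(raw) / 4096)))
    h <- (h * 33 + sum(chunk * (seq_along(chunk) %% 251 + 1))) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Simulate an experiment and write all artefacts
#'
#' Runs [simulate_cohort()] and writes the behaviour, truth and schedule
#' tables as CSV plus a `manifest.json` recording the package version,
#' experiment, master seed and a content hash, so a rerun with the same
#' seed is verifiably identical.
#'
#' @param config A `cq_cohort_config`.
#' @param experiment Experiment id.
#' @param out_dir Output directory (created if missing).
#' @param ... Passed to [simulate_cohort()].
#' @return Invisibly, the manifest list.
#' @export
simulate_run <- function(config, experiment, out_dir, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- simulate_cohort(config, experiment, ...)
  tables <- Filter(is.data.frame, res)
  for (nm in names(tables))
    write_cq_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  manifest <- list(package = "circlequest",
                   version = as.character(utils::packageVersion("circlequest")),
                   experiment = experiment, seed = config$seed,
                   n_per_group = config$n_per_group,
                   tables = names(tables),
                   content_hash = .manifest_hash(tables))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Analyse a simulated run directory
#'
#' Reads the tables written by [simulate_run()] and produces the
#' pipeline's estimates: per-subject sensitivities and group contrasts
#' for passive experiments (plus confidence-calibration slopes when
#' ratings exist), or oversampling metrics for the active experiment.
#' When a ground-truth table is present a recovery summary (correlation
#' of estimated with generative sensitivities) is appended.
#'
#' @param run_dir Directory from [simulate_run()].
#' @param write Write `sensitivities.csv` / `contrasts.csv` back into the
#'   directory?
#' @return A list of result tables.
#' @export
analyze_run <- function(run_dir, write = TRUE) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", run_dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  experiment <- manifest$experiment
  need <- function(name) {
    p <- file.path(run_dir, paste0(name, ".csv"))
    if (!file.exists(p)) stop("missing table: ", name, ".csv")
    read_cq_csv(p)
  }
  out <- list(manifest = manifest)
  if (experiment == "exp1") {
    trials <- need("trials")
    ee_curves <- need("ee_curves")
    om <- oversampling_metrics(trials, ee_curves)
    out$oversampling_cells <- om$cells
    out$cost_sensitivity <- om$cost_sensitivity
    grp <- trials$group[match(om$cost_sensitivity$subject_id,
                              trials$subject_id)]
    if (length(unique(grp)) == 2)
      out$contrasts <- group_contrast(om$cost_sensitivity$cost_sensitivity,
                                      grp, metric = "cost_sensitivity")
  } else {
    choices <- need("choices")
    sens <- fit_choice_sensitivities(choices, experiment)
    out$sensitivities <- sens
    terms <- grep("^beta_.*_hat$", names(sens), value = TRUE)
    if (length(unique(sens$group)) == 2) {
      out$contrasts <- do.call(rbind, lapply(terms, function(tm) {
        group_contrast(sens[[tm]], sens$group, metric = tm)
      }))
    }
    conf_path <- file.path(run_dir, "confidence.csv")
    if (file.exists(conf_path)) {
      out$estimation_accuracy <-
        uncertainty_estimation_accuracy(read_cq_csv(conf_path))
    }
    truth_path <- file.path(run_dir, "truth.csv")
    if (file.exists(truth_path)) {
      truth <- read_cq_csv(truth_path)
      m <- match(sens$subject_id, truth$subject_id)
      rec <- data.frame(
        term = c("beta_reward", "beta_uncertainty", "beta_effort"),
        correlation = NA_real_)
      for (j in seq_len(nrow(rec))) {
        est_col <- paste0(rec$term[j], "_hat")
        if (est_col %in% names(sens) && rec$term[j] %in% names(truth)) {
          gen <- truth[[rec$term[j]]][m]
          if (rec$term[j] %in% c("beta_reward", "beta_effort"))
            gen <- gen * ifelse(truth$group[m] == "lesion" &
                                  experiment != "exp3",
                                truth$gamma_context[m], 1)
          ok <- is.finite(sens[[est_col]]) & is.finite(gen)
          if (sum(ok) > 2 && stats::sd(gen[ok]) > 0)
            rec$correlation[j] <- stats::cor(sens[[est_col]][ok], gen[ok])
        }
      }
      out$recovery <- rec[!is.na(rec$correlation), , drop = FALSE]
    }
  }
  if (write) {
    for (nm in setdiff(names(out), "manifest"))
      if (is.data.frame(out[[nm]]))
        write_cq_csv(out[[nm]], file.path(run_dir, paste0(nm, ".csv")))
  }
  out
}
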