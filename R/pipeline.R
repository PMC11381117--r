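trial_table_version <- "proxylearn-trial-table-v1"

trial_cols <- c("subject", "task", "direction", "phase", "trial",
                "no_vision", "gain", "offset", "control", "error", "e0")

#' Write a trial table to delimited text
#'
#' Comma-separated with a versioned comment header line; round-trips through
#' [read_trial_table()] bit-exactly.
#'
#' @param data A trial table ([generate_dataset()] format).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path) {
  stopifnot(all(trial_cols %in% names(data)))
  writeLines(paste0("# ", trial_table_version), path)
  readr::write_csv(data[trial_cols], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Reads the delimited trial-table format, preserving row order, and
#' validates the schema: required columns, numeric finite errors, integer EA
#' levels on the study grid (gain 0–3, offset 0–2), phases in
#' learning/washout. Violations are reported with data line numbers.
#'
#' @param path File written by [write_trial_table()] (or any CSV with the
#'   documented columns; a leading `#` comment line is ignored).
#' @return A validated tibble of trial records.
#' @export
read_trial_table <- function(path) {
  stopifnot(file.exists(path))
  # base read.csv: its double parser is correctly rounded, so values written
  # with shortest-round-trip formatting come back bit-identical
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(trial_cols, names(raw))
  if (length(missing) > 0) {
    stop("trial table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(raw[trial_cols])
  for (col in c("subject", "task", "direction", "trial", "gain", "offset")) {
    out[[col]] <- as.integer(out[[col]])
  }
  for (col in c("no_vision", "control")) out[[col]] <- as.logical(out[[col]])
  for (col in c("error", "e0")) out[[col]] <- as.double(out[[col]])
  out$phase <- as.character(out$phase)
  if (nrow(out) == 0) return(out)
  line_of <- function(i) i + 2L   # comment line + header
  bad <- which(!out$gain %in% 0:3 | !out$offset %in% 0:2)
  if (length(bad) > 0) {
    stop("EA levels off the study grid (gain 0-3, offset 0-2) at line(s) ",
         paste(line_of(head(bad, 5)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(out$error))
  if (length(bad) > 0) {
    stop("non-numeric or non-finite error values at line(s) ",
         paste(line_of(head(bad, 5)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!out$phase %in% c("learning", "washout"))
  if (length(bad) > 0) {
    stop("phase must be learning/washout at line(s) ",
         paste(line_of(head(bad, 5)), collapse = ", "), call. = FALSE)
  }
  out
}

#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis. The `"test"` profile
#' shrinks the design and the optimiser/bootstrap effort so the whole
#' pipeline runs in minutes on one CPU; `"full"` keeps the reference design
#' and effort.
#'
#' @param design An [experiment_design()] list.
#' @param ground_truth A ground-truth map ([default_ground_truth()]).
#' @param structures Structures entered in model selection.
#' @param n_starts Multi-start count for all fits.
#' @param B Bootstrap replicates for the statistical tables.
#' @param seed Global seed; all stage seeds derive from it (stage i uses
#'   `(seed * 97 + i) mod (2^31 - 1)`).
#' @param profile `"test"` or `"full"`.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(design = NULL, ground_truth = NULL,
                            structures = NULL, n_starts = NULL, B = NULL,
                            seed = 1, profile = c("test", "full")) {
  profile <- match.arg(profile)
  if (profile == "test") {
    design <- design %||% experiment_design(
      n_subjects = 6, n_control = 2, n_tasks = 2, n_trials = 120,
      n_novision = 36, n_washout = 30)
    structures <- structures %||% c("1.1L", "1.1", "2.1", "3.1")
    n_starts <- n_starts %||% 8
    B <- B %||% 2000
  } else {
    design <- design %||% experiment_design()
    structures <- structures %||% proxy_models()$structure_id
    n_starts <- n_starts %||% 1000
    B <- B %||% 1e5
  }
  ground_truth <- ground_truth %||% default_ground_truth()
  stopifnot(inherits(design, "ea_design"), seed >= 0)
  structure(list(design = design, ground_truth = ground_truth,
                 structures = structures, n_starts = n_starts, B = B,
                 seed = as.integer(seed), profile = profile),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' Serialised as YAML; the ground-truth map travels as a column list.
#'
#' @param config A [pipeline_config()] object.
#' @param path File path.
#' @return `read_pipeline_config()` returns the configuration list;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- list(design = unclass(config$design),
              ground_truth = as.list(config$ground_truth),
              structures = config$structures, n_starts = config$n_starts,
              B = config$B, seed = config$seed, profile = config$profile)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  pipeline_config(
    design = do.call(experiment_design, obj$design),
    ground_truth = tibble::as_tibble(obj$ground_truth),
    structures = obj$structures, n_starts = obj$n_starts, B = obj$B,
    seed = obj$seed, profile = obj$profile)
}

#' Run the full analysis pipeline
#'
#' Executes the six stages in order: (1) simulate the experiment, (2) fit the
#' proxy-process structures to every learning curve, (3) cross-validate the
#' structures across subjects, (4) fit the multi-rate model per curve with
#' the second-order proxy coefficients fixed, (5) build the statistical
#' tables (parameter sign/rank-sum tests, steady-state errors), (6) fit the
#' washout decays and compare time constants. Intermediate tables are
#' written to `out_dir` as delimited text; with `resume = TRUE` a stage
#' whose output file already exists is reloaded instead of recomputed (the
#' manifest records which). Re-running with the same seed reproduces all
#' outputs bit-exactly.
#'
#' @param config A [pipeline_config()] list.
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse existing stage outputs (default `FALSE`).
#' @return A list with all stage results (`data`, `proxy_fits`, `cv`,
#'   `dpxmrml_fits`, `stats`, `washout`) and `manifest`, a six-row tibble
#'   (stage, seed, rows, file, md5 checksum, status, elapsed seconds) whose
#'   `config_hash` attribute fingerprints the configuration.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, i, rows, file, status, t0) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, index = i, seed = derive_seed(config$seed, i),
      rows = rows, file = file,
      md5 = unname(tools::md5sum(file)), status = status,
      elapsed = round(as.double(Sys.time()) - t0, 3))
  }
  ctl <- function(i) fit_control(n_starts = config$n_starts,
                                 seed = derive_seed(config$seed, i))

  # 1 simulate
  t0 <- as.double(Sys.time())
  f_data <- file.path(out_dir, "trials.csv")
  if (resume && file.exists(f_data)) {
    dat <- read_trial_table(f_data)
    note("simulate", 1L, nrow(dat), f_data, "cached", t0)
  } else {
    dat <- generate_dataset(config$design, config$ground_truth,
                            seed = derive_seed(config$seed, 1))
    write_trial_table(dat, f_data)
    note("simulate", 1L, nrow(dat), f_data, "run", t0)
  }

  # 2 fit proxy models
  t0 <- as.double(Sys.time())
  proxy_fits <- fit_learning_curves(dat, structures = config$structures,
                                    control = ctl(2))
  f_fits <- file.path(out_dir, "proxy_fits.csv")
  readr::write_csv(dplyr::select(proxy_fits, -"fit"), f_fits)
  note("fit_proxy", 2L, nrow(proxy_fits), f_fits, "run", t0)

  # 3 cross-validate
  t0 <- as.double(Sys.time())
  cv <- cross_validate(dat, structures = config$structures,
                       grouping = "subjects", control = ctl(3),
                       fits = proxy_fits)
  f_cv <- file.path(out_dir, "cv_partitions.csv")
  readr::write_csv(cv$partitions, f_cv)
  readr::write_csv(cv$scores, file.path(out_dir, "cv_scores.csv"))
  note("cross_validate", 3L, nrow(cv$partitions), f_cv, "run", t0)

  # 4 multi-rate model
  t0 <- as.double(Sys.time())
  dpx <- fit_dpxmrml_curves(dat, proxy_fits, control = ctl(4))
  f_dpx <- file.path(out_dir, "dpxmrml_fits.csv")
  readr::write_csv(dplyr::select(dpx, -"fit"), f_dpx)
  note("fit_dpxmrml", 4L, nrow(dpx), f_dpx, "run", t0)

  # 5 statistical tables
  t0 <- as.double(Sys.time())
  p21 <- dplyr::filter(proxy_fits, .data$structure_id == "2.1")
  coef_tbl <- tidyr::unnest_wider(
    dplyr::mutate(p21, coefs = purrr::map(.data$fit, "params")), "coefs")
  stats_tables <- list(
    a = parameter_table(coef_tbl, "a", 0, B = config$B,
                        seed = derive_seed(config$seed, 51)),
    b1 = parameter_table(coef_tbl, "b1", 0, B = config$B,
                         seed = derive_seed(config$seed, 52)),
    b2 = parameter_table(coef_tbl, "b2", 0, B = config$B,
                         seed = derive_seed(config$seed, 53)),
    steady_state = steady_state_table(
      p21, n = config$design$n_trials, B = config$B,
      seed = derive_seed(config$seed, 54)))
  f_stats <- file.path(out_dir, "parameter_tables.csv")
  readr::write_csv(dplyr::bind_rows(stats_tables[c("a", "b1", "b2")]),
                   f_stats)
  readr::write_csv(stats_tables$steady_state,
                   file.path(out_dir, "steady_state.csv"))
  note("stats", 5L, sum(vapply(stats_tables, nrow, integer(1))), f_stats,
       "run", t0)

  # 6 washout analysis
  t0 <- as.double(Sys.time())
  wfits <- fit_washout_curves(dat, per = "curve", control = ctl(6))
  wtab <- washout_table(wfits, B = config$B,
                        seed = derive_seed(config$seed, 61))
  f_w <- file.path(out_dir, "washout.csv")
  readr::write_csv(wtab, f_w)
  note("washout", 6L, nrow(wtab), f_w, "run", t0)

  manifest <- dplyr::bind_rows(manifest)
  attr(manifest, "config_hash") <- rlang::hash(
    list(config$design, config$ground_truth, config$structures,
         config$n_starts, config$B, config$seed))
  list(data = dat, proxy_fits = proxy_fits, cv = cv, dpxmrml_fits = dpx,
       stats = stats_tables, washout = wtab, manifest = manifest)
}
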