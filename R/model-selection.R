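#' Enumerate exhaustive train/test partitions
#'
#' All partitions of a unit set (subjects or tasks) into a training and a
#' test set at the 4/5 : 1/5 split ratio. The test-set size is
#' `max(1, round(n / 5))`; every subset of that size appears exactly once, so
#' the count is `choose(n, test_size)`.
#'
#' @param ids Vector of at least 2 unit identifiers.
#' @return A tibble with columns `partition` (index), `train` and `test`
#'   (list columns of ids).
#' @examples
#' nrow(enumerate_partitions(1:5))  # 5
#' nrow(enumerate_partitions(1:8))  # 28
#' @export
enumerate_partitions <- function(ids) {
  n <- length(ids)
  stopifnot(n >= 2)
  test_size <- max(1L, as.integer(round(n / 5)))
  test_sets <- combn(ids, test_size, simplify = FALSE)
  tibble::tibble(
    partition = seq_along(test_sets),
    train = lapply(test_sets, function(ts) setdiff(ids, ts)),
    test = test_sets)
}

#' Average a set of fitted proxy models
#'
#' The "average model" of a training set is the coefficient-wise arithmetic
#' mean of the fitted parameters (including `sigma`), yielding a single
#' parameter set applied to each test curve.
#'
#' @param fits List of `proxy_fit` objects sharing one structure.
#' @return A list with `structure_id`, `params` (named list of mean
#'   coefficients) and `sigma`.
#' @export
average_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  sids <- vapply(fits, function(f) f$structure_id, character(1))
  if (length(unique(sids)) != 1) {
    stop("cannot average fits of different structures: ",
         paste(unique(sids), collapse = ", "), call. = FALSE)
  }
  mat <- do.call(rbind, lapply(fits, function(f) unlist(f$params)))
  params <- as.list(colMeans(mat))
  list(structure_id = sids[1], params = params,
       sigma = mean(vapply(fits, function(f) f$sigma, double(1))))
}

#' Mode of a kernel density estimate
#'
#' The maximum-likelihood summary of a skewed sample (such as cross-validation
#' RMSE values): the argmax of a Gaussian kernel density estimate with
#' Silverman's bandwidth, evaluated on a 512-point grid spanning the data
#' range plus 3 bandwidths. A single value (or a zero-spread sample) is
#' returned as is.
#'
#' @param values Non-empty numeric vector.
#' @return The KDE mode (scalar).
#' @examples
#' kde_mode(c(1, 1, 1, 5))  # close to 1
#' @export
kde_mode <- function(values) {
  stopifnot(length(values) >= 1)
  if (length(values) == 1 || sd(values) == 0) return(values[1])
  d <- density(values, bw = "nrd0", n = 512, cut = 3)
  d$x[which.max(d$y)]
}

#' Pairwise significance matrix of cross-validated model errors
#'
#' Compares every ordered pair of models on their per-partition error values
#' with the left-tailed Wilcoxon signed-rank test (is model A's error
#' systematically lower than model B's?). P-values are
#' Bonferroni-corrected by the number of ordered pairs, `m (m - 1)` (110 for
#' the full 11-structure family); a win is recorded when the corrected p
#' falls below `alpha`. Zero differences are dropped (signed-rank
#' convention); the exact null distribution is used for 25 or fewer non-zero
#' pairs without ties, the tie-corrected normal approximation otherwise.
#'
#' @param values A data frame with columns `partition`, `structure_id` and
#'   `rmse` (one value per model per partition), or a partitions x models
#'   matrix with model ids as column names.
#' @param alpha Significance level after correction (default 0.01).
#' @return A tibble with one row per ordered pair: `model_a`, `model_b`,
#'   `p.value`, `p.adjusted`, `win` (logical: a significantly below b).
#' @export
pairwise_compare <- function(values, alpha = 0.01) {
  if (is.data.frame(values)) {
    wide <- tidyr::pivot_wider(values[c("partition", "structure_id", "rmse")],
                               names_from = "structure_id",
                               values_from = "rmse")
    mat <- as.matrix(wide[, -1, drop = FALSE])
  } else {
    mat <- as.matrix(values)
  }
  models <- colnames(mat)
  m <- length(models)
  if (m < 2) {
    return(tibble::tibble(model_a = character(), model_b = character(),
                          p.value = double(), p.adjusted = double(),
                          win = logical()))
  }
  n_pairs <- m * (m - 1)
  pairs <- expand.grid(a = seq_len(m), b = seq_len(m))
  pairs <- pairs[pairs$a != pairs$b, ]
  res <- purrr::pmap(pairs, function(a, b) {
    x <- mat[, a]; y <- mat[, b]
    d <- x - y
    d <- d[d != 0]
    p <- if (length(d) == 0) 1 else {
      suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE, alternative = "less",
                           exact = length(d) <= 25)$p.value)
    }
    tibble::tibble(model_a = models[a], model_b = models[b], p.value = p)
  })
  out <- dplyr::bind_rows(res)
  out$p.adjusted <- pmin(1, out$p.value * n_pairs)
  out$win <- out$p.adjusted < alpha
  out
}

#' Model scores from a significance matrix
#'
#' A model's score is the number of models it significantly outperforms
#' (lower cross-validated error) minus the number of models that
#' significantly outperform it. Scores always sum to zero across models.
#'
#' @param matrix Output of [pairwise_compare()].
#' @return A tibble `structure_id`, `wins`, `losses`, `score`, sorted by
#'   descending score.
#' @export
model_scores <- function(matrix) {
  models <- unique(c(matrix$model_a, matrix$model_b))
  if (length(models) == 0) {
    return(tibble::tibble(structure_id = character(), wins = integer(),
                          losses = integer(), score = integer()))
  }
  wins <- vapply(models, function(mo)
    sum(matrix$win[matrix$model_a == mo]), integer(1), USE.NAMES = FALSE)
  losses <- vapply(models, function(mo)
    sum(matrix$win[matrix$model_b == mo]), integer(1), USE.NAMES = FALSE)
  tibble::tibble(structure_id = models, wins = wins, losses = losses,
                 score = wins - losses) |>
    dplyr::arrange(dplyr::desc(.data$score))
}

#' Exhaustive cross-validation of the model family
#'
#' Selects among proxy-process structures by exhaustive cross-validation.
#' Two groupings mirror the experimental design: `"subjects"` partitions the
#' subjects within each EA coordinate (every coordinate with at least two
#' subjects; others are skipped with a log entry), and `"tasks"` partitions
#' the eight learning tasks within each control subject (only control
#' subjects share one EA coordinate across tasks). For every partition and
#' structure, the models fitted to the training curves are averaged
#' ([average_model()]); the average model is deterministically simulated from
#' each test curve's own first-exposure error and scored by RMSE at that
#' curve's no-vision trials; the partition's summary is the KDE mode
#' ([kde_mode()]) of the test-curve RMSEs. Per-curve fits are computed once
#' and reused across partitions (they do not depend on the partition).
#'
#' @param data A trial table ([generate_dataset()] format).
#' @param structures Character vector of structure ids to compare (default:
#'   all eleven).
#' @param grouping `"subjects"` or `"tasks"`.
#' @param control A [fit_control()] list used for the per-curve fits.
#' @param fits Optional precomputed [fit_learning_curves()] table covering
#'   `structures` (avoids refitting).
#' @param alpha Significance level of the pairwise comparison (default 0.01).
#' @return An object of class `"cv_report"`: `partitions` (per group x
#'   partition x structure KDE-mode RMSE), `matrix` (pairwise significance),
#'   `scores` ([model_scores()]), `skipped` (log of skipped groups) and
#'   `grouping`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
cross_validate <- function(data, structures = proxy_models()$structure_id,
                           grouping = c("subjects", "tasks"),
                           control = fit_control(), fits = NULL,
                           alpha = 0.01) {
  grouping <- match.arg(grouping)
  if (is.null(fits)) {
    fits <- fit_learning_curves(data, structures = structures,
                                control = control)
  }
  fits <- dplyr::filter(fits, .data$structure_id %in% structures)
  learning <- dplyr::filter(data, .data$phase == "learning")
  n_trials <- max(learning$trial)   # transitions from trial 0
  # test-curve observations, keyed per curve
  curve_obs <- learning |>
    dplyr::filter(.data$no_vision) |>
    dplyr::group_by(.data$subject, .data$task, .data$direction) |>
    tidyr::nest(.key = "obs") |>
    dplyr::ungroup()
  fits <- dplyr::left_join(fits, curve_obs,
                           by = c("subject", "task", "direction"))

  groups <- if (grouping == "subjects") {
    split(fits, paste0("EA{", fits$gain, ",", fits$offset, "}"))
  } else {
    ctrl <- dplyr::filter(fits, .data$gain == 1L, .data$offset == 0L)
    ctrl <- dplyr::semi_join(
      ctrl,
      dplyr::distinct(dplyr::filter(data, .data$control),
                      .data$subject),
      by = "subject")
    split(ctrl, paste0("subject ", ctrl$subject))
  }
  unit_col <- if (grouping == "subjects") "subject" else "task"

  skipped <- character(0)
  rows <- list()
  for (gname in names(groups)) {
    gf <- groups[[gname]]
    units <- sort(unique(gf[[unit_col]]))
    if (length(units) < 2) {
      skipped <- c(skipped, paste0(gname, ": fewer than 2 ",
                                   if (grouping == "subjects") "subjects"
                                   else "tasks"))
      next
    }
    parts <- enumerate_partitions(units)
    for (sid in unique(gf$structure_id)) {
      sf <- gf[gf$structure_id == sid, ]
      spec <- model_spec(sid)
      for (i in seq_len(nrow(parts))) {
        train <- sf[sf[[unit_col]] %in% parts$train[[i]], ]
        test <- sf[sf[[unit_col]] %in% parts$test[[i]], ]
        avg <- average_model(train$fit)
        th <- unname(theta_from_params(spec, avg$params))
        rmse <- purrr::pmap_dbl(
          list(test$e0, test$obs), function(e0, obs) {
            sim <- .sim_proxy_cpp(spec$type, spec$order, th, e0,
                                  n_trials, 0, numeric(0))
            pred <- sim[obs$trial + 1L]
            sqrt(mean((obs$error - pred)^2))
          })
        rmse[!is.finite(rmse)] <- 1e6   # divergent average model: penalty
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = gname, partition = i, structure_id = sid,
          rmse = kde_mode(rmse))
      }
    }
  }
  partitions <- dplyr::bind_rows(rows)
  if (nrow(partitions) > 0) {
    # one paired sequence per (group, partition) across structures
    partitions <- dplyr::mutate(
      partitions,
      partition = paste(.data$group, .data$partition, sep = "/"))
    matrix <- pairwise_compare(partitions, alpha = alpha)
  } else {
    partitions <- tibble::tibble(group = character(), partition = character(),
                                 structure_id = character(), rmse = double())
    matrix <- pairwise_compare(matrix(numeric(0), ncol = 0), alpha = alpha)
  }
  structure(list(partitions = partitions, matrix = matrix,
                 scores = model_scores(matrix), skipped = skipped,
                 grouping = grouping, alpha = alpha),
            class = "cv_report")
}

#' Top-ranked structures of a cross-validation report
#'
#' @param report A `cv_report`.
#' @return Character vector of the structure id(s) attaining the maximum
#'   model score (ties are reported as co-winners).
#' @export
top_models <- function(report) {
  s <- report$scores
  if (nrow(s) == 0) return(character(0))
  s$structure_id[s$score == max(s$score)]
}
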