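#' Tidy a fitted proxy-process model
#'
#' @param x A `proxy_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` (drift coefficients plus
#'   `sigma`).
#' @export
tidy.proxy_fit <- function(x, ...) {
  tibble::tibble(term = c(names(x$params), "sigma"),
                 estimate = c(unlist(x$params), x$sigma))
}

#' Glance at a fitted proxy-process model
#'
#' @param x A `proxy_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the structure id, fit statistics and flags.
#' @export
glance.proxy_fit <- function(x, ...) {
  tibble::tibble(structure_id = x$structure_id, sse = x$sse, rmse = x$rmse,
                 r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
                 sigma = x$sigma, n_obs = x$n_obs, divergent = x$divergent,
                 constant_data = x$constant_data)
}

#' @export
print.proxy_fit <- function(x, ...) {
  cat("Proxy-process model fit, structure", x$structure_id, "\n")
  cat("  coefficients:",
      paste(names(x$params), signif(unlist(x$params), 4), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  sigma = %.4g, RMSE = %.4g, R2 = %.3f, adj. R2 = %.3f (n = %d)\n",
              x$sigma, x$rmse, x$r.squared, x$adj.r.squared, x$n_obs))
  invisible(x)
}

#' @rdname tidy.proxy_fit
#' @export
tidy.dpxmrml_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unlist(x$params))
}

#' @rdname glance.proxy_fit
#' @export
glance.dpxmrml_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, rmse = x$rmse, r.squared = x$r.squared,
                 adj.r.squared = x$adj.r.squared, n_obs = x$n_obs)
}

#' @export
print.dpxmrml_fit <- function(x, ...) {
  cat("Multi-rate model fit (dynamic proxy support)\n")
  cat(sprintf("  Af = %.3f, As = %.3f, Bf = %.3f, Bs = %.3f\n",
              x$params$Af, x$params$As, x$params$Bf, x$params$Bs))
  cat(sprintf("  RMSE = %.4g, R2 = %.3f (n = %d)\n", x$rmse, x$r.squared,
              x$n_obs))
  invisible(x)
}

#' @rdname tidy.proxy_fit
#' @export
tidy.washout_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "tau"), estimate = c(x$A, x$tau))
}

#' @rdname glance.proxy_fit
#' @export
glance.washout_fit <- function(x, ...) {
  tibble::tibble(A = x$A, tau = x$tau, sse = x$sse, flagged = x$flagged)
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The per-partition KDE-mode RMSE table.
#' @export
tidy.cv_report <- function(x, ...) x$partitions

#' Glance at a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The model-score table with a `top` flag on the co-winners.
#' @export
glance.cv_report <- function(x, ...) {
  s <- x$scores
  s$top <- s$structure_id %in% top_models(x)
  s
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report (grouping:", x$grouping, ")\n")
  cat("  partitions:", length(unique(x$partitions$partition)),
      " structures:", length(unique(x$partitions$structure_id)), "\n")
  cat("  top model(s):", paste(top_models(x), collapse = ", "), "\n")
  print(x$scores)
  invisible(x)
}

#' Plot a fitted proxy-process model over its learning curve
#'
#' Observed no-vision errors as points, the deterministic model trajectory
#' as a line.
#'
#' @param object A `proxy_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proxy_fit <- function(object, ...) {
  sim <- simulate_proxy(object$structure_id, object$params, object$e0,
                        object$n_trials, sigma = 0)
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$trial, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = sim,
                       ggplot2::aes(x = .data$trial, y = .data$error),
                       colour = "#2166ac") +
    ggplot2::labs(x = "trial", y = "signed error (cm)",
                  title = paste("Proxy-process structure",
                                object$structure_id)) +
    ggplot2::theme_minimal()
}

#' Plot multi-rate model predictions against observations
#'
#' @param object A `dpxmrml_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dpxmrml_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), alpha = 0.6,
                        size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "#b2182b") +
    ggplot2::labs(x = "trial", y = "signed error (cm)",
                  title = "Multi-rate model prediction (no-vision trials)") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation win/loss matrix
#'
#' Mirrors the significance-matrix display: one tile per ordered model pair,
#' coloured by whether the row model's cross-validated error is significantly
#' lower (win), higher (loss) or not significantly different.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  m <- object$matrix
  loss <- m[, c("model_b", "model_a", "win")]
  names(loss) <- c("model_a", "model_b", "loss")
  df <- dplyr::left_join(m, loss, by = c("model_a", "model_b"))
  df$outcome <- ifelse(df$win, "win", ifelse(df$loss, "loss", "ns"))
  ord <- object$scores$structure_id
  df$model_a <- factor(df$model_a, levels = ord)
  df$model_b <- factor(df$model_b, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_b, y = .data$model_a,
                                   fill = .data$outcome)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(win = "#1b7837", loss = "#b2182b",
                                          ns = "grey85")) +
    ggplot2::labs(x = "compared against", y = "model",
                  title = "Cross-validated pairwise comparisons") +
    ggplot2::theme_minimal()
}

#' Plot an EA parameter table
#'
#' Medians with 95% bootstrap confidence intervals per EA coordinate;
#' coordinates whose sign test rejects are coloured by direction, and
#' significant differences from the control are marked.
#'
#' @param object An `"ea_table"` from [parameter_table()] or
#'   [steady_state_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ea_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$coordinate <- paste0("{", df$gain, ",", df$offset, "}")
  df$sign <- dplyr::case_when(
    !df$sign_decision ~ "ns",
    df$direction < 0 ~ "negative",
    TRUE ~ "positive")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coordinate, y = .data$median,
                                   colour = .data$sign)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(data = df[!is.na(df$vs_control) & df$vs_control, ],
                        ggplot2::aes(y = .data$ci_hi), shape = 8,
                        colour = "black",
                        position = ggplot2::position_nudge(y = 0.05)) +
    ggplot2::scale_colour_manual(values = c(negative = "#2166ac",
                                            positive = "#e6a400",
                                            ns = "#b2182b")) +
    ggplot2::labs(x = "EA coordinate {gain, offset}",
                  y = unique(df$parameter) %||% "value") +
    ggplot2::theme_minimal()
}

#' Plot learning curves of a trial table
#'
#' No-vision errors per trial, one facet per movement direction, for one
#' subject and task.
#'
#' @param data A trial table.
#' @param subject,task Which curve block to show (defaults: first of each).
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(data, subject = NULL, task = NULL) {
  subject <- subject %||% min(data$subject)
  task <- task %||% min(data$task)
  df <- dplyr::filter(data, .data$subject == !!subject, .data$task == !!task,
                      .data$phase == "learning", .data$no_vision)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$error)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::facet_wrap(~ direction, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "trial", y = "signed error (cm)",
                  title = sprintf("Subject %s, task %s (no-vision trials)",
                                  subject, task)) +
    ggplot2::theme_minimal()
}
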