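#' Target geometry of the reaching task
#'
#' Targets sit at the vertices of an equilateral triangle (15 cm side by
#' default); target-to-target reaching yields six directed movement
#' directions, all of equal length and pairwise at least 60 degrees apart.
#'
#' @param side Triangle side length in cm (> 0).
#' @return A tibble with one row per directed reach: `direction` (1–6),
#'   `from`, `to` (vertex ids), start/target coordinates `x0`, `y0`, `x1`,
#'   `y1`, and the unit direction vector `ux`, `uy`.
#' @examples
#' make_geometry(15)
#' @export
make_geometry <- function(side = 15) {
  stopifnot(side > 0)
  ang <- pi / 2 + c(0, 2, 4) * pi / 3
  vx <- side / sqrt(3) * cos(ang)
  vy <- side / sqrt(3) * sin(ang)
  pairs <- rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(3, 1), c(1, 3))
  dx <- vx[pairs[, 2]] - vx[pairs[, 1]]
  dy <- vy[pairs[, 2]] - vy[pairs[, 1]]
  len <- sqrt(dx^2 + dy^2)
  tibble::tibble(
    direction = 1:6, from = pairs[, 1], to = pairs[, 2],
    x0 = vx[pairs[, 1]], y0 = vy[pairs[, 1]],
    x1 = vx[pairs[, 2]], y1 = vy[pairs[, 2]],
    ux = dx / len, uy = dy / len
  )
}

#' Catch-trial schedule
#'
#' Draws a no-vision (catch-trial) mask with an exact count and no two
#' catch trials in succession, uniformly over all masks satisfying both
#' constraints. Uniformity is exact: the k catch positions are obtained by
#' drawing a uniform k-subset of `n_trials - n_novision + 1` slots and
#' shifting the i-th sorted slot by i - 1, a bijection onto the
#' non-adjacent configurations.
#'
#' @param n_trials Trials in the phase (250 in the reference design).
#' @param n_novision Number of catch trials (74 in the reference design);
#'   must satisfy `n_novision <= ceiling(n_trials / 2)`.
#' @param seed Optional integer seed (local RNG).
#' @return Logical vector of length `n_trials`, `TRUE` on catch trials.
#' @examples
#' sched <- make_schedule(250, 74, seed = 1)
#' sum(sched)                 # 74
#' any(sched[-1] & sched[-250])  # FALSE: never two in succession
#' @export
make_schedule <- function(n_trials, n_novision, seed = NULL) {
  stopifnot(n_trials >= 1, n_novision >= 0)
  if (n_novision > ceiling(n_trials / 2)) {
    stop("cannot place ", n_novision, " non-adjacent catch trials in ",
         n_trials, " trials", call. = FALSE)
  }
  mask <- rep(FALSE, n_trials)
  if (n_novision == 0) return(mask)
  slots <- n_trials - n_novision + 1L
  pos <- with_seed(seed, sort(sample.int(slots, n_novision))) +
    seq_len(n_novision) - 1L
  mask[pos] <- TRUE
  mask
}

#' The error-augmentation coordinate grid
#'
#' @return A tibble of the 12 EA coordinates: `gain` in 0–3 crossed with
#'   `offset` in 0–2, restricted to the study grid \{(0,0), (1,0), (2,0),
#'   (3,0), (0,1), (1,1), (2,1), (3,1), (0,2), (1,2), (2,2), (3,2)\}, plus a
#'   `control` flag marking \{gain 1, offset 0\} (unaltered feedback).
#' @export
ea_grid <- function() {
  g <- tidyr::expand_grid(offset = 0:2, gain = 0:3)[, c("gain", "offset")]
  g$control <- g$gain == 1L & g$offset == 0L
  g
}

#' Assign error-augmentation coordinates to subjects and tasks
#'
#' Control subjects receive unaltered feedback (gain 1, offset 0) for every
#' task; the remaining subjects draw, independently per task, one of the 11
#' non-control coordinates uniformly.
#'
#' @param n_subjects,n_control Total and control subject counts
#'   (`n_control <= n_subjects`).
#' @param n_tasks Number of learning tasks per subject.
#' @param seed Optional integer seed (local RNG).
#' @return A tibble with columns `subject`, `task`, `gain`, `offset`,
#'   `control`.
#' @export
assign_ea <- function(n_subjects = 15, n_control = 5, n_tasks = 8,
                      seed = NULL) {
  stopifnot(n_control <= n_subjects, n_subjects >= 1, n_tasks >= 1)
  grid <- ea_grid()
  non_control <- grid[!grid$control, ]
  out <- tidyr::expand_grid(subject = seq_len(n_subjects),
                            task = seq_len(n_tasks))
  is_ctrl <- out$subject <= n_control
  draw <- with_seed(seed,
                    sample.int(nrow(non_control), sum(!is_ctrl),
                               replace = TRUE))
  out$gain <- ifelse(is_ctrl, 1L, NA_integer_)
  out$offset <- ifelse(is_ctrl, 0L, NA_integer_)
  out$gain[!is_ctrl] <- non_control$gain[draw]
  out$offset[!is_ctrl] <- non_control$offset[draw]
  out$control <- is_ctrl
  out
}

#' Error-augmented cursor transformation
#'
#' Maps an unaugmented cursor sample to its displayed position:
#' \deqn{\hat c = c_d + \mathrm{gain}\,(c - c_d) + \mathrm{offset}\,(c_0 -
#' c_d),} where \eqn{c_d} is the nearest point of the ideal straight path and
#' \eqn{c_0} the corresponding sample of the first-exposure trajectory.
#' Gain 1 / offset 0 leaves the cursor unchanged (control feedback).
#'
#' @param c_xy Numeric length-2 unaugmented cursor position (or an n x 2
#'   matrix of samples).
#' @param c_d Matching ideal-path position(s).
#' @param c_0 Matching first-exposure position(s).
#' @param gain,offset EA levels (gain in 0–3, offset in 0–2).
#' @return Augmented position(s), same shape as `c_xy`.
#' @examples
#' augment_cursor(c(1, 1), c(0, 0), c(2, 0), gain = 2, offset = 1)  # (4, 2)
#' @export
augment_cursor <- function(c_xy, c_d, c_0, gain, offset) {
  stopifnot(gain %in% 0:3, offset %in% 0:2)
  c_d + gain * (c_xy - c_d) + offset * (c_0 - c_d)
}

#' Synthetic launch trajectory
#'
#' Builds a smooth stand-in for the first ballistic launch of a reach: the
#' ideal straight path plus a half-sine lateral bump whose signed peak
#' perpendicular deviation equals `lateral_amplitude` (positive = to the left
#' of the movement direction). Optional Gaussian jitter roughens the samples.
#'
#' @param reach One row of [make_geometry()].
#' @param lateral_amplitude Signed peak deviation in cm.
#' @param n_samples Number of samples (>= 2).
#' @param jitter_sd Sd of isotropic positional jitter (cm), default 0.
#' @param seed Optional integer seed (local RNG) for the jitter.
#' @return A tibble with columns `x`, `y` and attributes `x0`, `y0`, `x1`,
#'   `y1` carrying the ideal path endpoints.
#' @export
synth_trajectory <- function(reach, lateral_amplitude, n_samples = 50,
                             jitter_sd = 0, seed = NULL) {
  stopifnot(n_samples >= 2)
  t <- seq(0, 1, length.out = n_samples)
  len <- sqrt((reach$x1 - reach$x0)^2 + (reach$y1 - reach$y0)^2)
  # left-hand normal of the movement direction
  nx <- -reach$uy
  ny <- reach$ux
  dev <- lateral_amplitude * sin(pi * t)
  x <- reach$x0 + t * len * reach$ux + dev * nx
  y <- reach$y0 + t * len * reach$uy + dev * ny
  if (jitter_sd > 0) {
    j <- with_seed(seed, matrix(rnorm(2 * n_samples, sd = jitter_sd), ncol = 2))
    x <- x + j[, 1]
    y <- y + j[, 2]
  }
  out <- tibble::tibble(x = x, y = y)
  attr(out, "x0") <- reach$x0; attr(out, "y0") <- reach$y0
  attr(out, "x1") <- reach$x1; attr(out, "y1") <- reach$y1
  out
}

#' Signed maximum-deviation error of a launch trajectory
#'
#' The error magnitude is the maximum perpendicular (L2) distance between the
#' trajectory samples and the ideal straight path; always computed on
#' unaugmented cursor coordinates. The sign is positive when the
#' maximal-deviation sample lies on the same side of the path as on the first
#' exposure to that movement direction, negative otherwise.
#'
#' @param trajectory A tibble from [synth_trajectory()] (or any tibble with
#'   `x`, `y` and the path-endpoint attributes).
#' @param reference_side `+1` or `-1`: the deviation side (sign of the
#'   left-normal component) recorded on the first trial of the direction.
#' @return Signed error in cm.
#' @export
signed_error <- function(trajectory, reference_side = 1) {
  stopifnot(reference_side %in% c(-1, 1))
  x0 <- attr(trajectory, "x0"); y0 <- attr(trajectory, "y0")
  x1 <- attr(trajectory, "x1"); y1 <- attr(trajectory, "y1")
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("degenerate (zero-length) ideal path", call. = FALSE)
  # signed perpendicular offset: positive on the left of the path direction
  off <- ((trajectory$x - x0) * (-dy) + (trajectory$y - y0) * dx) / len
  i <- which.max(abs(off))
  side <- sign(off[i])
  if (side == 0) return(0)
  abs(off[i]) * side * reference_side
}

#' Experiment design parameters
#'
#' Bundles the structural constants of the reference experiment: 15 subjects
#' (5 control), 8 learning tasks of 250 trials with 74 non-adjacent catch
#' trials each, a 30-trial washout per task, and 6 movement directions on a
#' 15 cm triangular target layout.
#'
#' @param n_subjects,n_control,n_tasks,n_trials,n_novision,n_washout,n_directions,side
#'   Design constants; defaults are the reference values.
#' @param e0_range First-exposure error magnitudes are drawn uniformly from
#'   this range (cm); the sign is fixed per movement direction (alternating
#'   with direction parity).
#' @return A list of class `"ea_design"`.
#' @export
experiment_design <- function(n_subjects = 15, n_control = 5, n_tasks = 8,
                              n_trials = 250, n_novision = 74,
                              n_washout = 30, n_directions = 6, side = 15,
                              e0_range = c(2, 6)) {
  stopifnot(n_control <= n_subjects, n_novision <= ceiling(n_trials / 2),
            n_directions >= 1, n_directions <= 6, length(e0_range) == 2)
  structure(list(n_subjects = n_subjects, n_control = n_control,
                 n_tasks = n_tasks, n_trials = n_trials,
                 n_novision = n_novision, n_washout = n_washout,
                 n_directions = n_directions, side = side,
                 e0_range = e0_range),
            class = "ea_design")
}

#' Default ground-truth parameter map
#'
#' One second-order (`"2.1"`) proxy-process parameter set and one washout
#' decay time constant per EA coordinate. The defaults emulate the
#' qualitative structure of error-augmented learning: a stable second-order
#' error process (`b1 > 0`, `b2 < 0`), a constant drift `a` that grows more
#' negative with the offset level (driving negative, overcompensating steady
#' states there), and washout time constants that are long after high-gain
#' training (gain 3) and short after gain-2 training relative to control.
#'
#' @param process `"proxy"` (default) to generate learning curves from the
#'   `"2.1"` process, or `"dpxmrml"` to generate from the multi-rate model
#'   (whose rates are also tabulated here).
#' @return A tibble keyed by `gain`, `offset` with columns `a`, `b1`, `b2`,
#'   `sigma`, `tau` (washout trials), `Af`, `As`, `Bf`, `Bs` and `process`.
#' @export
default_ground_truth <- function(process = c("proxy", "dpxmrml")) {
  process <- match.arg(process)
  g <- ea_grid()
  g$a <- -0.02 * g$offset
  g$b1 <- 0.40
  g$b2 <- -0.45
  g$sigma <- 0.1
  g$tau <- 5
  g$tau[g$gain == 3 & g$offset == 0] <- 20
  g$tau[g$gain == 2 & g$offset == 0] <- 3
  g$Af <- -0.4
  g$As <- 0.92
  g$Bf <- 0.35 + 0.05 * pmin(g$gain, 2)
  g$Bs <- 0.06
  g$process <- process
  g
}

# generate one learning curve (error sequence over all trials) from the
# configured ground-truth process
generate_curve <- function(truth_row, e0, n_trials, mask, seed) {
  noise <- with_seed(seed, rnorm(n_trials))
  if (identical(truth_row$process, "dpxmrml")) {
    # observations are produced by the model itself: on "available" trials
    # the recorded error is the model prediction plus noise; gaps follow the
    # embedded proxy process. Trial 0 is pinned at e0.
    N <- n_trials
    th <- c(truth_row$a, truth_row$b1, truth_row$b2)
    xf <- 0; xs <- 0
    e <- numeric(N)
    ehat <- numeric(N)
    for (n in seq_len(N)) {
      yhat <- xf + xs
      if (n == 1) {
        e[n] <- e0
        ehat[n] <- e0
      } else if (mask[n]) {
        e[n] <- yhat + truth_row$sigma * noise[n]
        ehat[n] <- e[n]
      } else {
        e1 <- ehat[n - 1]
        e2 <- if (n >= 3) ehat[n - 2] else e1
        ehat[n] <- e1 + th[1] + th[2] * e1 + th[3] * e2
        e[n] <- ehat[n]
      }
      xf1 <- truth_row$Af * xf + truth_row$Bf * ehat[n]
      xs1 <- truth_row$As * xs + truth_row$Bs * ehat[n]
      xf <- xf1; xs <- xs1
    }
    e
  } else {
    params <- list(a = truth_row$a, b1 = truth_row$b1, b2 = truth_row$b2)
    sim <- simulate_proxy("2.1", params, e0, n_trials - 1L,
                          sigma = truth_row$sigma,
                          noise = noise[seq_len(n_trials - 1L)])
    sim$error
  }
}

#' Generate a synthetic experiment dataset
#'
#' Simulates the full trial table of the reference experiment: per subject and
#' task, an EA coordinate is assigned ([assign_ea()]); per movement direction,
#' a learning curve of `n_trials` signed errors evolves from a first-exposure
#' error `e0` under the coordinate's ground-truth process, with a non-adjacent
#' catch-trial schedule marking the no-vision trials on which the error metric
#' is defined; a washout phase follows whose error magnitudes decay as
#' \eqn{A e^{-n/\tau}} (A = final learning-phase magnitude, \eqn{\tau} from
#' the ground truth) plus half-normal noise. Errors on vision trials are
#' generated by the same process and flagged; downstream fitting uses
#' no-vision rows only. With a fixed seed the output is bit-reproducible.
#'
#' @param design An [experiment_design()] list.
#' @param ground_truth A tibble like [default_ground_truth()], keyed by
#'   `gain`, `offset`.
#' @param seed Integer seed; all schedule, assignment, e0 and noise draws
#'   derive from it.
#' @return A tibble of trial records: `subject`, `task`, `direction`,
#'   `phase` (`"learning"`/`"washout"`), `trial` (0-based within phase),
#'   `no_vision`, `gain`, `offset`, `control`, `error` (cm), `e0`.
#' @export
generate_dataset <- function(design = experiment_design(),
                             ground_truth = default_ground_truth(),
                             seed = 1) {
  assign_tbl <- assign_ea(design$n_subjects, design$n_control,
                          design$n_tasks, seed = derive_seed(seed, 1))
  key <- paste(assign_tbl$gain, assign_tbl$offset)
  truth_key <- paste(ground_truth$gain, ground_truth$offset)
  miss <- setdiff(unique(key), truth_key)
  if (length(miss) > 0) {
    stop("ground truth missing for EA coordinate(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cells <- tidyr::expand_grid(row = seq_len(nrow(assign_tbl)),
                              direction = seq_len(design$n_directions))
  res <- purrr::pmap(cells, function(row, direction) {
    sub <- assign_tbl$subject[row]
    task <- assign_tbl$task[row]
    truth <- ground_truth[truth_key == key[row], ][1, ]
    cell_seed <- derive_seed(seed, 100 + row * 13 + direction)
    sched <- make_schedule(design$n_trials, design$n_novision,
                           seed = derive_seed(cell_seed, 1))
    e0_mag <- with_seed(derive_seed(cell_seed, 2),
                        runif(1, design$e0_range[1], design$e0_range[2]))
    e0 <- e0_mag * ifelse(direction %% 2 == 1, 1, -1)
    err <- generate_curve(truth, e0, design$n_trials, sched,
                          seed = derive_seed(cell_seed, 3))
    learning <- tibble::tibble(
      subject = sub, task = task, direction = direction,
      phase = "learning", trial = seq_len(design$n_trials) - 1L,
      no_vision = sched, gain = assign_tbl$gain[row],
      offset = assign_tbl$offset[row], control = assign_tbl$control[row],
      error = err, e0 = e0)
    A <- abs(err[design$n_trials])
    wn <- seq_len(design$n_washout) - 1L
    wnoise <- with_seed(derive_seed(cell_seed, 4),
                        abs(rnorm(design$n_washout, sd = 0.1)))
    wmag <- A * exp(-wn / truth$tau) + wnoise
    washout <- tibble::tibble(
      subject = sub, task = task, direction = direction,
      phase = "washout", trial = wn, no_vision = FALSE,
      gain = assign_tbl$gain[row], offset = assign_tbl$offset[row],
      control = assign_tbl$control[row],
      error = wmag * sign(err[design$n_trials]), e0 = e0)
    dplyr::bind_rows(learning, washout)
  })
  dplyr::bind_rows(res)
}
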