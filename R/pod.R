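#' Configuration of the pseudo-overdominance classifier
#'
#' Numeric operationalisation of four qualitative criteria for
#' pseudo-overdominance: (i) elevated intermediate median allele frequencies,
#' (ii) a decelerated decline of population fitness, (iii) a continual
#' increase in the number of segregating mutations, and (iv) no concordant
#' increase in the number of fixed mutations. Verdicts are computed from two
#' generation windows -- an early window spanning the approach to equilibrium
#' and a late window at the end of the run -- and every threshold is exposed
#' here because the underlying criteria are qualitative.
#'
#' @param early_window Generation range `c(from, to)` of the early window.
#' @param late_window Generation range of the late window, or NULL for the
#'   last `late_span` generations of the trajectory.
#' @param late_span Width of the default late window.
#' @param af_threshold Minimum mean median allele frequency in the late
#'   window (criterion i).
#' @param decel_ratio Maximum late/early ratio of log-fitness decline slopes
#'   (criterion ii): the late slope must be at least `decel_ratio` times the
#'   early slope when the early slope is negative.
#' @param seg_slope_min Minimum late-window least-squares slope of the
#'   segregating count, in mutations per generation (criterion iii).
#' @param fix_ratio Maximum late/early ratio of fixation rates (criterion
#'   iv); with a zero early rate the criterion passes only if the late rate
#'   is also zero.
#' @param fitness_floor Positive floor applied before taking log fitness.
#' @return An object of class `pod_config`.
#' @export
pod_config <- function(early_window = c(500, 2500), late_window = NULL,
                       late_span = 2000, af_threshold = 0.25,
                       decel_ratio = 0.8, seg_slope_min = 1e-3,
                       fix_ratio = 0.5, fitness_floor = 1e-12) {
  stopifnot(length(early_window) == 2L, early_window[1] < early_window[2],
            is.null(late_window) || (length(late_window) == 2L &&
                                     late_window[1] < late_window[2]),
            late_span > 0, af_threshold >= 0, af_threshold <= 1,
            decel_ratio >= 0, fix_ratio >= 0, fitness_floor > 0)
  structure(list(early_window = as.numeric(early_window),
                 late_window = if (is.null(late_window)) NULL else as.numeric(late_window),
                 late_span = as.numeric(late_span),
                 af_threshold = af_threshold, decel_ratio = decel_ratio,
                 seg_slope_min = seg_slope_min, fix_ratio = fix_ratio,
                 fitness_floor = fitness_floor),
            class = "pod_config")
}

.ols_slope <- function(g, y) {
  ok <- is.finite(y)
  if (sum(ok) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(y[ok] ~ g[ok]))[2])
}

#' Classify a trajectory for pseudo-overdominance
#'
#' Applies the four criteria of [pod_config()] to a recorded trajectory:
#' \describe{
#'   \item{i}{mean median allele frequency in the late window at least
#'     `af_threshold` (NA rows from mutation-free generations excluded);}
#'   \item{ii}{the late-window least-squares slope of log mean fitness is at
#'     least `decel_ratio` times the early-window slope when the latter is
#'     negative (the decline decelerated), and non-negative when fitness
#'     never declined;}
#'   \item{iii}{the late-window slope of the segregating count is at least
#'     `seg_slope_min`;}
#'   \item{iv}{the late-window fixation rate is at most `fix_ratio` times the
#'     early-window rate.}
#' }
#' The overall verdict is the conjunction of all four.
#'
#' @param traj A `sim_trajectory`, or a data frame of trajectory rows.
#' @param config A [pod_config()].
#' @return An object of class `pod_call`: logical `criteria` (i-iv), logical
#'   `is_pod`, and a `diagnostics` list of the window statistics used.
#' @examples
#' classify_pod(make_fixture_trajectory("po"))
#' @export
classify_pod <- function(traj, config = pod_config()) {
  rows <- if (is.data.frame(traj)) traj else traj$rows
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  gmax <- max(rows$generation)
  ew <- config$early_window
  lw <- if (is.null(config$late_window)) c(gmax - config$late_span, gmax) else config$late_window
  if (gmax < ew[2] || lw[1] < 0 || gmax < lw[2])
    stop("trajectory is shorter than the classifier windows")
  early <- rows[rows$generation >= ew[1] & rows$generation <= ew[2], ]
  late <- rows[rows$generation >= lw[1] & rows$generation <= lw[2], ]
  if (nrow(early) < 3L || nrow(late) < 3L)
    stop("too few recorded rows inside the classifier windows")

  af_late <- mean(late$median_allele_freq, na.rm = TRUE)
  crit_i <- is.finite(af_late) && af_late >= config$af_threshold

  lf_early <- log(pmax(early$mean_fitness, config$fitness_floor))
  lf_late <- log(pmax(late$mean_fitness, config$fitness_floor))
  slope_early <- .ols_slope(early$generation, lf_early)
  slope_late <- .ols_slope(late$generation, lf_late)
  crit_ii <- is.finite(slope_late) && is.finite(slope_early) &&
    slope_late >= config$decel_ratio * min(slope_early, 0)

  seg_slope <- .ols_slope(late$generation, late$n_segregating)
  crit_iii <- is.finite(seg_slope) && seg_slope >= config$seg_slope_min

  rate_win <- function(w) {
    span <- max(w$generation) - min(w$generation)
    (w$n_fixed_cumulative[nrow(w)] - w$n_fixed_cumulative[1]) / span
  }
  fix_early <- rate_win(early)
  fix_late <- rate_win(late)
  crit_iv <- if (fix_early == 0) fix_late == 0 else
    fix_late <= config$fix_ratio * fix_early

  criteria <- c(i = crit_i, ii = crit_ii, iii = crit_iii, iv = crit_iv)
  structure(
    list(criteria = criteria, is_pod = all(criteria),
         diagnostics = list(
           late_mean_median_af = af_late, log_fitness_slope_early = slope_early,
           log_fitness_slope_late = slope_late, seg_slope_late = seg_slope,
           fixation_rate_early = fix_early, fixation_rate_late = fix_late,
           early_window = ew, late_window = lw)),
    class = "pod_call")
}

#' @export
print.pod_call <- function(x, ...) {
  cat(sprintf(
    "pseudo-overdominance call: %s\n  i (elevated median AF):        %s (late mean %.3f)\n  ii (decelerated fitness loss): %s\n  iii (segregating rising):      %s (slope %.4g /gen)\n  iv (fixation stalled):         %s (rate %.4g vs %.4g /gen)\n",
    if (x$is_pod) "POSITIVE" else "negative",
    x$criteria["i"], x$diagnostics$late_mean_median_af,
    x$criteria["ii"], x$criteria["iii"], x$diagnostics$seg_slope_late,
    x$criteria["iv"], x$diagnostics$fixation_rate_late,
    x$diagnostics$fixation_rate_early))
  invisible(x)
}

#' Synthetic fixture trajectories for the classifier
#'
#' Piecewise-linear trajectories with optional Gaussian jitter embodying four
#' canonical regimes, used to test the classifier without running the
#' simulator:
#' \describe{
#'   \item{po}{pseudo-overdominance: median AF ramps to a 0.4 plateau,
#'     fitness declines then levels off, segregating count rises throughout,
#'     fixations stop after an early trickle;}
#'   \item{ma}{mutation accumulation: low median AF, steady log-linear
#'     fitness decline, plateauing segregating count, steadily rising
#'     fixations;}
#'   \item{mimic}{high-recombination mimic: elevated median AF but steeply
#'     falling fitness and ongoing fixation;}
#'   \item{neutral}{flat fitness at 1, low median AF, plateauing segregating
#'     count, constant fixation rate.}
#' }
#' Jitter standard deviation is `noise_sd` times each series' amplitude;
#' cumulative fixation counts stay non-decreasing under noise.
#'
#' @param kind One of `"po"`, `"ma"`, `"mimic"`, `"neutral"`.
#' @param noise_sd Relative jitter (0 = noiseless).
#' @param generations Final generation of the fixture.
#' @param record_every Row stride in generations.
#' @return A `sim_trajectory` whose `rows` follow the named regime.
#' @examples
#' classify_pod(make_fixture_trajectory("ma"))$is_pod  # FALSE
#' @export
make_fixture_trajectory <- function(kind = c("po", "ma", "mimic", "neutral"),
                                    noise_sd = 0, generations = 10000,
                                    record_every = 10) {
  kind <- match.arg(kind)
  stopifnot(noise_sd >= 0)
  g <- seq(0, generations, by = record_every)
  ramp <- function(to, by_gen) to * pmin(g, by_gen) / by_gen
  base <- switch(kind,
    po = list(af = ramp(0.4, 2000),
              fit = 1 - ramp(0.2, 2000),
              seg = 0.05 * g,
              fix = ramp(5, 2000)),
    ma = list(af = rep(0.05, length(g)),
              fit = exp(-2e-5 * g),
              seg = 50 * (1 - exp(-g / 1000)),
              fix = 0.02 * g),
    mimic = list(af = ramp(0.35, 1000),
                 fit = exp(-5e-5 * g),
                 seg = 60 * (1 - exp(-g / 1000)),
                 fix = 0.05 * g),
    neutral = list(af = rep(0.1, length(g)),
                   fit = rep(1, length(g)),
                   seg = 80 * (1 - exp(-g / 500)),
                   fix = 0.01 * g))
  jit <- function(y) {
    if (noise_sd == 0) return(y)
    amp <- diff(range(y))
    if (amp == 0) amp <- max(abs(y), 1) * 0.05
    y + stats::rnorm(length(y), 0, noise_sd * amp)
  }
  af <- pmin(pmax(jit(base$af), 1e-3), 0.999)
  fit <- pmax(jit(base$fit), 1e-6)
  seg <- pmax(round(jit(base$seg)), 0)
  fix <- cummax(pmax(round(jit(base$fix)), 0))
  rows <- data.frame(
    generation = g, median_allele_freq = af, mean_fitness = fit,
    parental_mean_fitness = pmin(fit * 1.02, 1), n_segregating = seg,
    n_fixed_cumulative = fix)
  structure(list(rows = rows, params = NULL, model = NULL, replicate = NA_integer_,
                 seed = NA_integer_, offspring_fitness = list(),
                 substitutions = NULL, population = NULL, fixture_kind = kind),
            class = "sim_trajectory")
}

#' Compare pseudo-overdominance verdicts between ploidies over a grid
#'
#' Joins per-cell classifier calls for tetraploid and diploid runs of the same
#' parameter grid and tallies how much of the grid is pseudo-overdominance
#' positive at each ploidy -- the headline contrast being that the positive
#' region is far larger in autotetraploids.
#'
#' @param calls_tetra,calls_diploid Lists of `pod_call` objects (or logical
#'   vectors of verdicts), one per grid row, in grid order.
#' @param grid Data frame of parameter combinations (one row per cell).
#' @return A list with `cells` (grid plus per-ploidy verdicts) and `summary`
#'   (count and fraction of positive cells per ploidy).
#' @export
compare_ploidies <- function(calls_tetra, calls_diploid, grid) {
  stopifnot(is.data.frame(grid))
  as_verdict <- function(calls) {
    if (is.logical(calls)) return(calls)
    vapply(calls, function(x) {
      if (inherits(x, "pod_call")) x$is_pod else as.logical(x)
    }, logical(1))
  }
  vt <- as_verdict(calls_tetra)
  vd <- as_verdict(calls_diploid)
  if (length(vt) != nrow(grid) || length(vd) != nrow(grid))
    stop("call sets do not cover the same grid")
  cells <- cbind(grid, pod_tetraploid = vt, pod_diploid = vd)
  n <- nrow(grid)
  summary <- data.frame(
    ploidy = c(4L, 2L), n_pod = c(sum(vt), sum(vd)),
    fraction_pod = if (n == 0) c(NaN, NaN) else c(mean(vt), mean(vd)))
  list(cells = cells, summary = summary)
}
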