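#' Parameter sweep configuration
#'
#' Grids over population size, selection coefficient, recombination rate,
#' mutation rate and ploidy, with replicate and seed management. The full
#' study grid is N in {100, 200, 500}; s in {-0.0005, -0.001, -0.005, -0.01,
#' -0.02} or the empirical h-s DFE; rho and mu each in {1e-10, 1e-9, 5e-9,
#' 1e-8, 5e-8, 1e-7}; ploidy in {2, 4}; 10 replicates of 20,000 generations
#' per cell. `scale_factor` rescales to desk size: L is divided and the
#' per-bp rates multiplied by the factor, holding the per-chromosome totals
#' mu*L and rho*L fixed, under which trajectory statistics are invariant in
#' distribution.
#'
#' @param N Population size grid.
#' @param s Selection grid: numeric coefficients and/or the string
#'   `"empirical"` for the empirical h-s DFE.
#' @param rho,mu Per-base-pair rate grids (quoted at full scale).
#' @param ploidy Ploidy grid (2 and/or 4).
#' @param replicates Replicates per cell.
#' @param base_seed Base seed from which each run's seed is derived.
#' @param generations Generations per run.
#' @param record_every Trajectory stride.
#' @param L Full-scale chromosome length.
#' @param scale_factor Desk-scale factor (>= 1); 1 = full scale.
#' @param dfe Arguments passed to [selection_model()] for `"empirical"`
#'   cells.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(N = c(100L, 200L, 500L), s = c(-5e-4, -1e-3, -5e-3, -1e-2, -2e-2, "empirical"),
                         rho = c(1e-10, 1e-9, 5e-9, 1e-8, 5e-8, 1e-7),
                         mu = c(1e-10, 1e-9, 5e-9, 1e-8, 5e-8, 1e-7),
                         ploidy = c(2L, 4L), replicates = 10L, base_seed = 1L,
                         generations = 20000L, record_every = 10L, L = 1e6,
                         scale_factor = 1, dfe = list()) {
  stopifnot(replicates >= 1, scale_factor >= 1, all(ploidy %in% c(2L, 4L)))
  structure(list(N = as.integer(N), s = as.character(s), rho = as.numeric(rho),
                 mu = as.numeric(mu), ploidy = as.integer(ploidy),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 generations = as.integer(generations),
                 record_every = as.integer(record_every), L = as.numeric(L),
                 scale_factor = as.numeric(scale_factor), dfe = dfe),
            class = "sweep_config")
}

#' Derive the seed of one sweep run
#'
#' Stable string hash of (base seed, N, s, mu, rho, ploidy, replicate), so
#' any single cell can be reproduced in isolation and results are invariant
#' to execution order. The hash is a 31-multiplier polynomial over the UTF-8
#' bytes of the formatted key, reduced modulo 2^31 - 1.
#'
#' @param base_seed Integer base seed.
#' @param N,s,mu,rho,ploidy,replicate Cell coordinates; `s` may be a numeric
#'   coefficient or `"empirical"`.
#' @return A non-negative integer seed below 2^31.
#' @examples
#' derive_seed(1, 100, -0.005, 1e-7, 1e-10, 4, 1)
#' @export
derive_seed <- function(base_seed, N, s, mu, rho, ploidy, replicate) {
  key <- paste(base_seed, N, as.character(s),
               formatC(mu, format = "e", digits = 8),
               formatC(rho, format = "e", digits = 8), ploidy, replicate,
               sep = "|")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

.cell_model <- function(s_label, dfe = list()) {
  if (s_label == "empirical") {
    do.call(selection_model, c(list(mode = "empirical"), dfe))
  } else {
    selection_model("constant", s = as.numeric(s_label))
  }
}

#' Run a replicated parameter sweep
#'
#' Executes every grid cell times replicate with a per-run derived seed (see
#' [derive_seed()]), classifies each trajectory for pseudo-overdominance, and
#' collects a master results table. Runs are independent, so results do not
#' depend on execution order. A failing run is recorded with `status =
#' "error"` (or `"extinct"`) rather than aborting the sweep. Grid values are
#' echoed verbatim (full-scale mu, rho, L) in the results; the simulator is
#' invoked at the desk scale implied by `scale_factor`.
#'
#' @param config A [sweep_config()].
#' @param pod A [pod_config()] used to classify each run, or NULL to skip
#'   classification.
#' @param out_dir Optional directory; when given, one trajectory TSV per run
#'   plus `master_results.tsv` are written there.
#' @param keep_trajectories Keep the `sim_trajectory` objects in memory?
#' @return An object of class `sweep_result`: `results` (master data frame),
#'   `trajectories` (named list or NULL), `config`.
#' @export
run_sweep <- function(config, pod = pod_config(), out_dir = NULL,
                      keep_trajectories = TRUE) {
  stopifnot(inherits(config, "sweep_config"))
  cells <- expand.grid(N = config$N, s = config$s, rho = config$rho,
                       mu = config$mu, ploidy = config$ploidy,
                       stringsAsFactors = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  trajs <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    for (rep in seq_len(config$replicates)) {
      seed <- derive_seed(config$base_seed, cell$N, cell$s, cell$mu, cell$rho,
                          cell$ploidy, rep)
      params <- sim_params(
        N = cell$N, ploidy = cell$ploidy,
        mu = cell$mu * config$scale_factor,
        rho = cell$rho * config$scale_factor,
        generations = config$generations,
        L = config$L / config$scale_factor, seed = seed,
        record_every = config$record_every)
      model <- .cell_model(cell$s, config$dfe)
      run_name <- sprintf("N%d_s%s_rho%g_mu%g_p%d_rep%d", cell$N, cell$s,
                          cell$rho, cell$mu, cell$ploidy, rep)
      status <- "ok"
      traj <- tryCatch(
        run_simulation(params, model, replicate = rep,
                       keep_population = FALSE),
        error = function(e) {
          status <<- if (grepl("extinct", conditionMessage(e)))
            "extinct" else "error"
          NULL
        })
      row <- data.frame(N = cell$N, s = cell$s, rho = cell$rho, mu = cell$mu,
                        ploidy = cell$ploidy, replicate = rep, seed = seed,
                        status = status, stringsAsFactors = FALSE)
      if (!is.null(traj)) {
        last <- traj$rows[nrow(traj$rows), ]
        row$final_median_af <- last$median_allele_freq
        row$final_mean_fitness <- last$mean_fitness
        row$final_n_segregating <- last$n_segregating
        row$final_n_fixed <- last$n_fixed_cumulative
        if (!is.null(pod)) {
          call <- classify_pod(traj, pod)
          row$pod_i <- call$criteria[["i"]]
          row$pod_ii <- call$criteria[["ii"]]
          row$pod_iii <- call$criteria[["iii"]]
          row$pod_iv <- call$criteria[["iv"]]
          row$is_pod <- call$is_pod
        }
        if (!is.null(out_dir))
          write_trajectory_tsv(traj, file.path(out_dir, paste0(run_name, ".tsv")))
        if (keep_trajectories) trajs[[run_name]] <- traj
      } else {
        row$final_median_af <- NA_real_
        row$final_mean_fitness <- NA_real_
        row$final_n_segregating <- NA_integer_
        row$final_n_fixed <- NA_integer_
        if (!is.null(pod)) {
          row$pod_i <- row$pod_ii <- row$pod_iii <- row$pod_iv <- NA
          row$is_pod <- NA
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  if (!is.null(out_dir)) {
    hdr <- c(sprintf("base_seed=%d", config$base_seed),
             sprintf("scale_factor=%.17g", config$scale_factor),
             sprintf("generations=%d", config$generations))
    .write_tsv_with_header(results, file.path(out_dir, "master_results.tsv"),
                           hdr)
  }
  structure(list(results = results,
                 trajectories = if (keep_trajectories) trajs else NULL,
                 config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  r <- x$results
  cat(sprintf("sweep_result: %d runs over %d cells (%d ok)\n", nrow(r),
              nrow(unique(r[c("N", "s", "rho", "mu", "ploidy")])),
              sum(r$status == "ok")))
  if ("is_pod" %in% names(r))
    cat(sprintf("  pseudo-overdominance positive: %d runs\n",
                sum(r$is_pod, na.rm = TRUE)))
  invisible(x)
}

#' Aggregate sweep results into an allele-frequency heatmap table
#'
#' For a fixed (N, s, ploidy) slice, averages the final-generation median
#' allele frequency over replicates for every (mu, rho) cell. Replicates
#' whose final generation had no segregating mutations (NA median) are
#' excluded from the mean; a cell where all replicates are NA stays NA.
#' Cells absent from the results are flagged with a warning, never imputed.
#'
#' @param results A `sweep_result` or its master results data frame.
#' @param N,s,ploidy Slice coordinates (`s` as number or `"empirical"`).
#' @return A data frame of class `heatmap_table` with columns `mu`, `rho`,
#'   `mean_final_median_af`, `n_replicates`.
#' @export
aggregate_heatmap <- function(results, N, s, ploidy) {
  df <- if (inherits(results, "sweep_result")) results$results else results
  stopifnot(is.data.frame(df))
  slice <- df[df$N == N & df$s == as.character(s) & df$ploidy == ploidy, ]
  if (nrow(slice) == 0L)
    stop("no sweep results for the requested (N, s, ploidy) slice")
  cells <- unique(slice[c("mu", "rho")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- slice[slice$mu == cells$mu[i] & slice$rho == cells$rho[i], ]
    vals <- sub$final_median_af[sub$status == "ok"]
    data.frame(mu = cells$mu[i], rho = cells$rho[i],
               mean_final_median_af = if (all(is.na(vals))) NA_real_
                                      else mean(vals, na.rm = TRUE),
               n_replicates = sum(!is.na(vals)))
  }))
  failed <- sum(slice$status != "ok")
  if (failed > 0)
    warning(sprintf("%d run(s) in this slice failed and were excluded", failed))
  out <- out[order(out$mu, out$rho), ]
  rownames(out) <- NULL
  class(out) <- c("heatmap_table", "data.frame")
  out
}
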