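# Serialisation: config echo headers, trajectory TSV, VCF snapshots.

.fmt_num <- function(x) {
  if (is.character(x)) return(x)
  if (is.integer(x) || (is.numeric(x) && all(x == round(x)) && all(abs(x) < 2^31)))
    return(format(x, scientific = FALSE, trim = TRUE))
  sprintf("%.17g", x)
}

#' Config echo lines for a run
#'
#' Key-value lines (`key=value`) describing the parameter and selection-model
#' tuple of a run; numbers are printed at full precision so the echo parses
#' back to an equal configuration. Writers prefix each line with `#` and
#' place them at the top of every output file.
#'
#' @param params A [sim_params()] or NULL.
#' @param model A [selection_model()] or NULL.
#' @param extra Named list of additional scalar fields (e.g. replicate).
#' @return Character vector of `key=value` lines.
#' @export
config_lines <- function(params = NULL, model = NULL, extra = list()) {
  kv <- list()
  if (!is.null(params)) {
    kv <- c(kv, list(N = params$N, ploidy = params$ploidy, L = params$L,
                     mu = params$mu, rho = params$rho,
                     generations = params$generations,
                     record_every = params$record_every,
                     seed = if (is.null(params$seed)) NA else params$seed))
    if (length(params$snapshot_generations))
      kv$snapshot_generations <- paste(params$snapshot_generations, collapse = ",")
  }
  if (!is.null(model)) {
    kv <- c(kv, list(model_mode = model$mode, model_s = model$s,
                     model_alpha = model$alpha, model_beta = model$beta,
                     model_beta_is_mean = model$beta_is_mean,
                     model_theta_intercept = model$theta_intercept,
                     model_theta_rate = model$theta_rate))
  }
  kv <- c(kv, extra)
  vapply(names(kv), function(k) {
    v <- kv[[k]]
    paste0(k, "=", if (is.logical(v)) as.character(v) else .fmt_num(v))
  }, character(1))
}

#' Parse config echo lines
#'
#' Inverse of [config_lines()]: strips any leading `#`, splits on the first
#' `=`, and converts values back to numeric/logical where possible.
#'
#' @param lines Character vector of `key=value` (optionally `#`-prefixed)
#'   lines.
#' @return Named list of parsed values.
#' @export
parse_config_lines <- function(lines) {
  lines <- sub("^#+\\s*", "", lines)
  lines <- lines[nzchar(lines) & grepl("=", lines, fixed = TRUE)]
  keys <- sub("=.*$", "", lines)
  vals <- sub("^[^=]*=", "", lines)
  out <- lapply(vals, function(v) {
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    if (v == "NA") return(NA)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, keys)
}

.params_from_config <- function(cfg) {
  sim_params(N = cfg$N, ploidy = cfg$ploidy, mu = cfg$mu, rho = cfg$rho,
             generations = cfg$generations, L = cfg$L,
             seed = if (is.na(cfg$seed)) NULL else cfg$seed,
             record_every = cfg$record_every,
             snapshot_generations = if (is.null(cfg$snapshot_generations))
               integer(0) else as.integer(strsplit(as.character(cfg$snapshot_generations), ",")[[1]]))
}

.model_from_config <- function(cfg) {
  if (is.null(cfg$model_mode)) return(NULL)
  if (cfg$model_mode == "constant") {
    selection_model("constant", s = cfg$model_s)
  } else {
    selection_model("empirical", alpha = cfg$model_alpha, beta = cfg$model_beta,
                    beta_is_mean = isTRUE(cfg$model_beta_is_mean),
                    theta_intercept = cfg$model_theta_intercept,
                    theta_rate = cfg$model_theta_rate)
  }
}

.write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("#", header_lines), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, sprintf("%.17g", x)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

.read_tsv_with_header <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  list(config = parse_config_lines(hdr), data = df)
}

#' Write a trajectory as TSV
#'
#' One row per recorded generation with the summary statistics plus the full
#' parameter tuple, preceded by a `#`-prefixed config echo header.
#'
#' @param traj A `sim_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "sim_trajectory"))
  p <- traj$params
  rows <- traj$rows
  rows$replicate <- traj$replicate
  rows$N <- p$N
  rows$ploidy <- p$ploidy
  rows$L <- p$L
  rows$mu <- p$mu
  rows$rho <- p$rho
  rows$s <- if (traj$model$mode == "constant") traj$model$s else NA_real_
  rows$model <- traj$model$mode
  hdr <- config_lines(p, traj$model, extra = list(replicate = traj$replicate,
                                                  run_seed = traj$seed))
  .write_tsv_with_header(rows, path, hdr)
  invisible(path)
}

#' Read a trajectory TSV
#'
#' Inverse of [write_trajectory_tsv()]: rebuilds the trajectory rows,
#' parameters and selection model from the file and its config header.
#'
#' @param path File written by [write_trajectory_tsv()].
#' @return A `sim_trajectory` (without a final population).
#' @export
read_trajectory_tsv <- function(path) {
  parsed <- .read_tsv_with_header(path)
  cfg <- parsed$config
  rows <- parsed$data[, c("generation", "median_allele_freq", "mean_fitness",
                          "parental_mean_fitness", "n_segregating",
                          "n_fixed_cumulative")]
  structure(
    list(rows = rows, params = .params_from_config(cfg),
         model = .model_from_config(cfg),
         replicate = as.integer(cfg$replicate),
         seed = if (is.na(cfg$run_seed)) NA_integer_ else as.integer(cfg$run_seed),
         offspring_fitness = list(), substitutions = NULL, population = NULL),
    class = "sim_trajectory")
}

#' Write a population snapshot as VCF 4.2
#'
#' One record per segregating mutation on contig `chr1`, 1-based positions
#' (internal coordinates are 0-based half-open), INFO fields `S` (selection
#' coefficient), `H` (dominance coefficient) and `OG` (origin generation),
#' and unphased genotypes with `ploidy` alleles per sample (e.g. `0/0/1/1`
#' for a duplex tetraploid). Mutation ids become record IDs; the config echo
#' appears as `##podsim_*` meta lines. REF/ALT are placeholder alleles A/T:
#' the simulation tracks allele identity, not sequence.
#'
#' @param pop A `wf_population`.
#' @param path Output file path.
#' @param model Optional [selection_model()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(pop, path, model = NULL) {
  stopifnot(inherits(pop, "wf_population"))
  p <- pop$params
  full <- p$ploidy * p$N
  cnt <- .allele_counts(pop)
  seg <- which(cnt > 0L & cnt < full)
  muts <- pop$mutations[seg, , drop = FALSE]
  ord <- order(muts$position, muts$id)
  muts <- muts[ord, , drop = FALSE]
  dosage <- vapply(pop$individuals, function(ind) {
    ids <- unlist(ind, use.names = FALSE)
    tabulate(factor(ids, levels = muts$id), nbins = nrow(muts))
  }, integer(nrow(muts)))
  if (nrow(muts) == 1L) dosage <- matrix(dosage, nrow = 1L)
  gt_of <- function(d) {
    vapply(d, function(k) paste(c(rep.int(0L, p$ploidy - k), rep.int(1L, k)),
                                collapse = "/"), character(1))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr1,length=%d>", as.integer(p$L)),
    "##INFO=<ID=S,Number=1,Type=Float,Description=\"Selection coefficient of the homozygote\">",
    "##INFO=<ID=H,Number=1,Type=Float,Description=\"Dominance coefficient\">",
    "##INFO=<ID=OG,Number=1,Type=Integer,Description=\"Origin generation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##podsim_", config_lines(p, model)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("ind%d", seq_len(p$N))), collapse = "\t"))
  body <- character(nrow(muts))
  if (nrow(muts) > 0L) {
    gts <- apply(dosage, 2, gt_of)
    if (nrow(muts) == 1L) gts <- matrix(gts, nrow = 1L)
    for (i in seq_len(nrow(muts))) {
      body[i] <- paste(c(
        "chr1", format(muts$position[i] + 1, scientific = FALSE),
        sprintf("mut%d", muts$id[i]), "A", "T", ".", ".",
        sprintf("S=%g;H=%g;OG=%d", muts$s[i], muts$h[i],
                muts$origin_generation[i]),
        "GT", gts[i, ]), collapse = "\t")
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
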