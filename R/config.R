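#' Load a session configuration from JSON
#'
#' Reads a JSON configuration file and fills unspecified fields with the
#' standard defaults (six octave bands from 250 Hz, TMRs -5 to 15 dB in 5-dB
#' steps, 2 to 5 presented bands, a 300-trial budget, ridge 0.01).  An empty
#' file yields the all-default configuration.  Recognized fields:
#' `center_frequencies_hz`, `tmr_grid_db`, `presented_range`, `n_trials`,
#' `ridge`, `mode`, `link`, `seed`, `strategy`, `listener` (a list with
#' `weights`, `Q`, `N` for a simulated listener).
#'
#' @param path path to a JSON file.
#' @return a [qbif_config()]; any `strategy` / `listener` entries are
#'   attached as attributes.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (!nzchar(trimws(txt))) list() else
    tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
             error = function(e) stop("config file is not valid JSON: ",
                                      conditionMessage(e)))
  known <- c("center_frequencies_hz", "tmr_grid_db", "presented_range",
             "n_trials", "ridge", "mode", "link", "seed", "strategy",
             "listener")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ", "))
  grid <- if (is.null(raw$center_frequencies_hz)) band_grid() else
    band_grid(raw$center_frequencies_hz)
  cfg <- qbif_config(
    grid = grid,
    tmr_grid_db = if (is.null(raw$tmr_grid_db)) seq(-5, 15, 5) else raw$tmr_grid_db,
    presented_range = if (is.null(raw$presented_range)) c(2, 5) else raw$presented_range,
    n_trials = if (is.null(raw$n_trials)) 300L else raw$n_trials,
    ridge = if (is.null(raw$ridge)) 0.01 else raw$ridge,
    mode = if (is.null(raw$mode)) "refit" else raw$mode,
    link = if (is.null(raw$link)) "logistic" else raw$link,
    seed = if (is.null(raw$seed)) 1L else raw$seed)
  if (!is.null(raw$strategy)) attr(cfg, "strategy") <- raw$strategy
  if (!is.null(raw$listener)) attr(cfg, "listener") <- raw$listener
  cfg
}

#' Save a configuration to JSON
#'
#' Inverse of [load_config()]; a saved-then-loaded configuration is
#' identical.
#'
#' @param config a [qbif_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- list(center_frequencies_hz = config$grid$centers,
              tmr_grid_db = config$tmr_grid_db,
              presented_range = config$presented_range,
              n_trials = config$n_trials, ridge = config$ridge,
              mode = config$mode, link = config$link, seed = config$seed)
  if (!is.null(attr(config, "strategy"))) out$strategy <- attr(config, "strategy")
  if (!is.null(attr(config, "listener"))) out$listener <- attr(config, "listener")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write session results to a directory
#'
#' Serializes a [run_qbif()] session: a JSON-lines trial log (one record per
#' trial with index, phase, TMR, 0/1 mask string, response, interim
#' coefficients and interim `ln|cov|`), a final-estimate JSON (weights, SRT,
#' slope, covariance, seed, config echo, package version), and a metrics CSV
#' of the per-trial summaries.  A manifest lists the files with MD5 content
#' hashes.
#'
#' @param session a `qbif_session`.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly: a data frame of file names and hashes.
#' @export
write_results <- function(session, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0)
    stop("output directory is not writable: ", out_dir)

  log_path <- file.path(out_dir, "trials.jsonl")
  n <- length(session$records)
  lines <- vapply(seq_len(n), function(k) {
    jsonlite::toJSON(list(
      trial = k,
      phase = session$trials$phase[k],
      tmr_db = session$trials$tmr_db[k],
      mask = session$trials$mask[k],
      in_quiet = session$records[[k]]$stimulus$in_quiet,
      correct = session$trials$correct[k],
      interim_coef = as.numeric(session$interim_coef[k, ]),
      lndet = session$trials$lndet[k]), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, log_path)

  est_path <- file.path(out_dir, "estimates.json")
  cfg <- session$config
  jsonlite::write_json(list(
    weights = session$final$weights,
    srt_db = session$final$srt_db,
    beta = session$final$beta,
    coef_mean = session$final$posterior$coef_mean,
    coef_cov = session$final$posterior$coef_cov,
    n_training = session$n_training,
    n_adaptive = session$n_adaptive,
    seed = cfg$seed,
    config = list(center_frequencies_hz = cfg$grid$centers,
                  tmr_grid_db = cfg$tmr_grid_db,
                  presented_range = cfg$presented_range,
                  n_trials = cfg$n_trials, ridge = cfg$ridge,
                  mode = cfg$mode, link = cfg$link),
    package_version = as.character(utils::packageVersion("qbif"))),
    est_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  met_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(session$trials, met_path, row.names = FALSE)

  files <- c(log_path, est_path, met_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a JSON-lines trial log back into trial records
#'
#' @param path path to a `trials.jsonl` written by [write_results()].
#' @return list of trial records suitable for [fit_posterior()].
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    mask <- as.integer(strsplit(rec$mask, "")[[1]]) == 1L
    list(stimulus = stimulus_spec(rec$tmr_db, mask,
                                  in_quiet = isTRUE(rec$in_quiet)),
         correct = isTRUE(rec$correct))
  })
}
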