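CONFIG_SCHEMA_VERSION <- 1L

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [srnn_params()] and
#' [srnn_control()] (nested under `params:` and `control:`), plus optional
#' top-level `seed` and `schema_version`. Missing keys take the package
#' defaults; unknown keys are rejected. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path.
#' @return list of class `srnn_config` with `params`, `control`, `seed`,
#'   `schema_version`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("params", "control", "seed", "schema_version")
  bad <- setdiff(names(raw), known_top)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  sv <- raw$schema_version %||% CONFIG_SCHEMA_VERSION
  if (sv != CONFIG_SCHEMA_VERSION)
    stop("unsupported config schema version: ", sv)
  pargs <- raw$params %||% list()
  cargs <- raw$control %||% list()
  badp <- setdiff(names(pargs), names(formals(srnn_params)))
  if (length(badp)) stop("unknown params keys: ", paste(badp, collapse = ", "))
  badc <- setdiff(names(cargs), names(formals(srnn_control)))
  if (length(badc)) stop("unknown control keys: ", paste(badc, collapse = ", "))
  if (!is.null(pargs$cue_amp)) pargs$cue_amp <- as.numeric(pargs$cue_amp)
  structure(list(params = do.call(srnn_params, pargs),
                 control = do.call(srnn_control, cargs),
                 seed = as.integer(raw$seed %||% 1L),
                 schema_version = CONFIG_SCHEMA_VERSION),
            class = "srnn_config")
}

#' Save a run configuration to YAML
#'
#' Writes every parameter and control field explicitly, so
#' `load_config(save_config(cfg, f))` round-trips losslessly.
#'
#' @param config an `srnn_config` (or list with `params`/`control`).
#' @param path output file path.
#' @export
save_config <- function(config, path) {
  p <- config$params
  keep_p <- names(formals(srnn_params))
  keep_c <- names(formals(srnn_control))
  ctl <- config$control
  out <- list(schema_version = CONFIG_SCHEMA_VERSION,
              seed = config$seed %||% 1L,
              params = p[keep_p],
              control = ctl[keep_c])
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Save / load a network checkpoint
#'
#' Checkpoints hold the complete weight set (magnitudes, mask, input and
#' output matrices, SFA assignment, baseline currents), the parameters, the
#' RNG state and optional training metadata, and round-trip bit-exactly.
#'
#' @param weights an `srnn_weights` object or full [srnn()] fit.
#' @param path file path.
#' @param extra optional named list of metadata stored alongside.
#' @export
save_checkpoint <- function(weights, path, extra = list()) {
  obj <- list(format = "ruleSRNN-checkpoint", version = 1L,
              weights = resolve_weights(weights),
              fit = if (inherits(weights, "srnn")) weights else NULL,
              rng_state = if (exists(".Random.seed", globalenv()))
                get(".Random.seed", globalenv()) else NULL,
              extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_params if supplied, loading fails unless the checkpoint
#'   matches this network size and output count.
#' @export
load_checkpoint <- function(path, expected_params = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ruleSRNN-checkpoint"))
    stop("not a ruleSRNN checkpoint: ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported checkpoint version: ", obj$version)
  if (!is.null(expected_params)) {
    wp <- obj$weights$params
    if (wp$n_rec != expected_params$n_rec ||
        wp$n_outputs != expected_params$n_outputs)
      stop(sprintf(
        "checkpoint network (%d units, %d outputs) does not match config (%d, %d)",
        wp$n_rec, wp$n_outputs, expected_params$n_rec,
        expected_params$n_outputs))
  }
  obj
}

#' Export simulated trials as plain-text artifacts
#'
#' Writes a spike-event list (`spikes.csv`: trial_id, unit_id, time_ms,
#' unit_class), decoder voltages (`decoder.csv`), trial metadata
#' (`trials.json`) and a manifest with a configuration fingerprint
#' (`manifest.json`).
#'
#' @param records an `srnn_records` list.
#' @param out_dir output directory (created if missing).
#' @param params the [srnn_params()] used for simulation.
#' @param seed the seed the records were generated under (recorded in the
#'   manifest).
#' @return invisible vector of file paths.
#' @export
export_run <- function(records, out_dir, params, seed = NA_integer_) {
  if (!length(records)) stop("no records to export")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev <- lapply(seq_along(records), function(i) {
    idx <- which(records[[i]]$raster == 1, arr.ind = TRUE)
    if (!nrow(idx))
      return(data.frame(trial_id = integer(0), unit_id = integer(0),
                        time_ms = numeric(0), unit_class = character(0)))
    data.frame(trial_id = i, unit_id = idx[, 1],
               time_ms = idx[, 2] * params$dt,
               unit_class = ifelse(idx[, 1] <= params$n_exc, "E", "I"))
  })
  spikes <- do.call(rbind, ev)
  spikes <- spikes[order(spikes$trial_id, spikes$time_ms, spikes$unit_id), ]
  f_spk <- file.path(out_dir, "spikes.csv")
  write.csv(spikes, f_spk, row.names = FALSE)

  dec <- do.call(rbind, lapply(seq_along(records), function(i) {
    v <- records[[i]]$decoder_v
    data.frame(trial_id = i, step = seq_len(ncol(v)),
               time_ms = seq_len(ncol(v)) * params$dt,
               t(v))
  }))
  names(dec)[-(1:3)] <- paste0("output_", seq_len(params$n_outputs))
  f_dec <- file.path(out_dir, "decoder.csv")
  write.csv(dec, f_dec, row.names = FALSE)

  meta <- lapply(seq_along(records), function(i) {
    sp <- records[[i]]$spec
    c(list(trial_id = i, decision = records[[i]]$decision,
           n_spikes = sum(records[[i]]$raster)),
      if (!is.null(sp)) list(rule = sp$rule, visual_side = sp$visual_side,
                             auditory_side = sp$auditory_side,
                             mixture_q = sp$mixture_q,
                             delay_ms = sp$delay_ms,
                             correct_choice = sp$correct_choice,
                             seed = sp$seed))
  })
  f_meta <- file.path(out_dir, "trials.json")
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  cfg_str <- yaml::as.yaml(params[order(names(params))])
  manifest <- list(n_trials = length(records),
                   config_hash = fnv1a(cfg_str), seed = seed,
                   n_rec = params$n_rec, n_exc = params$n_exc,
                   dt_ms = params$dt,
                   files = c("spikes.csv", "decoder.csv", "trials.json"))
  f_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(f_spk, f_dec, f_meta, f_man))
}
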