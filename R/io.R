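# On-disk formats: recording container (JSON metadata + TSV tables),
# sequence-dataset persistence, candidate tables, and the strict YAML run
# configuration.

CONTAINER_SCHEMA <- 1L

# write a table with doubles in 17-significant-digit decimal form, enough for
# an exact binary round trip through fread
fwrite_full <- function(df, path) {
  df <- data.table::as.data.table(df)
  for (j in names(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
}

#' Write a gait recording to a plain-text container
#'
#' The container is a directory holding `meta.json` (subject, sampling rate,
#' MVIC references, schema version), `signals.tsv` (one row per sample;
#' columns BF, TA, VL, SOL, HA, KA plus, when present, the ground-truth
#' `label` and per-muscle envelope columns) and `events.tsv`. Numeric values
#' are written in shortest-round-trip decimal form, so a write/read cycle is
#' bit-identical.
#'
#' @param rec a `gait_recording` (raw, 1500 Hz) or `processed_recording`
#'   (500 Hz).
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  processed <- inherits(rec, "processed_recording")
  meta <- list(schema = CONTAINER_SCHEMA,
               type = if (processed) "processed" else "raw",
               subject_id = rec$subject_id, fs = rec$fs,
               mvic = if (processed) NULL else as.list(rec$mvic),
               provenance = if (processed) as.list(rec$provenance) else list())
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  sig <- data.table::as.data.table(t(rec$emg))
  data.table::setnames(sig, CHANNELS)
  sig$HA <- rec$hip_deg
  sig$KA <- rec$knee_deg
  if (!is.null(rec$labels)) sig$label <- rec$labels
  if (!is.null(rec$envelopes)) {
    for (m in CHANNELS) sig[[paste0("env_", m)]] <- rec$envelopes[m, ]
  }
  fwrite_full(sig, file.path(path, "signals.tsv"))
  ev <- if (is.null(rec$events)) tibble::tibble(sample = integer(0), type = character(0)) else rec$events
  data.table::fwrite(ev, file.path(path, "events.tsv"), sep = "\t")
  invisible(path)
}

#' Read a gait recording container
#'
#' @param path directory written by [write_recording()].
#' @return A `gait_recording` or `processed_recording`, matching what was
#'   written.
#' @export
read_recording <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    abort(sprintf("not a recording container (missing %s)", meta_file),
          class = "gaitphase_format_error")
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (is.null(meta$schema) || meta$schema != CONTAINER_SCHEMA) {
    abort(sprintf("unsupported container schema version: %s", meta$schema),
          class = "gaitphase_format_error")
  }
  if (!meta$fs %in% c(1500, 500)) {
    abort(sprintf("invalid sampling rate in meta.json: %s", meta$fs),
          class = "gaitphase_format_error")
  }
  sig <- data.table::fread(file.path(path, "signals.tsv"), sep = "\t")
  for (key in c(CHANNELS, "HA", "KA")) {
    if (!key %in% names(sig)) {
      abort(sprintf("malformed container: missing channel '%s'", key),
            class = "gaitphase_format_error")
    }
  }
  ev <- data.table::fread(file.path(path, "events.tsv"), sep = "\t")
  events <- if (nrow(ev)) tibble::tibble(sample = as.integer(ev$sample),
                                         type = as.character(ev$type)) else NULL
  emg <- t(as.matrix(sig[, CHANNELS, with = FALSE]))
  rownames(emg) <- CHANNELS
  common <- list(subject_id = meta$subject_id, fs = meta$fs, emg = emg,
                 hip_deg = sig$HA, knee_deg = sig$KA, events = events,
                 labels = if ("label" %in% names(sig)) as.integer(sig$label) else NULL)
  if (identical(meta$type, "processed")) {
    out <- c(list(emg = emg, hip_deg = sig$HA, knee_deg = sig$KA,
                  fs = meta$fs, subject_id = meta$subject_id,
                  provenance = unlist(meta$provenance)),
             common["labels"], list(events = events))
    return(structure(out, class = "processed_recording"))
  }
  env_cols <- paste0("env_", CHANNELS)
  if (all(env_cols %in% names(sig))) {
    env <- t(as.matrix(sig[, env_cols, with = FALSE]))
    rownames(env) <- CHANNELS
    common$envelopes <- env
  }
  common$mvic <- unlist(meta$mvic)[CHANNELS]
  structure(common, class = "gait_recording")
}

#' Persist a sequence dataset
#'
#' Writes `manifest.tsv` (subject, window start, labeling mode per window)
#' and long-format `x.tsv` / `y.tsv` arrays.
#'
#' @param ds a `sequence_dataset`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "sequence_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(dataset_manifest(ds), file.path(path, "manifest.tsv"), sep = "\t")
  dims <- dim(ds$x)
  jsonlite::write_json(list(schema = CONTAINER_SCHEMA, dim_x = dims, dim_y = dim(ds$y)),
                       file.path(path, "meta.json"), auto_unbox = FALSE, digits = NA)
  fwrite_full(data.table::data.table(value = as.vector(ds$x)),
              file.path(path, "x.tsv"))
  fwrite_full(data.table::data.table(value = as.vector(ds$y)),
              file.path(path, "y.tsv"))
  invisible(path)
}

#' Load a sequence dataset written by [write_dataset()]
#'
#' @param path dataset directory.
#' @return A `sequence_dataset`.
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  man <- data.table::fread(file.path(path, "manifest.tsv"), sep = "\t")
  x <- array(as.numeric(data.table::fread(file.path(path, "x.tsv"))$value),
             dim = meta$dim_x)
  y <- array(as.numeric(data.table::fread(file.path(path, "y.tsv"))$value),
             dim = meta$dim_y)
  structure(list(x = x, y = y, subject_ids = man$subject_id,
                 window_start = man$window_start,
                 labeling_mode = man$labeling_mode[1]),
            class = "sequence_dataset")
}

# ---- run configuration -----------------------------------------------------

default_run_config <- function() {
  list(
    seed = 1L,
    simulation = list(n_subjects = 2L, n_strides = 12L, cadence = 35,
                      stance_fraction = 0.60, lead_ms = 120, noise_sd = 1,
                      baseline_sd = 0.02),
    preprocessing = list(sg_order = 1L, sg_window = 39L),
    labeling = list(shift_frames = 0L, win = 500L, step = 50L,
                    quiet_window_s = 1, quiet_thresh = 0.5),
    model = list(name = "pruned", M = 15L, P = 53L),
    training = list(max_epochs = 5L, initial_lr = 4e-4, lr_drop = 0.9,
                    lr_period = 2L, batch_size = 128L, patience = 10L),
    hpo = list(n_trials = 5L),
    selection = list(L = 1, alpha = 0.05, ad_floor = -1,
                     alphas = c(0.001, 0.005, 0.01, 0.05)),
    streaming = list(window_raw = 1500L, hop_raw = 150L)
  )
}

check_known_keys <- function(user, defaults, prefix = "") {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown configuration key: '%s'", full),
            class = "gaitphase_config_error")
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      check_known_keys(user[[key]], defaults[[key]], paste0(full, "."))
    }
  }
  invisible(user)
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected loudly (naming the offending key); known keys
#' override the package defaults (smoothing
#' window 39, label shift 60 frames when enabled, 500-frame windows at step
#' 50, initial learning rate 4e-4, and so on).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- default_run_config()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  check_known_keys(user, defaults)
  modifyList(defaults, user)
}
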