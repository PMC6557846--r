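# Plain-text containers: epoch CSV matrices + one JSON sidecar per dataset,
# models and threshold scans as JSON, waiting times as commented CSV.

#' Write / read a trial dataset as CSV matrices with a JSON sidecar
#'
#' One delimited-text matrix per (subject, channel) -- rows are time
#' samples, columns are trials -- plus `dataset.json` holding the sampling
#' rate, units, epoch window relative to the event, `t0_index`, channel
#' list, and (when the dataset came from the synthetic generator) the
#' ground-truth coefficients and seed.
#'
#' @param dataset A `trial_dataset`.
#' @param dir Output directory (created if missing).
#' @return `write_dataset()`: `dir`, invisibly. `read_dataset()`: the
#'   reconstructed `trial_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- as_tibble(dataset) |>
    group_by(.data$subject_id, .data$channel_id) |>
    group_split()
  files <- purrr::map_chr(groups, function(g) {
    m <- do.call(cbind, g$samples)
    colnames(m) <- paste0("trial_", g$trial_index)
    fname <- paste0(g$subject_id[1], "_", g$channel_id[1], ".csv")
    utils::write.csv(m, file.path(dir, fname), row.names = FALSE)
    fname
  })
  cfg <- attr(dataset, "config")
  sidecar <- list(
    fs = attr(dataset, "fs"),
    units = attr(dataset, "units"),
    window = attr(dataset, "window"),
    t0_index = attr(dataset, "t0_index"),
    subjects = unique(dataset$subject_id),
    channels = unique(dataset$channel_id),
    files = files
  )
  if (!is.null(cfg)) {
    sidecar$ground_truth <- list(
      drift_coeffs = cfg$drift_coeffs,
      noise_coeffs = cfg$noise_coeffs,
      amplitude_scale = cfg$amplitude_scale,
      seed = cfg$seed
    )
  }
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  sidecar_path <- file.path(dir, "dataset.json")
  if (!file.exists(sidecar_path)) abort("no dataset.json sidecar found.")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  rows <- purrr::map(meta$files, function(fname) {
    parts <- strsplit(sub("\\.csv$", "", fname), "_")[[1]]
    m <- as.matrix(utils::read.csv(file.path(dir, fname), check.names = FALSE))
    tibble(
      subject_id = parts[1],
      channel_id = parts[2],
      trial_index = as.integer(sub("^trial_", "", colnames(m))),
      samples = lapply(seq_len(ncol(m)), function(j) unname(m[, j])),
      fs = meta$fs,
      t0_index = as.integer(meta$t0_index)
    )
  })
  df <- arrange(list_rbind(rows), .data$subject_id, .data$channel_id,
                .data$trial_index)
  new_trial_dataset(df, fs = meta$fs, t0_index = as.integer(meta$t0_index),
                    window = meta$window, units = meta$units)
}

#' Write / read a Langevin model as JSON
#'
#' Stores degrees, coefficient lists (highest-degree-first), state range and
#' provenance (including any display scale factor).
#'
#' @param model A [langevin_model()].
#' @param path Output file.
#' @return `write_model()`: `path`, invisibly; `read_model()`: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "langevin_model"))
  jsonlite::write_json(
    list(
      drift_coeffs = model$drift_coeffs,
      noise_coeffs = model$noise_coeffs,
      degree_g = model$degree_g,
      degree_h = model$degree_h,
      state_units = model$state_units,
      state_range = model$state_range,
      provenance = model$provenance
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  langevin_model(j$drift_coeffs, j$noise_coeffs,
                 state_units = j$state_units %||% "model units",
                 state_range = j$state_range,
                 provenance = as.list(j$provenance))
}

#' Write / read waiting times as commented CSV
#'
#' One positive waiting time (seconds) per line; `#`-prefixed header lines
#' carry the censored-run count.
#'
#' @param sample A `wt_sample` or numeric vector.
#' @param path File path.
#' @return `write_wt_sample()`: `path`, invisibly; `read_wt_sample()`: a
#'   `wt_sample`.
#' @export
write_wt_sample <- function(sample, path) {
  w <- waiting_times(sample)
  n_cens <- if (inherits(sample, "wt_sample")) attr(sample, "n_censored") else 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# first-passage waiting times (seconds), one per line",
    paste0("# n_censored: ", n_cens)
  ), con)
  writeLines(format(w, digits = 17, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_wt_sample
#' @export
read_wt_sample <- function(path) {
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  n_cens <- 0L
  cens_line <- grep("n_censored:", comments, value = TRUE)
  if (length(cens_line)) {
    n_cens <- as.integer(sub(".*n_censored:\\s*", "", cens_line[1]))
  }
  w <- as.numeric(lines[!startsWith(lines, "#") & nzchar(lines)])
  new_wt_sample(w, n_cens, provenance = list(source = path))
}
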