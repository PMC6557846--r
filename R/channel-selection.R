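#' Event-related field (trial average) per channel
#'
#' Pointwise mean across trials of each (subject, channel)'s epochs, aligned
#' on the shared event sample.
#'
#' @param dataset A `trial_dataset` (epochs must share length and `t0_index`).
#' @return A tibble with one row per (subject, channel) and an `erf`
#'   list-column (Tesla); attributes `fs` and `t0_index` are carried over.
#' @export
compute_erf <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (nrow(dataset) == 0L) abort("empty dataset.")
  lens <- lengths(dataset$samples)
  if (length(unique(lens)) != 1L) {
    abort("misaligned epochs: lengths differ across trials.")
  }
  out <- as_tibble(dataset) |>
    group_by(.data$subject_id, .data$channel_id) |>
    summarise(
      erf = list(Reduce(`+`, .data$samples) / length(.data$samples)),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  structure(out, fs = attr(dataset, "fs"), t0_index = attr(dataset, "t0_index"))
}

#' Readiness weight of an event-related field
#'
#' Scores how much an ERF resembles a readiness potential: locate the ERF
#' maximum within a `2 * search_halfwidth` window centred on the event, then
#' average the ERF over a `2 * avg_halfwidth` window centred on that maximum
#' (truncated at the epoch edges). Ties at the maximum resolve to the first
#' occurrence. At 250 Hz with the defaults this is a 101-sample search
#' window and a 51-sample averaging window.
#'
#' @param erf Numeric vector, the trial-averaged field (Tesla).
#' @param fs Sampling rate, Hz.
#' @param t0_index 1-based sample index of the event.
#' @param search_halfwidth Half-width of the peak search window, seconds.
#' @param avg_halfwidth Half-width of the averaging window, seconds.
#' @param absolute Rank by `|ERF|` instead of the signed field (for channels
#'   whose field polarity is orientation-ambiguous). Default `FALSE`: a
#'   readiness-type field is a signed maximum near the event.
#' @return A one-row tibble with `W` (Tesla) and `peak_index`.
#' @export
readiness_weight <- function(erf, fs, t0_index,
                             search_halfwidth = 0.2, avg_halfwidth = 0.1,
                             absolute = FALSE) {
  n <- length(erf)
  hw <- round(search_halfwidth * fs)
  lo <- t0_index - hw
  hi <- t0_index + hw
  if (lo < 1L || hi > n) {
    abort("peak search window exceeds the epoch.")
  }
  seg <- erf[lo:hi]
  if (absolute) seg <- abs(seg)
  peak <- lo + which.max(seg) - 1L # first occurrence wins ties
  aw <- round(avg_halfwidth * fs)
  a_lo <- max(1L, peak - aw)
  a_hi <- min(n, peak + aw)
  tibble(W = mean(erf[a_lo:a_hi]), peak_index = as.integer(peak))
}

#' Select channels most resembling a readiness potential
#'
#' Computes per-channel readiness weights from the trial-averaged field and
#' keeps the `k` largest per subject, sorted by decreasing `W` with ties
#' broken by channel order (stable).
#'
#' @param dataset A `trial_dataset`.
#' @param k Channels to keep per subject.
#' @inheritParams readiness_weight
#' @return A tibble with columns `subject_id`, `channel_id`, `W`,
#'   `peak_index`, `rank`, ordered by subject then rank.
#' @export
select_channels <- function(dataset, k = 5L,
                            search_halfwidth = 0.2, avg_halfwidth = 0.1,
                            absolute = FALSE) {
  if (k < 1) abort("`k` must be at least 1.")
  erfs <- compute_erf(dataset)
  fs <- attr(erfs, "fs")
  t0 <- attr(erfs, "t0_index")
  weights <- erfs |>
    mutate(w = map(.data$erf, readiness_weight, fs = fs, t0_index = t0,
                   search_halfwidth = search_halfwidth,
                   avg_halfwidth = avg_halfwidth, absolute = absolute)) |>
    select(!"erf") |>
    unnest("w")
  n_per <- weights |> count(.data$subject_id)
  if (any(n_per$n < k)) {
    abort(sprintf("`k` = %d exceeds the number of channels (%d).",
                  k, min(n_per$n)))
  }
  weights |>
    group_by(.data$subject_id) |>
    arrange(desc(.data$W), .data$channel_id, .by_group = TRUE) |>
    slice_head(n = k) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("subject_id", "channel_id", "W", "peak_index", "rank")
}
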