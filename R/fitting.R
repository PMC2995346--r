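#' Rescale direction-discrimination data and model output
#'
#' For the RMS fit, percent-correct data and model NE are mapped to a
#' common `[-0.5, 0.5]` range: data as `P/100 - 0.5`, so that 50%
#' performance (no consistent apparent motion direction) becomes zero,
#' and model output as `ne/2`, so that `ne = 0` corresponds exactly to
#' chance. The model mapping is affine, not min-max, which is the only
#' mapping that ties `ne = 0` to 50%.
#'
#' @param percent Percent responses in the two-stroke direction, in
#'   `[0, 100]`.
#' @return Numeric vector in `[-0.5, 0.5]`.
#' @export
rescale_dd <- function(percent) {
  if (any(percent < 0 | percent > 100)) {
    stop("dd percentages must lie in [0, 100]")
  }
  percent / 100 - 0.5
}

#' @rdname rescale_dd
#' @param ne Model normalised net energy in `[-1, 1]`.
#' @export
rescale_model_dd <- function(ne) {
  ne / 2
}

#' Rescale motion-after-effect data and model output
#'
#' MAE durations are normalised to `[0, 1]` by the observer's own maximum
#' duration; model NE for the adaptor is floored at 0 (durations cannot
#' be negative) and normalised by its own maximum for the given k.
#'
#' @param durations Non-negative MAE durations (seconds), at least one
#'   positive.
#' @return Numeric vector in `[0, 1]`.
#' @export
rescale_mae <- function(durations) {
  if (any(durations < 0)) stop("MAE durations must be non-negative")
  m <- max(durations)
  if (m <= 0) stop("all MAE durations are zero: uninformative observer")
  durations / m
}

#' @rdname rescale_mae
#' @param ne Model normalised net energy for the adapting stimulus.
#' @export
rescale_model_mae <- function(ne) {
  pos <- pmax(ne, 0)
  m <- max(pos)
  if (m <= 0) {
    warning("model MAE curve has no positive net energy; returning zeros")
    return(pos)
  }
  pos / m
}

#' Root-mean-squared error between rescaled curves
#'
#' @param model_rescaled,data_rescaled Equal-length numeric vectors
#'   (one value per ISI).
#' @return `sqrt(mean((model - data)^2))`.
#' @export
rms_error <- function(model_rescaled, data_rescaled) {
  if (length(model_rescaled) != length(data_rescaled)) {
    stop("model and data curves must have equal length")
  }
  sqrt(mean((model_rescaled - data_rescaled)^2))
}

#' Default k grid for fitting
#'
#' Temporal scale factors 20 to 200 in steps of 5 (1/seconds).
#'
#' @param from,to,by Grid limits and step.
#' @return Numeric vector.
#' @export
k_grid_default <- function(from = 20, to = 200, by = 5) {
  seq(from, to, by = by)
}

#' Fit the temporal scale factor k to one observer's data
#'
#' Sweeps `k_grid`, computes the model curve for the observer's task at
#' each k, rescales model and data to a common range ([rescale_dd()] /
#' [rescale_mae()]), and selects the k with minimal RMS error. Ties are
#' broken toward the smaller k, so the fit is deterministic.
#'
#' @param data A data frame with columns `task` ("dd" or "mae"), `isi_ms`
#'   and `value` (percent for dd, seconds for mae) for a single
#'   observer/condition/task; typically one group of
#'   [simulate_dd_observer()] / [read_psycho_csv()] output.
#' @param k_grid Candidate k values (default [k_grid_default()]).
#' @param cfg A [model_config()].
#' @param curves Optional precomputed NE matrix from [model_curve_grid()]
#'   for `k_grid` at the data's ISIs (rows in `k_grid` order); computed
#'   if missing.
#' @return An object of class `fit_result`: list with `k_best`, `rms`,
#'   `task`, `k_grid`, `rms_by_k`, `curve_model` and `curve_data`
#'   (both rescaled, in ISI order), and `isi_ms`.
#' @export
fit_k <- function(data, k_grid = k_grid_default(), cfg = model_config(),
                  curves = NULL) {
  if (nrow(data) == 0) stop("empty data")
  if (length(k_grid) == 0) stop("empty k grid")
  task <- unique(data$task)
  if (length(task) != 1 || !task %in% c("dd", "mae")) {
    stop("data must contain a single task, 'dd' or 'mae'")
  }
  data <- data[order(data$isi_ms), , drop = FALSE]
  isi <- data$isi_ms / 1000
  k_grid <- sort(k_grid)
  if (is.null(curves)) {
    curves <- model_curve_grid(task, k_grid, isi = isi, cfg = cfg)
  }
  stopifnot(nrow(curves) == length(k_grid), ncol(curves) == length(isi))

  data_rescaled <- if (task == "dd") rescale_dd(data$value)
                   else rescale_mae(data$value)
  model_rescaled <- function(ne) {
    if (task == "dd") rescale_model_dd(ne) else rescale_model_mae(ne)
  }
  rms_by_k <- apply(curves, 1, function(ne) {
    rms_error(model_rescaled(ne), data_rescaled)
  })
  best <- which.min(rms_by_k)  # first minimum = smallest k on a sorted grid
  structure(
    list(k_best = k_grid[best], rms = rms_by_k[[best]], task = task,
         k_grid = k_grid, rms_by_k = unname(rms_by_k),
         curve_model = unname(model_rescaled(curves[best, ])),
         curve_data = unname(data_rescaled), isi_ms = data$isi_ms),
    class = "fit_result"
  )
}

#' Fit k for every observer/condition/task in a dataset
#'
#' Splits a psychophysical dataset by observer, condition and task, fits
#' each subset with [fit_k()], and reports the fitted k, its RMS error
#' and the centre frequencies of the fitted slow and fast temporal
#' filters. With `pool = "mean"`, values are first averaged across
#' observers per condition/task/ISI and a single group fit is reported
#' per condition/task (observer label `"Group"`).
#'
#' @param data A psychophysical dataset (see [read_psycho_csv()] for the
#'   schema).
#' @param k_grid Candidate k values.
#' @param cfg A [model_config()].
#' @param pool `"none"` (per-observer fits) or `"mean"` (fit the
#'   observer-averaged data).
#' @return A tibble with columns `observer`, `condition`, `task`,
#'   `k_best`, `rms`, `centre_freq_slow_hz`, `centre_freq_fast_hz`.
#' @export
fit_dataset <- function(data, k_grid = k_grid_default(),
                        cfg = model_config(), pool = c("none", "mean")) {
  pool <- match.arg(pool)
  if (pool == "mean") {
    data <- data |>
      dplyr::group_by(.data$condition, .data$task, .data$isi_ms) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(observer = "Group")
  }
  # warm the curve cache once per task so each per-observer fit is a lookup
  isi <- sort(unique(data$isi_ms)) / 1000
  for (task in unique(data$task)) {
    model_curve_grid(task, sort(k_grid), isi = isi, cfg = cfg)
  }
  groups <- split(
    data, interaction(data$observer, data$condition, data$task, drop = TRUE)
  )
  rows <- lapply(groups, function(d) {
    fit <- fit_k(d, k_grid = k_grid, cfg = cfg)
    tibble::tibble(
      observer = d$observer[1], condition = d$condition[1],
      task = d$task[1], k_best = fit$k_best, rms = fit$rms,
      centre_freq_slow_hz = centre_frequency(
        temporal_filter_spec(fit$k_best, cfg$n_slow, cfg$beta,
                             cfg$temporal_extent, cfg$grid$dt)),
      centre_freq_fast_hz = centre_frequency(
        temporal_filter_spec(fit$k_best, cfg$n_fast, cfg$beta,
                             cfg$temporal_extent, cfg$grid$dt))
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$condition, out$task, out$observer), ]
}
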