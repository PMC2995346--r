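#' Synthetic observer model
#'
#' A generative stand-in for a psychophysical observer, used for
#' parameter-recovery testing of the fitting pipeline. Direction
#' discrimination is modelled as Bernoulli trials whose success
#' probability follows the model curve at `k_true` with a small lapse
#' rate; MAE durations as a linear gain on the (floored) adaptor NE plus
#' truncated Gaussian noise.
#'
#' @param k_true True temporal scale factor, 1/seconds.
#' @param lapse Lapse probability in `[0, 0.5)` (default 0.02): on a
#'   lapse trial the response is random regardless of the stimulus.
#' @param mae_gain MAE duration per unit NE, seconds (default 15).
#' @param mae_noise_sd Duration noise SD, seconds (default 3).
#' @param seed Optional integer seed; when given, simulation functions
#'   seed the generator before drawing.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(k_true, lapse = 0.02, mae_gain = 15,
                           mae_noise_sd = 3, seed = NULL) {
  stopifnot(k_true > 0, lapse >= 0, lapse < 0.5, mae_gain > 0,
            mae_noise_sd >= 0)
  structure(
    list(k_true = k_true, lapse = lapse, mae_gain = mae_gain,
         mae_noise_sd = mae_noise_sd, seed = seed),
    class = "observer_model"
  )
}

.maybe_seed <- function(obs) {
  if (!is.null(obs$seed)) set.seed(obs$seed)
}

#' Simulate a direction-discrimination observer
#'
#' Per ISI, the probability of reporting the two-stroke direction is
#' `p = (1 - 2*lapse) * (0.5 + ne/2) + lapse` where `ne` is the model's
#' normalised net energy at `k_true`; the reported value is the percent
#' of `n_trials` Bernoulli successes (40 trials per motion direction in
#' the emulated design, collapsed to 80).
#'
#' @param obs An [observer_model()].
#' @param isi Vector of ISI durations in seconds (default [isi_set()]).
#' @param n_trials Trials per ISI (default 80).
#' @param observer,condition Labels for the output rows.
#' @param cfg A [model_config()].
#' @return A tibble with columns `observer`, `condition`, `task` ("dd"),
#'   `isi_ms`, `value` (percent in `[0, 100]`, a multiple of
#'   `100/n_trials`).
#' @export
simulate_dd_observer <- function(obs, isi = isi_set(), n_trials = 80,
                                 observer = "S1", condition = "photopic",
                                 cfg = model_config()) {
  stopifnot(inherits(obs, "observer_model"), n_trials >= 1)
  ne <- model_curve("dd", obs$k_true, isi = isi, cfg = cfg)$ne
  p <- (1 - 2 * obs$lapse) * (0.5 + ne / 2) + obs$lapse
  if (any(p < -1e-9 | p > 1 + 1e-9)) {
    stop("response probability outside [0, 1]: ne out of range")
  }
  p <- pmin(pmax(p, 0), 1)
  .maybe_seed(obs)
  hits <- stats::rbinom(length(p), size = n_trials, prob = p)
  tibble::tibble(observer = observer, condition = condition, task = "dd",
                 isi_ms = round(isi * 1000), value = 100 * hits / n_trials)
}

#' Simulate a motion-after-effect observer
#'
#' Per repeat, `duration = max(0, mae_gain * max(0, ne) + noise)` with
#' Gaussian noise; zero durations stand for "no after-effect" reports.
#' The reported value per ISI is the mean of `n_repeats` measurements.
#'
#' @param obs An [observer_model()].
#' @param isi Vector of ISI durations in seconds.
#' @param n_repeats Measurements per ISI (default 4).
#' @param observer,condition Labels for the output rows.
#' @param cfg A [model_config()].
#' @return A tibble with columns `observer`, `condition`, `task`
#'   ("mae"), `isi_ms`, `value` (mean duration in seconds, >= 0).
#' @export
simulate_mae_observer <- function(obs, isi = isi_set(), n_repeats = 4,
                                  observer = "S1", condition = "photopic",
                                  cfg = model_config()) {
  stopifnot(inherits(obs, "observer_model"), n_repeats >= 1)
  ne <- model_curve("mae", obs$k_true, isi = isi, cfg = cfg)$ne
  signal <- obs$mae_gain * pmax(ne, 0)
  .maybe_seed(obs)
  value <- vapply(signal, function(mu) {
    mean(pmax(0, mu + stats::rnorm(n_repeats, 0, obs$mae_noise_sd)))
  }, numeric(1))
  tibble::tibble(observer = observer, condition = condition, task = "mae",
                 isi_ms = round(isi * 1000), value = value)
}

#' Default true-k layout for the synthetic cohort
#'
#' Per-observer true temporal scale factors mirroring the published
#' individual best fits: five observers per condition and task, photopic
#' values near 110 (dd) / 87 (mae) and scotopic values near 47 (dd) /
#' 56 (mae).
#'
#' @return A tibble with columns `condition`, `task` and `k1`..`k5`.
#' @export
fixture_k_layout <- function() {
  tibble::tribble(
    ~condition, ~task, ~k1, ~k2, ~k3, ~k4, ~k5,
    "photopic", "dd", 110, 110, 110, 110, 105,
    "scotopic", "dd",  60,  40,  45,  40,  50,
    "photopic", "mae", 85,  85,  85,  90,  90,
    "scotopic", "mae", 55,  55,  65,  50,  55
  )
}

#' Build the default synthetic dataset
#'
#' Simulates a full cohort — by default five observers, two luminance
#' conditions, both tasks, nine ISIs — with per-observer true k values
#' from [fixture_k_layout()]. All randomness flows through one generator
#' seeded once at entry, so the dataset is bit-reproducible from
#' `(layout, seed)`.
#'
#' @param seed Integer seed.
#' @param layout A k layout as returned by [fixture_k_layout()].
#' @param n_trials Direction-discrimination trials per ISI.
#' @param n_repeats MAE measurements per ISI.
#' @param lapse,mae_gain,mae_noise_sd Observer-model parameters shared by
#'   the cohort.
#' @param isi ISI set in seconds.
#' @param cfg A [model_config()].
#' @param path Optional path; when given the dataset is also written as
#'   CSV with [write_results()].
#' @return A tibble with columns `observer`, `condition`, `task`,
#'   `isi_ms`, `value`.
#' @export
make_fixture_dataset <- function(seed = 1, layout = fixture_k_layout(),
                                 n_trials = 80, n_repeats = 4,
                                 lapse = 0.02, mae_gain = 15,
                                 mae_noise_sd = 3, isi = isi_set(),
                                 cfg = model_config(), path = NULL) {
  set.seed(seed)
  k_cols <- grep("^k", names(layout), value = TRUE)
  rows <- list()
  for (i in seq_len(nrow(layout))) {
    for (j in seq_along(k_cols)) {
      obs <- observer_model(k_true = layout[[k_cols[j]]][i], lapse = lapse,
                            mae_gain = mae_gain, mae_noise_sd = mae_noise_sd)
      label <- paste0("S", j)
      rows[[length(rows) + 1]] <-
        if (layout$task[i] == "dd") {
          simulate_dd_observer(obs, isi = isi, n_trials = n_trials,
                               observer = label,
                               condition = layout$condition[i], cfg = cfg)
        } else {
          simulate_mae_observer(obs, isi = isi, n_repeats = n_repeats,
                                observer = label,
                                condition = layout$condition[i], cfg = cfg)
        }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) write_results(path, out)
  out
}
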