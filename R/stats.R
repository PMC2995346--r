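#' Group summary statistics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' set of individual parameter values, as reported in the group ("Av Ss"
#' and "SD") rows of the fitted-k tables.
#'
#' @param values Numeric vector, length >= 2.
#' @return A list with elements `mean` and `sd`.
#' @export
summary_stats <- function(values) {
  if (length(values) < 2) stop("sd undefined for fewer than 2 values")
  list(mean = mean(values), sd = stats::sd(values))
}

#' Two-tailed paired-samples t-test
#'
#' Compares paired measurements (e.g. each observer's fitted k under
#' photopic vs scotopic viewing). Thin wrapper over [stats::t.test()]
#' returning the statistic, degrees of freedom and two-tailed p-value.
#'
#' @param a,b Equal-length numeric vectors of paired values, n >= 2.
#' @return A list with elements `t`, `df`, `p`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  if (stats::sd(a - b) == 0) {
    stop("zero-variance differences: paired t statistic undefined")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Format a p-value for reporting
#'
#' Three decimals, with values below 0.001 reported as `"< .001"`.
#'
#' @param p A p-value.
#' @return Character scalar.
#' @export
format_p <- function(p) {
  if (p < 0.001) "< .001" else sub("^0", "", sprintf("%.3f", p))
}

#' Luminance attenuation by neutral density filters
#'
#' Attenuating a luminance by `log_units` log10 units divides it by
#' `10^log_units`; e.g. 45.99 cd/m2 through 2.3 log units gives
#' 0.23 cd/m2.
#'
#' @param luminance Luminance in cd/m2, > 0.
#' @param log_units Attenuation in log10 units.
#' @return Attenuated luminance in cd/m2.
#' @export
luminance_attenuation <- function(luminance, log_units) {
  stopifnot(luminance > 0)
  luminance / 10^log_units
}

#' Published best-fitting k values for the two-stroke study design
#'
#' Individual best-fitting temporal scale factors (k, 1/s) and RMS
#' errors for five observers per task under high (photopic) and low
#' (scotopic) luminance, for the direction-discrimination and
#' motion-after-effect experiments. These printed values are the inputs
#' to the group statistics: their means/SDs and the paired t-tests
#' comparing luminance conditions reproduce the published group rows.
#'
#' @return A tibble with columns `observer`, `task` ("dd"/"mae"),
#'   `condition` ("photopic"/"scotopic"), `k`, `rms`.
#' @export
reference_k_table <- function() {
  dd <- tibble::tribble(
    ~observer, ~k_high, ~rms_high, ~k_low, ~rms_low,
    "KLC", 110, 0.04, 60, 0.06,
    "BBB", 110, 0.07, 40, 0.16,
    "CM",  110, 0.05, 45, 0.07,
    "BIH", 110, 0.06, 40, 0.15,
    "CNJ", 105, 0.06, 50, 0.14
  )
  mae <- tibble::tribble(
    ~observer, ~k_high, ~rms_high, ~k_low, ~rms_low,
    "KLC", 85, 0.29, 55, 0.08,
    "BBB", 85, 0.37, 55, 0.22,
    "CM",  85, 0.23, 65, 0.09,
    "RMH", 90, 0.05, 50, 0.15,
    "AIG", 90, 0.21, 55, 0.20
  )
  long <- function(d, task) {
    dplyr::bind_rows(
      tibble::tibble(observer = d$observer, task = task,
                     condition = "photopic", k = d$k_high, rms = d$rms_high),
      tibble::tibble(observer = d$observer, task = task,
                     condition = "scotopic", k = d$k_low, rms = d$rms_low)
    )
  }
  dplyr::bind_rows(long(dd, "dd"), long(mae, "mae"))
}

#' Group rows of a fitted-k table
#'
#' Appends the mean ("Av Ss") and sample SD of the individual k and RMS
#' values per condition to a table of per-observer fits.
#'
#' @param fits A tibble with columns `observer`, `condition`, `task`,
#'   `k` (or `k_best`) and `rms`.
#' @return A tibble with columns `condition`, `task`, `k_mean`, `k_sd`,
#'   `rms_mean`, `rms_sd`, `n`.
#' @export
k_table_summary <- function(fits) {
  if ("k_best" %in% names(fits) && !"k" %in% names(fits)) {
    fits$k <- fits$k_best
  }
  fits |>
    dplyr::group_by(.data$condition, .data$task) |>
    dplyr::summarise(
      k_mean = mean(.data$k), k_sd = stats::sd(.data$k),
      rms_mean = mean(.data$rms), rms_sd = stats::sd(.data$rms),
      n = dplyr::n(), .groups = "drop"
    )
}

#' Read a psychophysical data table
#'
#' Reads delimiter-separated text with columns `observer`, `condition`
#' (`photopic`|`scotopic`), `task` (`dd`|`mae`), `isi_ms` and `value`
#' (percent in `[0, 100]` for dd, non-negative seconds for mae), and
#' validates every row; malformed rows are reported with their line
#' numbers.
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @return A validated tibble.
#' @export
read_psycho_csv <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("observer", "condition", "task", "isi_ms", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header occupies line 1
  bad <- character(0)
  flag <- function(rows, why) {
    if (any(rows)) {
      bad <<- c(bad, paste0("line ", paste(line_no[rows], collapse = ", "),
                            ": ", why))
    }
  }
  flag(!raw$condition %in% c("photopic", "scotopic"),
       "condition must be 'photopic' or 'scotopic'")
  flag(!raw$task %in% c("dd", "mae"), "task must be 'dd' or 'mae'")
  flag(!is.finite(raw$isi_ms) | raw$isi_ms < 0, "isi_ms must be >= 0")
  flag(!is.finite(raw$value), "value must be numeric")
  is_dd <- raw$task == "dd"
  flag(is_dd & is.finite(raw$value) & (raw$value < 0 | raw$value > 100),
       "dd value must be a percent in [0, 100]")
  flag(!is_dd & is.finite(raw$value) & raw$value < 0,
       "mae value must be a non-negative duration")
  if (length(bad) > 0) {
    stop("invalid psychophysical data:\n", paste(bad, collapse = "\n"))
  }
  tibble::as_tibble(raw)
}

#' Write a results table as CSV
#'
#' @param path File path.
#' @param table A data frame.
#' @return `path`, invisibly.
#' @export
write_results <- function(path, table) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
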