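#' Oriented motion-energy sensor bank
#'
#' Builds the four oriented space-time filters of the opponent energy
#' model from the even/odd spatial pair (SE, SO) and the fast/slow
#' biphasic temporal pair (TF, TS), as outer-product combinations:
#' \deqn{R1 = SE \otimes TF + SO \otimes TS, \quad
#'       R2 = SO \otimes TF - SE \otimes TS}
#' \deqn{L1 = SE \otimes TF - SO \otimes TS, \quad
#'       L2 = SO \otimes TF + SE \otimes TS}
#' Each pair (R1, R2) and (L1, L2) is a quadrature pair tuned to one
#' direction of motion. The direction labels are fixed by a drift
#' calibration: a grating drifting toward +x yields positive net energy.
#'
#' @param spatial A [spatial_filter_spec()].
#' @param fast A [temporal_filter_spec()] for the fast filter (n = 6).
#' @param slow A [temporal_filter_spec()] for the slow filter (n = 9).
#' @return An object of class `sensor_bank`: four space x time matrices
#'   `R1`, `R2`, `L1`, `L2` (rows = space, columns = time) plus the
#'   underlying specs.
#' @export
build_sensors <- function(spatial, fast, slow) {
  stopifnot(inherits(spatial, "spatial_filter_spec"),
            inherits(fast, "temporal_filter_spec"),
            inherits(slow, "temporal_filter_spec"))
  if (abs(fast$dt - slow$dt) > 1e-12) {
    stop("fast and slow temporal filters must share dt")
  }
  se <- spatial_even(spatial)
  so <- spatial_odd(spatial)
  tf <- temporal_response(fast)
  ts <- temporal_response(slow)
  if (length(tf) != length(ts)) {
    stop("fast and slow temporal filters must share extent")
  }
  structure(
    list(
      R1 = outer(se, tf) + outer(so, ts),
      R2 = outer(so, tf) - outer(se, ts),
      L1 = outer(se, tf) - outer(so, ts),
      L2 = outer(so, tf) + outer(se, ts),
      spatial = spatial, fast = fast, slow = slow
    ),
    class = "sensor_bank"
  )
}

# FFT-based 2-D cross-correlation machinery. The stimulus and (rotated)
# kernel are zero-padded to a common highly-composite size so the circular
# product equals the linear convolution. Energies are pooled over the full
# linear-correlation support (every space-time lag with any overlap, zero
# boundary): full-support pooling makes the opponent antisymmetries
# (time reversal, spatial mirror) exact matrix identities, which a central
# 'same'-size trim breaks at the edges by ~1e-2.

.pad_dims <- function(ns, nk) {
  c(stats::nextn(ns[1] + nk[1] - 1L), stats::nextn(ns[2] + nk[2] - 1L))
}

.fft2_padded <- function(m, dims) {
  p <- matrix(0, dims[1], dims[2])
  p[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  stats::fft(p)
}

# Cross-correlation of the stimulus with a kernel equals convolution with
# the kernel rotated 180 degrees.
.fft2_kernel <- function(kern, dims) {
  .fft2_padded(kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern))),
                    drop = FALSE], dims)
}

# Sum of squares of the full linear cross-correlation, given pre-computed
# padded transforms.
.xcorr_ssq <- function(f_stim, f_kern, ns, nk, dims) {
  full <- Re(stats::fft(f_stim * f_kern, inverse = TRUE)) / prod(dims)
  sum(full[seq_len(ns[1] + nk[1] - 1L), seq_len(ns[2] + nk[2] - 1L)]^2)
}

.bank_dims <- function(bank) dim(bank$R1)

#' Pooled opponent-energy summary of a stimulus
#'
#' Cross-correlates each oriented filter with the stimulus over all
#' space-time positions (full linear-correlation support, zero boundary),
#' squares the responses, and pools them over space, time and the
#' quadrature pair to give rightward energy `e_R`, leftward energy
#' `e_L`, flicker energy
#' (their sum) and normalised net energy
#' `ne = (e_R - e_L) / (e_R + e_L)`, bounded in `[-1, 1]`. A blank
#' stimulus (zero flicker energy) yields `ne = 0` with a warning.
#'
#' @param stim A `stimulus_xt` object.
#' @param bank A [build_sensors()] bank on the same `dx`/`dt`.
#' @return An object of class `energy_summary`: list with `e_R`, `e_L`,
#'   `flicker`, `ne`.
#' @export
energy_summary <- function(stim, bank) {
  stopifnot(inherits(stim, "stimulus_xt"), inherits(bank, "sensor_bank"))
  if (abs(stim$grid$dx - bank$spatial$dx) > 1e-12 ||
      abs(stim$grid$dt - bank$fast$dt) > 1e-12) {
    stop("stimulus and sensor bank must share the sampling grid (dx, dt)")
  }
  ns <- dim(stim$values)
  nk <- .bank_dims(bank)
  dims <- .pad_dims(ns, nk)
  f_stim <- .fft2_padded(stim$values, dims)
  ssq <- vapply(
    bank[c("R1", "R2", "L1", "L2")],
    function(kern) .xcorr_ssq(f_stim, .fft2_kernel(kern, dims),
                                   ns, nk, dims),
    numeric(1)
  )
  .energy_from_ssq(ssq)
}

.energy_from_ssq <- function(ssq) {
  e_r <- ssq[["R1"]] + ssq[["R2"]]
  e_l <- ssq[["L1"]] + ssq[["L2"]]
  flicker <- e_r + e_l
  if (flicker < 1e-20) {
    warning("flicker energy is zero (blank stimulus); ne set to 0")
    ne <- 0
  } else {
    ne <- (e_r - e_l) / flicker
  }
  structure(list(e_R = e_r, e_L = e_l, flicker = flicker, ne = ne),
            class = "energy_summary")
}

#' Model configuration
#'
#' Bundles the sampling grid, stimulus parameters and filter parameters
#' shared by every model run. Defaults are the study conditions: 8 deg x
#' 1.5 s grid at (0.05 deg, 5 ms); 1.6 cpd gratings at contrast 0.5 with
#' 40 ms frames; spatial filters at 1.1 cpd, sigma 0.5 deg over 4 deg;
#' temporal filters with n = 9 (slow) / 6 (fast), beta = 0.9, over 0.5 s.
#'
#' @param grid A [sampling_grid()].
#' @param spatial_frequency Stimulus spatial frequency, cycles/degree.
#' @param contrast Stimulus contrast.
#' @param frame_duration Grating frame duration, seconds.
#' @param phase_step Spatial phase step, +90 or -90 degrees.
#' @param filter_f Spatial filter carrier frequency, cycles/degree.
#' @param filter_sigma Spatial filter envelope scale, degrees.
#' @param filter_extent Spatial filter support, degrees.
#' @param n_slow,n_fast Temporal filter exponents.
#' @param beta Temporal filter negative-lobe weighting.
#' @param temporal_extent Temporal filter support, seconds.
#' @return A list of class `model_config`.
#' @export
model_config <- function(grid = sampling_grid(),
                         spatial_frequency = 1.6,
                         contrast = 0.5,
                         frame_duration = 0.040,
                         phase_step = 90,
                         filter_f = 1.1,
                         filter_sigma = 0.5,
                         filter_extent = 4,
                         n_slow = 9, n_fast = 6,
                         beta = 0.9,
                         temporal_extent = 0.5) {
  stopifnot(inherits(grid, "sampling_grid"))
  structure(
    list(grid = grid, spatial_frequency = spatial_frequency,
         contrast = contrast, frame_duration = frame_duration,
         phase_step = phase_step, filter_f = filter_f,
         filter_sigma = filter_sigma, filter_extent = filter_extent,
         n_slow = n_slow, n_fast = n_fast, beta = beta,
         temporal_extent = temporal_extent),
    class = "model_config"
  )
}

.cfg_bank <- function(k, cfg) {
  spatial <- spatial_filter_spec(cfg$filter_f, cfg$filter_sigma,
                                 cfg$filter_extent, cfg$grid$dx)
  fast <- temporal_filter_spec(k, cfg$n_fast, cfg$beta,
                               cfg$temporal_extent, cfg$grid$dt)
  slow <- temporal_filter_spec(k, cfg$n_slow, cfg$beta,
                               cfg$temporal_extent, cfg$grid$dt)
  build_sensors(spatial, fast, slow)
}

.cfg_stimulus <- function(task, isi, cfg) {
  mode <- if (task == "dd") "single_cycle" else "repeating"
  spec <- stimulus_spec(isi_duration = isi,
                        frame_duration = cfg$frame_duration,
                        spatial_frequency = cfg$spatial_frequency,
                        contrast = cfg$contrast,
                        phase_step = cfg$phase_step,
                        mode = mode)
  if (task == "dd") make_two_stroke_xt(spec, cfg$grid)
  else make_repeating_xt(spec, cfg$grid)
}

# Session cache for model curves: computing ne for one (task, k, isi)
# costs several FFTs, and fitting sweeps the same k grid for every
# observer, so results are memoised on the full parameter set.
.curve_cache <- new.env(parent = emptyenv())

.cfg_key <- function(task, cfg) {
  paste(task, cfg$grid$dx, cfg$grid$dt, cfg$grid$x_extent, cfg$grid$t_extent,
        cfg$spatial_frequency, cfg$contrast, cfg$frame_duration,
        cfg$phase_step, cfg$filter_f, cfg$filter_sigma, cfg$filter_extent,
        cfg$n_slow, cfg$n_fast, cfg$beta, cfg$temporal_extent, sep = "|")
}

#' Model curve: normalised net energy per ISI
#'
#' Builds the task's stimulus for each ISI (single seven-epoch cycle for
#' direction discrimination, repeating cycle for the after-effect
#' adaptor), runs the opponent energy model with temporal scale factor
#' `k`, and returns NE per ISI. Results are memoised within the session.
#'
#' @param task `"dd"` (direction discrimination) or `"mae"`
#'   (motion after-effect).
#' @param k Temporal scale factor, 1/seconds.
#' @param isi Vector of ISI durations in seconds (default [isi_set()]).
#' @param cfg A [model_config()].
#' @return A [tibble::tibble()] with columns `isi`, `ne` and attributes
#'   `task` and `k`.
#' @export
model_curve <- function(task = c("dd", "mae"), k, isi = isi_set(),
                        cfg = model_config()) {
  task <- match.arg(task)
  stopifnot(k > 0, all(isi >= 0))
  key <- .cfg_key(task, cfg)
  ne <- vapply(isi, function(one_isi) {
    id <- paste(key, format(k, digits = 15), format(one_isi, digits = 15))
    if (!is.null(.curve_cache[[id]])) return(.curve_cache[[id]])
    bank <- .cfg_bank(k, cfg)
    stim <- .cfg_stimulus(task, one_isi, cfg)
    val <- energy_summary(stim, bank)$ne
    .curve_cache[[id]] <- val
    val
  }, numeric(1))
  out <- tibble::tibble(isi = isi, ne = ne)
  attr(out, "task") <- task
  attr(out, "k") <- k
  out
}

#' Model curves over a grid of k values
#'
#' Computes [model_curve()] for every k in `k_grid`, reusing the padded
#' stimulus transforms across k and the filter transforms across ISI, so
#' a full fitting sweep costs far less than independent runs.
#'
#' @inheritParams model_curve
#' @param k_grid Vector of k values.
#' @return Matrix of NE values, rows = `k_grid` (rownames), columns =
#'   `isi`.
#' @export
model_curve_grid <- function(task = c("dd", "mae"), k_grid,
                             isi = isi_set(), cfg = model_config()) {
  task <- match.arg(task)
  stopifnot(length(k_grid) >= 1, all(k_grid > 0))
  key <- .cfg_key(task, cfg)
  out <- matrix(NA_real_, length(k_grid), length(isi),
                dimnames = list(format(k_grid, trim = TRUE), NULL))

  todo <- matrix(TRUE, length(k_grid), length(isi))
  for (i in seq_along(k_grid)) {
    for (j in seq_along(isi)) {
      id <- paste(key, format(k_grid[i], digits = 15),
                  format(isi[j], digits = 15))
      if (!is.null(.curve_cache[[id]])) {
        out[i, j] <- .curve_cache[[id]]
        todo[i, j] <- FALSE
      }
    }
  }
  if (!any(todo)) return(out)

  ns <- c(cfg$grid$nx, cfg$grid$nt)
  nk <- c(as.integer(round(cfg$filter_extent / cfg$grid$dx)),
          as.integer(round(cfg$temporal_extent / cfg$grid$dt)))
  dims <- .pad_dims(ns, nk)
  stim_fft <- lapply(seq_along(isi), function(j) {
    if (any(todo[, j])) {
      .fft2_padded(.cfg_stimulus(task, isi[j], cfg)$values, dims)
    }
  })
  for (i in seq_along(k_grid)) {
    if (!any(todo[i, ])) next
    bank <- .cfg_bank(k_grid[i], cfg)
    kern_fft <- lapply(bank[c("R1", "R2", "L1", "L2")], .fft2_kernel,
                       dims = dims)
    for (j in seq_along(isi)) {
      if (!todo[i, j]) next
      ssq <- vapply(kern_fft, function(fk) {
        .xcorr_ssq(stim_fft[[j]], fk, ns, nk, dims)
      }, numeric(1))
      val <- suppressWarnings(.energy_from_ssq(ssq)$ne)
      out[i, j] <- val
      id <- paste(key, format(k_grid[i], digits = 15),
                  format(isi[j], digits = 15))
      .curve_cache[[id]] <- val
    }
  }
  out
}
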