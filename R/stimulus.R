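#' Space-time sampling grid
#'
#' Defines the discretisation of the one-dimensional space x time window on
#' which model stimuli and filter responses are evaluated. Defaults give an
#' 8 degree window sampled every 0.05 degrees and a 1.5 s window sampled
#' every 5 ms, so a 40 ms grating frame occupies exactly 8 temporal samples.
#'
#' @param dx Spatial sample spacing, degrees of visual angle.
#' @param dt Temporal sample spacing, seconds.
#' @param x_extent Total spatial extent, degrees.
#' @param t_extent Total temporal extent, seconds.
#' @return An object of class `sampling_grid` with elements `dx`, `dt`,
#'   `x_extent`, `t_extent`, `nx`, `nt`, and sample coordinate vectors
#'   `x` (starting at 0) and `t` (starting at 0).
#' @export
sampling_grid <- function(dx = 0.05, dt = 0.005, x_extent = 8, t_extent = 1.5) {
  stopifnot(dx > 0, dt > 0, x_extent > 0, t_extent > 0)
  nx <- x_extent / dx
  nt <- t_extent / dt
  if (abs(nx - round(nx)) > 1e-8 || abs(nt - round(nt)) > 1e-8) {
    stop("x_extent/dx and t_extent/dt must be whole numbers of samples")
  }
  nx <- as.integer(round(nx))
  nt <- as.integer(round(nt))
  structure(
    list(
      dx = dx, dt = dt, x_extent = x_extent, t_extent = t_extent,
      nx = nx, nt = nt,
      x = seq(0, by = dx, length.out = nx),
      t = seq(0, by = dt, length.out = nt)
    ),
    class = "sampling_grid"
  )
}

#' Two-stroke stimulus specification
#'
#' Parameters of the seven-epoch two-stroke sequence
#' (grating 1 - ISI - grating 2 - grating 1 - ISI - grating 2 - grating 1),
#' where grating 2 is grating 1 shifted in spatial phase by `phase_step`
#' degrees. The blank inter-stimulus interval (ISI) is background grey,
#' coded 0 in contrast units.
#'
#' @param isi_duration ISI duration in seconds (>= 0). The modelled set is
#'   0, 0.040, 0.085, 0.125, 0.165, 0.200, 0.240, 0.285, 0.315 s.
#' @param frame_duration Grating frame duration in seconds (default 0.040).
#' @param spatial_frequency Grating spatial frequency, cycles/degree
#'   (default 1.6).
#' @param contrast Michelson contrast in (0, 1] (default 0.5).
#' @param phase_step Spatial phase step between the two frames, degrees;
#'   must be +90 or -90.
#' @param mode `"single_cycle"` (direction-discrimination stimulus) or
#'   `"repeating"` (adaptation stimulus for the motion after-effect).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(isi_duration,
                          frame_duration = 0.040,
                          spatial_frequency = 1.6,
                          contrast = 0.5,
                          phase_step = 90,
                          mode = c("single_cycle", "repeating")) {
  mode <- match.arg(mode)
  stopifnot(isi_duration >= 0, frame_duration > 0)
  if (spatial_frequency <= 0) stop("spatial_frequency must be positive")
  if (!(contrast > 0 && contrast <= 1)) stop("contrast must be in (0, 1]")
  if (abs(abs(phase_step) - 90) > 1e-9) stop("phase_step must be +90 or -90")
  structure(
    list(
      isi_duration = isi_duration, frame_duration = frame_duration,
      spatial_frequency = spatial_frequency, contrast = contrast,
      phase_step = phase_step, mode = mode
    ),
    class = "stimulus_spec"
  )
}

#' The modelled ISI set, in seconds
#'
#' ISI durations used for the model stimuli: 0, 40, 85, 125, 165, 200,
#' 240, 285 and 315 ms.
#'
#' @return Numeric vector of 9 ISI durations in seconds.
#' @export
isi_set <- function() {
  c(0, 0.040, 0.085, 0.125, 0.165, 0.200, 0.240, 0.285, 0.315)
}

#' Spatial luminance-contrast profile of a grating frame
#'
#' One spatial sample row of a sine grating,
#' `v(x) = contrast * sin(2*pi*sf*x + phase)`, in background-relative
#' contrast units (background grey = 0).
#'
#' @param phase_deg Spatial phase in degrees.
#' @param spec A [stimulus_spec()].
#' @param grid A [sampling_grid()].
#' @return Numeric vector of length `grid$nx`.
#' @export
make_grating_profile <- function(phase_deg, spec, grid) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(grid, "sampling_grid"))
  spec$contrast *
    sin(2 * pi * spec$spatial_frequency * grid$x + phase_deg * pi / 180)
}

# Sample counts of the 7 epochs (5 grating frames, 2 ISIs), rounded to the
# nearest temporal sample. Default parameters land exactly on samples.
.epoch_samples <- function(spec, grid) {
  nf <- as.integer(round(spec$frame_duration / grid$dt))
  ni <- as.integer(round(spec$isi_duration / grid$dt))
  list(nf = nf, ni = ni, total = 5L * nf + 2L * ni)
}

# One 7-epoch cycle as an nx x total matrix: G1 ISI G2 G1 ISI G2 G1.
.two_stroke_cycle <- function(spec, grid) {
  ep <- .epoch_samples(spec, grid)
  g1 <- make_grating_profile(0, spec, grid)
  g2 <- make_grating_profile(spec$phase_step, spec, grid)
  blank <- rep(0, grid$nx)
  cols <- c(
    rep(list(g1), ep$nf), rep(list(blank), ep$ni),
    rep(list(g2), ep$nf), rep(list(g1), ep$nf),
    rep(list(blank), ep$ni), rep(list(g2), ep$nf),
    rep(list(g1), ep$nf)
  )
  do.call(cbind, cols)
}

.new_stimulus_xt <- function(values, grid, spec) {
  structure(list(values = values, grid = grid, spec = spec),
            class = "stimulus_xt")
}

#' Single-cycle two-stroke stimulus in space-time
#'
#' Builds the direction-discrimination model stimulus: one seven-epoch
#' two-stroke cycle centred in the temporal window, zero (background grey)
#' elsewhere. With equal padding impossible, the split is rounded toward an
#' earlier onset.
#'
#' @param spec A [stimulus_spec()] with `mode = "single_cycle"`.
#' @param grid A [sampling_grid()].
#' @return An object of class `stimulus_xt` with elements `values`
#'   (matrix, rows = space, columns = time), `grid` and `spec`.
#' @export
make_two_stroke_xt <- function(spec, grid) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(grid, "sampling_grid"))
  if (spec$mode != "single_cycle") {
    stop("make_two_stroke_xt requires mode = 'single_cycle'")
  }
  cyc <- .two_stroke_cycle(spec, grid)
  n_active <- ncol(cyc)
  if (n_active > grid$nt) {
    stop("two-stroke sequence (", n_active * grid$dt,
         " s) does not fit in t_extent (", grid$t_extent, " s)")
  }
  pad <- grid$nt - n_active
  before <- pad %/% 2L
  values <- matrix(0, grid$nx, grid$nt)
  if (n_active > 0) values[, before + seq_len(n_active)] <- cyc
  .new_stimulus_xt(values, grid, spec)
}

#' Repeating two-stroke stimulus in space-time
#'
#' Builds the adaptation stimulus used to predict the motion after-effect:
#' the seven-epoch cycle tiled from t = 0 until the temporal window is
#' filled, with the final partial cycle truncated.
#'
#' @param spec A [stimulus_spec()] with `mode = "repeating"`.
#' @param grid A [sampling_grid()].
#' @return A `stimulus_xt` object.
#' @export
make_repeating_xt <- function(spec, grid) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(grid, "sampling_grid"))
  if (spec$mode != "repeating") {
    stop("make_repeating_xt requires mode = 'repeating'")
  }
  cyc <- .two_stroke_cycle(spec, grid)
  n_cyc <- ncol(cyc)
  reps <- ceiling(grid$nt / n_cyc)
  values <- cyc[, rep_len(seq_len(n_cyc), grid$nt), drop = FALSE]
  stopifnot(ncol(values) == grid$nt)
  .new_stimulus_xt(values, grid, spec)
}

#' Drifting sine grating in space-time
#'
#' Calibration stimulus: `v(x, t) = contrast * sin(2*pi*(sf*x - dir*tf*t))`,
#' a grating translating toward +x for `direction = +1`. Used to fix the
#' sign convention of the oriented energy sensors.
#'
#' @param sf Spatial frequency, cycles/degree.
#' @param tf Temporal frequency, Hz (must be below the temporal Nyquist).
#' @param direction +1 (drift toward +x) or -1.
#' @param contrast Contrast amplitude.
#' @param grid A [sampling_grid()].
#' @return A `stimulus_xt` object (its `spec` field carries the drift
#'   parameters).
#' @export
make_drifting_grating_xt <- function(sf, tf, direction = 1, contrast = 0.5,
                                     grid = sampling_grid()) {
  stopifnot(inherits(grid, "sampling_grid"), sf > 0, tf >= 0,
            direction %in% c(-1, 1))
  if (sf >= 1 / (2 * grid$dx)) stop("sf at or above spatial Nyquist")
  if (tf >= 1 / (2 * grid$dt)) stop("tf at or above temporal Nyquist")
  phase <- outer(sf * grid$x, -direction * tf * grid$t, `+`)
  values <- contrast * sin(2 * pi * phase)
  spec <- list(sf = sf, tf = tf, direction = direction, contrast = contrast,
               mode = "drifting")
  .new_stimulus_xt(values, grid, spec)
}
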