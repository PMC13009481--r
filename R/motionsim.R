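#' Periodic motion schedule for artifact simulation
#'
#' Describes the reproducible periodic head-motion pattern used to corrupt
#' k-space. Time is measured in echo groups (EG) — blocks of consecutively
#' acquired k-space lines, the minimal time unit; all motion durations are
#' integer multiples of EG. One repetition period consists of: rotate left
#' over 2 EG, hold 5 EG, rotate back over 2 EG (9 EG displaced), rest `Ts`,
#' the mirrored rightward excursion (9 EG displaced), rest `Ts` — i.e. 18 EG
#' displaced and `2 Ts` at the starting position per period. Before the first
#' period the subject holds the starting position for `Ts`.
#'
#' @param Ts_in_EG Stationary interval between motion events, in EG units.
#' @param EG Echoes (k-space lines) per echo group (default 80).
#' @param angle_inplane_deg In-plane rotation angle in degrees (default 5).
#' @param angle_throughplane_deg Through-plane (nodding) angle (default 0).
#' @param n_lines Total number of k-space lines to fill (set from the volume
#'   when corrupting; may be `NULL` here).
#' @return An object of class `motion_schedule`.
#' @export
motion_schedule <- function(Ts_in_EG, EG = 80L, angle_inplane_deg = 5,
                            angle_throughplane_deg = 0, n_lines = NULL) {
  if (Ts_in_EG < 1) stop("Ts_in_EG must be >= 1", call. = FALSE)
  if (EG < 1) stop("EG must be >= 1", call. = FALSE)
  structure(list(Ts_in_EG = as.integer(Ts_in_EG), EG = as.integer(EG),
                 angle_inplane_deg = angle_inplane_deg,
                 angle_throughplane_deg = angle_throughplane_deg,
                 trajectory = "centric",
                 n_lines = if (is.null(n_lines)) NULL else as.integer(n_lines)),
            class = "motion_schedule")
}

# State labels for one full repetition period (steps 2-7), in EG units.
# Both 2-EG rotation ramps are modeled at the full displaced angle.
period_states_eg <- function(Ts) {
  c(rep("rotated_left", 9L),      # 2 EG ramp + 5 EG hold + 2 EG ramp back
    rep("original", Ts),
    rep("rotated_right", 9L),
    rep("original", Ts))
}

#' Materialize the per-line motion timeline
#'
#' Expands the periodic schedule into one state label per acquired k-space
#' line: an initial stationary block of `Ts`, then the steps 2-7 period
#' repeated until `n_lines` lines are filled.
#'
#' @param ms A [motion_schedule()] with `n_lines` set, or pass `n_lines`.
#' @param n_lines Total lines to label (overrides the schedule's value).
#' @return Character vector of length `n_lines` with values `"original"`,
#'   `"rotated_left"`, `"rotated_right"`.
#' @export
build_timeline <- function(ms, n_lines = ms$n_lines) {
  stopifnot(inherits(ms, "motion_schedule"))
  if (is.null(n_lines) || n_lines < 1) stop("n_lines must be >= 1", call. = FALSE)
  n_eg <- ceiling(n_lines / ms$EG)
  states_eg <- c(rep("original", ms$Ts_in_EG),
                 rep_len(period_states_eg(ms$Ts_in_EG),
                         max(0L, n_eg - ms$Ts_in_EG)))[seq_len(n_eg)]
  rep(states_eg, each = ms$EG)[seq_len(n_lines)]
}

#' Displaced-line fraction of the periodic motion pattern
#'
#' Over one full repetition period of steps 2-7 the head is displaced for
#' 18 EG (two 9-EG excursions) and at rest for `2 Ts`, giving the closed form
#' `18 / (18 + 2 Ts)`. For `Ts` of 9, 18, 36 and 72 EG this yields corruption
#' ratios of 50%, 33%, 20% and 11%.
#'
#' @param ms A [motion_schedule()].
#' @return Fraction in \[0, 1\].
#' @export
corruption_ratio <- function(ms) {
  stopifnot(inherits(ms, "motion_schedule"))
  18 / (18 + 2 * ms$Ts_in_EG)
}

#' Rigidly rotate a volume about its center
#'
#' Trilinear resampling; voxels mapped from outside the field of view are
#' filled with 0. `inplane` rotates within the FE-PE plane (about the SL
#' axis); `throughplane` rotates within the PE-SL plane (about the FE axis,
#' i.e. head nodding, which mixes information across slices).
#'
#' @param v Numeric 3D array.
#' @param angle_deg Rotation angle in degrees, |angle| <= 30.
#' @param axis `"inplane"` or `"throughplane"`.
#' @return Rotated volume, same shape.
#' @export
rotate_volume <- function(v, angle_deg, axis = c("inplane", "throughplane")) {
  assert_volume(v)
  axis <- match.arg(axis)
  if (abs(angle_deg) > 30) stop("|angle_deg| must be <= 30", call. = FALSE)
  if (angle_deg == 0) return(v)
  d <- dim(v)
  th <- angle_deg * pi / 180
  ctr <- (d + 1) / 2
  g1 <- seq_len(d[1]) - ctr[1]
  g2 <- seq_len(d[2]) - ctr[2]
  g3 <- seq_len(d[3]) - ctr[3]
  X <- array(rep(g1, times = d[2] * d[3]), d)
  Y <- array(rep(rep(g2, each = d[1]), times = d[3]), d)
  Z <- array(rep(g3, each = d[1] * d[2]), d)
  co <- cos(-th); si <- sin(-th)              # inverse mapping
  if (axis == "inplane") {
    Xs <- co * X - si * Y; Ys <- si * X + co * Y; Zs <- Z
  } else {
    Xs <- X; Ys <- co * Y - si * Z; Zs <- si * Y + co * Z
  }
  trilinear_sample(v, Xs + ctr[1], Ys + ctr[2], Zs + ctr[3])
}

# Trilinear interpolation at arbitrary (fractional) 1-based coordinates,
# zero outside the volume.
trilinear_sample <- function(v, X, Y, Z) {
  d <- dim(v)
  x0 <- floor(X); y0 <- floor(Y); z0 <- floor(Z)
  fx <- X - x0; fy <- Y - y0; fz <- Z - z0
  # pad volume with a zero border so out-of-field taps read 0
  vp <- array(0, d + 2L)
  vp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  cl <- function(i, n) pmin(pmax(i, 0), n + 1) + 1   # into padded coords
  at <- function(ix, iy, iz) {
    vp[cbind(as.vector(cl(ix, d[1])), as.vector(cl(iy, d[2])),
             as.vector(cl(iz, d[3])))]
  }
  out <-
    at(x0,     y0,     z0)     * as.vector((1 - fx) * (1 - fy) * (1 - fz)) +
    at(x0 + 1, y0,     z0)     * as.vector(fx       * (1 - fy) * (1 - fz)) +
    at(x0,     y0 + 1, z0)     * as.vector((1 - fx) * fy       * (1 - fz)) +
    at(x0,     y0,     z0 + 1) * as.vector((1 - fx) * (1 - fy) * fz) +
    at(x0 + 1, y0 + 1, z0)     * as.vector(fx       * fy       * (1 - fz)) +
    at(x0 + 1, y0,     z0 + 1) * as.vector(fx       * (1 - fy) * fz) +
    at(x0,     y0 + 1, z0 + 1) * as.vector((1 - fx) * fy       * fz) +
    at(x0 + 1, y0 + 1, z0 + 1) * as.vector(fx       * fy       * fz)
  array(out, d)
}

#' Centric k-space filling order
#'
#' Orders phase-encoding line indices by ascending distance from the center
#' line (the DC line at 0-based index `floor(n/2)`), so the low-frequency
#' core is acquired first. Ties are broken toward the lower index.
#'
#' @param n Number of phase-encoding lines.
#' @return Integer permutation of `0:(n-1)` (0-based line indices).
#' @export
centric_order <- function(n) {
  stopifnot(n >= 1)
  idx <- 0:(n - 1)
  ctr <- floor(n / 2)
  idx[order(abs(idx - ctr), idx)]
}

#' Corrupt a volume with periodic-motion k-space splicing
#'
#' Simulates motion artifacts retrospectively: the volume is rigidly rotated
#' to each displaced state (left/right at the scheduled angles), each slice of
#' the original and rotated volumes is transformed to 2D k-space, and each
#' phase-encoding line is taken from the k-space of the state active at its
#' acquisition time. Lines are acquired in centric order within each slice;
#' the timeline advances continuously across slices (mimicking a single 3D
#' acquisition) unless `timeline = "per-slice"`. Slices stack along the third
#' axis; phase encoding is the second axis.
#'
#' @param v Numeric 3D array.
#' @param ms A [motion_schedule()].
#' @param timeline `"continuous"` (default) or `"per-slice"` (restart the
#'   timeline at every slice).
#' @return List with `volume` (corrupted, rescaled to \[0, 1\]),
#'   `realized_corruption` (displaced fraction of the lines actually
#'   acquired), and `ratio_periodic` (the closed-form periodic ratio).
#' @export
corrupt <- function(v, ms, timeline = c("continuous", "per-slice")) {
  assert_volume(v)
  stopifnot(inherits(ms, "motion_schedule"))
  timeline <- match.arg(timeline)
  d <- dim(v)
  n_pe <- d[2]; n_sl <- d[3]
  n_lines <- n_pe * n_sl
  labels <- if (timeline == "continuous") {
    build_timeline(ms, n_lines)
  } else {
    rep(build_timeline(ms, n_pe), n_sl)
  }
  # one precomputed rotated volume per distinct displaced state
  states <- list(original = v)
  rot <- function(sgn) {
    r <- v
    if (ms$angle_inplane_deg != 0)
      r <- rotate_volume(r, sgn * ms$angle_inplane_deg, "inplane")
    if (ms$angle_throughplane_deg != 0)
      r <- rotate_volume(r, sgn * ms$angle_throughplane_deg, "throughplane")
    r
  }
  if ("rotated_left" %in% labels) states$rotated_left <- rot(+1)
  if ("rotated_right" %in% labels) states$rotated_right <- rot(-1)
  # Acquisition order: centric indices are defined in the DC-centered layout;
  # map them to unshifted FFT columns (DC at column 1).
  ord_centered <- centric_order(n_pe)
  ord <- ((ord_centered - floor(n_pe / 2)) %% n_pe) + 1L
  out <- array(0, d)
  kcache <- new.env(parent = emptyenv())
  for (sl in seq_len(n_sl)) {
    lab_sl <- labels[((sl - 1) * n_pe + 1):(sl * n_pe)]
    need <- unique(lab_sl)
    ks <- lapply(need, function(nm) {
      key <- paste0(nm, ":", sl)
      if (is.null(kcache[[key]]))
        kcache[[key]] <- stats::fft(states[[nm]][, , sl])
      kcache[[key]]
    })
    names(ks) <- need
    kout <- ks[[lab_sl[1]]]
    if (length(need) > 1L) {
      for (t in seq_len(n_pe)) {
        pe <- ord[t]
        kout[, pe] <- ks[[lab_sl[t]]][, pe]
      }
    }
    out[, , sl] <- Mod(stats::fft(kout, inverse = TRUE)) / (d[1] * n_pe)
    rm(list = ls(kcache), envir = kcache)
  }
  list(volume = rescale01(out),
       realized_corruption = mean(labels != "original"),
       ratio_periodic = corruption_ratio(ms))
}
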