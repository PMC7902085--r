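#' Langevin dynamics parameters
#'
#' @param temperature Kelvin (default 300).
#' @param friction damping constant in ps^-1 (default 1).
#' @param timestep integration step in fs.
#' @param n_steps number of integration steps.
#' @param save_stride steps between saved frames.
#' @param seed integer RNG seed; every source of randomness in a run flows
#'   through it.
#' @return an object of class `langevin_params`.
#' @export
langevin_params <- function(temperature = 300, friction = 1, timestep = 5,
                            n_steps = 10000, save_stride = 100, seed = 1) {
  stopifnot(temperature > 0, friction >= 0, timestep > 0,
            n_steps >= 1, save_stride >= 1)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride),
                 seed = as.integer(seed)),
            class = "langevin_params")
}

#' Propagate a complex with BAOAB Langevin dynamics
#'
#' Velocities are drawn from the Maxwell-Boltzmann distribution at the run
#' temperature; trajectories are bit-for-bit reproducible for a given seed.
#'
#' @param cx a [build_complex()] object.
#' @param params a [langevin_params()].
#' @param start starting positions: `NULL` for the reference pose, the
#'   string `"dissociated"` for a randomized pose with chain B placed at a
#'   random orientation and COM radius between 60% and 90% of the cavity
#'   radius, or an n x 3 matrix.
#' @param bias optional [umbrella_bias()] applied during propagation.
#' @return an object of class `run_result` with fields `frames` (matrix,
#'   one row per saved frame, bead coordinates flattened x1 y1 z1 x2 ...),
#'   `frame_times` (ns), `frame_interval` (ns), `params`, `window`, and the
#'   generating complex `cx`.
#' @export
run_langevin <- function(cx, params, start = NULL, bias = NULL) {
  stopifnot(inherits(cx, "cg_complex"), inherits(params, "langevin_params"))
  set.seed(params$seed)
  if (is.character(start) && identical(start, "dissociated")) {
    start <- dissociated_pose(cx)
  }
  start <- check_positions(cx, start)
  b <- bias_args(bias)
  out <- run_baoab_cpp(cg_sys_list(cx), start, params$timestep,
                       params$friction, params$temperature, params$n_steps,
                       params$save_stride, b$has, b$d0, b$k,
                       draw_velocities = TRUE)
  dt_ns <- params$timestep * params$save_stride * 1e-6
  n_frames <- nrow(out$frames)
  structure(list(frames = out$frames,
                 frame_times = (seq_len(n_frames) - 1) * dt_ns,
                 frame_interval = dt_ns,
                 params = params, window = bias, cx = cx,
                 bias_energies = NULL),
            class = "run_result")
}

# Random dissociated pose: chain B rigidly rotated and placed at a random
# COM radius in [0.6, 0.9] r_cavity (uses the current RNG stream).
dissociated_pose <- function(cx) {
  pos <- cx$reference
  b <- cx$nA + seq_len(cx$nB)
  xb <- pos[b, , drop = FALSE]
  com <- colSums(xb * cx$mass[b]) / sum(cx$mass[b])
  xb <- sweep(xb, 2, com)
  R <- random_rotation()
  xb <- xb %*% t(R)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  r <- runif(1, 0.6, 0.9) * cx$confinement$r_cavity
  pos[b, ] <- sweep(xb, 2, r * u, "+")
  pos
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("run_result: %d frames x %d beads, %.4g ns (interval %.4g ns)%s\n",
              nrow(x$frames), ncol(x$frames) / 3,
              max(x$frame_times), x$frame_interval,
              if (!is.null(x$window))
                sprintf(", umbrella at %.3g A", x$window$center) else ""))
  invisible(x)
}

#' Frame coordinates of a run
#'
#' @param run a `run_result`.
#' @param t frame index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
get_frame <- function(run, t) {
  matrix(run$frames[t, ], ncol = 3, byrow = TRUE)
}

#' Uniform umbrella window grid
#'
#' @param start,stop first and last window centre, Angstrom.
#' @param spacing window spacing, Angstrom (> 0).
#' @param spring_k common harmonic spring constant, kcal/mol/A^2 (default 1).
#' @return an object of class `window_set` with fields `centers`, `spring_k`.
#' @export
make_window_grid <- function(start, stop, spacing, spring_k = 1) {
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (stop < start) stop("stop must be >= start")
  centers <- seq(start, stop, by = spacing)
  structure(list(centers = centers, spring_k = spring_k),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows, %.3g - %.3g A, k = %g kcal/mol/A^2\n",
              length(x$centers), min(x$centers), max(x$centers), x$spring_k))
  invisible(x)
}

#' Run an umbrella-sampling campaign
#'
#' One biased run per window.  Each run is seeded deterministically as
#' `params$seed + window index`, so campaigns are reproducible and
#' order-independent.  For every run the bias energy of each saved frame is
#' evaluated in the potential of *every* window (the TRAM input matrix) and
#' stored in units of kBT at the run temperature.
#'
#' @param cx a [build_complex()] object.
#' @param windows a [make_window_grid()] object.
#' @param params a [langevin_params()]; the per-window seed is derived from
#'   `params$seed`.
#' @return list of `run_result`, one per window, each carrying a
#'   `bias_energies` matrix (frames x windows, kBT).
#' @export
run_umbrella_set <- function(cx, windows, params) {
  stopifnot(inherits(windows, "window_set"))
  if (length(windows$centers) == 0) stop("window set is empty")
  runs <- vector("list", length(windows$centers))
  for (w in seq_along(windows$centers)) {
    bias <- umbrella_bias(windows$centers[w], windows$spring_k)
    pw <- params
    pw$seed <- params$seed + w
    start <- start_at_distance(cx, windows$centers[w])
    runs[[w]] <- run_langevin(cx, pw, start = start, bias = bias)
    runs[[w]]$bias_energies <- window_bias_energies(runs[[w]], windows)
  }
  runs
}

# Rigidly translate chain B so the COM separation equals d0 (direction of the
# reference displacement, +x if the chains are concentric).
start_at_distance <- function(cx, d0) {
  pos <- cx$reference
  a <- seq_len(cx$nA); b <- cx$nA + seq_len(cx$nB)
  ca <- colSums(pos[a, , drop = FALSE] * cx$mass[a]) / sum(cx$mass[a])
  cb <- colSums(pos[b, , drop = FALSE] * cx$mass[b]) / sum(cx$mass[b])
  v <- cb - ca
  d <- sqrt(sum(v^2))
  u <- if (d > 1e-12) v / d else c(1, 0, 0)
  pos[b, ] <- sweep(pos[b, , drop = FALSE], 2, (d0 - d) * u, "+")
  pos
}

#' Bias energies of a run's frames in every window potential
#'
#' @param run a `run_result`.
#' @param windows a [make_window_grid()] object.
#' @return frames x windows matrix of reduced bias energies u_k(x)/kBT.
#' @export
window_bias_energies <- function(run, windows) {
  d <- com_series(run)
  kt <- kBT(run$params$temperature)
  outer(d, windows$centers,
        function(di, ck) 0.5 * windows$spring_k * (di - ck)^2 / kt)
}

# Per-frame COM separation of a run (A).
com_series <- function(run) {
  cx <- run$cx
  a <- seq_len(cx$nA); b <- cx$nA + seq_len(cx$nB)
  ma <- cx$mass[a] / sum(cx$mass[a])
  mb <- cx$mass[b] / sum(cx$mass[b])
  n <- cx$n
  xs <- run$frames[, seq(1, 3 * n, by = 3), drop = FALSE]
  ys <- run$frames[, seq(2, 3 * n, by = 3), drop = FALSE]
  zs <- run$frames[, seq(3, 3 * n, by = 3), drop = FALSE]
  dx <- xs[, a, drop = FALSE] %*% ma - xs[, b, drop = FALSE] %*% mb
  dy <- ys[, a, drop = FALSE] %*% ma - ys[, b, drop = FALSE] %*% mb
  dz <- zs[, a, drop = FALSE] %*% ma - zs[, b, drop = FALSE] %*% mb
  as.numeric(sqrt(dx^2 + dy^2 + dz^2))
}
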