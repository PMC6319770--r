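# Synthetic two-channel time-lapse generator with known ground truth.
# The dye channel is the z-projection of per-cell radial reaction-diffusion
# solutions; the reference channel is a constant filled ellipse (a stable
# nuclear-localisation marker). A shared depleting bath couples the cells;
# it is handled by a two-pass mean-field scheme: one average-cell solve
# with the coupled bath yields u_ext(t), which then forces each per-cell
# solve.

#' Configuration of a synthetic cell population
#'
#' Defaults are sized for desk-scale runs (256 x 256 px, 0.65 um/px, 50
#' frames at 60 s, <= 30 cells). Heterogeneity defaults emulate the
#' observed population structure: a 60/40 G1/G2 capacity bimodality (G2
#' cells carry twice the DNA), ~12% intra-class capacity variability
#' (steady-state intensity CV ~0.12-0.15), and a log-normal membrane
#' coefficient whose CV of 0.7 yields a fitted relaxation-rate CV of
#' ~0.6: the rate responds sub-linearly to `h_m` (elasticity ~0.8 at the
#' default operating point) but also inherits the geometry and capacity
#' spread. The movie ends at 18 h (an overnight incubation) so that even
#' slow cells reach their plateau before the classification frames.
#'
#' @param n_cells number of nuclei.
#' @param frame_dim frame size, pixels (rows, cols).
#' @param pixel_size um per pixel.
#' @param n_frames frames in the movie.
#' @param dt frame interval of the dense early phase, s.
#' @param total_time movie end time, s. The default schedule is
#'   two-phase: `n_frames - 9` dense frames at `dt` resolve the uptake
#'   kinetics, then 9 log-spaced frames reach `total_time` so that even
#'   the slowest cells are at their steady-state plateau for the final
#'   frames (classification uses the last frames).
#' @param frame_times optional explicit frame timestamps, s (overrides
#'   `n_frames`/`dt`/`total_time`).
#' @param a_mean mean major semi-axis, um; `a_cv` its log-normal CV.
#' @param a_cv see `a_mean`.
#' @param ab_ratio range of the axis ratio b/a (uniform).
#' @param hm_median median membrane coefficient, um/s.
#' @param hm_cv log-normal CV of the membrane coefficient.
#' @param c0 G1 specific capacity, uM; G2 cells get twice this.
#' @param g2_fraction fraction of cells in G2.
#' @param capacity_cv intra-class log-normal CV of total site number.
#' @param cn_ratio non-specific to specific capacity ratio.
#' @param dye_conc initial bath dye concentration, uM.
#' @param protocol optional [protocol_spec()] (default: single addition
#'   at time zero via `dye_conc`).
#' @param well_volume_ul,well_cells shared-bath well volume and cell
#'   count (the bath couples all cells in the well, not only those in the
#'   rendered field of view).
#' @param gain photon gain: shot-noise variance is `intensity / gain`;
#'   `Inf` disables shot noise.
#' @param read_sd additive Gaussian read noise SD.
#' @param jitter_sd per-frame rigid stage-jitter SD, pixels.
#' @param ref_level reference-channel plateau intensity, a.u.
#' @param nr radial nodes per cell in the forward model.
#' @param D free-dye diffusion coefficient, um^2/s.
#' @param seed RNG seed (full reproducibility).
#' @return object of class `population_config`.
#' @export
population_config <- function(n_cells = 25, frame_dim = c(256, 256),
                              pixel_size = 0.65, n_frames = 50, dt = 60,
                              total_time = 64800, frame_times = NULL,
                              a_mean = 7, a_cv = 0.08,
                              ab_ratio = c(0.7, 0.95),
                              hm_median = 1.5, hm_cv = 0.7,
                              c0 = 25, g2_fraction = 0.4,
                              capacity_cv = 0.12, cn_ratio = 100,
                              dye_conc = 1, protocol = NULL,
                              well_volume_ul = 150, well_cells = 5e4,
                              gain = 5, read_sd = 2, jitter_sd = 0.5,
                              ref_level = 500, nr = 48, D = 500,
                              seed = 1) {
  stopifnot(n_cells >= 1, n_frames >= 2, length(frame_dim) == 2)
  if (g2_fraction < 0 || g2_fraction > 1)
    stop_domain("g2_fraction must be in [0, 1]")
  for (nm in c("pixel_size", "dt", "a_mean", "hm_median", "c0",
               "dye_conc", "ref_level"))
    check_num(get(nm), nm, lower = 0, len = 1)
  if (!is.null(protocol)) stopifnot(inherits(protocol, "protocol_spec"))
  if (is.null(frame_times)) {
    n1 <- max(n_frames - 9, 2)
    t1 <- seq(0, by = dt, length.out = n1)
    frame_times <- if (n_frames > n1 && total_time > max(t1) * 1.2)
      c(t1, exp(seq(log(max(t1) * 1.2), log(total_time),
                    length.out = n_frames - n1)))
    else t1
  }
  if (is.unsorted(frame_times, strictly = TRUE))
    stop_domain("frame_times must be strictly increasing")
  n_frames <- length(frame_times)
  structure(as.list(environment()), class = "population_config")
}

#' Sample per-cell ground truth
#'
#' Samples nucleus geometry, membrane coefficient, cell-cycle class and
#' binding capacity for each cell and places the nuclei without overlap.
#' Capacities are stored as concentrations scaled by the cell's volume so
#' that the *total* site number (hence steady-state intensity) carries
#' the class factor and the intra-class CV, independent of nuclear size.
#' Deterministic under the configuration seed.
#'
#' @param config a [population_config()].
#' @return data.frame of class `ground_truth`, one row per cell: `id`,
#'   placement (`x0`, `y0`, pixels), geometry (`a_um`, `b_um`, `theta`,
#'   `R_n`), `h_m`, `cls` ("G1"/"G2"), `capacity` (uM), `beta_true`
#'   (filled by [render_stack()]).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  n <- config$n_cells
  sdl <- function(cv) sqrt(log(1 + cv^2))
  a_um <- rlnorm(n, log(config$a_mean), sdl(config$a_cv))
  b_um <- a_um * runif(n, config$ab_ratio[1], config$ab_ratio[2])
  theta <- runif(n, 0, pi)
  h_m <- rlnorm(n, log(config$hm_median), sdl(config$hm_cv))
  cls <- ifelse(runif(n) < config$g2_fraction, "G2", "G1")
  site_factor <- rlnorm(n, -sdl(config$capacity_cv)^2 / 2,
                        sdl(config$capacity_cv))
  b_ref <- config$a_mean * mean(config$ab_ratio)
  V_ref <- (4 / 3) * pi * config$a_mean * b_ref^2
  V <- (4 / 3) * pi * a_um * b_um^2
  capacity <- config$c0 * ifelse(cls == "G2", 2, 1) * site_factor * V_ref / V
  R_n <- (a_um * b_um^2)^(1 / 3)
  # non-overlapping placement (0-based pixel coordinates, x = column)
  a_px <- a_um / config$pixel_size
  H <- config$frame_dim[1]; W <- config$frame_dim[2]
  pad <- a_px + 3
  if (max(2 * pad) >= min(W, H))
    stop_domain("infeasible geometry: nuclei larger than the frame")
  x0 <- y0 <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 20000L)
      stop_domain("infeasible geometry: could not place ", n,
                  " non-overlapping nuclei in a ", H, " x ", W, " frame")
    i <- placed + 1L
    cx <- runif(1, pad[i], W - 1 - pad[i])
    cy <- runif(1, pad[i], H - 1 - pad[i])
    if (placed > 0) {
      j <- seq_len(placed)
      if (any((x0[j] - cx)^2 + (y0[j] - cy)^2 <
              (a_px[j] + a_px[i] + 4)^2)) next
    }
    x0[i] <- cx; y0[i] <- cy
    placed <- i
  }
  out <- data.frame(id = seq_len(n), x0 = x0, y0 = y0, a_um = a_um,
                    b_um = b_um, theta = theta, R_n = R_n, h_m = h_m,
                    cls = cls, capacity = capacity,
                    beta_true = NA_real_)
  class(out) <- c("ground_truth", "data.frame")
  attr(out, "config") <- config
  out
}

#' Apply shot and read noise to frames
#'
#' Photon (Poisson) noise scaled by the gain -- the detected value is
#' `rpois(gain * I) / gain`, so a flat field at level `L` acquires
#' variance `L / gain` -- followed by additive Gaussian read noise,
#' clipped at zero. `gain = Inf` with `read_sd = 0` leaves frames
#' unchanged.
#'
#' @param frames a matrix or list of matrices (non-negative).
#' @param gain photon gain (> 0, may be `Inf`).
#' @param read_sd read-noise SD (>= 0).
#' @param seed optional RNG seed.
#' @return same shape as `frames`.
#' @export
apply_noise <- function(frames, gain, read_sd, seed = NULL) {
  if (!is.numeric(gain) || length(gain) != 1 || is.na(gain) || gain <= 0)
    stop_domain("gain must be > 0")
  check_num(read_sd, "read_sd", lower = 0, len = 1)
  if (!is.null(seed)) set.seed(seed)
  one <- function(m) {
    if (any(m < 0)) stop_domain("frames must be non-negative")
    x <- if (is.finite(gain)) {
      matrix(rpois(length(m), gain * m) / gain, nrow(m), ncol(m))
    } else m
    if (read_sd > 0)
      x <- x + matrix(rnorm(length(m), 0, read_sd), nrow(m), ncol(m))
    pmax(x, 0)
  }
  if (is.list(frames)) lapply(frames, one) else one(frames)
}

# Stamp one cell's projected profile into a frame (in place via return).
stamp_cell <- function(frame, prof, cx, cy, a_px, b_px, theta) {
  H <- nrow(frame); W <- ncol(frame)
  rmax <- ceiling(a_px) + 2
  xs <- max(0, floor(cx - rmax)):min(W - 1, ceiling(cx + rmax))
  ys <- max(0, floor(cy - rmax)):min(H - 1, ceiling(cy + rmax))
  ell <- list(center = c(cx, cy), a = a_px, b = b_px, theta = theta)
  rho <- outer(ys, xs, function(y, x) elliptic_radius(x, y, ell))
  inside <- rho <= 1
  if (any(inside)) {
    vals <- approx(prof$rho, prof$P, xout = rho[inside], rule = 2)$y
    block <- frame[ys + 1, xs + 1]
    block[inside] <- block[inside] + vals
    frame[ys + 1, xs + 1] <- block
  }
  frame
}

#' Render a synthetic two-channel time-lapse stack
#'
#' Runs the buffered reaction-diffusion forward model for every cell
#' (membrane coefficient, capacity and geometry from the ground truth),
#' with the shared depleting bath resolved by a mean-field average-cell
#' pass whose `u_ext(t)` trajectory forces the per-cell solves. Each
#' frame projects the specifically bound dye through the spheroid at the
#' cell's (stage-jittered) position; the reference channel is a constant
#' filled ellipse. Noise is applied last.
#'
#' @param truth a `ground_truth` from [generate_population()].
#' @param config the matching [population_config()] (default: the one
#'   attached to `truth`).
#' @return object of class `synthetic_stack`: lists `ref` and `dye` of
#'   per-frame matrices, `times`, `pixel_size`, `truth` (with
#'   `beta_true` filled), `shifts` (per-frame stage offsets), `u_ext`
#'   (bath trajectory), `config`.
#' @export
render_stack <- function(truth, config = attr(truth, "config")) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "population_config"))
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  times <- config$frame_times
  defaults <- dye_defaults()
  spec_site <- function(cap) binding_site(
    k_off = defaults$specific$k_off, K_d = defaults$specific$K_d,
    capacity = cap)
  ns_site <- function(cap) binding_site(
    k_off = defaults$nonspecific$k_off, K_d = defaults$nonspecific$K_d,
    capacity = config$cn_ratio * cap)
  # mean-field bath pass
  t_fine <- sort(unique(c(seq(0, max(times), length.out = 4 * length(times)),
                          times)))
  avg <- simulate_nonspecific(
    nucleus_geometry(R_n = mean(truth$R_n), nr = config$nr),
    transport_params(D = config$D, h_m = mean(truth$h_m)),
    spec_site(mean(truth$capacity)), ns_site(mean(truth$capacity)),
    bath_state(config$dye_conc, config$well_volume_ul, config$well_cells,
               depleting = TRUE),
    config$protocol, t_fine)
  u_fun <- approxfun(t_fine, avg$u_ext, rule = 2)
  # per-cell forward solves
  H <- config$frame_dim[1]; W <- config$frame_dim[2]
  shifts <- cbind(x = c(0, rnorm(config$n_frames - 1, 0, config$jitter_sd)),
                  y = c(0, rnorm(config$n_frames - 1, 0, config$jitter_sd)))
  dye <- rep(list(matrix(0, H, W)), config$n_frames)
  ref <- rep(list(matrix(0, H, W)), config$n_frames)
  beta_true <- numeric(n)
  for (i in seq_len(n)) {
    st <- simulate_nonspecific(
      nucleus_geometry(R_n = truth$R_n[i], nr = config$nr),
      transport_params(D = config$D, h_m = truth$h_m[i]),
      spec_site(truth$capacity[i]), ns_site(truth$capacity[i]),
      bath_state(u_fun(0), config$well_volume_ul, config$well_cells,
                 depleting = FALSE, u_fun = u_fun),
      config$protocol, times)
    I_gen <- drop(st$v %*% st$vol) / sum(st$vol)
    beta_true[i] <- fit_relaxation(times, I_gen)$beta
    a_px <- truth$a_um[i] / config$pixel_size
    b_px <- truth$b_um[i] / config$pixel_size
    for (f in seq_len(config$n_frames)) {
      prof <- project_profile(st$r / truth$R_n[i], st$v[f, ],
                              z_half = truth$b_um[i],
                              n_rho = 160, n_z = 64)
      cx <- truth$x0[i] + shifts[f, 1]
      cy <- truth$y0[i] + shifts[f, 2]
      dye[[f]] <- stamp_cell(dye[[f]], prof, cx, cy, a_px, b_px,
                             truth$theta[i])
      ref[[f]] <- stamp_cell(ref[[f]],
                             list(rho = c(0, 1), P = rep(config$ref_level, 2)),
                             cx, cy, a_px, b_px, truth$theta[i])
    }
  }
  truth$beta_true <- beta_true
  if (is.finite(config$gain) || config$read_sd > 0) {
    dye <- apply_noise(dye, config$gain, config$read_sd,
                       seed = config$seed + 2L)
    ref <- apply_noise(ref, config$gain, config$read_sd)
  }
  structure(list(ref = ref, dye = dye, times = times,
                 pixel_size = config$pixel_size, truth = truth,
                 shifts = shifts,
                 u_ext = data.frame(t = t_fine, u_ext = avg$u_ext),
                 config = config),
            class = "synthetic_stack")
}

#' @export
print.synthetic_stack <- function(x, ...) {
  cat("Synthetic stack:", nrow(x$truth), "cells,", length(x$times),
      "frames of", nrow(x$ref[[1]]), "x", ncol(x$ref[[1]]), "px at",
      x$pixel_size, "um/px\n")
  invisible(x)
}

#' Analyse a time-lapse stack with the imaging pipeline
#'
#' Segments the reference channel, tracks nuclei, extracts per-cell
#' records from the dye channel (median background subtraction),
#' computes traces and relaxation fits, and assembles population
#' statistics. When ground truth is available (synthetic input), cells
#' are matched to it by first-frame position.
#'
#' @param stack a `synthetic_stack`, or a directory written by
#'   [write_stack()].
#' @param min_area,max_displacement segmentation / tracking parameters.
#' @param damage optional per-cell damage-marker intensities (matched by
#'   cell order).
#' @param damage_threshold dichotomisation threshold, a.u.
#' @return object of class `stack_analysis`: `records`, `traces`,
#'   `cells` (per-cell summary, with `truth_id` when matched),
#'   `population` (a `population_summary`).
#' @export
analyze_stack <- function(stack, min_area = 64, max_displacement = 15,
                          damage = NULL, damage_threshold = 100) {
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "synthetic_stack"))
  labels <- lapply(stack$ref, segment_nuclei, min_area = min_area)
  tracks <- track_nuclei(labels, max_displacement = max_displacement)
  records <- extract_records(stack$dye, labels, tracks, stack$times)
  traces <- lapply(records, intensity_traces)
  cells <- summarize_records(records)
  if (!is.null(stack$truth)) {
    first <- tracks[tracks$frame == 1, ]
    cells$truth_id <- NA_integer_
    for (k in seq_len(nrow(cells))) {
      row <- first[first$track == cells$cell_id[k], ]
      if (!nrow(row)) next
      d2 <- (stack$truth$x0 - row$cx[1])^2 + (stack$truth$y0 - row$cy[1])^2
      if (min(d2) < 100) cells$truth_id[k] <- stack$truth$id[which.min(d2)]
    }
  }
  population <- population_stats(cells, damage = damage,
                                 damage_threshold = damage_threshold)
  structure(list(records = records, traces = traces, cells = cells,
                 population = population, stack = stack),
            class = "stack_analysis")
}

#' @export
print.stack_analysis <- function(x, ...) {
  cat("Stack analysis:", length(x$records), "tracked nuclei\n")
  print(x$population)
  invisible(x)
}
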