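# Chord-integrated projection of a radial field through a sphere/ellipsoid.
# At normalised planar radius rho the projected value is
#   P(rho) = 2 * z_half * int_0^sqrt(1-rho^2) f(sqrt(rho^2 + z^2)) dz
# with z in units of the half-thickness z_half (um).

project_profile <- function(r_norm, values, z_half, n_rho = 256, n_z = 96) {
  rho <- seq(0, 1, length.out = n_rho)
  fint <- approxfun(c(0, r_norm, 1), c(values[1], values,
                                       values[length(values)]), rule = 2)
  P <- vapply(rho, function(s) {
    zmax <- sqrt(max(1 - s^2, 0))
    if (zmax == 0) return(0)
    z <- seq(0, zmax, length.out = n_z)
    f <- fint(sqrt(s^2 + z^2))
    2 * z_half * sum((f[-1] + f[-n_z]) / 2) * (zmax / (n_z - 1))
  }, 0)
  list(rho = rho, P = P)
}

#' Project a radial bound-dye field to a 2-D image
#'
#' Renders the confocal-plane view of one stored time point: the image
#' value at planar elliptic radius `rho` is the line integral of the
#' specifically bound dye along z through the spheroid (chord-weighted);
#' pixels outside the projected boundary are zero. A uniform field
#' therefore projects to a profile proportional to the chord length
#' `sqrt(1 - rho^2)`.
#'
#' @param state an `rd_state`.
#' @param frame index into `state$times`.
#' @param pixel_size pixel size, um (must not exceed `R_n`).
#' @param field which field to project (`"v"`, `"u"`, `"vn"`).
#' @param ligand ligand index.
#' @return numeric matrix (image, arbitrary units of uM * um), with the
#'   generating ellipse (pixel units) attached as attribute `"ellipse"`.
#' @export
project_intensity <- function(state, frame = length(state$times),
                              pixel_size = 0.65, field = "v", ligand = 1) {
  stopifnot(inherits(state, "rd_state"))
  geom <- state$geometry
  if (pixel_size > geom$R_n)
    stop_domain("pixel size exceeds the nuclear radius")
  vals <- state$ligands[[ligand]][[field]][frame, ]
  prof <- project_profile(state$r / geom$R_n, vals, z_half = geom$b)
  a_px <- geom$a / pixel_size
  b_px <- geom$b / pixel_size
  nx <- 2L * ceiling(a_px) + 3L
  ny <- 2L * ceiling(b_px) + 3L
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  xs <- (seq_len(nx) - 1 - cx) / a_px
  ys <- (seq_len(ny) - 1 - cy) / b_px
  rho <- sqrt(outer(ys^2, xs^2, `+`))
  img <- matrix(0, ny, nx)
  inside <- rho <= 1
  img[inside] <- approx(prof$rho, prof$P, xout = rho[inside], rule = 2)$y
  attr(img, "ellipse") <- list(center = c(cx, cy), a = a_px, b = b_px,
                               theta = 0)
  img
}

#' Whole-nucleus traces of a reaction-diffusion solution
#'
#' Computes the volume-averaged bound dye `I_tot(t)` (per unit volume; the
#' simulated analogue of total fluorescence), its normalised form
#' `I_tot(t)/I_tot(T)`, and the image moment `M_2(t)` of the projected
#' frames via the imaging module's moment operation.
#'
#' @param state an `rd_state`.
#' @param frames indices of time points to project for `M_2` (default:
#'   all stored times).
#' @param pixel_size rendering pixel size for the moment images, um.
#' @param include_nonspecific if `TRUE`, add the non-specifically bound
#'   dye into `I_tot` (off by default: fluorescence reports minor-groove
#'   binding only).
#' @param ligand ligand index.
#' @return object of class `moment_trace` with `times`, `I_tot`,
#'   `I_norm`, `M2`.
#' @export
trace_outputs <- function(state, frames = seq_along(state$times),
                          pixel_size = state$geometry$R_n / 48,
                          include_nonspecific = FALSE, ligand = 1) {
  stopifnot(inherits(state, "rd_state"))
  lg <- state$ligands[[ligand]]
  f <- lg$v
  if (include_nonspecific) f <- f + lg$vn
  I_tot <- drop(f %*% state$vol) / sum(state$vol)
  M2 <- vapply(frames, function(i) {
    img <- project_intensity(state, i, pixel_size, ligand = ligand)
    if (sum(img) <= 0) return(NA_real_)
    image_moments(img, attr(img, "ellipse"), orders = 2)[["M2"]]
  }, 0)
  structure(list(times = state$times, I_tot = I_tot,
                 I_norm = I_tot / I_tot[length(I_tot)],
                 M2_times = state$times[frames], M2 = M2),
            class = "moment_trace")
}

#' @export
print.moment_trace <- function(x, ...) {
  cat("Moment trace:", length(x$times), "time points\n")
  cat("  final I_tot =", signif(x$I_tot[length(x$I_tot)], 5), "\n")
  if (!is.null(x$M2)) {
    m2 <- x$M2[!is.na(x$M2)]
    if (length(m2))
      cat("  M2:", signif(m2[1], 4), "->", signif(m2[length(m2)], 4), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.moment_trace <- function(x, ...) {
  df <- data.frame(t = x$times, I_tot = x$I_tot, I_norm = x$I_norm)
  if (!is.null(x$M2)) df$M2 <- x$M2[match(x$times, x$M2_times)]
  if (!is.null(x$CV_p)) df$CVp <- x$CV_p
  if (!is.null(x$I_sub)) df$I_sub <- x$I_sub
  df
}
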