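# Imaging conventions: pixel centres at 0-based coordinates (x = column - 1,
# y = row - 1); the normalised elliptic radius is 1 on the fitted ellipse
# boundary, so geometric reference moments are dimensionless constants.

#' Normalised elliptic radius of pixel coordinates
#'
#' `r = sqrt(x'^2/a^2 + y'^2/b^2)` in the frame of a fitted ellipse
#' (centre subtracted, rotated by the orientation); `r = 1` on the
#' boundary.
#'
#' @param x,y 0-based pixel coordinates.
#' @param ellipse list with `center` (x, y), semi-axes `a`, `b` (pixels)
#'   and orientation `theta` (radians).
#' @return numeric vector of radii.
#' @export
elliptic_radius <- function(x, y, ellipse) {
  dx <- x - ellipse$center[1]
  dy <- y - ellipse$center[2]
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  xr <- ct * dx + st * dy
  yr <- -st * dx + ct * dy
  sqrt((xr / ellipse$a)^2 + (yr / ellipse$b)^2)
}

#' Image moments of the pixel intensity distribution
#'
#' `M_n = sum_j I_j r_j^n / sum_j I_j` with `r_j` the normalised elliptic
#' radius of pixel `j`. Because the radius is normalised to the fitted
#' ellipse, the moments are invariant under translation, rotation and
#' spatial rescaling of the image (with the ellipse co-transformed).
#'
#' @param intensity numeric matrix of pixel intensities (>= 0), or a
#'   vector when `coords` is supplied.
#' @param ellipse ellipse as in [elliptic_radius()].
#' @param orders integer vector of moment orders.
#' @param coords optional 2-column matrix of 0-based (x, y) pixel
#'   coordinates matching a vector `intensity`.
#' @return named numeric vector `M<order>`.
#' @export
image_moments <- function(intensity, ellipse, orders = 2, coords = NULL) {
  if (is.null(coords)) {
    stopifnot(is.matrix(intensity))
    coords <- cbind(x = rep(seq_len(ncol(intensity)) - 1,
                            each = nrow(intensity)),
                    y = rep(seq_len(nrow(intensity)) - 1,
                            times = ncol(intensity)))
    intensity <- as.vector(intensity)
  }
  if (any(intensity < 0)) stop_domain("intensities must be >= 0")
  tot <- sum(intensity)
  if (tot <= 0) stop_domain("moments undefined: all-zero intensity")
  r <- elliptic_radius(coords[, 1], coords[, 2], ellipse)
  out <- vapply(orders, function(n) sum(intensity * r^n) / tot, 0)
  names(out) <- paste0("M", orders)
  out
}

#' Geometric reference values of the projected second moment
#'
#' The second moment `M_2` of the z-projection (chord integral) of simple
#' uniform-density shapes, in normalised-radius units: a solid ball gives
#' 2/5, an infinitesimally thin shell 2/3, and a thick shell of inner
#' radius fraction `f` an intermediate value. These are the reference
#' lines against which measured `M_2(t)` traces are read: front
#' propagation starts near the thin-shell value and relaxes towards the
#' solid-ball value as the nucleus fills in.
#'
#' @param shape one of `"solid-ball"`, `"thin-shell"`, `"thick-shell"`.
#' @param f inner-radius fraction of the thick shell, in (0, 1); the
#'   default 3/4 corresponds to a shell of thickness R/4.
#' @return the reference `M_2` value.
#' @export
reference_m2 <- function(shape = c("solid-ball", "thin-shell",
                                   "thick-shell"), f = 0.75) {
  shape <- match.arg(shape)
  proj <- switch(shape,
    "solid-ball" = function(r) sqrt(pmax(1 - r^2, 0)),
    "thin-shell" = function(r) 1 / sqrt(pmax(1 - r^2, 1e-300)),
    "thick-shell" = {
      if (f <= 0 || f >= 1) stop_domain("f must be in (0, 1)")
      function(r) sqrt(pmax(1 - r^2, 0)) - sqrt(pmax(f^2 - r^2, 0))
    })
  num <- integrate(function(r) proj(r) * r^3, 0, 1,
                   rel.tol = 1e-10)$value
  den <- integrate(function(r) proj(r) * r, 0, 1,
                   rel.tol = 1e-10)$value
  num / den
}

#' Segment nuclei in a reference-channel frame
#'
#' Binarises the nuclear-marker channel (Otsu threshold by default),
#' fills holes, labels connected components and removes objects below
#' `min_area`. The dye channel never influences segmentation.
#'
#' @param frame single-channel 2-D numeric matrix.
#' @param min_area minimum object area, pixels.
#' @param threshold `"otsu"` or `"fixed"`.
#' @param value threshold value when `threshold = "fixed"`.
#' @return integer label matrix (0 = background); a blank frame yields an
#'   all-zero labelling.
#' @export
segment_nuclei <- function(frame, min_area = 64,
                           threshold = c("otsu", "fixed"), value = NULL) {
  threshold <- match.arg(threshold)
  stopifnot(is.matrix(frame))
  rng <- range(frame)
  if (rng[2] <= rng[1])
    return(matrix(0L, nrow(frame), ncol(frame)))
  if (threshold == "otsu") {
    norm <- (frame - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > th
  } else {
    if (is.null(value)) stop_domain("fixed threshold requires a value")
    mask <- frame > value
  }
  lbl <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(mask)))
  lbl <- EBImage::imageData(lbl)
  if (max(lbl) > 0) {
    sizes <- tabulate(lbl[lbl > 0])
    keep <- which(sizes >= min_area)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lbl[lbl > 0] <- relab[lbl[lbl > 0]]
  }
  matrix(as.integer(lbl), nrow(frame), ncol(frame))
}

label_centroids <- function(lbl) {
  ids <- sort(unique(lbl[lbl > 0]))
  if (!length(ids))
    return(data.frame(label = integer(0), cx = numeric(0), cy = numeric(0),
                      area = integer(0)))
  idx <- which(lbl > 0, arr.ind = TRUE)
  lab <- lbl[lbl > 0]
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  data.frame(label = ids,
             cx = as.numeric(tapply(x, lab, mean)),
             cy = as.numeric(tapply(y, lab, mean)),
             area = as.integer(tabulate(lab)[ids]))
}

#' Track nuclei across frames
#'
#' Greedy nearest-centroid matching within a displacement gate: at each
#' frame transition, candidate pairs are sorted by centroid distance and
#' accepted in order (ties broken by smallest distance, then smallest
#' label); unmatched objects terminate or start tracks.
#'
#' @param labels list of integer label matrices, one per frame.
#' @param max_displacement matching gate, pixels.
#' @return data.frame with columns `track`, `frame`, `label`, `cx`, `cy`,
#'   `area`.
#' @export
track_nuclei <- function(labels, max_displacement = 15) {
  stopifnot(is.list(labels), length(labels) >= 1)
  cents <- lapply(labels, label_centroids)
  out <- list()
  next_track <- 1L
  prev <- cents[[1]]
  prev$track <- if (nrow(prev)) seq_len(nrow(prev)) else integer(0)
  next_track <- nrow(prev) + 1L
  out[[1]] <- cbind(frame = 1L, prev)
  for (f in seq_along(cents)[-1]) {
    cur <- cents[[f]]
    cur$track <- NA_integer_
    if (nrow(prev) && nrow(cur)) {
      dmat <- outer(prev$cx, cur$cx, `-`)^2 + outer(prev$cy, cur$cy, `-`)^2
      cand <- which(dmat <= max_displacement^2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand], prev$label[cand[, 1]], cur$label[cand[, 2]])
        used_p <- logical(nrow(prev)); used_c <- logical(nrow(cur))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_p[i] && !used_c[j]) {
            cur$track[j] <- prev$track[i]
            used_p[i] <- TRUE; used_c[j] <- TRUE
          }
        }
      }
    }
    new <- is.na(cur$track)
    if (any(new)) {
      cur$track[new] <- seq.int(next_track, length.out = sum(new))
      next_track <- next_track + sum(new)
    }
    out[[f]] <- cbind(frame = f, cur)
    prev <- cur
  }
  res <- do.call(rbind, out)
  res[, c("track", "frame", "label", "cx", "cy", "area")]
}

#' Fit an equivalent-area ellipse to a nucleus
#'
#' Centre = (intensity-weighted) centroid; orientation and axis ratio from
#' the eigen-decomposition of the second central moments; semi-axes scaled
#' so that the ellipse area equals the mask area (or, for weighted fits,
#' the pixel count).
#'
#' @param mask logical or 0/1 matrix, or `NULL` when `coords` given.
#' @param weights optional intensity weights (reference-channel values).
#' @param coords optional 2-column 0-based (x, y) coordinate matrix.
#' @return list with `center` (x, y), `a`, `b` (pixels, `a >= b`),
#'   `theta` (radians), `area` (pixels).
#' @export
fit_ellipse <- function(mask = NULL, weights = NULL, coords = NULL) {
  if (is.null(coords)) {
    stopifnot(is.matrix(mask))
    idx <- which(mask > 0, arr.ind = TRUE)
    if (!nrow(idx)) stop_domain("empty mask")
    coords <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
    if (!is.null(weights)) weights <- weights[idx]
  }
  n <- nrow(coords)
  if (n < 3) stop_domain("degenerate mask: fewer than 3 pixels")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (sum(w) <= 0) stop_domain("non-positive total weight")
  w <- w / sum(w)
  cx <- sum(w * coords[, 1]); cy <- sum(w * coords[, 2])
  dx <- coords[, 1] - cx; dy <- coords[, 2] - cy
  S <- matrix(c(sum(w * dx * dx), sum(w * dx * dy),
                sum(w * dx * dy), sum(w * dy * dy)), 2, 2)
  eg <- eigen(S, symmetric = TRUE)
  if (eg$values[2] <= .Machine$double.eps * eg$values[1])
    stop_domain("degenerate (collinear) mask")
  ratio <- sqrt(eg$values[1] / eg$values[2])
  area <- n
  a <- sqrt(area / pi * ratio)
  b <- sqrt(area / pi / ratio)
  theta <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  if (theta < 0) theta <- theta + pi  # orientation is mod pi
  list(center = c(cx, cy), a = a, b = b, theta = theta, area = area)
}

#' Per-cell record of a tracked nucleus
#'
#' Bundles, for one tracked nucleus, the per-frame mask pixel coordinates,
#' background-subtracted dye intensities and fitted ellipse. Built by
#' [extract_records()]; consumed by [record_moments()],
#' [radial_profile()] and [intensity_traces()].
#'
#' @param id track id.
#' @param times frame timestamps, s.
#' @param coords list (per frame) of 2-column 0-based coordinate matrices.
#' @param values list (per frame) of dye intensity vectors.
#' @param ellipses list (per frame) of ellipse fits.
#' @return object of class `nucleus_record`.
#' @export
nucleus_record <- function(id, times, coords, values, ellipses) {
  stopifnot(length(times) == length(coords),
            length(coords) == length(values),
            length(values) == length(ellipses))
  structure(list(id = id, times = times, coords = coords, values = values,
                 ellipses = ellipses), class = "nucleus_record")
}

#' @export
print.nucleus_record <- function(x, ...) {
  cat("Nucleus record", x$id, ":", length(x$times), "frames,",
      nrow(x$coords[[1]]), "pixels in frame 1\n")
  invisible(x)
}

#' Extract per-cell records from a segmented, tracked stack
#'
#' Applies the reference-channel masks to the dye channel, subtracts the
#' per-frame background (median of non-mask pixels) and collects
#' per-track [nucleus_record()]s. Tracks covering fewer than
#' `min_frames` frames are dropped.
#'
#' @param dye list of dye-channel matrices (one per frame).
#' @param labels list of label matrices from [segment_nuclei()].
#' @param tracks track table from [track_nuclei()].
#' @param times frame timestamps, s.
#' @param min_frames minimum track length retained.
#' @param background `"median"` (median of non-mask pixels, subtracted,
#'   clamped at zero) or `"none"`.
#' @return list of `nucleus_record`s.
#' @export
extract_records <- function(dye, labels, tracks, times,
                            min_frames = length(times),
                            background = c("median", "none")) {
  background <- match.arg(background)
  stopifnot(length(dye) == length(labels))
  bg <- vapply(seq_along(dye), function(f) {
    if (background == "none") return(0)
    out <- dye[[f]][labels[[f]] == 0]
    if (length(out)) median(out) else 0
  }, 0)
  keep <- names(which(table(tracks$track) >= min_frames))
  recs <- list()
  for (tr in as.integer(keep)) {
    sub <- tracks[tracks$track == tr, ]
    sub <- sub[order(sub$frame), ]
    coords <- values <- ellipses <- vector("list", nrow(sub))
    ok <- TRUE
    for (k in seq_len(nrow(sub))) {
      f <- sub$frame[k]
      idx <- which(labels[[f]] == sub$label[k], arr.ind = TRUE)
      if (!nrow(idx)) { ok <- FALSE; break }
      coords[[k]] <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
      values[[k]] <- pmax(dye[[f]][idx] - bg[f], 0)
      ellipses[[k]] <- fit_ellipse(coords = coords[[k]])
    }
    if (ok)
      recs[[length(recs) + 1]] <-
        nucleus_record(tr, times[sub$frame], coords, values, ellipses)
  }
  recs
}

#' Moments of one frame of a nucleus record
#'
#' @param record a [nucleus_record()].
#' @param frame frame index within the record.
#' @param orders moment orders.
#' @return named vector of moments.
#' @export
record_moments <- function(record, frame, orders = 2) {
  stopifnot(inherits(record, "nucleus_record"))
  image_moments(record$values[[frame]], record$ellipses[[frame]],
                orders = orders, coords = record$coords[[frame]])
}

#' Radial intensity profile of one frame
#'
#' Mean intensity in bins of the normalised elliptic radius; empty bins
#' are `NA` and flagged.
#'
#' @param record a [nucleus_record()].
#' @param frame frame index.
#' @param n_bins number of radial bins over [0, 1] (>= 2).
#' @return data.frame with `r_mid`, `intensity`, `n_pixels`; attribute
#'   `"empty_bins"` lists empty bins.
#' @export
radial_profile <- function(record, frame, n_bins = 20) {
  stopifnot(inherits(record, "nucleus_record"))
  if (n_bins < 2) stop_domain("need at least 2 bins")
  co <- record$coords[[frame]]
  r <- elliptic_radius(co[, 1], co[, 2], record$ellipses[[frame]])
  bins <- pmin(pmax(ceiling(r * n_bins), 1), n_bins)
  val <- record$values[[frame]]
  m <- rep(NA_real_, n_bins); np <- integer(n_bins)
  agg <- tapply(val, bins, mean)
  cnt <- table(bins)
  m[as.integer(names(agg))] <- agg
  np[as.integer(names(cnt))] <- as.integer(cnt)
  out <- data.frame(r_mid = (seq_len(n_bins) - 0.5) / n_bins,
                    intensity = m, n_pixels = np)
  attr(out, "empty_bins") <- which(np == 0)
  out
}

#' Intensity, moment and homogenisation traces of one nucleus
#'
#' Computes `I_tot(t)` (sum over the mask), the normalised
#' `I*_tot(t) = I_tot(t)/I_tot(T)`, the pixel coefficient of variation
#' `CV_p(t)`, the second moment `M_2(t)`, and the central sub-region
#' trace (the 10% of pixels with smallest elliptic radius, a
#' shape-preserving shrink of the nucleus).
#'
#' @param record a [nucleus_record()] with >= 2 frames.
#' @param subregion_fraction fraction of pixels in the central sub-region.
#' @return a `moment_trace` with `times`, `I_tot`, `I_norm`, `M2`,
#'   `CV_p`, `I_sub` (sub-region mean intensity), `sub_fraction`.
#' @export
intensity_traces <- function(record, subregion_fraction = 0.10) {
  stopifnot(inherits(record, "nucleus_record"))
  nt <- length(record$times)
  if (nt < 2) stop_domain("need at least 2 frames")
  I_tot <- M2 <- CV_p <- I_sub <- numeric(nt)
  for (k in seq_len(nt)) {
    val <- record$values[[k]]
    I_tot[k] <- sum(val)
    CV_p[k] <- if (mean(val) > 0) sd(val) / mean(val) else 0
    co <- record$coords[[k]]
    r <- elliptic_radius(co[, 1], co[, 2], record$ellipses[[k]])
    M2[k] <- if (I_tot[k] > 0) sum(val * r^2) / I_tot[k] else NA_real_
    n_sub <- max(1L, floor(subregion_fraction * length(val)))
    I_sub[k] <- mean(val[order(r)[seq_len(n_sub)]])
  }
  if (I_tot[nt] <= 0)
    stop_domain("normalisation undefined: zero total intensity at final frame")
  structure(list(times = record$times, I_tot = I_tot,
                 I_norm = I_tot / I_tot[nt], M2 = M2, M2_times = record$times,
                 CV_p = CV_p, I_sub = I_sub,
                 sub_fraction = subregion_fraction, id = record$id),
            class = "moment_trace")
}

#' Fit a saturating-exponential relaxation
#'
#' Least-squares fit of `I(t) = A (1 - exp(-beta t)) + B`, the operational
#' summary of uptake kinetics (the full buffered model is not a single
#' exponential; `beta` is the standard empirical relaxation rate, with
#' half-life `tau_1/2 = ln 2 / beta`).
#'
#' @param times time grid, s (>= 5 points).
#' @param y intensity trace.
#' @return object of class `relaxation_fit`: `beta`, `tau_half`, `A`,
#'   `B`, `beta_se`, `ci` (95%), `converged`, `fitted`. Non-convergence
#'   (e.g. a constant trace) is flagged, not an error.
#' @export
fit_relaxation <- function(times, y) {
  if (length(times) < 5 || length(y) != length(times))
    stop_domain("need >= 5 matching time points")
  bad <- structure(list(beta = NA_real_, tau_half = NA_real_, A = NA_real_,
                        B = NA_real_, beta_se = NA_real_,
                        ci = c(NA_real_, NA_real_), converged = FALSE,
                        fitted = rep(NA_real_, length(y))),
                   class = "relaxation_fit")
  if (sd(y) <= .Machine$double.eps * max(abs(y), 1)) return(bad)
  rise <- y - y[1]
  amp <- rise[length(rise)]
  t_half <- times[which(abs(rise) >= abs(amp) / 2)[1]]
  beta0 <- if (!is.na(t_half) && t_half > 0) log(2) / t_half
           else 1 / max(times[times > 0], 1)
  fit <- try(minpack.lm::nlsLM(
    y ~ A * (1 - exp(-beta * times)) + B,
    start = list(A = amp, beta = beta0, B = y[1]),
    lower = c(-Inf, 1e-10, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(bad)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))[["beta"]]
  dfree <- length(y) - 3
  ci <- cf[["beta"]] + c(-1, 1) * qt(0.975, dfree) * se
  structure(list(beta = cf[["beta"]], tau_half = log(2) / cf[["beta"]],
                 A = cf[["A"]], B = cf[["B"]], beta_se = se, ci = ci,
                 converged = TRUE, fitted = predict(fit)),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Relaxation fit: not converged (flagged)\n")
  } else {
    cat("Relaxation fit: beta =", signif(x$beta, 4), "s^-1 (tau_1/2 =",
        signif(x$tau_half / 60, 4), "min), 95% CI [",
        signif(x$ci[1], 4), ",", signif(x$ci[2], 4), "]\n")
  }
  invisible(x)
}

#' @export
coef.relaxation_fit <- function(object, ...) {
  c(beta = object$beta, A = object$A, B = object$B)
}
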