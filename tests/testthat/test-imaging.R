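# Imaging pipeline: segmentation, tracking, ellipse fits, moments, traces.

jaccard <- function(a, b) sum(a & b) / sum(a | b)

test_that("segmentation finds rendered nuclei and ignores blank frames", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
  f1 <- make_ellipse_image(n = 120, center = c(30, 36), a = 16, b = 11)
  f2 <- make_ellipse_image(n = 120, center = c(85, 80), a = 14, b = 10)
  frame <- 100 * (f1$img + f2$img) + 1
  lbl <- segment_nuclei(frame, min_area = 50)
  expect_equal(max(lbl), 2)
  for (fx in list(f1, f2)) {
    ids <- unique(lbl[fx$mask]); ids <- ids[ids > 0]
    expect_length(ids, 1)
    expect_gte(jaccard(lbl == ids, fx$mask), 0.95)
  }
  # objects below the minimum area are removed
  tiny <- matrix(0, 40, 40); tiny[20:21, 20:21] <- 1
  expect_equal(max(segment_nuclei(tiny, min_area = 10)), 0)
})

test_that("tracking preserves identity and splits on gate violations", {
  mk <- function(cx, cy) {
    e <- make_ellipse_image(n = 100, center = c(cx, cy), a = 10, b = 8)
    segment_nuclei(100 * e$img + 1, min_area = 20)
  }
  static <- replicate(6, mk(50, 50), simplify = FALSE)
  tr <- track_nuclei(static)
  expect_equal(unique(tr$track), 1L)
  expect_equal(nrow(tr), 6)
  # drift within the gate keeps identity; a jump beyond it splits
  drift <- lapply(c(50, 53, 56, 59), function(cx) mk(cx, 50))
  expect_equal(length(unique(track_nuclei(drift, 15)$track)), 1)
  jump <- list(mk(30, 30), mk(70, 70))
  expect_equal(length(unique(track_nuclei(jump, 10)$track)), 2)
})

test_that("equivalent-area ellipse fits recover axes and orientation", {
  e <- make_ellipse_image(n = 101, a = 30, b = 20)
  f <- fit_ellipse(e$img > 0)
  expect_equal(f$a, 30, tolerance = 0.02)
  expect_equal(f$b, 20, tolerance = 0.02)
  expect_equal(f$center, c(50, 50), tolerance = 1e-6)
  # disk: the two axes agree
  d <- make_ellipse_image(n = 81, a = 25, b = 25)
  fd <- fit_ellipse(d$img > 0)
  expect_lt(abs(fd$a - fd$b) / fd$b, 0.01)
  # rotation by 90 degrees swaps the axes and shifts the orientation
  r <- make_ellipse_image(n = 101, a = 30, b = 20, theta = pi / 2)
  fr <- fit_ellipse(r$img > 0)
  expect_equal(fr$a, 30, tolerance = 0.02)
  expect_equal(abs(sin(fr$theta - f$theta)), 1, tolerance = 1e-3)
  expect_error(fit_ellipse(matrix(0, 10, 10)), "empty")
  line <- matrix(0, 20, 20); line[10, 3:18] <- 1
  expect_error(fit_ellipse(line > 0), "degenerate")
})

test_that("intensity moments follow the elliptic-radius definition", {
  e <- make_ellipse_image(n = 121, a = 40, b = 28)
  # all intensity at the centre pixel: higher moments vanish
  centre <- matrix(0, 121, 121); centre[61, 61] <- 5
  m <- image_moments(centre, e$ellipse, orders = 1:3)
  expect_equal(unname(m), c(0, 0, 0))
  # uniform intensity on the ellipse: M2 = 1/2
  expect_equal(image_moments(e$img, e$ellipse)[["M2"]], 0.5,
               tolerance = 0.01)
  expect_error(image_moments(matrix(0, 5, 5), e$ellipse), "all-zero")
  expect_error(image_moments(matrix(-1, 5, 5), e$ellipse), ">= 0")
})

test_that("M2 is invariant under translation, rotation and rescaling", {
  base <- make_ellipse_image(n = 161, center = c(80, 80), a = 55, b = 38,
                             intensity = function(r) 1 + r^2)
  m0 <- image_moments(base$img, base$ellipse)[["M2"]]
  # integer translation with a co-translated ellipse: exact
  shifted <- matrix(0, 161, 161)
  shifted[11:161, 6:161] <- base$img[1:151, 1:156]
  ell_t <- base$ellipse; ell_t$center <- ell_t$center + c(5, 10)
  expect_equal(image_moments(shifted, ell_t)[["M2"]], m0, tolerance = 1e-12)
  # bilinear rotation with a co-rotated ellipse
  for (ang in c(33, 45, 120) * pi / 180) {
    rimg <- rotate_bilinear(base$img, ang, base$ellipse$center)
    ell_r <- base$ellipse; ell_r$theta <- ang
    m1 <- image_moments(rimg, ell_r)[["M2"]]
    expect_lt(abs(m1 - m0) / m0, 1e-3)
  }
  # 2x rescaling with a co-scaled ellipse (pixel replication)
  big <- base$img %x% matrix(1, 2, 2)
  ell_s <- list(center = 2 * base$ellipse$center + 0.5,
                a = 2 * base$ellipse$a, b = 2 * base$ellipse$b, theta = 0)
  expect_lt(abs(image_moments(big, ell_s)[["M2"]] - m0) / m0, 1e-3)
})

make_record <- function(values_by_frame, e, times = NULL) {
  nf <- length(values_by_frame)
  coords <- which(e$mask, arr.ind = TRUE)
  coords <- cbind(x = coords[, 2] - 1, y = coords[, 1] - 1)
  nucleus_record(1L, times %||% (seq_len(nf) - 1) * 60,
                 rep(list(coords), nf), values_by_frame,
                 rep(list(e$ellipse), nf))
}

test_that("radial profiles are flat for uniform images and flag empty bins", {
  e <- make_ellipse_image(n = 101, a = 30, b = 22)
  vals <- rep(3, sum(e$mask))
  rec <- make_record(list(vals, vals), e)
  pr <- radial_profile(rec, 1, n_bins = 10)
  expect_true(all(abs(pr$intensity - 3) < 1e-12))
  zero <- make_record(list(rep(0, sum(e$mask)), vals), e)
  expect_true(all(radial_profile(zero, 1, 10)$intensity == 0))
  expect_error(radial_profile(rec, 1, n_bins = 1), "2 bins")
})

test_that("radial profile of a front frame matches the generative profile", {
  fx <- rd_fixture(nr = 64)
  st <- simulate_nonspecific(fx$geom, fx$transport, fx$specific,
                             fx$nonspecific, bath_state(1, depleting = TRUE),
                             times = c(0, 240, 2400))
  img <- project_intensity(st, frame = 2, pixel_size = 0.2)
  ell <- attr(img, "ellipse")
  n <- nrow(img)
  coords <- cbind(x = rep(seq_len(ncol(img)) - 1, each = n),
                  y = rep(seq_len(n) - 1, ncol(img)))
  rho <- elliptic_radius(coords[, 1], coords[, 2], ell)
  keep <- rho <= 1
  rec <- nucleus_record(1L, c(0, 240), list(coords[keep, ], coords[keep, ]),
                        list(as.vector(img)[keep], as.vector(img)[keep]),
                        list(ell, ell))
  pr <- radial_profile(rec, 2, n_bins = 16)
  prof <- dyefront:::project_profile(st$r / fx$geom$R_n, st$v[2, ],
                                     z_half = fx$geom$b)
  oracle <- approx(prof$rho, prof$P, xout = pr$r_mid)$y
  expect_lt(sqrt(mean((pr$intensity - oracle)^2)) / mean(oracle), 0.02)
  # front frame: profile increases outward early on
  expect_gt(pr$intensity[14], pr$intensity[2])
})

test_that("intensity traces normalise, measure CV_p and the central sub-region", {
  e <- make_ellipse_image(n = 101, a = 30, b = 22)
  npix <- sum(e$mask)
  vals <- rep(2, npix)
  rec <- make_record(rep(list(vals), 4), e)
  tr <- intensity_traces(rec)
  expect_equal(tr$I_norm, rep(1, 4))
  expect_equal(tr$CV_p, rep(0, 4))
  expect_equal(tr$I_sub, rep(2, 4))
  expect_equal(tr$sub_fraction, 0.10)
  expect_error(intensity_traces(make_record(list(vals), e)), "2 frames")
  rec0 <- make_record(list(vals, rep(0, npix)), e)
  expect_error(intensity_traces(rec0), "zero total")
})

test_that("relaxation fitting recovers rates and flags degenerate traces", {
  times <- seq(0, 6000, by = 120)
  y <- 40 * (1 - exp(-1e-3 * times)) + 3
  fit <- fit_relaxation(times, y)
  expect_true(fit$converged)
  expect_equal(fit$beta, 1e-3, tolerance = 1e-3)
  expect_equal(fit$tau_half, log(2) / 1e-3, tolerance = 1e-3)
  expect_false(fit_relaxation(times, rep(5, length(times)))$converged)
  expect_error(fit_relaxation(1:3, 1:3), "5 matching")
  set.seed(8)
  fitn <- fit_relaxation(times, y + rnorm(length(y), 0, 0.5))
  expect_equal(fitn$beta, 1e-3, tolerance = 0.05)
  expect_true(fitn$ci[1] < 1e-3 && 1e-3 < fitn$ci[2])
})

test_that("a background offset removed by the median rule leaves outputs unchanged", {
  f1 <- make_ellipse_image(n = 90, center = c(30, 40), a = 14, b = 10)
  dye <- 50 * f1$img * (0.5 + 0.5 * 0)  # flat dye signal inside the nucleus
  dye_frames <- list(dye * 0.5, dye)
  labels <- replicate(2, segment_nuclei(200 * f1$img + 1, min_area = 20),
                      simplify = FALSE)
  tracks <- track_nuclei(labels)
  base_rec <- extract_records(dye_frames, labels, tracks, c(0, 60))[[1]]
  off_rec <- extract_records(lapply(dye_frames, `+`, 37), labels, tracks,
                             c(0, 60))[[1]]
  expect_equal(intensity_traces(off_rec)$I_tot,
               intensity_traces(base_rec)$I_tot, tolerance = 1e-12)
  expect_equal(record_moments(off_rec, 2), record_moments(base_rec, 2),
               tolerance = 1e-12)
})
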