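# Independent oracles used across the suite. Each solves the relevant
# problem by a route different from the package implementation
# (eigenfunction series, direct ODE integration, jump-chain sampling,
# inverse-map resampling), so agreement is a genuine cross-check.

# Analytic series for diffusion into a sphere, zero initial condition,
# Robin boundary D du/dr = h_m (u_ext - u) at r = R.
robin_sphere_series <- function(r, t, R, D, h_m, u_ext, nterms = 80) {
  Bi <- h_m * R / D
  roots <- vapply(seq_len(nterms), function(n) {
    uniroot(function(z) 1 - z / tan(z) - Bi,
            c((n - 1) * pi + 1e-9, n * pi - 1e-9), tol = 1e-13)$root
  }, 0)
  Cn <- 4 * (sin(roots) - roots * cos(roots)) / (2 * roots - sin(2 * roots))
  vapply(r, function(ri) {
    x <- roots * ri / R
    s <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
    u_ext * (1 - sum(Cn * exp(-roots^2 * D * t / R^2) * s))
  }, 0)
}

# Analytic series for the Dirichlet boundary (u = u_ext at r = R).
dirichlet_sphere_series <- function(r, t, R, D, u_ext, nterms = 200) {
  n <- seq_len(nterms)
  vapply(r, function(ri) {
    if (ri < 1e-12) {
      s <- sum((-1)^n * exp(-n^2 * pi^2 * D * t / R^2))
      return(u_ext * (1 + 2 * s))
    }
    s <- sum(((-1)^n / n) * sin(n * pi * ri / R) *
             exp(-n^2 * pi^2 * D * t / R^2))
    u_ext * (1 + (2 * R / (pi * ri)) * s)
  }, 0)
}

# Direct ODE integration of free-target mass-action kinetics at constant
# dye concentration u0.
ode_free_target <- function(k_on, k_off, capacity, u0, times) {
  sol <- deSolve::ode(
    y = c(v = capacity), times = times,
    func = function(t, y, p)
      list(-k_on * u0 * y + k_off * (capacity - y)),
    parms = NULL, rtol = 1e-12, atol = 1e-14)
  unname(sol[, "v"])
}

# Well-mixed three-pool oracle with membrane flux and depleting bath:
# interior free dye u, specifically bound v, non-specifically bound w.
wellmixed_threepool <- function(R, h_m, specific, nonspecific, u_ext0,
                                V_per_cell, times) {
  A_over_V <- 3 / R  # membrane area / nucleus volume
  Vn <- (4 / 3) * pi * R^3
  rhs <- function(t, y, p) {
    u <- y[1]; v <- y[2]; w <- y[3]; ue <- y[4]
    Rs <- specific$k_on * u * (specific$capacity - v) - specific$k_off * v
    Rn <- nonspecific$k_on * u * (nonspecific$capacity - w) -
      nonspecific$k_off * w
    flux <- h_m * (ue - u)
    list(c(A_over_V * flux - Rs - Rn, Rs, Rn,
           -4 * pi * R^2 * flux / V_per_cell))
  }
  sol <- deSolve::ode(y = c(0, 0, 0, u_ext0), times = times, func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  list(times = times, u = sol[, 2], v = sol[, 3], w = sol[, 4],
       u_ext = sol[, 5])
}

# Jump-chain sample of the two-state (free/bound) occupancy: alternating
# exponential sojourns, free first.
two_state_mc <- function(k_plus, k_minus, times, n, max_jumps = 60,
                         seed = 1) {
  set.seed(seed)
  dur <- matrix(0, n, max_jumps)
  odd <- seq(1, max_jumps, by = 2)
  dur[, odd] <- matrix(rexp(n * length(odd), k_plus), n)
  dur[, -odd] <- matrix(rexp(n * (max_jumps / 2), k_minus), n)
  jumps <- t(apply(dur, 1, cumsum))
  stopifnot(all(jumps[, max_jumps] > max(times)))
  vapply(times, function(t) {
    njump <- rowSums(jumps <= t)
    mean(njump %% 2 == 0)  # even number of jumps: back in the free state
  }, 0)
}

# Inverse-map bilinear rotation about an explicit centre (0-based pixel
# coordinates), independent of any package rendering code.
rotate_bilinear <- function(img, angle, center) {
  n <- nrow(img); m <- ncol(img)
  ct <- cos(-angle); st <- sin(-angle)
  xs <- rep(0:(m - 1), each = n) - center[1]
  ys <- rep(0:(n - 1), m) - center[2]
  sx <- ct * xs - st * ys + center[1]
  sy <- st * xs + ct * ys + center[2]
  i0 <- floor(sx); j0 <- floor(sy); fx <- sx - i0; fy <- sy - j0
  val <- function(ii, jj) {
    ok <- ii >= 0 & ii < m & jj >= 0 & jj < n
    v <- numeric(length(ii))
    v[ok] <- img[cbind(jj[ok] + 1, ii[ok] + 1)]
    v
  }
  v <- (1 - fx) * (1 - fy) * val(i0, j0) + fx * (1 - fy) * val(i0 + 1, j0) +
    (1 - fx) * fy * val(i0, j0 + 1) + fx * fy * val(i0 + 1, j0 + 1)
  matrix(v, n, m)
}

# Rendered axis-aligned (or rotated) solid ellipse fixture.
make_ellipse_image <- function(n = 101, center = c((n - 1) / 2, (n - 1) / 2),
                               a = 30, b = 20, theta = 0,
                               intensity = function(rho) rep(1, length(rho))) {
  xs <- matrix(rep(0:(n - 1), each = n), n)
  ys <- t(xs)
  ell <- list(center = center, a = a, b = b, theta = theta)
  rho <- elliptic_radius(as.vector(xs), as.vector(ys), ell)
  img <- matrix(0, n, n)
  inside <- rho <= 1
  img[matrix(inside, n)] <- intensity(rho[inside])
  list(img = img, mask = matrix(inside, n), ellipse = ell)
}

# Default-parameter shortcuts for reaction-diffusion tests.
rd_fixture <- function(nr = 96) {
  d <- dye_defaults()
  list(geom = nucleus_geometry(R_n = 10, nr = nr),
       transport = d$transport, specific = d$specific,
       nonspecific = d$nonspecific)
}

vol_avg <- function(state, field = "v", ligand = 1) {
  drop(state$ligands[[ligand]][[field]] %*% state$vol) / sum(state$vol)
}
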