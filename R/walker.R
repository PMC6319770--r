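#' Configuration of a lattice trapping random walk
#'
#' A particle hops on a `d`-dimensional integer lattice (spacing 1) and
#' can reversibly bind to immobile traps: while free it hops at rate `D`
#' per direction (so the free mean-square displacement is `2 d D t`) and
#' binds at rate `k_plus`; while bound it is immobile and unbinds at rate
#' `k_minus`. Optionally (1-d only) the binding rate is spatially
#' perturbed, `k_plus(x) = k_plus + amplitude * sin(omega x + theta)`.
#'
#' @param dimension lattice dimension, 1, 2 or 3.
#' @param D free diffusion coefficient, lattice units^2 per unit time.
#' @param k_plus binding rate per unit time.
#' @param k_minus unbinding rate per unit time.
#' @param amplitude amplitude of the sinusoidal binding-rate perturbation
#'   (must not exceed `k_plus` so rates stay non-negative).
#' @param omega spatial frequency of the perturbation.
#' @param theta phase; `NULL` draws one phase per walker uniformly.
#' @param n_walkers ensemble size.
#' @param horizon simulated time span.
#' @param seed RNG seed; identical configurations give identical output.
#' @return object of class `walk_config`.
#' @export
walk_config <- function(dimension = 1, D = 0.088, k_plus = 0.58,
                        k_minus = 0.035, amplitude = 0, omega = 2 * pi / 5,
                        theta = NULL, n_walkers = 2e4, horizon = 200,
                        seed = 1) {
  if (!dimension %in% 1:3) stop_domain("dimension must be 1, 2 or 3")
  check_num(D, "D", lower = 0, len = 1)
  check_num(k_plus, "k_plus", lower = 0, len = 1)
  check_num(k_minus, "k_minus", lower = 0, len = 1)
  check_num(amplitude, "amplitude", lower = 0, len = 1)
  if (amplitude > 0 && dimension != 1)
    stop_domain("spatial perturbation is implemented for dimension 1 only")
  if (k_plus - amplitude < 0)
    stop_domain("amplitude must not exceed k_plus (rates must stay >= 0)")
  if (n_walkers < 1) stop_domain("n_walkers must be >= 1")
  check_num(horizon, "horizon", lower = 0, len = 1)
  structure(list(dimension = dimension, D = D, k_plus = k_plus,
                 k_minus = k_minus, amplitude = amplitude, omega = omega,
                 theta = theta, n_walkers = as.integer(n_walkers),
                 horizon = horizon, seed = as.integer(seed)),
            class = "walk_config")
}

#' Long-time effective diffusion coefficient of the trap walk
#'
#' `D* = D * k_minus / (k_minus + k_plus)`: the free-diffusion coefficient
#' scaled by the stationary probability of being unbound.
#'
#' @param D free diffusion coefficient.
#' @param k_plus binding rate.
#' @param k_minus unbinding rate.
#' @return effective diffusion coefficient.
#' @export
dstar <- function(D, k_plus, k_minus) {
  check_num(D, "D", lower = 0, len = 1)
  check_num(k_plus, "k_plus", lower = 0, len = 1)
  check_num(k_minus, "k_minus", lower = 0, len = 1)
  if (k_plus + k_minus == 0) stop_domain("k_plus + k_minus must be > 0")
  D * k_minus / (k_minus + k_plus)
}

#' Transient offset of the exact mean-square displacement
#'
#' `delta = 2 d D k_plus / (k_minus + k_plus)^2`, the plateau by which the
#' early-time normal diffusion overshoots the late-time asymptote
#' `2 d D* t`.
#'
#' @inheritParams dstar
#' @param dimension lattice dimension.
#' @return offset, lattice units^2.
#' @export
msd_offset <- function(D, k_plus, k_minus, dimension = 1) {
  if (k_plus + k_minus == 0) stop_domain("k_plus + k_minus must be > 0")
  2 * dimension * D * k_plus / (k_minus + k_plus)^2
}

#' Exact free-state occupancy of the two-state chain
#'
#' `p0(t) = k_minus/(k_minus+k_plus) + k_plus/(k_minus+k_plus) *
#' exp(-(k_minus+k_plus) t)`, the probability that a walker starting free
#' is free at time `t`. The exact MSD is `2 d D` times its time integral.
#'
#' @inheritParams dstar
#' @param times time grid.
#' @return numeric vector `p0(times)`.
#' @export
free_prob_exact <- function(k_plus, k_minus, times) {
  if (k_plus + k_minus == 0) stop_domain("k_plus + k_minus must be > 0")
  k <- k_plus + k_minus
  k_minus / k + (k_plus / k) * exp(-k * times)
}

#' Logarithmic output time grid
#'
#' @param t_min,t_max grid range (> 0).
#' @param points_per_decade grid density (default 32).
#' @return increasing numeric vector.
#' @export
msd_time_grid <- function(t_min, t_max, points_per_decade = 32) {
  if (t_min <= 0 || t_max <= t_min) stop_domain("need 0 < t_min < t_max")
  n <- ceiling(log10(t_max / t_min) * points_per_decade) + 1
  10^seq(log10(t_min), log10(t_max), length.out = n)
}

#' Exact mean-square displacement of the uniform trap walk
#'
#' `<x^2>(t) = delta * (1 - exp(-(k_minus+k_plus) t)) + 2 d D* t`, valid
#' for spatially uniform rates only.
#'
#' @param config a [walk_config()] with `amplitude = 0`.
#' @param times time grid (default: logarithmic over the horizon).
#' @return object of class `msd_curve` with `times`, `msd`, `delta`,
#'   `Dstar`.
#' @export
msd_exact <- function(config, times = NULL) {
  stopifnot(inherits(config, "walk_config"))
  if (config$amplitude != 0)
    stop_domain("exact MSD is valid only for uniform rates (amplitude = 0)")
  if (is.null(times))
    times <- msd_time_grid(min(0.1, config$horizon / 100), config$horizon)
  d <- config$dimension
  if (config$k_plus + config$k_minus == 0) {
    msd <- 2 * d * config$D * times
    delta <- 0; Ds <- config$D
  } else {
    k <- config$k_plus + config$k_minus
    delta <- msd_offset(config$D, config$k_plus, config$k_minus, d)
    Ds <- dstar(config$D, config$k_plus, config$k_minus)
    msd <- delta * (1 - exp(-k * times)) + 2 * d * Ds * times
  }
  structure(list(times = times, msd = msd, se = rep(0, length(times)),
                 n = Inf, config = config, delta = delta, Dstar = Ds,
                 method = "exact"),
            class = "msd_curve")
}

# Late-time linear fit of an MSD curve. MSD values at different times are
# strongly correlated (same walkers), so slope/intercept uncertainties come
# from refitting independent walker batches, not from the single-curve
# regression.
fit_msd_asymptote <- function(times, batch_msd, d, rate, horizon) {
  # window: past the two-state transient, and in any case excluding the
  # first quarter so that slowly decaying anomalous transients
  # (heterogeneous environments) do not bias the slope
  t_min <- if (rate > 0) max(min(8 / rate, horizon / 2), horizon / 4)
           else horizon / 4
  keep <- times >= t_min
  if (sum(keep) < 3) keep <- times >= median(times)
  tt <- times[keep]
  msd <- colMeans(batch_msd)
  cf <- coef(lm(msd[keep] ~ tt))
  B <- nrow(batch_msd)
  co <- vapply(seq_len(B),
               function(b) coef(lm(batch_msd[b, keep] ~ tt)), numeric(2))
  list(Dstar_hat = cf[[2]] / (2 * d),
       Dstar_se = sd(co[2, ]) / sqrt(B) / (2 * d),
       delta_hat = cf[[1]], delta_se = sd(co[1, ]) / sqrt(B))
}

#' Monte-Carlo simulation of the trapping random walk
#'
#' Simulates the ensemble with exact (Gillespie-style) event scheduling:
#' exponential waiting times between hop, bind and unbind events, so the
#' MSD carries no time-discretisation bias. With a spatial perturbation
#' the binding rate is evaluated at the walker's current site; the phase
#' is drawn per walker unless fixed in the configuration.
#'
#' @param config a [walk_config()].
#' @param times output time grid (default logarithmic, 32 points/decade).
#' @return object of class `msd_curve` with ensemble `msd`, standard
#'   error `se`, `n`, and late-time estimates `Dstar_hat`, `delta_hat`
#'   (with standard errors) from a weighted linear fit.
#' @export
simulate_walk <- function(config, times = NULL) {
  stopifnot(inherits(config, "walk_config"))
  if (config$n_walkers < 1) stop_domain("zero walkers")
  if (is.null(times))
    times <- msd_time_grid(min(0.1, config$horizon / 100), config$horizon)
  check_num(times, "times", lower = 0)
  set.seed(config$seed)
  d <- config$dimension
  hop_rate <- 2 * d * config$D
  nw <- config$n_walkers
  nt <- length(times)
  s1 <- numeric(nt); s2 <- numeric(nt)
  B <- min(16L, nw)
  bsum <- matrix(0, B, nt); bn <- tabulate((seq_len(nw) - 1L) %% B + 1L, B)
  finals <- matrix(0L, nrow = nw, ncol = d)
  perturbed <- config$amplitude > 0
  for (w in seq_len(nw)) {
    theta_w <- if (perturbed) {
      if (is.null(config$theta)) runif(1, 0, 2 * pi) else config$theta
    } else 0
    cap <- 64L
    th <- numeric(cap); sq <- numeric(cap)
    m <- 1L  # history length; th[1] = 0, sq[1] = 0
    t <- 0; pos <- integer(d); free <- TRUE
    repeat {
      if (free) {
        kb <- if (perturbed)
          config$k_plus + config$amplitude * sin(config$omega * pos[1] + theta_w)
        else config$k_plus
        tot <- hop_rate + kb
        if (tot <= 0) break
        t <- t + rexp(1, tot)
        if (t >= config$horizon) break
        if (runif(1) < hop_rate / tot) {
          ax <- if (d == 1) 1L else sample.int(d, 1L)
          pos[ax] <- pos[ax] + (if (runif(1) < 0.5) 1L else -1L)
          m <- m + 1L
          if (m > cap) {
            cap <- cap * 2L
            th <- c(th, numeric(cap - length(th)))
            sq <- c(sq, numeric(cap - length(sq)))
          }
          th[m] <- t; sq[m] <- sum(pos^2)
        } else free <- FALSE
      } else {
        if (config$k_minus <= 0) break
        t <- t + rexp(1, config$k_minus)
        if (t >= config$horizon) break
        free <- TRUE
      }
    }
    x2 <- sq[findInterval(times, th[seq_len(m)])]
    s1 <- s1 + x2
    s2 <- s2 + x2^2
    bi <- (w - 1L) %% B + 1L
    bsum[bi, ] <- bsum[bi, ] + x2
    finals[w, ] <- pos
  }
  msd <- s1 / nw
  se <- sqrt(pmax(s2 / nw - msd^2, 0) / nw)
  fit <- fit_msd_asymptote(times, bsum / bn, d,
                           config$k_plus + config$k_minus, config$horizon)
  structure(c(list(times = times, msd = msd, se = se, n = nw,
                   config = config, final_displacement = finals,
                   method = "monte-carlo"), fit),
            class = "msd_curve")
}

#' Multi-walker trap walk with finite site capacity
#'
#' Several walkers share a periodic lattice whose binding sites (placed
#' with density `site_density`, capacity one) can each hold a single
#' walker; a free walker binds only where an unoccupied site is present.
#' At vanishing walker density this reduces to [simulate_walk()]; with the
#' mean-field substitution `k_plus ~ k_bind * site_density` the late-time
#' slope follows `D * k_minus / (k_minus + k_bind * site_density)`.
#'
#' @param config a [walk_config()]; `k_plus` is interpreted as the binding
#'   rate `k_bind` at an available site.
#' @param site_density probability that a lattice node carries a binding
#'   site, in (0, 1].
#' @param lattice_size nodes per dimension of the periodic lattice.
#' @param replicates independent lattice realisations; the ensemble size
#'   is `replicates * n_walkers`.
#' @param blockers if `TRUE`, all sites are pre-occupied by immobile
#'   blockers, so walkers diffuse freely.
#' @param times output time grid.
#' @return an `msd_curve`, plus `final_displacement` (the ensemble of
#'   per-walker displacement vectors at the horizon, one row per walker).
#' @export
simulate_multi_walker <- function(config, site_density = 1,
                                  lattice_size = 512, replicates = 1,
                                  blockers = FALSE, times = NULL) {
  stopifnot(inherits(config, "walk_config"))
  if (config$n_walkers < 1) stop_domain("zero walkers")
  if (site_density <= 0 || site_density > 1)
    stop_domain("site_density must be in (0, 1]")
  if (is.null(times))
    times <- msd_time_grid(min(0.1, config$horizon / 100), config$horizon)
  set.seed(config$seed)
  d <- config$dimension
  L <- as.integer(lattice_size)
  n_nodes <- L^d
  hop_rate <- 2 * d * config$D
  nw <- config$n_walkers
  nt <- length(times)
  s1 <- numeric(nt); s2 <- numeric(nt)
  n_tot <- nw * replicates
  B <- min(16L, n_tot)
  bsum <- matrix(0, B, nt)
  bn <- tabulate((seq_len(n_tot) - 1L) %% B + 1L, B)
  finals <- matrix(0, nrow = nw * replicates, ncol = d)
  lin_index <- function(pos) {
    # pos: nw x d integer matrix of wrapped coordinates in [0, L)
    idx <- pos[, 1]
    if (d > 1) for (k in 2:d) idx <- idx + pos[, k] * L^(k - 1)
    idx + 1L
  }
  for (rep_i in seq_len(replicates)) {
    has_site <- runif(n_nodes) < site_density
    occupied <- if (blockers) has_site else rep(FALSE, n_nodes)
    pos0 <- matrix(sample.int(L, nw * d, replace = TRUE) - 1L, ncol = d)
    pos <- pos0
    bound <- rep(FALSE, nw)
    t <- 0
    hist_t <- vector("list", nw); hist_sq <- vector("list", nw)
    for (w in seq_len(nw)) { hist_t[[w]] <- 0; hist_sq[[w]] <- 0 }
    node <- lin_index(pos %% L)
    repeat {
      can_bind <- !bound & has_site[node] & !occupied[node]
      rates <- ifelse(bound, config$k_minus,
                      hop_rate + config$k_plus * can_bind)
      total <- sum(rates)
      if (total <= 0) break
      t <- t + rexp(1, total)
      if (t >= config$horizon) break
      w <- sample.int(nw, 1L, prob = rates)
      if (bound[w]) {
        occupied[node[w]] <- FALSE
        bound[w] <- FALSE
      } else if (can_bind[w] &&
                 runif(1) < config$k_plus / (hop_rate + config$k_plus)) {
        occupied[node[w]] <- TRUE
        bound[w] <- TRUE
      } else {
        ax <- if (d == 1) 1L else sample.int(d, 1L)
        pos[w, ax] <- pos[w, ax] + (if (runif(1) < 0.5) 1L else -1L)
        node[w] <- lin_index(matrix(pos[w, ] %% L, ncol = d))
        hist_t[[w]] <- c(hist_t[[w]], t)
        hist_sq[[w]] <- c(hist_sq[[w]], sum((pos[w, ] - pos0[w, ])^2))
      }
    }
    for (w in seq_len(nw)) {
      g <- (rep_i - 1) * nw + w
      x2 <- hist_sq[[w]][findInterval(times, hist_t[[w]])]
      s1 <- s1 + x2
      s2 <- s2 + x2^2
      bi <- (g - 1L) %% B + 1L
      bsum[bi, ] <- bsum[bi, ] + x2
      finals[g, ] <- pos[w, ] - pos0[w, ]
    }
  }
  msd <- s1 / n_tot
  se <- sqrt(pmax(s2 / n_tot - msd^2, 0) / n_tot)
  fit <- fit_msd_asymptote(times, bsum / bn,  d,
                           config$k_plus * site_density + config$k_minus,
                           config$horizon)
  structure(c(list(times = times, msd = msd, se = se, n = n_tot,
                   config = config, site_density = site_density,
                   final_displacement = finals, method = "multi-walker"),
              fit),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat("MSD curve (", x$method, "), ", length(x$times), " time points, n = ",
      x$n, "\n", sep = "")
  if (!is.null(x$Dstar_hat))
    cat("  late-time fit: D* =", signif(x$Dstar_hat, 4), "+/-",
        signif(x$Dstar_se, 2), ", offset delta =", signif(x$delta_hat, 4),
        "+/-", signif(x$delta_se, 2), "\n")
  if (!is.null(x$delta) && x$method == "exact")
    cat("  delta =", signif(x$delta, 4), ", D* =", signif(x$Dstar, 4), "\n")
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ..., log = "xy") {
  graphics::plot(x$times, x$msd, log = log, type = "l",
                 xlab = "time", ylab = "<x^2>", ...)
  invisible(x)
}

#' @export
as.data.frame.msd_curve <- function(x, ...) {
  data.frame(t = x$times, msd = x$msd, se = x$se,
             n = rep(if (is.finite(x$n)) x$n else NA_integer_,
                     length(x$times)))
}
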