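#' Binding-site parameters
#'
#' Bundles the mass-action parameters of one class of dye binding sites:
#' association rate `k_on` (uM^-1 s^-1), dissociation rate `k_off` (s^-1),
#' site concentration (capacity) `capacity` (uM) and the dissociation
#' constant `K_d = k_off / k_on` (uM). Two of `k_on`, `k_off`, `K_d`
#' determine the third; if all three are given they must be consistent to
#' a relative tolerance of 1e-12.
#'
#' The minor-groove ("specific") site of Hoechst 33342 is high affinity and
#' low capacity (in vitro `k_off` of order 0.1 s^-1 and `K_d` of order
#' 0.01 uM); the generic non-specific site is low affinity and roughly
#' 100-fold higher capacity.
#'
#' @param k_off dissociation rate, s^-1.
#' @param k_on association rate, uM^-1 s^-1 (optional if `K_d` given).
#' @param K_d dissociation constant, uM (optional if `k_on` given).
#' @param capacity binding-site concentration, uM.
#' @return An object of class `binding_site`.
#' @examples
#' hoechst_specific <- binding_site(k_off = 0.1, K_d = 0.01, capacity = 25)
#' hoechst_specific$k_on   # 10 uM^-1 s^-1
#' @export
binding_site <- function(k_off, k_on = NULL, K_d = NULL, capacity = 0) {
  check_num(k_off, "k_off", lower = 0, len = 1)
  check_num(capacity, "capacity", lower = 0, len = 1)
  if (is.null(k_on) && is.null(K_d))
    stop_domain("one of k_on or K_d is required")
  if (is.null(k_on)) {
    check_num(K_d, "K_d", lower = 0, len = 1)
    if (K_d == 0) stop_domain("K_d must be > 0 when k_on is derived")
    k_on <- k_off / K_d
  } else if (is.null(K_d)) {
    check_num(k_on, "k_on", lower = 0, len = 1)
    K_d <- if (k_on == 0) Inf else k_off / k_on  # inert ligand: no affinity
  } else {
    check_num(k_on, "k_on", lower = 0, len = 1)
    check_num(K_d, "K_d", lower = 0, len = 1)
    if (abs(K_d * k_on - k_off) > 1e-12 * max(k_off, K_d * k_on))
      stop_domain("inconsistent rates: K_d * k_on must equal k_off")
  }
  structure(list(k_on = k_on, k_off = k_off, K_d = K_d, capacity = capacity),
            class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat("Binding site: k_on =", x$k_on, "uM^-1 s^-1, k_off =", x$k_off,
      "s^-1, K_d =", x$K_d, "uM, capacity =", x$capacity, "uM\n")
  invisible(x)
}

#' Well-mixed relaxation rate
#'
#' Relaxation rate of second-order binding / first-order dissociation at a
#' constant free-dye concentration `u0`:
#' `beta = k_on * u0 + k_off = k_off * (1 + u0 / K_d)`.
#'
#' With the in vitro constants of the Hoechst-DNA minor-groove complex
#' (`k_off` ~ 0.1 s^-1, `K_d` ~ 0.01 uM) this predicts relaxation of order
#' 10 s^-1 at micromolar dye, some four orders of magnitude faster than the
#' ~1e-3 s^-1 observed in intact nuclei -- the discrepancy the
#' reaction-diffusion and buffering machinery of this package explains.
#'
#' @param site a [binding_site()].
#' @param u0 free dye concentration, uM.
#' @return relaxation rate, s^-1.
#' @export
relaxation_rate <- function(site, u0) {
  stopifnot(inherits(site, "binding_site"))
  check_num(u0, "u0", lower = 0)
  if (site$k_off <= 0) stop_domain("relaxation_rate requires k_off > 0")
  site$k_off * (1 + u0 / site$K_d)
}

#' Well-mixed binding time course
#'
#' Closed-form solution for the free-target concentration `v(t)` when the
#' dye concentration is held constant at `u0`:
#' `v(t) = v_st + (capacity - v_st) * exp(-beta t)` with
#' `v_st = (k_off / beta) * capacity`. The bound-target trace is
#' `capacity - v(t)`; free plus bound target always sums to `capacity`.
#'
#' @param site a [binding_site()] with `capacity > 0`.
#' @param u0 constant free dye concentration, uM.
#' @param times sorted, non-negative time grid, s.
#' @return An object of class `well_mixed_solution` with elements `times`,
#'   `v` (free target, uM), `bound` (uM), `v_st`, `beta`.
#' @export
well_mixed_solution <- function(site, u0, times) {
  stopifnot(inherits(site, "binding_site"))
  check_num(u0, "u0", lower = 0, len = 1)
  if (length(times) == 0) stop_domain("empty time grid")
  check_num(times, "times", lower = 0)
  if (is.unsorted(times)) stop_domain("times must be sorted")
  beta <- relaxation_rate(site, u0)
  v_st <- (site$k_off / beta) * site$capacity
  v <- v_st + (site$capacity - v_st) * exp(-beta * times)
  structure(list(times = times, v = v, bound = site$capacity - v,
                 v_st = v_st, beta = beta, u0 = u0, site = site),
            class = "well_mixed_solution")
}

#' @export
print.well_mixed_solution <- function(x, ...) {
  cat("Well-mixed binding kinetics\n",
      " beta =", x$beta, "s^-1 (tau_1/2 =", round(log(2) / x$beta, 3), "s)\n",
      " v_st =", x$v_st, "uM free target of capacity", x$site$capacity, "uM\n")
  invisible(x)
}

#' Effective diffusion coefficient of a buffered ligand
#'
#' In the rapid-buffering limit a ligand that binds immobile sites of
#' dissociation constant `K_d` present at free concentration `rho` diffuses
#' with `D* = D * K_d / (K_d + rho)`. For sub-micromolar non-specific `K_d`
#' and intracellular site concentrations of 100 uM or more this predicts a
#' 1e2-1e3-fold slowdown relative to free aqueous diffusion.
#'
#' @param D free diffusion coefficient, um^2 s^-1.
#' @param K_d dissociation constant of the buffering sites, uM.
#' @param rho free buffering-site concentration, uM (vectorised).
#' @return effective diffusion coefficient(s), um^2 s^-1.
#' @seealso [effective_diffusion_t()] for the time-dependent form driven by
#'   a bath-depletion solution.
#' @export
effective_diffusion <- function(D, K_d, rho) {
  check_num(D, "D", lower = 0, len = 1)
  check_num(K_d, "K_d", lower = 0, len = 1)
  check_num(rho, "rho", lower = 0)
  if (K_d == 0 && any(rho == 0))
    stop_domain("K_d and rho cannot both be zero")
  D * K_d / (K_d + rho)
}

#' Time-dependent effective diffusion along a depletion trajectory
#'
#' Evaluates `D_eff(t) = D * K_d / (K_d + rho(t))` where `rho(t)` is the
#' available binding-site concentration from a bath-depletion solution.
#'
#' @param D free diffusion coefficient, um^2 s^-1.
#' @param K_d dissociation constant, uM.
#' @param depletion a `depletion_solution` from [solve_depletion()] or
#'   [depletion_closed_form()].
#' @return data.frame with columns `time_s` and `D_eff`.
#' @export
effective_diffusion_t <- function(D, K_d, depletion) {
  stopifnot(inherits(depletion, "depletion_solution"))
  data.frame(time_s = depletion$times,
             D_eff = effective_diffusion(D, K_d, depletion$rho))
}

#' Bookkeeping quantities of a cell-culture well
#'
#' Back-of-envelope quantities used to argue that specific minor-groove
#' sites alone cannot deplete the dye pool: number of dye molecules per
#' well, number of DNA base pairs per well, and the DNA mass concentration
#' of a suspension.
#'
#' @param dye_conc dye concentration, uM.
#' @param well_volume_ul well volume, microlitres.
#' @param n_cells cells per well.
#' @param bp_per_cell base pairs per cell (default the ~3e9 of a human
#'   genome copy).
#' @param cell_density cells per ml.
#' @param dna_per_cell_pg DNA mass per cell, picograms.
#' @return `well_bookkeeping()` returns a list with `dye_molecules`,
#'   `bp_total` and `dna_ug_per_ml`.
#' @examples
#' bk <- well_bookkeeping(dye_conc = 1, well_volume_ul = 150, n_cells = 5e4)
#' bk$dye_molecules  # ~9e13
#' @export
well_bookkeeping <- function(dye_conc = 1, well_volume_ul = 150,
                             n_cells = 5e4, bp_per_cell = 3e9,
                             cell_density = 2.5e5, dna_per_cell_pg = 6) {
  avogadro <- 6.02214076e23
  moles <- dye_conc * 1e-6 * well_volume_ul * 1e-6
  list(
    dye_molecules = moles * avogadro,
    bp_total = n_cells * bp_per_cell,
    dna_ug_per_ml = cell_density * dna_per_cell_pg * 1e-6
  )
}

#' Diffusive homogenisation time of a nucleus
#'
#' `R^2 / D`, the time scale on which free diffusion evens out a
#' concentration difference across a sphere of radius `R`. For dye in
#' water (`D` ~ 500 um^2/s) and a 20 um nucleus this is under a second,
#' orders of magnitude faster than observed front in-fill.
#'
#' @param R radius, um.
#' @param D diffusion coefficient, um^2 s^-1.
#' @return time, s.
#' @export
homogenization_time <- function(R, D) {
  check_num(R, "R", lower = 0, len = 1)
  check_num(D, "D", lower = 0, len = 1)
  if (D == 0) stop_domain("D must be > 0")
  R^2 / D
}
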