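#' Nucleus geometry for the radial reaction-diffusion model
#'
#' The PDE is solved on a radially symmetric sphere of radius `R_n`; the
#' semi-axes `a`, `b` are carried for rendering and for the normalised
#' elliptic radius of the imaging module (ellipticity does not enter the
#' radial solver).
#'
#' @param R_n nuclear radius, um.
#' @param a,b semi-axes for rendering, um (default `R_n`).
#' @param nr number of radial nodes (>= 16; default 96). Nodes are
#'   cell-centred at `(i - 1/2) * R_n / nr`.
#' @return object of class `nucleus_geometry`.
#' @export
nucleus_geometry <- function(R_n = 10, a = R_n, b = R_n, nr = 96) {
  check_num(R_n, "R_n", lower = 0, len = 1)
  if (R_n <= 0) stop_domain("R_n must be > 0")
  if (a <= 0 || b <= 0) stop_domain("semi-axes must be > 0")
  if (nr < 16) stop_domain("grid must have >= 16 nodes")
  structure(list(R_n = R_n, a = a, b = b, nr = as.integer(nr)),
            class = "nucleus_geometry")
}

#' Membrane transport parameters
#'
#' @param D free-dye diffusion coefficient inside the nucleus, um^2 s^-1.
#' @param h_m membrane mass-transfer coefficient, um s^-1. Dye flux
#'   through the membrane is `h_m * (u_ext - u(R_n))` per unit area
#'   (Robin boundary condition).
#' @return object of class `transport_params`.
#' @export
transport_params <- function(D = 500, h_m = 1) {
  check_num(D, "D", lower = 0, len = 1)
  if (D <= 0) stop_domain("D must be > 0")
  check_num(h_m, "h_m", lower = 0, len = 1)
  structure(list(D = D, h_m = h_m), class = "transport_params")
}

#' Biot number of membrane-limited uptake
#'
#' `Bi = h_m * R_n / D`, comparing membrane transfer to internal
#' diffusion; `Bi << 1` means uptake is membrane-limited.
#'
#' @param transport a [transport_params()].
#' @param geometry a [nucleus_geometry()].
#' @return dimensionless Biot number.
#' @export
biot_number <- function(transport, geometry) {
  stopifnot(inherits(transport, "transport_params"),
            inherits(geometry, "nucleus_geometry"))
  transport$h_m * geometry$R_n / transport$D
}

#' External bath state
#'
#' The bath is the shared extracellular dye pool. When `depleting`, its
#' concentration obeys `V du_ext/dt = -4 pi R_n^2 h_m (u_ext - u(R_n))`
#' with `V` the well volume per cell; otherwise it follows the protocol
#' schedule exactly (or a prescribed trajectory `u_fun`).
#'
#' @param u_ext initial external dye concentration, uM.
#' @param well_volume_ul well volume, microlitres (default 150).
#' @param n_cells number of cells sharing the well (default 5e4).
#' @param depleting logical; couple the bath to cellular uptake?
#' @param u_fun optional function of time prescribing `u_ext(t)` (used by
#'   the synthetic generator's mean-field pass; overrides `depleting`).
#' @return object of class `bath_state`.
#' @export
bath_state <- function(u_ext = 1, well_volume_ul = 150, n_cells = 5e4,
                       depleting = TRUE, u_fun = NULL) {
  check_num(u_ext, "u_ext", lower = 0, len = 1)
  if (well_volume_ul <= 0 || n_cells <= 0)
    stop_domain("well volume and cell count must be > 0")
  structure(list(u_ext = u_ext,
                 V_per_cell = well_volume_ul * 1e9 / n_cells,  # um^3
                 n_cells = n_cells, depleting = isTRUE(depleting),
                 u_fun = u_fun),
            class = "bath_state")
}

#' Timed protocol events
#'
#' A protocol is an ordered list of timed bath events encoding the
#' experimental designs: single or sequential dye addition, cold chase
#' (bath replacement with dye-free buffer), permeabilisation, and
#' doxorubicin addition for competition runs.
#'
#' `proto_add(time, conc, ligand)` adds `conc` uM of a ligand to the bath;
#' `proto_replace(time, conc, ligand)` replaces the bath concentration
#' (default 0 = cold chase; `ligand = NULL` replaces all ligands);
#' `proto_permeabilize(time, hm_factor, cn_factor)` multiplies the
#' membrane transfer coefficient by `hm_factor` and reduces the
#' non-specific capacity to a fraction `cn_factor` (released
#' non-specifically bound dye rejoins the free pool, conserving mass).
#'
#' @param ... event objects created by the `proto_*` helpers.
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(...) {
  events <- list(...)
  if (length(events) == 1 && is.list(events[[1]]) &&
      !inherits(events[[1]], "proto_event"))
    events <- events[[1]]
  if (!all(vapply(events, inherits, TRUE, "proto_event")))
    stop_domain("all protocol entries must be proto_* events")
  tt <- vapply(events, `[[`, 0, "time")
  if (any(diff(tt) <= 0)) stop_domain("event times must be strictly increasing")
  structure(list(events = events[order(tt)]), class = "protocol_spec")
}

#' @rdname protocol_spec
#' @param time event time, s.
#' @param conc concentration, uM.
#' @param ligand ligand index (1 = dye, 2 = competitor).
#' @export
proto_add <- function(time, conc, ligand = 1) {
  check_num(conc, "conc", lower = 0, len = 1)
  structure(list(time = time, action = "add", ligand = ligand, conc = conc),
            class = "proto_event")
}

#' @rdname protocol_spec
#' @export
proto_replace <- function(time, conc = 0, ligand = NULL) {
  check_num(conc, "conc", lower = 0, len = 1)
  structure(list(time = time, action = "replace", ligand = ligand,
                 conc = conc),
            class = "proto_event")
}

#' @rdname protocol_spec
#' @param hm_factor multiplier on `h_m` (>= 0).
#' @param cn_factor fraction of non-specific capacity retained, in [0, 1].
#' @export
proto_permeabilize <- function(time, hm_factor = 10, cn_factor = 1) {
  check_num(hm_factor, "hm_factor", lower = 0, len = 1)
  if (cn_factor < 0 || cn_factor > 1)
    stop_domain("cn_factor must be in [0, 1]")
  structure(list(time = time, action = "permeabilize",
                 hm_factor = hm_factor, cn_factor = cn_factor),
            class = "proto_event")
}

# ---------------------------------------------------------------------------
# Core engine. State layout: per node, m = 3 * n_ligand fields interleaved
# (u, v, vn) per ligand, followed by one bath concentration per ligand.
# Finite-volume discretisation in spherical shells so that zero-flux systems
# conserve mass to solver tolerance; membrane flux per unit area is
# f = h_m (u_ext - u_N) / (1 + h_m dr / (2 D)), the Robin condition applied
# at the outer face with linear reconstruction of the face value.
# ---------------------------------------------------------------------------

rd_engine <- function(geometry, transports, specifics, nonspecifics,
                      bath, bath2_conc, protocol, times, ligands) {
  nr <- geometry$nr
  R <- geometry$R_n
  dr <- R / nr
  faces <- (0:nr) * dr
  area <- faces^2                       # 4*pi omitted (cancels)
  vol <- diff(faces^3) / 3
  nl <- length(ligands)
  m <- 3L * nl
  nstate <- m * nr + nl

  parms <- list(
    D = vapply(transports, `[[`, 0, "D"),
    h_m = vapply(transports, `[[`, 0, "h_m"),
    kon = vapply(specifics, `[[`, 0, "k_on"),
    koff = vapply(specifics, `[[`, 0, "k_off"),
    c_cap = specifics[[1]]$capacity,
    konn = vapply(nonspecifics, function(s) if (is.null(s)) 0 else s$k_on, 0),
    koffn = vapply(nonspecifics, function(s) if (is.null(s)) 0 else s$k_off, 0),
    cn = vapply(nonspecifics, function(s) if (is.null(s)) 0 else s$capacity, 0)
  )

  iu <- function(l) seq(3L * (l - 1L) + 1L, m * nr, by = m)
  iv <- function(l) iu(l) + 1L
  iw <- function(l) iu(l) + 2L
  ib <- function(l) m * nr + l

  u_forced <- !is.null(bath$u_fun)

  rhs <- function(t, y, p) {
    dy <- numeric(nstate)
    v_shared <- 0
    for (l in seq_len(nl)) v_shared <- v_shared + y[iv(l)]
    free_sites <- pmax(p$c_cap - v_shared, 0)
    for (l in seq_len(nl)) {
      u <- y[iu(l)]; v <- y[iv(l)]; w <- y[iw(l)]
      uext <- if (l == 1 && u_forced) bath$u_fun(t) else y[ib(l)]
      Dl <- p$D[l]; hm <- p$h_m[l]
      Fint <- Dl * diff(u) / dr
      fmem <- hm * (uext - u[nr]) / (1 + hm * dr / (2 * Dl))
      Ffull <- c(0, Fint, fmem)
      lap <- (area[-1] * Ffull[-1] - area[-(nr + 1)] * Ffull[-(nr + 1)]) / vol
      Rs <- p$kon[l] * u * free_sites - p$koff[l] * v
      Rn <- p$konn[l] * u * (p$cn[l] - w) - p$koffn[l] * w
      dy[iu(l)] <- lap - Rs - Rn
      dy[iv(l)] <- Rs
      dy[iw(l)] <- Rn
      dy[ib(l)] <- if (l == 1 && u_forced) 0
        else if (bath$depleting) -area[nr + 1] * 4 * pi * fmem / bath$V_per_cell
        else 0
    }
    list(dy)
  }

  y0 <- numeric(nstate)
  y0[ib(1)] <- bath$u_ext
  if (nl == 2) y0[ib(2)] <- bath2_conc

  ev_times <- if (is.null(protocol)) numeric(0) else
    vapply(protocol$events, `[[`, 0, "time")
  check_num(times, "times", lower = 0)
  if (is.unsorted(times)) stop_domain("times must be sorted")
  bounds <- sort(unique(c(times[1], ev_times[ev_times > times[1] &
                                             ev_times < max(times)],
                          max(times))))
  out <- matrix(NA_real_, nrow = length(times), ncol = nstate)
  rownames(out) <- NULL
  if (times[1] == bounds[1]) out[1, ] <- y0
  y <- y0
  for (s in seq_len(length(bounds) - 1)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1]
    # apply any event scheduled at t0
    if (!is.null(protocol)) {
      for (e in protocol$events) {
        if (e$time != t0) next
        if (e$action == "add") {
          y[ib(e$ligand)] <- y[ib(e$ligand)] + e$conc
        } else if (e$action == "replace") {
          lig <- if (is.null(e$ligand)) seq_len(nl) else e$ligand
          for (l in lig) y[ib(l)] <- e$conc
        } else if (e$action == "permeabilize") {
          parms$h_m <- parms$h_m * e$hm_factor
          for (l in seq_len(nl)) {
            released <- y[iw(l)] * (1 - e$cn_factor)
            y[iu(l)] <- y[iu(l)] + released
            y[iw(l)] <- y[iw(l)] * e$cn_factor
          }
          parms$cn <- parms$cn * e$cn_factor
        }
      }
    }
    seg <- sort(unique(c(t0, times[times > t0 & times < t1], t1)))
    sol <- deSolve::ode(y = y, times = seg, func = rhs, parms = parms,
                        method = "lsoda", jactype = "bandint",
                        bandup = m, banddown = m,
                        rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0)
      stop_domain("reaction-diffusion solver failed in segment [", t0, ", ",
                  t1, "] s; istate = ", attr(sol, "istate")[1])
    hit <- match(times, seg)
    keep <- !is.na(hit)
    out[keep, ] <- sol[hit[keep], -1, drop = FALSE]
    y <- sol[nrow(sol), -1]
  }

  r <- (seq_len(nr) - 0.5) * dr
  lig_out <- lapply(seq_len(nl), function(l) {
    uext <- out[, ib(l)]
    if (l == 1 && u_forced) uext <- vapply(times, bath$u_fun, 0)
    list(u = out[, iu(l), drop = FALSE],
         v = out[, iv(l), drop = FALSE],
         vn = out[, iw(l), drop = FALSE],
         u_ext = uext)
  })
  structure(list(times = times, r = r, geometry = geometry,
                 transport = transports[[1]], bath = bath,
                 capacity = parms$c_cap, cn = parms$cn,
                 specific = specifics, nonspecific = nonspecifics,
                 ligands = lig_out,
                 u = lig_out[[1]]$u, v = lig_out[[1]]$v,
                 vn = lig_out[[1]]$vn, u_ext = lig_out[[1]]$u_ext,
                 vol = vol, n_ligands = nl),
            class = "rd_state")
}

#' Base reaction-diffusion model of dye uptake
#'
#' Solves free-dye diffusion with specific binding only inside a sphere,
#' with the Robin membrane condition at `r = R_n` and symmetry at the
#' origin. Internally the bound-dye convention is used (`v` = bound dye,
#' reaction `k_on u (c - v) - k_off v`); [free_target()] converts to the
#' free-target convention `c - v` in which the reaction reads
#' `k_on u v_free - k_off (c - v_free)`.
#'
#' @param geometry a [nucleus_geometry()].
#' @param transport a [transport_params()].
#' @param specific a [binding_site()] for the specific (fluorescent) site.
#' @param bath a [bath_state()].
#' @param protocol optional [protocol_spec()].
#' @param times sorted output times, s.
#' @return object of class `rd_state`: matrices `u`, `v`, `vn`
#'   (time x node, uM), bath trace `u_ext`, node radii `r`.
#' @export
simulate_base <- function(geometry, transport, specific, bath,
                          protocol = NULL, times) {
  rd_engine(geometry, list(transport), list(specific), list(NULL),
            bath, 0, protocol, times, ligands = 1)
}

#' Reaction-diffusion model with non-specific buffering
#'
#' Adds a second, high-capacity low-affinity binding pool (default
#' capacity ~100-fold the specific capacity) that buffers free dye and is
#' the source of the anomalous slow-down; with `nonspecific` capacity 0
#' the result equals [simulate_base()].
#'
#' @inheritParams simulate_base
#' @param nonspecific a [binding_site()] for the non-specific pool.
#' @return an `rd_state`.
#' @export
simulate_nonspecific <- function(geometry, transport, specific, nonspecific,
                                 bath, protocol = NULL, times) {
  rd_engine(geometry, list(transport), list(specific), list(nonspecific),
            bath, 0, protocol, times, ligands = 1)
}

#' Two-ligand competition for shared specific sites
#'
#' Both ligands bind the same specific pool (`v1 + v2 <= c` pointwise)
#' with their own rate constants and their own non-specific pools; the
#' fluorescence proxy is the specifically bound first ligand (the dye).
#' Used to model doxorubicin-Hoechst competition: co-addition of a
#' slower-entering, higher-affinity competitor produces a rise-peak-fall
#' dye trace, pre-incubation a reduced monotone plateau.
#'
#' @inheritParams simulate_nonspecific
#' @param ligand2 a [binding_site()] for the competitor's specific binding
#'   (its `capacity` field is ignored; the pool is shared).
#' @param ligand2_nonspecific optional [binding_site()] for the
#'   competitor's non-specific pool.
#' @param transport2 competitor transport (default: same as `transport`).
#' @param bath2_conc initial competitor bath concentration, uM.
#' @return an `rd_state` with `ligands[[2]]` holding the competitor
#'   fields.
#' @export
simulate_competition <- function(geometry, transport, specific, nonspecific,
                                 ligand2, ligand2_nonspecific = NULL,
                                 transport2 = transport, bath2_conc = 0,
                                 bath, protocol = NULL, times) {
  rd_engine(geometry, list(transport, transport2),
            list(specific, ligand2),
            list(nonspecific, ligand2_nonspecific),
            bath, bath2_conc, protocol, times, ligands = 1:2)
}

#' Free-target view of a bound-dye solution
#'
#' @param state an `rd_state`.
#' @param ligand ligand index.
#' @return matrix of free-target concentration `c - v`, uM.
#' @export
free_target <- function(state, ligand = 1) {
  stopifnot(inherits(state, "rd_state"))
  state$capacity - state$ligands[[ligand]]$v
}

#' Total dye mass of a reaction-diffusion state
#'
#' Volume integral of free plus bound dye over the nucleus plus the bath
#' content of one cell-equivalent well volume; constant in closed systems
#' (`h_m = 0`).
#'
#' @param state an `rd_state`.
#' @param ligand ligand index.
#' @return numeric vector (one value per stored time), uM * um^3.
#' @export
total_mass <- function(state, ligand = 1) {
  stopifnot(inherits(state, "rd_state"))
  lg <- state$ligands[[ligand]]
  inside <- (lg$u + lg$v + lg$vn) %*% (4 * pi * state$vol)
  drop(inside) + lg$u_ext * state$bath$V_per_cell
}

#' @export
print.rd_state <- function(x, ...) {
  cat("Reaction-diffusion state:", x$n_ligands, "ligand(s),",
      length(x$r), "radial nodes, R_n =", x$geometry$R_n, "um,",
      length(x$times), "time points\n")
  cat("  Bi =", signif(x$transport$h_m * x$geometry$R_n / x$transport$D, 4),
      "; final bath u_ext =", signif(x$u_ext[length(x$u_ext)], 4), "uM\n")
  invisible(x)
}
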