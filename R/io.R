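# File interfaces: YAML configs, CSV traces with JSON sidecars of derived
# constants, multi-page TIFF stacks with a JSON metadata sidecar.

#' Read a YAML parameter/protocol configuration
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: ", path)
  yaml::read_yaml(path)
}

# Field-level validation with informative messages.
require_fields <- function(cfg, fields, where) {
  missing <- setdiff(fields, names(cfg))
  if (length(missing))
    stop_domain("config validation failed (", where, "): missing field(s) ",
                paste(missing, collapse = ", "))
  for (f in fields) {
    v <- cfg[[f]]
    if (is.null(v) || (is.numeric(v) && any(!is.finite(v))))
      stop_domain("config validation failed (", where, "): field '", f,
                  "' is empty or non-finite")
  }
  invisible(cfg)
}

parse_protocol_config <- function(events) {
  if (is.null(events)) return(NULL)
  evs <- lapply(events, function(e) {
    require_fields(e, c("time", "action"), "protocol event")
    switch(e$action,
      add = proto_add(e$time, e$conc, e$ligand %||% 1),
      replace = proto_replace(e$time, e$conc %||% 0, e$ligand),
      permeabilize = proto_permeabilize(e$time, e$hm_factor %||% 1,
                                        e$cn_factor %||% 1),
      stop_domain("config validation failed (protocol): unknown action '",
                  e$action, "'"))
  })
  protocol_spec(evs)
}

#' Write a kinetic solution as CSV plus a JSON sidecar
#'
#' The CSV has columns `time_s`, `value`; the sidecar collects the
#' derived constants (`beta`, `v_st`, equilibrium levels, effective
#' diffusion if supplied).
#'
#' @param solution a `well_mixed_solution` or `depletion_solution`.
#' @param csv_path,json_path output paths.
#' @param extra named list merged into the sidecar (e.g. `D_star`).
#' @return invisibly, the sidecar list.
#' @export
write_solution <- function(solution, csv_path, json_path = NULL,
                           extra = list()) {
  if (inherits(solution, "well_mixed_solution")) {
    df <- data.frame(time_s = solution$times, value = solution$v)
    side <- list(beta = solution$beta, v_st = solution$v_st,
                 capacity = solution$site$capacity, u0 = solution$u0)
  } else if (inherits(solution, "depletion_solution")) {
    df <- data.frame(time_s = solution$times, value = solution$rho)
    side <- list(beta = solution$beta %||% NA, rho_inf = solution$rho_inf,
                 rho1 = solution$rho1 %||% NA, rho2 = solution$rho2 %||% NA,
                 rho3 = solution$rho3 %||% NA)
  } else stop_domain("unsupported solution class")
  write.csv(df, csv_path, row.names = FALSE)
  side <- c(side, extra)
  if (!is.null(json_path))
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  invisible(side)
}

#' Write radial reaction-diffusion fields as long-format CSV
#'
#' @param state an `rd_state`.
#' @param path output CSV (`time_s`, `r_um`, `u`, `v`, `vn`).
#' @param ligand ligand index.
#' @export
write_fields_csv <- function(state, path, ligand = 1) {
  stopifnot(inherits(state, "rd_state"))
  lg <- state$ligands[[ligand]]
  nt <- length(state$times); nr <- length(state$r)
  df <- data.frame(time_s = rep(state$times, each = nr),
                   r_um = rep(state$r, nt),
                   u = as.vector(t(lg$u)), v = as.vector(t(lg$v)),
                   vn = as.vector(t(lg$vn)))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a synthetic stack to a directory
#'
#' Channels are written as multi-page 32-bit float TIFF (one file per
#' channel, values scaled to [0, 1] with the scale factor recorded in
#' `metadata.json`), the ground truth as CSV, the configuration echo as
#' YAML, and timestamps/shifts/bath trace as JSON metadata.
#'
#' @param stack a `synthetic_stack`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "synthetic_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- vapply(c("ref", "dye"), function(ch)
    max(1e-12, max(unlist(lapply(stack[[ch]], max)))), 0)
  tiff::writeTIFF(lapply(stack$ref, function(m) m / sc[["ref"]]),
                  file.path(dir, "ref.tif"), bits.per.sample = 32)
  tiff::writeTIFF(lapply(stack$dye, function(m) m / sc[["dye"]]),
                  file.path(dir, "dye.tif"), bits.per.sample = 32)
  write.csv(stack$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- stack$config
  if (!is.null(cfg)) {
    cfg_list <- cfg[!vapply(cfg, is.function, TRUE)]
    cfg_list$protocol <- if (!is.null(cfg$protocol))
      lapply(cfg$protocol$events, unclass) else NULL
    class(cfg_list) <- NULL
    yaml::write_yaml(cfg_list, file.path(dir, "config.yml"))
  }
  meta <- list(times = stack$times, pixel_size = stack$pixel_size,
               shifts = unname(as.matrix(stack$shifts)),
               scale = as.list(sc), u_ext = stack$u_ext,
               package_version = as.character(packageVersion("dyefront")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a stack directory written by [write_stack()]
#'
#' @param dir stack directory.
#' @return a `synthetic_stack` (config not reconstructed).
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  rd <- function(ch) {
    pages <- tiff::readTIFF(file.path(dir, paste0(ch, ".tif")), all = TRUE)
    lapply(pages, function(m) m * meta$scale[[ch]])
  }
  truth <- NULL
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) {
    truth <- read.csv(tp, stringsAsFactors = FALSE)
    class(truth) <- c("ground_truth", "data.frame")
  }
  structure(list(ref = rd("ref"), dye = rd("dye"), times = meta$times,
                 pixel_size = meta$pixel_size, truth = truth,
                 shifts = meta$shifts,
                 u_ext = as.data.frame(meta$u_ext), config = NULL),
            class = "synthetic_stack")
}
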