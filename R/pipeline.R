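# Pipeline entry points tying the stages into reproducible runs. Each run
# writes its outputs plus a JSON manifest (subcommand, config hash, seed,
# package version, paths, timestamp). The thin command-line wrapper in
# inst/cli/dyefront forwards to run_pipeline() and exits with its status.

write_manifest <- function(out_dir, subcommand, config_path, seed, outputs) {
  manifest <- list(
    subcommand = subcommand,
    config = config_path,
    config_md5 = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NULL,
    seed = seed,
    package_version = as.character(packageVersion("dyefront")),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

pipeline_walk <- function(cfg, seed, out_dir) {
  require_fields(cfg, c("D", "k_plus", "k_minus"), "walk")
  config <- walk_config(
    dimension = cfg$dimension %||% 1, D = cfg$D, k_plus = cfg$k_plus,
    k_minus = cfg$k_minus, amplitude = cfg$amplitude %||% 0,
    omega = cfg$omega %||% (2 * pi / 5), theta = cfg$theta,
    n_walkers = cfg$n_walkers %||% 2e4, horizon = cfg$horizon %||% 200,
    seed = seed %||% cfg$seed %||% 1)
  mc <- simulate_walk(config)
  df <- as.data.frame(mc)
  summary <- list(Dstar_hat = mc$Dstar_hat, Dstar_se = mc$Dstar_se,
                  delta_hat = mc$delta_hat, delta_se = mc$delta_se)
  if (config$amplitude == 0) {
    ex <- msd_exact(config, mc$times)
    df$msd_exact <- ex$msd
    summary$delta_exact <- ex$delta
    summary$Dstar_exact <- ex$Dstar
  }
  write.csv(df, file.path(out_dir, "walk_msd.csv"), row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "walk_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  c("walk_msd.csv", "walk_summary.json")
}

pipeline_simulate_rd <- function(cfg, seed, out_dir) {
  require_fields(cfg, "model", "simulate-rd")
  times <- if (!is.null(cfg$times)) unlist(cfg$times) else
    seq(0, cfg$t_max %||% 3600, by = cfg$dt %||% 60)
  d <- dye_defaults()
  site_from <- function(x, fallback) {
    if (is.null(x)) return(fallback)
    binding_site(k_off = x$k_off %||% fallback$k_off,
                 K_d = x$K_d %||% fallback$K_d,
                 capacity = x$capacity %||% fallback$capacity)
  }
  if (cfg$model == "well-mixed") {
    site <- site_from(cfg$specific, d$specific)
    sol <- well_mixed_solution(site, cfg$u0 %||% 1, times)
    write_solution(sol, file.path(out_dir, "well_mixed.csv"),
                   file.path(out_dir, "well_mixed.json"))
    return(c("well_mixed.csv", "well_mixed.json"))
  }
  if (cfg$model == "depletion") {
    p <- depletion_params(k_on = cfg$k_on, k_off = cfg$k_off,
                          u0 = cfg$u0, rho_tot = cfg$rho_tot)
    sol <- depletion_closed_form(p, times)
    Kd <- cfg$K_d %||% (cfg$k_off / cfg$k_on)
    extra <- list(D_star = effective_diffusion(cfg$D %||% d$transport$D,
                                               Kd, sol$rho_inf))
    write_solution(sol, file.path(out_dir, "depletion.csv"),
                   file.path(out_dir, "depletion.json"), extra = extra)
    return(c("depletion.csv", "depletion.json"))
  }
  geometry <- nucleus_geometry(R_n = cfg$R_n %||% d$geometry$R_n,
                               nr = cfg$nr %||% d$geometry$nr)
  transport <- transport_params(D = cfg$D %||% d$transport$D,
                                h_m = cfg$h_m %||% d$transport$h_m)
  specific <- site_from(cfg$specific, d$specific)
  bath <- bath_state(u_ext = cfg$u_ext %||% 1,
                     well_volume_ul = cfg$well_volume_ul %||% 150,
                     n_cells = cfg$well_cells %||% 5e4,
                     depleting = cfg$depleting %||% TRUE)
  protocol <- parse_protocol_config(cfg$protocol)
  state <- switch(cfg$model,
    base = simulate_base(geometry, transport, specific, bath, protocol,
                         times),
    nonspecific = simulate_nonspecific(
      geometry, transport, specific,
      site_from(cfg$nonspecific, binding_site(
        k_off = d$nonspecific$k_off, K_d = d$nonspecific$K_d,
        capacity = d$cn_ratio * specific$capacity)),
      bath, protocol, times),
    competition = simulate_competition(
      geometry, transport, specific,
      site_from(cfg$nonspecific, binding_site(
        k_off = d$nonspecific$k_off, K_d = d$nonspecific$K_d,
        capacity = d$cn_ratio * specific$capacity)),
      ligand2 = site_from(cfg$ligand2, d$competitor),
      ligand2_nonspecific = site_from(cfg$ligand2_nonspecific,
        binding_site(k_off = d$nonspecific$k_off, K_d = d$nonspecific$K_d,
                     capacity = d$cn_ratio * specific$capacity)),
      transport2 = transport_params(D = cfg$D2 %||% transport$D,
                                    h_m = cfg$h_m2 %||%
                                          d$competitor_transport$h_m),
      bath2_conc = cfg$u_ext2 %||% 0,
      bath = bath, protocol = protocol, times = times),
    stop_domain("config validation failed (simulate-rd): unknown model '",
                cfg$model, "'"))
  tr <- trace_outputs(state,
                      frames = unique(round(seq(1, length(times),
                                                length.out = min(25,
                                                  length(times))))))
  write.csv(as.data.frame(tr), file.path(out_dir, "traces.csv"),
            row.names = FALSE)
  write_fields_csv(state, file.path(out_dir, "fields.csv"))
  side <- list(Bi = biot_number(transport, geometry),
               u_ext_final = state$u_ext[length(state$u_ext)],
               I_tot_final = tr$I_tot[length(tr$I_tot)])
  jsonlite::write_json(side, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  c("traces.csv", "fields.csv", "summary.json")
}

pipeline_synth <- function(cfg, seed, out_dir) {
  args <- cfg
  args$protocol <- parse_protocol_config(cfg$protocol)
  if (!is.null(args$frame_dim)) args$frame_dim <- unlist(args$frame_dim)
  if (!is.null(args$ab_ratio)) args$ab_ratio <- unlist(args$ab_ratio)
  if (!is.null(seed)) args$seed <- seed
  keep <- intersect(names(args), names(formals(population_config)))
  config <- do.call(population_config, args[keep])
  stack <- render_stack(generate_population(config))
  write_stack(stack, file.path(out_dir, "stack"))
  "stack"
}

pipeline_analyze <- function(cfg, seed, out_dir) {
  require_fields(cfg, "stack", "analyze")
  if (!dir.exists(cfg$stack))
    stop_domain("config validation failed (analyze): stack directory '",
                cfg$stack, "' does not exist")
  an <- analyze_stack(cfg$stack,
                      min_area = cfg$min_area %||% 64,
                      max_displacement = cfg$max_displacement %||% 15)
  percell <- do.call(rbind, lapply(an$traces, function(tr)
    data.frame(cell_id = tr$id, t = tr$times, I_tot = tr$I_tot,
               I_norm = tr$I_norm, M2 = tr$M2, CVp = tr$CV_p)))
  write.csv(percell, file.path(out_dir, "cells.csv"), row.names = FALSE)
  write.csv(an$population$cells, file.path(out_dir, "population.csv"),
            row.names = FALSE)
  stats <- an$population$class_stats
  if (!is.null(stats))
    write.csv(stats, file.path(out_dir, "class_stats.csv"),
              row.names = FALSE)
  c("cells.csv", "population.csv",
    if (!is.null(stats)) "class_stats.csv")
}

pipeline_figures <- function(cfg, seed, out_dir) {
  seed <- seed %||% 1
  # trap-walk MSD, uniform and periodically perturbed rates
  base_cfg <- walk_config(n_walkers = cfg$n_walkers %||% 3000,
                          horizon = cfg$horizon %||% 200, seed = seed)
  mc_u <- simulate_walk(base_cfg)
  ex <- msd_exact(base_cfg, mc_u$times)
  pert_cfg <- walk_config(amplitude = base_cfg$k_plus / 2,
                          n_walkers = base_cfg$n_walkers,
                          horizon = base_cfg$horizon, seed = seed + 1)
  mc_p <- simulate_walk(pert_cfg)
  df <- data.frame(t = mc_u$times, msd_uniform = mc_u$msd,
                   msd_perturbed = mc_p$msd, msd_exact = ex$msd)
  write.csv(df, file.path(out_dir, "walk_msd_figure.csv"),
            row.names = FALSE)
  # uptake per unit volume across Biot numbers
  d <- dye_defaults()
  times <- seq(0, 3600, by = 120)
  uptake <- sapply(c(0.1, 1, 10), function(Bi) {
    h_m <- Bi * d$transport$D / d$geometry$R_n
    st <- simulate_nonspecific(d$geometry,
                               transport_params(d$transport$D, h_m),
                               d$specific, d$nonspecific, d$bath,
                               times = times)
    drop(st$v %*% st$vol) / sum(st$vol)
  })
  df2 <- data.frame(t = times, Bi_0.1 = uptake[, 1], Bi_1 = uptake[, 2],
                    Bi_10 = uptake[, 3])
  write.csv(df2, file.path(out_dir, "uptake_biot_figure.csv"),
            row.names = FALSE)
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 9, height = 4)
  graphics::par(mfrow = c(1, 2))
  graphics::matplot(df$t, df[, -1], type = "l", log = "xy", lty = c(1, 1, 2),
                    xlab = "time", ylab = "<x^2>",
                    main = "Trapping walk MSD")
  graphics::matplot(df2$t, df2[, -1], type = "l", lty = 1,
                    xlab = "time (s)", ylab = "bound dye (uM)",
                    main = "Uptake vs Biot number")
  grDevices::dev.off()
  c("walk_msd_figure.csv", "uptake_biot_figure.csv", "figures.pdf")
}

#' Run a pipeline stage
#'
#' Executes one subcommand (`simulate-rd`, `walk`, `synth`, `analyze`,
#' `reproduce-figures`) from a YAML configuration, writes its outputs and
#' a JSON run manifest into `out_dir`, and returns an exit status:
#' 0 on success, 2 for a missing configuration file (usage error), 1 for
#' a validation or runtime failure (with a field-level message).
#' Identical configurations and seeds produce byte-identical CSV outputs
#' (the manifest timestamp aside).
#'
#' @param subcommand stage name.
#' @param config path to a YAML configuration (optional for
#'   `reproduce-figures`).
#' @param seed integer seed forwarded to every stochastic stage.
#' @param out_dir output directory (created).
#' @param overrides character vector of `key=value` pairs overriding
#'   configuration fields (values parsed as YAML).
#' @return integer exit status, invisibly.
#' @export
run_pipeline <- function(subcommand, config = NULL, seed = NULL,
                         out_dir = ".", overrides = character()) {
  runners <- list("simulate-rd" = pipeline_simulate_rd,
                  "walk" = pipeline_walk,
                  "synth" = pipeline_synth,
                  "analyze" = pipeline_analyze,
                  "reproduce-figures" = pipeline_figures)
  if (!subcommand %in% names(runners)) {
    message("unknown subcommand '", subcommand, "'")
    return(invisible(2L))
  }
  cfg <- list()
  if (!is.null(config) || subcommand != "reproduce-figures") {
    if (is.null(config) || !file.exists(config)) {
      message("missing config file", if (!is.null(config))
        paste0(": ", config))
      return(invisible(2L))
    }
    cfg <- read_config(config)
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      message("bad override (expected key=value): ", ov)
      return(invisible(2L))
    }
    cfg[[kv[1]]] <- yaml::yaml.load(kv[2])
  }
  status <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(seed)) set.seed(seed)
    outputs <- runners[[subcommand]](cfg, seed, out_dir)
    write_manifest(out_dir, subcommand, config, seed, outputs)
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
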