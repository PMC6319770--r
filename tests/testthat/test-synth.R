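# Synthetic-movie generator: determinism, sampling structure, noise
# model, protocol phenomenology and IO round trips.

tiny_cfg <- function(...) {
  args <- list(n_cells = 2, frame_dim = c(96, 96), n_frames = 8,
               dt = 300, total_time = 20000, a_mean = 5,
               gain = Inf, read_sd = 0, jitter_sd = 0, nr = 32)
  do.call(population_config, utils::modifyList(args, list(...)))
}

test_that("population sampling is seeded and matches configured fractions", {
  cfg <- population_config(n_cells = 200, frame_dim = c(3000, 3000),
                           seed = 7)
  t1 <- generate_population(cfg)
  t2 <- generate_population(cfg)
  expect_identical(t1, t2)
  # empirical class fraction within the binomial 99% interval around 0.4
  p_hat <- mean(t1$cls == "G2")
  expect_lt(abs(p_hat - 0.4), 2.58 * sqrt(0.4 * 0.6 / 200))
  # zero-CV configuration collapses to identical cells
  cfg0 <- population_config(n_cells = 5, frame_dim = c(512, 512),
                            a_cv = 0, ab_ratio = c(0.8, 0.8), hm_cv = 0,
                            capacity_cv = 0, g2_fraction = 0, seed = 1)
  t0 <- generate_population(cfg0)
  for (col in c("a_um", "b_um", "h_m", "capacity"))
    expect_equal(diff(range(t0[[col]])), 0)
  expect_error(generate_population(
    population_config(n_cells = 50, frame_dim = c(64, 64))), "infeasible")
})

test_that("rendering is deterministic under the configuration seed", {
  cfg <- tiny_cfg(seed = 9)
  s1 <- render_stack(generate_population(cfg))
  s2 <- render_stack(generate_population(cfg))
  expect_identical(s1$dye, s2$dye)
  expect_identical(s1$truth, s2$truth)
})

test_that("the noise model has the stated variance and is seeded", {
  flat <- matrix(400, 150, 150)
  noisy <- apply_noise(flat, gain = 2, read_sd = 3, seed = 5)
  expect_equal(var(as.vector(noisy)), 400 / 2 + 9, tolerance = 0.05)
  expect_identical(apply_noise(flat, 2, 3, seed = 5), noisy)
  expect_identical(apply_noise(flat, Inf, 0), flat)
  expect_error(apply_noise(flat, gain = -1, read_sd = 0), "> 0")
  expect_error(apply_noise(matrix(-1, 2, 2), 1, 0), "non-negative")
})

test_that("noiseless closed loop recovers the generative M2 and I_tot", {
  cfg <- population_config(n_cells = 1, frame_dim = c(96, 96),
                           pixel_size = 0.25, a_mean = 9, a_cv = 0,
                           ab_ratio = c(0.9, 0.9), hm_cv = 0,
                           capacity_cv = 0, g2_fraction = 0,
                           n_frames = 25, dt = 120, total_time = 30000,
                           gain = Inf, read_sd = 0, jitter_sd = 0,
                           nr = 48, seed = 3)
  stk <- render_stack(generate_population(cfg))
  an <- analyze_stack(stk)
  expect_length(an$records, 1)
  tr <- an$traces[[1]]
  truth <- stk$truth
  st <- simulate_nonspecific(
    nucleus_geometry(R_n = truth$R_n, nr = cfg$nr),
    transport_params(D = cfg$D, h_m = truth$h_m),
    binding_site(k_off = 0.1, K_d = 0.01, capacity = truth$capacity),
    binding_site(k_off = 0.5, K_d = 0.05, capacity = 100 * truth$capacity),
    bath_state(stk$u_ext$u_ext[1], depleting = FALSE,
               u_fun = approxfun(stk$u_ext$t, stk$u_ext$u_ext, rule = 2)),
    times = stk$times)
  gen <- trace_outputs(st, pixel_size = cfg$pixel_size)
  ok <- which(is.finite(tr$M2) & is.finite(gen$M2))
  expect_gt(length(ok), 20)
  expect_lt(sqrt(mean((tr$M2[ok] - gen$M2[ok])^2)) / mean(gen$M2[ok]), 0.01)
  expect_lt(sqrt(mean((tr$I_norm - gen$I_norm)^2)) / mean(gen$I_norm), 0.01)
})

test_that("cold chase leaves rendered intensity nearly flat after the chase", {
  t_c <- 3600
  prot <- protocol_spec(proto_replace(time = t_c, conc = 0))
  cfg <- population_config(n_cells = 3, frame_dim = c(128, 128),
                           a_mean = 5, frame_times = c(seq(0, 3600, 400),
                                                       seq(4200, 10800, 600)),
                           protocol = prot, gain = Inf, read_sd = 0,
                           jitter_sd = 0, nr = 32, seed = 4)
  stk <- render_stack(generate_population(cfg))
  an <- analyze_stack(stk)
  for (tr in an$traces) {
    post <- tr$times > t_c
    I <- tr$I_tot[post]
    k_eff <- -unname(coef(lm(log(I) ~ tr$times[post]))[2])
    expect_lt(abs(k_eff), 0.1 / 100)  # >= 100-fold below in vitro k_off
  }
})

test_that("sequential addition of a smaller dose still raises intensity", {
  prot <- protocol_spec(proto_add(time = 7200, conc = 0.12))
  cfg <- population_config(n_cells = 3, frame_dim = c(128, 128),
                           a_mean = 5, dye_conc = 0.25,
                           frame_times = c(seq(0, 7200, 600),
                                           seq(8400, 21600, 1200)),
                           protocol = prot, gain = Inf, read_sd = 0,
                           jitter_sd = 0, nr = 32, seed = 6)
  stk <- render_stack(generate_population(cfg))
  an <- analyze_stack(stk)
  Imat <- vapply(an$traces, function(tr) tr$I_tot,
                 numeric(length(stk$times)))
  pop_mean <- rowMeans(Imat)
  i2 <- which(stk$times == 7200)
  expect_gt(pop_mean[length(pop_mean)], 1.1 * pop_mean[i2])
})

test_that("stacks and ground truth round-trip through disk", {
  cfg <- tiny_cfg(seed = 10, gain = 5, read_sd = 2)
  stk <- render_stack(generate_population(cfg))
  dir <- file.path(tempdir(), "stack-roundtrip")
  write_stack(stk, dir)
  back <- read_stack(dir)
  expect_equal(back$times, stk$times)
  truth_out <- stk$truth
  attr(truth_out, "config") <- NULL
  expect_equal(as.data.frame(back$truth), as.data.frame(truth_out),
               tolerance = 1e-12)
  rel <- max(abs(back$dye[[5]] - stk$dye[[5]])) / max(stk$dye[[5]])
  expect_lt(rel, 1e-6)  # 32-bit float storage
  an <- analyze_stack(dir)
  expect_length(an$records, cfg$n_cells)
  unlink(dir, recursive = TRUE)
})
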