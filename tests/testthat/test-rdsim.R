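# Reaction-diffusion simulator: analytic oracles, conservation laws,
# protocol behaviour and the buffering phenomenology.

test_that("Biot number and constructors validate", {
  g <- nucleus_geometry(R_n = 10)
  expect_equal(biot_number(transport_params(D = 500, h_m = 0), g), 0)
  expect_equal(biot_number(transport_params(D = 500, h_m = 50), g), 1)
  expect_error(nucleus_geometry(R_n = 10, nr = 8), "16")
  expect_error(transport_params(D = 0), "> 0")
  expect_error(protocol_spec(proto_add(10, 1), proto_add(5, 1)),
               "increasing")
  expect_error(proto_permeabilize(0, cn_factor = 2), "0, 1")
})

test_that("empty bath and zero initial condition stay identically zero", {
  fx <- rd_fixture(nr = 32)
  st <- simulate_base(fx$geom, fx$transport, fx$specific,
                      bath_state(u_ext = 0, depleting = FALSE),
                      times = seq(0, 100, by = 50))
  expect_true(all(st$u == 0) && all(st$v == 0) && all(st$vn == 0))
})

test_that("pure diffusion matches the Robin-sphere eigenfunction series", {
  geom <- nucleus_geometry(R_n = 10, nr = 96)
  tr <- transport_params(D = 50, h_m = 5)  # Bi = 1
  st <- simulate_base(geom, tr, binding_site(k_off = 0.1, K_d = 0.01,
                                             capacity = 0),
                      bath_state(1, depleting = FALSE),
                      times = c(0, 0.05, 0.2, 0.5, 1, 2))
  for (k in 2:6) {
    oracle <- robin_sphere_series(st$r, st$times[k], 10, 50, 5, 1)
    expect_lt(max(abs(st$u[k, ] - oracle)), 0.005)  # <= 0.5% of u_ext
  }
})

test_that("large Biot numbers approach the Dirichlet series", {
  geom <- nucleus_geometry(R_n = 10, nr = 96)
  tr <- transport_params(D = 50, h_m = 2500)  # Bi = 500
  st <- simulate_base(geom, tr, binding_site(k_off = 0.1, K_d = 0.01,
                                             capacity = 0),
                      bath_state(1, depleting = FALSE),
                      times = c(0, 0.1, 0.3, 1))
  for (k in 2:4) {
    oracle <- dirichlet_sphere_series(st$r, st$times[k], 10, 50, 1)
    expect_lt(max(abs(st$u[k, ] - oracle)), 0.01)  # <= 1% of u_ext
  }
})

test_that("the base model saturates at the Langmuir steady state", {
  fx <- rd_fixture(nr = 48)
  s <- fx$specific
  st <- simulate_base(fx$geom, fx$transport, s,
                      bath_state(1, depleting = FALSE),
                      times = c(0, 5000))
  bound <- vol_avg(st)
  expect_equal(bound[2], s$capacity * 1 / (s$K_d + 1), tolerance = 5e-3)
  # free-target view recovers the complementary convention
  expect_equal(free_target(st)[2, ], s$capacity - st$v[2, ])
})

test_that("well-mixed limit agrees with a three-pool ODE oracle", {
  d <- dye_defaults()
  geom <- nucleus_geometry(R_n = 10, nr = 48)
  tr <- transport_params(D = 5e4, h_m = 1)  # interior mixing instantaneous
  times <- seq(0, 2000, by = 100)
  st <- simulate_nonspecific(geom, tr, d$specific, d$nonspecific,
                             bath_state(1, depleting = TRUE), times = times)
  orc <- wellmixed_threepool(10, 1, d$specific, d$nonspecific, 1,
                             st$bath$V_per_cell, times)
  expect_equal(vol_avg(st)[-1], unname(orc$v[-1]), tolerance = 1e-4)
  expect_equal(vol_avg(st, "vn")[-1], unname(orc$w[-1]), tolerance = 1e-4)
  expect_equal(st$u_ext[-1], unname(orc$u_ext[-1]), tolerance = 1e-4)
})

test_that("zero non-specific capacity reduces to the base model", {
  fx <- rd_fixture(nr = 48)
  times <- seq(0, 600, by = 100)
  bath <- bath_state(1, depleting = TRUE)
  st0 <- simulate_base(fx$geom, fx$transport, fx$specific, bath,
                       times = times)
  stn <- simulate_nonspecific(fx$geom, fx$transport, fx$specific,
                              binding_site(k_off = 0.5, K_d = 0.05,
                                           capacity = 0),
                              bath, times = times)
  expect_lt(max(abs(st0$v - stn$v)) / max(st0$v), 1e-8)
  expect_true(all(stn$vn == 0))
})

test_that("closed systems conserve dye mass", {
  fx <- rd_fixture(nr = 64)
  prot <- protocol_spec(proto_permeabilize(time = 200, hm_factor = 0))
  st <- simulate_nonspecific(fx$geom, fx$transport, fx$specific,
                             fx$nonspecific, bath_state(1, depleting = TRUE),
                             prot, times = seq(0, 2000, by = 50))
  m <- total_mass(st)
  closed <- st$times >= 200
  drift <- (max(m[closed]) - min(m[closed])) / m[closed][1]
  expect_lt(drift, 1e-6)
  # fields stay within physical bounds
  expect_true(all(st$v >= -1e-9 & st$v <= fx$specific$capacity * (1 + 1e-9)))
  expect_true(all(st$vn <= fx$nonspecific$capacity * (1 + 1e-9)))
})

test_that("doubling the radial grid changes traces by less than 0.2%", {
  d <- dye_defaults()
  times <- seq(0, 1800, by = 120)
  runs <- lapply(c(64, 128), function(nr)
    simulate_nonspecific(nucleus_geometry(R_n = 10, nr = nr), d$transport,
                         d$specific, d$nonspecific,
                         bath_state(1, depleting = TRUE), times = times))
  I <- lapply(runs, vol_avg)
  expect_lt(max(abs(I[[1]] - I[[2]]) / pmax(I[[2]], max(I[[2]]) * 1e-3)),
            0.002)
})

test_that("buffered, depleting uptake is dose-sensitive where the base model is not", {
  fx <- rd_fixture(nr = 48)
  doses <- c(0.1, 1, 10)
  base_finals <- vapply(doses, function(u0) {
    st <- simulate_base(fx$geom, fx$transport, fx$specific,
                        bath_state(u0, depleting = FALSE),
                        times = c(0, 5000))
    vol_avg(st)[2]
  }, 0)
  ns_finals <- vapply(doses, function(u0) {
    st <- simulate_nonspecific(fx$geom, fx$transport, fx$specific,
                               fx$nonspecific,
                               bath_state(u0, depleting = TRUE),
                               times = c(0, 9000))
    vol_avg(st)[2]
  }, 0)
  # base model: dose-insensitive once u_ext >> K_d
  expect_lt(diff(range(base_finals[2:3])) / max(base_finals), 0.01)
  # buffering + depletion: strong sensitivity over the same range,
  # monotone in dose
  expect_gt(diff(range(ns_finals)) / max(ns_finals), 0.20)
  expect_true(all(diff(ns_finals) > 0))
  expect_gt(diff(range(ns_finals)) / max(ns_finals),
            10 * diff(range(base_finals[2:3])) / max(base_finals))
})

test_that("cold chase decays at least 100-fold slower than k_off", {
  d <- dye_defaults()
  geom <- nucleus_geometry(R_n = 10, nr = 48)
  prot <- protocol_spec(proto_replace(time = 3600, conc = 0))
  tt <- c(seq(0, 3600, by = 300), seq(3900, 7200, by = 300))
  st <- simulate_nonspecific(geom, d$transport, d$specific, d$nonspecific,
                             bath_state(1, depleting = TRUE), prot, tt)
  I <- vol_avg(st)
  post <- tt > 3600
  k_eff <- -unname(coef(lm(log(I[post]) ~ tt[post]))[2])
  expect_lt(k_eff, d$specific$k_off / 100)
  expect_equal(st$u_ext[match(3600, tt)], 0)  # bath actually replaced
})

test_that("the documented permeabilisation set accelerates initial uptake 2.5-3.5x", {
  d <- dye_defaults()
  geom <- nucleus_geometry(R_n = 10, nr = 48)
  times <- seq(0, 600, by = 30)
  slope0 <- function(st) {
    I <- vol_avg(st)
    (I[4] - I[1]) / (st$times[4] - st$times[1])
  }
  intact <- simulate_nonspecific(geom, d$transport, d$specific,
                                 d$nonspecific,
                                 bath_state(1, depleting = TRUE),
                                 times = times)
  perm <- simulate_nonspecific(
    geom,
    transport_params(d$transport$D,
                     d$transport$h_m * d$permeabilize$hm_factor),
    d$specific,
    binding_site(k_off = d$nonspecific$k_off, K_d = d$nonspecific$K_d,
                 capacity = d$nonspecific$capacity * d$permeabilize$cn_factor),
    bath_state(1, depleting = TRUE), times = times)
  ratio <- slope0(perm) / slope0(intact)
  expect_gte(ratio, 2.5)
  expect_lte(ratio, 3.5)
})

test_that("protocol events modify the bath and membrane as specified", {
  fx <- rd_fixture(nr = 32)
  prot <- protocol_spec(proto_add(time = 100, conc = 2),
                        proto_replace(time = 200, conc = 0.5))
  st <- simulate_nonspecific(fx$geom, fx$transport, fx$specific,
                             fx$nonspecific,
                             bath_state(1, depleting = FALSE), prot,
                             times = c(0, 99, 100, 150, 200, 250))
  expect_equal(st$u_ext[1], 1)
  expect_equal(st$u_ext[3], 3)       # 1 + 2 added
  expect_equal(st$u_ext[5], 0.5)     # replaced
  # permeabilisation releases non-specifically bound dye, conserving mass
  prot2 <- protocol_spec(proto_permeabilize(time = 300, hm_factor = 0,
                                            cn_factor = 0.5))
  st2 <- simulate_nonspecific(fx$geom, fx$transport, fx$specific,
                              fx$nonspecific, bath_state(1, depleting = TRUE),
                              prot2, times = seq(0, 600, by = 25))
  m <- total_mass(st2)
  expect_lt(abs(m[length(m)] - m[1]) / m[1], 1e-5)
})

test_that("competition reproduces co-addition peaks and pre-incubation plateaus", {
  d <- dye_defaults()
  geom <- nucleus_geometry(R_n = 10, nr = 48)
  tt <- seq(0, 10000, by = 250)
  # competitor absent (zero on-rate): identical to the buffered model
  inert <- binding_site(k_off = 0.02, k_on = 0)
  st_ref <- simulate_nonspecific(geom, d$transport, d$specific,
                                 d$nonspecific,
                                 bath_state(2, depleting = TRUE),
                                 times = tt)
  st_in <- simulate_competition(geom, d$transport, d$specific,
                                d$nonspecific, ligand2 = inert,
                                transport2 = d$competitor_transport,
                                bath2_conc = 2,
                                bath = bath_state(2, depleting = TRUE),
                                times = tt)
  expect_equal(vol_avg(st_in), vol_avg(st_ref), tolerance = 1e-6)
  # co-addition: rise, peak, fall of the dye signal
  co <- simulate_competition(geom, d$transport, d$specific, d$nonspecific,
                             ligand2 = d$competitor,
                             ligand2_nonspecific = d$nonspecific,
                             transport2 = d$competitor_transport,
                             bath2_conc = 2,
                             bath = bath_state(2, depleting = TRUE),
                             times = tt)
  I1 <- vol_avg(co)
  peak <- which.max(I1)
  expect_gt(peak, 3)
  expect_lt(peak, length(tt))
  expect_gt(max(I1) / I1[length(I1)], 1.2)
  expect_true(all(co$ligands[[1]]$v + co$ligands[[2]]$v <=
                  d$specific$capacity * (1 + 1e-6)))
  # pre-incubation: monotone plateau, decreasing with competitor dose
  t_pre <- 18000
  prot <- protocol_spec(proto_add(time = t_pre, conc = 2, ligand = 1))
  tt2 <- seq(0, t_pre + 10000, by = 500)
  plateaus <- vapply(c(1, 4), function(dox0) {
    pre <- simulate_competition(geom, d$transport, d$specific,
                                d$nonspecific, ligand2 = d$competitor,
                                ligand2_nonspecific = d$nonspecific,
                                transport2 = d$competitor_transport,
                                bath2_conc = dox0,
                                bath = bath_state(0, depleting = TRUE),
                                prot, times = tt2)
    I <- vol_avg(pre)
    post <- tt2 >= t_pre
    # monotone to within 1% of the plateau (no co-addition-style peak)
    expect_gt(I[length(I)], 0.99 * max(I[post]))
    I[length(I)]
  }, 0)
  expect_lt(plateaus[2], plateaus[1])
})
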