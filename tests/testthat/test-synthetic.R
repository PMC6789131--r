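test_that("the forward simulator reproduces closed-form two-state relaxation", {
  # two equal-dof residues coupled only to each other: the energy difference
  # decays as exp(-2 k t) and the total is conserved
  topo <- build_topology(2, "none", terminal_factor = 1)
  k <- 1.2
  model <- kinetic_model(topo, 300, k_backbone = k, k_hbond = 0, k_solvent = 0)
  tr <- simulate_master_equation(model, heater_protocol(delta_T = 670, duration = 1),
                                 t_total = 4, seed = 1, noise_scale = 0)[[1]]
  E <- energy_matrix_for_test(tr)
  times <- unique(tr$time)
  free <- times > 1 + 1e-9
  d0_idx <- which(free)[1]
  d0 <- E[1, d0_idx] - E[2, d0_idx]
  expected <- d0 * exp(-2 * k * (times[free] - times[d0_idx]))
  expect_rel_equal(E[1, free] - E[2, free], expected, 1e-6)

  total <- colSums(E[, free])
  expect_lt(max(abs(total - total[1])) / total[1], 1e-9)

  # all rates zero: energies frozen after release
  model0 <- kinetic_model(topo, 300, k_backbone = 0, k_hbond = 0, k_solvent = 0)
  tr0 <- simulate_master_equation(model0, heater_protocol(duration = 1),
                                  t_total = 3, seed = 1, noise_scale = 0)[[1]]
  E0 <- energy_matrix_for_test(tr0)
  post <- unique(tr0$time) > 1
  expect_equal(max(apply(E0[, post], 1, function(x) diff(range(x)))), 0)
})

test_that("total energy is conserved without solvent coupling over 50 ps", {
  run <- reference_run()
  model <- kinetic_model(run$topology, 300, k_backbone = 1.5, k_hbond = 0.5,
                         k_solvent = 0)
  tr <- simulate_master_equation(model, heater_protocol(),
                                 t_total = 50, seed = 1, noise_scale = 0)[[1]]
  E <- energy_matrix_for_test(tr)
  free <- unique(tr$time) > 1 + 1e-9
  total <- colSums(E[, free])
  expect_lt(max(abs(total - total[1])) / total[1], 1e-9)
})

test_that("with solvent coupling every residue relaxes to the bath energy", {
  topo <- build_topology(6, "310", terminal_factor = 1)
  ks <- 0.3
  model <- kinetic_model(topo, 280, k_backbone = 1.5, k_hbond = 0.5,
                         k_solvent = ks)
  tr <- simulate_master_equation(model, heater_protocol(delta_T = 500),
                                 t_total = 30, seed = 1, noise_scale = 0)[[1]]
  E <- energy_matrix_for_test(tr)
  times <- unique(tr$time)
  Es <- energy_from_temperature(280, topo$dof)
  dev <- colSums(abs(E - Es))
  # relaxation envelope: total deviation bounded by exp(-ks t / 2) decay
  i1 <- which(times > 2)[1]
  late <- times > 2
  bound <- dev[i1] * exp(-ks * (times[late] - times[i1]) / 2)
  expect_true(all(dev[late] <= bound * 1.05))
  expect_lt(dev[length(dev)] / dev[i1], 1e-3)
})

test_that("equipartition initial conditions are a fixed point of the dynamics", {
  topo <- build_topology(5, "310")
  model <- kinetic_model(topo, 300, k_backbone = 2, k_hbond = 0.7,
                         k_solvent = 0.4)
  # no heater perturbation: delta_T = 0 keeps the chain at the bath
  tr <- simulate_master_equation(model, heater_protocol(delta_T = 0),
                                 t_total = 5, seed = 1, noise_scale = 0)[[1]]
  E <- energy_matrix_for_test(tr)
  E0 <- energy_from_temperature(300, topo$dof)
  expect_lt(max(abs(E - E0)) / max(E0), 1e-12)
})

test_that("Arrhenius mode reduces to constant rates at zero barrier", {
  topo <- build_topology(6, "310")
  om <- 1.7
  m_arr <- kinetic_model(topo, 300, k_solvent = 0.05,
                         temperature_dependent = TRUE, omega = om, barrier = 0)
  m_const <- kinetic_model(topo, 300, k_backbone = om, k_hbond = om,
                           k_solvent = 0.05)
  t1 <- simulate_master_equation(m_arr, heater_protocol(), t_total = 3,
                                 seed = 1, noise_scale = 0)[[1]]
  t2 <- simulate_master_equation(m_const, heater_protocol(), t_total = 3,
                                 seed = 1, noise_scale = 0)[[1]]
  expect_equal(t1$energy, t2$energy, tolerance = 1e-12)
})

test_that("recorded noise matches the equipartition fluctuation model", {
  topo <- build_topology(2, "none", terminal_factor = 1)
  model <- kinetic_model(topo, 300, k_backbone = 0, k_hbond = 0, k_solvent = 0)
  scale <- 0.5
  # equilibrium chain, many members: recorded-energy variance must match
  # (f/2) (kB T)^2 scale^2 within 5% at ~1e4 samples
  ens <- simulate_master_equation(model, heater_protocol(delta_T = 0),
                                  t_total = 25, n_members = 40, seed = 7,
                                  noise_scale = scale)
  samples <- unlist(lapply(ens, function(tr) tr$energy[tr$residue == 1]))
  expect_gt(length(samples), 1e4 - 1)
  expected_var <- (topo$dof[1] / 2) * (kB * 300)^2 * scale^2
  expect_equal(stats::var(samples), expected_var, tolerance = 0.05)
})

test_that("member noise streams are reproducible and order-independent", {
  run1 <- reference_run(t_total = 1, n_members = 3, noise_scale = 1, seed = 11)
  run2 <- reference_run(t_total = 1, n_members = 3, noise_scale = 1, seed = 11)
  expect_identical(run1$ensemble[[2]]$energy, run2$ensemble[[2]]$energy)
  # a larger ensemble reproduces the smaller one's members
  run3 <- reference_run(t_total = 1, n_members = 5, noise_scale = 1, seed = 11)
  expect_identical(run3$ensemble[[2]]$energy, run1$ensemble[[2]]$energy)
  # different seed, different noise
  run4 <- reference_run(t_total = 1, n_members = 3, noise_scale = 1, seed = 12)
  expect_false(identical(run4$ensemble[[1]]$energy, run1$ensemble[[1]]$energy))
})

test_that("the RK4 integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  topo <- build_topology(4, "310", terminal_factor = 1.5)
  model <- kinetic_model(topo, 300, k_backbone = 1.5, k_hbond = 0.5,
                         k_solvent = 0.2)
  tr <- simulate_master_equation(model, heater_protocol(duration = 1),
                                 t_total = 3, seed = 1, noise_scale = 0)[[1]]
  E <- energy_matrix_for_test(tr)
  times <- unique(tr$time)
  # independent route: deSolve::lsoda from the state at heater release
  f <- topo$dof
  Es <- energy_from_temperature(300, f)
  i0 <- which(times >= 1 - 1e-9)[1]
  rhs <- function(t, y, parms) {
    dy <- -topo$surface_factor * 0.2 * (y - Es)
    for (r in seq_len(nrow(topo$pairs))) {
      a <- topo$pairs$i[r]; b <- topo$pairs$j[r]
      k <- if (topo$pairs$channel[r] == "backbone") 1.5 else 0.5
      X <- k * (y[a] - (f[a] / f[b]) * y[b])
      dy[a] <- dy[a] - X
      dy[b] <- dy[b] + X
    }
    list(dy)
  }
  ref <- deSolve::lsoda(y = E[, i0], times = times[i0:length(times)] - times[i0],
                        func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_rel_equal(as.numeric(t(ref[, -1])),
                   as.numeric(E[, i0:length(times)]), 1e-6)
})

test_that("the fixture battery is deterministic and recoverable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_fixture_suite(5, d1, members_constant = 1, members_arrhenius = 2,
                           t_total = 3)
  m2 <- make_fixture_suite(5, d2, members_constant = 1, members_arrhenius = 2,
                           t_total = 3)
  # same seed -> byte-identical files
  for (f in m1$file) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # six bath temperatures for each battery
  expect_equal(sum(m1$kind == "constant"), 6)
  expect_equal(sum(m1$kind == "arrhenius"), 12)

  # a constant-rate fixture passed back through the fit recovers its rates
  topo <- build_topology(10, "310")
  tr <- read_energy_trajectory(file.path(d1, "constant_T270_m001.dat"))
  rates <- fit_rates(tr, topo)
  bb <- tibble::as_tibble(rates)
  bb <- bb[bb$channel == "backbone" & bb$time > 1.15, ]
  expect_rel_equal(bb$rate, rep(1.5, nrow(bb)), 0.05)
})

test_that("the harmonic lattice conserves energy and carries sound-speed pulses", {
  # microcanonical harmonic chain with one kicked site
  v0 <- numeric(64); v0[8] <- 3
  frames <- simulate_lattice(n_sites = 64, quartic_beta = 0, t_bath = 0,
                             delta_T = 0, heat_duration = 0, friction = 0,
                             dt = 2e-5, t_total = 10, record_interval = 0.05,
                             equil_time = 0, seed = 3, thermostat_bath = FALSE,
                             v0 = v0)
  en <- lattice_total_energy(frames, quartic_beta = 0)
  expect_lt(max(abs(en$energy - en$energy[1])) / en$energy[1], 1e-8)

  # the pulse front propagates at the band-edge sound speed a sqrt(k/m)
  cs <- attr(frames, "sound_speed")
  tr <- aggregate_atoms(frames, bath_temperature = 0, heater_index = 1L,
                        dof = NULL)
  agg <- matrix(tr$energy, nrow = length(attr(tr, "dof")))
  # use per-site kinetic energy arrival times over mid-chain sites
  V <- matrix(frames$vx, nrow = 64)
  ke <- 0.5 * 12 * V^2 * eV_per_u_nm2_ps2
  times <- unique(frames$time)
  thresh <- 0.02 * max(ke)
  sites <- 16:48
  arr <- vapply(sites, function(s) times[which(ke[s, ] > thresh)[1]], 0)
  dist <- (sites - 8) * attr(frames, "spacing")
  fit <- stats::lm(dist ~ arr)
  v_meas <- unname(stats::coef(fit)["arr"])
  expect_equal(v_meas, cs, tolerance = 0.05)
})

test_that("the thermostatted lattice equilibrates to the bath temperature", {
  frames <- simulate_lattice(n_sites = 32, t_bath = 300, delta_T = 0,
                             heat_duration = 0, friction = 5, dt = 2e-4,
                             t_total = 40, record_interval = 0.02,
                             equil_time = 5, seed = 13,
                             thermostat_always = TRUE)
  V <- matrix(frames$vx, nrow = 32)
  # per-site kinetic temperature: m <v^2> / kB (one dof per site)
  kin_T <- 12 * rowMeans(V^2) * eV_per_u_nm2_ps2 / kB
  # mean over sites within 3 sem of the target
  sem <- stats::sd(kin_T) / sqrt(length(kin_T))
  expect_lt(abs(mean(kin_T) - 300), 3 * sem + 3)
})
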