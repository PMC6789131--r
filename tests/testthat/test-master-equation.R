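test_that("topologies enumerate helix hydrogen bonds and validate custom pairs", {
  t310 <- build_topology(10, "310")
  bb <- t310$pairs[t310$pairs$channel == "backbone", ]
  hb <- t310$pairs[t310$pairs$channel == "hbond", ]
  expect_equal(nrow(bb), 9)
  expect_equal(bb$i, 1:9)
  expect_equal(hb$i, 1:7)
  expect_equal(hb$j, 4:10)

  talpha <- build_topology(10, "alpha")
  hba <- talpha$pairs[talpha$pairs$channel == "hbond", ]
  expect_equal(hba$j - hba$i, rep(4L, 6))

  # two residues: backbone only, whatever the helix class
  t2 <- build_topology(2, "310")
  expect_equal(nrow(t2$pairs), 1)

  expect_error(build_topology(10, "custom", hbond_pairs = cbind(1, 12)),
               "out of range")
  expect_error(build_topology(10, "custom", hbond_pairs = rbind(c(1, 4), c(1, 4))),
               "duplicated")
  # terminal surface factors
  expect_equal(t310$surface_factor, c(1.5, rep(1, 8), 1.5))
})

test_that("detailed balance fixes the reverse rate so equipartition is stationary", {
  expect_equal(detailed_balance_reverse(2, 39, 39), 2)
  expect_equal(detailed_balance_reverse(2, dof_donor = 78, dof_acceptor = 39), 4)
  # stationarity: pair fluxes cancel at E proportional to f
  f <- c(78, 39)
  E <- energy_from_temperature(300, f)
  k_fwd <- 2
  k_rev <- detailed_balance_reverse(k_fwd, f[1], f[2])
  expect_equal(k_fwd * E[1], k_rev * E[2], tolerance = 1e-12)
  expect_error(detailed_balance_reverse(1, -3, 3), "positive")
})

test_that("solvent rate recovers pure bath relaxation and guards degenerate bins", {
  # forward-simulate pure solvent relaxation (no intra-peptide coupling)
  topo <- build_topology(4, "none", terminal_factor = 1)
  model <- kinetic_model(topo, 300, k_backbone = 0, k_hbond = 0, k_solvent = 0.8)
  tr <- simulate_master_equation(model, heater_protocol(delta_T = 400, duration = 0.5),
                                 t_total = 3, seed = 1, noise_scale = 0)[[1]]
  for (n in c(10, 15, 25)) {  # bins after heater release
    sv <- solvent_rate(tr, topo, n)
    expect_equal(sv$k_s, 0.8, tolerance = 0.01)
    expect_false(sv$clamped)
  }

  # constant energies -> zero rate
  Ec <- matrix(0.6, 3, 4)
  trc <- as_energy_trajectory(Ec, times = seq(0, 0.3, 0.1), dof = 39,
                              bath_temperature = 300)
  topo3 <- build_topology(3, "none")
  expect_equal(solvent_rate(trc, topo3, 2)$k_s, 0)

  # single residue dropping from Es + 2 delta to Es + delta in one 0.1 ps bin:
  # the estimator returns 1/dt (cooling is a positive solvent rate)
  delta <- 0.01
  Es <- energy_from_temperature(300, 39)
  E2 <- rbind(c(Es + 2 * delta, Es + delta), c(Es, Es))
  tr2 <- as_energy_trajectory(E2, times = c(0, 0.1), dof = 39,
                              bath_temperature = 300)
  topo2 <- build_topology(2, "none", terminal_factor = 1)
  sv2 <- solvent_rate(tr2, topo2, 2, guard = 1e-6)
  # midpoint denominator: -(-delta) / (1.5 delta * 0.1)
  expect_equal(sv2$k_s, 1 / (1.5 * 0.1), tolerance = 1e-9)

  # everything at the bath energy: guarded out, flagged degenerate
  Eb <- matrix(Es, 2, 3)
  trb <- as_energy_trajectory(Eb, times = c(0, 0.1, 0.2), dof = 39,
                              bath_temperature = 300)
  svb <- solvent_rate(trb, topo2, 2)
  expect_true(svb$degenerate)
  expect_equal(svb$k_s, 0)

  expect_error(solvent_rate(tr2, topo2, 1), "n must be in")
})

test_that("assembled systems have the documented shape and null cases", {
  # equipartition with k_s = 0: G and d identically zero
  topo <- build_topology(3, "none", terminal_factor = 1)
  Es <- energy_from_temperature(300, 39)
  Eq <- matrix(Es, 3, 2)
  treq <- as_energy_trajectory(Eq, times = c(0, 0.1), dof = 39,
                               bath_temperature = 300)
  sys <- assemble_system(treq, topo, 2, k_s = 0)
  expect_true(all(sys$G == 0))
  expect_true(all(sys$d == 0))

  # 2-residue, equal dof, E = (2, 1): backbone column is (-1, +1)
  E2 <- cbind(c(2, 1), c(2, 1))
  tr2 <- as_energy_trajectory(E2, times = c(0, 0.1), dof = 39,
                              bath_temperature = 300)
  topo2 <- build_topology(2, "none", terminal_factor = 1)
  sys2 <- assemble_system(tr2, topo2, 2, k_s = 0)
  expect_equal(sys2$G[, 1], c(-1, 1))

  # 10-residue 3_10 system: G is 10 x 10 (9 backbone + 1 hbond column)
  run <- reference_run(t_total = 1)
  sys10 <- assemble_system(run$ensemble[[1]], run$topology, 5, k_s = 0.05)
  expect_equal(dim(sys10$G), c(10, 10))
  expect_error(assemble_system(run$ensemble[[1]], run$topology, 999, 0), "n must be in")
})

test_that("fitting recovers constant rates on noiseless synthetic relaxation", {
  run <- reference_run(t_total = 6)
  tr <- run$ensemble[[1]]
  rates <- fit_rates(tr, run$topology)
  expect_true(all(rates$rate[!is.na(rates$rate)] >= 0))

  # free-relaxation bins away from equipartition (skipping the single
  # release-transient bin, where the steep post-release transient carries an
  # O((lambda dt)^2) finite-difference bias): every rate within 5%, and
  # within 2% once the relaxation has settled
  fx <- compute_fluxes(tr, run$topology, rates)
  informative <- dplyr::filter(tibble::as_tibble(fx),
                               .data$time > 1.15, abs(.data$gradient) >= 1)
  joined <- dplyr::inner_join(
    informative,
    tibble::as_tibble(rates)[, c("time", "i", "j", "rate", "channel")],
    by = c("time", "i", "j", "channel"), suffix = c("", "_fit")
  )
  bb <- joined[joined$channel == "backbone", ]
  expect_gt(nrow(bb), 50)
  expect_rel_equal(bb$rate, rep(1.5, nrow(bb)), 0.05)
  settled <- bb[bb$time > 1.25, ]
  expect_rel_equal(settled$rate, rep(1.5, nrow(settled)), 0.02)

  ks <- dplyr::filter(tibble::as_tibble(rates), term == "k_solvent", time > 1.15)
  expect_rel_equal(ks$rate, rep(0.05, nrow(ks)), 0.02)

  # equilibrium trajectory: degenerate flag, zero rates
  Es <- energy_from_temperature(300, run$topology$dof)
  Eq <- matrix(Es, 10, 5)
  treq <- as_energy_trajectory(Eq, times = seq(0, 0.4, 0.1),
                               dof = run$topology$dof, bath_temperature = 300)
  req <- fit_rates(treq, run$topology)
  expect_true(all(req$degenerate))
  expect_true(all(req$rate[req$channel != "solvent"] == 0, na.rm = TRUE))
})

test_that("a three-residue single-window fit matches the brute-force grid oracle", {
  topo <- build_topology(3, "none", terminal_factor = 1)
  model <- kinetic_model(topo, 300, k_backbone = c(1.2, 0.7), k_hbond = 0,
                         k_solvent = 0.1)
  tr <- simulate_master_equation(model, heater_protocol(delta_T = 500),
                                 t_total = 3, seed = 3, noise_scale = 0)[[1]]
  n <- 20
  sv <- solvent_rate(tr, topo, n)
  sys <- assemble_system(tr, topo, n, sv$k_s)
  G <- sys$G[, 1:2]  # no hbond column for a bare 3-chain
  sol <- nnls_fit(G, sys$d)
  oracle <- grid_nnls_oracle(G, sys$d, upper = 3, n_grid = 301)
  expect_lt(max(abs(sol$x - oracle$x)), 2 * oracle$step)
})

test_that("fluxes carry the away-from-heater sign convention and gradients are consistent", {
  run <- reference_run(t_total = 3)
  tr <- run$ensemble[[1]]
  rates <- fit_rates(tr, run$topology)
  fx <- tibble::as_tibble(compute_fluxes(tr, run$topology, rates))

  # k = 0 gives zero flux
  zero_rates <- rates
  zero_rates$rate[zero_rates$channel != "solvent"] <- 0
  fx0 <- compute_fluxes(tr, run$topology, zero_rates)
  expect_true(all(fx0$flux == 0))

  # early after the heater releases, flow through (1,2) is away from residue 1
  early <- fx[fx$i == 1 & fx$j == 2 & fx$time > 1.1 & fx$time < 2, ]
  expect_true(all(early$flux > 0))
  expect_true(all(early$gradient > 0))

  # J = k * X with the published bracket: spot check one record
  E <- energy_matrix_for_test(tr)
  times <- unique(tr$time)
  n <- 15
  Em <- (E[, n] + E[, n - 1]) / 2
  rec <- fx[fx$time == times[n] & fx$i == 1 & fx$j == 2, ]
  k <- rates$rate[rates$time == times[n] & rates$term == "k_1_2"]
  expect_equal(rec$flux, k * (Em[1] - Em[2]), tolerance = 1e-12)

  # heater on the far side flips the sign convention
  tr2 <- tr
  attr(tr2, "heater_index") <- 10L
  fx2 <- tibble::as_tibble(compute_fluxes(tr2, run$topology, rates))
  expect_equal(fx2$flux, -fx$flux, tolerance = 1e-12)
})

test_that("the effective gradient vanishes at equipartition and inverts cleanly", {
  kB <- thermokin::kB_eV
  # equipartition null
  expect_equal(effective_gradient(2 * 0.3, 0.3, 78, 39, 13), 0)
  # equal dof: E difference of (3/2) N kB 10 K maps to exactly 10 K
  dE <- 1.5 * 13 * kB * 10
  expect_equal(effective_gradient(0.5 + dE, 0.5, 39, 39, 13), 10,
               tolerance = 1e-12)
  # arithmetic spot value: 2 * 0.01 / (3 * 13 * kB)
  expect_equal(effective_gradient(0.51, 0.50, 39, 39, 13), 5.95,
               tolerance = 1e-3)
  expect_error(effective_gradient(1, 1, 39, 39, 0), "n_atoms")
})

test_that("fitted model closes the energy budget and leaves equipartition stationary", {
  run <- reference_run(t_total = 4)
  tr <- run$ensemble[[1]]
  rates <- fit_rates(tr, run$topology)
  E <- energy_matrix_for_test(tr)
  times <- unique(tr$time)
  per_bin <- dplyr::distinct(tibble::as_tibble(rates)[, c("time", "residual_norm")])
  for (n in c(15, 25, 35)) {
    fd <- (E[, n] - E[, n - 1]) / (times[n] - times[n - 1])
    rhs <- model_rhs(tr, run$topology, rates, n)
    res <- per_bin$residual_norm[abs(per_bin$time - times[n]) < 1e-9]
    expect_lte(sqrt(sum((fd - rhs)^2)), res + 1e-8)
  }

  # forward dynamics built from the fitted rates keep equipartition fixed
  f <- run$topology$dof
  Eeq <- energy_from_temperature(300, f)
  n <- 20
  rhs_eq <- model_rhs_at_energy_for_test(Eeq, run$topology, rates, times[n])
  expect_lt(max(abs(rhs_eq)), 1e-12)
})

test_that("fitted rates are invariant under a global energy rescaling", {
  run <- reference_run(t_total = 3)
  tr <- run$ensemble[[1]]
  rates1 <- fit_rates(tr, run$topology)
  tr2 <- tr
  tr2$energy <- tr$energy * 3.7
  attr(tr2, "bath_temperature") <- 300 * 3.7  # scales E_s by the same factor
  rates2 <- fit_rates(tr2, run$topology)
  expect_equal(rates2$rate, rates1$rate, tolerance = 1e-9)
})
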