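# shared in-code fixtures for the suite

kB <- thermokin::kB_eV

# small trajectory built directly from a matrix
toy_trajectory <- function(E = rbind(c(2, 1.5, 1.2), c(1, 1.25, 1.3)),
                           times = c(0, 0.1, 0.2), dof = 39, tb = 300) {
  as_energy_trajectory(E, times = times, dof = dof, bath_temperature = tb,
                       heater_index = 1L)
}

# noiseless constant-rate reference ensemble (the standard study conditions:
# 10 residues, 3_10 topology, heater at residue 1, kBB 1.5 / kHB 0.5 /
# ks 0.05 ps^-1)
reference_run <- function(t_total = 6, tb = 300, n_members = 1,
                          noise_scale = 0, seed = 1) {
  topo <- build_topology(10, helix = "310")
  model <- kinetic_model(topo, tb, k_backbone = 1.5, k_hbond = 0.5,
                         k_solvent = 0.05)
  ens <- simulate_master_equation(model, heater_protocol(),
                                  t_total = t_total, n_members = n_members,
                                  seed = seed, noise_scale = noise_scale)
  list(topology = topo, model = model, ensemble = ens)
}

# dense non-negative grid minimiser of ||G k - d||^2: brute-force oracle for
# systems with <= 3 unknowns
grid_nnls_oracle <- function(G, d, upper = NULL, n_grid = 61) {
  p <- ncol(G)
  d <- as.numeric(d)
  stopifnot(p <= 3)
  if (is.null(upper)) {
    upper <- max(2 * sum(abs(qr.coef(qr(G), d)), na.rm = TRUE), 1)
  }
  axes <- rep(list(seq(0, upper, length.out = n_grid)), p)
  grid <- as.matrix(expand.grid(axes))
  obj <- colSums((G %*% t(grid) - d)^2)
  list(x = grid[which.min(obj), ], step = upper / (n_grid - 1))
}

# build a transport_profile directly from an elevation matrix (residues x bins)
profile_from_matrix_for_test <- function(M, times, spacing = 0.2,
                                         heater = 1L, tb = 300) {
  out <- tibble::tibble(
    time = rep(times, each = nrow(M)),
    residue = rep(seq_len(nrow(M)), times = length(times)),
    elevation = as.numeric(M),
    sem = 0
  )
  structure(out, n_members = 1L, label = "test", bath_temperature = tb,
            dof = rep(39, nrow(M)), heater_index = heater,
            class = c("transport_profile", class(out)))
}

# residue-by-frame matrix view used by assertions
energy_matrix_for_test <- function(tr) {
  matrix(tr$energy, nrow = length(attr(tr, "dof")))
}

textConnection_path <- function(lines) {
  p <- tempfile()
  writeLines(lines, p)
  p
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}

# evaluate the fitted master-equation right-hand side at an arbitrary energy
# vector, using the rates of the bin closest to `time`
model_rhs_at_energy_for_test <- function(E, topo, rates, time) {
  f <- topo$dof
  kbin <- rates[abs(rates$time - time) < 1e-9, ]
  k_of <- stats::setNames(kbin$rate, kbin$term)
  Es <- thermokin::solvent_energy(f, attr(rates, "bath_temperature"))
  rhs <- numeric(topo$n_residues)
  for (r in seq_len(nrow(topo$pairs))) {
    a <- topo$pairs$i[r]; b <- topo$pairs$j[r]
    k <- if (topo$pairs$channel[r] == "backbone") {
      k_of[sprintf("k_%d_%d", a, b)]
    } else k_of["k_hbond"]
    X <- k * (E[a] - (f[a] / f[b]) * E[b])
    rhs[a] <- rhs[a] - X
    rhs[b] <- rhs[b] + X
  }
  rhs - topo$surface_factor * k_of["k_solvent"] * (E - Es)
}

# bin-then-average route: average members first, then block-average the mean
block_average_profile_for_test <- function(ens, dt) {
  ensemble_profile(list(block_average(ensemble_mean_trajectory(ens), dt)),
                   label = "x")
}

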