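#' Kinetic model for the forward master-equation simulator
#'
#' Bundles a contact topology with transfer-rate parameters. Two modes:
#'
#' * constant rates: `k_backbone` (scalar or per-link), `k_hbond`;
#' * activated (Arrhenius) rates, `temperature_dependent = TRUE`:
#'   `k = omega * exp(-barrier / (kB T_local))` per channel, with `T_local`
#'   the arithmetic mean of the pair's instantaneous kinetic temperatures.
#'
#' Solvent coupling is always `R_j k_solvent (E_j - E_s,j)` with
#' `E_s,j = (f_j/2) kB T_B` constant.
#'
#' @param topology A `contact_topology`.
#' @param bath_temperature Bath temperature T_B, K.
#' @param k_backbone,k_hbond Constant-rate mode rates, ps^-1.
#' @param k_solvent Solvent rate, ps^-1.
#' @param temperature_dependent Use Arrhenius rates?
#' @param omega,barrier Arrhenius parameters per channel: scalars or named
#'   vectors `c(backbone = , hbond = )` (ps^-1 and eV).
#' @return A `kinetic_model` list.
#' @export
kinetic_model <- function(topology, bath_temperature,
                          k_backbone = 1.5, k_hbond = 0.5, k_solvent = 0.05,
                          temperature_dependent = FALSE,
                          omega = 5, barrier = 0.05) {
  stopifnot(inherits(topology, "contact_topology"))
  pairs <- topology$pairs
  n_bb <- sum(pairs$channel == "backbone")
  k_bb <- rep_len(k_backbone, n_bb)
  if (any(k_bb < 0) || any(k_hbond < 0) || k_solvent < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  chan <- function(x) {
    if (is.null(names(x))) rep_len(x, 2) else c(x[["backbone"]], x[["hbond"]])
  }
  om <- chan(omega); dg <- chan(barrier)
  if (any(om < 0) || any(dg < 0)) stop("omega and barrier must be >= 0", call. = FALSE)
  structure(
    list(
      topology = topology,
      bath_temperature = bath_temperature,
      k_pairs = {
        kp <- rep(as.numeric(k_hbond), nrow(pairs))
        kp[pairs$channel == "backbone"] <- k_bb[pairs$i[pairs$channel == "backbone"]]
        kp
      },
      omega_pairs = ifelse(pairs$channel == "backbone", om[1], om[2]),
      barrier_pairs = ifelse(pairs$channel == "backbone", dg[1], dg[2]),
      k_solvent = k_solvent,
      temperature_dependent = temperature_dependent,
      solvent_e = solvent_energy(topology$dof, bath_temperature)
    ),
    class = "kinetic_model"
  )
}

#' Transient heater protocol
#'
#' One residue is pinned at the elevated energy
#' `(f/2) kB (T_B + delta_T)` for `duration` picoseconds (the deterministic
#' analogue of thermostatting it), then the whole chain relaxes freely.
#'
#' @param heater_index Heated residue, 1-based (default 1).
#' @param delta_T Temperature jump, K (default 670).
#' @param duration Heating window, ps (default 1.0).
#' @param record_interval Output sampling interval, ps (default 0.1, the
#'   analysis timescale).
#' @return A `heater_protocol` list.
#' @export
heater_protocol <- function(heater_index = 1L, delta_T = 670, duration = 1.0,
                            record_interval = 0.1) {
  stopifnot(duration > 0, record_interval > 0)
  structure(list(heater_index = as.integer(heater_index), delta_T = delta_T,
                 duration = duration, record_interval = record_interval),
            class = "heater_protocol")
}

#' Forward-simulate the master equation with a transient heater
#'
#' Deterministic RK4 integration (internal step `h`, default 1e-3 ps) of the
#' residue-energy master equation, recorded every
#' `protocol$record_interval`. During the heater window the heater residue's
#' energy is pinned; afterwards all residues evolve freely. Finite-ensemble
#' noise is emulated per member by perturbing each recorded energy with an
#' independent Gaussian of standard deviation
#' `sqrt(f_j / 2) kB T_j(t) * noise_scale` (the equipartition fluctuation of
#' a residue's kinetic energy, scaled); noisy energies are floored at 0.
#' Member noise streams derive deterministically from `seed` and the member
#' counter, so ensembles are reproducible and order-independent.
#'
#' @param model A `kinetic_model`.
#' @param protocol A `heater_protocol` (residue count must fit the topology).
#' @param t_total Simulated time after heater switch-on, ps.
#' @param n_members Ensemble size.
#' @param seed Master seed (integer).
#' @param noise_scale Noise scale factor; 1 is the full equipartition
#'   fluctuation, 0 gives the noiseless ensemble.
#' @param h Internal RK4 step, ps.
#' @return A list of `n_members` `energy_trajectory` objects.
#' @export
simulate_master_equation <- function(model, protocol, t_total = 10,
                                     n_members = 1L, seed = 1L,
                                     noise_scale = 1, h = 1e-3) {
  stopifnot(inherits(model, "kinetic_model"), inherits(protocol, "heater_protocol"))
  topo <- model$topology
  if (protocol$heater_index < 1 || protocol$heater_index > topo$n_residues) {
    stop("heater index outside the chain", call. = FALSE)
  }
  f <- topo$dof
  Tb <- model$bath_temperature
  E0 <- energy_from_temperature(Tb, f)
  E_pin <- energy_from_temperature(Tb + protocol$delta_T, f[protocol$heater_index])

  sim <- simulate_me_cpp(
    E0 = E0, f = f, R = topo$surface_factor, Es = model$solvent_e,
    pair_a = topo$pairs$i - 1L, pair_b = topo$pairs$j - 1L,
    k_const = model$k_pairs, omega = model$omega_pairs,
    barrier = model$barrier_pairs,
    temp_dependent = model$temperature_dependent,
    k_s = model$k_solvent, heater = protocol$heater_index - 1L,
    E_pin = E_pin, duration = protocol$duration, h = h,
    t_total = t_total, record_interval = protocol$record_interval
  )
  E <- sim$energies
  times <- sim$times

  lapply(seq_len(n_members), function(m) {
    Em <- E
    if (noise_scale > 0) {
      old <- .Random.seed_get()
      set.seed(member_seed(seed, m))
      sdmat <- sqrt(f / 2) * kB_eV *
        temperature_from_energy(E, f) * noise_scale
      Em <- pmax(E + matrix(stats::rnorm(length(E), sd = as.numeric(sdmat)),
                            nrow = nrow(E)), 0)
      .Random.seed_restore(old)
    }
    as_energy_trajectory(Em, times = times, dof = f,
                         bath_temperature = Tb,
                         heater_index = protocol$heater_index,
                         ensemble_id = sprintf("member-%d", m))
  })
}

# save/restore the global RNG state so simulation noise draws do not disturb
# a caller's random stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Nonlinear-lattice (FPU-beta) surrogate simulation
#'
#' A one-dimensional chain with harmonic plus quartic nearest-neighbour
#' interactions - a minimal nonlinear heat-conduction model standing in for
#' an all-atom run. Integration is velocity Verlet with BAOAB Langevin
#' thermostatting of the heater segment (at `t_bath + delta_T`) and,
#' optionally, the remaining sites (at `t_bath`) during the heating window;
#' afterwards the chain is microcanonical unless `thermostat_always`.
#' Consecutive groups of `group_size` sites form pseudo-residues so lattice
#' output feeds the same pipeline as peptide data.
#'
#' @param n_sites Chain length (default 64).
#' @param mass Site mass, u (default 12).
#' @param harmonic_k Harmonic constant, eV/nm^2 (default 3.1, giving a sound
#'   speed near 1 nm/ps at the default spacing).
#' @param quartic_beta Quartic (FPU-beta) constant, eV/nm^4 (default 15).
#' @param spacing Lattice constant, nm (default 0.2); sets distances only.
#' @param t_bath Bath temperature, K.
#' @param delta_T Heater elevation, K (default 670).
#' @param heater_sites Integer range of heated sites (default `1:8`).
#' @param heat_duration Heating window, ps (default 1).
#' @param friction Langevin friction, ps^-1 (default 10).
#' @param dt Timestep, ps (default 2e-4).
#' @param t_total Simulated time after the window opens, ps.
#' @param record_interval Frame output interval, ps (default 0.1).
#' @param equil_time Thermostatted pre-equilibration, ps (default 5).
#' @param group_size Sites per pseudo-residue (default 8).
#' @param seed Integer seed for the thermostat noise.
#' @param thermostat_bath Thermostat non-heater sites during the window
#'   (default `TRUE`).
#' @param thermostat_always Keep the whole chain thermostatted at `t_bath`
#'   for the entire run (equilibrium sampling mode; default `FALSE`).
#' @param v0 Optional explicit initial site velocities, nm/ps (skips Maxwell
#'   initialisation).
#' @return A tibble of per-atom frames (`time`, `atom_id`, `residue`, `mass`,
#'   `vx`, `vy`, `vz`; 1-D motion, so `vy = vz = 0`), ready for
#'   [aggregate_atoms()]. Attributes: `spacing`, `group_size`,
#'   `displacements` (site-by-frame matrix), `sound_speed` (the analytic
#'   harmonic band-edge group velocity `spacing * sqrt(k/m)`).
#' @export
simulate_lattice <- function(n_sites = 64L, mass = 12, harmonic_k = 3.1,
                             quartic_beta = 15, spacing = 0.2,
                             t_bath = 300, delta_T = 670,
                             heater_sites = 1:8, heat_duration = 1,
                             friction = 10, dt = 2e-4, t_total = 20,
                             record_interval = 0.1, equil_time = 5,
                             group_size = 8L, seed = 1L,
                             thermostat_bath = TRUE,
                             thermostat_always = FALSE, v0 = numeric(0)) {
  stopifnot(n_sites >= 2, mass > 0, harmonic_k > 0, quartic_beta >= 0)
  sim <- simulate_lattice_cpp(
    n_sites = as.integer(n_sites), mass = mass, k_harm_ev = harmonic_k,
    beta_ev = quartic_beta, t_bath = t_bath, t_hot = t_bath + delta_T,
    heater_lo = min(heater_sites), heater_hi = max(heater_sites),
    heat_duration = heat_duration, friction = friction, dt = dt,
    t_total = t_total, record_interval = record_interval,
    seed = as.numeric(seed), thermostat_bath = thermostat_bath,
    thermostat_always = thermostat_always, equil_time = equil_time, v0 = v0
  )
  V <- sim$velocities
  times <- sim$times
  n_rec <- length(times)
  res_of <- ((seq_len(n_sites) - 1L) %/% as.integer(group_size)) + 1L
  frames <- tibble::tibble(
    time = rep(times, each = n_sites),
    atom_id = rep(seq_len(n_sites), times = n_rec),
    residue = rep(res_of, times = n_rec),
    mass = mass,
    vx = as.numeric(V),
    vy = 0, vz = 0
  )
  structure(frames, spacing = spacing, group_size = as.integer(group_size),
            displacements = sim$displacements,
            sound_speed = spacing * sqrt((harmonic_k / eV_per_u_nm2_ps2) / mass),
            class = class(frames))
}

#' Total lattice energy per recorded frame
#'
#' Kinetic plus harmonic plus quartic potential energy, eV. Used to audit
#' energy conservation of the symplectic integrator in the microcanonical
#' phase.
#'
#' @param frames The tibble returned by [simulate_lattice()].
#' @param mass,harmonic_k,quartic_beta The parameters the run used.
#' @return A tibble `time`, `energy` (eV).
#' @export
lattice_total_energy <- function(frames, mass = 12, harmonic_k = 3.1,
                                 quartic_beta = 15) {
  U <- attr(frames, "displacements")
  times <- unique(frames$time)
  n_sites <- nrow(U)
  V <- matrix(frames$vx, nrow = n_sites)
  ke <- colSums(0.5 * mass * V^2) * eV_per_u_nm2_ps2
  d <- U[-1, , drop = FALSE] - U[-n_sites, , drop = FALSE]
  pe <- colSums(0.5 * harmonic_k * d^2 + 0.25 * quartic_beta * d^4)
  tibble::tibble(time = times, energy = ke + pe)
}

#' Generate the standard synthetic fixture battery
#'
#' Writes, under `out_dir`:
#'
#' 1. noiseless constant-rate ensembles (10 residues, 3_10 topology, heater
#'    at residue 1, `k_BB = 1.5`, `k_HB = 0.5`, `k_s = 0.05` ps^-1) at the
#'    six bath temperatures 230-330 K in 20 K steps;
#' 2. Arrhenius ensembles at the same six temperatures: constant-in-time
#'    rates set by the bath temperature, `k = omega exp(-barrier/(kB T_B))`
#'    with `barrier = 0.05` eV and `omega = 5` ps^-1, recorded with
#'    block-average-scale noise (default 0.35; see the methods vignette);
#' 3. one lattice surrogate run (per-atom dump).
#'
#' Every file is listed in `manifest.tsv` with its generating parameters and
#' derived seed; identical `(seed, out_dir)` calls produce byte-identical
#' files.
#'
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param members_constant,members_arrhenius Members per temperature
#'   (defaults 1 noiseless, 20 noisy; the generators scale to any size).
#' @param t_total Simulated span per trajectory, ps (default 10).
#' @param noise_scale Noise for the Arrhenius battery (default 0.35,
#'   the block-averaged-record fluctuation scale).
#' @return The manifest tibble, invisibly written to
#'   `file.path(out_dir, "manifest.tsv")`.
#' @export
make_fixture_suite <- function(seed, out_dir, members_constant = 1L,
                               members_arrhenius = 20L, t_total = 10,
                               noise_scale = 0.35) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  topo <- build_topology(10, helix = "310")
  temps <- seq(230, 330, by = 20)
  rows <- list()
  add <- function(path, kind, tb, member, sd) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      file = basename(path), kind = kind, bath_temperature = tb,
      member = member, seed = sd, k_backbone = 1.5, k_hbond = 0.5,
      k_solvent = 0.05, omega = 5, barrier = 0.05, t_total = t_total,
      heater_index = 1L, n_residues = 10L
    )
  }
  for (tb in temps) {
    mod_c <- kinetic_model(topo, tb, k_backbone = 1.5, k_hbond = 0.5,
                           k_solvent = 0.05)
    ens <- simulate_master_equation(mod_c, heater_protocol(), t_total = t_total,
                                    n_members = members_constant, seed = seed,
                                    noise_scale = 0)
    for (m in seq_along(ens)) {
      path <- file.path(out_dir, sprintf("constant_T%d_m%03d.dat", tb, m))
      write_energy_trajectory(ens[[m]], path)
      add(path, "constant", tb, m, member_seed(seed, m))
    }
    k_arr <- arrhenius_rate(5, 0.05, tb)
    mod_a <- kinetic_model(topo, tb, k_backbone = k_arr, k_hbond = k_arr,
                           k_solvent = 0.05)
    ens <- simulate_master_equation(mod_a, heater_protocol(), t_total = t_total,
                                    n_members = members_arrhenius, seed = seed + 1L,
                                    noise_scale = noise_scale)
    for (m in seq_along(ens)) {
      path <- file.path(out_dir, sprintf("arrhenius_T%d_m%03d.dat", tb, m))
      write_energy_trajectory(ens[[m]], path)
      add(path, "arrhenius", tb, m, member_seed(seed + 1L, m))
    }
  }
  lat <- simulate_lattice(t_total = 5, record_interval = 0.1, seed = seed)
  lat_path <- file.path(out_dir, "lattice_run.dump")
  write_atom_dump(lat, lat_path)
  add(lat_path, "lattice", 300, 1L, seed)

  manifest <- dplyr::bind_rows(rows)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Write per-atom frames in the fixed-column dump format
#'
#' Inverse of [read_atom_dump()].
#'
#' @param frames Tibble with `time`, `atom_id`, `residue`, `mass`, `vx`,
#'   `vy`, `vz`.
#' @param path Output path.
#' @export
write_atom_dump <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tm in unique(frames$time)) {
    blk <- frames[frames$time == tm, ]
    writeLines(sprintf("t %s natoms %d", format_full(tm), nrow(blk)), con)
    writeLines(sprintf("%d %d %s %s %s %s", blk$atom_id, blk$residue,
                       format_full(blk$mass), format_full(blk$vx),
                       format_full(blk$vy), format_full(blk$vz)), con)
  }
  invisible(path)
}
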