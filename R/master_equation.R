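#' Detailed-balance reverse rate
#'
#' The master equation uses one fitted rate per coupled pair, the donor rate
#' for transfer from the residue with `dof_donor` degrees of freedom to the
#' one with `dof_acceptor`. The reverse rate is fixed by detailed balance so
#' that equipartition (`E_j` proportional to `f_j`) is exactly stationary:
#'
#' `k_reverse = k_forward * dof_donor / dof_acceptor`
#'
#' since then `k_forward * E_donor = k_reverse * E_acceptor` at equilibrium.
#'
#' @param k_forward Donor rate, ps^-1 (>= 0).
#' @param dof_donor,dof_acceptor Degrees of freedom of the two residues (> 0).
#' @return The reverse (acceptor-to-donor) rate, ps^-1.
#' @examples
#' detailed_balance_reverse(2, dof_donor = 78, dof_acceptor = 39)  # 4
#' @export
detailed_balance_reverse <- function(k_forward, dof_donor, dof_acceptor) {
  if (any(dof_donor <= 0) || any(dof_acceptor <= 0)) {
    stop("degrees of freedom must be positive", call. = FALSE)
  }
  k_forward * dof_donor / dof_acceptor
}

#' Solvent energy of a residue
#'
#' The kinetic energy density of the bath surrounding residue j, scaled to the
#' residue's degrees of freedom and treated as constant in time:
#' `E_s,j = (f_j / 2) kB T_B` (equivalently `3 N_j kB T_B / 2`).
#'
#' @param dof Per-residue degrees of freedom.
#' @param bath_temperature Bath temperature, K.
#' @return eV, same length as `dof`.
#' @export
solvent_energy <- function(dof, bath_temperature) {
  energy_from_temperature(bath_temperature, dof)
}

# midpoint energies between two consecutive analysis bins; second-order in dt
bin_midpoint <- function(E, n) (E[, n] + E[, n - 1]) / 2

#' Solvent coupling rate at one analysis bin
#'
#' Estimates the peptide-to-solvent rate from the net energy exchanged with
#' the bath over one bin. Intra-peptide exchange conserves total peptide
#' energy, so the total energy change is attributable to the solvent channel:
#'
#' `k_s(t_n) = - sum_j [E_j(t_n) - E_j(t_{n-1})] / (dt * sum_j R_j (Ebar_j - E_s,j))`
#'
#' with `Ebar` the bin-midpoint energies and `R_j` the per-residue surface
#' factors. Denominator terms with magnitude below `guard` are omitted; if
#' the whole denominator is guarded out the rate is 0 and flagged degenerate.
#' A negative estimate (net heating from an already-cooler bath, possible
#' under noise) is clamped to 0 and flagged.
#'
#' @param traj A coarse-grained `energy_trajectory`.
#' @param topology A `contact_topology` (for surface factors).
#' @param n Bin index (>= 2; the estimate uses bins n-1 and n).
#' @param guard Small-denominator guard, eV (default 1e-6).
#' @return List: `k_s` (ps^-1), `clamped`, `degenerate`, `n_guarded`.
#' @export
solvent_rate <- function(traj, topology, n, guard = 1e-6) {
  E <- energy_matrix(traj)
  times <- traj_times(traj)
  if (n < 2 || n > ncol(E)) stop("bin index n must be in 2..n_bins", call. = FALSE)
  dt <- times[n] - times[n - 1]
  Es <- solvent_energy(attr(traj, "dof"), attr(traj, "bath_temperature"))
  R <- topology$surface_factor
  dE <- E[, n] - E[, n - 1]
  dev <- R * (bin_midpoint(E, n) - Es)
  keep <- abs(dev) >= guard
  n_guarded <- sum(!keep)
  denom <- sum(dev[keep])
  if (!any(keep) || abs(denom) < guard) {
    return(list(k_s = 0, clamped = FALSE, degenerate = TRUE, n_guarded = n_guarded))
  }
  ks <- -sum(dE[keep]) / (dt * denom)
  clamped <- ks < 0
  list(k_s = max(ks, 0), clamped = clamped, degenerate = FALSE,
       n_guarded = n_guarded)
}

#' Assemble the linear system for one analysis bin
#'
#' Builds the design matrix `G` and target `d` of the constrained fit
#' `min_{k>=0} 1/2 ||G k - d||^2`. The unknown vector is
#' `(k_{1,2}, ..., k_{N-1,N}, k_HB)`: one donor rate per backbone link plus a
#' single shared hydrogen-bond rate. Rows are residues:
#'
#' * `d_j = [E_j(t_n) - E_j(t_{n-1})]/dt + R_j k_s (Ebar_j - E_s,j)`
#' * backbone column `p` (pair p, p+1): exchange term
#'   `X_p = Ebar_p - (f_p / f_{p+1}) Ebar_{p+1}`, entering row `p` as `-X_p`
#'   and row `p+1` as `+X_p` (reverse rate eliminated by detailed balance);
#' * hydrogen-bond column: for each pair (a, b), `-X_ab` on row a and `+X_ab`
#'   on row b with `X_ab = Ebar_a - (f_a / f_b) Ebar_b`.
#'
#' Energies enter at the bin midpoint `(E(t_n) + E(t_{n-1}))/2`, making the
#' implied integration rule second-order in `dt`. With
#' `convention = "unscaled"` the dof ratios are dropped
#' (`X = E_i - E_j` as sometimes written); the two coincide when all residues
#' have equal dof.
#'
#' @param traj A coarse-grained `energy_trajectory`.
#' @param topology A `contact_topology`.
#' @param n Bin index (>= 2).
#' @param k_s Solvent rate for this bin, ps^-1.
#' @param convention `"scaled"` (default, detailed-balance consistent) or
#'   `"unscaled"`.
#' @return List: `G` (N x N matrix), `d` (length N), `dt`.
#' @export
assemble_system <- function(traj, topology, n, k_s,
                            convention = c("scaled", "unscaled")) {
  convention <- match.arg(convention)
  E <- energy_matrix(traj)
  times <- traj_times(traj)
  if (n < 2 || n > ncol(E)) stop("bin index n must be in 2..n_bins", call. = FALSE)
  dt <- times[n] - times[n - 1]
  f <- attr(traj, "dof")
  N <- nrow(E)
  if (N != topology$n_residues) stop("trajectory and topology disagree on residue count", call. = FALSE)
  Es <- solvent_energy(f, attr(traj, "bath_temperature"))
  Em <- bin_midpoint(E, n)
  R <- topology$surface_factor

  d <- (E[, n] - E[, n - 1]) / dt + R * k_s * (Em - Es)

  n_bb <- N - 1L
  G <- matrix(0, nrow = N, ncol = n_bb + 1L)
  ratio <- function(a, b) if (convention == "scaled") f[a] / f[b] else 1
  for (p in seq_len(n_bb)) {
    X <- Em[p] - ratio(p, p + 1L) * Em[p + 1L]
    G[p, p] <- -X
    G[p + 1L, p] <- X
  }
  hb <- topology$pairs[topology$pairs$channel == "hbond", ]
  if (nrow(hb)) {
    for (r in seq_len(nrow(hb))) {
      a <- hb$i[r]; b <- hb$j[r]
      X <- Em[a] - ratio(a, b) * Em[b]
      G[a, n_bb + 1L] <- G[a, n_bb + 1L] - X
      G[b, n_bb + 1L] <- G[b, n_bb + 1L] + X
    }
  }
  list(G = G, d = d, dt = dt)
}

#' Fit time-dependent rate constants to a trajectory
#'
#' The core inverse problem. For every analysis bin `n >= 2`: estimate the
#' solvent rate ([solvent_rate()]), assemble the linear system
#' ([assemble_system()]), and solve the non-negativity-constrained
#' least-squares problem ([nnls_fit()]). Bins whose design matrix is all
#' (numerically) zero - the system at equipartition - are flagged degenerate
#' and get zero rates.
#'
#' The trajectory should already be coarse-grained to the analysis timescale
#' (see [block_average()]; 0.1 ps by default in this package).
#'
#' A structural identifiability caveat: every column of the design matrix
#' sums to zero (pairwise exchange conserves energy), so a single bin offers
#' at most N - 1 independent equations for the N unknowns, and a shared
#' hydrogen-bond rate is exactly degenerate with a chain of backbone
#' increments along the contact. With `window = 1` the fit is therefore the
#' bare per-bin problem and, on a hydrogen-bonded topology, returns one of a
#' family of exact solutions. The default `window = 2` stacks the systems of
#' two consecutive bins (rates are assumed locally constant at the
#' coarse-graining scale), which breaks the degeneracy because the exchange
#' patterns differ between bins; the estimate is attributed to the first bin
#' of its window.
#'
#' @param traj A coarse-grained `energy_trajectory`.
#' @param topology A `contact_topology`.
#' @param convention Passed to [assemble_system()].
#' @param guard Passed to [solvent_rate()].
#' @param window Consecutive bins stacked per fit (default 2 when the
#'   topology has hydrogen bonds, else 1).
#' @return A `rate_fit` tibble, one row per (bin, parameter):
#'   `time` (bin time, ps), `term` (`"k_1_2"`, ..., `"k_hbond"`,
#'   `"k_solvent"`), `channel`, `i`, `j` (NA for pooled terms), `rate`
#'   (ps^-1), plus per-bin diagnostics `residual_norm`, `feasible`,
#'   `degenerate`, `solvent_clamped`. Attributes: `topology`, `convention`,
#'   `dt`, `bath_temperature`, `heater_index`, `dof`.
#' @export
fit_rates <- function(traj, topology, convention = c("scaled", "unscaled"),
                      guard = 1e-6, window = NULL) {
  convention <- match.arg(convention)
  E <- energy_matrix(traj)
  times <- traj_times(traj)
  if (ncol(E) < 2) stop("need at least 2 analysis bins", call. = FALSE)
  N <- nrow(E)
  n_bb <- N - 1L
  terms <- c(sprintf("k_%d_%d", seq_len(n_bb), seq_len(n_bb) + 1L), "k_hbond")
  has_hb <- any(topology$pairs$channel == "hbond")
  if (is.null(window)) window <- if (has_hb) 2L else 1L
  window <- max(1L, min(as.integer(window), ncol(E) - 1L))

  systems <- lapply(2:ncol(E), function(n) {
    sv <- solvent_rate(traj, topology, n, guard = guard)
    sys <- assemble_system(traj, topology, n, sv$k_s, convention = convention)
    list(sv = sv, G = sys$G, d = sys$d)
  })

  per_bin <- lapply(2:ncol(E), function(n) {
    sv <- systems[[n - 1L]]$sv
    lo <- min(n, ncol(E) - window + 1L)
    block <- systems[(lo:(lo + window - 1L)) - 1L]
    G <- do.call(rbind, lapply(block, `[[`, "G"))
    d <- do.call(c, lapply(block, `[[`, "d"))
    Gscale <- max(abs(G))
    if (Gscale < 1e-14) {
      k <- numeric(n_bb + 1L)
      res <- sqrt(sum(d^2))
      feas <- TRUE
      degen <- TRUE
    } else {
      sol <- nnls_fit(G, d)
      k <- sol$x
      res <- sol$residual_norm
      feas <- sol$converged
      degen <- FALSE
    }
    if (!has_hb) k[n_bb + 1L] <- NA_real_
    tibble::tibble(
      time = times[n],
      term = c(terms, "k_solvent"),
      channel = c(rep("backbone", n_bb), "hbond", "solvent"),
      i = c(seq_len(n_bb), NA_integer_, NA_integer_),
      j = c(seq_len(n_bb) + 1L, NA_integer_, NA_integer_),
      rate = c(k, sv$k_s),
      residual_norm = res,
      feasible = feas,
      degenerate = degen || sv$degenerate,
      solvent_clamped = sv$clamped
    )
  })
  out <- dplyr::bind_rows(per_bin)
  structure(out,
            topology = topology, convention = convention, window = window,
            dt = if (length(times) > 1) times[2] - times[1] else NA_real_,
            bath_temperature = attr(traj, "bath_temperature"),
            heater_index = attr(traj, "heater_index"),
            dof = attr(traj, "dof"),
            class = c("rate_fit", class(out)))
}

# direction of "away from the heater" for a pair (a < b): +1 if the a -> b
# exchange flux is outbound, -1 if inbound, 0 for a pair straddling the heater
pair_direction <- function(a, b, heater) {
  ifelse(a >= heater, 1, ifelse(b <= heater, -1, 0))
}

#' Effective temperature gradient across a coupled pair
#'
#' Expresses the detailed-balance-weighted energy difference of a pair in
#' kelvin: `dT_eff = 2 [E_i - (f_i / f_j) E_j] / (3 N kB)`, where `N` is the
#' atom count of the residue the flux is incident on (the acceptor; the
#' downstream residue by default elsewhere). The gradient vanishes exactly at
#' equipartition (`E_i / f_i = E_j / f_j`).
#'
#' @param E_i,E_j Pair energies, eV.
#' @param f_i,f_j Pair degrees of freedom.
#' @param n_atoms Atom count of the accepting residue (>= 1).
#' @return Gradient, K.
#' @examples
#' effective_gradient(0.51, 0.50, 39, 39, 13)
#' @export
effective_gradient <- function(E_i, E_j, f_i, f_j, n_atoms) {
  if (any(n_atoms < 1)) stop("n_atoms must be >= 1", call. = FALSE)
  if (any(f_i <= 0) || any(f_j <= 0)) stop("dof must be positive", call. = FALSE)
  2 * (E_i - (f_i / f_j) * E_j) / (3 * n_atoms * kB_eV)
}

#' Pairwise heat fluxes from fitted rates
#'
#' For every coupled pair and bin, the net exchange flux
#' `J = k [Ebar_i - (f_i / f_j) Ebar_j]` (eV/ps), with `k` the fitted donor
#' rate of the pair's channel and energies at the bin midpoint - the same
#' quantities the fit itself saw. The sign convention follows the heater:
#' positive flux is flow away from the heater residue. Each record also
#' carries the effective temperature gradient (same sign convention), the
#' pair-mean temperature elevation over the bath, and the bath temperature.
#'
#' @param traj The coarse-grained `energy_trajectory` used for the fit.
#' @param topology The `contact_topology`.
#' @param rates The `rate_fit` returned by [fit_rates()].
#' @return A `flux_records` tibble: `time`, `i`, `j`, `channel`, `rate`,
#'   `flux` (eV/ps), `gradient` (K), `elevation` (K), `bath_temperature`,
#'   `ensemble_id`.
#' @export
compute_fluxes <- function(traj, topology, rates) {
  stopifnot(inherits(rates, "rate_fit"))
  E <- energy_matrix(traj)
  times <- traj_times(traj)
  f <- attr(traj, "dof")
  n_at <- topology$n_atoms
  tb <- attr(traj, "bath_temperature")
  heater <- attr(traj, "heater_index")
  pairs <- topology$pairs
  bins <- sort(unique(rates$time))

  rate_lookup <- rates[, c("time", "term", "rate")]

  out <- lapply(seq_along(bins), function(bi) {
    tm <- bins[bi]
    n <- match(TRUE, abs(times - tm) < 1e-9)
    if (is.na(n) || n < 2) return(NULL)
    Em <- bin_midpoint(E, n)
    kb_bin <- rate_lookup[rate_lookup$time == tm, ]
    k_of <- stats::setNames(kb_bin$rate, kb_bin$term)
    a <- pairs$i; b <- pairs$j
    k <- ifelse(pairs$channel == "backbone",
                k_of[sprintf("k_%d_%d", a, b)], k_of["k_hbond"])
    dirn <- pair_direction(a, b, heater)
    dirn[dirn == 0] <- 1  # pair straddling the heater: report a -> b as-is
    X <- Em[a] - (f[a] / f[b]) * Em[b]
    # acceptor in the away-from-heater direction
    acceptor <- ifelse(dirn >= 0, b, a)
    grad <- 2 * X / (3 * n_at[acceptor] * kB_eV) * dirn
    Tm <- temperature_from_energy(Em, f)
    tibble::tibble(
      time = tm, i = a, j = b, channel = pairs$channel,
      rate = as.numeric(k),
      flux = as.numeric(k * X * dirn),
      gradient = as.numeric(grad),
      elevation = as.numeric((Tm[a] + Tm[b]) / 2 - tb),
      bath_temperature = tb,
      ensemble_id = attr(traj, "ensemble_id")
    )
  })
  out <- dplyr::bind_rows(out)
  structure(out, heater_index = heater,
            class = c("flux_records", class(out)))
}

#' Average an ensemble of trajectories into one mean trajectory
#'
#' Per-(residue, frame) arithmetic mean over members sharing a grid; finite
#' ensemble noise shrinks as `1/sqrt(n)`, so fitting the mean trajectory is
#' the low-noise route to ensemble rate estimates ("ensemble-mean mode").
#'
#' @param trajs List of `energy_trajectory` on a common grid.
#' @param ensemble_id Label for the result.
#' @return An `energy_trajectory`.
#' @export
ensemble_mean_trajectory <- function(trajs, ensemble_id = "ensemble-mean") {
  stopifnot(length(trajs) >= 1)
  m <- traj_meta(trajs[[1]])
  Esum <- Reduce(`+`, lapply(trajs, energy_matrix))
  as_energy_trajectory(Esum / length(trajs), times = traj_times(trajs[[1]]),
                       dof = m$dof, bath_temperature = m$bath_temperature,
                       heater_index = m$heater_index, ensemble_id = ensemble_id)
}

#' Model right-hand side implied by a fitted bin
#'
#' Reconstructs `dE_j/dt` from fitted rates at one bin (pairwise exchange plus
#' solvent relaxation, energies at the bin midpoint). Used to verify
#' conservation closure: on data generated by the master equation the
#' reconstruction matches the finite-difference energy change within the
#' stored residual.
#'
#' @param traj,topology,rates As in [compute_fluxes()].
#' @param n Bin index (>= 2).
#' @return Numeric vector, eV/ps per residue.
#' @keywords internal
#' @export
model_rhs <- function(traj, topology, rates, n) {
  E <- energy_matrix(traj)
  times <- traj_times(traj)
  f <- attr(traj, "dof")
  Em <- bin_midpoint(E, n)
  Es <- solvent_energy(f, attr(traj, "bath_temperature"))
  kb_bin <- rates[abs(rates$time - times[n]) < 1e-9, ]
  k_of <- stats::setNames(kb_bin$rate, kb_bin$term)
  rhs <- numeric(nrow(E))
  for (r in seq_len(nrow(topology$pairs))) {
    a <- topology$pairs$i[r]; b <- topology$pairs$j[r]
    k <- if (topology$pairs$channel[r] == "backbone") {
      k_of[sprintf("k_%d_%d", a, b)]
    } else k_of["k_hbond"]
    X <- k * (Em[a] - (f[a] / f[b]) * Em[b])
    rhs[a] <- rhs[a] - X
    rhs[b] <- rhs[b] + X
  }
  rhs - topology$surface_factor * k_of["k_solvent"] * (Em - Es)
}
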