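#' Block-average flux records in effective-gradient bins
#'
#' Pools flux records into uniform gradient bins (default 1.0 K, half-open
#' `[m w, (m+1) w)`), separately for bath-temperature classes. The default
#' classes follow the low/high partition 230-270 K and 290-330 K (closed
#' intervals; records at bath temperatures in the gap belong to neither) plus
#' an `"all"` class containing every record.
#'
#' @param records A `flux_records` tibble (rows may pool many ensemble
#'   members).
#' @param width Bin width, K (default 1.0).
#' @param classes Named list of `c(lo, hi)` bath-temperature intervals;
#'   default `list(low = c(230, 270), high = c(290, 330))`. An `"all"` class
#'   is always added.
#' @param channel Restrict to one coupling channel (default `"backbone"`;
#'   `NULL` keeps all).
#' @param min_count Bins with fewer records are flagged unreliable
#'   (default 10).
#' @return A `gradient_bins` tibble: `temperature_class`, `bin_left`,
#'   `bin_center`, `mean_flux`, `sem_flux`, `mean_rate`, `sem_rate`,
#'   `mean_elevation`, `mean_bath`, `n`, `reliable`. Attribute `width`.
#' @export
bin_by_gradient <- function(records, width = 1.0,
                            classes = list(low = c(230, 270), high = c(290, 330)),
                            channel = "backbone", min_count = 10L) {
  stopifnot(width > 0)
  if (!nrow(records)) stop("empty record set", call. = FALSE)
  if (!is.null(channel)) records <- records[records$channel == channel, ]
  if (!nrow(records)) stop("no records in the requested channel", call. = FALSE)

  classes <- c(classes, list(all = c(-Inf, Inf)))
  per_class <- lapply(names(classes), function(cl) {
    rng <- classes[[cl]]
    rec <- records[records$bath_temperature >= rng[1] &
                     records$bath_temperature <= rng[2], ]
    if (!nrow(rec)) return(NULL)
    rec$bin_left <- floor(rec$gradient / width) * width
    g <- dplyr::group_by(rec, .data$bin_left)
    g <- dplyr::summarise(
      g,
      mean_flux = mean(.data$flux),
      sem_flux = if (dplyr::n() >= 2) stats::sd(.data$flux) / sqrt(dplyr::n()) else NA_real_,
      mean_rate = mean(.data$rate, na.rm = TRUE),
      sem_rate = if (dplyr::n() >= 2) stats::sd(.data$rate) / sqrt(dplyr::n()) else NA_real_,
      mean_elevation = mean(.data$elevation),
      mean_bath = mean(.data$bath_temperature),
      n = dplyr::n(),
      .groups = "drop"
    )
    g$temperature_class <- cl
    g
  })
  out <- dplyr::bind_rows(per_class)
  out$bin_center <- out$bin_left + width / 2
  out$reliable <- out$n >= min_count
  out <- out[, c("temperature_class", "bin_left", "bin_center", "mean_flux",
                 "sem_flux", "mean_rate", "sem_rate", "mean_elevation",
                 "mean_bath", "n", "reliable")]
  out <- dplyr::arrange(out, .data$temperature_class, .data$bin_left)
  structure(out, width = width, min_count = as.integer(min_count),
            class = c("gradient_bins", class(out)))
}

#' Linear (Fourier) fit of flux against gradient over one regime
#'
#' Weighted least squares of `mean_flux` on `bin_center` over a gradient
#' range (weights `1 / sem^2`; unweighted where sems are unavailable). The
#' slope is the per-link effective conductivity `kappa_eff` (eV K^-1 ps^-1);
#' dividing by the per-link heat capacity and multiplying by the squared
#' inter-residue spacing converts it to an effective diffusivity
#' `D_eff = slope * dx^2 / C` (nm^2/ps), via the lattice relation
#' `k = D / dx^2` and `J = k C dT`. The intercept is the zero-gradient
#' (ballistic) flux offset. Bins with `|gradient| < exclude_below` are
#' dropped: right around zero gradient a residual ballistic component
#' inflates apparent rate constants.
#'
#' @param bins A `gradient_bins` tibble (one temperature class, or filter via
#'   `temperature_class`).
#' @param range Gradient interval `c(lo, hi)`, K; bins with
#'   `lo <= bin_center < hi` are used.
#' @param temperature_class Class to fit (default `"all"`).
#' @param spacing Inter-residue distance dx, nm (default 0.2).
#' @param heat_capacity Per-link heat capacity, eV/K; default
#'   `(3/2) * n_atoms * kB` with `n_atoms = 13`.
#' @param exclude_below Zero-gradient exclusion cutoff, K (default 4).
#' @param label Region label carried through (default `NA`).
#' @return A one-row `regime_fit` tibble: `label`, `range_lo`, `range_hi`,
#'   `kappa_eff`, `kappa_sem`, `d_eff`, `d_sem`, `intercept`,
#'   `intercept_sem`, `n_bins`, `negative_slope`, `converged`. Attributes
#'   `spacing`, `heat_capacity`.
#' @export
fit_linear_regime <- function(bins, range, temperature_class = "all",
                              spacing = 0.2,
                              heat_capacity = 1.5 * 13 * kB_eV,
                              exclude_below = 4, label = NA_character_) {
  stopifnot(inherits(bins, "gradient_bins") || is.data.frame(bins))
  b <- bins[bins$temperature_class == temperature_class &
              bins$reliable &
              bins$bin_center >= range[1] & bins$bin_center < range[2] &
              abs(bins$bin_center) >= exclude_below, ]
  empty <- tibble::tibble(
    label = label, range_lo = range[1], range_hi = range[2],
    kappa_eff = NA_real_, kappa_sem = NA_real_, d_eff = NA_real_,
    d_sem = NA_real_, intercept = NA_real_, intercept_sem = NA_real_,
    n_bins = nrow(b), negative_slope = NA, converged = FALSE
  )
  if (nrow(b) < 3) {
    out <- empty
  } else {
    w <- 1 / b$sem_flux^2
    if (any(!is.finite(w))) w <- NULL
    fit <- stats::lm(mean_flux ~ bin_center, data = b, weights = w)
    cf <- suppressWarnings(summary(fit))$coefficients
    slope <- cf["bin_center", "Estimate"]
    out <- tibble::tibble(
      label = label, range_lo = range[1], range_hi = range[2],
      kappa_eff = slope,
      kappa_sem = cf["bin_center", "Std. Error"],
      d_eff = slope * spacing^2 / heat_capacity,
      d_sem = cf["bin_center", "Std. Error"] * spacing^2 / heat_capacity,
      intercept = cf["(Intercept)", "Estimate"],
      intercept_sem = cf["(Intercept)", "Std. Error"],
      n_bins = nrow(b),
      negative_slope = slope < 0,
      converged = TRUE
    )
  }
  structure(out, spacing = spacing, heat_capacity = heat_capacity,
            class = c("regime_fit", class(out)))
}

#' Segment the flux profile into transport regimes and fit each
#'
#' Splits the gradient axis at the given boundaries (defaults 15, 30, 50 and
#' 77 K) into regions labelled A, B, C, ... in order, fits each independently
#' with [fit_linear_regime()], and discards data beyond the last boundary
#' (the strong-localization, earliest-time regime). Region A additionally
#' starts at the zero-gradient exclusion cutoff.
#'
#' @param bins A `gradient_bins` tibble.
#' @param boundaries Strictly increasing boundary list, K (default
#'   `c(15, 30, 50, 77)`).
#' @inheritParams fit_linear_regime
#' @return A `regime_fit` tibble with one row per region (rows with too few
#'   reliable bins carry `converged = FALSE`).
#' @export
segment_regimes <- function(bins, boundaries = c(15, 30, 50, 77),
                            temperature_class = "all", spacing = 0.2,
                            heat_capacity = 1.5 * 13 * kB_eV,
                            exclude_below = 4) {
  if (any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing", call. = FALSE)
  }
  edges <- c(exclude_below, boundaries)
  labels <- LETTERS[seq_len(length(edges) - 1L)]
  fits <- lapply(seq_along(labels), function(r) {
    fit_linear_regime(bins, range = c(edges[r], edges[r + 1L]),
                      temperature_class = temperature_class, spacing = spacing,
                      heat_capacity = heat_capacity,
                      exclude_below = exclude_below, label = labels[r])
  })
  out <- dplyr::bind_rows(fits)
  structure(out, spacing = spacing, heat_capacity = heat_capacity,
            boundaries = boundaries,
            class = c("regime_fit", class(out)))
}

#' Free-energy barrier from a high/low-temperature flux ratio
#'
#' Activated (Arrhenius) transport `k = Omega exp(-dF / kB T)` implies
#' `J_H / J_L = exp(-dF / kB T_H + dF / kB T_L)` at matched gradients, so
#'
#' `dF = ln(J_H / J_L) / (1 / (kB T_L) - 1 / (kB T_H))`.
#'
#' A negative result (high-temperature flux below low-temperature) is
#' reported as-is - it signals inverted ordering, not an error.
#'
#' @param J_high,J_low Class-mean fluxes (or rates), same units, > 0.
#' @param T_low,T_high Class temperatures, K, with `T_high > T_low`; defaults
#'   250 and 310 K (the means of the 230-270 and 290-330 K classes).
#' @return Barrier, eV.
#' @examples
#' barrier_from_ratio(1.2, 1)  # ~0.0203 eV
#' @export
barrier_from_ratio <- function(J_high, J_low, T_low = 250, T_high = 310) {
  if (any(J_high <= 0) || any(J_low <= 0)) {
    stop("fluxes must be positive for a barrier estimate", call. = FALSE)
  }
  stopifnot(all(T_high > T_low), all(T_low > 0))
  log(J_high / J_low) / (1 / (kB_eV * T_low) - 1 / (kB_eV * T_high))
}

#' Arrhenius rate (forward map)
#'
#' `k = Omega exp(-dG / (kB T))`; the exact inverse of
#' [barrier_from_ratio()] when evaluated at two temperatures.
#'
#' @param omega Attempt frequency, ps^-1.
#' @param barrier Free-energy barrier, eV.
#' @param temperature K.
#' @return Rate, ps^-1.
#' @export
arrhenius_rate <- function(omega, barrier, temperature) {
  omega * exp(-barrier / (kB_eV * temperature))
}

#' Per-gradient-bin free-energy barrier profile
#'
#' Applies [barrier_from_ratio()] bin by bin to the low- and high-temperature
#' flux curves. Bins missing or unreliable in either class are omitted.
#' Standard errors propagate to first order:
#' `sem(dF) = |1 / (1/kB T_L - 1/kB T_H)| * sqrt((sem_H/J_H)^2 + (sem_L/J_L)^2)`.
#'
#' @param bins A `gradient_bins` tibble containing `low` and `high` classes.
#' @param T_low,T_high Class temperatures, K (defaults 250 / 310). Set
#'   `use_local = TRUE` to add each bin's mean temperature elevation to the
#'   class temperature (appropriate when rates follow the local, not the
#'   bath, temperature).
#' @param use_local Logical, default `FALSE`.
#' @param statistic `"flux"` (default) or `"rate"`.
#' @return A tibble: `bin_center`, `barrier` (eV), `barrier_sem`, `n_low`,
#'   `n_high`.
#' @export
barrier_profile <- function(bins, T_low = 250, T_high = 310,
                            use_local = FALSE,
                            statistic = c("flux", "rate")) {
  statistic <- match.arg(statistic)
  lo <- bins[bins$temperature_class == "low" & bins$reliable, ]
  hi <- bins[bins$temperature_class == "high" & bins$reliable, ]
  merged <- dplyr::inner_join(lo, hi, by = "bin_center",
                              suffix = c("_low", "_high"))
  if (!nrow(merged)) {
    return(tibble::tibble(bin_center = numeric(), barrier = numeric(),
                          barrier_sem = numeric(), n_low = integer(),
                          n_high = integer()))
  }
  vcol <- paste0("mean_", statistic)
  scol <- paste0("sem_", statistic)
  JL <- merged[[paste0(vcol, "_low")]]
  JH <- merged[[paste0(vcol, "_high")]]
  sL <- merged[[paste0(scol, "_low")]]
  sH <- merged[[paste0(scol, "_high")]]
  ok <- JL > 0 & JH > 0
  merged <- merged[ok, ]; JL <- JL[ok]; JH <- JH[ok]; sL <- sL[ok]; sH <- sH[ok]
  TL <- if (use_local) T_low + merged$mean_elevation_low else rep(T_low, nrow(merged))
  TH <- if (use_local) T_high + merged$mean_elevation_high else rep(T_high, nrow(merged))
  denom <- 1 / (kB_eV * TL) - 1 / (kB_eV * TH)
  tibble::tibble(
    bin_center = merged$bin_center,
    barrier = log(JH / JL) / denom,
    barrier_sem = sqrt((sH / JH)^2 + (sL / JL)^2) / abs(denom),
    n_low = merged$n_low,
    n_high = merged$n_high
  )
}

#' Diffusivity from peak-arrival times
#'
#' For each residue, the time `t_max` to reach its maximal temperature
#' elevation is located (arg-max over bins, refined by a parabola through the
#' three neighbouring bins unless `refine = FALSE`). Under the model
#' `t_max = d^2 / D`, with `d` the distance from the heater, the diffusivity
#' is the slope of a least-squares fit of `d^2` against `t_max` through the
#' origin. The heater residue (`d = 0`) and residues whose elevation is
#' monotone over the window (no interior peak) are excluded. Note the model
#' is used as stated, without the factor 2 of a 1-D point-source solution;
#' see the methods vignette.
#'
#' @param profile A `transport_profile`.
#' @param spacing Inter-residue distance, nm (default 0.2).
#' @param refine Parabolic sub-bin refinement of the peak (default `TRUE`).
#' @return List: `D` (nm^2/ps), `D_sem`, and `peaks` - a tibble `residue`,
#'   `distance`, `t_max`.
#' @export
tmax_diffusivity <- function(profile, spacing = 0.2, refine = TRUE) {
  stopifnot(inherits(profile, "transport_profile"))
  heater <- attr(profile, "heater_index")
  M <- profile_matrix(profile)
  times <- unique(profile$time)
  rows <- lapply(seq_len(nrow(M)), function(r) {
    if (r == heater) return(NULL)
    y <- M[r, ]
    p <- which.max(y)
    if (p == 1L || p == length(y)) return(NULL)  # no interior peak
    t_pk <- times[p]
    if (refine) {
      y3 <- y[(p - 1):(p + 1)]
      denom <- y3[1] - 2 * y3[2] + y3[3]
      if (abs(denom) > 0) {
        delta <- 0.5 * (y3[1] - y3[3]) / denom
        delta <- max(min(delta, 0.5), -0.5)
        t_pk <- t_pk + delta * (times[p + 1] - times[p])
      }
    }
    tibble::tibble(residue = r, distance = abs(r - heater) * spacing,
                   t_max = t_pk)
  })
  peaks <- dplyr::bind_rows(rows)
  if (nrow(peaks) < 3) {
    stop("fewer than 3 residues with an interior temperature peak", call. = FALSE)
  }
  fit <- stats::lm(I(distance^2) ~ t_max - 1, data = peaks)
  list(
    D = unname(stats::coef(fit)["t_max"]),
    D_sem = suppressWarnings(summary(fit))$coefficients["t_max", "Std. Error"],
    peaks = peaks
  )
}
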