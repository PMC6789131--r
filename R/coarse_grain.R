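#' Block-average a trajectory in time
#'
#' Partitions frames into left-closed windows `[t0 + m dt, t0 + (m+1) dt)`
#' anchored at the first frame time, replaces each window by the unweighted
#' mean of its member frames, and stamps the window centre as the output time.
#' A partial trailing window is dropped. The analysis default is `dt = 0.1`
#' ps, long enough to average over most coherent motion while resolving the
#' energy relaxation.
#'
#' @param traj An `energy_trajectory`.
#' @param dt Window width, ps (>= the native frame spacing).
#' @return A coarser `energy_trajectory` with the same metadata.
#' @export
block_average <- function(traj, dt = 0.1) {
  stopifnot(inherits(traj, "energy_trajectory"))
  times <- traj_times(traj)
  if (length(times) < 1) stop("empty trajectory", call. = FALSE)
  native <- min(diff(times))
  if (dt < native - 1e-12) {
    stop("dt (", dt, " ps) is smaller than the native frame spacing (",
         native, " ps)", call. = FALSE)
  }
  t0 <- times[1]
  idx <- floor((times - t0) / dt + 1e-9)
  # a window is complete when the frame grid covers its full width; the
  # trailing partial window is dropped
  t_last <- times[length(times)]
  n_bins <- max(idx) + 1L
  ends <- t0 + seq_len(n_bins) * dt
  complete <- which(ends <= t_last + native + 1e-9) - 1L
  complete <- complete[complete %in% idx]
  if (!length(complete)) stop("dt spans no complete window of frames", call. = FALSE)

  E <- energy_matrix(traj)
  m <- traj_meta(traj)
  out <- vapply(complete, function(b) rowMeans(E[, idx == b, drop = FALSE]),
                numeric(nrow(E)))
  out <- matrix(out, nrow = nrow(E))
  centers <- t0 + (complete + 0.5) * dt
  as_energy_trajectory(out, times = centers, dof = m$dof,
                       bath_temperature = m$bath_temperature,
                       heater_index = m$heater_index, ensemble_id = m$ensemble_id)
}

#' Ensemble temperature-elevation profile
#'
#' Averages the per-residue kinetic temperature over an ensemble of
#' trajectories sharing the time grid, topology and bath temperature, and
#' reports the elevation over the bath, `dT_j(t) = <T_j(t)> - T_B`, with the
#' standard error of the mean (sample sd / sqrt(n)).
#'
#' @param trajs A list of `energy_trajectory` objects on a common grid.
#' @param label Subensemble label (e.g. "helical", "full").
#' @return A `transport_profile` tibble: `time`, `residue`, `elevation` (K),
#'   `sem` (K), with attributes `n_members`, `label`, `bath_temperature`,
#'   `dof`, `heater_index`.
#' @export
ensemble_profile <- function(trajs, label = "full") {
  stopifnot(length(trajs) >= 1)
  m1 <- traj_meta(trajs[[1]])
  t1 <- traj_times(trajs[[1]])
  for (tr in trajs) {
    m <- traj_meta(tr)
    if (!isTRUE(all.equal(traj_times(tr), t1)) ||
        !isTRUE(all.equal(m$dof, m1$dof)) ||
        !isTRUE(all.equal(m$bath_temperature, m1$bath_temperature))) {
      stop("ensemble members must share time grid, dof and bath temperature",
           call. = FALSE)
    }
  }
  n <- length(trajs)
  temps <- lapply(trajs, function(tr) {
    temperature_from_energy(energy_matrix(tr), m1$dof)
  })
  mean_T <- Reduce(`+`, temps) / n
  if (n >= 2) {
    ss <- Reduce(`+`, lapply(temps, function(Tm) (Tm - mean_T)^2))
    sem <- sqrt(ss / (n - 1)) / sqrt(n)
  } else {
    sem <- array(NA_real_, dim(mean_T))
  }
  out <- tibble::tibble(
    time = rep(t1, each = nrow(mean_T)),
    residue = rep(seq_len(nrow(mean_T)), times = length(t1)),
    elevation = as.numeric(mean_T - m1$bath_temperature),
    sem = as.numeric(sem)
  )
  structure(out,
            n_members = n, label = label,
            bath_temperature = m1$bath_temperature,
            dof = m1$dof, heater_index = m1$heater_index,
            class = c("transport_profile", class(out)))
}

profile_matrix <- function(profile, what = "elevation") {
  n_res <- length(attr(profile, "dof"))
  matrix(profile[[what]], nrow = n_res)
}

#' Differential transport profile between two ensembles
#'
#' Elementwise difference `sub - full` of two matched elevation profiles,
#' with standard errors combined in quadrature. Used to compare a structural
#' subensemble (helical, hairpin, unstructured) against the full ensemble.
#'
#' @param sub,full `transport_profile` objects on identical grids.
#' @return A `transport_profile` of the differences, labelled
#'   `"<sub> - <full>"`; `n_members` is taken from `sub`.
#' @export
profile_difference <- function(sub, full) {
  stopifnot(inherits(sub, "transport_profile"), inherits(full, "transport_profile"))
  if (nrow(sub) != nrow(full) ||
      !isTRUE(all.equal(sub$time, full$time)) ||
      !identical(sub$residue, full$residue)) {
    stop("profiles must share the (time, residue) grid", call. = FALSE)
  }
  out <- sub
  out$elevation <- sub$elevation - full$elevation
  out$sem <- sqrt(sub$sem^2 + full$sem^2)
  attr(out, "label") <- paste(attr(sub, "label"), "-", attr(full, "label"))
  out
}

#' Net heat transferred across a residue pair
#'
#' Accumulates the pairwise flux in time: `Q(t_n) = sum_{m<=n} J(t_m) dt`
#' (rectangle rule; `method = "trapezoid"` uses the cumulative trapezoid).
#' Positive flux means flow away from the heater, so Q is the net heat moved
#' in that direction through the contact.
#'
#' @param flux_records A `flux_records` tibble (see [compute_fluxes()]).
#' @param pair Integer pair `c(i, j)` identifying the contact.
#' @param method `"rectangle"` (default) or `"trapezoid"`.
#' @return A tibble `time`, `heat` (eV).
#' @export
net_heat <- function(flux_records, pair, method = c("rectangle", "trapezoid")) {
  method <- match.arg(method)
  pair <- sort(as.integer(pair))
  rec <- flux_records[flux_records$i == pair[1] & flux_records$j == pair[2], ]
  if (!nrow(rec)) {
    stop("pair (", pair[1], ", ", pair[2], ") not present in the flux records",
         call. = FALSE)
  }
  rec <- dplyr::summarise(dplyr::group_by(rec, .data$time),
                          flux = mean(.data$flux), .groups = "drop")
  rec <- dplyr::arrange(rec, .data$time)
  dts <- diff(rec$time)
  if (length(dts) && (max(dts) - min(dts)) > 1e-9 * max(dts)) {
    stop("flux records must lie on uniform bins", call. = FALSE)
  }
  dt <- if (length(dts)) dts[1] else NA_real_
  heat <- if (method == "rectangle") {
    cumsum(rec$flux * dt)
  } else {
    c(0, cumsum((utils::head(rec$flux, -1) + utils::tail(rec$flux, -1)) / 2 * dts))
  }
  tibble::tibble(time = rec$time, heat = heat)
}

#' Ballistic front velocity from arrival times
#'
#' Detects, per residue, the first bin at which the temperature elevation
#' reaches `threshold` for `consecutive` bins in a row (rejecting single-bin
#' noise), converts residue offsets from the heater into distances, and fits
#' distance against arrival time by least squares. The slope is the front
#' speed. A quadratic term in the arrival-time/distance relation is also
#' tested: diffusive spreading has `t ~ d^2`, so significant positive
#' curvature flags the profile as not ballistic.
#'
#' @param profile A `transport_profile`.
#' @param threshold Arrival threshold, K (> 0); default 5 K.
#' @param spacing Inter-residue distance, nm; default 0.2.
#' @param consecutive Bins that must consecutively exceed the threshold
#'   (default 2).
#' @return A one-row tibble: `velocity` (nm/ps), `velocity_sem`, `n_arrivals`,
#'   `ballistic` (logical curvature verdict), `curvature_p`; the per-residue
#'   arrival table is attached as attribute `arrivals`.
#' @export
front_velocity <- function(profile, threshold = 5, spacing = 0.2,
                           consecutive = 2L) {
  stopifnot(inherits(profile, "transport_profile"), threshold > 0)
  heater <- attr(profile, "heater_index")
  M <- profile_matrix(profile)
  times <- unique(profile$time)
  arrivals <- lapply(seq_len(nrow(M)), function(r) {
    hit <- M[r, ] >= threshold
    run <- stats::filter(as.numeric(hit), rep(1, consecutive), sides = 1)
    k <- which(run == consecutive)[1]
    if (is.na(k)) return(NULL)
    tibble::tibble(residue = r, distance = abs(r - heater) * spacing,
                   arrival = times[k - consecutive + 1L])
  })
  arr <- dplyr::bind_rows(arrivals)
  if (nrow(arr)) arr <- arr[arr$residue != heater, ]
  if (nrow(arr) < 3) {
    stop("fewer than 3 residues reach the threshold; cannot fit a front",
         call. = FALSE)
  }
  fit <- stats::lm(distance ~ arrival, data = arr)
  v <- unname(stats::coef(fit)["arrival"])
  v_sem <- suppressWarnings(summary(fit))$coefficients["arrival", "Std. Error"]
  # curvature test on t(d): diffusive arrival grows quadratically in distance
  curv_p <- NA_real_
  ballistic <- TRUE
  if (nrow(arr) >= 4 && length(unique(arr$distance)) >= 3) {
    qfit <- stats::lm(arrival ~ distance + I(distance^2), data = arr)
    cf <- suppressWarnings(summary(qfit))$coefficients
    if ("I(distance^2)" %in% rownames(cf)) {
      curv_p <- cf["I(distance^2)", "Pr(>|t|)"]
      ballistic <- !(is.finite(curv_p) && curv_p < 0.05 &&
                       cf["I(distance^2)", "Estimate"] > 0)
    }
  }
  out <- tibble::tibble(velocity = v, velocity_sem = v_sem,
                        n_arrivals = nrow(arr), ballistic = ballistic,
                        curvature_p = curv_p)
  attr(out, "arrivals") <- arr
  out
}
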