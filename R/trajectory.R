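#' Per-residue kinetic-energy trajectory
#'
#' The central container of the package: a tidy tibble with one row per
#' (frame, residue) holding the residue kinetic energy, carrying run metadata
#' as attributes. Columns: `time` (ps), `residue` (1-based integer), `energy`
#' (eV). Attributes: `dof` (per-residue degrees of freedom, `f_j = 3 N_j`
#' unless overridden), `bath_temperature` (K), `heater_index` (1-based),
#' `ensemble_id` (label).
#'
#' @param data A data frame with columns `time`, `residue`, `energy`, or a
#'   residue-by-frame numeric matrix (then `times` must be given).
#' @param times Frame times, ps (matrix input only).
#' @param dof Per-residue degrees of freedom (each >= 3).
#' @param bath_temperature Solvent bath temperature, K.
#' @param heater_index Residue transiently heated, 1-based.
#' @param ensemble_id Free-form member label.
#' @return An `energy_trajectory` tibble.
#' @examples
#' E <- rbind(c(0.5, 0.5, 0.5), c(0.6, 0.55, 0.52))
#' as_energy_trajectory(E, times = c(0, 0.1, 0.2), dof = 39,
#'                      bath_temperature = 300, heater_index = 1)
#' @export
as_energy_trajectory <- function(data, times = NULL, dof,
                                 bath_temperature = NA_real_,
                                 heater_index = 1L,
                                 ensemble_id = "member-1") {
  if (is.matrix(data)) {
    if (is.null(times)) stop("matrix input needs `times`", call. = FALSE)
    if (length(times) != ncol(data)) {
      stop("length(times) must equal ncol(data)", call. = FALSE)
    }
    data <- tibble::tibble(
      time = rep(as.numeric(times), each = nrow(data)),
      residue = rep(seq_len(nrow(data)), times = ncol(data)),
      energy = as.numeric(data)
    )
  }
  data <- tibble::as_tibble(data)
  stopifnot(all(c("time", "residue", "energy") %in% names(data)))
  data <- dplyr::arrange(data[, c("time", "residue", "energy")],
                         .data$time, .data$residue)

  residues <- sort(unique(data$residue))
  n_res <- length(residues)
  if (n_res < 2) stop("a trajectory needs at least 2 residues", call. = FALSE)
  if (!identical(as.integer(residues), seq_len(n_res))) {
    stop("residue indices must be 1..n without gaps", call. = FALSE)
  }
  tgrid <- unique(data$time)
  if (any(diff(tgrid) <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
  if (nrow(data) != n_res * length(tgrid)) {
    stop("every residue must be present in every frame", call. = FALSE)
  }
  if (any(data$energy < 0)) {
    stop_bad_rows("negative energy", which(data$energy < 0))
  }
  dof <- rep_len(as.numeric(dof), n_res)
  if (any(dof < 3)) stop("per-residue dof must be >= 3", call. = FALSE)

  structure(
    data,
    dof = dof,
    bath_temperature = as.numeric(bath_temperature),
    heater_index = as.integer(heater_index),
    ensemble_id = as.character(ensemble_id),
    class = c("energy_trajectory", class(data))
  )
}

traj_meta <- function(traj) {
  list(
    dof = attr(traj, "dof"),
    bath_temperature = attr(traj, "bath_temperature"),
    heater_index = attr(traj, "heater_index"),
    ensemble_id = attr(traj, "ensemble_id")
  )
}

#' @export
print.energy_trajectory <- function(x, ...) {
  m <- traj_meta(x)
  cat("<energy_trajectory> ", length(m$dof), " residues x ",
      length(unique(x$time)), " frames; T_B = ", m$bath_temperature,
      " K; heater = ", m$heater_index, "; member ", m$ensemble_id, "\n", sep = "")
  NextMethod()
}

# residue-by-frame matrix view (residues in rows); fast path used internally
energy_matrix <- function(traj) {
  n_res <- length(attr(traj, "dof"))
  tgrid <- unique(traj$time)
  matrix(traj$energy, nrow = n_res, ncol = length(tgrid),
         dimnames = list(NULL, NULL))
}

traj_times <- function(traj) unique(traj$time)

#' Add kinetic temperature to a trajectory
#'
#' Appends `temperature = 2 E / (f kB)` (K) per row.
#'
#' @param traj An `energy_trajectory`.
#' @return The trajectory with a `temperature` column.
#' @export
kinetic_temperature <- function(traj) {
  dof <- attr(traj, "dof")
  traj$temperature <- temperature_from_energy(traj$energy, dof[traj$residue])
  traj
}

#' Read a per-residue energy (or temperature) table
#'
#' Expects a delimited text file (whitespace or comma) with one header line:
#' first column time in ps, remaining columns one per residue. Columns are
#' energies in eV unless `temperature = TRUE`, in which case they are kinetic
#' temperatures in K and are converted via `E = (f/2) kB T` using `dof`.
#'
#' @param path File path.
#' @param dof Per-residue degrees of freedom (recycled).
#' @param temperature Logical: columns are temperatures (K)?
#' @param bath_temperature,heater_index,ensemble_id Run metadata stored on the
#'   result.
#' @return An `energy_trajectory`.
#' @export
read_energy_table <- function(path, dof, temperature = FALSE,
                              bath_temperature = NA_real_, heater_index = 1L,
                              ensemble_id = basename(path)) {
  lines <- readLines(path)
  meta <- parse_header_meta(lines)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("table needs a header line and at least one frame", call. = FALSE)
  sep_split <- function(x) strsplit(trimws(gsub(",", " ", x)), "\\s+")
  header <- sep_split(lines[1])[[1]]
  if (length(header) < 3) stop("need a time column plus >= 2 residue columns", call. = FALSE)
  rows <- sep_split(lines[-1])
  bad <- which(lengths(rows) != length(header))
  if (length(bad)) stop_bad_rows("wrong field count", bad + 1L)
  num <- matrix(as.numeric(unlist(rows)), ncol = length(header), byrow = TRUE)
  if (anyNA(num)) stop_bad_rows("non-numeric field", which(rowSums(is.na(num)) > 0) + 1L)

  times <- num[, 1]
  if (any(diff(times) <= 0)) {
    stop_bad_rows("non-increasing time", which(diff(times) <= 0) + 2L)
  }
  vals <- t(num[, -1, drop = FALSE])  # residues x frames
  n_res <- nrow(vals)
  dof <- rep_len(as.numeric(dof), n_res)
  if (isTRUE(temperature) || identical(meta[["mode"]], "temperature")) {
    vals <- energy_from_temperature(vals, dof)
  }
  if (any(vals < 0)) {
    stop_bad_rows("negative energy", which(colSums(vals < 0) > 0) + 1L)
  }
  if (!is.null(meta[["bath_temperature"]]) && is.na(bath_temperature)) {
    bath_temperature <- as.numeric(meta[["bath_temperature"]])
  }
  if (!is.null(meta[["heater_index"]])) heater_index <- as.integer(meta[["heater_index"]])
  as_energy_trajectory(vals, times = times, dof = dof,
                       bath_temperature = bath_temperature,
                       heater_index = heater_index, ensemble_id = ensemble_id)
}

#' Write a per-residue energy table
#'
#' Inverse of [read_energy_table()]: metadata goes into `# key value` comment
#' lines, values are written at full double precision so that a read/write
#' cycle is bitwise stable.
#'
#' @param traj An `energy_trajectory`.
#' @param path Output path.
#' @export
write_energy_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "energy_trajectory"))
  m <- traj_meta(traj)
  E <- energy_matrix(traj)
  hdr <- c(
    paste("# bath_temperature", format_full(m$bath_temperature)),
    paste("# heater_index", m$heater_index),
    paste("# ensemble_id", m$ensemble_id),
    paste("# dof", paste(format_full(m$dof), collapse = " ")),
    paste(c("time_ps", paste0("E_res", seq_len(nrow(E)))), collapse = " ")
  )
  body <- vapply(seq_len(ncol(E)), function(i) {
    paste(format_full(c(traj_times(traj)[i], E[, i])), collapse = " ")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an energy table written by [write_energy_trajectory()]
#'
#' Recovers metadata from the comment header.
#'
#' @param path File path.
#' @return An `energy_trajectory`.
#' @export
read_energy_trajectory <- function(path) {
  lines <- readLines(path, n = 50)
  meta <- parse_header_meta(lines)
  if (is.null(meta$dof)) stop("file lacks a '# dof' header line", call. = FALSE)
  read_energy_table(
    path,
    dof = as.numeric(strsplit(meta$dof, "\\s+")[[1]]),
    bath_temperature = as.numeric(meta$bath_temperature %||% NA),
    heater_index = as.integer(meta$heater_index %||% 1L),
    ensemble_id = meta$ensemble_id %||% basename(path)
  )
}

#' Read a fixed-column per-atom velocity dump
#'
#' Minimal frame-block format: each frame starts with a line
#' `t <time_ps> natoms <n>` followed by `n` rows `id res mass vx vy vz`
#' (mass in u, velocities in nm/ps).
#'
#' @param path File path.
#' @return A tibble with columns `time`, `atom_id`, `residue`, `mass`, `vx`,
#'   `vy`, `vz`.
#' @export
read_atom_dump <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    hd <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(hd) != 4 || hd[1] != "t" || hd[3] != "natoms") {
      stop("malformed frame header at line ", i, call. = FALSE)
    }
    tm <- as.numeric(hd[2]); nat <- as.integer(hd[4])
    if (i + nat > length(lines)) stop("truncated frame at line ", i, call. = FALSE)
    block <- lines[(i + 1L):(i + nat)]
    num <- matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"))),
                  ncol = 6, byrow = TRUE)
    out[[length(out) + 1L]] <- tibble::tibble(
      time = tm, atom_id = as.integer(num[, 1]), residue = as.integer(num[, 2]),
      mass = num[, 3], vx = num[, 4], vy = num[, 5], vz = num[, 6]
    )
    i <- i + nat + 1L
  }
  dplyr::bind_rows(out)
}

#' Aggregate per-atom frames into per-residue kinetic energies
#'
#' Sums `1/2 m |v|^2` over the atoms of each residue per frame and converts
#' from u nm^2 ps^-2 to eV. Degrees of freedom are recorded as `3 N_j` with
#' `N_j` the residue atom count; the kinetic temperature is then
#' `T_j = 2 E_j / (f_j kB)`.
#'
#' @param atoms A tibble as returned by [read_atom_dump()] (columns `time`,
#'   `atom_id`, `residue`, `mass`, `vx`, `vy`, `vz`).
#' @param bath_temperature,heater_index,ensemble_id Metadata for the result.
#' @param dof Optional per-residue dof override (default `3 N_j`).
#' @return An `energy_trajectory`.
#' @export
aggregate_atoms <- function(atoms, bath_temperature = NA_real_,
                            heater_index = 1L, ensemble_id = "member-1",
                            dof = NULL) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("time", "atom_id", "residue", "mass", "vx", "vy", "vz") %in% names(atoms)))
  if (any(atoms$mass <= 0)) stop_bad_rows("nonpositive mass", which(atoms$mass <= 0))
  if (any(atoms$residue < 1)) stop_bad_rows("residue index < 1", which(atoms$residue < 1))

  amap <- dplyr::distinct(atoms, .data$atom_id, .data$residue)
  if (anyDuplicated(amap$atom_id)) {
    stop("atom(s) assigned to more than one residue: ",
         paste(utils::head(amap$atom_id[duplicated(amap$atom_id)], 5), collapse = ", "),
         call. = FALSE)
  }
  n_res <- max(amap$residue)
  counts <- tabulate(amap$residue, nbins = n_res)
  if (any(counts == 0)) {
    stop("residue(s) with zero atoms: ", paste(which(counts == 0), collapse = ", "),
         call. = FALSE)
  }
  per_frame <- dplyr::count(atoms, .data$time, .data$residue)
  if (length(unique(per_frame$n[order(per_frame$residue)])) >= 1) {
    chk <- dplyr::group_by(per_frame, .data$residue)
    chk <- dplyr::summarise(chk, bad = dplyr::n_distinct(.data$n) > 1, .groups = "drop")
    if (any(chk$bad)) {
      stop("atom count per residue varies across frames", call. = FALSE)
    }
  }

  res <- dplyr::group_by(atoms, .data$time, .data$residue)
  res <- dplyr::summarise(
    res,
    energy = 0.5 * sum(.data$mass * (.data$vx^2 + .data$vy^2 + .data$vz^2)) *
      eV_per_u_nm2_ps2,
    .groups = "drop"
  )
  if (is.null(dof)) dof <- 3 * counts
  as_energy_trajectory(res, dof = dof, bath_temperature = bath_temperature,
                       heater_index = heater_index, ensemble_id = ensemble_id)
}

#' Write / read tabular result records
#'
#' Generic round-trip-stable text serialisation for the package's tabular
#' result types (rate fits, flux records, binned statistics, regime fits,
#' transport profiles). Attributes other than class are stored in `# key
#' value` header lines as JSON; the body is a full-precision TSV.
#'
#' @param x A tibble-backed result object (or plain data frame).
#' @param path Output path.
#' @return `read_results()` returns the reconstructed object;
#'   `write_results()` returns `path` invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "energy_trajectory")) return(write_energy_trajectory(x, path))
  df <- as.data.frame(x)
  keep <- setdiff(names(attributes(x)),
                  c("names", "row.names", "class", "dim", "dimnames"))
  meta <- attributes(x)[keep]
  # only plain scalar/vector attributes survive serialisation; structured
  # attachments (topologies, arrival tables, ...) are session objects
  meta <- meta[vapply(meta, function(a) is.atomic(a) && is.null(dim(a)), TRUE)]
  hdr <- c(
    paste("# class", paste(class(x), collapse = " ")),
    if (length(meta)) paste("# attrs", as.character(
      jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null")
    )),
    paste(names(df), collapse = "\t")
  )
  fmt <- function(col) {
    if (is.numeric(col) && !is.integer(col)) format_full(col)
    else if (is.logical(col)) ifelse(col, "TRUE", "FALSE")
    else as.character(col)
  }
  body <- if (nrow(df)) do.call(paste, c(lapply(df, fmt), sep = "\t")) else character()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  meta <- parse_header_meta(lines)
  if (!is.null(meta$dof) && is.null(meta$class)) return(read_energy_trajectory(path))
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- body[-1]
  if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    cols <- lapply(seq_along(header), function(k) vapply(parts, `[[`, "", k))
  } else {
    cols <- rep(list(character()), length(header))
  }
  names(cols) <- header
  df <- tibble::as_tibble(lapply(cols, function(v) {
    if (!length(v)) return(numeric())
    if (all(v %in% c("TRUE", "FALSE"))) return(v == "TRUE")
    suppressWarnings(num <- as.numeric(v))
    if (!anyNA(num) || all(is.na(num) == (v %in% c("NA", "NaN")))) num else v
  }))
  if (!is.null(meta$attrs)) {
    att <- jsonlite::fromJSON(meta$attrs, simplifyVector = TRUE)
    for (nm in names(att)) attr(df, nm) <- att[[nm]]
  }
  if (!is.null(meta$class)) {
    cls <- strsplit(meta$class, " ")[[1]]
    class(df) <- unique(c(setdiff(cls, c("tbl_df", "tbl", "data.frame")), class(df)))
  }
  df
}
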