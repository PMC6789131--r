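#' Build a residue contact topology
#'
#' A contact topology is the coupling graph the master-equation fit runs over:
#' the backbone chain (pairs j, j+1) plus hydrogen-bond contacts. For an ideal
#' 3_10 helix the hydrogen-bond partners are (j, j+3); for an ideal alpha helix
#' (j, j+4); `helix = "custom"` takes an explicit pair list (and `"none"`
#' yields a bare chain).
#'
#' Terminal residues expose more surface to the solvent, which is modelled by
#' a per-residue multiplicative factor on the solvent coupling rate
#' (`surface_factor`, default 1 in the interior and `terminal_factor` at the
#' two chain ends).
#'
#' @param n_residues Number of residues (>= 2).
#' @param helix One of `"310"`, `"alpha"`, `"custom"`, `"none"`.
#' @param hbond_pairs For `helix = "custom"`: a two-column matrix or data frame
#'   of residue index pairs (i < j, non-adjacent).
#' @param n_atoms Atoms per residue; scalar or length-`n_residues` vector.
#'   Default 13 (an aminoisobutyric-acid residue).
#' @param dof Per-residue degrees of freedom; default `3 * n_atoms`. Override
#'   when constraints remove degrees of freedom.
#' @param terminal_factor Surface factor applied to residues 1 and
#'   `n_residues`; default 1.5.
#' @param surface_factor Optional full per-residue vector overriding the
#'   terminal-factor construction.
#' @param spacing Inter-residue distance along the transport axis, nm
#'   (default 0.2).
#' @return An object of class `contact_topology`: a list with `n_residues`,
#'   `pairs` (tibble: `i`, `j`, `channel`), `n_atoms`, `dof`, `surface_factor`,
#'   `spacing`.
#' @examples
#' topo <- build_topology(10, helix = "310")
#' topo$pairs
#' @export
build_topology <- function(n_residues,
                           helix = c("310", "alpha", "custom", "none"),
                           hbond_pairs = NULL,
                           n_atoms = 13,
                           dof = NULL,
                           terminal_factor = 1.5,
                           surface_factor = NULL,
                           spacing = 0.2) {
  helix <- match.arg(helix)
  n_residues <- as.integer(n_residues)
  if (n_residues < 2) stop("a topology needs at least 2 residues", call. = FALSE)

  n_atoms <- rep_len(as.numeric(n_atoms), n_residues)
  if (any(n_atoms < 1)) stop("n_atoms must be >= 1", call. = FALSE)
  if (is.null(dof)) dof <- 3 * n_atoms
  dof <- rep_len(as.numeric(dof), n_residues)
  if (any(dof < 3)) stop("per-residue dof must be >= 3", call. = FALSE)

  if (is.null(surface_factor)) {
    surface_factor <- rep(1, n_residues)
    surface_factor[c(1L, n_residues)] <- terminal_factor
  }
  surface_factor <- rep_len(as.numeric(surface_factor), n_residues)
  if (any(surface_factor <= 0)) stop("surface factors must be positive", call. = FALSE)

  backbone <- tibble::tibble(
    i = seq_len(n_residues - 1L),
    j = seq_len(n_residues - 1L) + 1L,
    channel = "backbone"
  )

  hb <- switch(helix,
    "310" = if (n_residues >= 4) cbind(seq_len(n_residues - 3L), seq_len(n_residues - 3L) + 3L),
    "alpha" = if (n_residues >= 5) cbind(seq_len(n_residues - 4L), seq_len(n_residues - 4L) + 4L),
    "custom" = {
      if (is.null(hbond_pairs)) stop("helix = 'custom' requires hbond_pairs", call. = FALSE)
      hp <- as.matrix(as.data.frame(hbond_pairs)[, 1:2])
      storage.mode(hp) <- "integer"
      hp
    },
    "none" = NULL
  )

  if (!is.null(hb) && nrow(hb) > 0) {
    hb <- t(apply(hb, 1, sort))
    if (any(hb < 1) || any(hb > n_residues)) {
      stop("hydrogen-bond pair index out of range 1..", n_residues, call. = FALSE)
    }
    if (any(hb[, 2] - hb[, 1] <= 1)) {
      stop("hydrogen-bond pairs must be non-adjacent (|i - j| > 1)", call. = FALSE)
    }
    key <- paste(hb[, 1], hb[, 2])
    if (anyDuplicated(key)) stop("duplicated hydrogen-bond pair", call. = FALSE)
    hb_tbl <- tibble::tibble(i = as.integer(hb[, 1]), j = as.integer(hb[, 2]),
                             channel = "hbond")
  } else {
    hb_tbl <- tibble::tibble(i = integer(), j = integer(), channel = character())
  }

  structure(
    list(
      n_residues = n_residues,
      pairs = dplyr::bind_rows(backbone, hb_tbl),
      n_atoms = n_atoms,
      dof = dof,
      surface_factor = surface_factor,
      spacing = spacing
    ),
    class = "contact_topology"
  )
}

#' @export
print.contact_topology <- function(x, ...) {
  n_hb <- sum(x$pairs$channel == "hbond")
  cat("<contact_topology> ", x$n_residues, " residues, ",
      x$n_residues - 1L, " backbone links, ", n_hb, " hydrogen bonds\n", sep = "")
  cat("  dof: ", paste(utils::head(x$dof, 6), collapse = " "),
      if (x$n_residues > 6) " ...", "\n", sep = "")
  invisible(x)
}

#' Read / write a topology pair list
#'
#' Plain-text exchange format: one pair per line, `i j channel`, plus header
#' comment lines (`# key value`) carrying residue count, atoms, dof, surface
#' factors and spacing.
#'
#' @param topology A `contact_topology`.
#' @param path File path.
#' @return `read_topology()` returns a `contact_topology`.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "contact_topology"))
  hdr <- c(
    paste("# n_residues", topology$n_residues),
    paste("# n_atoms", paste(format_full(topology$n_atoms), collapse = " ")),
    paste("# dof", paste(format_full(topology$dof), collapse = " ")),
    paste("# surface_factor", paste(format_full(topology$surface_factor), collapse = " ")),
    paste("# spacing", format_full(topology$spacing)),
    "i j channel"
  )
  body <- sprintf("%d %d %s", topology$pairs$i, topology$pairs$j, topology$pairs$channel)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  meta <- parse_header_meta(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))][-1]  # drop column header
  pairs <- if (length(body)) {
    parts <- strsplit(trimws(body), "\\s+")
    tibble::tibble(
      i = as.integer(vapply(parts, `[[`, "", 1L)),
      j = as.integer(vapply(parts, `[[`, "", 2L)),
      channel = vapply(parts, `[[`, "", 3L)
    )
  } else {
    tibble::tibble(i = integer(), j = integer(), channel = character())
  }
  hb <- pairs[pairs$channel == "hbond", c("i", "j")]
  build_topology(
    n_residues = as.integer(meta$n_residues),
    helix = if (nrow(hb)) "custom" else "none",
    hbond_pairs = if (nrow(hb)) hb else NULL,
    n_atoms = as.numeric(strsplit(meta$n_atoms, "\\s+")[[1]]),
    dof = as.numeric(strsplit(meta$dof, "\\s+")[[1]]),
    surface_factor = as.numeric(strsplit(meta$surface_factor, "\\s+")[[1]]),
    spacing = as.numeric(meta$spacing)
  )
}
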