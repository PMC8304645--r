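#' Constant-velocity harmonic-trap pulling protocol
#'
#' Parameters of a steered-pulling run: trap velocity `v` (Angstrom/ns),
#' spring constant `k` (kcal/mol/Angstrom^2), pull direction (unit 3-vector),
#' duration (ns) and bath temperature (K). Defaults are the package's standard
#' protocol for the MTP complex: v = 10 Angstrom/ns, k = 10 kcal/mol/Angstrom^2,
#' 2 ns at 300 K.
#'
#' @param v Trap velocity, Angstrom/ns.
#' @param k Trap spring constant, kcal/mol/Angstrom^2.
#' @param direction Pull direction; normalised internally.
#' @param duration Pull duration, ns.
#' @param temperature Bath temperature, K.
#' @return A list of class `iface_protocol`.
#' @export
pulling_protocol <- function(v = 10, k = 10, direction = c(1, 0, 0),
                             duration = 2, temperature = 300) {
  if (v <= 0 || k <= 0 || temperature <= 0 || duration <= 0) {
    abort("v, k, duration and temperature must all be positive")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) abort("direction must be a non-zero vector")
  structure(list(v = v, k = k, direction = direction / nrm,
                 duration = duration, temperature = temperature),
            class = "iface_protocol")
}

#' Pull direction between two C-alpha atoms
#'
#' Unit vector from the C-alpha of residue `from` toward the C-alpha of
#' residue `to` on one chain — the convention used to orient the pull along
#' the helix marking the interface midline (residues 595 to 591 of the
#' MTP-alpha subunit in the standard setup).
#'
#' @param structure A structure data frame.
#' @param chain Chain identifier.
#' @param from,to Author residue numbers.
#' @return Unit 3-vector.
#' @export
pull_direction <- function(structure, chain, from = 595, to = 591) {
  ca <- calpha(structure)
  p1 <- dplyr::filter(ca, .data$chain == !!chain, .data$resno == from)
  p2 <- dplyr::filter(ca, .data$chain == !!chain, .data$resno == to)
  if (nrow(p1) == 0 || nrow(p2) == 0) {
    abort("marker residue CA atoms not found")
  }
  d <- c(p2$x[1] - p1$x[1], p2$y[1] - p1$y[1], p2$z[1] - p1$z[1])
  d / sqrt(sum(d^2))
}

#' Instantaneous trap force
#'
#' For a trap moving at constant velocity from the initial pulled-coordinate
#' value `x0`, the applied force is `F = k * (x0 + v * t - x)`: positive when
#' the trap is ahead of the coordinate.
#'
#' @param protocol An [pulling_protocol()].
#' @param t Time, ns (>= 0).
#' @param x Current pulled-coordinate value, Angstrom.
#' @param x0 Initial pulled-coordinate value, Angstrom.
#' @return Force in kcal/mol/Angstrom.
#' @export
trap_force <- function(protocol, t, x, x0 = 0) {
  if (any(t < 0)) abort("t must be non-negative")
  protocol$k * (x0 + protocol$v * t - x)
}

#' Accumulated external work of a pulling record
#'
#' Work done by the moving trap, `W(t_n) = integral of F(t) * v dt` up to
#' `t_n`, by trapezoidal quadrature on the stored time grid.
#'
#' @param times Strictly increasing times, ns.
#' @param forces Trap forces on the same grid, kcal/mol/Angstrom.
#' @param v Trap velocity, Angstrom/ns.
#' @return Numeric vector `W(t)` (kcal/mol), starting at 0.
#' @export
accumulate_work <- function(times, forces, v) {
  if (length(times) != length(forces)) {
    abort("times and forces must have equal length")
  }
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  dt <- diff(times)
  increments <- v * dt * (head(forces, -1) + tail(forces, -1)) / 2
  c(0, cumsum(increments))
}

#' Read / write steered-pulling records
#'
#' CSV with columns `replica`, `time_ns`, `position_A`, `force_kcal_mol_A`
#' and optionally `work_kcal_mol`; absent work columns are recomputed with
#' [accumulate_work()] (which requires `v`).
#'
#' @param path CSV path.
#' @param v Trap velocity (Angstrom/ns), used to recompute work when absent.
#' @return A tibble with the five columns above.
#' @export
read_pulling_records <- function(path, v = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("replica", "time_ns", "position_A", "force_kcal_mol_A")
  if (!all(needed %in% names(df))) {
    abort(paste0("pulling record CSV needs columns ",
                 paste(needed, collapse = ", ")))
  }
  if (!"work_kcal_mol" %in% names(df)) {
    if (is.null(v)) abort("work column absent: supply v to recompute it")
    df <- df |>
      dplyr::group_by(.data$replica) |>
      dplyr::mutate(work_kcal_mol = accumulate_work(
        .data$time_ns, .data$force_kcal_mol_A, v)) |>
      dplyr::ungroup()
  }
  as_tibble(df)
}

#' @rdname read_pulling_records
#' @param records A pulling-record tibble (long, one row per replica and
#'   time point).
#' @export
write_pulling_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Harmonic restraint network over C-alpha atoms
#'
#' Connects every pair of C-alpha atoms of one chain whose distance in the
#' initial structure is at or below `cutoff` (inclusive) with a spring of
#' constant `k`; rest lengths are the initial distances. Used to keep a
#' pulled subunit internally rigid.
#'
#' @param structure Initial structure.
#' @param chain Chain identifier(s) of the restrained subunit.
#' @param cutoff Distance cutoff, Angstrom, inclusive. Default 7.
#' @param k Spring constant, kcal/mol/Angstrom^2. Default 10.
#' @return A tibble of class `iface_spring_network` with columns `i`, `j`
#'   (roster indices into the chain's C-alpha set), `resno_i`, `resno_j`,
#'   `rest_length`; attribute `k`.
#' @export
build_spring_network <- function(structure, chain, cutoff = 7, k = 10) {
  ca <- dplyr::filter(calpha(structure), .data$chain %in% !!chain)
  if (nrow(ca) < 2) abort("need at least 2 CA atoms to build a spring network")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- cross_dist(xyz, xyz)
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  out <- tibble(
    i = idx[, 1], j = idx[, 2],
    resno_i = ca$resno[idx[, 1]], resno_j = ca$resno[idx[, 2]],
    rest_length = d[idx]
  )
  attr(out, "k") <- k
  class(out) <- unique(c("iface_spring_network", class(out)))
  out
}
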