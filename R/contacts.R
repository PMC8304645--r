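# cross-partner Euclidean distance matrix, chunked to bound memory
cross_dist <- function(a_xyz, b_xyz) {
  a2 <- rowSums(a_xyz^2)
  b2 <- rowSums(b_xyz^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a_xyz, b_xyz)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

select_chain <- function(structure, chains, what = "selection") {
  out <- dplyr::filter(structure, .data$chain %in% chains)
  if (nrow(out) == 0) abort(paste0("empty ", what, ": no atoms on chain(s) ",
                                   paste(chains, collapse = ", ")))
  out
}

#' Count interface atom pairs between two binding partners
#'
#' Two atoms, one from each partner, form an interface atom pair when their
#' Euclidean distance is at or below `cutoff` (5 Angstrom by convention;
#' the bound is inclusive). Counts are decomposed by the region of the
#' partner-b (PDI-side) atom.
#'
#' @param structure A structure data frame (one conformation).
#' @param partner_a,partner_b Chain identifier(s) of the two partners
#'   (disjoint; partner_b is the PDI side used for region decomposition).
#' @param cutoff Distance cutoff in Angstrom, inclusive. Default 5.
#' @param region_map A region map, or `NULL` to skip decomposition.
#' @param heavy_only Drop hydrogen atoms before counting.
#' @return A tibble with one row per region (plus `"unassigned"` where
#'   applicable) and columns `region`, `n_pairs`; attributes `total` and
#'   `cutoff`. Class `iface_pair_count`.
#' @export
count_interface_atom_pairs <- function(structure, partner_a, partner_b,
                                       cutoff = 5, region_map = NULL,
                                       heavy_only = FALSE) {
  structure <- as_structure(structure)
  if (length(intersect(partner_a, partner_b)) > 0) {
    abort("partner selections overlap")
  }
  if (heavy_only) {
    structure <- dplyr::filter(structure, toupper(.data$element) != "H")
  }
  a <- select_chain(structure, partner_a, "partner_a")
  b <- select_chain(structure, partner_b, "partner_b")
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]))
  hit <- d <= cutoff
  per_b_atom <- colSums(hit)
  if (is.null(region_map)) {
    b_region <- rep("unassigned", nrow(b))
  } else {
    b_region <- assign_region(region_map, b$chain, b$resno)
  }
  out <- tibble(region = b_region, n = per_b_atom) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_pairs = sum(.data$n), .groups = "drop")
  attr(out, "total") <- sum(per_b_atom)
  attr(out, "cutoff") <- cutoff
  class(out) <- unique(c("iface_pair_count", class(out)))
  out
}

new_contact_set <- function(pairs, source) {
  pairs <- dplyr::distinct(as_tibble(pairs))
  attr(pairs, "source") <- source
  class(pairs) <- unique(c("iface_contact_set", class(pairs)))
  pairs
}

#' @export
print.iface_contact_set <- function(x, ...) {
  cat(sprintf("<iface_contact_set> %d contacts (source: %s)\n",
              nrow(x), attr(x, "source") %||% "unknown"))
  NextMethod()
}

contact_pairs_from_calpha <- function(ca_a, ca_b, xyz_a, xyz_b, cutoff,
                                      hit = NULL) {
  if (is.null(hit)) hit <- cross_dist(xyz_a, xyz_b) <= cutoff
  idx <- which(hit, arr.ind = TRUE)
  tibble(
    chain_a = ca_a$chain[idx[, 1]],
    resno_a = ca_a$resno[idx[, 1]],
    chain_b = ca_b$chain[idx[, 2]],
    resno_b = ca_b$resno[idx[, 2]]
  )
}

label_contacts <- function(pairs, region_map) {
  if (is.null(region_map)) {
    pairs$region <- "other"
  } else {
    pdi_region <- assign_region(region_map, pairs$chain_b, pairs$resno_b)
    pairs$region <- contact_region_label(pdi_region)
  }
  pairs
}

get_calpha_partner <- function(structure, chains, what) {
  ca <- dplyr::filter(structure, .data$chain %in% chains)
  lacking <- ca |>
    dplyr::group_by(.data$chain, .data$resno) |>
    dplyr::summarise(has_ca = any(.data$name == "CA"), .groups = "drop") |>
    dplyr::filter(!.data$has_ca)
  if (nrow(lacking) > 0) {
    warn(sprintf("%d residue(s) in %s lack a CA atom and are skipped",
                 nrow(lacking), what))
  }
  ca <- dplyr::filter(ca, .data$name == "CA")
  if (nrow(ca) == 0) abort(paste0("no CA atoms in ", what))
  ca
}

#' Interface residue contacts of a single conformation
#'
#' Residue pairs, one residue per partner, whose C-alpha to C-alpha distance
#' is at or below `cutoff` (7 Angstrom by convention, inclusive). Contacts are
#' labelled region1/region2/region3/region3_prime according to the PDI-side
#' domain (a, b', a', C-terminal), or `"other"`.
#'
#' @inheritParams count_interface_atom_pairs
#' @param cutoff C-alpha distance cutoff in Angstrom, inclusive. Default 7.
#' @return A tibble of class `iface_contact_set` with columns `chain_a`,
#'   `resno_a`, `chain_b`, `resno_b`, `region`; attribute
#'   `source = "single-structure"`.
#' @export
contacts_from_structure <- function(structure, partner_a, partner_b,
                                    cutoff = 7, region_map = NULL) {
  structure <- as_structure(structure)
  ca_a <- get_calpha_partner(structure, partner_a, "partner_a")
  ca_b <- get_calpha_partner(structure, partner_b, "partner_b")
  pairs <- contact_pairs_from_calpha(
    ca_a, ca_b,
    as.matrix(ca_a[, c("x", "y", "z")]), as.matrix(ca_b[, c("x", "y", "z")]),
    cutoff)
  new_contact_set(label_contacts(pairs, region_map), "single-structure")
}

#' Interface residue contacts over a trajectory
#'
#' A residue pair is an interface contact if its C-alpha distance is at or
#' below `cutoff` in any one frame of the trajectory (union over frames).
#'
#' @inheritParams contacts_from_structure
#' @param trajectory An `iface_trajectory`.
#' @return An `iface_contact_set`, `source = "trajectory-union"`.
#' @export
contacts_from_trajectory <- function(trajectory, partner_a, partner_b,
                                     cutoff = 7, region_map = NULL) {
  roster <- trajectory$roster
  ca_a <- get_calpha_partner(roster, partner_a, "partner_a")
  ca_b <- get_calpha_partner(roster, partner_b, "partner_b")
  key <- paste(roster$chain, roster$resno, roster$name, roster$serial)
  ia <- match(paste(ca_a$chain, ca_a$resno, ca_a$name, ca_a$serial), key)
  ib <- match(paste(ca_b$chain, ca_b$resno, ca_b$name, ca_b$serial), key)
  any_hit <- matrix(FALSE, nrow(ca_a), nrow(ca_b))
  for (k in seq_len(n_frames(trajectory))) {
    xa <- trajectory$coords[ia, , k, drop = FALSE][, , 1, drop = TRUE]
    xb <- trajectory$coords[ib, , k, drop = FALSE][, , 1, drop = TRUE]
    xa <- matrix(xa, ncol = 3)
    xb <- matrix(xb, ncol = 3)
    any_hit <- any_hit | (cross_dist(xa, xb) <= cutoff)
  }
  pairs <- contact_pairs_from_calpha(ca_a, ca_b, NULL, NULL, cutoff,
                                     hit = any_hit)
  new_contact_set(label_contacts(pairs, region_map), "trajectory-union")
}

#' Union of contact sets
#'
#' Deduplicated union of residue-contact sets, e.g. the trajectory-derived
#' sets of several simulation conditions together with the crystal-structure
#' set.
#'
#' @param ... Contact sets, or a single list of them.
#' @return An `iface_contact_set`, `source = "multi-source-union"`.
#' @export
union_contacts <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "data.frame")) {
    sets <- sets[[1]]
  }
  if (length(sets) < 1) abort("union_contacts needs at least one set")
  merged <- dplyr::bind_rows(lapply(sets, as_tibble)) |>
    dplyr::distinct(.data$chain_a, .data$resno_a, .data$chain_b,
                    .data$resno_b, .data$region)
  new_contact_set(merged, "multi-source-union")
}
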