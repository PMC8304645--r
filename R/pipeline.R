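#' Analysis configuration
#'
#' Collects the constants of the interface-stability analysis. Every default
#' equals the package's standard protocol for the MTP complex: 5 Angstrom
#' atom-pair cutoff, 7 Angstrom C-alpha contact cutoff, 14 Angstrom^2 tail
#' exclusion threshold, 1 Angstrom^2 comparison margin, 300 K, and the
#' 886-894 alpha-subunit tail.
#'
#' @param pair_cutoff Atom-pair cutoff, Angstrom.
#' @param contact_cutoff C-alpha contact cutoff, Angstrom.
#' @param exclusion_threshold Tail-exclusion MSFD threshold, Angstrom^2.
#' @param margin Condition-comparison margin, Angstrom^2.
#' @param tail Alpha-subunit C-terminal tail interval.
#' @param temperature Temperature, K.
#' @param region_map A region map ([default_region_map()]).
#' @param partner_a,partner_b Chain selections of the two partners
#'   (partner_b = PDI side).
#' @param area_method Interface-area method, see [interface_area()].
#' @param heavy_only Drop hydrogens in atom-pair counts.
#' @return A list of class `iface_config`.
#' @export
analysis_config <- function(pair_cutoff = 5, contact_cutoff = 7,
                            exclusion_threshold = 14, margin = 1,
                            tail = c(886L, 894L), temperature = 300,
                            region_map = default_region_map(),
                            partner_a = "A", partner_b = "B",
                            area_method = "buried-sasa",
                            heavy_only = FALSE) {
  if (pair_cutoff <= 0 || contact_cutoff <= 0 || exclusion_threshold <= 0 ||
      margin < 0) {
    abort("cutoffs must be positive")
  }
  structure(
    list(pair_cutoff = pair_cutoff, contact_cutoff = contact_cutoff,
         exclusion_threshold = exclusion_threshold, margin = margin,
         tail = as.integer(tail), temperature = temperature,
         region_map = region_map, partner_a = partner_a,
         partner_b = partner_b, area_method = area_method,
         heavy_only = heavy_only),
    class = "iface_config"
  )
}

#' Run the full interface-stability analysis
#'
#' Orchestrates the per-condition pipeline: residue contacts as the union
#' over trajectory frames (optionally merged with a crystal structure's
#' contact set), per-contact MSFD per condition, the C-terminal tail
#' exclusion filter, pairwise condition comparisons at the configured margin,
#' region-average MSFD, and (from each condition's final frame) atom-pair
#' counts and interface areas in the standard region layout. Deterministic
#' given its inputs.
#'
#' @param trajectories Named list of `iface_trajectory`, one per condition;
#'   names are the condition labels and must be unique.
#' @param config An [analysis_config()].
#' @param crystal Optional `iface_structure` whose contact set is merged into
#'   the contact universe.
#' @param verbose Log each stage.
#' @return A list of class `iface_report` with elements `contacts`, `msfd`,
#'   `exclusion`, `kept_msfd`, `comparisons`, `region_averages`,
#'   `atom_pairs`, `areas`.
#' @export
run_interface_analysis <- function(trajectories, config = analysis_config(),
                                   crystal = NULL, verbose = FALSE) {
  labels <- names(trajectories)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    abort("trajectories must be a uniquely named list of conditions")
  }
  say <- function(...) if (verbose) inform(sprintf(...))
  rm_ <- config$region_map
  say("contacts: union over frames at %.1f Angstrom", config$contact_cutoff)
  per_cond <- lapply(trajectories, contacts_from_trajectory,
                     partner_a = config$partner_a,
                     partner_b = config$partner_b,
                     cutoff = config$contact_cutoff, region_map = rm_)
  sets <- per_cond
  if (!is.null(crystal)) {
    sets <- c(sets, list(crystal = contacts_from_structure(
      crystal, config$partner_a, config$partner_b,
      cutoff = config$contact_cutoff, region_map = rm_)))
  }
  universe <- union_contacts(sets)
  say("contact universe: %d contacts", nrow(universe))
  msfd_tables <- lapply(labels, function(lb) {
    msfd_table(trajectories[[lb]], universe, label = lb)
  })
  names(msfd_tables) <- labels
  excl <- apply_cterm_exclusion(msfd_tables, tail = config$tail,
                                threshold = config$exclusion_threshold)
  kept_keys <- contact_key(excl$kept)
  kept_tables <- lapply(msfd_tables, function(t) {
    t[contact_key(t) %in% kept_keys, ]
  })
  comparisons <- list()
  if (length(labels) >= 2) {
    combs <- utils::combn(labels, 2, simplify = FALSE)
    comparisons <- lapply(combs, function(pr) {
      cc <- compare_conditions(kept_tables[[pr[1]]], kept_tables[[pr[2]]],
                               margin = config$margin)
      tibble(condition_a = pr[1], condition_b = pr[2],
             n_a_higher = cc$n_a_higher, n_b_higher = cc$n_b_higher)
    })
    comparisons <- dplyr::bind_rows(comparisons)
  }
  region_avg <- dplyr::bind_rows(lapply(labels, function(lb) {
    dplyr::mutate(region_average_msfd(kept_tables[[lb]]), label = lb)
  }))
  final_frames <- lapply(trajectories, function(tr) {
    trajectory_frame(tr, n_frames(tr))
  })
  atom_pairs <- dplyr::bind_rows(lapply(labels, function(lb) {
    pc <- count_interface_atom_pairs(
      final_frames[[lb]], config$partner_a, config$partner_b,
      cutoff = config$pair_cutoff, region_map = rm_,
      heavy_only = config$heavy_only)
    dplyr::mutate(as_tibble(pc), label = lb, total = attr(pc, "total"))
  }))
  areas <- dplyr::bind_rows(lapply(labels, function(lb) {
    ar <- interface_area(final_frames[[lb]], config$partner_a,
                         config$partner_b, method = config$area_method,
                         region_map = rm_)
    dplyr::mutate(as_tibble(ar), label = lb, total = attr(ar, "total"))
  }))
  structure(
    list(contacts = universe, msfd = msfd_tables, exclusion = excl,
         kept_msfd = kept_tables, comparisons = comparisons,
         region_averages = region_avg, atom_pairs = atom_pairs,
         areas = areas, config = config),
    class = "iface_report"
  )
}

#' Run the pulling / free-energy analysis
#'
#' Per condition: accumulated-work checks, the PMF curve (both Jarzynski
#' estimators) truncated at `lambda_max`, and, when per-replica trajectories
#' are supplied, the averaged force-distance profile.
#'
#' @param ensembles Named list of replica ensembles
#'   ([simulate_brownian_pull()] output or compatible), one per condition.
#' @param lambda_max Truncation of the pulled distance, Angstrom (`NULL` for
#'   the full pull).
#' @param trajectories Optional named list (same names) of per-replica
#'   trajectory lists for force-distance profiles.
#' @param markers,marker_chain Marker residues for the midpoint distance.
#' @return A list of class `iface_pull_report` with `pmf` (named list of
#'   `iface_pmf`) and `force_distance` (named list of profiles or `NULL`).
#' @export
run_pulling_analysis <- function(ensembles, lambda_max = NULL,
                                 trajectories = NULL,
                                 markers = c(595L, 591L),
                                 marker_chain = "A") {
  labels <- names(ensembles)
  if (is.null(labels) || anyDuplicated(labels)) {
    abort("ensembles must be a uniquely named list of conditions")
  }
  pmf <- lapply(ensembles, pmf_curve, lambda_max = lambda_max)
  fd <- NULL
  if (!is.null(trajectories)) {
    fd <- lapply(labels, function(lb) {
      force_distance_profile(ensembles[[lb]], trajectories[[lb]],
                             chain = marker_chain, markers = markers)
    })
    names(fd) <- labels
  }
  structure(list(pmf = pmf, force_distance = fd), class = "iface_pull_report")
}
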