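#' Per-frame C-alpha distance of one interface contact
#'
#' @param trajectory An `iface_trajectory`.
#' @param chain_a,resno_a,chain_b,resno_b Identity of the residue pair (one
#'   residue per partner).
#' @return Numeric vector of per-frame Euclidean C-alpha distances, Angstrom.
#' @export
distance_series <- function(trajectory, chain_a, resno_a, chain_b, resno_b) {
  roster <- trajectory$roster
  ia <- which(roster$chain == chain_a & roster$resno == resno_a &
                roster$name == "CA")
  ib <- which(roster$chain == chain_b & roster$resno == resno_b &
                roster$name == "CA")
  if (length(ia) == 0 || length(ib) == 0) {
    abort(sprintf("missing CA atom for contact %s%d - %s%d",
                  chain_a, resno_a, chain_b, resno_b))
  }
  diffs <- trajectory$coords[ia[1], , ] - trajectory$coords[ib[1], , ]
  diffs <- matrix(diffs, nrow = 3)
  sqrt(colSums(diffs^2))
}

#' Mean-square fluctuation of a distance series
#'
#' The population variance of the series: the mean of squared deviations from
#' the series mean, with divisor N (the number of conformations), not N - 1.
#'
#' @param values Numeric vector of per-frame distances (length >= 2).
#' @return MSFD in Angstrom squared.
#' @examples
#' msfd(c(1, 2, 3)) # 2/3
#' @export
msfd <- function(values) {
  n <- length(values)
  if (n < 2) abort("MSFD needs at least 2 frames")
  mean((values - mean(values))^2)
}

#' MSFD of every contact of a contact set over one trajectory
#'
#' @param trajectory An `iface_trajectory`.
#' @param contacts An `iface_contact_set` (or compatible data frame).
#' @param label Trajectory/condition label stored in the result.
#' @param stride Frame stride; 1 keeps every stored frame.
#' @return A tibble of class `iface_msfd_table`: contact key columns,
#'   `region`, `msfd` (Angstrom squared), `label`, `n_frames`.
#' @export
msfd_table <- function(trajectory, contacts, label = "trajectory",
                       stride = 1) {
  contacts <- as_tibble(contacts)
  frames <- seq(1, n_frames(trajectory), by = stride)
  if (length(frames) < 2) abort("MSFD needs at least 2 frames after striding")
  sub <- trajectory
  sub$coords <- trajectory$coords[, , frames, drop = FALSE]
  vals <- purrr::pmap_dbl(
    contacts[, c("chain_a", "resno_a", "chain_b", "resno_b")],
    function(chain_a, resno_a, chain_b, resno_b) {
      msfd(distance_series(sub, chain_a, resno_a, chain_b, resno_b))
    })
  out <- contacts
  out$msfd <- vals
  out$label <- label
  out$n_frames <- length(frames)
  class(out) <- unique(c("iface_msfd_table", class(out)))
  out
}

contact_key <- function(df) {
  paste(df$chain_a, df$resno_a, df$chain_b, df$resno_b, sep = "|")
}

check_same_universe <- function(tables) {
  keys <- lapply(tables, function(t) sort(contact_key(t)))
  if (length(unique(keys)) != 1) {
    abort("MSFD tables do not share one contact universe")
  }
}

#' Exclude flexible C-terminal tail contacts
#'
#' A contact is excluded when (a) its partner-a (MTP-alpha side) residue lies
#' in the flexible C-terminal tail interval and (b) its MSFD exceeds
#' `threshold` (strictly) in at least one of the supplied tables. Both
#' conditions are required; a large MSFD outside the tail is kept.
#'
#' @param tables A list of `iface_msfd_table`s over the same contact universe
#'   (e.g. one per simulation condition).
#' @param tail Integer length-2 inclusive residue interval of the tail on the
#'   partner-a chain. Default `c(886, 894)`.
#' @param threshold MSFD threshold in Angstrom squared, strict. Default 14.
#' @return A list with tibbles `kept` and `excluded`; `excluded` carries
#'   `max_msfd` and `n_tables_over` provenance columns.
#' @export
apply_cterm_exclusion <- function(tables, tail = c(886L, 894L),
                                  threshold = 14) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  check_same_universe(tables)
  wide <- dplyr::bind_rows(lapply(tables, as_tibble)) |>
    dplyr::group_by(.data$chain_a, .data$resno_a, .data$chain_b,
                    .data$resno_b, .data$region) |>
    dplyr::summarise(max_msfd = max(.data$msfd),
                     n_tables_over = sum(.data$msfd > threshold),
                     .groups = "drop")
  in_tail <- wide$resno_a >= tail[1] & wide$resno_a <= tail[2]
  excl <- in_tail & wide$n_tables_over >= 1
  list(kept = wide[!excl, ], excluded = wide[excl, ])
}

#' Compare per-contact MSFD between two conditions
#'
#' Counts contacts whose MSFD in condition a exceeds condition b by more than
#' `margin` (strictly), and vice versa; contacts within the margin band count
#' in neither.
#'
#' @param table_a,table_b `iface_msfd_table`s over the same contact universe.
#' @param margin Margin in Angstrom squared, strict. Default 1.
#' @return A list: `n_a_higher`, `n_b_higher`, and `deltas`, a tibble with the
#'   per-contact `delta = msfd_a - msfd_b`.
#' @export
compare_conditions <- function(table_a, table_b, margin = 1) {
  check_same_universe(list(table_a, table_b))
  a <- as_tibble(table_a)[, c("chain_a", "resno_a", "chain_b", "resno_b",
                              "region", "msfd")]
  b <- as_tibble(table_b)[, c("chain_a", "resno_a", "chain_b", "resno_b",
                              "msfd")]
  joined <- dplyr::left_join(
    a, b, by = c("chain_a", "resno_a", "chain_b", "resno_b"),
    suffix = c("_a", "_b"))
  joined$delta <- joined$msfd_a - joined$msfd_b
  list(
    n_a_higher = sum(joined$delta > margin),
    n_b_higher = sum(-joined$delta > margin),
    deltas = joined
  )
}

#' Region-average MSFD
#'
#' Arithmetic mean of MSFD per interface region over the member contacts,
#' plus `all_four`, the pooled mean over all contacts belonging to regions
#' 1, 2, 3 and 3'. Regions with no contacts are absent from the result
#' (not reported as zero).
#'
#' @param table An `iface_msfd_table` (with `region` labels).
#' @param pooled If `FALSE`, `all_four` is the mean of the four region
#'   averages instead of the pooled per-contact mean.
#' @return A tibble with columns `region`, `mean_msfd`, `n_contacts`.
#' @export
region_average_msfd <- function(table, pooled = TRUE) {
  t <- as_tibble(table)
  four <- c("region1", "region2", "region3", "region3_prime")
  per_region <- t |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mean_msfd = mean(.data$msfd), n_contacts = dplyr::n(),
                     .groups = "drop")
  members <- dplyr::filter(t, .data$region %in% four)
  if (nrow(members) > 0) {
    all_four <- if (pooled) {
      mean(members$msfd)
    } else {
      mean(dplyr::filter(per_region, .data$region %in% four)$mean_msfd)
    }
    per_region <- dplyr::bind_rows(
      per_region,
      tibble(region = "all_four", mean_msfd = all_four,
             n_contacts = nrow(members)))
  }
  per_region
}
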