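#' Domain / region maps for the MTP heterodimer
#'
#' A region map is a tibble with columns `chain`, `region`, `start`, `end`
#' giving inclusive author-numbered residue intervals. Intervals within one
#' chain must not overlap; residues falling in no interval are reported as
#' `"unassigned"`.
#'
#' `default_region_map()` encodes the canonical domain architecture of the
#' human MTP complex: the PDI (beta) subunit's N-terminal segment (18-25),
#' thioredoxin domains a (26-133), b (137-232), b' (235-349), x linker
#' (350-368), a' (369-479) and C-terminal tail (480-508); and the alpha
#' subunit's beta-barrel (19-297), alpha-helical (298-603) and lipid-binding
#' (604-894) domains. The alpha subunit's modeled C-terminal tail (default
#' 886-894) is carried as the `tail` attribute and drives the MSFD exclusion
#' rule.
#'
#' @param pdi_chain,mtpa_chain Chain identifiers of the PDI and MTP-alpha
#'   subunits in the coordinates being analysed.
#' @param tail Integer length-2 vector, inclusive residue interval of the
#'   alpha-subunit C-terminal tail.
#' @return A tibble of class `iface_region_map` with attributes `pdi_chain`,
#'   `mtpa_chain`, `tail`.
#' @export
default_region_map <- function(pdi_chain = "B", mtpa_chain = "A",
                               tail = c(886L, 894L)) {
  df <- dplyr::bind_rows(
    tibble(chain = pdi_chain,
           region = c("N_terminal", "a", "b", "b_prime", "x", "a_prime",
                      "C_terminal"),
           start = c(18L, 26L, 137L, 235L, 350L, 369L, 480L),
           end = c(25L, 133L, 232L, 349L, 368L, 479L, 508L)),
    tibble(chain = mtpa_chain,
           region = c("beta_barrel", "alpha_helical", "lipid_binding"),
           start = c(19L, 298L, 604L),
           end = c(297L, 603L, 894L))
  )
  region_map(df, pdi_chain = pdi_chain, mtpa_chain = mtpa_chain, tail = tail)
}

#' @rdname default_region_map
#' @param df A data frame with columns `chain`, `region`, `start`, `end`.
#' @export
region_map <- function(df, pdi_chain, mtpa_chain, tail = c(886L, 894L)) {
  needed <- c("chain", "region", "start", "end")
  if (!all(needed %in% names(df))) {
    abort("region map needs columns chain, region, start, end")
  }
  if (any(df$end < df$start)) abort("region intervals must have start <= end")
  # overlap check within each chain
  by_chain <- split(df, df$chain)
  for (ch in by_chain) {
    ch <- ch[order(ch$start), ]
    if (nrow(ch) > 1 && any(ch$start[-1] <= ch$end[-nrow(ch)])) {
      abort(sprintf("overlapping region intervals on chain %s", ch$chain[1]))
    }
  }
  out <- as_tibble(df)
  attr(out, "pdi_chain") <- pdi_chain
  attr(out, "mtpa_chain") <- mtpa_chain
  attr(out, "tail") <- as.integer(tail)
  class(out) <- unique(c("iface_region_map", class(out)))
  out
}

#' Look up the region of a residue
#'
#' @param map A region map ([default_region_map()]).
#' @param chain Chain identifier (vectorised with `residue_number`).
#' @param residue_number Author residue number(s).
#' @return Character vector of region names; `"unassigned"` where the residue
#'   falls in an interval gap.
#' @examples
#' m <- default_region_map()
#' assign_region(m, "B", 256) # b_prime
#' @export
assign_region <- function(map, chain, residue_number) {
  if (!all(chain %in% map$chain)) {
    abort(sprintf("unknown chain(s): %s",
                  paste(setdiff(unique(chain), map$chain), collapse = ", ")))
  }
  n <- max(length(chain), length(residue_number))
  chain <- rep_len(chain, n)
  residue_number <- rep_len(residue_number, n)
  vapply(seq_len(n), function(i) {
    hit <- map$chain == chain[i] & map$start <= residue_number[i] &
      map$end >= residue_number[i]
    if (any(hit)) map$region[which(hit)[1]] else "unassigned"
  }, character(1))
}

# Table-layout region label of an interface contact, keyed to the PDI-side
# domain: region1 = a, region2 = b', region3 = a', region3' = C-terminal.
contact_region_label <- function(pdi_region) {
  dplyr::case_match(pdi_region,
    "a" ~ "region1",
    "b_prime" ~ "region2",
    "a_prime" ~ "region3",
    "C_terminal" ~ "region3_prime",
    .default = "other"
  )
}
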