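#' Atomic structures as tibbles
#'
#' An `iface_structure` is a tibble with one row per atom and columns
#' `serial`, `name` (PDB atom name), `element`, `resno` (author residue
#' number), `resid` (3-letter residue name), `chain` and the Cartesian
#' coordinates `x`, `y`, `z` in Angstrom. All analysis functions in the
#' package accept any data frame with these columns; `as_structure()`
#' validates and stamps the class.
#'
#' @param df A data frame with at least the columns listed above.
#' @return A tibble of class `iface_structure`.
#' @examples
#' s <- as_structure(tibble::tibble(
#'   serial = 1:2, name = c("CA", "CA"), element = c("C", "C"),
#'   resno = c(1L, 2L), resid = "GLY", chain = c("A", "B"),
#'   x = c(0, 3), y = 0, z = 0
#' ))
#' @export
as_structure <- function(df) {
  needed <- c("serial", "name", "element", "resno", "resid", "chain",
              "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("structure is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("structure has non-finite coordinates")
  }
  if (any(!nzchar(df$element) | is.na(df$element))) {
    abort("structure has atoms with an empty element field")
  }
  out <- as_tibble(df)
  for (col in c("serial", "resno", "x", "y", "z")) {
    out[[col]] <- unname(out[[col]])
  }
  class(out) <- unique(c("iface_structure", class(out)))
  out
}

#' @export
print.iface_structure <- function(x, ...) {
  cat(sprintf("<iface_structure> %d atoms, %d chain(s): %s\n",
              nrow(x), length(unique(x$chain)),
              paste(sort(unique(x$chain)), collapse = ", ")))
  NextMethod()
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records of one model of a PDB file (via bio3d), keeping
#' author residue numbering. Alternate-location duplicates are resolved to the
#' highest-occupancy copy; ties keep the first listed.
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based model to extract from a multi-model file.
#' @return An [as_structure()] tibble.
#' @export
read_pdb <- function(path, model_index = 1) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path))
  }
  check_pdb_coordinate_lines(path)
  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)))
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    abort(sprintf("model_index %d out of range: file has %d model(s)",
                  model_index, n_models))
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at <- pdb$atom
  df <- tibble(
    serial = as.integer(at$eleno),
    name = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                     guess_element(at$elety), trimws(at$elesy)),
    resno = as.integer(at$resno),
    resid = at$resid,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  # altloc resolution: keep highest occupancy per (chain, resno, atom name),
  # ties resolved to the first listed record
  df <- df |>
    dplyr::group_by(.data$chain, .data$resno, .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$serial) |>
    dplyr::select(-"altloc", -"occupancy")
  as_structure(df)
}

# element symbol from a PDB atom name when columns 77-78 are blank
guess_element <- function(name) {
  stripped <- sub("^[0-9]+", "", trimws(name))
  two <- toupper(substr(stripped, 1, 2))
  one <- toupper(substr(stripped, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "SE"),
         two, one)
}

# spec'd error contract: a coordinate field that does not parse must be
# reported with its line number (bio3d would silently yield NA)
check_pdb_coordinate_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  idx <- which(is_atom)
  for (i in idx) {
    ln <- lines[i]
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- trimws(substr(ln, cols[1], cols[2]))
      if (!nzchar(fld) || is.na(suppressWarnings(as.numeric(fld)))) {
        abort(sprintf(
          "malformed coordinate field '%s' on line %d of %s", fld, i, path))
      }
    }
  }
  invisible(TRUE)
}

format_pdb_atom_line <- function(serial, name, resid, chain, resno,
                                 x, y, z, element) {
  # atom names of 1-3 characters start in column 14 by PDB convention
  name_fmt <- ifelse(nchar(name) >= 4, substr(name, 1, 4),
                     sprintf(" %-3s", name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, name_fmt, resid, chain, resno, x, y, z,
          1, 0, substr(element, 1, 2))
}

#' Write a structure to a PDB file
#'
#' @param structure An [as_structure()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  s <- as_structure(structure)
  lines <- format_pdb_atom_line(s$serial, s$name, s$resid, s$chain, s$resno,
                                s$x, s$y, s$z, s$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Extract the C-alpha atoms of a structure
#'
#' @param structure A structure data frame.
#' @return An `iface_structure` tibble with only `CA` atoms.
#' @export
calpha <- function(structure) {
  out <- dplyr::filter(as_structure(structure), .data$name == "CA")
  as_structure(out)
}
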