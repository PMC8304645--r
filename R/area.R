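# Bondi-type van der Waals radii (Angstrom); unknown elements fall back to
# 1.7 with a warning.
vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.40,
  MN = 1.40
)

atom_radii <- function(element) {
  key <- toupper(element)
  r <- unname(vdw_radii[key])
  if (any(is.na(r))) {
    warn(sprintf("unknown element radius for %s; using 1.7 Angstrom",
                 paste(unique(key[is.na(r)]), collapse = ", ")))
    r[is.na(r)] <- 1.7
  }
  r
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom
#'
#' Shrake-Rupley numerical SASA: each atom's solvent-accessible sphere
#' (van der Waals radius plus probe radius) is sampled with a deterministic
#' quasi-uniform point set; a point is accessible when it lies outside every
#' neighbour's solvent-accessible sphere. Areas are reported on the expanded
#' (accessible-surface) sphere, in Angstrom squared.
#'
#' @param structure A structure data frame.
#' @param probe Probe (solvent) radius in Angstrom. Default 1.4.
#' @param n_points Sample points per atom. Default 960.
#' @return Numeric vector of per-atom SASA, one value per row of `structure`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960) {
  s <- as_structure(structure)
  n <- nrow(s)
  radii <- atom_radii(s$element) + probe
  xyz <- as.matrix(s[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  out <- numeric(n)
  # neighbour lists from one distance matrix; fine at the package's scale
  d <- cross_dist(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < radii[i] + radii & seq_len(n) != i)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * radii[i]^2
      next
    }
    # orient the point set in a local frame built from the neighbour
    # geometry (z along the nearest neighbour, x toward the next one), so
    # the quadrature is exactly equivariant under rigid motion of the input
    nb <- nb[order(d[i, nb], nb)]
    p <- pts %*% t(local_frame(xyz, i, nb)) * radii[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      buried <- buried | dj2 < radii[j]^2
      if (all(buried)) break
    }
    out[i] <- 4 * pi * radii[i]^2 * mean(!buried)
  }
  out
}

# rotation matrix whose columns are a right-handed frame anchored on the
# directions from atom i to its nearest neighbours
local_frame <- function(xyz, i, nb) {
  z <- xyz[nb[1], ] - xyz[i, ]
  z <- z / sqrt(sum(z^2))
  x <- NULL
  for (j in nb[-1]) {
    cand <- xyz[j, ] - xyz[i, ]
    cand <- cand - sum(cand * z) * z
    if (sum(cand^2) > 1e-12) {
      x <- cand / sqrt(sum(cand^2))
      break
    }
  }
  if (is.null(x)) {
    seedv <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    x <- seedv - sum(seedv * z) * z
    x <- x / sqrt(sum(x^2))
  }
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

#' Interface area between two binding partners
#'
#' Default method `"buried-sasa"`: per-atom buried area is the atom's SASA in
#' the isolated partner minus its SASA in the complex; the reported interface
#' area sums buried area over the partner-b (PDI-side) atoms and decomposes
#' it by region. Method `"voronoi-contact"` instead integrates, for every
#' cross-partner atom pair within `r_i + r_j + 2 * probe`, the area of the
#' shared facet of a radical-plane (power) tessellation clipped to the
#' accessible sphere, estimated on a polar grid.
#'
#' @inheritParams count_interface_atom_pairs
#' @param method `"buried-sasa"` or `"voronoi-contact"`.
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere sample points for the SASA method.
#' @return A tibble with columns `region`, `area` (Angstrom squared);
#'   attributes `total` and `method`. Class `iface_area`.
#' @export
interface_area <- function(structure, partner_a, partner_b,
                           method = c("buried-sasa", "voronoi-contact"),
                           region_map = NULL, probe = 1.4, n_points = 960) {
  method <- match.arg(method)
  structure <- as_structure(structure)
  a <- select_chain(structure, partner_a, "partner_a")
  b <- select_chain(structure, partner_b, "partner_b")
  if (method == "buried-sasa") {
    complex_ab <- as_structure(dplyr::bind_rows(a, b))
    sasa_complex <- sasa(complex_ab, probe = probe, n_points = n_points)
    sasa_b_alone <- sasa(b, probe = probe, n_points = n_points)
    buried_b <- pmax(sasa_b_alone - sasa_complex[(nrow(a) + 1):nrow(complex_ab)],
                     0)
    per_atom <- buried_b
  } else {
    per_atom <- power_facet_areas(a, b, probe = probe)
  }
  if (is.null(region_map)) {
    b_region <- rep("unassigned", nrow(b))
  } else {
    b_region <- assign_region(region_map, b$chain, b$resno)
  }
  out <- tibble(region = b_region, a = per_atom) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(area = sum(.data$a), .groups = "drop")
  attr(out, "total") <- sum(per_atom)
  attr(out, "method") <- method
  class(out) <- unique(c("iface_area", class(out)))
  out
}

# Shared radical-plane facet area between each partner-b atom and all
# partner-a atoms, clipped to b's accessible sphere, by polar-grid quadrature
# on the radical plane. Returns one value per partner-b atom.
power_facet_areas <- function(a, b, probe = 1.4, n_r = 24, n_theta = 48) {
  ra <- atom_radii(a$element) + probe
  rb <- atom_radii(b$element) + probe
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  all_xyz <- rbind(xa, xb)
  all_r <- c(ra, rb)
  d <- cross_dist(xa, xb)
  out <- numeric(nrow(b))
  pair_idx <- which(d <= outer(ra, rb, "+"), arr.ind = TRUE)
  if (nrow(pair_idx) == 0) return(out)
  for (row in seq_len(nrow(pair_idx))) {
    i <- pair_idx[row, 1]
    j <- pair_idx[row, 2]
    dij <- d[i, j]
    if (dij < 1e-9) next
    u <- (xb[j, ] - xa[i, ]) / dij
    # radical plane: signed distance t from atom i along u
    t <- (dij^2 + ra[i]^2 - rb[j]^2) / (2 * dij)
    rho2_max <- min(ra[i]^2 - t^2, rb[j]^2 - (dij - t)^2)
    if (rho2_max <= 0) next
    centre <- xa[i, ] + t * u
    # orthonormal basis of the plane
    e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * u) * u
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    rho_max <- sqrt(rho2_max)
    # midpoint polar grid; equal-area annuli
    r_edges <- rho_max * sqrt(seq(0, 1, length.out = n_r + 1))
    r_mid <- (r_edges[-1] + r_edges[-(n_r + 1)]) / 2
    cell_area <- diff(r_edges^2) * pi / n_theta
    th <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
    grid <- expand.grid(r = r_mid, th = th)
    px <- centre[1] + grid$r * (cos(grid$th) * e1[1] + sin(grid$th) * e2[1])
    py <- centre[2] + grid$r * (cos(grid$th) * e1[2] + sin(grid$th) * e2[2])
    pz <- centre[3] + grid$r * (cos(grid$th) * e1[3] + sin(grid$th) * e2[3])
    pow_ij <- (px - xa[i, 1])^2 + (py - xa[i, 2])^2 + (pz - xa[i, 3])^2 -
      ra[i]^2
    keep <- rep(TRUE, length(px))
    for (k in seq_len(nrow(all_xyz))) {
      if (k == i || k == nrow(xa) + j) next
      pow_k <- (px - all_xyz[k, 1])^2 + (py - all_xyz[k, 2])^2 +
        (pz - all_xyz[k, 3])^2 - all_r[k]^2
      keep <- keep & pow_ij <= pow_k
      if (!any(keep)) break
    }
    w <- rep(cell_area, times = n_theta)
    out[j] <- out[j] + sum(w[keep])
  }
  out
}
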