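# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the implementation.

oracle_atom_pairs <- function(structure, chain_a, chain_b, cutoff) {
  a <- structure[structure$chain %in% chain_a, ]
  b <- structure[structure$chain %in% chain_b, ]
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d <= cutoff) n <- n + 1L
    }
  }
  n
}

oracle_contact_keys <- function(structure, chain_a, chain_b, cutoff) {
  ca <- structure[structure$name == "CA" & structure$chain %in% chain_a, ]
  cb <- structure[structure$name == "CA" & structure$chain %in% chain_b, ]
  keys <- character(0)
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(cb))) {
      d <- sqrt((ca$x[i] - cb$x[j])^2 + (ca$y[i] - cb$y[j])^2 +
                  (ca$z[i] - cb$z[j])^2)
      if (d <= cutoff) {
        keys <- c(keys, paste(ca$chain[i], ca$resno[i],
                              cb$chain[j], cb$resno[j]))
      }
    }
  }
  sort(unique(keys))
}

oracle_trajectory_contact_keys <- function(trajectory, chain_a, chain_b,
                                           cutoff) {
  keys <- character(0)
  for (k in seq_len(n_frames(trajectory))) {
    fr <- trajectory_frame(trajectory, k)
    keys <- c(keys, oracle_contact_keys(fr, chain_a, chain_b, cutoff))
  }
  sort(unique(keys))
}

contact_set_keys <- function(cs) {
  sort(paste(cs$chain_a, cs$resno_a, cs$chain_b, cs$resno_b))
}

# analytic buried area of one of two equal spheres of accessible radius R at
# centre distance d: the spherical cap cut off by the half-distance plane
two_sphere_cap_area <- function(R, d) 2 * pi * R * (R - d / 2)

rotate_structure <- function(s, angles, shift = c(0, 0, 0)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  M <- Rz %*% Ry %*% Rx
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(M)
  s$x <- xyz[, 1] + shift[1]
  s$y <- xyz[, 2] + shift[2]
  s$z <- xyz[, 3] + shift[3]
  s
}

# minimal hand-built two-chain structure at controlled separation
two_atom_structure <- function(d, name = "CA") {
  as_structure(tibble::tibble(
    serial = 1:2, name = name, element = "C", resno = c(1L, 2L),
    resid = "GLY", chain = c("A", "B"), x = c(0, d), y = 0, z = 0
  ))
}

kBT300 <- 0.0019872041 * 300
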