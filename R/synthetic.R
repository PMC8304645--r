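#' Synthetic two-chain complex with a controllable interface
#'
#' Builds a toy heterodimer: chain-a C-alpha atoms on a jittered cubic
#' lattice, chain-b residues either designed into contact (placed at a
#' C-alpha distance drawn uniformly from 3.8-6.8 Angstrom of a chain-a
#' residue) or placed across an inter-chain gap. Each residue also carries a
#' dummy sidechain atom so atom-pair counting and surface-area methods can be
#' exercised on the same fixture. The exact inter-chain C-alpha <= `cutoff`
#' pair set is returned alongside as ground truth (computed by direct
#' enumeration at build time).
#'
#' @param n_a,n_b Residues per chain.
#' @param gap Inter-chain gap for non-contact residues, Angstrom.
#' @param contact_fraction Fraction of chain-b residues designed into
#'   contact.
#' @param chain_a,chain_b Chain identifiers.
#' @param resno_start_a,resno_start_b First author residue number per chain;
#'   defaults put chain a in the MTP-alpha lipid-binding domain numbering and
#'   chain b in the PDI b' domain numbering.
#' @param cutoff Ground-truth contact cutoff, Angstrom. Default 7.
#' @param seed Random seed; the seed fully determines the output.
#' @return A list: `structure` (an `iface_structure`) and `contacts`
#'   (ground-truth `iface_contact_set`).
#' @export
make_toy_complex <- function(n_a = 10, n_b = 10, gap = 30,
                             contact_fraction = 0.3,
                             chain_a = "A", chain_b = "B",
                             resno_start_a = 604L, resno_start_b = 235L,
                             cutoff = 7, seed = 1) {
  if (contact_fraction < 0 || contact_fraction > 1) {
    abort("contact_fraction must be in [0, 1]")
  }
  set.seed(seed)
  # chain a: jittered lattice, ~6 A spacing so neighbours stay resolvable
  side <- ceiling(n_a^(1 / 3))
  grid <- expand.grid(ix = seq_len(side), iy = seq_len(side),
                      iz = seq_len(side))[seq_len(n_a), ]
  xa <- as.matrix(grid) * 6 + matrix(runif(3 * n_a, -0.8, 0.8), ncol = 3)
  n_contact <- round(contact_fraction * n_b)
  xb <- matrix(NA_real_, n_b, 3)
  for (i in seq_len(n_b)) {
    if (i <= n_contact) {
      anchor <- xa[1 + (i - 1) %% n_a, ]
      repeat {
        dirv <- rnorm(3)
        dirv <- dirv / sqrt(sum(dirv^2))
        cand <- anchor + dirv * runif(1, 3.8, 6.8)
        # keep the designed partner the nearest chain-a residue
        if (min(sqrt(rowSums(sweep(xa, 2, cand)^2))) >= 3.5) break
      }
      xb[i, ] <- cand
    } else {
      xb[i, ] <- c(max(xa[, 1]) + gap + runif(1, 0, 6) + 6 * (i - n_contact),
                   runif(1, 0, 12), runif(1, 0, 12))
    }
  }
  mk_chain <- function(xyz, chain, resno0, serial0) {
    n <- nrow(xyz)
    side_off <- matrix(rnorm(3 * n), ncol = 3)
    side_off <- side_off / sqrt(rowSums(side_off^2)) * 1.53
    dplyr::bind_rows(
      tibble(serial = serial0 + 2 * seq_len(n) - 2L, name = "CA",
             element = "C", resno = resno0 + seq_len(n) - 1L, resid = "ALA",
             chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
      tibble(serial = serial0 + 2 * seq_len(n) - 1L, name = "CB",
             element = "C", resno = resno0 + seq_len(n) - 1L, resid = "ALA",
             chain = chain, x = xyz[, 1] + side_off[, 1],
             y = xyz[, 2] + side_off[, 2], z = xyz[, 3] + side_off[, 3])
    ) |>
      dplyr::arrange(.data$serial)
  }
  s <- as_structure(dplyr::bind_rows(
    mk_chain(xa, chain_a, as.integer(resno_start_a), 1L),
    mk_chain(xb, chain_b, as.integer(resno_start_b), 2L * n_a + 1L)
  ))
  # ground truth by direct enumeration over all inter-chain CA pairs
  truth <- list()
  for (i in seq_len(n_a)) {
    for (j in seq_len(n_b)) {
      if (sqrt(sum((xa[i, ] - xb[j, ])^2)) <= cutoff) {
        truth[[length(truth) + 1]] <- tibble(
          chain_a = chain_a, resno_a = as.integer(resno_start_a) + i - 1L,
          chain_b = chain_b, resno_b = as.integer(resno_start_b) + j - 1L)
      }
    }
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble(chain_a = character(), resno_a = integer(),
           chain_b = character(), resno_b = integer())
  truth$region <- "other"
  list(structure = s, contacts = new_contact_set(truth, "single-structure"))
}

#' Synthetic trajectory with prescribed distance fluctuations
#'
#' Starting from a base structure, designated inter-chain contacts fluctuate:
#' in every frame the chain-b residue of each designated contact is displaced
#' rigidly along the initial contact axis so that the C-alpha distance becomes
#' `d0 + delta_k`, with `delta_k` i.i.d. Gaussian of standard deviation
#' `sigma` (`model = "iid-gaussian"`) or `amplitude * sin(2 pi k / period)`
#' (`model = "sinusoidal"`). All other atoms stay fixed, so each designated
#' contact's distance variance is known in closed form: `sigma^2`, or
#' `amplitude^2 / 2` over whole periods.
#'
#' Each chain-b residue may appear in at most one designated contact.
#'
#' @param structure Base structure (e.g. from [make_toy_complex()]).
#' @param contacts Data frame of designated contacts (`chain_a`, `resno_a`,
#'   `chain_b`, `resno_b`).
#' @param n_frames Number of frames (>= 2).
#' @param model `"iid-gaussian"` or `"sinusoidal"`.
#' @param sigma Target distance standard deviation, Angstrom.
#' @param amplitude,period Sinusoid amplitude (Angstrom) and period (frames).
#' @param seed Random seed.
#' @return A list: `trajectory` (an `iface_trajectory`) and `ground_truth`, a
#'   tibble with the designated contacts and their exact target MSFD.
#' @export
make_fluctuation_trajectory <- function(structure, contacts, n_frames = 1000,
                                        model = c("iid-gaussian",
                                                  "sinusoidal"),
                                        sigma = 1, amplitude = 2,
                                        period = NULL, seed = 1) {
  model <- match.arg(model)
  if (n_frames < 2) abort("need at least 2 frames")
  if (sigma < 0) abort("sigma must be non-negative")
  contacts <- as_tibble(contacts)
  # one displacement law per chain-b residue: when a residue appears in
  # several designated contacts, the first contact defines its motion axis
  # and carries the exact target MSFD
  contacts <- contacts[!duplicated(paste(contacts$chain_b,
                                         contacts$resno_b)), ]
  set.seed(seed)
  s <- as_structure(structure)
  na <- nrow(s)
  coords0 <- as.matrix(s[, c("x", "y", "z")])
  coords <- array(rep(coords0, n_frames), dim = c(na, 3, n_frames))
  if (is.null(period)) period <- n_frames
  truth <- contacts
  truth$target_msfd <- NA_real_
  for (ci in seq_len(nrow(contacts))) {
    ia <- which(s$chain == contacts$chain_a[ci] &
                  s$resno == contacts$resno_a[ci] & s$name == "CA")[1]
    moved <- which(s$chain == contacts$chain_b[ci] &
                     s$resno == contacts$resno_b[ci])
    ib <- moved[s$name[moved] == "CA"][1]
    if (is.na(ia) || is.na(ib)) abort("designated contact lacks CA atoms")
    axis <- coords0[ib, ] - coords0[ia, ]
    d0 <- sqrt(sum(axis^2))
    axis <- axis / d0
    delta <- switch(model,
      "iid-gaussian" = rnorm(n_frames, 0, sigma),
      "sinusoidal" = amplitude * sin(2 * pi * seq_len(n_frames) / period)
    )
    for (m in moved) {
      coords[m, 1, ] <- coords0[m, 1] + delta * axis[1]
      coords[m, 2, ] <- coords0[m, 2] + delta * axis[2]
      coords[m, 3, ] <- coords0[m, 3] + delta * axis[3]
    }
    truth$target_msfd[ci] <- switch(model,
      "iid-gaussian" = sigma^2,
      "sinusoidal" = amplitude^2 / 2
    )
  }
  list(trajectory = trajectory(s, coords), ground_truth = truth)
}

#' Brownian steered-pulling ensemble with closed-form free energy
#'
#' Overdamped Langevin dynamics of a single coordinate pulled by a moving
#' harmonic trap — the same mathematical object a steered-MD work analysis
#' consumes, at one-dimensional desk scale. The Euler-Maruyama step is
#' `x <- x + (dt / gamma) * (-U'(x) + F_trap) + sqrt(2 kB T dt / gamma) * xi`.
#' The potential is `"flat"` (U = 0; exact free-energy change 0) or
#' `"harmonic"` (`U = kappa x^2 / 2`; exact free-energy change
#' `kappa k lambda^2 / (2 (kappa + k))` for trap stiffness k). Work is
#' accumulated analytically per step as `F * v * dt` at full resolution and
#' stored on a thinned save grid.
#'
#' @param protocol An [pulling_protocol()].
#' @param potential `"flat"` or `"harmonic"`.
#' @param kappa Harmonic well stiffness, kcal/mol/Angstrom^2.
#' @param gamma Friction, kcal mol^-1 ns Angstrom^-2. Default 0.1.
#' @param dt Integration step, ns. Must satisfy the stability guard
#'   `(k + kappa) * dt / gamma < 0.1`.
#' @param n_replicas Number of independent replicas.
#' @param save_every Store every `save_every`-th step.
#' @param seed Random seed; the seed fully determines the ensemble.
#' @return A list of class `iface_ensemble`: `times` (ns), matrices
#'   `position`, `force`, `work` (`n_times x n_replicas`), the `protocol`,
#'   and `ground_truth`, a function of lambda returning the exact free-energy
#'   change.
#' @export
simulate_brownian_pull <- function(protocol = pulling_protocol(),
                                   potential = c("flat", "harmonic"),
                                   kappa = 1, gamma = 0.1, dt = 1e-5,
                                   n_replicas = 10, save_every = NULL,
                                   seed = 1) {
  potential <- match.arg(potential)
  k <- protocol$k
  v <- protocol$v
  temperature <- protocol$temperature
  stiff <- k + if (potential == "harmonic") kappa else 0
  if (stiff * dt / gamma >= 0.1) {
    abort("unstable step: (k + kappa) * dt / gamma must be < 0.1")
  }
  set.seed(seed)
  n_steps <- round(protocol$duration / dt)
  if (is.null(save_every)) save_every <- max(1L, floor(n_steps / 200))
  noise_sd <- sqrt(2 * KB_KCAL_MOL_K * temperature * dt / gamma)
  x <- numeric(n_replicas) # start at the trap centre (x0 = 0)
  w <- numeric(n_replicas)
  save_idx <- seq(0, n_steps, by = save_every)
  n_save <- length(save_idx)
  pos <- frc <- wrk <- matrix(NA_real_, n_save, n_replicas)
  pos[1, ] <- x
  frc[1, ] <- k * (0 - x)
  wrk[1, ] <- 0
  si <- 2
  for (step in seq_len(n_steps)) {
    trap_centre <- v * (step - 1) * dt
    f_trap <- k * (trap_centre - x)
    f_pot <- if (potential == "harmonic") -kappa * x else 0
    # work increment of the moving trap over this step (trap moves v*dt)
    w <- w + f_trap * v * dt
    x <- x + (dt / gamma) * (f_pot + f_trap) + noise_sd * rnorm(n_replicas)
    if (si <= n_save && step == save_idx[si]) {
      t_now <- step * dt
      pos[si, ] <- x
      frc[si, ] <- k * (v * t_now - x)
      wrk[si, ] <- w
      si <- si + 1
    }
  }
  gt <- if (potential == "flat") {
    function(lambda) rep(0, length(lambda))
  } else {
    function(lambda) kappa * k * lambda^2 / (2 * (kappa + k))
  }
  structure(
    list(times = save_idx * dt, position = pos, force = frc, work = wrk,
         protocol = protocol, potential = potential,
         kappa = if (potential == "harmonic") kappa else NA_real_,
         gamma = gamma, dt = dt, seed = seed, ground_truth = gt),
    class = "iface_ensemble"
  )
}

#' @export
print.iface_ensemble <- function(x, ...) {
  cat(sprintf(
    "<iface_ensemble> %d replicas x %d stored points (%s potential, v = %g A/ns)\n",
    ncol(x$work), length(x$times), x$potential, x$protocol$v))
  invisible(x)
}

#' @method tidy iface_ensemble
#' @export
tidy.iface_ensemble <- function(x, ...) {
  nrep <- ncol(x$work)
  nt <- length(x$times)
  tibble(
    replica = rep(seq_len(nrep), each = nt),
    time_ns = rep(x$times, nrep),
    position_A = as.vector(x$position),
    force_kcal_mol_A = as.vector(x$force),
    work_kcal_mol = as.vector(x$work)
  )
}
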