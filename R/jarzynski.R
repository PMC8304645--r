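log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Jarzynski free-energy estimate from a work sample
#'
#' Estimates the free-energy difference at one value of the pulling
#' coordinate from replicate nonequilibrium work values, via Jarzynski's
#' equality `exp(-beta dF) = <exp(-beta W)>`. Two estimators:
#' `"cumulant2"`, the second-order cumulant expansion
#' `mean(W) - beta * popvar(W) / 2` (population variance, divisor N), and
#' `"exponential"`, the direct exponential average evaluated with a
#' numerically safe log-sum-exp.
#'
#' @param works Numeric vector of work values, kcal/mol (length >= 2).
#' @param temperature Temperature, K. Default 300.
#' @param method `"cumulant2"` (headline estimator) or `"exponential"`.
#' @return Free-energy estimate, kcal/mol.
#' @export
jarzynski_delta_f <- function(works, temperature = 300,
                              method = c("cumulant2", "exponential")) {
  method <- match.arg(method)
  n <- length(works)
  if (n < 2) abort("need at least 2 work values")
  if (n < 10) {
    warn(sprintf(
      "only %d replicas; nonequilibrium work averaging calls for at least 10",
      n))
  }
  beta <- 1 / (KB_KCAL_MOL_K * temperature)
  if (method == "cumulant2") {
    mean(works) - beta * mean((works - mean(works))^2) / 2
  } else {
    -log_mean_exp(-beta * works) / beta
  }
}

#' Potential of mean force from a replica ensemble
#'
#' At every stored time point, the pulled distance is `lambda = v * t` and the
#' free energy is estimated from the replicas' accumulated work with
#' [jarzynski_delta_f()]; both the cumulant and the direct exponential
#' estimators are reported, together with the work mean and population
#' variance.
#'
#' @param ensemble A replica ensemble as returned by
#'   [simulate_brownian_pull()], or any list with elements `times` (length m),
#'   `work` (m x n_replicas matrix) and `protocol`.
#' @param lambda_max Optional truncation of the pulled distance, Angstrom
#'   (analysis of the early, more reliable pulling window).
#' @return A tibble of class `iface_pmf` with columns `lambda_A`,
#'   `dF_cumulant`, `dF_exponential`, `mean_W`, `var_W`, `n_replicas`;
#'   attribute `temperature`.
#' @export
pmf_curve <- function(ensemble, lambda_max = NULL) {
  times <- ensemble$times
  W <- ensemble$work
  prot <- ensemble$protocol
  if (is.null(dim(W))) W <- matrix(W, ncol = 1)
  if (nrow(W) != length(times)) {
    abort("work matrix and time grid do not match")
  }
  nrep <- ncol(W)
  if (nrep > 1 && nrep < 10) {
    warn(sprintf(
      "only %d replicas; nonequilibrium work averaging calls for at least 10",
      nrep))
  }
  beta <- 1 / (KB_KCAL_MOL_K * prot$temperature)
  lambda <- prot$v * times
  keep <- if (is.null(lambda_max)) rep(TRUE, length(lambda)) else
    lambda <= lambda_max + 1e-12
  lambda <- lambda[keep]
  W <- W[keep, , drop = FALSE]
  mean_w <- rowMeans(W)
  var_w <- rowMeans((W - mean_w)^2)
  d_cum <- mean_w - beta * var_w / 2
  d_exp <- vapply(seq_len(nrow(W)), function(i) {
    -log_mean_exp(-beta * W[i, ]) / beta
  }, numeric(1))
  out <- tibble(
    lambda_A = lambda, dF_cumulant = d_cum, dF_exponential = d_exp,
    mean_W = mean_w, var_W = var_w, n_replicas = nrep
  )
  attr(out, "temperature") <- prot$temperature
  class(out) <- unique(c("iface_pmf", class(out)))
  out
}

#' @method tidy iface_pmf
#' @export
tidy.iface_pmf <- function(x, ...) as_tibble(x)

#' @method glance iface_pmf
#' @export
glance.iface_pmf <- function(x, ...) {
  tibble(
    lambda_max_A = max(x$lambda_A),
    dF_final = x$dF_cumulant[which.max(x$lambda_A)],
    mean_W_final = x$mean_W[which.max(x$lambda_A)],
    n_replicas = x$n_replicas[1],
    temperature = attr(x, "temperature") %||% NA_real_
  )
}

#' Averaged force-distance profile across pulling replicas
#'
#' Per replica, the reported distance at time t is the Euclidean displacement
#' of the midpoint of two marker C-alpha atoms (residues 595 and 591 of the
#' pulled subunit in the standard setup) from its position at t = 0; the
#' profile is the per-time-point mean of distances and of trap forces across
#' replicas. Set `projection = TRUE` to report instead the displacement
#' projected on the pull direction.
#'
#' @param ensemble A replica ensemble (list with `times`, `force` matrix,
#'   `protocol`).
#' @param trajectories A list of `iface_trajectory`, one per replica, frames
#'   aligned with the ensemble time grid.
#' @param chain Chain of the marker residues.
#' @param markers Length-2 integer vector of marker residue numbers.
#' @param projection Report projected displacement instead of its magnitude.
#' @return A tibble with `time_ns`, `distance_A`, `force_kcal_mol_A`.
#' @export
force_distance_profile <- function(ensemble, trajectories, chain = "A",
                                   markers = c(595L, 591L),
                                   projection = FALSE) {
  times <- ensemble$times
  forces <- ensemble$force
  if (is.null(dim(forces))) forces <- matrix(forces, ncol = 1)
  nrep <- ncol(forces)
  if (length(trajectories) != nrep) {
    abort("need one trajectory per replica")
  }
  dists <- vapply(seq_len(nrep), function(r) {
    tr <- trajectories[[r]]
    if (n_frames(tr) != length(times)) {
      abort(sprintf("replica %d trajectory has %d frames, grid has %d",
                    r, n_frames(tr), length(times)))
    }
    mid <- marker_midpoint(tr, chain, markers)
    disp <- sweep(mid, 2, mid[1, ], "-")
    if (projection) {
      as.vector(disp %*% ensemble$protocol$direction)
    } else {
      sqrt(rowSums(disp^2))
    }
  }, numeric(length(times)))
  dists <- matrix(dists, nrow = length(times))
  tibble(
    time_ns = times,
    distance_A = rowMeans(dists),
    force_kcal_mol_A = rowMeans(forces)
  )
}

# nframes x 3 midpoint track of the two marker CA atoms
marker_midpoint <- function(trajectory, chain, markers) {
  roster <- trajectory$roster
  i1 <- which(roster$chain == chain & roster$resno == markers[1] &
                roster$name == "CA")
  i2 <- which(roster$chain == chain & roster$resno == markers[2] &
                roster$name == "CA")
  if (length(i1) == 0 || length(i2) == 0) {
    abort("marker residue CA atoms missing from the roster")
  }
  m1 <- t(matrix(trajectory$coords[i1[1], , ], nrow = 3))
  m2 <- t(matrix(trajectory$coords[i2[1], , ], nrow = 3))
  (m1 + m2) / 2
}
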