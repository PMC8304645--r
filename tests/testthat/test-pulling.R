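test_that("trap force follows the moving-trap law", {
  p <- pulling_protocol(v = 10, k = 10)
  expect_equal(trap_force(p, t = 0, x = 0, x0 = 0), 0)
  expect_equal(trap_force(p, t = 0.1, x = 0, x0 = 0), 10) # trap 1 A ahead
  expect_equal(trap_force(p, t = 0.37, x = 10 * 0.37, x0 = 0), 0)
  expect_error(trap_force(p, t = -1, x = 0), "non-negative")
})

test_that("protocol validates and normalises its direction", {
  p <- pulling_protocol(direction = c(3, 4, 0))
  expect_equal(sqrt(sum(p$direction^2)), 1, tolerance = 1e-9)
  expect_error(pulling_protocol(v = -1), "positive")
  expect_error(pulling_protocol(direction = c(0, 0, 0)), "non-zero")
})

test_that("work accumulation integrates F * v over the trap displacement", {
  # constant force: W = F0 * d
  t <- seq(0, 1, by = 0.01)
  w <- accumulate_work(t, rep(2.5, length(t)), v = 10)
  expect_equal(tail(w, 1), 2.5 * 10)
  expect_equal(w[1], 0)
  # linear ramp 0 -> F1: W = F1 * d / 2
  w2 <- accumulate_work(t, 8 * t, v = 10)
  expect_equal(tail(w2, 1), 8 * 10 / 2, tolerance = 1e-12)
  expect_error(accumulate_work(c(0, 1, 1), rep(1, 3), 1), "increasing")
})

test_that("trapezoid work matches fine-grained quadrature on a rough force", {
  set.seed(12)
  t <- seq(0, 2, length.out = 4001)
  f_fun <- function(tt) 3 + 2 * sin(5 * tt) + 0.5 * cos(17 * tt)
  w <- accumulate_work(t, f_fun(t), v = 10)
  oracle <- vapply(t, function(tn) {
    if (tn == 0) return(0)
    ts <- seq(0, tn, length.out = 2001)
    sum((f_fun(ts)[-1] + f_fun(ts)[-length(ts)]) / 2 * diff(ts)) * 10
  }, numeric(1))
  expect_equal(w, oracle, tolerance = 1e-6)
})

test_that("work accumulation is additive over interval concatenation", {
  set.seed(3)
  t <- sort(runif(50, 0, 2))
  f <- rnorm(50, 5, 1)
  whole <- accumulate_work(t, f, v = 10)
  w1 <- accumulate_work(t[1:25], f[1:25], v = 10)
  w2 <- accumulate_work(t[25:50], f[25:50], v = 10)
  expect_equal(tail(whole, 1), tail(w1, 1) + tail(w2, 1), tolerance = 1e-10)
})

test_that("pulling record CSV round-trips and recomputes absent work", {
  en <- simulate_brownian_pull(
    pulling_protocol(v = 10, duration = 0.05), potential = "flat",
    n_replicas = 3, dt = 1e-4, save_every = 10, seed = 2)
  rec <- tidy(en)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pulling_records(rec, f)
  back <- read_pulling_records(f)
  expect_equal(back$work_kcal_mol, rec$work_kcal_mol, tolerance = 1e-9)
  # drop the work column: recomputation needs v and reproduces the trapezoid
  write_pulling_records(rec[, -5], f)
  expect_error(read_pulling_records(f), "supply v")
  back2 <- read_pulling_records(f, v = 10)
  recomputed <- accumulate_work(rec$time_ns[rec$replica == 1],
                                rec$force_kcal_mol_A[rec$replica == 1], 10)
  expect_equal(back2$work_kcal_mol[back2$replica == 1], recomputed)
})

test_that("spring networks connect CA pairs at or below the cutoff", {
  s <- as_structure(tibble::tibble(
    serial = 1:3, name = "CA", element = "C", resno = 1:3, resid = "GLY",
    chain = "A", x = c(0, 5, 11), y = 0, z = 0
  ))
  net <- build_spring_network(s, "A", cutoff = 7)
  expect_equal(nrow(net), 2) # 0-5 and 5-11; 0-11 excluded
  expect_equal(sort(net$rest_length), c(5, 6))
  # inclusive boundary at exactly 7
  s7 <- as_structure(tibble::tibble(
    serial = 1:2, name = "CA", element = "C", resno = 1:2, resid = "GLY",
    chain = "A", x = c(0, 7), y = 0, z = 0
  ))
  expect_equal(nrow(build_spring_network(s7, "A")), 1)
  expect_error(build_spring_network(s7[1, ], "A"), "at least 2")
})

test_that("spring networks match brute-force pair enumeration", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 50
    s <- as_structure(tibble::tibble(
      serial = seq_len(n), name = "CA", element = "C", resno = seq_len(n),
      resid = "GLY", chain = "A",
      x = runif(n, 0, 25), y = runif(n, 0, 25), z = runif(n, 0, 25)
    ))
    net <- build_spring_network(s, "A", cutoff = 7)
    want <- 0L
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 +
                    (s$z[i] - s$z[j])^2)
        if (d <= 7) want <- want + 1L
      }
    }
    expect_equal(nrow(net), want)
  }
})

test_that("marker-midpoint distances track rigid translation", {
  n <- 4
  r <- as_structure(tibble::tibble(
    serial = 1:n, name = "CA", element = "C",
    resno = c(591L, 595L, 600L, 610L), resid = "GLY", chain = "A",
    x = c(0, 4, 8, 12), y = 0, z = 0
  ))
  nf <- 5
  shifts <- seq(0, 2, length.out = nf)
  coords <- array(0, dim = c(n, 3, nf))
  for (k in seq_len(nf)) {
    fr <- as.matrix(r[, c("x", "y", "z")])
    fr[, 2] <- fr[, 2] + shifts[k] # translate whole chain along y
    coords[, , k] <- fr
  }
  tr <- trajectory(r, coords)
  ens <- list(times = seq(0, 0.4, length.out = nf),
              force = matrix(1, nf, 1),
              protocol = pulling_protocol(v = 5))
  prof <- force_distance_profile(ens, list(tr), chain = "A",
                                 markers = c(595L, 591L))
  expect_equal(prof$distance_A, abs(shifts))
  # static trajectory: distance identically zero
  tr0 <- trajectory(r, array(rep(as.matrix(r[, c("x", "y", "z")]), nf),
                             dim = c(n, 3, nf)))
  prof0 <- force_distance_profile(ens, list(tr0))
  expect_equal(prof0$distance_A, rep(0, nf))
})

test_that("the averaged profile equals the hand-built replica mean", {
  n <- 2
  r <- as_structure(tibble::tibble(
    serial = 1:2, name = "CA", element = "C", resno = c(591L, 595L),
    resid = "GLY", chain = "A", x = c(0, 4), y = 0, z = 0
  ))
  nf <- 4
  laws <- list(function(t) t, function(t) 2 * t, function(t) t^2)
  times <- seq(0, 3, length.out = nf)
  trs <- lapply(laws, function(fn) {
    coords <- array(0, dim = c(n, 3, nf))
    for (k in seq_len(nf)) {
      fr <- as.matrix(r[, c("x", "y", "z")])
      fr[, 1] <- fr[, 1] + fn(times[k])
      coords[, , k] <- fr
    }
    trajectory(r, coords)
  })
  forces <- cbind(rep(1, nf), rep(2, nf), rep(3, nf))
  ens <- list(times = times, force = forces,
              protocol = pulling_protocol(v = 1))
  prof <- force_distance_profile(ens, trs)
  want_d <- rowMeans(cbind(times, 2 * times, times^2))
  expect_equal(prof$distance_A, want_d)
  expect_equal(prof$force_kcal_mol_A, rep(2, nf))
})
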