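test_that("MSFD follows the population-variance formula", {
  expect_equal(msfd(c(1, 2, 3)), 2 / 3) # mean 2, deviations 1, 0, 1
  expect_equal(msfd(rep(4.2, 10)), 0)
  expect_error(msfd(5), "at least 2")
})

test_that("distance_series returns per-frame CA distances", {
  r <- two_atom_structure(5)
  coords <- array(0, dim = c(2, 3, 2))
  coords[, , 1] <- rbind(c(0, 0, 0), c(3, 4, 0))
  coords[, , 2] <- rbind(c(0, 0, 0), c(6, 8, 0))
  tr <- trajectory(r, coords)
  expect_equal(distance_series(tr, "A", 1, "B", 2), c(5, 10))
  expect_error(distance_series(tr, "A", 99, "B", 2), "missing CA")
})

test_that("MSFD is invariant under per-frame rigid-body motion", {
  tc <- make_toy_complex(n_a = 5, n_b = 5, contact_fraction = 0.4, seed = 2)
  fl <- make_fluctuation_trajectory(tc$structure, tc$contacts,
                                    n_frames = 50, sigma = 1, seed = 3)
  base <- msfd_table(fl$trajectory, tc$contacts)$msfd
  moved <- fl$trajectory
  set.seed(99)
  for (k in seq_len(n_frames(moved))) {
    fr <- rotate_structure(trajectory_frame(moved, k),
                           runif(3, 0, 2 * pi), runif(3, -30, 30))
    moved$coords[, , k] <- as.matrix(fr[, c("x", "y", "z")])
  }
  expect_equal(msfd_table(moved, tc$contacts)$msfd, base, tolerance = 1e-9)
})

test_that("MSFD scales as the square of a coordinate scaling", {
  tc <- make_toy_complex(n_a = 5, n_b = 5, contact_fraction = 0.4, seed = 6)
  fl <- make_fluctuation_trajectory(tc$structure, tc$contacts,
                                    n_frames = 40, sigma = 1, seed = 7)
  base <- msfd_table(fl$trajectory, tc$contacts)$msfd
  scaled <- fl$trajectory
  scaled$coords <- scaled$coords * 2.5
  expect_equal(msfd_table(scaled, tc$contacts)$msfd, base * 2.5^2,
               tolerance = 1e-9)
})

test_that("sinusoidal fluctuations converge to A^2/2 over whole periods", {
  tc <- make_toy_complex(n_a = 3, n_b = 3, contact_fraction = 0.4, seed = 1)
  fl <- make_fluctuation_trajectory(tc$structure, tc$contacts[1, ],
                                    n_frames = 1e4, model = "sinusoidal",
                                    amplitude = 2, period = 100, seed = 1)
  got <- msfd_table(fl$trajectory, tc$contacts[1, ])$msfd[1]
  expect_equal(got, 2, tolerance = 0.01)
})

test_that("iid Gaussian fluctuations recover sigma^2", {
  tc <- make_toy_complex(n_a = 3, n_b = 3, contact_fraction = 0.4, seed = 1)
  n_frames <- 4000
  got <- vapply(1:5, function(seed) {
    fl <- make_fluctuation_trajectory(tc$structure, tc$contacts[1, ],
                                      n_frames = n_frames, sigma = 1.5,
                                      seed = seed)
    msfd_table(fl$trajectory, tc$contacts[1, ])$msfd[1]
  }, numeric(1))
  # mean over seeded replicates within 3 SE of the target variance
  se <- 1.5^2 * sqrt(2 / n_frames) / sqrt(length(got))
  expect_lt(abs(mean(got) - 2.25), 3 * se)
})

test_that("the tail exclusion needs both a tail residue and a large MSFD", {
  mk_tables <- function(msfds_by_table, resno_a) {
    lapply(msfds_by_table, function(v) {
      tibble::tibble(chain_a = "A", resno_a = resno_a, chain_b = "B",
                     resno_b = seq_along(v), region = "region1", msfd = v)
    })
  }
  # contact with MSFDs 2,3,15,4 across four conditions, residue in the tail
  tabs <- lapply(c(2, 3, 15, 4), function(m) {
    tibble::tibble(chain_a = "A", resno_a = c(890L, 700L), chain_b = "B",
                   resno_b = c(1L, 2L), region = "region1",
                   msfd = c(m, 20))
  })
  res <- apply_cterm_exclusion(tabs, tail = c(886L, 894L), threshold = 14)
  expect_equal(res$excluded$resno_a, 890L)   # tail + spike -> excluded
  expect_equal(res$kept$resno_a, 700L)       # large MSFD outside tail -> kept
  # boundary: threshold is strict
  tabs14 <- mk_tables(list(c(14, 14)), c(890L, 891L))
  res14 <- apply_cterm_exclusion(tabs14, threshold = 14)
  expect_equal(nrow(res14$excluded), 0)
})

test_that("exclusion partition matches direct predicate evaluation", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30
    resno_a <- sample(600:894, n)
    base <- tibble::tibble(chain_a = "A", resno_a = resno_a, chain_b = "B",
                           resno_b = seq_len(n), region = "region1")
    tabs <- lapply(1:4, function(i) {
      dplyr::mutate(base, msfd = runif(n, 0, 20))
    })
    res <- apply_cterm_exclusion(tabs, tail = c(886L, 894L), threshold = 14)
    msfd_mat <- sapply(tabs, function(t) t$msfd)
    want_excl <- resno_a >= 886 & resno_a <= 894 &
      apply(msfd_mat > 14, 1, any)
    expect_equal(sort(res$excluded$resno_b), sort(base$resno_b[want_excl]))
    expect_equal(nrow(res$kept) + nrow(res$excluded), n)
  }
})

test_that("condition comparison counts strict exceedances beyond the margin", {
  base <- tibble::tibble(chain_a = "A", resno_a = 1:3, chain_b = "B",
                         resno_b = 1:3, region = "region1")
  a <- dplyr::mutate(base, msfd = c(3.5, 1.5, 1.0))
  b <- dplyr::mutate(base, msfd = c(2.0, 2.0, 3.0))
  # deltas +1.5, -0.5, -2.0 at margin 1 -> one each way
  cc <- compare_conditions(a, b, margin = 1)
  expect_equal(cc$n_a_higher, 1)
  expect_equal(cc$n_b_higher, 1)
  # identical tables compare as (0, 0)
  cc0 <- compare_conditions(a, a)
  expect_equal(c(cc0$n_a_higher, cc0$n_b_higher), c(0, 0))
  # boundary delta of exactly the margin falls in the neutral band
  a1 <- dplyr::mutate(base, msfd = c(3.0, 1, 1))
  b1 <- dplyr::mutate(base, msfd = c(2.0, 1, 1))
  cc1 <- compare_conditions(a1, b1, margin = 1)
  expect_equal(c(cc1$n_a_higher, cc1$n_b_higher), c(0, 0))
  expect_error(compare_conditions(a, dplyr::mutate(b, resno_b = 4:6)),
               "universe")
})

test_that("comparison counts match a brute-force oracle and swap on swap", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- 93
    base <- tibble::tibble(chain_a = "A", resno_a = seq_len(n), chain_b = "B",
                           resno_b = seq_len(n), region = "region1")
    a <- dplyr::mutate(base, msfd = runif(n, 0, 8))
    b <- dplyr::mutate(base, msfd = runif(n, 0, 8))
    cc <- compare_conditions(a, b, margin = 1)
    expect_equal(cc$n_a_higher, sum(a$msfd - b$msfd > 1))
    expect_equal(cc$n_b_higher, sum(b$msfd - a$msfd > 1))
    sw <- compare_conditions(b, a, margin = 1)
    expect_equal(c(sw$n_a_higher, sw$n_b_higher),
                 c(cc$n_b_higher, cc$n_a_higher))
  }
})

test_that("region averages are member means and all_four pools contacts", {
  t <- tibble::tibble(
    chain_a = "A", resno_a = 1:5, chain_b = "B", resno_b = 1:5,
    region = c("region1", "region1", "region2", "region3_prime", "other"),
    msfd = c(1, 3, 5, 7, 100)
  )
  ra <- region_average_msfd(t)
  get <- function(r) ra$mean_msfd[ra$region == r]
  expect_equal(get("region1"), 2)
  expect_equal(get("region2"), 5)
  expect_equal(get("all_four"), mean(c(1, 3, 5, 7))) # 'other' not pooled
  expect_false("region_absent" %in% ra$region)
  # mean-of-means alternative
  ra2 <- region_average_msfd(t, pooled = FALSE)
  expect_equal(ra2$mean_msfd[ra2$region == "all_four"], mean(c(2, 5, 7)))
  # all contacts in one region: all_four equals that region's average
  t1 <- dplyr::mutate(t, region = "region2")
  ra1 <- region_average_msfd(t1)
  expect_equal(ra1$mean_msfd[ra1$region == "all_four"],
               ra1$mean_msfd[ra1$region == "region2"])
  # averages lie within member range
  expect_true(all(ra$mean_msfd >= min(t$msfd) & ra$mean_msfd <= max(t$msfd)))
})

test_that("constructed region means are recovered exactly", {
  t <- tibble::tibble(
    chain_a = "A", resno_a = 1:6, chain_b = "B", resno_b = 1:6,
    region = rep(c("region1", "region2", "region3"), each = 2),
    msfd = c(1.25, 1.75, 2.5, 3.5, 4, 6)
  )
  ra <- region_average_msfd(t)
  expect_equal(ra$mean_msfd[ra$region == "region1"], 1.5, tolerance = 1e-12)
  expect_equal(ra$mean_msfd[ra$region == "region2"], 3, tolerance = 1e-12)
  expect_equal(ra$mean_msfd[ra$region == "region3"], 5, tolerance = 1e-12)
  expect_equal(ra$mean_msfd[ra$region == "all_four"], mean(t$msfd),
               tolerance = 1e-12)
})
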