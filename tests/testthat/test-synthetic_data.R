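test_that("toy fibril has the expected geometry and atom bookkeeping", {
  fib <- build_toy_fibril(n_layers = 2L, residues_per_layer = 8L)
  expect_equal(nrow(fib$atoms), 2L * 8L * 6L)
  expect_equal(length(unique(paste(fib$atoms$chain, fib$atoms$resno))), 16L)

  fib10 <- build_toy_fibril(n_layers = 10L, residues_per_layer = 4L,
                            rise = 0.48)
  cents <- layer_centroids(fib10)
  expect_equal(unname(cents[10, 3] - cents[1, 3]), 9 * 0.48,
               tolerance = 1e-9)
  # N-H vectors all along +z -> axis is +z
  ax <- protofilament_axis(fib10, axis_definition(start_residue = 1L,
                                                  stride = 2L,
                                                  residue_span = c(1L, 4L)))
  expect_equal(ax, c(x = 0, y = 0, z = 1), tolerance = 1e-9)
})

test_that("zero jump rates give a single censored dwell over the whole run", {
  fib <- build_toy_fibril(6L, 4L)
  lig <- anle138b_topology()
  spec <- hopping_spec(n_sites = 3L, rate_up = 0, rate_down = 0,
                       jitter_sigma = 0, n_frames = 50L, seed = 5L)
  hp <- simulate_hopping(spec, lig, fib)
  expect_equal(nrow(hp$events), 1L)
  expect_true(hp$events$censored[1])
  expect_equal(hp$events$duration_ns[1], 50L * 0.1)
  expect_equal(length(unique(hp$sites[[1]])), 1L)
})

test_that("hopping ground truth tiles the trajectory length exactly", {
  fib <- build_toy_fibril(8L, 4L)
  lig <- anle138b_topology()
  for (seed in c(1L, 2L, 3L)) {
    spec <- hopping_spec(n_sites = 5L, rate_up = 0.8, rate_down = 0.8,
                         n_frames = 500L, seed = seed)
    hp <- simulate_hopping(spec, lig, fib)
    total <- 500L * 0.1
    for (tr in unique(hp$events$trajectory)) {
      e <- hp$events[hp$events$trajectory == tr, ]
      expect_equal(sum(e$duration_ns), total, tolerance = 1e-9)
      # contiguous, time-ordered
      expect_equal(e$start_ns[-1],
                   (e$start_ns + e$duration_ns)[-nrow(e)], tolerance = 1e-9)
    }
  }
})

test_that("generators are bit-identical under a fixed seed", {
  fib <- build_toy_fibril(6L, 4L)
  lig <- anle138b_topology()
  spec <- hopping_spec(n_sites = 4L, n_frames = 200L, seed = 77L)
  a <- simulate_hopping(spec, lig, fib)
  b <- simulate_hopping(spec, lig, fib)
  expect_identical(a$ensemble$trajectories, b$ensemble$trajectories)
  expect_identical(a$events, b$events)

  pa <- generate_peak_tables(10L, perturbation_spec(3L, seed = 4L,
                                                    noise_sd = 0.05,
                                                    intensity_noise_cv = 0.1))
  pb <- generate_peak_tables(10L, perturbation_spec(3L, seed = 4L,
                                                    noise_sd = 0.05,
                                                    intensity_noise_cv = 0.1))
  expect_identical(pa, pb)

  da <- sample_boltzmann_depths(potential_spec(c(0, 1), c(0, 2)), 100L, seed = 8L)
  db <- sample_boltzmann_depths(potential_spec(c(0, 1), c(0, 2)), 100L, seed = 8L)
  expect_identical(da, db)
})

test_that("symmetric hopping reaches a uniform stationary occupancy", {
  fib <- build_toy_fibril(8L, 4L)
  lig <- anle138b_topology()
  # 20 independent trajectories; occupancy fraction per site compared
  # to 1/n_sites within 4 SEM across trajectories
  spec <- hopping_spec(n_sites = 4L, rate_up = 1, rate_down = 1,
                       jitter_sigma = 0, n_frames = 1000L,
                       n_trajectories = 20L, seed = 31L)
  hp <- simulate_hopping(spec, lig, fib)
  occ <- t(vapply(hp$sites, function(s) {
    vapply(0:3, function(k) mean(s == k), numeric(1))
  }, numeric(4)))
  m <- colMeans(occ)
  sem <- apply(occ, 2, stats::sd) / sqrt(nrow(occ))
  expect_true(all(abs(m - 0.25) <= 4 * sem + 1e-6))
})

test_that("ground-truth dwell times are exponential with mean 1/k", {
  fib <- build_toy_fibril(22L, 4L)
  lig <- anle138b_topology()
  spec <- hopping_spec(n_sites = 20L, rate_up = 0.25, rate_down = 0.25,
                       jitter_sigma = 0, n_frames = 25000L, seed = 13L)
  hp <- simulate_hopping(spec, lig, fib)
  # interior sites have total exit rate 0.5/ns; the reflecting end
  # sites have half that and are excluded from the law check
  interior <- hp$events$site > 0L & hp$events$site < 19L
  d <- hp$events$duration_ns[!hp$events$censored & interior]
  expect_gte(length(d), 1000L)
  expect_equal(mean(d), 2, tolerance = 0.1)
})

test_that("Boltzmann sampler matches flat and two-level references", {
  # flat potential -> uniform
  flat <- potential_spec(c(0, 1), c(0, 0))
  x <- sample_boltzmann_depths(flat, 1e4, seed = 21L)
  ks <- suppressWarnings(stats::ks.test(x, "punif", 0, 1))
  expect_lt(unname(ks$statistic), 0.02)

  # two plateaus separated by RT ln 4 -> occupancy ratio 4:1
  RT <- rt_kjmol(300)
  two <- potential_spec(c(0, 0.48, 0.52, 1), c(0, 0, RT * log(4), RT * log(4)))
  y <- sample_boltzmann_depths(two, 2e4, seed = 22L)
  n_low <- sum(y < 0.48); n_high <- sum(y > 0.52)
  ratio <- n_low / n_high
  se <- ratio * sqrt(1 / n_low + 1 / n_high)
  expect_lt(abs(ratio - 4), 3 * se)

  expect_length(sample_boltzmann_depths(flat, 1L, seed = 3L), 1L)
  expect_true(is.finite(sample_boltzmann_depths(flat, 1L, seed = 3L)))
})

test_that("peak-table generator encodes the configured perturbation", {
  spec <- perturbation_spec(4:6, csp_ppm = c(HN = 0.02, N = 0.2,
                                             CA = 0.1, CB = 0.08),
                            attenuation_factor = 0.5, seed = 2L)
  pk <- generate_peak_tables(10L, spec, glycine_residues = 5L)
  # glycine-like residue has no CB row
  expect_false(any(pk$free$residue == 5L & pk$free$nucleus == "CB"))
  # noise-free: bound = free + offsets on perturbed residues only
  pert <- pk$bound$residue %in% 4:6
  delta <- pk$bound$shift_ppm - pk$free$shift_ppm
  expect_equal(delta[!pert], rep(0, sum(!pert)))
  expect_equal(delta[pert],
               unname(spec$csp_ppm[pk$bound$nucleus[pert]]))
  expect_equal(pk$bound$intensity / pk$free$intensity,
               ifelse(pert, 0.5, 1))

  # empty perturbed set -> identical tables
  pk0 <- generate_peak_tables(6L, perturbation_spec(integer(0), seed = 2L))
  expect_equal(pk0$free$shift_ppm, pk0$bound$shift_ppm)
  expect_equal(pk0$free$intensity, pk0$bound$intensity)
})
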