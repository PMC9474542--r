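test_that("two-bin occupancy split gives the closed-form RT ln 4", {
  depths <- c(rep(0.025, 800), rep(0.075, 200))
  prof <- free_energy_profile(depths, bin_width = 0.05, range = c(0, 0.1))
  occ <- prof[!prof$masked, ]
  expect_equal(nrow(occ), 2L)
  dG <- occ$G_kJmol[2] - occ$G_kJmol[1]
  expect_equal(dG, rt_kjmol(300) * log(4), tolerance = 1e-9)
  expect_equal(dG, 3.458, tolerance = 1e-3)
  expect_equal(min(occ$G_kJmol), 0)
})

test_that("uniform samples give a flat profile and masked empty bins", {
  set.seed(14)
  depths <- lapply(1:4, function(i) runif(5000, 0, 1))
  prof <- free_energy_profile(depths, bin_width = 0.1)
  occ <- prof[!prof$masked, ]
  expect_true(all(occ$G_kJmol <= 3 * occ$sem + 0.15))
  # empty bins are masked, not zero
  prof2 <- free_energy_profile(c(runif(100, 0, 0.3), runif(100, 0.7, 1)),
                               bin_width = 0.1, range = c(0, 1))
  expect_true(any(prof2$masked))
  expect_true(all(is.na(prof2$G_kJmol[prof2$masked])))
})

test_that("profile is invariant to sample order and count scaling", {
  set.seed(4)
  x <- runif(2000, 0, 1)
  p1 <- free_energy_profile(x, bin_width = 0.1, range = c(0, 1))
  p2 <- free_energy_profile(sample(x), bin_width = 0.1, range = c(0, 1))
  expect_equal(p1$G_kJmol, p2$G_kJmol)
  # tripling every bin's count leaves delta-G unchanged
  p3 <- free_energy_profile(rep(x, 3), bin_width = 0.1, range = c(0, 1))
  expect_equal(p1$G_kJmol, p3$G_kJmol, tolerance = 1e-12)
})

test_that("coarser bins never unmask empty regions", {
  x <- c(runif(200, 0, 0.25), runif(200, 0.75, 1))
  fine <- free_energy_profile(x, bin_width = 0.05, range = c(0, 1))
  coarse <- free_energy_profile(x, bin_width = 0.1, range = c(0, 1))
  # every coarse masked bin is covered by fine masked bins
  fe <- attr(fine, "bin_edges"); ce <- attr(coarse, "bin_edges")
  for (i in which(coarse$masked)) {
    inside <- fine$bin_center_nm > ce[i] & fine$bin_center_nm < ce[i + 1]
    expect_true(all(fine$masked[inside]))
  }
})

test_that("sampler and profile analysis invert each other", {
  RT <- rt_kjmol(300)
  pot <- potential_spec(c(0, 0.6, 1.2, 1.8, 2.4),
                        c(0, 6, 0, 6, 0))
  x <- sample_boltzmann_depths(pot, 5e4, seed = 33L)
  prof <- free_energy_profile(x, bin_width = 0.05, range = c(0, 2.4))
  p <- prof$count / sum(prof$count)
  sel <- !prof$masked & p > 0.01
  g_true <- stats::approx(pot$x, pot$G, xout = prof$bin_center_nm[sel])$y
  g_true <- g_true - min(g_true)
  g_est <- prof$G_kJmol[sel] - min(prof$G_kJmol[sel])
  expect_lt(sqrt(mean((g_est - g_true)^2)), 0.5)
})

test_that("dwell detection on a hand-constructed site sequence", {
  x <- c(0, 0, 0, 1, 1, 2) * 0.48
  ev <- detect_dwell_events(x, site_spacing = 0.48, origin = 0)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$site, c(0L, 1L, 2L))
  expect_equal(ev$duration_ns, c(0.3, 0.2, 0.1), tolerance = 1e-9)
  expect_equal(ev$censored, c(TRUE, FALSE, TRUE))
  # constant series: one fully censored dwell, no transitions
  ev2 <- detect_dwell_events(rep(0.48, 10), site_spacing = 0.48)
  expect_equal(nrow(ev2), 1L)
  expect_true(ev2$censored[1])
  expect_equal(ev2$duration_ns, 1.0, tolerance = 1e-9)
  expect_error(detect_dwell_events(x, site_spacing = 0), "positive")
})

test_that("noise-free detection reproduces the simulated ground truth", {
  fib <- build_toy_fibril(10L, 4L)
  lig <- anle138b_topology()
  spec <- hopping_spec(n_sites = 8L, rate_up = 0.05, rate_down = 0.05,
                       jitter_sigma = 0, n_frames = 5000L, seed = 19L)
  hp <- simulate_hopping(spec, lig, fib)
  ax <- depth_series(hp$ensemble, lig, fib, projection = TRUE)
  ev <- detect_dwell_events(ax, site_spacing = 0.48, origin = 0.48,
                            core_fraction = 1, min_residence_frames = 1L)
  expect_equal(nrow(ev), nrow(hp$events))
  expect_equal(ev$site, hp$events$site)
  # durations agree to within one frame interval per boundary
  expect_lt(max(abs(ev$duration_ns - hp$events$duration_ns)), 0.2 + 1e-9)
})

test_that("dwell summary reports mean, SEM and cumulative histogram", {
  ev <- dwell_event_set(
    data.frame(trajectory = 1L, site = 0L,
               start_ns = c(0, 1, 3), duration_ns = c(1, 2, 3),
               censored = FALSE),
    site_spacing = 0.48)
  sm <- dwell_time_summary(ev, breaks = c(0, 1.5, 2.5, 3.5))
  expect_equal(sm$mean_ns, 2)
  expect_equal(sm$sem_ns, 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(sm$cumulative$cum_count, c(1L, 2L, 3L))
  expect_equal(max(sm$cumulative$cum_fraction), 1)

  one <- dwell_event_set(
    data.frame(trajectory = 1L, site = 0L, start_ns = 0,
               duration_ns = 2, censored = FALSE), 0.48)
  expect_true(is.na(dwell_time_summary(one)$sem_ns))

  cens <- dwell_event_set(
    data.frame(trajectory = 1L, site = 0L, start_ns = 0,
               duration_ns = 2, censored = TRUE), 0.48)
  expect_error(dwell_time_summary(cens), "exclude_censored")
})

test_that("overlapping or non-positive dwells are rejected", {
  expect_error(dwell_event_set(
    data.frame(trajectory = 1L, site = 0L, start_ns = 0,
               duration_ns = 0, censored = FALSE), 0.48), "positive")
  expect_error(dwell_event_set(
    data.frame(trajectory = 1L, site = c(0L, 1L), start_ns = c(0, 1),
               duration_ns = c(2, 1), censored = FALSE), 0.48),
    "overlap")
})
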