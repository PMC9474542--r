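test_that("protofilament axis averages the selected N-H unit vectors", {
  fib <- build_toy_fibril(4L, 4L)
  adef <- axis_definition(start_residue = 1L, stride = 2L,
                          residue_span = c(1L, 4L))
  expect_equal(unname(protofilament_axis(fib, adef)), c(0, 0, 1),
               tolerance = 1e-9)

  # hand-built pair of N-H vectors (1,0,1)/sqrt(2) and (-1,0,1)/sqrt(2)
  atoms <- data.frame(
    atom_id = 1:4,
    atom_name = c("N", "H", "N", "H"),
    element = c("N", "H", "N", "H"),
    resno = c(1L, 1L, 3L, 3L),
    chain = "A", layer = NA_integer_,
    x = c(0, 1 / sqrt(2) * 0.1, 1, 1 - 1 / sqrt(2) * 0.1),
    y = 0,
    z = c(0, 1 / sqrt(2) * 0.1, 0, 1 / sqrt(2) * 0.1))
  m <- fibril_model(atoms)
  ax <- protofilament_axis(m, axis_definition(1L, 2L, c(1L, 3L)))
  expect_equal(unname(ax), c(0, 0, 1), tolerance = 1e-9)
})

test_that("axis flips sign when the layer order is reversed", {
  fib <- build_toy_fibril(4L, 4L)
  adef <- axis_definition(1L, 2L, c(1L, 4L))
  ax <- protofilament_axis(fib, adef)
  rev_at <- fib$atoms
  rev_at$layer <- fib$layer_count - 1L - rev_at$layer
  fib_rev <- fibril_model(rev_at, layer_count = fib$layer_count)
  expect_equal(protofilament_axis(fib_rev, adef), -ax, tolerance = 1e-9)
  expect_equal(sqrt(sum(ax^2)), 1, tolerance = 1e-9)
})

test_that("a selected residue without an amide hydrogen is reported", {
  fib <- build_toy_fibril(2L, 4L)
  at <- fib$atoms[!(fib$atoms$resno == 3L & fib$atoms$atom_name == "H"), ]
  m <- fibril_model(at, layer_count = 2L)
  expect_error(
    protofilament_axis(m, axis_definition(1L, 2L, c(1L, 4L))),
    "residue 3")
})

test_that("insertion depth is the pyrazole-to-tip centroid distance", {
  fib <- build_toy_fibril(6L, 4L)
  lig <- anle138b_topology()
  tip_at <- fib$atoms[fib$atoms$layer == 0L, ]
  tip_com <- fibrilsite:::.com(fibrilsite:::.coords(tip_at),
                               fibrilsite:::.element_mass(tip_at$element))
  expect_equal(insertion_depth(ligand_frame_at(lig, tip_com), lig, fib), 0,
               tolerance = 1e-9)
  # 3-4-5 triangle
  fr <- ligand_frame_at(lig, tip_com + c(0.3, 0.4, 0))
  expect_equal(insertion_depth(fr, lig, fib), 0.5, tolerance = 1e-9)
})

test_that("insertion depth uses mass-weighted centroids", {
  # hand-picked 5-atom pyrazole at known coordinates; oracle computed
  # with explicit weighted means here
  lig <- anle138b_topology()
  fib <- build_toy_fibril(2L, 2L)
  fr <- lig$ref_coords
  pyr <- ligand_group_idx(lig, "pyrazole_ring")
  mass <- fibrilsite:::.element_mass(lig$atoms$element[pyr])
  com_hand <- colSums(fr[pyr, ] * mass) / sum(mass)
  tip_at <- fib$atoms[fib$atoms$layer == 0L, ]
  tip_hand <- colSums(fibrilsite:::.coords(tip_at) *
                        fibrilsite:::.element_mass(tip_at$element)) /
    sum(fibrilsite:::.element_mass(tip_at$element))
  expect_equal(insertion_depth(fr, lig, fib),
               sqrt(sum((com_hand - tip_hand)^2)), tolerance = 1e-12)
  # geometric-centroid variant differs (masses are unequal)
  expect_false(isTRUE(all.equal(
    insertion_depth(fr, lig, fib),
    insertion_depth(fr, lig, fib, mass_weighted = FALSE))))
})

test_that("insertion depth is invariant under global rigid motion", {
  fib <- build_toy_fibril(4L, 4L)
  lig <- anle138b_topology()
  fr <- ligand_frame_at(lig, c(1, 0.5, 1.2))
  d0 <- insertion_depth(fr, lig, fib)
  R <- rot_matrix(c(1, 2, 3), 0.7)
  shift <- c(5, -3, 2)
  at2 <- fib$atoms
  xyz2 <- fibrilsite:::.coords(at2) %*% t(R)
  at2$x <- xyz2[, 1] + shift[1]; at2$y <- xyz2[, 2] + shift[2]
  at2$z <- xyz2[, 3] + shift[3]
  fib2 <- fibril_model(at2, layer_count = fib$layer_count)
  fr2 <- sweep(fr %*% t(R), 2, shift, "+")
  expect_equal(insertion_depth(fr2, lig, fib2), d0, tolerance = 1e-9)
})

test_that("equilibration trimming follows the floor convention", {
  lig <- anle138b_topology()
  frames <- replicate(100, lig$ref_coords, simplify = FALSE)
  ens <- ensemble_from_frames(list(frames))
  expect_equal(n_frames(discard_equilibration(ens, 0.25)), 75L)
  expect_equal(n_frames(discard_equilibration(ens, 0)), 100L)
  ens3 <- ensemble_from_frames(list(frames[1:3]))
  expect_equal(n_frames(discard_equilibration(ens3, 0.25)), 3L)
  # retained frames are the last ones
  tr <- discard_equilibration(ens, 0.25)$trajectories[[1]]
  expect_equal(tr$times[1], 25 * 0.1)
})

test_that("RMSF is zero for a static trajectory and matches hand math", {
  fib <- build_toy_fibril(4L, 2L)
  ref <- fibrilsite:::.coords(fib)
  ens <- ensemble_from_frames(list(replicate(5, ref, simplify = FALSE)))
  tab <- rmsf(ens, fib, superpose = FALSE)
  expect_true(all(tab$rmsf_nm == 0))

  # two frames, one atom displaced by 0.2 nm -> RMSF 0.1 nm for it
  fr2 <- ref; fr2[1, 1] <- fr2[1, 1] + 0.2
  ens2 <- ensemble_from_frames(list(list(ref, fr2)))
  tab2 <- rmsf(ens2, fib, superpose = FALSE)
  per_atom <- attr(tab2, "per_atom")
  expect_equal(per_atom[1, 1], 0.1, tolerance = 1e-12)
  expect_equal(per_atom[2, 1], 0, tolerance = 1e-12)
})

test_that("isotropic Gaussian jitter gives per-atom RMSF near sigma*sqrt(3)", {
  fib <- build_toy_fibril(4L, 2L)
  ref <- fibrilsite:::.coords(fib)
  sigma <- 0.05
  set.seed(101)
  frames <- lapply(1:2000, function(i) {
    ref + matrix(rnorm(length(ref), 0, sigma), ncol = 3)
  })
  ens <- ensemble_from_frames(list(frames))
  tab <- rmsf(ens, fib, superpose = FALSE)
  per_atom <- attr(tab, "per_atom")
  expect_equal(mean(per_atom), sigma * sqrt(3), tolerance = 0.03)
})

test_that("superposition never increases RMSF for rigid-body noise", {
  fib <- build_toy_fibril(4L, 3L)
  ref <- fibrilsite:::.coords(fib)
  set.seed(55)
  frames <- lapply(1:40, function(i) {
    R <- rot_matrix(rnorm(3), rnorm(1, 0, 0.2))
    sweep(ref %*% t(R), 2, rnorm(3, 0, 0.3), "+")
  })
  ens <- ensemble_from_frames(list(frames))
  fit <- rmsf(ens, fib, superpose = TRUE)
  raw <- rmsf(ens, fib, superpose = FALSE)
  expect_true(all(attr(fit, "per_atom") <=
                    attr(raw, "per_atom") + 1e-9))
  # pure rigid-body motion is removed almost completely
  expect_lt(max(attr(fit, "per_atom")), 1e-6)
})

test_that("strand classes average core layers and exclude the edges", {
  fib <- build_toy_fibril(6L, 3L)
  ref <- fibrilsite:::.coords(fib)
  set.seed(7)
  frames <- lapply(1:30, function(i) ref + matrix(rnorm(length(ref), 0, 0.02),
                                                  ncol = 3))
  ens <- ensemble_from_frames(list(frames, frames))
  tab <- rmsf(ens, fib, superpose = FALSE, contact_layers = c(2L, 3L))
  expect_setequal(unique(tab$class), c("contact", "non_contact"))
  expect_true(all(tab$residue %in% 1:3))
  expect_true(all(is.finite(tab$sem_nm)))
})
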