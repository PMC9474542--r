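test_that("heavy-atom contact respects the 0.4 nm cutoff", {
  hit <- heavy_atom_contact(matrix(c(0, 0, 0), 1), "C",
                            matrix(c(0.35, 0, 0), 1), "C")
  expect_true(hit$contact)
  expect_equal(hit$n_in_contact, 1L)
  miss <- heavy_atom_contact(matrix(c(0, 0, 0), 1), "C",
                             matrix(c(0.45, 0, 0), 1), "C")
  expect_false(miss$contact)
  # hydrogens are excluded by element
  h <- heavy_atom_contact(matrix(c(0, 0, 0, 5, 5, 5), 2, byrow = TRUE),
                          c("H", "C"),
                          matrix(c(0.1, 0, 0), 1), "C")
  expect_false(h$contact)
})

test_that("cell-list contact detection equals all-pairs brute force", {
  set.seed(2024)
  for (rep in 1:120) {
    nA <- sample(5:25, 1); nB <- sample(50:200, 1)
    A <- matrix(runif(3 * nA, 0, 3), ncol = 3)
    B <- matrix(runif(3 * nB, 0, 3), ncol = 3)
    for (cutoff in c(0.4, 0.5)) {
      got <- fibrilsite:::.contact_query(A, B, cutoff)
      want <- brute_contact(A, B, cutoff)
      expect_identical(got$any, want$any)
      expect_identical(got$n_in_contact, want$n_in_contact)
      expect_identical(got$in_contact, want$in_contact)
    }
  }
})

test_that("contact set grows monotonically with the cutoff", {
  set.seed(9)
  A <- matrix(runif(30, 0, 2), ncol = 3)
  B <- matrix(runif(90, 0, 2), ncol = 3)
  small <- fibrilsite:::.contact_query(A, B, 0.3)$in_contact
  large <- fibrilsite:::.contact_query(A, B, 0.6)$in_contact
  expect_true(all(large[small]))
})

test_that("the 0.5 nm rule sees backbone C/N atoms only", {
  lig <- anle138b_topology()
  fib <- build_toy_fibril(2L, 2L)
  res <- fib$atoms[fib$atoms$resno == 1L & fib$atoms$chain == "A", ]
  n1 <- ligand_group_idx(lig, "pyrazole_N")[1]
  ca <- which(res$atom_name == "CA")
  cb <- which(res$atom_name == "CB")
  place_n1_near <- function(target, gap) {
    fr <- lig$ref_coords
    sweep(fr, 2, fr[n1, ] - (target + c(gap, 0, 0)), "-")
  }
  ca_pos <- unlist(res[ca, c("x", "y", "z")])
  cb_pos <- unlist(res[cb, c("x", "y", "z")])
  # 0.49 nm from backbone CA -> contact; same gap from sidechain -> not
  fr <- place_n1_near(ca_pos, 0.49)
  expect_true(nitrogen_backbone_contact(fr, lig, res))
  # move the whole ligand far, then put N1 near the sidechain CB only
  fr2 <- place_n1_near(cb_pos + c(0, 0, 5), 0.49)
  res2 <- res; res2$z[cb] <- res2$z[cb] + 5
  expect_false(nitrogen_backbone_contact(fr2, lig, res2))
  # CA excluded on request
  expect_false(nitrogen_backbone_contact(fr, lig,
                                         res[res$atom_name == "CA", ],
                                         include_ca = FALSE))
})

test_that("hydrogen-bond decisions follow the distance and angle criteria", {
  crit <- polar_bond_criteria()
  # linear N-H...O at 0.30 nm
  hb <- detect_hydrogen_bonds(matrix(c(0, 0, 0), 1),
                              matrix(c(0, 0, 0.1), 1),
                              matrix(c(0, 0, 0.30), 1), crit)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$angle_deg, 180, tolerance = 1e-9)
  expect_lt(hb$energy_kJmol, 0)
  # bent geometry at 120 degrees fails the angle test
  r <- 0.2788
  acc <- c(r * sin(pi / 3), 0, 0.1 + r * cos(pi / 3))
  hb2 <- detect_hydrogen_bonds(matrix(c(0, 0, 0), 1),
                               matrix(c(0, 0, 0.1), 1),
                               matrix(acc, 1), crit)
  expect_equal(nrow(hb2), 0L)
  # distance beyond 0.35 nm fails even when linear
  hb3 <- detect_hydrogen_bonds(matrix(c(0, 0, 0), 1),
                               matrix(c(0, 0, 0.1), 1),
                               matrix(c(0, 0, 0.36), 1), crit)
  expect_equal(nrow(hb3), 0L)
})

test_that("halogen-bond decisions follow the 0.36 nm / 150 degree rule", {
  lig <- anle138b_topology()
  crit <- polar_bond_criteria()
  br <- ligand_group_idx(lig, "halogen")
  cc <- ligand_group_idx(lig, "halogen_bonded_carbon")
  fr <- lig$ref_coords
  u_cb <- (fr[cc, ] - fr[br, ]) / sqrt(sum((fr[cc, ] - fr[br, ])^2))
  place_O <- function(d, theta_deg) {
    # rotate u_cb by theta about z to set the C-Br...O angle
    R <- rot_matrix(c(0, 0, 1), theta_deg * pi / 180)
    fr[br, ] + d * as.vector(R %*% u_cb)
  }
  o_yes <- place_O(0.35, 165)
  o_angle <- place_O(0.35, 140)
  o_dist <- place_O(0.37, 179)
  expect_equal(nrow(detect_halogen_bonds(fr, lig, matrix(o_yes, 1), crit)), 1L)
  expect_equal(nrow(detect_halogen_bonds(fr, lig, matrix(o_angle, 1), crit)), 0L)
  expect_equal(nrow(detect_halogen_bonds(fr, lig, matrix(o_dist, 1), crit)), 0L)
})

test_that("random polar-bond geometries match direct inequality evaluation", {
  crit <- polar_bond_criteria()
  lig <- anle138b_topology()
  set.seed(77)
  n_bad_hb <- 0L; n_bad_xb <- 0L
  for (i in 1:500) {
    D <- runif(3, -0.2, 0.2)
    H <- D + runif(3, -0.12, 0.12)
    A <- runif(3, -0.5, 0.5)
    got <- nrow(detect_hydrogen_bonds(matrix(D, 1), matrix(H, 1),
                                      matrix(A, 1), crit)) == 1L
    d <- sqrt(sum((A - D)^2))
    ang <- fibrilsite:::.angle_deg(D - H, A - H)
    want <- d <= 0.35 && ang >= 150
    if (got != want) n_bad_hb <- n_bad_hb + 1L

    O <- runif(3, -0.5, 0.5)
    fr <- lig$ref_coords
    br <- ligand_group_idx(lig, "halogen")
    cc <- ligand_group_idx(lig, "halogen_bonded_carbon")
    O <- fr[br, ] + runif(3, -0.45, 0.45)
    gotx <- nrow(detect_halogen_bonds(fr, lig, matrix(O, 1), crit)) == 1L
    dx <- sqrt(sum((O - fr[br, ])^2))
    angx <- fibrilsite:::.angle_deg(fr[cc, ] - fr[br, ], O - fr[br, ])
    wantx <- dx <= 0.36 && angx >= 150
    if (gotx != wantx) n_bad_xb <- n_bad_xb + 1L
  }
  expect_equal(n_bad_hb, 0L)
  expect_equal(n_bad_xb, 0L)
})

test_that("contact probabilities average over frames then trajectories", {
  fib <- build_toy_fibril(4L, 4L)
  lig <- anle138b_topology()
  cents <- layer_centroids(fib)
  near <- cents[2, ]                      # inside, in contact
  far <- cents[2, ] + c(50, 0, 0)        # far away
  f_near <- ligand_frame_at(lig, near)
  f_far <- ligand_frame_at(lig, far)
  # traj 1: 1 of 5 frames in contact; traj 2: 3 of 5
  ens <- ensemble_from_frames(list(
    list(f_near, f_far, f_far, f_far, f_far),
    list(f_near, f_near, f_near, f_far, f_far)))
  cm <- contact_probabilities(ens, lig, fib, "heavy")
  hit <- cm$probability[cm$probability > 0]
  expect_true(length(hit) > 0)
  expect_true(all(abs(hit - 0.4) < 1e-12))

  # single trajectory, 1 of 4 frames
  ens2 <- ensemble_from_frames(list(list(f_near, f_far, f_far, f_far)))
  cm2 <- contact_probabilities(ens2, lig, fib, "heavy")
  expect_true(all(abs(cm2$probability[cm2$probability > 0] - 0.25) < 1e-12))

  # welded ligand -> probability 1
  ens3 <- ensemble_from_frames(list(list(f_near, f_near)))
  cm3 <- contact_probabilities(ens3, lig, fib, "heavy")
  expect_true(any(cm3$probability == 1))
  expect_true(all(cm3$probability >= 0 & cm3$probability <= 1))
})

test_that("edge-layer exclusion never adds residues to the map", {
  fib <- build_toy_fibril(4L, 4L)
  lig <- anle138b_topology()
  f <- ligand_frame_at(lig, layer_centroids(fib)[1, ])
  ens <- ensemble_from_frames(list(list(f)))
  with_excl <- contact_probabilities(ens, lig, fib, "heavy",
                                     contact_criteria(exclude_edge_layers = TRUE))
  without <- contact_probabilities(ens, lig, fib, "heavy",
                                   contact_criteria(exclude_edge_layers = FALSE))
  expect_lte(nrow(with_excl), nrow(without))
})
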