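test_that("isolated and unoccluded atoms give the closed-form sphere area", {
  a <- one_atom("C1", "C", "UNK", 1, "A", c(0, 0, 0))
  s <- shrake_rupley_sasa(a)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 0.01 * 4 * pi * 3.1^2)
  expect_equal(s$total, sum(s$per_atom_area), tolerance = 1e-6)
  # two identical atoms beyond 2 (r + probe): no occlusion
  b <- rbind(a, one_atom("C2", "C", "UNK", 2, "A", c(2 * 3.1 + 0.5, 0, 0)))
  s2 <- shrake_rupley_sasa(b)
  expect_equal(s2$per_atom_area, rep(s$total, 2), tolerance = 1e-9)
  expect_error(shrake_rupley_sasa(one_atom(element = "ZZ")), "ZZ")
})

test_that("two overlapping spheres match the spherical-cap closed form within 2%", {
  for (d in c(2.0, 3.0, 4.5, 6.0)) {
    fx <- make_interface_fixture("two_spheres", r_a = 1.7, r_b = 1.52, d = d)
    both <- rbind(fx$set_a, fx$set_b)
    s <- shrake_rupley_sasa(both, probe = fx$probe, radii_table = fx$radii_table)
    # closed-form remaining area: 4 pi R^2 minus the buried cap, per atom
    Ra <- 1.7 + fx$probe; Rb <- 1.52 + fx$probe
    ha <- Ra - (d^2 + Ra^2 - Rb^2) / (2 * d)
    hb <- Rb - (d^2 + Rb^2 - Ra^2) / (2 * d)
    exp_a <- 4 * pi * Ra^2 - 2 * pi * Ra * max(0, ha)
    exp_b <- 4 * pi * Rb^2 - 2 * pi * Rb * max(0, hb)
    expect_equal(s$per_atom_area[1], exp_a, tolerance = 0.02 * exp_a)
    expect_equal(s$per_atom_area[2], exp_b, tolerance = 0.02 * exp_b)
    # and the buried area against the fixture's analytic value
    bsa <- buried_surface_area(fx$set_a, fx$set_b, probe = fx$probe,
                               radii_table = fx$radii_table)
    # 2% relative where the quadrature can resolve it; one sample-point area
    # (4 pi R^2 / n_points ~ 0.13 A^2) as the absolute floor near tangency
    tol <- max(0.02 * fx$expected_bsa, 4 * pi * 3.1^2 / 960)
    expect_lt(abs(bsa - fx$expected_bsa), tol)
  }
})

test_that("SASA is deterministic, convergent, and monotone under occlusion", {
  set.seed(5)
  n <- 40
  cloud <- data.frame(serial = 1:n, name = "C1", element = "C", res_name = "UNK",
                      res_seq = 1:n, chain_id = "A",
                      x = runif(n, 0, 12), y = runif(n, 0, 12), z = runif(n, 0, 12),
                      occupancy = 1, b_factor = 0)
  s1 <- shrake_rupley_sasa(cloud)
  s2 <- shrake_rupley_sasa(cloud)
  expect_identical(s1$per_atom_area, s2$per_atom_area)   # bit-reproducible
  s_dbl <- shrake_rupley_sasa(cloud, n_points = 1920)
  expect_lt(abs(s_dbl$total - s1$total) / s1$total, 0.01) # quadrature convergence
  # adding an occluder never increases any existing atom's area
  extra <- one_atom("CX", "C", "UNK", 99, "B", c(6, 6, 6))
  s3 <- shrake_rupley_sasa(rbind(cloud, extra))
  expect_true(all(s3$per_atom_area[1:n] <= s1$per_atom_area + 1e-9))
})

test_that("buried surface area is symmetric, non-negative, zero at distance", {
  fx <- make_interface_fixture("two_spheres", d = 3.0)
  b_ab <- buried_surface_area(fx$set_a, fx$set_b, probe = fx$probe,
                              radii_table = fx$radii_table)
  b_ba <- buried_surface_area(fx$set_b, fx$set_a, probe = fx$probe,
                              radii_table = fx$radii_table)
  expect_equal(b_ab, b_ba, tolerance = 1e-9)
  expect_gte(b_ab, 0)
  far <- fx$set_b; far$x <- 50
  expect_lt(abs(buried_surface_area(fx$set_a, far, probe = fx$probe,
                                    radii_table = fx$radii_table)), 1e-9)
  expect_error(buried_surface_area(fx$set_a, fx$set_a, probe = fx$probe,
                                   radii_table = fx$radii_table), "overlap")
})

test_that("two-slab interface matches the planar closed form within 5%", {
  sl <- make_interface_fixture("two_slabs", side_a = 44, side_b = 30)
  bsa <- buried_surface_area(sl$set_a, sl$set_b, probe = sl$probe,
                             radii_table = sl$radii_table)
  expect_equal(bsa, sl$expected_bsa, tolerance = 0.05 * sl$expected_bsa)
  # the face area is the dominant term of the closed form
  expect_gt(sl$expected_bsa, sl$face_area)
})

test_that("contact networks equal the brute-force all-pairs oracle", {
  fix <- shell_100_130()
  cap <- expand_capsid(fix$au, fix$ops)
  # two neighbouring chain groups, < 1000 atoms each
  a <- select_atoms(cap, chain = "A_0")
  xyz0 <- as.matrix(a[, c("x", "y", "z")])
  b <- cap$atoms[cap$atoms$copy == 7, ]
  for (cutoff in c(4, 8)) {
    got <- contact_network(a, b, cutoff)
    want <- brute_force_contacts(a, b, cutoff)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      key <- paste(got$chain_a, got$res_seq_a, got$chain_b, got$res_seq_b, sep = "\r")
      expect_setequal(key, want$key)
      ord <- match(want$key, key)
      expect_equal(got$min_distance[ord], want$min_distance, tolerance = 1e-9)
      expect_identical(got$n_atom_pairs[ord], want$n_atom_pairs)
    }
  }
  expect_identical(nrow(contact_network(a, b, 0)), 0L)
  # min_distance respects the cutoff invariant
  g4 <- contact_network(a, b, 4)
  if (nrow(g4) > 0) expect_true(all(g4$min_distance <= 4))
})

test_that("contact edges report per-pair minima for a hand-built case", {
  a <- one_atom("CA", "C", "GLY", 1, "A", c(0, 0, 0))
  b <- rbind(one_atom("CA", "C", "GLY", 2, "B", c(3.5, 0, 0)),
             one_atom("CB", "C", "GLY", 2, "B", c(3.9, 0, 0)))
  got <- contact_network(a, b, 4)
  expect_identical(nrow(got), 1L)
  expect_equal(got$min_distance, 3.5)
  expect_identical(got$n_atom_pairs, 2L)
})

test_that("capsid buried area: isolated AU gives zero, contacting shell a stable positive sum", {
  ops <- ico_ops()
  # a tight cluster deep inside one wedge: no neighbour within the cutoff
  clump <- structure_model(data.frame(
    serial = 1:5, name = "C1", element = "C", res_name = "UNK", res_seq = 1:5,
    chain_id = "A", x = 20, y = 41, z = 79 + (0:4) * 1.2,
    occupancy = 1, b_factor = 0))
  z <- capsid_buried_area(clump, ops, n_points = 240)
  expect_identical(z$n_interfaces, 0L)
  expect_identical(z$area, 0)
  # shell AU in contact with neighbours: oracle = manual sum of per-copy BSA
  small <- make_shell_capsid(60, 70, atoms_per_au = 120, seed = 9)
  got <- capsid_buried_area(small$au, small$ops, n_points = 240)
  expect_gt(got$n_interfaces, 0)
  manual <- 0
  xyz0 <- coords(small$au)
  for (k in got$neighbor_copies) {
    img <- small$au$atoms
    p <- xyz0 %*% t(small$ops$rotations[[k + 1]])
    img$x <- p[, 1]; img$y <- p[, 2]; img$z <- p[, 3]
    img$chain_id <- paste0(img$chain_id, "_img")
    manual <- manual + buried_surface_area(small$au$atoms, img, n_points = 240)
  }
  expect_equal(got$area, manual / 1e5, tolerance = 1e-9)
  tot <- capsid_buried_area(small$au, small$ops, mode = "total", n_points = 240)
  expect_equal(tot$area, got$area * 30, tolerance = 1e-9)
})

test_that("axis neighbourhoods attribute chains placed at the five-fold vertices", {
  ops <- ico_ops()
  ax <- find_axes(ops)
  f5 <- as.numeric(ax[ax$order == 5, c("dx", "dy", "dz")][1, ])
  f2 <- as.numeric(ax[ax$order == 2, c("dx", "dy", "dz")][1, ])
  au <- structure_model(rbind(
    one_atom("C1", "C", "UNK", 1, "X", f5 * 100),        # on a five-fold vertex
    one_atom("C1", "C", "UNK", 1, "Y", f2 * 100)))       # on a two-fold edge
  rep <- axis_neighborhood_report(au, ops, radius_shell = 5)
  five <- rep[rep$axis_order == 5, ]
  expect_identical(five$chain[which.max(five$n_atoms)], "X")
  two <- rep[rep$axis_order == 2, ]
  expect_identical(two$chain[which.max(two$n_atoms)], "Y")
  # an empty shell far from every axis shell yields no rows
  empty_rep <- axis_neighborhood_report(
    structure_model(one_atom("C1", "C", "UNK", 1, "Q",
                             c(30, 41, 60) / sqrt(sum(c(30, 41, 60)^2)) * 100)),
    ops, radius_shell = 0.5)
  expect_true(!"Q" %in% empty_rep$chain || all(empty_rep$n_atoms < 60))
})
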