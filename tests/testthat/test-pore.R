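test_that("analytic cylinder radii are recovered within grid tolerance", {
  cyl <- cylinder_model(radius = 8, vdw = 1.7)
  pp <- pore_profile(cyl, c(0, 0, 1), origin = c(0, 0, 0), slab = c(-8, 8))
  expect_equal(pp$min_radius, 8 - 1.7, tolerance = 0.05)
  # one atom moved to 4 A from the axis: the on-axis clearance drops to
  # 4 - 1.7, while the off-axis disc search balances the intruder against
  # the far wall at (4 + 8)/2 - 1.7
  cyl2 <- cyl
  cyl2$atoms$x[1] <- 4 * cos(0.3); cyl2$atoms$y[1] <- 4 * sin(0.3)
  cyl2$atoms$z[1] <- 0
  on_axis <- pore_profile(cyl2, c(0, 0, 1), origin = c(0, 0, 0),
                          slab = c(-8, 8), disc_radius = 1e-6)
  expect_equal(on_axis$min_radius, 4 - 1.7, tolerance = 0.05)
  expect_lt(abs(on_axis$z_at_min), 1)
  pp2 <- pore_profile(cyl2, c(0, 0, 1), origin = c(0, 0, 0), slab = c(-8, 8))
  expect_equal(pp2$min_radius, (4 + 8) / 2 - 1.7, tolerance = 0.05)
})

test_that("profiles agree with an exhaustive fine-grid oracle", {
  set.seed(11)
  for (rep in 1:3) {
    xyz <- cbind(runif(30, -6, 6), runif(30, -6, 6), runif(30, -4, 4))
    m <- toy_model(xyz, vdw = 1.7)
    for (z in c(-1, 0.5)) {
      pp <- pore_profile(m, c(0, 0, 1), origin = c(0, 0, 0),
                         slab = c(z, z))
      expect_equal(pp$min_radius,
                   max(brute_pore_radius(m, c(0, 0, 1), c(0, 0, 0), z), 0),
                   tolerance = 0.05)
    }
  }
})

test_that("deleting atoms never narrows the pore", {
  set.seed(12)
  xyz <- cbind(runif(40, -7, 7), runif(40, -7, 7), runif(40, -5, 5))
  m <- toy_model(xyz)
  full <- pore_profile(m, c(0, 0, 1), origin = c(0, 0, 0), slab = c(-4, 4))
  m2 <- m
  m2$atoms <- m2$atoms[-(1:10), ]
  sub <- pore_profile(m2, c(0, 0, 1), origin = c(0, 0, 0), slab = c(-4, 4))
  expect_true(all(sub$samples$radius >= full$samples$radius - 1e-9))
})

test_that("profile is invariant under joint rigid motion of model and axis", {
  cyl <- cylinder_model(radius = 6, vdw = 1.5, zs = seq(-5, 5, 1))
  pp <- pore_profile(cyl, c(0, 0, 1), origin = c(0, 0, 0), slab = c(-4, 4))
  R <- aa_rotation(c(0.5, -0.2, 0.9))
  cylr <- rigid_transform_model(cyl, v = c(0.5, -0.2, 0.9), t = c(3, 4, -2))
  ppr <- pore_profile(cylr, as.numeric(R %*% c(0, 0, 1)),
                      origin = as.numeric(R %*% c(0, 0, 0)) + c(3, 4, -2),
                      slab = c(-4, 4))
  expect_equal(ppr$min_radius, pp$min_radius, tolerance = 0.02)
})

test_that("halving the grid step moves the minimum by less than 0.05 A", {
  cyl <- cylinder_model(radius = 8, vdw = 1.7, zs = seq(-4, 4, 1))
  p1 <- pore_profile(cyl, c(0, 0, 1), origin = c(0, 0, 0), slab = c(-3, 3),
                     step = 0.5, coarse = 0.5)
  p2 <- pore_profile(cyl, c(0, 0, 1), origin = c(0, 0, 0), slab = c(-3, 3),
                     step = 0.25, coarse = 0.25)
  expect_lt(abs(p1$min_radius - p2$min_radius), 0.05)
})

test_that("blocked slices are floored at zero and flagged", {
  # solid wall of atoms across the plane z = 0
  g <- expand.grid(x = seq(-6, 6, 1.5), y = seq(-6, 6, 1.5))
  m <- toy_model(cbind(g$x, g$y, 0), vdw = 1.7)
  pp <- pore_profile(m, c(0, 0, 1), origin = c(0, 0, 0), slab = c(0, 0))
  expect_equal(pp$min_radius, 0)
  expect_true(all(pp$samples$blocked))
})

test_that("poly-alanine keeps N, CA, C, O, CB and records identities", {
  seqs <- paste(c("W", "G", rep("A", 227)), collapse = "")
  bar <- generate_barrel(barrel_spec(n_strands = 16, strand_length = 10,
                                     sequence = seqs))
  pa <- polyalanine(bar$model)
  a1 <- pa$atoms[pa$atoms$residue_index == 1, ]
  expect_equal(sort(a1$atom_name), sort(c("N", "CA", "C", "O", "CB")))
  expect_equal(unique(a1$residue_name), "ALA")
  expect_equal(unique(a1$orig_residue), "TRP")
  a2 <- pa$atoms[pa$atoms$residue_index == 2, ]
  expect_equal(nrow(a2), 4)  # glycine gains no atoms
  expect_equal(unique(a2$residue_name), "GLY")
})

test_that("core and poly-alanine minima are at least the whole-structure minima", {
  bar <- generate_barrel(barrel_spec(
    n_strands = 8, strand_length = 8,
    constriction_loop = list(index = 1, depth = 0.25)))
  ann <- annotate_topology(bar$model)
  pa <- pore_analysis(bar$model, ann)
  expect_gte(pa$core$min_radius, pa$whole$min_radius - 1e-9)
  expect_gte(pa$polyA$min_radius, pa$whole$min_radius - 1e-9)
})

test_that("barrel radius grows with strand count, and so does the pore", {
  p8 <- generate_barrel(barrel_spec(n_strands = 8, strand_length = 8))
  p26 <- generate_barrel(barrel_spec(n_strands = 26, strand_length = 8))
  a8 <- annotate_topology(p8$model); a26 <- annotate_topology(p26$model)
  pp8 <- pore_profile(p8$model, attr(a8, "axis"), attr(a8, "origin"),
                      attr(a8, "slab"))
  pp26 <- pore_profile(p26$model, attr(a26, "axis"), attr(a26, "origin"),
                       attr(a26, "slab"))
  expect_gt(pp26$min_radius, pp8$min_radius)
  # unobstructed analytic radius: R - cb_reach - vdw
  expect_equal(pp8$min_radius, p8$geometry$R - 1.5 - 1.7, tolerance = 0.2)
  expect_equal(pp26$min_radius, p26$geometry$R - 1.5 - 1.7, tolerance = 0.2)
})
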