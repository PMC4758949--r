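test_that("side-chain centroids follow the mean / glycine-CA rules", {
  # alanine: single side-chain atom is its own centroid
  m <- toy_model(toy_residue_model(1, "A", matrix(c(1, 1, 1), 1)))
  expect_equal(unname(sidechain_centroid(m$atoms)), c(1, 1, 1))

  # four side-chain atoms: arithmetic mean
  side <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0))
  m2 <- toy_model(toy_residue_model(2, "L", side))
  expect_equal(unname(sidechain_centroid(m2$atoms)), c(1, 1, 0))

  # glycine: falls back to CA
  mg <- toy_model(toy_residue_model(3, "G", NULL, ca = c(4, 5, 6)))
  expect_equal(unname(sidechain_centroid(mg$atoms)), c(4, 5, 6))
})

test_that("inter-residue distances: 3-4-5 triangle, symmetry, self-zero", {
  spec <- c(toy_residue_model(1, "A", matrix(c(0, 0, 0), 1), ca = c(-3, 0, 0)),
            toy_residue_model(2, "A", matrix(c(3, 4, 0), 1), ca = c(6, 4, 0)))
  m <- toy_model(spec)
  # single side-chain atoms at (0,0,0) and (3,4,0): centroid distance 5
  expect_equal(centroid_distance(m, 1, 2), 5)
  expect_equal(centroid_distance(m, 2, 1), centroid_distance(m, 1, 2))
  expect_equal(shortest_heavy_atom_distance(m, 1, 1), 0)
  expect_equal(centroid_distance(m, 1, 1), 0)
  # shortest heavy-atom distance cannot exceed the centroid distance by
  # more than the intra-residue spread (here backbone included)
  expect_lte(shortest_heavy_atom_distance(m, 1, 2),
             centroid_distance(m, 1, 2) + 10)
})

test_that("homo-oligomer convention reports the minimum over chain pairs", {
  spec <- c(toy_residue_model(1, "A", matrix(c(0, 0, 0), 1), chain = "A"),
            toy_residue_model(1, "A", matrix(c(20, 0, 0), 1), chain = "B"),
            toy_residue_model(2, "A", matrix(c(18, 0, 0), 1), chain = "A"),
            toy_residue_model(2, "A", matrix(c(40, 0, 0), 1), chain = "B"))
  m <- toy_model(spec)
  # residue 2 of chain A is 2 A from residue 1 of chain B
  expect_equal(centroid_distance(m, 1, 2), 2)
  # restricted to chain A only, the distance is 18
  expect_equal(centroid_distance(m, 1, 2, chain_x = "A", chain_y = "A"), 18)
})

test_that("superposition recovers rigid motions and matches bio3d", {
  bun <- generate_helix_bundle(n_helices = 3, helix_len = 8, seed = 11)
  m <- bun$model
  expect_equal(superpose(m, m)$rmsd, 0, tolerance = 1e-9)

  # rigidly moved copy superposes back to rmsd ~ 0
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m2$atoms$x <- xyz[, 1] + 5; m2$atoms$y <- xyz[, 2] - 3
  m2$atoms$z <- xyz[, 3] + 11
  sp <- superpose(m2, m, "backbone")
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  # against an independent implementation on deformed coordinates
  set.seed(42)
  m3 <- m
  m3$atoms$x <- m3$atoms$x + rnorm(nrow(m3$atoms), 0, 1.5)
  m3$atoms$y <- m3$atoms$y + rnorm(nrow(m3$atoms), 0, 1.5)
  m3$atoms$z <- m3$atoms$z + rnorm(nrow(m3$atoms), 0, 1.5)
  ours <- superpose(m3, m, "CA")$rmsd
  ca <- m$atoms$elety == "CA"
  fixed <- as.vector(t(as.matrix(m$atoms[ca, c("x", "y", "z")])))
  mobile <- as.vector(t(as.matrix(m3$atoms[ca, c("x", "y", "z")])))
  moved <- suppressWarnings(bio3d::fit.xyz(fixed, mobile))
  theirs <- sqrt(mean(colSums((matrix(moved - fixed, nrow = 3))^2)))
  expect_equal(ours, theirs, tolerance = 1e-6)

  # symmetry of the rmsd in its arguments
  expect_equal(superpose(m3, m, "CA")$rmsd, superpose(m, m3, "CA")$rmsd,
               tolerance = 1e-9)
})

test_that("ensemble RMSF is zero for identical models and exact for a
           planted two-model displacement", {
  bun <- generate_helix_bundle(n_helices = 4, helix_len = 16, seed = 2)
  m1 <- bun$model
  ens0 <- structure_ensemble(list(m1, m1))
  expect_true(all(ensemble_rmsf(ens0)$rmsf < 1e-9))

  # displace one residue's CA by 2 A in model 2: each model then deviates
  # by ~1 A from the mean structure at that residue, so its RMSF is ~1
  # (the refit over the other 63 residues absorbs a few percent)
  m2 <- m1
  i <- which(m2$atoms$resno == 1 & m2$atoms$elety == "CA")
  m2$atoms$x[i] <- m2$atoms$x[i] + 2
  ens <- structure_ensemble(list(m1, m2))
  rmsf <- ensemble_rmsf(ens)
  expect_equal(rmsf$rmsf[rmsf$resno == 1], 1.0, tolerance = 0.05)
  expect_error(ensemble_rmsf(structure_ensemble(list(m1))), "at least 2")
})

test_that("Shrake-Rupley areas match the analytic sphere and converge", {
  # one isolated carbon atom: accessible area is the full probe-inflated
  # sphere, 4*pi*(1.7+1.4)^2
  m <- toy_model(list(list(resno = 1, aa = "A", elety = "CB",
                           x = 0, y = 0, z = 0)))
  s <- sasa(m, n_points = 960)
  expect_equal(s$asa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)

  # an atom caged by a shell of atoms has zero accessibility
  shell <- supprox:::golden_spiral(60) * 3.0
  spec <- list(list(resno = 1, aa = "A", elety = "CB", x = 0, y = 0, z = 0))
  for (i in seq_len(nrow(shell)))
    spec <- c(spec, list(list(resno = 2, aa = "X",
                              elety = paste0("C", i), elesy = "C",
                              x = shell[i, 1], y = shell[i, 2],
                              z = shell[i, 3])))
  s2 <- sasa(toy_model(spec), n_points = 480)
  expect_equal(s2$asa[s2$resno == 1], 0)

  # convergence: doubling the point count from the default moves
  # per-residue ASA by < 2%
  bun <- generate_helix_bundle(n_helices = 3, helix_len = 8, seed = 5)
  a1 <- sasa(bun$model, n_points = 960)$asa
  a2 <- sasa(bun$model, n_points = 1920)$asa
  expect_lt(max(abs(a1 - a2) / pmax(a2, 5)), 0.02)

  # total over residues equals total over atoms
  s3 <- sasa(bun$model, n_points = 240)
  expect_equal(sum(s3$asa), sum(attr(s3, "atom_area")), tolerance = 1e-9)
})

test_that("residue depth: isolated atom, monotone burial, ASA anticorrelation", {
  m <- toy_model(list(list(resno = 1, aa = "A", elety = "CB",
                           x = 0, y = 0, z = 0)))
  d <- residue_depth(m, n_points = 480)
  expect_equal(d$depth, 1.7 + 1.4, tolerance = 0.01)

  # concentric cluster: central atom deeper than peripheral ones
  pts <- rbind(c(0, 0, 0), supprox:::golden_spiral(30) * 3,
               supprox:::golden_spiral(40) * 6)
  spec <- lapply(seq_len(nrow(pts)), function(i)
    list(resno = i, aa = "A", elety = "CB",
         x = pts[i, 1], y = pts[i, 2], z = pts[i, 3]))
  dd <- residue_depth(toy_model(spec), n_points = 240)
  expect_gt(dd$depth[1], max(dd$depth[32:71]))

  # compact globule: depth anti-correlates with relative ASA
  g <- generate_helix_bundle(n_helices = 7, helix_len = 14,
                             layout = "packed", seed = 1)
  dp <- residue_depth(g$model, n_points = 120)
  sp <- sasa(g$model, n_points = 240)
  ct <- cor.test(dp$depth, sp$rel_asa, method = "spearman", exact = FALSE)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  expect_gte(nrow(dp), 50)
})
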