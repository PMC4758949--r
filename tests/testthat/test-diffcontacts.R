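test_that("contact maps are symmetric position pairs with min-over-chain
           distances and respect cutoff monotonicity", {
  tp <- generate_toy_conformation_pair(seed = 5)
  map7 <- contact_map(tp$A, cutoff = 7)
  expect_true(all(map7$pos_x < map7$pos_y))
  expect_true(all(map7$dist <= 7 + 1e-9))
  map5 <- contact_map(tp$A, cutoff = 5)
  k7 <- paste(map7$pos_x, map7$pos_y)
  k5 <- paste(map5$pos_x, map5$pos_y)
  expect_true(all(k5 %in% k7))   # tightening never adds pairs

  # rigid motion leaves the map unchanged
  th <- 0.6
  sp <- structure(list(rotation = matrix(c(cos(th), -sin(th), 0,
                                           sin(th), cos(th), 0, 0, 0, 1),
                                         3, byrow = TRUE),
                       translation = c(3, -8, 1)), class = "superposition")
  moved <- structure_ensemble(
    list(apply_superposition(tp$A$models[[1]], sp)), tp$A$helices)
  mmap <- contact_map(moved, cutoff = 7)
  expect_equal(paste(mmap$pos_x, mmap$pos_y), k7)
  expect_equal(mmap$dist, map7$dist, tolerance = 1e-9)
})

test_that("inter-helical filtering removes intra-helix pairs and the
           excluded range", {
  tp <- generate_toy_conformation_pair(seed = 5)
  helix_len <- tp$A$helices$end[1] - tp$A$helices$start[1] + 1
  m <- contact_map(tp$A, cutoff = 7, inter_helical_only = TRUE)
  hx <- (m$pos_x - 1) %/% helix_len
  hy <- (m$pos_y - 1) %/% helix_len
  expect_true(all(hx != hy))

  m2 <- contact_map(tp$A, cutoff = 7, exclude_range = 1:20)
  expect_true(all(m2$pos_x > 20 & m2$pos_y > 20))
})

test_that("identical conformations give no differential candidates; a swap
           plants recoverable ones", {
  tp0 <- generate_toy_conformation_pair(swap = FALSE, seed = 8)
  mA <- contact_map(tp0$A, inter_helical_only = TRUE)
  mB <- contact_map(tp0$B, inter_helical_only = TRUE)
  rep0 <- select_pim_candidates(mA, mB, tp0$sequence)
  expect_equal(nrow(rep0), 0)

  tp <- generate_toy_conformation_pair(seed = 8)
  mA <- contact_map(tp$A, inter_helical_only = TRUE)
  mB <- contact_map(tp$B, inter_helical_only = TRUE)
  rep1 <- select_pim_candidates(mA, mB, tp$sequence)
  expect_gt(nrow(rep1), 0)
  sel <- rep1[rep1$selected, , drop = FALSE]
  expect_gt(nrow(sel), 0)
  # selected implies every criterion flag passes
  expect_true(all(sel$charged_removed & sel$hbond_excluded &
                    sel$min_partner_count & sel$seq_separation &
                    sel$partner_divergence))
  # no selected candidate is charged
  expect_false(any(sel$aa %in% AA_GROUPS$charged))

  # making one criterion unsatisfiable empties the selection
  rep2 <- select_pim_candidates(mA, mB, tp$sequence, min_sep = 10000)
  expect_false(any(rep2$selected))
  rep3 <- select_pim_candidates(mA, mB, tp$sequence, min_partner_shift = 1e6)
  expect_false(any(rep3$selected))
  rep4 <- select_pim_candidates(mA, mB, tp$sequence, min_partners = 1e6)
  expect_false(any(rep4$selected))

  expect_error(select_pim_candidates(mA, mB, tp$sequence[1:5]),
               "sequence length mismatch")
})

test_that("suppressor pairs arbitrate between rival conformations", {
  tp <- generate_toy_conformation_pair(seed = 21)
  expect_gt(nrow(tp$planted), 0)
  # generator contract: close in A, far in B
  expect_true(all(tp$planted$dist_A <= 7))
  expect_true(all(tp$planted$dist_B > 7))

  sup <- evaluate_suppressor_support(tp$planted, tp$A, tp$B)
  expect_true(all(sup$verdict == "supports_A"))

  # swapping the argument order flips the verdicts
  sup_rev <- evaluate_suppressor_support(tp$planted, tp$B, tp$A)
  expect_true(all(sup_rev$verdict == "supports_B"))

  # planted pair close in both -> "both"; far in both -> "neither"
  both <- evaluate_suppressor_support(
    data.frame(pim_pos = tp$planted$pim_pos[1],
               sup_pos = tp$planted$sup_pos[1]), tp$A, tp$A)
  expect_equal(both$verdict, "both")
  far <- evaluate_suppressor_support(
    data.frame(pim_pos = tp$planted$pim_pos[1],
               sup_pos = tp$planted$sup_pos[1]), tp$B, tp$B)
  expect_equal(far$verdict, "neither")

  # unresolvable positions fail per pair without stopping the run
  mix <- evaluate_suppressor_support(
    data.frame(pim_pos = c(tp$planted$pim_pos[1], 9999),
               sup_pos = c(tp$planted$sup_pos[1], 1)), tp$A, tp$B)
  expect_equal(mix$verdict, c("supports_A", "error"))
})

test_that("side-chain hydrogen bonds flag candidate exclusion", {
  # two residues with serine-like side-chain oxygens 2.8 A apart
  spec <- c(toy_residue_model(1, "S", matrix(c(0, 0, 0), 1)),
            toy_residue_model(40, "S", matrix(c(2.8, 0, 0), 1)))
  m <- toy_model(spec)
  m$atoms$elesy[m$atoms$elety == "CB"] <- "O"
  m$atoms$elety[m$atoms$elety == "CB"] <- "OG"
  map <- contact_map(structure_ensemble(list(m)), cutoff = 7)
  expect_true(map$hbond[map$pos_x == 1 & map$pos_y == 40])
})
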