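planted_pairs_from_native <- function(model, n = 6, max_dist = 6,
                                      min_sep = 5) {
  cen <- sidechain_centroids(model)
  X <- as.matrix(cen[, c("x", "y", "z")])
  d <- as.matrix(dist(X))
  idx <- which(upper.tri(d) & d < max_dist &
                 abs(outer(cen$resno, cen$resno, "-")) > min_sep,
               arr.ind = TRUE)
  idx <- idx[order(d[idx]), , drop = FALSE][seq_len(min(n, nrow(idx))), ,
                                            drop = FALSE]
  contact_pairs(data.frame(pos_x = cen$resno[idx[, 1]],
                           pos_y = cen$resno[idx[, 2]]))
}

test_that("ContactScore counts satisfied constraints and is rigid-motion
           invariant", {
  bun <- generate_helix_bundle(seed = 3)
  pairs <- planted_pairs_from_native(bun$model)
  expect_equal(contact_score(bun$model, pairs), pairs$n)

  # rigid motion leaves the score unchanged
  sp <- list(rotation = diag(3)[, c(2, 1, 3)] * c(1, 1, -1),
             translation = c(10, -4, 2))
  # build a proper rotation
  th <- 1.1
  sp$rotation <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0,
                          0, 0, 1), 3, byrow = TRUE)
  class(sp) <- "superposition"
  moved <- apply_superposition(bun$model, sp)
  expect_equal(contact_score(moved, pairs), pairs$n)

  # pushing every residue apart empties the score
  blown <- bun$model
  blown$atoms$x <- blown$atoms$x * 10
  blown$atoms$y <- blown$atoms$y * 10
  blown$atoms$z <- blown$atoms$z * 10
  expect_equal(contact_score(blown, pairs), 0)

  # constructed model with exactly 3 of 6 planted contacts satisfied
  p6 <- pairs$pairs[1:6, ]
  half <- bun$model
  for (p in p6$pos_x[4:6]) {
    i <- half$atoms$resno == p
    half$atoms$x[i] <- half$atoms$x[i] + 50
  }
  got <- contact_score(half, contact_pairs(p6))
  cen <- sidechain_centroids(half)
  direct <- sum(vapply(1:6, function(i) {
    a <- cen[cen$resno == p6$pos_x[i], c("x", "y", "z")]
    b <- cen[cen$resno == p6$pos_y[i], c("x", "y", "z")]
    sqrt(sum((a - b)^2)) < 7
  }, logical(1)))
  expect_equal(got, direct)
  expect_equal(got, 3)
})

test_that("rdepthscore is the RankScore-depth correlation with exclusions", {
  d <- data.frame(chain = "A", resno = 1:20, insert = "", aa = "L",
                  depth = seq(3, 8, length.out = 20))
  rk <- data.frame(position = 1:20, rank_score = seq(1, 96, length.out = 20),
                   n_mutants = 10)
  expect_equal(rdepth_score(rk, d), 1.0)

  # an excluded active-site outlier no longer disturbs the correlation
  rk2 <- rk; rk2$rank_score[20] <- 1
  expect_lt(rdepth_score(rk2, d), 1)
  expect_equal(rdepth_score(rk2, d, exclude = 20),
               1.0, tolerance = 1e-12)

  # permuted RankScores decorrelate
  set.seed(1)
  r <- replicate(200, {
    rk3 <- rk; rk3$rank_score <- sample(rk3$rank_score)
    rdepth_score(rk3, d)
  })
  expect_lt(median(abs(r)), 0.25)
  expect_error(rdepth_score(rk[1:2, ], d[1:2, ]), "at least 3")
  rk4 <- rk; rk4$rank_score <- 5
  expect_error(rdepth_score(rk4, d), "zero variance")
})

test_that("R_s sums relative deviations from reference packing", {
  prof <- data.frame(chain = "A", resno = 1:3, insert = "",
                     aa = c("L", "K", "G"), asa = c(10, 80, 30))
  class(prof) <- c("sasa_profile", "data.frame")
  ref <- c(L = 10, K = 40, G = 15)
  # |10-10|/10 + |80-40|/40 + |30-15|/15 = 0 + 1 + 1
  expect_equal(rs_score(prof, ref), 2)
  # every residue at its reference mean scores 0
  prof0 <- prof; prof0$asa <- ref[prof$aa]
  expect_equal(rs_score(prof0, ref), 0)
  # scale invariance: scaling ASA and reference together changes nothing
  prof2 <- prof; prof2$asa <- prof$asa * 3.7
  expect_equal(rs_score(prof2, ref * 3.7), rs_score(prof, ref))
  expect_error(rs_score(prof, ref[-2]), "missing reference")
})

test_that("score_decoys scores the reference itself perfectly and degrades
           with RMSD", {
  bun <- generate_helix_bundle(seed = 13)
  pairs <- planted_pairs_from_native(bun$model)
  self <- score_decoys(list(native = bun$model), bun$model, pairs)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$contact_score, pairs$n)

  dec <- generate_decoys(bun$model, n_models = 40,
                         amplitudes = c(0.5, 1.5, 4, 9), seed = 5)
  sc <- score_decoys(dec$models, bun$model, pairs)
  expect_equal(sc$rmsd, dec$truth$rmsd, tolerance = 1e-9)
  q <- cut(sc$rmsd, quantile(sc$rmsd, 0:4 / 4), include.lowest = TRUE)
  med <- tapply(sc$contact_score, q, median)
  expect_true(all(diff(med) <= 0))
  expect_lt(med[4], med[1])
})

test_that("recovery histogram bins (lower, upper] and counts selections", {
  sc <- data.frame(model = sprintf("m%02d", 1:10),
                   rmsd = c(rep(0.3, 5), rep(0.8, 5)),
                   contact_score = c(6, 6, 6, 1, 0, 0, 0, 0, 0, 0))
  class(sc) <- c("model_scores", "data.frame")
  h <- recovery_histogram(sc, function(s) s$contact_score == 6)
  expect_equal(h$models_total[1:2], c(5, 5))
  expect_equal(h$recovery[1:2], c(0.6, 0))
  # always-true predicate recovers every non-empty bin fully
  h2 <- recovery_histogram(sc, function(s) rep(TRUE, nrow(s)))
  expect_true(all(h2$recovery[h2$models_total > 0] == 1))
  # boundary value 0.5 falls in the (0, 0.5] bin
  sc$rmsd[1] <- 0.5
  h3 <- recovery_histogram(sc, function(s) s$contact_score == 6)
  expect_equal(h3$models_total[1], 5)
})

test_that("model ranking is ascending for R_s, descending otherwise,
           ties by id", {
  sc <- data.frame(model = c("a", "b", "c"),
                   contact_score = c(4, 4, 4),
                   r_s = c(0.5, 0.2, 0.9))
  class(sc) <- c("model_scores", "data.frame")
  expect_equal(rank_models_by(sc, "r_s")$model, c("b", "a", "c"))
  expect_equal(rank_models_by(sc, "contact_score")$model, c("a", "b", "c"))

  set.seed(3)
  sc2 <- data.frame(model = sprintf("m%03d", 1:100),
                    r_s = round(runif(100), 2))
  class(sc2) <- c("model_scores", "data.frame")
  got <- rank_models_by(sc2, "r_s")$model
  want <- sc2$model[order(sc2$r_s, sc2$model)]
  expect_equal(got, want)
})

test_that("a reference ASA table built from structures covers all types and
           scores the source models lowest on average", {
  g <- generate_helix_bundle(n_helices = 7, helix_len = 14,
                             layout = "packed", seed = 2)
  ref <- mean_asa_reference(list(g$model), n_points = 120)
  expect_length(ref, 20)
  expect_true(all(ref > 0))
  rs_native <- rs_score(sasa(g$model, n_points = 120), ref)
  blown <- g$model
  blown$atoms$x <- blown$atoms$x * 3
  blown$atoms$y <- blown$atoms$y * 3
  blown$atoms$z <- blown$atoms$z * 3
  expect_gt(rs_score(sasa(blown, n_points = 120), ref), rs_native)
})
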