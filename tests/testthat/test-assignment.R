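random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3)
}

test_that("Kabsch superposition is exact on rigid copies and closed forms", {
  ca <- ca_coords(make_ideal_helix(30))
  R <- random_rotation(1)
  moved <- sweep(ca %*% R, 2, c(5, -3, 11), "+")
  fit <- kabsch_superpose(ca, moved)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # one atom displaced by d among n pairs: rmsd = d / sqrt(n) before
  # refitting; the optimal fit can only reduce it, and only slightly
  d <- 2.4
  moved2 <- ca
  moved2[7, 1] <- moved2[7, 1] + d
  r1 <- kabsch_superpose(ca, moved2)$rmsd
  expect_lte(r1, d / sqrt(nrow(ca)) + 1e-9)
  expect_gt(r1, 0.95 * d / sqrt(nrow(ca)))
  expect_error(kabsch_superpose(ca[1:2, ], ca[1:2, ]), "3")
  col <- cbind(1:10, 0, 0)
  expect_error(kabsch_superpose(col, col), "degenerate")
})

test_that("SVD superposition agrees with an independent quaternion solver", {
  for (seed in 1:25) {
    set.seed(seed)
    A <- matrix(rnorm(60), 20, 3)
    B <- matrix(rnorm(60), 20, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, quaternion_rmsd(A, B),
                 tolerance = 1e-8)
  }
})

test_that("TM-score self-alignment is exactly 1 and rigid-motion invariant", {
  b <- make_bundle(3L, 18L, 9.5)
  r <- align_structures(b, b)
  expect_equal(r$score, 1.0, tolerance = 1e-9)
  expect_equal(r$query_overlap, 1.0)
  expect_equal(r$rmsd, 0, tolerance = 1e-9)
  for (seed in c(2, 9)) {
    moved <- transform_model(b, random_rotation(seed), c(20, -7, 3))
    expect_equal(align_structures(b, moved)$score, 1.0, tolerance = 1e-6)
    expect_equal(align_structures(moved, b)$score, 1.0, tolerance = 1e-6)
  }
  expect_error(align_structures(make_ideal_helix(10), b), "20")
})

test_that("TM-score separates perturbed homologs from unrelated folds", {
  b <- make_bundle(3L, 18L, 9.5)
  # homologs: bounds verified empirically on this battery before assertion
  for (seed in 1:5)
    expect_gt(align_structures(b, perturb(b, 0.5, seed))$score, 0.8)
  expect_gt(align_structures(b, perturb(b, 1, 3))$score, 0.7)
  # unrelated architectures stay below the fold threshold
  others <- list(make_bundle(4L, 14L, 10), make_bundle(2L, 26L, 9),
                 make_bundle(5L, 12L, 10.5))
  for (o in others)
    expect_lt(align_structures(b, o)$score, 0.5)
  # normalising by the shorter chain makes swapped calls agree
  small <- make_bundle(2L, 20L, 9)
  ab <- align_structures(small, b, normalize = "shorter")
  ba <- align_structures(b, small, normalize = "shorter")
  expect_equal(ab$score, ba$score, tolerance = 0.05)
})

test_that("hit acceptance applies class-specific bitscore and overlap cuts", {
  mk <- function(score, type, overlap)
    comparison_result("q", "t", score, type, round(overlap * 100), 100, 100)
  thr <- assignment_thresholds()
  expect_true(accept_hit(mk(120, "bitscore", 0.7), 1, thr))
  expect_true(accept_hit(mk(120, "bitscore", 0.7), 3, thr))
  expect_false(accept_hit(mk(120, "bitscore", 0.7), 2, thr))   # needs 165
  expect_true(accept_hit(mk(165, "bitscore", 0.7), 2, thr))
  expect_false(accept_hit(mk(200, "bitscore", 0.5), 1, thr))   # overlap < 0.60
  expect_error(accept_hit(mk(200, "bitscore", 0.7), 4, thr), "class 4")
  # unknown class: strictest cut
  expect_false(accept_hit(mk(120, "bitscore", 0.7), NA, thr))
  expect_true(accept_hit(mk(170, "bitscore", 0.7), NA, thr))
  expect_true(accept_hit(mk(85, "ssap", 0.8), 1, thr))
  expect_false(accept_hit(mk(75, "ssap", 0.8), 1, thr))
  expect_true(accept_hit(mk(0.6, "tmscore", 0.9), 1, thr))
  expect_false(accept_hit(mk(0.45, "tmscore", 0.9), 1, thr))
})

test_that("library scans return the best accepted hit deterministically", {
  b <- make_bundle(3L, 18L, 9.5)
  lib <- domain_library(
    c(lapply(1:3, function(i) {
        m <- perturb(b, 0.4, i); m$protein_id <- paste0("copy", i); m
      }),
      lapply(1:4, function(i) {
        m <- make_bundle(4L, 13L + i, 10); m$protein_id <- paste0("far", i); m
      })),
    c(rep("1.10.10.10", 3), rep("3.40.10.10", 4)))
  # self in the library: maximal self-hit
  self_lib <- domain_library(list(b), "1.10.10.10", "self")
  hit <- scan_library(b, self_lib)
  expect_equal(hit$target_id, "self")
  expect_equal(hit$result$score, 1.0, tolerance = 1e-9)
  # best hit among mixed library is one of the perturbed copies
  hit2 <- scan_library(b, lib)
  expect_true(grepl("^copy", hit2$target_id))
  # impossible thresholds: empty result
  expect_null(scan_library(b, lib,
                           thresholds = assignment_thresholds(tm = 1.1)))
})

test_that("the cascade assigns at the right stage and audits its hits", {
  bench <- make_assignment_benchmark(n_sfams = 4L, n_reps = 2L,
                                     n_queries = 4L, n_decoys = 2L,
                                     sigma = 0.5, seed = 5L)
  thr <- assignment_thresholds()
  q <- bench$queries[[1]]
  # confident correct prediction: stage-1 assignment
  dec <- cascade_assign(q$model, prediction = q$prediction,
                        library = bench$library, thresholds = thr)
  expect_equal(dec$stage, "predicted_superfamily_scan")
  expect_equal(dec$assigned_superfamily, q$true_superfamily)
  # prediction below the probability cut is ignored; the all-superfamily
  # stage still recovers the assignment
  weak <- prediction_record(q$model$protein_id, q$true_superfamily, 0.2)
  dec2 <- cascade_assign(q$model, prediction = weak,
                         library = bench$library, thresholds = thr)
  expect_equal(dec2$stage, "all_scan")
  expect_equal(dec2$assigned_superfamily, q$true_superfamily)
  # unrelated decoy: unassigned everywhere
  dec3 <- cascade_assign(bench$decoys[[1]], library = bench$library,
                         thresholds = thr)
  expect_equal(dec3$stage, "unassigned")
  expect_equal(dec3$assigned_superfamily, "")
  # decisions never contradict accept_hit
  for (d in list(dec, dec2)) {
    expect_true(accept_hit(d$best_hit, sfam_class(d$assigned_superfamily),
                           thr))
  }
  # order robustness: shuffling the library leaves the superfamily fixed
  shuf <- unclass(bench$library)[rev(seq_along(bench$library))]
  class(shuf) <- "domain_library"
  dec4 <- cascade_assign(q$model, prediction = q$prediction, library = shuf,
                         thresholds = thr)
  expect_equal(dec4$assigned_superfamily, dec$assigned_superfamily)
})

test_that("a wrong but same-topology prediction is recovered by widening", {
  # two superfamilies under one topology code, with dissimilar geometry so
  # the scan of the wrongly predicted superfamily genuinely misses
  hairpin <- make_bundle(2L, 26L, 9, protein_id = "hp")
  five <- make_bundle(5L, 12L, 10.5, protein_id = "fv")
  lib <- domain_library(
    c(lapply(1:2, function(i) {
        m <- perturb(hairpin, 0.3, i); m$protein_id <- paste0("hp", i); m
      }),
      lapply(1:2, function(i) {
        m <- perturb(five, 0.3, i + 5); m$protein_id <- paste0("fv", i); m
      })),
    c(rep("1.10.10.10", 2), rep("1.10.10.20", 2)))
  q <- perturb(five, 0.5, 33)
  q$protein_id <- "query"
  wrong <- prediction_record("query", "1.10.10.10", 0.9)
  dec <- cascade_assign(q, prediction = wrong, library = lib)
  expect_equal(dec$stage, "class_scan")
  expect_equal(dec$stage_detail, "topology")
  expect_equal(dec$assigned_superfamily, "1.10.10.20")
})
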