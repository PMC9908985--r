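test_that("mean pLDDT is the arithmetic residue mean", {
  m <- inject_plddt(make_ideal_helix(10), 70)
  expect_equal(mean_plddt(m), 70)
  m2 <- inject_plddt(make_ideal_helix(10), rep(c(60, 80), 5))
  expect_equal(mean_plddt(m2), 70)
  set.seed(11)
  prof <- runif(100, 30, 100)
  m3 <- inject_plddt(make_ideal_helix(100), prof)
  expect_equal(mean_plddt(m3), sum(prof) / 100)
})

test_that("LUR detection finds maximal low-confidence runs of length >= 5", {
  s <- c(rep(80, 10), rep(60, 6), rep(90, 10))
  lurs <- find_lurs(s)
  expect_equal(nrow(lurs), 1L)
  expect_equal(lurs$start, 11L)
  expect_equal(lurs$length, 6L)
  # short dips are not LURs
  expect_equal(nrow(find_lurs(c(rep(90, 5), rep(50, 4), rep(90, 5)))), 0L)
  # brute-force equivalence on random profiles
  set.seed(7)
  for (i in 1:1000) {
    p <- sample(c(50, 65, 72, 95), sample(5:40, 1L), replace = TRUE)
    expect_identical(find_lurs(p), brute_lurs(p))
  }
})

test_that("the single-LUR rule is strict at 30%", {
  base <- make_bundle(4L, 24L, 9)   # 122 residues
  n <- n_residues(base)
  mk <- function(k) inject_plddt(base, c(rep(60, k), rep(95, n - k)))
  over <- ceiling(0.30 * n) + 1L    # just over 30%
  at <- floor(0.30 * n)             # at most 30%
  expect_equal(lur_verdict(mk(over)), "fail")
  expect_equal(lur_verdict(mk(at)), "pass")
  # two disjoint sub-threshold LURs do not fail
  two <- inject_plddt(base, c(rep(60, at %/% 2), rep(95, 10),
                              rep(60, at %/% 2),
                              rep(95, n - 2 * (at %/% 2) - 10)))
  expect_equal(lur_verdict(two), "pass")
})

test_that("secondary-structure assignment recovers planted geometry", {
  hel <- assign_ss(make_ideal_helix(20))
  expect_gte(sum(hel$per_residue == "H"), 16L)
  expect_equal(nrow(hel$elements), 1L)
  expect_equal(hel$elements$kind, "H")
  ext <- assign_ss(make_extended_chain(20))
  expect_true(all(ext$per_residue == "C"))
  sheet <- assign_ss(make_sheet(8))
  expect_equal(sheet$elements$kind[sheet$elements$kind == "E"],
               c("E", "E"))
  expect_gte(sum(sheet$per_residue == "E"), 6L)
})

test_that("order metrics count coil fraction and cleaned elements", {
  ann <- ss_annotation(paste0(strrep("H", 20), strrep("C", 60),
                              strrep("E", 20)), cleanup = FALSE)
  om <- order_metrics(ann)
  expect_equal(om$unordered_fraction, 0.60)
  expect_equal(om$n_sses, 2L)
  expect_equal(order_metrics(ss_annotation(strrep("C", 30))),
               list(unordered_fraction = 1.0, n_sses = 0L))
  # random annotations match an independent counter
  set.seed(5)
  for (i in 1:50) {
    s <- sample(c("H", "E", "C"), 60, replace = TRUE)
    om <- order_metrics(ss_annotation(s, cleanup = FALSE))
    expect_equal(om$unordered_fraction, sum(s == "C") / 60)
  }
  # cleanup: short elements dissolve, single gaps absorb
  cl <- ss_annotation("CCHHHCCEEECCHHHHHCHHCC")
  expect_equal(cl$per_residue[3:5], rep("C", 3))   # 3-helix too short
  expect_equal(cl$elements$kind, c("E", "H"))
})

test_that("packing density equals all-pairs brute force", {
  # two isolated hydrophobic residues far apart
  far <- structure_model("far",
    data.frame(seq_index = 1:2, aa = "L", plddt = 90),
    data.frame(seq_index = 1:2, name = "CA", element = "C",
               x = c(0, 50), y = 0, z = 0))
  expect_equal(packing_density(far), 0)
  # three mutually close hydrophobic residues: complete graph
  tri <- structure_model("tri",
    data.frame(seq_index = 1:3, aa = "V", plddt = 90),
    data.frame(seq_index = 1:3, name = "CA", element = "C",
               x = c(0, 3, 1.5), y = c(0, 0, 2.5), z = 0))
  expect_equal(packing_density(tri), 2)
  expect_error(packing_density(structure_model("g",
    data.frame(seq_index = 1L, aa = "G", plddt = 90),
    data.frame(seq_index = 1L, name = "CA", element = "C",
               x = 0, y = 0, z = 0))), "hydrophobic")
  # spatial-index implementation vs O(n^2) oracle, exact equality
  for (seed in 1:100) {
    m <- random_blob_model(sample(15:35, 1L), seed)
    expect_equal(packing_density(m), brute_packing(m))
  }
})

test_that("grid SES recovers the sphere closed form and converges", {
  one <- list(atoms = data.frame(seq_index = 1L, name = "CA", element = "C",
                                 x = 0, y = 0, z = 0))
  s <- ses_area_volume(one, probe_radius = 0, voxel = 0.5, radii = 3)
  expect_equal(s$ses_per_volume, 1, tolerance = 0.05)  # area/volume = 3/r
  expect_equal(s$area, 4 * pi * 9, tolerance = 0.05)
  expect_equal(s$volume, 4 / 3 * pi * 27, tolerance = 0.05)
  # self-convergence under voxel refinement on a real fixture; the volume
  # converges tightly, the area more slowly because the inter-helix grooves
  # of a backbone-only model sit near the grid resolution
  b <- make_bundle(3L, 14L, 9)
  c1 <- ses_area_volume(b, voxel = 0.5)
  c2 <- ses_area_volume(b, voxel = 0.25)
  expect_lt(abs(c1$volume - c2$volume) / c2$volume, 0.03)
  expect_lt(abs(c1$area - c2$area) / c2$area, 0.08)
  # extended shapes have a strictly larger quotient than compact ones
  helix80 <- make_ideal_helix(80)
  bundle80 <- make_bundle(4L, 17L, 9)
  expect_gt(ses_area_volume(helix80)$ses_per_volume,
            ses_area_volume(bundle80)$ses_per_volume)
  expect_error(ses_area_volume(structure_model("d",
    data.frame(seq_index = 1:2, aa = "A", plddt = 90),
    data.frame(seq_index = 1:2, name = "CA", element = "C",
               x = 0, y = 0, z = 0))), "degenerate")
})

test_that("threshold calibration matches the order-statistics oracle", {
  mk <- function(pd, sv) data.frame(packing_density = pd, ses_per_volume = sv)
  thr <- calibrate_thresholds(mk(1:100, (1:100) / 100))
  expect_equal(thr$max_ses_per_volume,
               unname(quantile((1:100) / 100, 0.95, type = 7)))
  expect_equal(thr$max_ses_per_volume, 0.9505)
  expect_equal(thr$min_packing_density,
               unname(quantile(1:100, 0.05, type = 7)))
  # constant reference: threshold equals the constant
  thr2 <- calibrate_thresholds(mk(rep(7, 30), rep(0.4, 30)))
  expect_equal(thr2$min_packing_density, 7)
  expect_equal(thr2$max_ses_per_volume, 0.4)
  expect_error(calibrate_thresholds(mk(1:5, 1:5)), "at least 20")
  # uncalibrated defaults are the published values
  def <- default_thresholds()
  expect_equal(def$min_packing_density, 9.75)
  expect_equal(def$max_ses_per_volume, 0.494)
  expect_equal(def$min_mean_plddt, 70)
})

test_that("percentile-1 calibration passes every reference structure", {
  set.seed(31)
  ref <- data.frame(packing_density = runif(50, 5, 15),
                    ses_per_volume = runif(50, 0.3, 0.6))
  thr <- calibrate_thresholds(ref, percentile = 1.0)
  expect_true(all(ref$packing_density >= thr$min_packing_density))
  expect_true(all(ref$ses_per_volume <= thr$max_ses_per_volume))
})

test_that("qc verdict applies every rule and records all failures", {
  pass <- compact_pass_model()
  thr <- calibrated_thr()
  r <- qc_report(pass, thr)
  expect_equal(r$verdict, "pass")
  expect_length(r$failed_rules, 0L)
  expect_gte(r$n_sses, 3L)
  # low confidence fails both the mean and the LUR rule
  low <- inject_plddt(pass, 55)
  rl <- qc_report(low, thr)
  expect_setequal(rl$failed_rules,
                  c("min_mean_plddt", "max_single_lur_fraction"))
  # ses_per_volume consistency invariant
  expect_equal(r$ses_per_volume, r$ses_area / r$ses_volume)
})

test_that("qc verdict is monotone in the thresholds", {
  m <- inject_plddt(compact_pass_model(),
                    c(rep(62, 30), rep(92, n_residues(compact_pass_model()) - 30)))
  thr <- default_thresholds()
  r1 <- qc_report(m, thr)
  # relaxing every cut can only turn failures into passes
  thr2 <- thr
  thr2$min_mean_plddt <- 0
  thr2$max_single_lur_fraction <- 1
  thr2$max_unordered_fraction <- 1
  thr2$min_residues <- 1L
  thr2$min_sses <- 0L
  thr2$min_packing_density <- 0
  thr2$max_ses_per_volume <- Inf
  r2 <- qc_report(m, thr2)
  expect_true(all(r2$failed_rules %in% r1$failed_rules))
  expect_equal(r2$verdict, "pass")
})
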