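test_that("sequence_md5 matches an independent MD5 and is injective in practice", {
  # independent oracle: base R file-level md5sum over the exact bytes
  oracle <- function(s) {
    f <- tempfile()
    writeBin(charToRaw(s), f)
    unname(tools::md5sum(f))
  }
  expect_identical(sequence_md5("A"), oracle("A"))
  expect_identical(sequence_md5("ACDEFGHIKLMNPQRSTVWY"),
                   oracle("ACDEFGHIKLMNPQRSTVWY"))
  expect_identical(sequence_md5("MKV"), sequence_md5("MKV"))
  expect_false(sequence_md5("MKV") == sequence_md5("MKL"))
  expect_error(sequence_md5(""), "non-empty")
  # no collision over a battery of random distinct sequences
  set.seed(42)
  seqs <- unique(vapply(1:2000, function(i)
    paste(sample(LETTERS[1:20], 30, replace = TRUE), collapse = ""), ""))
  digests <- vapply(seqs, sequence_md5, "")
  expect_equal(anyDuplicated(digests), 0L)
})

test_that("write + parse round-trips a model field-identically", {
  m <- make_ideal_helix(15, protein_id = "P12345")
  f <- tempfile(fileext = ".pdb")
  write_domain(m, NULL, f, metadata = list(domain_md5 = "abc123"))
  expect_true(any(grepl("abc123", readLines(f), fixed = TRUE)))
  m2 <- parse_model(f, "P12345")
  expect_equal(m2$residues$seq_index, m$residues$seq_index)
  expect_equal(m2$residues$aa, m$residues$aa)
  expect_equal(m2$residues$plddt, m$residues$plddt, tolerance = 1e-6)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  # coordinates survive to PDB precision (3 decimals)
  expect_equal(ca_coords(m2), ca_coords(m), tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("parse ignores non-ATOM records and reads pLDDT from the CA B-factor", {
  m <- make_ideal_helix(10, plddt = 88)
  f <- tempfile(fileext = ".pdb")
  write_domain(m, NULL, f)
  lines <- readLines(f)
  body <- lines[startsWith(lines, "ATOM")]
  # interleave HETATM and extra TER records
  noisy <- c("HEADER    SYNTHETIC", body[1:10],
             "HETATM    1  O   HOH A 900      10.000  10.000  10.000  1.00  0.00           O",
             "TER", body[-(1:10)], "TER", "END")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(noisy, f2)
  m1 <- parse_model(f, "X"); m2 <- parse_model(f2, "X")
  expect_equal(m2$residues, m1$residues)
  expect_equal(m2$atoms, m1$atoms)
  expect_true(all(m2$residues$plddt == 88))
})

test_that("parse rejects pathological input with clear errors", {
  m <- make_ideal_helix(8)
  f <- tempfile(fileext = ".pdb")
  write_domain(m, NULL, f)
  lines <- readLines(f)
  # drop the CA of residue 3
  drop_ca <- lines[!(grepl("^ATOM", lines) & grepl(" CA ", lines) &
                       substr(lines, 23, 26) == "   3")]
  f2 <- tempfile(fileext = ".pdb"); writeLines(drop_ca, f2)
  expect_error(parse_model(f2), "CA")
  # second chain: flip the chain id (column 22) of the last residue's atoms
  two_chain <- lines
  atom_idx <- which(grepl("^ATOM", two_chain) &
                      substr(two_chain, 23, 26) == "   8")
  for (k in atom_idx) substr(two_chain[k], 22, 22) <- "B"
  f3 <- tempfile(fileext = ".pdb"); writeLines(two_chain, f3)
  expect_error(parse_model(f3), "chain")
})

test_that("hit tables parse segment strings and reject malformed rows", {
  f <- tempfile()
  writeLines(c("P1\t1.10.10.10\t55.5\t12-110",
               "P1\tPF00001\t40\t5-60,80-140\tPfam"), f)
  hits <- load_hits(f)
  expect_length(hits, 2L)
  expect_equal(hits[[1]]$segments, cbind(start = 12L, stop = 110L))
  expect_equal(hit_length(hits[[1]]), 99L)
  expect_equal(nrow(hits[[2]]$segments), 2L)
  expect_equal(hit_length(hits[[2]]), 117L)
  expect_equal(hits[[2]]$source, "Pfam")
  writeLines("P1\tF\t10\t60-5", f)
  expect_error(load_hits(f), "row 1")
  writeLines("P1\tF\t10\t5-60,50-90", f)
  expect_error(load_hits(f), "overlap")
  writeLines("P1\tF\tten\t5-60", f)
  expect_error(load_hits(f), "score")
  # round trip
  writeLines(c("P1\t1.10.10.10\t55.5\t12-110",
               "P1\tPF00001\t40\t5-60,80-140\tPfam"), f)
  hits <- load_hits(f)
  f2 <- tempfile(); write_hits(hits, f2)
  expect_equal(load_hits(f2), hits)
})

test_that("fragment layouts follow the 1400/200 overlapping-window scheme", {
  fs <- fragment_set("P", 2700L)
  fr <- fs$fragments
  # regular starts step by 200 while the window fits, plus a terminal window
  expect_equal(fr$first_residue[1:7], seq(1L, 1201L, by = 200L))
  expect_equal(fr$last_residue[nrow(fr)], 2700L)
  expect_equal(fr$first_residue[nrow(fr)], 1301L)
  expect_true(all(fr$last_residue - fr$first_residue + 1L == 1400L))
  # consecutive overlap and full coverage
  expect_true(all(diff(fr$first_residue) <= 200L))
  covered <- sort(unique(unlist(Map(seq.int, fr$first_residue,
                                    fr$last_residue))))
  expect_equal(covered, 1:2700)
  # short protein: single fragment
  fs1 <- fragment_set("P", 300L)
  expect_equal(nrow(fs1$fragments), 1L)
  expect_equal(fs1$fragments$last_residue, 300L)
})
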