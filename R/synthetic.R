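#' @name synthetic
#' @title Deterministic synthetic structure fixtures
#' @description Generators for every fixture class the pipeline needs:
#' ideal secondary-structure geometry, compact and non-globular domains,
#' pLDDT profiles, perturbed homolog pairs, fragmented long proteins, hit
#' tables and prediction records -- each with recorded ground truth, and
#' byte-identical under a fixed seed. Side chains are approximated by an
#' ideally placed CB; inter-element loops are interpolated coil, not
#' physically valid geometry, so secondary-structure assertions should
#' target element cores.
NULL

deg <- function(x) x * pi / 180

vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

vnorm <- function(a) a / sqrt(sum(a^2))

# NeRF atom placement: d at distance `bond` from c, angle b-c-d, torsion a-b-c-d
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg(angle); chi <- deg(torsion)
  bc <- vnorm(c - b)
  n <- vnorm(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi), bond * sin(th) * sin(chi))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

# ideal backbone from phi/psi torsions; returns per-residue N/CA/C/O/CB coords
build_backbone <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(180, n)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- deg(111.2)
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7,
                              omega[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.2,
                             phi[i + 1])
  }
  for (i in seq_len(n))
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.5,
                         (if (i < n) psi[i] else psi[n]) + 180)
  for (i in seq_len(n)) {
    b1 <- vnorm(N[i, ] - CA[i, ])
    b2 <- vnorm(C[i, ] - CA[i, ])
    CB[i, ] <- CA[i, ] + 1.53 * (-0.620 * vnorm(b1 + b2) +
                                 0.785 * vnorm(vcross(b1, b2)))
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

# assemble a structure_model from backbone coordinate blocks
backbone_model <- function(bb, sequence, protein_id, plddt = 90,
                           first_residue = 1L, fragment_index = 1L) {
  n <- nrow(bb$N)
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == n)
  if (length(plddt) == 1L) plddt <- rep(plddt, n)
  seqi <- seq.int(first_residue, length.out = n)
  blocks <- list(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  rows <- list()
  for (i in seq_len(n)) {
    for (nm in c("N", "CA", "C", "O", "CB")) {
      if (nm == "CB" && aa[i] == "G") next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_index = seqi[i], name = nm, element = blocks[[nm]],
        x = bb[[nm]][i, 1], y = bb[[nm]][i, 2], z = bb[[nm]][i, 3])
    }
  }
  atoms <- do.call(rbind, rows)
  residues <- data.frame(seq_index = seqi, aa = aa, plddt = plddt)
  structure_model(protein_id, residues, atoms, fragment_index)
}

hydrophobic_seq <- function(n) {
  paste(rep_len(strsplit("AVLEKIMSAF", "")[[1]], n), collapse = "")
}

#' Ideal alpha-helix model
#'
#' Canonical helical torsions (phi -57, psi -47) with full N/CA/C/O (+CB)
#' backbone, so the hydrogen-bond secondary-structure assigner labels it H.
#' Deterministic: the same arguments always give identical coordinates.
#'
#' @param n residues (>= 5).
#' @param seed kept in the fixture provenance (the builder itself is
#'   deterministic).
#' @param protein_id,plddt,first_residue passed to the model.
#' @export
make_ideal_helix <- function(n, seed = 1L, protein_id = "helix", plddt = 90,
                             first_residue = 1L) {
  if (n < 5L) stop("a helix fixture needs at least 5 residues")
  bb <- build_backbone(rep(-57, n), rep(-47, n))
  backbone_model(bb, hydrophobic_seq(n), protein_id, plddt, first_residue)
}

#' Ideal extended (beta) chain
#'
#' Classic antiparallel-strand torsions (phi -139, psi 135). On its own it
#' has no hydrogen-bond partner, so the assigner reports coil.
#'
#' @inheritParams make_ideal_helix
#' @export
make_extended_chain <- function(n, seed = 1L, protein_id = "strand",
                                plddt = 90, first_residue = 1L) {
  if (n < 3L) stop("need at least 3 residues")
  bb <- build_backbone(rep(-139, n), rep(135, n))
  backbone_model(bb, hydrophobic_seq(n), protein_id, plddt, first_residue)
}

rot_x180 <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3)

#' Apply a rigid transform to a model
#' @param model a `structure_model`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 shift, Angstrom.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% rotation
  xyz <- sweep(xyz, 2, translation, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- vnorm(a); b <- vnorm(b)
  v <- vcross(a, b); s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) return(if (cth > 0) diag(3) else rot_x180)
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# straight interpolated coil between two anchor points; non-physical by design
loop_atoms <- function(from, to, n_loop, seq_start) {
  dir <- to - from
  len <- sqrt(sum(dir^2))
  dir <- dir / max(len, 1e-9)
  perp <- vnorm(vcross(dir, if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  rows <- list()
  for (k in seq_len(n_loop)) {
    t <- k / (n_loop + 1)
    ca <- from + dir * (len * t) + perp * 1.2 * sin(pi * t)
    nn <- ca - dir * 0.75
    cc <- ca + dir * 0.75
    oo <- cc + perp * 1.23
    for (p in list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"))) {
      xyz <- switch(p[1], N = nn, CA = ca, C = cc, O = oo)
      rows[[length(rows) + 1L]] <- data.frame(
        seq_index = seq_start + k - 1L, name = p[1], element = p[2],
        x = xyz[1], y = xyz[2], z = xyz[3])
    }
  }
  do.call(rbind, rows)
}

#' Helix-bundle model
#'
#' `n_helices` ideal helices with axes parallel to z, placed on a regular
#' polygon with side `packing_distance` Angstrom, alternating direction,
#' joined by interpolated coil loops. At separations around 10 A this gives
#' a compact, QC-passing domain; at 25 A or more the helices are too far
#' apart to touch, a planted packing-density failure.
#'
#' @param n_helices >= 2.
#' @param len residues per helix.
#' @param packing_distance axis separation, Angstrom (>= 4; closer would
#'   clash).
#' @param seed provenance only; construction is deterministic.
#' @param protein_id,plddt model metadata.
#' @export
make_bundle <- function(n_helices = 3L, len = 20L, packing_distance = 10,
                        seed = 1L, protein_id = "bundle", plddt = 90) {
  if (n_helices < 2L) stop("need at least 2 helices")
  if (packing_distance < 4) stop("helix separation below 4 A would clash")
  bb <- build_backbone(rep(-57, len), rep(-47, len))
  # align the helix axis with z, centre at the origin
  axis <- vnorm(bb$CA[len, ] - bb$CA[1, ])
  R <- rotation_between(axis, c(0, 0, 1))
  centre <- colMeans(bb$CA)
  blocks <- lapply(bb, function(m) sweep(m, 2, centre) %*% R)
  radius <- if (n_helices == 2L) packing_distance / 2 else
    packing_distance / (2 * sin(pi / n_helices))
  helix_sets <- list()
  for (h in seq_len(n_helices)) {
    th <- 2 * pi * (h - 1) / n_helices
    shift <- c(radius * cos(th), radius * sin(th), 0)
    hb <- blocks
    if (h %% 2L == 0L) hb <- lapply(hb, function(m) m %*% rot_x180)
    hb <- lapply(hb, function(m) sweep(m, 2, shift, "+"))
    helix_sets[[h]] <- hb
  }
  # assemble: helix, loop, helix, ...
  atoms <- list(); aa <- character(0); next_res <- 1L
  helix_res <- strsplit(hydrophobic_seq(len), "")[[1]]
  for (h in seq_len(n_helices)) {
    hb <- helix_sets[[h]]
    seqi <- seq.int(next_res, length.out = len)
    for (i in seq_len(len))
      for (nm in c("N", "CA", "C", "O", "CB"))
        atoms[[length(atoms) + 1L]] <- data.frame(
          seq_index = seqi[i], name = nm,
          element = c(N = "N", CA = "C", C = "C", O = "O", CB = "C")[[nm]],
          x = hb[[nm]][i, 1], y = hb[[nm]][i, 2], z = hb[[nm]][i, 3])
    aa <- c(aa, helix_res)
    next_res <- next_res + len
    if (h < n_helices) {
      from <- hb$C[len, ]
      to <- helix_sets[[h + 1L]]$N[1, ]
      n_loop <- max(2L, round(sqrt(sum((to - from)^2)) / 3.3))
      atoms[[length(atoms) + 1L]] <- loop_atoms(from, to, n_loop, next_res)
      aa <- c(aa, rep("G", n_loop))
      next_res <- next_res + n_loop
    }
  }
  atoms <- do.call(rbind, atoms)
  n <- next_res - 1L
  if (length(plddt) == 1L) plddt <- rep(plddt, n)
  residues <- data.frame(seq_index = seq_len(n), aa = aa, plddt = plddt)
  structure_model(protein_id, residues, atoms)
}

#' Two-strand antiparallel sheet model
#'
#' One ideal strand plus an antiparallel copy placed at hydrogen-bonding
#' separation, joined by an interpolated loop, so the assigner reports two
#' strand elements.
#'
#' @param strand_len residues per strand.
#' @param seed provenance only.
#' @param protein_id,plddt model metadata.
#' @export
make_sheet <- function(strand_len = 8L, seed = 1L, protein_id = "sheet",
                       plddt = 90) {
  n <- strand_len
  bb <- build_backbone(rep(-120, n), rep(120, n))
  axis <- vnorm(bb$CA[n, ] - bb$CA[1, ])
  R <- rotation_between(axis, c(1, 0, 0))
  centre <- colMeans(bb$CA)
  s1 <- lapply(bb, function(m) sweep(m, 2, centre) %*% R)
  # antiparallel partner: flip about x and offset (tuned for the H-bond ladder)
  s2 <- lapply(s1, function(m) sweep(m %*% rot_x180, 2,
                                     c(SHEET_DX, SHEET_DY, 0), "+"))
  atoms <- list(); next_res <- 1L
  add_strand <- function(sb) {
    seqi <- seq.int(next_res, length.out = n)
    for (i in seq_len(n))
      for (nm in c("N", "CA", "C", "O", "CB"))
        atoms[[length(atoms) + 1L]] <<- data.frame(
          seq_index = seqi[i], name = nm,
          element = c(N = "N", CA = "C", C = "C", O = "O", CB = "C")[[nm]],
          x = sb[[nm]][i, 1], y = sb[[nm]][i, 2], z = sb[[nm]][i, 3])
    next_res <<- next_res + n
  }
  add_strand(s1)
  from <- s1$C[n, ]; to <- s2$N[1, ]
  n_loop <- max(2L, round(sqrt(sum((to - from)^2)) / 3.3))
  atoms[[length(atoms) + 1L]] <- loop_atoms(from, to, n_loop, next_res)
  next_res <- next_res + n_loop
  add_strand(s2)
  atoms <- do.call(rbind, atoms)
  total <- next_res - 1L
  aa <- c(strsplit(hydrophobic_seq(n), "")[[1]], rep("G", n_loop),
          strsplit(hydrophobic_seq(n), "")[[1]])
  if (length(plddt) == 1L) plddt <- rep(plddt, total)
  residues <- data.frame(seq_index = seq_len(total), aa = aa, plddt = plddt)
  structure_model(protein_id, residues, atoms)
}

#' Gaussian coordinate perturbation
#'
#' Adds isotropic Gaussian displacement (sigma per coordinate, Angstrom) to
#' every atom; sequence, numbering and pLDDT are unchanged. Used to make
#' structural homolog pairs of controlled similarity.
#'
#' With `smooth = 0` (the default) every atom moves independently. A
#' positive `smooth` draws one displacement per residue and averages it
#' over a window of that half-width along the sequence (rescaled so the
#' per-coordinate standard deviation stays `sigma`): neighbouring residues
#' then move together, which preserves local backbone geometry -- closer
#' to how real homologs differ, and kinder to hydrogen-bond-based
#' secondary-structure assignment.
#'
#' @param model a `structure_model`.
#' @param sigma standard deviation per coordinate.
#' @param seed RNG seed (the caller's RNG state is restored).
#' @param smooth half-width (residues) of sequence smoothing; 0 for
#'   independent atomic noise.
#' @export
perturb <- function(model, sigma, seed = 1L, smooth = 0L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(model)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (smooth <= 0L) {
    na <- nrow(model$atoms)
    model$atoms$x <- model$atoms$x + rnorm(na, 0, sigma)
    model$atoms$y <- model$atoms$y + rnorm(na, 0, sigma)
    model$atoms$z <- model$atoms$z + rnorm(na, 0, sigma)
    return(model)
  }
  n <- n_residues(model)
  g <- matrix(rnorm(n * 3), n, 3)
  w <- seq.int(-smooth, smooth)
  kern <- exp(-(w / max(smooth / 1.5, 1))^2 / 2)
  kern <- kern / sum(kern)
  sm <- apply(g, 2, function(col) {
    padded <- c(rep(col[1], smooth), col, rep(col[n], smooth))
    stats::filter(padded, kern, sides = 2)[(smooth + 1):(smooth + n)]
  })
  sm <- sm * sigma / sqrt(sum(kern^2))   # restore the marginal sd
  idx <- match(model$atoms$seq_index, model$residues$seq_index)
  model$atoms$x <- model$atoms$x + sm[idx, 1]
  model$atoms$y <- model$atoms$y + sm[idx, 2]
  model$atoms$z <- model$atoms$z + sm[idx, 3]
  model
}

#' Overwrite the pLDDT profile of a model
#' @param model a `structure_model`.
#' @param profile scalar or per-residue numeric vector in [0, 100].
#' @export
inject_plddt <- function(model, profile) {
  n <- n_residues(model)
  if (length(profile) == 1L) profile <- rep(profile, n)
  if (length(profile) != n)
    stop("profile length ", length(profile), " != ", n, " residues")
  model$residues$plddt <- profile
  model
}

#' Concatenate two models into one chain
#'
#' Places `b` after `a` along x with a spacer gap and renumbers its
#' residues to continue `a`'s numbering; used to build multidomain
#' fixtures.
#'
#' @param a,b `structure_model`s.
#' @param spacer gap between bounding boxes, Angstrom.
#' @param protein_id id of the combined model.
#' @export
concat_models <- function(a, b, spacer = 6, protein_id = NULL) {
  if (is.null(protein_id)) protein_id <- paste0(a$protein_id, "+", b$protein_id)
  shift <- c(max(a$atoms$x) - min(b$atoms$x) + spacer, 0, 0)
  b <- transform_model(b, diag(3), shift)
  off <- max(a$residues$seq_index)
  b$residues$seq_index <- b$residues$seq_index -
    min(b$residues$seq_index) + off + 1L
  b$atoms$seq_index <- b$atoms$seq_index - min(b$atoms$seq_index) + off + 1L
  structure_model(protein_id, rbind(a$residues, b$residues),
                  rbind(a$atoms, b$atoms))
}

#' Fragmented long protein with planted domains
#'
#' Emulates the overlapping-window prediction scheme for proteins longer
#' than one window: builds the fragment layout, one helical model per
#' fragment (numbered in protein coordinates), a hit table matching the
#' planted domain layout, and ground truth recording which fragments fully
#' contain each planted domain (and which, by the centre-closest rule,
#' should be chosen for chopping).
#'
#' @param protein_length total residues (> 1400 to exercise fragmentation).
#' @param domain_layout data.frame with columns `start`, `stop` and
#'   optionally `family_id`, `score`.
#' @param seed provenance only.
#' @param protein_id accession.
#' @return list with `fragset`, `models` (one per fragment), `hits` and
#'   `ground_truth` (data.frame: start, stop, containing_fragments,
#'   true_fragment -- NA when unchoppable).
#' @export
make_fragmented_protein <- function(protein_length, domain_layout,
                                    seed = 1L, protein_id = "longprot") {
  fs <- fragment_set(protein_id, protein_length)
  models <- lapply(seq_len(nrow(fs$fragments)), function(i) {
    fr <- fs$fragments[i, ]
    make_ideal_helix(fr$last_residue - fr$first_residue + 1L, seed,
                     protein_id, plddt = 90,
                     first_residue = fr$first_residue)
  })
  for (i in seq_along(models)) models[[i]]$fragment_index <- i
  if (is.null(domain_layout$family_id))
    domain_layout$family_id <- sprintf("FAM%d", seq_len(nrow(domain_layout)))
  if (is.null(domain_layout$score))
    domain_layout$score <- 100
  hits <- lapply(seq_len(nrow(domain_layout)), function(i)
    domain_hit(protein_id, "Pfam", domain_layout$family_id[i],
               c(domain_layout$start[i], domain_layout$stop[i]),
               domain_layout$score[i]))
  gt <- do.call(rbind, lapply(seq_len(nrow(domain_layout)), function(i) {
    lo <- domain_layout$start[i]; hi <- domain_layout$stop[i]
    fr <- fs$fragments
    contains <- which(fr$first_residue <= lo & fr$last_residue >= hi)
    truef <- if (length(contains) == 0L) NA_integer_ else {
      centre <- (lo + hi) / 2
      d <- abs((fr$first_residue[contains] + fr$last_residue[contains]) / 2 -
               centre)
      contains[order(d, contains)][1L]
    }
    data.frame(start = lo, stop = hi,
               containing_fragments = paste(contains, collapse = ","),
               true_fragment = truef)
  }))
  list(fragset = fs, models = models, hits = hits, ground_truth = gt)
}

# deterministic fold vocabulary for benchmark libraries: each entry is a
# geometrically distinct bundle/sheet architecture with a CATH-style code
fold_specs <- function() {
  # the first six architectures stay compact (>= 3 helices, tight packing)
  # so they can double as QC-passing pipeline inputs; the tail adds hairpin
  # and loosely packed folds for assignment-only batteries
  list(
    list(code = "1.10.10.10", n = 3L, len = 18L, sep = 9.5),
    list(code = "1.10.20.10", n = 4L, len = 14L, sep = 10.0),
    list(code = "1.20.30.10", n = 5L, len = 12L, sep = 10.5),
    list(code = "1.20.40.10", n = 4L, len = 20L, sep = 9.0),
    list(code = "1.10.10.20", n = 3L, len = 24L, sep = 10.0),
    list(code = "2.30.10.10", n = 5L, len = 16L, sep = 9.5),
    list(code = "1.20.10.10", n = 2L, len = 26L, sep = 9.0),
    list(code = "2.10.10.10", n = 2L, len = 18L, sep = 11.5),
    list(code = "3.10.10.10", n = 3L, len = 14L, sep = 12.5),
    list(code = "3.40.10.10", n = 4L, len = 24L, sep = 11.5))
}

#' Benchmark library of labelled folds with queries and decoys
#'
#' Generates `n_sfams` geometrically distinct fold templates (labelled with
#' CATH-style codes), `n_reps` perturbed representatives per superfamily,
#' `n_queries` query domains (each a sigma-perturbed copy of a template,
#' with a prediction record), and `n_decoys` unrelated decoys (bundles
#' with geometries absent from the library). Ground truth records the true
#' superfamily of every query and that decoys have none.
#'
#' @param n_sfams superfamilies (<= 10).
#' @param n_reps representatives per superfamily.
#' @param n_queries query domains.
#' @param n_decoys unrelated decoys.
#' @param sigma coordinate noise for queries/representatives, Angstrom.
#' @param seed master seed; every member derives its own sub-seed.
#' @param smooth sequence-correlation half-width for the noise (see
#'   [perturb()]); 0 for independent atomic noise.
#' @return list with `library` ([domain_library()]), `queries` (list of
#'   model/prediction/true_superfamily), `decoys` (list of models).
#' @export
make_assignment_benchmark <- function(n_sfams = 10L, n_reps = 3L,
                                      n_queries = 30L, n_decoys = 10L,
                                      sigma = 0.5, seed = 1L, smooth = 0L) {
  specs <- head(fold_specs(), n_sfams)
  templates <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    make_bundle(s$n, s$len, s$sep, protein_id = sprintf("tpl%02d", i))
  })
  lib_models <- list(); lib_labels <- character(0); lib_ids <- character(0)
  for (i in seq_along(specs)) {
    for (r in seq_len(n_reps)) {
      m <- perturb(templates[[i]], 0.3, seed = seed * 1000L + i * 10L + r,
                   smooth = smooth)
      m$protein_id <- sprintf("rep%02d_%d", i, r)
      lib_models[[length(lib_models) + 1L]] <- m
      lib_labels <- c(lib_labels, specs[[i]]$code)
      lib_ids <- c(lib_ids, m$protein_id)
    }
  }
  library <- domain_library(lib_models, lib_labels, lib_ids)
  queries <- lapply(seq_len(n_queries), function(q) {
    i <- ((q - 1L) %% length(specs)) + 1L
    m <- perturb(templates[[i]], sigma, seed = seed * 2000L + q,
                 smooth = smooth)
    m$protein_id <- sprintf("query%02d", q)
    list(model = m,
         prediction = prediction_record(m$protein_id, specs[[i]]$code, 0.9),
         true_superfamily = specs[[i]]$code)
  })
  # decoy geometries disjoint from the library vocabulary
  decoy_specs <- list(
    list(n = 2L, len = 40L, sep = 18), list(n = 6L, len = 10L, sep = 14),
    list(n = 8L, len = 11L, sep = 14), list(n = 7L, len = 9L, sep = 13),
    list(n = 3L, len = 34L, sep = 17), list(n = 6L, len = 13L, sep = 16),
    list(n = 2L, len = 32L, sep = 22), list(n = 5L, len = 24L, sep = 15),
    list(n = 4L, len = 9L, sep = 19), list(n = 7L, len = 14L, sep = 18))
  decoys <- lapply(seq_len(n_decoys), function(d) {
    s <- decoy_specs[[((d - 1L) %% length(decoy_specs)) + 1L]]
    m <- make_bundle(s$n, s$len, s$sep, protein_id = sprintf("decoy%02d", d))
    perturb(m, 0.3, seed = seed * 3000L + d)
  })
  list(library = library, queries = queries, decoys = decoys)
}

#' Write a fixture ground-truth manifest as JSON
#' @param truth any list/data.frame of ground-truth records.
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
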