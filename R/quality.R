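#' Default quality-control thresholds
#'
#' The filter battery applied to every chopped domain before superfamily
#' assignment: minimum mean pLDDT 70 (the predictor's "confident" band);
#' long unordered regions (LURs) are runs of at least `lur_min_len` residues
#' with pLDDT below `lur_plddt_cut`, and a domain fails when a single LUR
#' holds more than 30% of its residues; more than 65% of residues outside
#' secondary-structure elements fails; domains must have at least 40 residues
#' and 3 secondary-structure elements; and the two globularity metrics must
#' look like curated globular domains: the hydrophobic packing density must
#' not fall BELOW its cut (sparse, poorly packed models fail) and the SES
#' area per volume must not rise ABOVE its cut (extended, stringy models
#' fail). The shipped globularity defaults (9.75 and 0.494) are the
#' published calibration values, set so that the top 95% of a curated
#' domain reference passes each rule; because both metrics are
#' implementation-coupled, recalibrating on a reference set via
#' [calibrate_thresholds()] is the recommended path.
#'
#' "More than 30%" and "more than 65%" are strict inequalities; the pLDDT
#' rule uses >= 70 and the size rules use >= 40 residues / >= 3 elements.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(min_mean_plddt = 70,
       lur_min_len = 5L,
       lur_plddt_cut = 70,
       max_single_lur_fraction = 0.30,
       max_unordered_fraction = 0.65,
       min_residues = 40L,
       min_sses = 3L,
       min_packing_density = 9.75,
       max_ses_per_volume = 0.494,
       calibration_percentile = 0.95)
}

#' Mean pLDDT of a model
#' @param model a `structure_model`.
#' @export
mean_plddt <- function(model) {
  if (n_residues(model) < 1L) stop("empty model")
  mean(model$residues$plddt)
}

#' Find long unordered regions in a pLDDT series
#'
#' A LUR is a maximal run of at least `min_len` consecutive residues with
#' pLDDT below `cut`. Shorter low-confidence runs are not LURs.
#'
#' @param plddt numeric vector aligned to residues.
#' @param min_len minimum run length (default 5).
#' @param cut pLDDT cutoff (default 70, strict `<`).
#' @return data.frame with columns `start`, `stop`, `length` (1-based
#'   positions in the series).
#' @export
find_lurs <- function(plddt, min_len = 5L, cut = 70) {
  low <- plddt < cut
  r <- rle(low)
  stop_pos <- cumsum(r$lengths)
  start_pos <- stop_pos - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = start_pos[keep], stop = stop_pos[keep],
             length = r$lengths[keep])
}

#' Largest fraction of residues in a single LUR
#' @param model a `structure_model`.
#' @param thresholds see [default_thresholds()].
#' @export
max_single_lur_fraction <- function(model, thresholds = default_thresholds()) {
  lurs <- find_lurs(model$residues$plddt, thresholds$lur_min_len,
                    thresholds$lur_plddt_cut)
  if (nrow(lurs) == 0L) return(0)
  max(lurs$length) / n_residues(model)
}

#' LUR verdict for a domain
#'
#' Fails when more than `max_single_lur_fraction` (default 30%) of the
#' residues fall in one single LUR; several smaller LURs do not fail.
#'
#' @inheritParams max_single_lur_fraction
#' @return "pass" or "fail".
#' @export
lur_verdict <- function(model, thresholds = default_thresholds()) {
  if (max_single_lur_fraction(model, thresholds) >
      thresholds$max_single_lur_fraction) "fail" else "pass"
}

backbone_coords <- function(model, name) {
  at <- model$atoms[model$atoms$name == name, ]
  idx <- match(model$residues$seq_index, at$seq_index)
  if (anyNA(idx))
    stop("missing backbone atom ", name, " for residue(s): ",
         paste(model$residues$seq_index[is.na(idx)], collapse = ", "))
  as.matrix(at[idx, c("x", "y", "z")])
}

#' Assign secondary structure from backbone geometry
#'
#' A Kabsch-Sander-style assignment: amide hydrogens are placed 1 Angstrom
#' from N opposite the preceding carbonyl, hydrogen bonds are called where
#' the electrostatic energy
#' 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol falls below -0.5,
#' runs of i -> i+4 bonds give helix and ladder-paired bridges give strand;
#' everything else is coil. Elements are then cleaned up: single-residue
#' gaps inside an element are absorbed, helices shorter than 4 and strands
#' shorter than 3 residues revert to coil.
#'
#' An externally computed per-residue string (e.g. from DSSP itself) can be
#' ingested instead via [ss_annotation()].
#'
#' @param model a `structure_model` with N, CA, C, O for every residue.
#' @return object of class `sse_annotation`: `per_residue` (character over
#'   H/E/C) and `elements` (data.frame kind/start/stop in positions).
#' @export
assign_ss <- function(model) {
  n <- n_residues(model)
  N <- backbone_coords(model, "N")
  C <- backbone_coords(model, "C")
  O <- backbone_coords(model, "O")
  # amide H: 1 A from N, anti-parallel to the previous residue's C=O
  H <- matrix(NA_real_, n, 3)
  if (n >= 2L) {
    v <- C[-n, , drop = FALSE] - O[-n, , drop = FALSE]
    v <- v / sqrt(rowSums(v^2))
    H[-1L, ] <- N[-1L, , drop = FALSE] + v
  }
  # hb[j, i]: C=O of residue j accepts the N-H of residue i
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  for (i in 2:n) {
    rON <- sqrt(colSums((t(O) - N[i, ])^2))
    rCN <- sqrt(colSums((t(C) - N[i, ])^2))
    rOH <- sqrt(colSums((t(O) - H[i, ])^2))
    rCH <- sqrt(colSums((t(C) - H[i, ])^2))
    e <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    ok <- e < -0.5 & abs(seq_len(n) - i) >= 2L
    hb[ok, i] <- TRUE
  }
  ss <- rep("C", n)
  # 4-turns: CO(i) <- NH(i+4); two consecutive turns make a minimal helix
  turn4 <- rep(FALSE, n)
  if (n >= 5L)
    for (i in 1:(n - 4L)) turn4[i] <- hb[i, i + 4L]
  if (n >= 6L)
    for (i in 2:(n - 4L))
      if (turn4[i] && turn4[i - 1L]) ss[(i + 1L):(i + 4L)] <- "H"
  # beta bridges (parallel and antiparallel ladder patterns)
  if (n >= 6L) {
    for (i in 2:(n - 1L)) {
      js <- seq.int(i + 3L, n - 1L)
      js <- js[js >= i + 3L & js <= n - 1L]
      for (j in js) {
        anti <- (hb[i, j] && hb[j, i]) ||
          (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
        para <- (hb[i - 1L, j] && hb[j, i + 1L]) ||
          (hb[j - 1L, i] && hb[i, j + 1L])
        if (anti || para) {
          if (ss[i] != "H") ss[i] <- "E"
          if (ss[j] != "H") ss[j] <- "E"
        }
      }
    }
  }
  ss_annotation(ss, cleanup = TRUE)
}

#' Build a secondary-structure annotation from a per-residue string
#'
#' Accepts H/E/C states (eight-state DSSP letters are mapped: G,I -> H;
#' B -> E; T,S,blank -> C), optionally applies element cleanup, and derives
#' the element list as maximal runs of H or E.
#'
#' @param per_residue character vector or single string of states.
#' @param cleanup apply minimum-length/gap-absorption cleanup (default TRUE).
#' @param min_helix,min_strand minimum element lengths.
#' @return `sse_annotation`.
#' @export
ss_annotation <- function(per_residue, cleanup = TRUE, min_helix = 4L,
                          min_strand = 3L) {
  if (length(per_residue) == 1L && nchar(per_residue) > 1L)
    per_residue <- strsplit(per_residue, "")[[1]]
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E")
  ss <- unname(ifelse(per_residue %in% names(map), map[per_residue], "C"))
  if (cleanup) {
    # absorb single-residue coil gaps flanked by the same element type
    n <- length(ss)
    if (n >= 3L)
      for (i in 2:(n - 1L))
        if (ss[i] == "C" && ss[i - 1L] != "C" && ss[i - 1L] == ss[i + 1L])
          ss[i] <- ss[i - 1L]
    r <- rle(ss)
    drop <- (r$values == "H" & r$lengths < min_helix) |
      (r$values == "E" & r$lengths < min_strand)
    r$values[drop] <- "C"
    ss <- inverse.rle(r)
  }
  r <- rle(ss)
  stop_pos <- cumsum(r$lengths)
  start_pos <- stop_pos - r$lengths + 1L
  keep <- r$values %in% c("H", "E")
  ann <- list(per_residue = ss,
              elements = data.frame(kind = r$values[keep],
                                    start = start_pos[keep],
                                    stop = stop_pos[keep]))
  class(ann) <- "sse_annotation"
  ann
}

#' Order metrics from a secondary-structure annotation
#' @param ss an `sse_annotation`.
#' @return list with `unordered_fraction` (fraction of coil residues) and
#'   `n_sses` (number of cleaned elements).
#' @export
order_metrics <- function(ss) {
  list(unordered_fraction = mean(ss$per_residue == "C"),
       n_sses = nrow(ss$elements))
}

#' Hydrophobic packing density
#'
#' Mean number of neighbouring residues per hydrophobic residue, where two
#' residues are neighbours when any heavy-atom pair lies within `cutoff`
#' Angstrom. Sequence neighbours count. Unusually high values indicate
#' non-globular or collapsed models.
#'
#' @param model a `structure_model`.
#' @param cutoff contact distance, Angstrom (default 5).
#' @param hydrophobic one-letter codes treated as hydrophobic.
#' @return mean neighbour count (>= 0).
#' @export
packing_density <- function(model, cutoff = 5,
                            hydrophobic = DEFAULT_HYDROPHOBIC) {
  hyd <- model$residues$aa %in% hydrophobic
  if (!any(hyd))
    stop("packing density undefined: no hydrophobic residues in model")
  res_index <- match(model$atoms$seq_index, model$residues$seq_index)
  counts <- cpp_contact_counts(as.matrix(model$atoms[, c("x", "y", "z")]),
                               as.integer(res_index), n_residues(model),
                               cutoff)
  mean(counts[hyd])
}

#' Solvent-excluded surface area and volume
#'
#' Grid-based SES: voxels inside any probe-inflated atom form the occupancy
#' mask, which is eroded back by the probe radius (the morphological closing
#' of the van der Waals solid). Volume is the voxel count times the voxel
#' volume; area is estimated from the gradient magnitude of the smoothed
#' mask. The area/volume quotient decreases as a shape becomes more compact.
#'
#' @param model a `structure_model` (or a list with an `atoms` data.frame).
#' @param probe_radius solvent probe, Angstrom (default 1.4).
#' @param voxel grid spacing, Angstrom (default 0.5).
#' @param radii optional explicit per-atom radii; defaults to element-typed
#'   van der Waals radii.
#' @return list with `area` (A^2), `volume` (A^3), `ses_per_volume` (1/A).
#' @export
ses_area_volume <- function(model, probe_radius = 1.4, voxel = 0.5,
                            radii = NULL) {
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (nrow(xyz) > 1L && all(apply(xyz, 2, function(v) diff(range(v))) < 1e-9))
    stop("degenerate coordinates: all atoms coincident")
  if (is.null(radii)) {
    radii <- VDW_RADII[at$element]
    radii[is.na(radii)] <- DEFAULT_VDW
  }
  g <- cpp_ses_grid(xyz, as.numeric(radii), probe_radius, voxel)
  list(area = g$area, volume = g$volume, ses_per_volume = g$area / g$volume)
}

#' Calibrate globularity thresholds from a reference set
#'
#' Sets the globularity cuts so that the top `percentile` of a reference
#' distribution of QC reports (e.g. computed over curated globular domains)
#' passes each rule: the packing-density floor is the `1 - percentile`
#' quantile and the SES-per-volume ceiling the `percentile` quantile, both
#' with linear interpolation between order statistics
#' (`stats::quantile(type = 7)`). All other thresholds keep their defaults.
#'
#' @param reference_reports list of [qc_report()] results or a data.frame
#'   with columns `packing_density` and `ses_per_volume`.
#' @param percentile quantile in (0, 1), default 0.95.
#' @param base thresholds to update.
#' @return a thresholds list.
#' @export
calibrate_thresholds <- function(reference_reports, percentile = 0.95,
                                 base = default_thresholds()) {
  if (is.data.frame(reference_reports)) {
    pd <- reference_reports$packing_density
    sv <- reference_reports$ses_per_volume
  } else {
    pd <- vapply(reference_reports, function(r) r$packing_density, 1.0)
    sv <- vapply(reference_reports, function(r) r$ses_per_volume, 1.0)
  }
  if (length(pd) < 20L)
    stop("need at least 20 reference reports to calibrate (got ", length(pd), ")")
  if (percentile <= 0 || percentile > 1) stop("percentile must be in (0, 1]")
  base$min_packing_density <- unname(quantile(pd, 1 - percentile, type = 7))
  base$max_ses_per_volume <- unname(quantile(sv, percentile, type = 7))
  base$calibration_percentile <- percentile
  base
}

#' Quality-control report and verdict for one domain model
#'
#' Applies, in order: mean pLDDT >= `min_mean_plddt`; the single-LUR rule;
#' unordered fraction <= `max_unordered_fraction`; residue count >=
#' `min_residues`; element count >= `min_sses`; packing density >= its
#' floor; SES area/volume <= its ceiling. All failing rules are recorded,
#' not just the
#' first. A metric that cannot be computed (e.g. packing density with no
#' hydrophobic residue) is recorded as a failure of its rule, so the domain
#' is excluded conservatively.
#'
#' @param model a `structure_model`.
#' @param thresholds see [default_thresholds()].
#' @param ss optional precomputed [ss_annotation()]; computed from geometry
#'   otherwise.
#' @param lur_from "plddt" (default) defines LURs from the confidence
#'   profile; "ss" defines them as runs of coil residues instead.
#' @return object of class `qc_report` with every metric, `verdict`
#'   ("pass"/"fail") and `failed_rules`.
#' @export
qc_report <- function(model, thresholds = default_thresholds(), ss = NULL,
                      lur_from = c("plddt", "ss")) {
  lur_from <- match.arg(lur_from)
  failed <- character(0)
  n <- n_residues(model)
  mp <- mean_plddt(model)
  if (mp < thresholds$min_mean_plddt) failed <- c(failed, "min_mean_plddt")

  if (is.null(ss)) ss <- assign_ss(model)
  om <- order_metrics(ss)

  lur_series <- if (lur_from == "plddt") model$residues$plddt else
    ifelse(ss$per_residue == "C", 0, 100)
  lurs <- find_lurs(lur_series, thresholds$lur_min_len,
                    thresholds$lur_plddt_cut)
  lur_frac <- if (nrow(lurs) == 0L) 0 else max(lurs$length) / n
  if (lur_frac > thresholds$max_single_lur_fraction)
    failed <- c(failed, "max_single_lur_fraction")

  if (om$unordered_fraction > thresholds$max_unordered_fraction)
    failed <- c(failed, "max_unordered_fraction")
  if (n < thresholds$min_residues) failed <- c(failed, "min_residues")
  if (om$n_sses < thresholds$min_sses) failed <- c(failed, "min_sses")

  pd <- tryCatch(packing_density(model), error = function(e) NA_real_)
  if (is.na(pd) || pd < thresholds$min_packing_density)
    failed <- c(failed, "min_packing_density")

  sv <- tryCatch(ses_area_volume(model), error = function(e) NULL)
  if (is.null(sv)) {
    failed <- c(failed, "max_ses_per_volume")
    sv <- list(area = NA_real_, volume = NA_real_, ses_per_volume = NA_real_)
  } else if (sv$ses_per_volume > thresholds$max_ses_per_volume) {
    failed <- c(failed, "max_ses_per_volume")
  }

  rep <- list(protein_id = model$protein_id,
              mean_plddt = mp, n_residues = n,
              max_single_lur_fraction = lur_frac,
              unordered_fraction = om$unordered_fraction,
              n_sses = om$n_sses,
              packing_density = pd,
              ses_area = sv$area, ses_volume = sv$volume,
              ses_per_volume = sv$ses_per_volume,
              verdict = if (length(failed) == 0L) "pass" else "fail",
              failed_rules = failed)
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s", x$protein_id, x$verdict))
  if (length(x$failed_rules)) cat(" [", paste(x$failed_rules, collapse = ", "), "]")
  cat(sprintf("\n  n=%d  mean pLDDT=%.1f  LURmax=%.2f  unordered=%.2f  SSEs=%d  packing=%.2f  SES/V=%.3f\n",
              x$n_residues, x$mean_plddt, x$max_single_lur_fraction,
              x$unordered_fraction, x$n_sses, x$packing_density,
              x$ses_per_volume))
  invisible(x)
}

#' Tabulate QC reports
#' @param reports list of [qc_report()] results.
#' @return data.frame, one row per domain, one column per metric plus
#'   `verdict` and a semicolon-joined `failed_rules`.
#' @export
qc_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(protein_id = r$protein_id, n_residues = r$n_residues,
               mean_plddt = r$mean_plddt,
               max_single_lur_fraction = r$max_single_lur_fraction,
               unordered_fraction = r$unordered_fraction, n_sses = r$n_sses,
               packing_density = r$packing_density,
               ses_area = r$ses_area, ses_volume = r$ses_volume,
               ses_per_volume = r$ses_per_volume, verdict = r$verdict,
               failed_rules = paste(r$failed_rules, collapse = ";"))))
}
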