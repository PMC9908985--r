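#' Construct a structure model
#'
#' A structure model is an ordered set of residues with heavy-atom
#' coordinates and a per-residue confidence (pLDDT, 0-100), plus provenance:
#' the protein accession and, for long proteins predicted in overlapping
#' windows, the fragment index. Residue numbering is 1-based and preserved
#' through every operation (chopping never renumbers).
#'
#' @param protein_id accession string.
#' @param residues data.frame with columns `seq_index` (strictly increasing
#'   integers), `aa` (one-letter code) and `plddt` (0-100).
#' @param atoms data.frame with columns `seq_index`, `name` (e.g. "CA"),
#'   `element`, `x`, `y`, `z` (Angstrom). Every residue must carry a CA atom.
#' @param fragment_index integer >= 1.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(protein_id, residues, atoms, fragment_index = 1L) {
  stopifnot(is.data.frame(residues), is.data.frame(atoms))
  if (nrow(residues) < 1L) stop("a structure model needs at least one residue")
  if (any(diff(residues$seq_index) <= 0L))
    stop("residue seq_index must be strictly increasing")
  if (any(residues$plddt < 0 | residues$plddt > 100))
    stop("pLDDT values must lie in [0, 100]")
  has_ca <- residues$seq_index %in% atoms$seq_index[atoms$name == "CA"]
  if (!all(has_ca))
    stop("missing CA atom for residue(s): ",
         paste(residues$seq_index[!has_ca], collapse = ", "))
  m <- list(protein_id = as.character(protein_id),
            fragment_index = as.integer(fragment_index),
            residues = residues[, c("seq_index", "aa", "plddt")],
            atoms = atoms[, c("seq_index", "name", "element", "x", "y", "z")])
  rownames(m$residues) <- NULL
  rownames(m$atoms) <- NULL
  class(m) <- "structure_model"
  m
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s (fragment %d): %d residues [%d..%d], mean pLDDT %.1f\n",
              x$protein_id, x$fragment_index, nrow(x$residues),
              min(x$residues$seq_index), max(x$residues$seq_index),
              mean(x$residues$plddt)))
  invisible(x)
}

#' Number of residues in a model
#' @param model a `structure_model`.
#' @export
n_residues <- function(model) nrow(model$residues)

#' One-letter sequence of a model
#' @param model a `structure_model`.
#' @export
model_sequence <- function(model) paste(model$residues$aa, collapse = "")

#' C-alpha coordinate matrix of a model
#' @param model a `structure_model`.
#' @return numeric matrix (n_residues x 3), rows in residue order.
#' @export
ca_coords <- function(model) {
  ca <- model$atoms[model$atoms$name == "CA", ]
  ca <- ca[match(model$residues$seq_index, ca$seq_index), ]
  as.matrix(ca[, c("x", "y", "z")])
}

#' MD5 digest of a protein sequence
#'
#' Sequence identity across the pipeline is tracked by the MD5 of the exact
#' one-letter byte string, as in the AlphaFold metadata convention.
#'
#' @param sequence non-empty uppercase one-letter amino-acid string.
#' @return 32-character lowercase hex digest.
#' @export
sequence_md5 <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  digest::digest(sequence, algo = "md5", serialize = FALSE)
}

#' Parse a predicted-model PDB file
#'
#' Reads a single-chain PDB file whose B-factor column holds the per-residue
#' pLDDT (AlphaFold convention). All non-ATOM records are ignored. The pLDDT
#' of a residue is taken from its CA atom.
#'
#' Alternate locations and insertion codes are rejected: they do not occur in
#' predicted models and silently accepting them risks mis-numbering.
#'
#' @param path PDB file.
#' @param protein_id accession; defaults to the file stem.
#' @param fragment_index integer >= 1.
#' @return a `structure_model`.
#' @export
parse_model <- function(path, protein_id = NULL, fragment_index = 1L) {
  if (is.null(protein_id))
    protein_id <- sub("\\.pdb$", "", basename(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (any(!is.na(at$alt) & at$alt != ""))
    stop("alternate location indicators are not supported: ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported: ", path)
  chains <- unique(at$chain[!is.na(at$chain)])
  if (length(chains) > 1L)
    stop("multi-chain input is not supported (chains: ",
         paste(chains, collapse = ", "), "): ", path)
  if (any(is.na(at$b)))
    stop("non-numeric B-factor (pLDDT) field in ", path)
  resno <- at$resno
  ord <- order(resno)
  at <- at[ord, , drop = FALSE]
  resno <- resno[ord]
  ures <- unique(resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(ures, ca$resno)
  if (length(missing_ca) > 0L)
    stop("missing CA atom for residue(s): ", paste(missing_ca, collapse = ", "))
  ca <- ca[match(ures, ca$resno), , drop = FALSE]
  aa <- unname(AA1[ca$resid])
  aa[is.na(aa)] <- "X"
  residues <- data.frame(seq_index = ures, aa = aa, plddt = ca$b,
                         stringsAsFactors = FALSE)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- substr(gsub("[0-9]", "", at$elety), 1L, 1L)
  atoms <- data.frame(seq_index = resno, name = at$elety, element = elem,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  structure_model(protein_id, residues, atoms, fragment_index)
}

#' Write a chopped domain to a PDB file with provenance headers
#'
#' Emits REMARK records carrying the domain MD5, the source model file and
#' any family/superfamily label, followed by ATOM records for the region
#' residues only. Original residue numbering is preserved. The conventional
#' filename stem is "<protein>_<start>-<stop>[_<start>-<stop>...]", the
#' "accession/start-stop" identifier with "/" made filesystem-safe.
#'
#' @param model a `structure_model`.
#' @param region a [domain_region()] (or NULL to write the whole model).
#' @param path output file.
#' @param metadata named character list written verbatim into REMARK lines.
#' @return `path`, invisibly.
#' @export
write_domain <- function(model, region = NULL, path, metadata = list()) {
  sub <- if (is.null(region)) model else chop(model, region)
  at <- sub$atoms
  res <- sub$residues
  plddt <- setNames(res$plddt, res$seq_index)
  aa3 <- setNames(unname(AA3[res$aa]), res$seq_index)
  aa3[is.na(aa3)] <- "UNK"
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(list(protein = model$protein_id), metadata)
  for (k in names(hdr))
    writeLines(sprintf("REMARK 350 %s %s", toupper(k), as.character(hdr[[k]])), con)
  for (i in seq_len(nrow(at))) {
    ri <- as.character(at$seq_index[i])
    # cols: 13-16 atom name, 18-20 residue name, 22 chain, 23-26 residue number
    writeLines(sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       i,
                       ifelse(nchar(at$name[i]) < 4L, paste0(" ", at$name[i]), at$name[i]),
                       aa3[ri], at$seq_index[i], at$x[i], at$y[i], at$z[i],
                       1.0, plddt[ri], at$element[i]), con)
  }
  writeLines("TER", con)
  writeLines("END", con)
  invisible(path)
}

#' Filename stem for a chopped domain
#' @param protein_id accession.
#' @param segments two-column matrix of (start, stop).
#' @export
domain_stem <- function(protein_id, segments) {
  paste0(protein_id, "_",
         paste(sprintf("%d-%d", segments[, 1], segments[, 2]), collapse = "_"))
}

#' Construct a domain hit
#'
#' One candidate domain region on a protein: a sorted, non-overlapping
#' segment list (1-based inclusive), the source channel (existing structural
#' assignment, HMM match, Pfam match, or an unassigned domain-sized region),
#' the candidate family and a score (HMM bitscore or equivalent).
#'
#' @param protein_id accession.
#' @param source one of "CATH-PDB", "CATH-HMM", "Pfam", "NewFam".
#' @param family_id family/superfamily label ("" for NewFam).
#' @param segments two-column integer matrix of inclusive (start, stop) pairs.
#' @param score non-negative numeric.
#' @export
domain_hit <- function(protein_id, source, family_id, segments, score) {
  source <- match.arg(source, c("CATH-PDB", "CATH-HMM", "Pfam", "NewFam"))
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "stop")))
  if (any(segments[, 1] > segments[, 2]))
    stop("segment start > stop")
  if (nrow(segments) > 1L) {
    segments <- segments[order(segments[, 1]), , drop = FALSE]
    if (any(segments[-1L, 1] <= segments[-nrow(segments), 2]))
      stop("segments within one hit overlap")
  }
  h <- list(protein_id = as.character(protein_id), source = source,
            family_id = as.character(family_id), segments = segments,
            score = as.numeric(score))
  class(h) <- "domain_hit"
  h
}

#' Residue indices covered by a hit or region
#' @param x a `domain_hit` or `domain_region`.
#' @export
hit_residues <- function(x) {
  unlist(lapply(seq_len(nrow(x$segments)),
                function(i) seq.int(x$segments[i, 1], x$segments[i, 2])))
}

#' Total residue count of a hit or region
#' @param x a `domain_hit` or `domain_region`.
#' @export
hit_length <- function(x) sum(x$segments[, 2] - x$segments[, 1] + 1L)

#' Load a domain-hit table
#'
#' Reads a whitespace-separated hit table in the resolver input convention:
#' query id, family id, score, segment string "s1-e1,s2-e2,...", and
#' optionally a source column. Malformed rows are rejected with their row
#' number; segment strings with start > stop or overlapping segments are
#' errors.
#'
#' @param path text file.
#' @param default_source source assigned to rows without a fifth column.
#' @return list of [domain_hit()] objects.
#' @export
load_hits <- function(path, default_source = "CATH-HMM") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0L & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) < 4L)
      stop(sprintf("row %d: expected at least 4 fields, got %d", i, length(f)))
    score <- suppressWarnings(as.numeric(f[3]))
    if (is.na(score)) stop(sprintf("row %d: non-numeric score '%s'", i, f[3]))
    segs <- parse_segments(f[4], row = i)
    src <- if (length(f) >= 5L) f[5] else default_source
    fam <- if (f[2] == "-") "" else f[2]   # "-" marks an empty family
    out[[i]] <- tryCatch(
      domain_hit(f[1], src, fam, segs, score),
      error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
  }
  out
}

parse_segments <- function(s, row = NA) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop(sprintf("row %s: malformed segment string '%s'", row, s), call. = FALSE)
  segs <- t(vapply(m, function(x) as.integer(x[2:3]), integer(2)))
  colnames(segs) <- c("start", "stop")
  segs
}

#' Write a domain-hit table
#' @param hits list of [domain_hit()].
#' @param path output file.
#' @export
write_hits <- function(hits, path) {
  lines <- vapply(hits, function(h) {
    segs <- paste(sprintf("%d-%d", h$segments[, 1], h$segments[, 2]),
                  collapse = ",")
    fam <- if (nzchar(h$family_id)) h$family_id else "-"
    sprintf("%s\t%s\t%g\t%s\t%s", h$protein_id, fam, h$score, segs, h$source)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fragment layout of a long predicted protein
#'
#' Proteins longer than the prediction window are modelled as overlapping
#' fragments: windows of `fragment_length` residues (default 1400) whose
#' starts step by `step` (default 200) while `start + fragment_length - 1`
#' fits in the protein, plus a terminal window ending at the last residue if
#' the regular windows stop short. Every residue is covered by at least one
#' fragment.
#'
#' @param protein_id accession.
#' @param protein_length total residue count.
#' @param fragment_length window size, residues.
#' @param step start-to-start shift, residues.
#' @return object of class `fragment_set` with a `fragments` data.frame
#'   (`fragment_index`, `first_residue`, `last_residue`).
#' @export
fragment_set <- function(protein_id, protein_length, fragment_length = 1400L,
                         step = 200L) {
  protein_length <- as.integer(protein_length)
  if (protein_length <= fragment_length) {
    frags <- data.frame(fragment_index = 1L, first_residue = 1L,
                        last_residue = protein_length)
  } else {
    starts <- seq.int(1L, protein_length - fragment_length + 1L, by = step)
    last_end <- starts[length(starts)] + fragment_length - 1L
    if (last_end < protein_length)
      starts <- c(starts, protein_length - fragment_length + 1L)
    frags <- data.frame(fragment_index = seq_along(starts),
                        first_residue = starts,
                        last_residue = starts + fragment_length - 1L)
  }
  fs <- list(protein_id = as.character(protein_id),
             protein_length = protein_length,
             fragment_length = as.integer(fragment_length),
             step = as.integer(step), fragments = frags)
  class(fs) <- "fragment_set"
  fs
}

#' Write a manifest mapping proteins to sequence MD5s and fragment files
#' @param entries data.frame with columns protein_id, sequence_md5, file.
#' @param path output TSV.
#' @export
write_manifest <- function(entries, path) {
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
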