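#' Construct a domain region
#'
#' A confirmed domain on a protein: sorted disjoint segments (1-based,
#' inclusive), the source channel, an optional candidate superfamily code
#' ("C.A.T.H") with its prediction confidence. Regions shorter than
#' `min_length` residues (default 40, the domain-size criterion used to
#' recognise domain-sized regions) are rejected.
#'
#' @param protein_id accession.
#' @param segments two-column matrix of (start, stop).
#' @param source one of "CATH-PDB", "CATH-HMM", "Pfam", "NewFam".
#' @param candidate_superfamily CATH-style code or "".
#' @param confidence prediction probability in [0,1], or NA.
#' @param min_length minimum total residue count.
#' @export
domain_region <- function(protein_id, segments, source = "NewFam",
                          candidate_superfamily = "", confidence = NA_real_,
                          min_length = 40L) {
  source <- match.arg(source, c("CATH-PDB", "CATH-HMM", "Pfam", "NewFam"))
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "stop")))
  segments <- segments[order(segments[, 1]), , drop = FALSE]
  if (any(segments[, 1] > segments[, 2])) stop("segment start > stop")
  if (nrow(segments) > 1L &&
      any(segments[-1L, 1] <= segments[-nrow(segments), 2]))
    stop("segments overlap")
  len <- sum(segments[, 2] - segments[, 1] + 1L)
  if (len < min_length)
    stop("region of ", len, " residues is below the ", min_length,
         "-residue domain-size criterion")
  r <- list(protein_id = as.character(protein_id), segments = segments,
            source = source,
            candidate_superfamily = as.character(candidate_superfamily),
            confidence = as.numeric(confidence))
  class(r) <- "domain_region"
  r
}

#' Region identifier in "accession/start-stop" style
#' @param region a `domain_region`.
#' @export
region_id <- function(region) {
  paste0(region$protein_id, "/",
         paste(sprintf("%d-%d", region$segments[, 1], region$segments[, 2]),
               collapse = "_"))
}

#' Resolve overlapping domain hits to the optimal non-overlapping layout
#'
#' Selects the score-maximal subset of hits such that no two selected hits
#' share more than `overlap_tolerance` residues -- the "best possible
#' combination of domains for optimal coverage". Discontinuous hits take
#' part through their residue sets, not their bounding intervals, so nested
#' domains are handled correctly. The optimum is exact (branch-and-bound
#' with a remaining-score upper bound over hits in a deterministic order);
#' ties are broken towards larger total length, then smaller start sum.
#'
#' @param hits list of [domain_hit()] on one protein.
#' @param overlap_tolerance residues of pairwise overlap allowed (default 10).
#' @param protein_length for the coverage figure; inferred from the hits'
#'   maximum stop when NULL.
#' @return object of class `resolved_layout` with `selected`, `rejected`
#'   (each with a reason) and `coverage`.
#' @export
resolve_hits <- function(hits, overlap_tolerance = 10L, protein_length = NULL) {
  stopifnot(length(hits) >= 0L)
  if (length(hits) == 0L) {
    out <- list(protein_id = NA_character_, selected = list(),
                rejected = list(), coverage = 0)
    class(out) <- "resolved_layout"
    return(out)
  }
  pid <- unique(vapply(hits, function(h) h$protein_id, ""))
  if (length(pid) != 1L) stop("all hits must be on one protein")
  if (any(vapply(hits, function(h) h$score, 1.0) < 0))
    stop("scores must be non-negative")
  n <- length(hits)
  # deterministic hit order: higher score, then longer, then lower start
  lens <- vapply(hits, hit_length, 1L)
  starts <- vapply(hits, function(h) h$segments[1, 1], 1L)
  scores <- vapply(hits, function(h) h$score, 1.0)
  ord <- order(-scores, -lens, starts)
  hits <- hits[ord]
  lens <- lens[ord]; starts <- starts[ord]; scores <- scores[ord]
  res_sets <- lapply(hits, hit_residues)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    ov <- length(intersect(res_sets[[i]], res_sets[[j]]))
    conflict[i, j] <- conflict[j, i] <- ov > overlap_tolerance
  }
  suffix_score <- rev(cumsum(rev(scores)))
  best <- list(key = c(-Inf, -Inf, Inf), sel = integer(0))
  # DFS over hits in order; prune when even taking everything left cannot win
  recurse <- function(i, sel, score, len, ssum) {
    if (i > n) {
      key <- c(score, len, ssum)
      if (key[1] > best$key[1] ||
          (key[1] == best$key[1] && (key[2] > best$key[2] ||
           (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <<- list(key = key, sel = sel)
      }
      return(invisible(NULL))
    }
    if (score + suffix_score[i] < best$key[1]) return(invisible(NULL))
    ok <- length(sel) == 0L || !any(conflict[sel, i])
    if (ok)
      recurse(i + 1L, c(sel, i), score + scores[i], len + lens[i],
              ssum + starts[i])
    recurse(i + 1L, sel, score, len, ssum)
    invisible(NULL)
  }
  recurse(1L, integer(0), 0, 0L, 0L)
  sel_idx <- sort(best$sel)
  rejected <- lapply(setdiff(seq_len(n), sel_idx), function(i)
    list(hit = hits[[i]],
         reason = sprintf("overlaps a selected hit by more than %d residues",
                          overlap_tolerance)))
  covered <- unique(unlist(res_sets[sel_idx]))
  if (is.null(protein_length))
    protein_length <- max(vapply(hits, function(h) max(h$segments[, 2]), 1L))
  out <- list(protein_id = pid, selected = hits[sel_idx], rejected = rejected,
              coverage = length(covered) / protein_length,
              total_score = sum(scores[sel_idx]),
              overlap_tolerance = overlap_tolerance)
  class(out) <- "resolved_layout"
  out
}

#' @export
print.resolved_layout <- function(x, ...) {
  cat(sprintf("<resolved_layout> %s: %d selected, %d rejected, coverage %.2f\n",
              x$protein_id, length(x$selected), length(x$rejected), x$coverage))
  invisible(x)
}

#' Tabulate a resolved layout
#' @param layout a `resolved_layout`.
#' @export
layout_table <- function(layout) {
  row <- function(h, status, reason = "") {
    data.frame(protein_id = h$protein_id, family_id = h$family_id,
               source = h$source, score = h$score,
               segments = paste(sprintf("%d-%d", h$segments[, 1],
                                        h$segments[, 2]), collapse = ","),
               status = status, reason = reason)
  }
  rbind(do.call(rbind, lapply(layout$selected, row, status = "selected")),
        do.call(rbind, lapply(layout$rejected,
                              function(r) row(r$hit, "rejected", r$reason))))
}

#' Choose the model fragment containing a domain
#'
#' Among the fragments whose residue range contains every region residue,
#' returns the one whose centre lies closest to the region centre: fragment
#' edges carry degraded prediction confidence, so the most central placement
#' is preferred. If no fragment contains the whole region the domain is
#' unchoppable and an error of class `domassign_unchoppable` is raised.
#'
#' @param region a [domain_region()].
#' @param fragset a [fragment_set()].
#' @return fragment index (integer).
#' @export
choose_fragment <- function(region, fragset) {
  lo <- min(region$segments[, 1])
  hi <- max(region$segments[, 2])
  fr <- fragset$fragments
  contains <- fr$first_residue <= lo & fr$last_residue >= hi
  if (!any(contains))
    stop(structure(class = c("domassign_unchoppable", "error", "condition"),
                   list(message = sprintf(
                     "region %d-%d of %s fits in no fragment (unchoppable)",
                     lo, hi, fragset$protein_id), call = sys.call(-1))))
  cand <- fr[contains, , drop = FALSE]
  centre <- (lo + hi) / 2
  d <- abs((cand$first_residue + cand$last_residue) / 2 - centre)
  cand$fragment_index[order(d, cand$fragment_index)][1L]
}

#' Chop a region out of a model
#'
#' Restricts a model to the region's residues. Numbering and pLDDT are
#' carried over unchanged; provenance keeps the source protein id.
#'
#' @param model a `structure_model`.
#' @param region a [domain_region()] (or an integer vector of residues).
#' @return a `structure_model` containing exactly the region residues.
#' @export
chop <- function(model, region) {
  want <- if (inherits(region, "domain_region") ||
              inherits(region, "domain_hit")) hit_residues(region)
          else as.integer(region)
  missing <- setdiff(want, model$residues$seq_index)
  if (length(missing) > 0L)
    stop("region residues absent from model: ",
         paste(missing, collapse = ", "))
  res <- model$residues[model$residues$seq_index %in% want, , drop = FALSE]
  at <- model$atoms[model$atoms$seq_index %in% want, , drop = FALSE]
  structure_model(model$protein_id, res, at, model$fragment_index)
}
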