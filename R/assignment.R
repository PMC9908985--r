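#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of corresponding point sets by SVD of the
#' covariance matrix, with the usual determinant correction so the result is
#' a proper rotation.
#'
#' @param A,B n x 3 coordinate matrices (A is moved onto B).
#' @return list with `rotation` (3x3), `translation` (length 3) and `rmsd`;
#'   the transform maps a point x to `x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("correspondence length mismatch")
  if (nrow(A) < 3L) stop("need at least 3 corresponding pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)
  s <- svd(H)
  if (s$d[2] < 1e-12) stop("degenerate (collinear) correspondence")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t <- cb - as.vector(ca %*% R)
  moved <- sweep(A %*% R, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' TM-score normalisation distance
#' @param l_norm normalisation length (residues).
#' @return d0 in Angstrom, floored at 0.5.
#' @export
tm_d0 <- function(l_norm) max(0.5, 1.24 * (l_norm - 15)^(1 / 3) - 1.8)

#' Construct a comparator result
#'
#' @param query_id,target_id identifiers.
#' @param score similarity score.
#' @param score_type "bitscore", "ssap" or "tmscore"; determines which
#'   acceptance threshold applies.
#' @param n_aligned aligned residue count.
#' @param query_length,target_length chain lengths (overlaps are
#'   `n_aligned` over the respective length).
#' @param rmsd superposition RMSD over the aligned pairs (Angstrom).
#' @export
comparison_result <- function(query_id, target_id, score, score_type,
                              n_aligned, query_length, target_length,
                              rmsd = NA_real_) {
  score_type <- match.arg(score_type, c("bitscore", "ssap", "tmscore"))
  r <- list(query_id = query_id, target_id = target_id,
            score = as.numeric(score), score_type = score_type,
            n_aligned = as.integer(n_aligned),
            query_overlap = n_aligned / query_length,
            target_overlap = n_aligned / target_length,
            rmsd = as.numeric(rmsd))
  class(r) <- "comparison_result"
  r
}

#' Sequence-independent structural alignment with a TM-score
#'
#' The built-in structure comparator: gapless threadings of the two CA
#' traces seed rigid superpositions, each refined by iterating a
#' dynamic-programming re-alignment under a TM-score-weighted similarity
#' matrix (S = 1/(1 + (d/d0)^2), semi-global, linear gap penalty) with
#' re-superposition on the close aligned pairs, until the correspondence is
#' stable. The reported score is the TM-score of the best final alignment,
#' normalised by the query length by default (d0 = 1.24 (L-15)^(1/3) - 1.8,
#' floored at 0.5 A). Deterministic for fixed inputs.
#'
#' @param query,target `structure_model`s of at least 20 residues.
#' @param normalize "query" (default) or "shorter" chain length.
#' @param gap DP gap penalty (default 0.6).
#' @param max_iter refinement iterations per seed.
#' @return a [comparison_result()] with `score_type = "tmscore"`.
#' @export
align_structures <- function(query, target, normalize = c("query", "shorter"),
                             gap = 0.6, max_iter = 15L) {
  normalize <- match.arg(normalize)
  cq <- ca_coords(query); ct <- ca_coords(target)
  lq <- nrow(cq); lt <- nrow(ct)
  if (lq < 20L || lt < 20L)
    stop("both structures must have at least 20 residues")
  l_norm <- if (normalize == "query") lq else min(lq, lt)
  d0 <- tm_d0(l_norm)
  d02 <- d0 * d0

  tm_of <- function(pairs) {
    # TM-score of a correspondence: superpose on progressively close pairs
    sub <- pairs
    fit <- NULL
    for (it in 1:5) {
      if (nrow(sub) < 3L) break
      f <- tryCatch(kabsch_superpose(cq[sub[, 1], , drop = FALSE],
                                     ct[sub[, 2], , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(f)) break
      fit <- f
      moved <- sweep(cq[pairs[, 1], , drop = FALSE] %*% f$rotation, 2,
                     f$translation, "+")
      d2 <- rowSums((moved - ct[pairs[, 2], , drop = FALSE])^2)
      keep <- d2 < 64 # 8 A
      new_sub <- pairs[keep, , drop = FALSE]
      if (nrow(new_sub) == nrow(sub) && all(new_sub == sub)) break
      sub <- new_sub
    }
    if (is.null(fit)) return(list(tm = 0, fit = NULL, d2 = NULL))
    moved <- sweep(cq[pairs[, 1], , drop = FALSE] %*% fit$rotation, 2,
                   fit$translation, "+")
    d2 <- rowSums((moved - ct[pairs[, 2], , drop = FALSE])^2)
    list(tm = sum(1 / (1 + d2 / d02)) / l_norm, fit = fit, d2 = d2)
  }

  # gapless seeds
  min_ov <- min(20L, lq, lt)
  offs <- seq.int(-(lq - min_ov), lt - min_ov)
  if (length(offs) > 21L)
    offs <- unique(c(0L, offs[round(seq(1L, length(offs),
                                        length.out = 21L))]))
  best <- list(tm = -1, pairs = NULL, fit = NULL, d2 = NULL)
  for (o in offs) {
    i0 <- max(1L, 1L - o); i1 <- min(lq, lt - o)
    if (i1 - i0 + 1L < min_ov) next
    pairs <- cbind(i0:i1, (i0:i1) + o)
    prev <- NULL
    for (iter in seq_len(max_iter)) {
      r <- tm_of(pairs)
      if (is.null(r$fit)) break
      if (r$tm > best$tm)
        best <- list(tm = r$tm, pairs = pairs, fit = r$fit, d2 = r$d2)
      moved <- sweep(cq %*% r$fit$rotation, 2, r$fit$translation, "+")
      dm2 <- outer(rowSums(moved^2), rowSums(ct^2), "+") -
        2 * tcrossprod(moved, ct)
      S <- 1 / (1 + pmax(dm2, 0) / d02)
      pairs <- cpp_nw_align(S, gap)
      if (nrow(pairs) < 3L) break
      sig <- paste(pairs[, 1], pairs[, 2], collapse = ";")
      if (!is.null(prev) && sig == prev) break
      prev <- sig
    }
  }
  if (is.null(best$pairs))
    return(comparison_result(query$protein_id, target$protein_id, 0,
                             "tmscore", 0L, lq, lt))
  close <- best$d2 < 64
  n_aligned <- sum(close)
  rmsd <- if (n_aligned > 0L) sqrt(mean(best$d2[close])) else NA_real_
  comparison_result(query$protein_id, target$protein_id, best$tm, "tmscore",
                    n_aligned, lq, lt, rmsd)
}

#' Acceptance thresholds for comparator hits
#'
#' The benchmarked acceptance cascade thresholds: a minimum query overlap of
#' 60% for every score type; bitscores must reach 106 for classes 1 and 3
#' and 165 for class 2 (class 4 has no published cut and must be configured
#' explicitly); queries with no candidate class use the strictest bitscore
#' (165). SSAP-style scores accept at 80 (of 100) by default and TM-scores
#' at 0.5, both configurable. Library scans pre-filter candidates whose
#' best achievable query overlap is below `prefilter_overlap` (0.4).
#' Superfamily predictions are trusted only at probability >= 0.40 (the
#' operating point corresponding to a 5% error rate).
#'
#' @param overlap minimum query overlap.
#' @param bitscore named numeric, cut per class ("1".."4", NA = unset).
#' @param strictest_bitscore used when the query class is unknown.
#' @param ssap,tm score cuts for the other score types.
#' @param prefilter_overlap scan pre-filter.
#' @param min_probability prediction acceptance cut.
#' @export
assignment_thresholds <- function(overlap = 0.60,
                                  bitscore = c("1" = 106, "2" = 165,
                                               "3" = 106, "4" = NA),
                                  strictest_bitscore = 165,
                                  ssap = 80, tm = 0.5,
                                  prefilter_overlap = 0.4,
                                  min_probability = 0.40) {
  list(overlap = overlap, bitscore = bitscore,
       strictest_bitscore = strictest_bitscore, ssap = ssap, tm = tm,
       prefilter_overlap = prefilter_overlap,
       min_probability = min_probability)
}

#' CATH-style code helpers
#'
#' `sfam_class` returns the class digit (first field) of a "C.A.T.H" code;
#' `sfam_prefix` the first `n` fields.
#' @param code superfamily code string.
#' @export
sfam_class <- function(code) {
  if (is.na(code) || code == "") return(NA_integer_)
  as.integer(strsplit(code, ".", fixed = TRUE)[[1]][1])
}

#' @rdname sfam_class
#' @param n number of leading fields to keep.
#' @export
sfam_prefix <- function(code, n) {
  paste(head(strsplit(code, ".", fixed = TRUE)[[1]], n), collapse = ".")
}

#' Accept or reject a comparator hit
#'
#' Applies the score-type-specific acceptance rule: every type requires
#' query overlap at least the overlap threshold; bitscores additionally use
#' the class-specific cut (106 for classes 1 and 3, 165 for class 2), SSAP
#' scores the SSAP cut and TM-scores the TM cut. Bitscore cuts are never
#' applied to TM-scores or vice versa.
#'
#' @param result a [comparison_result()].
#' @param query_class integer 1-4, or NA when unknown (bitscore hits then
#'   use the strictest cut).
#' @param thresholds see [assignment_thresholds()].
#' @return logical.
#' @export
accept_hit <- function(result, query_class = NA,
                       thresholds = assignment_thresholds()) {
  if (result$query_overlap < thresholds$overlap) return(FALSE)
  switch(result$score_type,
    bitscore = {
      cut <- if (is.na(query_class)) thresholds$strictest_bitscore
             else thresholds$bitscore[as.character(query_class)]
      if (is.na(cut))
        stop("no bitscore threshold configured for class ", query_class)
      result$score >= cut
    },
    ssap = result$score >= thresholds$ssap,
    tmscore = result$score >= thresholds$tm)
}

#' Build a labelled domain library
#' @param models list of `structure_model`s.
#' @param superfamilies character vector of "C.A.T.H" labels.
#' @param ids optional domain ids (default: model protein ids).
#' @return object of class `domain_library` (list of entries with
#'   `id`, `superfamily`, `model`).
#' @export
domain_library <- function(models, superfamilies, ids = NULL) {
  if (is.null(ids))
    ids <- vapply(models, function(m) m$protein_id, "")
  stopifnot(length(models) == length(superfamilies),
            length(ids) == length(models))
  lib <- Map(function(m, s, i) list(id = i, superfamily = s, model = m),
             models, superfamilies, ids)
  class(lib) <- "domain_library"
  lib
}

#' Subset a library by a predicate on its superfamily labels
#' @param library a [domain_library()].
#' @param keep logical vector or predicate function on the label.
#' @export
library_subset <- function(library, keep) {
  labs <- vapply(library, function(e) e$superfamily, "")
  sel <- if (is.function(keep)) vapply(labs, keep, TRUE) else keep
  out <- unclass(library)[sel]
  class(out) <- "domain_library"
  out
}

#' Scan a query against a labelled library
#'
#' Compares the query to every library member (after a cheap pre-filter
#' dropping targets whose best achievable query overlap is below the
#' pre-filter cut) and returns the highest-scoring hit that passes
#' [accept_hit()]; ties are broken by overlap, then target id.
#'
#' @param query a `structure_model`.
#' @param library a [domain_library()].
#' @param comparator function(query, target) -> [comparison_result()].
#' @param thresholds see [assignment_thresholds()].
#' @param query_class class digit for bitscore cuts, or NA.
#' @return list(result, target_id, superfamily) of the best accepted hit,
#'   or NULL when nothing is accepted.
#' @export
scan_library <- function(query, library, comparator = align_structures,
                         thresholds = assignment_thresholds(),
                         query_class = NA) {
  if (length(library) == 0L) return(NULL)
  lq <- n_residues(query)
  best <- NULL
  ord <- order(vapply(library, function(e) e$id, ""))
  for (e in unclass(library)[ord]) {
    lt <- n_residues(e$model)
    if (min(lq, lt) / lq < thresholds$prefilter_overlap) next
    r <- comparator(query, e$model)
    if (!accept_hit(r, query_class, thresholds)) next
    if (is.null(best) || r$score > best$result$score ||
        (r$score == best$result$score &&
         r$query_overlap > best$result$query_overlap))
      best <- list(result = r, target_id = e$id, superfamily = e$superfamily)
  }
  best
}

#' Prediction record for a domain
#' @param domain_id id.
#' @param predicted_superfamily "C.A.T.H" code.
#' @param probability in [0,1]; accepted when >= the probability cut.
#' @export
prediction_record <- function(domain_id, predicted_superfamily, probability) {
  stopifnot(probability >= 0, probability <= 1)
  list(domain_id = domain_id,
       predicted_superfamily = predicted_superfamily,
       probability = probability)
}

#' Cascade superfamily assignment
#'
#' Runs the validation cascade, stopping at the first accepted hit:
#' (1) scan the representatives of the candidate superfamily (the HMM match
#' for HMM-sourced domains, otherwise the predicted superfamily when its
#' probability reaches the acceptance cut) with the fast comparator,
#' falling back to the sensitive comparator on a miss; (2) widen to the
#' candidate topology, then architecture; (3) scan all superfamilies;
#' (4) scan peer domains already assigned in this run. A query with no
#' accepted hit anywhere is unassigned.
#'
#' @param query a `structure_model` (the chopped domain).
#' @param region optional [domain_region()] carrying source and candidate.
#' @param prediction optional [prediction_record()].
#' @param library a [domain_library()].
#' @param peers optional [domain_library()] of already-assigned peers.
#' @param comparators list with `fast` and optional `sensitive` comparator
#'   functions.
#' @param thresholds see [assignment_thresholds()].
#' @return object of class `cascade_decision`: `query_id`, `stage`
#'   (predicted_superfamily_scan / class_scan / all_scan / peer_scan /
#'   unassigned), `stage_detail`, `assigned_superfamily`, `best_hit`.
#' @export
cascade_assign <- function(query, region = NULL, prediction = NULL,
                           library, peers = NULL,
                           comparators = list(fast = align_structures),
                           thresholds = assignment_thresholds()) {
  decide <- function(stage, detail, hit) {
    d <- list(query_id = query$protein_id, stage = stage,
              stage_detail = detail,
              assigned_superfamily = if (is.null(hit)) "" else hit$superfamily,
              best_hit = if (is.null(hit)) NULL else hit$result,
              target_id = if (is.null(hit)) "" else hit$target_id)
    class(d) <- "cascade_decision"
    d
  }
  candidate <- ""
  if (!is.null(region) && region$source == "CATH-HMM" &&
      nzchar(region$candidate_superfamily)) {
    candidate <- region$candidate_superfamily
  } else if (!is.null(prediction) &&
             prediction$probability >= thresholds$min_probability) {
    candidate <- prediction$predicted_superfamily
  }
  qclass <- if (nzchar(candidate)) sfam_class(candidate) else NA
  scan2 <- function(lib) {
    # fast comparator, then the sensitive one on a miss
    hit <- scan_library(query, lib, comparators$fast, thresholds, qclass)
    if (is.null(hit) && !is.null(comparators$sensitive))
      hit <- scan_library(query, lib, comparators$sensitive, thresholds,
                          qclass)
    hit
  }
  labs <- vapply(library, function(e) e$superfamily, "")
  if (nzchar(candidate)) {
    hit <- scan2(library_subset(library, labs == candidate))
    if (!is.null(hit))
      return(decide("predicted_superfamily_scan", candidate, hit))
    for (lvl in c(3L, 2L)) {
      pre <- sfam_prefix(candidate, lvl)
      sel <- vapply(labs, function(x) sfam_prefix(x, lvl) == pre, TRUE) &
        labs != candidate
      hit <- scan2(library_subset(library, sel))
      if (!is.null(hit))
        return(decide("class_scan",
                      if (lvl == 3L) "topology" else "architecture", hit))
    }
  }
  hit <- scan2(library)
  if (!is.null(hit)) return(decide("all_scan", "all_superfamilies", hit))
  if (!is.null(peers) && length(peers) > 0L) {
    hit <- scan2(peers)
    if (!is.null(hit)) return(decide("peer_scan", "assigned_peers", hit))
  }
  decide("unassigned", "", NULL)
}

#' @export
print.cascade_decision <- function(x, ...) {
  cat(sprintf("<cascade_decision> %s: %s%s\n", x$query_id, x$stage,
              if (nzchar(x$assigned_superfamily))
                paste0(" -> ", x$assigned_superfamily) else ""))
  invisible(x)
}
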