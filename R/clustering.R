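#' All-vs-all comparison of unassigned domains
#'
#' Scores every unordered pair once, in canonical id order, after the usual
#' length pre-filter. An edge passes when its weight reaches
#' `edge_threshold` and the query overlap reaches the overlap threshold.
#'
#' @param domains a [domain_library()] or named list of `structure_model`s
#'   (names are the domain ids).
#' @param comparator function(query, target) -> [comparison_result()].
#' @param edge_threshold minimum score for a passing edge.
#' @param overlap minimum overlap for a passing edge (default 0.60).
#' @param prefilter_overlap length pre-filter (default 0.4).
#' @return data.frame of `similarity edges`: id_a, id_b, weight, overlap,
#'   passed.
#' @export
all_vs_all <- function(domains, comparator = align_structures,
                       edge_threshold, overlap = 0.60,
                       prefilter_overlap = 0.4) {
  models <- as_model_list(domains)
  ids <- sort(names(models))
  rows <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        a <- models[[ids[i]]]; b <- models[[ids[j]]]
        la <- n_residues(a); lb <- n_residues(b)
        if (min(la, lb) / max(la, lb) < prefilter_overlap) next
        # score with the shorter chain as query so the edge is symmetric
        r <- if (la <= lb) comparator(a, b) else comparator(b, a)
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = ids[i], id_b = ids[j], weight = r$score,
          overlap = r$query_overlap,
          passed = r$score >= edge_threshold && r$query_overlap >= overlap)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      weight = numeric(0), overlap = numeric(0),
                      passed = logical(0)))
  do.call(rbind, rows)
}

as_model_list <- function(domains) {
  if (inherits(domains, "domain_library")) {
    models <- lapply(domains, function(e) e$model)
    names(models) <- vapply(domains, function(e) e$id, "")
    models
  } else {
    if (is.null(names(domains)))
      names(domains) <- vapply(domains, function(m) m$protein_id, "")
    domains
  }
}

#' Single-linkage clustering at a fixed similarity cutoff
#'
#' Single linkage with a fixed cut is exactly the connected components of
#' the similarity graph restricted to edges whose weight reaches the
#' cutoff. Domains touching no such edge form singleton clusters. Member
#' order within a cluster and cluster order are deterministic
#' (lexicographic).
#'
#' @param edges data.frame from [all_vs_all()] (columns id_a, id_b, weight;
#'   a `passed` column, when present, is respected in addition to the
#'   cutoff).
#' @param cutoff minimum edge weight.
#' @param ids all domain ids (so isolated domains appear); defaults to the
#'   ids present in `edges`.
#' @return list of objects of class `domain_cluster`, each with sorted
#'   `members` and a `triage` slot (NA until [triage_cluster()]).
#' @export
single_linkage <- function(edges, cutoff, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(edges$id_a, edges$id_b)))
  ids <- sort(unique(ids))
  keep <- edges$weight >= cutoff
  if ("passed" %in% names(edges)) keep <- keep & edges$passed
  g <- igraph::graph_from_data_frame(
    edges[keep, c("id_a", "id_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  lapply(unname(groups), function(m) {
    cl <- list(members = m, triage = NA_character_)
    class(cl) <- "domain_cluster"
    cl
  })
}

#' Pick a cluster representative
#'
#' The member with the highest mean pLDDT (ties broken by id order).
#' @param cluster a `domain_cluster`.
#' @param models named list of `structure_model`s.
#' @export
cluster_representative <- function(cluster, models) {
  mp <- vapply(cluster$members, function(id) mean_plddt(models[[id]]), 1.0)
  cluster$members[order(-mp, cluster$members)][1L]
}

#' Triage a cluster of unassigned domains
#'
#' The cluster representative (highest mean pLDDT) is scanned against the
#' library of PDB structures not yet classified; a full accepted hit labels
#' the cluster `pdb_unclassified_match`. Otherwise the representative is
#' scanned against the assigned-domain library looking for a sub-region
#' match -- an alignment covering less than the overlap threshold of the
#' query but at least the overlap threshold of the target over >= 40
#' aligned residues, at acceptance-level per-residue score -- which labels
#' it `multidomain` (part of the region is an already-classified domain).
#' Everything else is a `putative_new` superfamily.
#'
#' @param cluster a `domain_cluster`.
#' @param models named list of `structure_model`s for the members.
#' @param pdb_unclassified a [domain_library()] of unclassified-PDB
#'   structures (possibly empty).
#' @param assigned a [domain_library()] of already-assigned domains.
#' @param comparator comparison function.
#' @param thresholds see [assignment_thresholds()].
#' @param min_subregion minimum aligned residues for a multidomain call.
#' @return the cluster with its `triage` slot set.
#' @export
triage_cluster <- function(cluster, models, pdb_unclassified = NULL,
                           assigned = NULL,
                           comparator = align_structures,
                           thresholds = assignment_thresholds(),
                           min_subregion = 40L) {
  rep_id <- cluster_representative(cluster, models)
  query <- models[[rep_id]]
  cluster$representative <- rep_id
  if (!is.null(pdb_unclassified) && length(pdb_unclassified) > 0L) {
    hit <- scan_library(query, pdb_unclassified, comparator, thresholds)
    if (!is.null(hit)) {
      cluster$triage <- "pdb_unclassified_match"
      return(cluster)
    }
  }
  if (!is.null(assigned) && length(assigned) > 0L) {
    for (e in unclass(assigned)[order(vapply(assigned, function(x) x$id, ""))]) {
      r <- comparator(query, e$model)
      if (r$n_aligned < min_subregion) next
      if (r$query_overlap >= thresholds$overlap) next # full match, not partial
      if (r$target_overlap < thresholds$overlap) next
      good <- switch(r$score_type,
        # per-aligned-residue TM quality: rescale the query-normalised score
        tmscore = r$score * n_residues(query) / r$n_aligned >= thresholds$tm,
        ssap = r$score >= thresholds$ssap,
        bitscore = r$score >= thresholds$strictest_bitscore)
      if (good) {
        cluster$triage <- "multidomain"
        return(cluster)
      }
    }
  }
  cluster$triage <- "putative_new"
  cluster
}

#' Tabulate clusters
#' @param clusters list of `domain_cluster`s.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_id = i, member = cl$members,
               triage = if (is.null(cl$triage)) NA_character_ else cl$triage)
  }))
}
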