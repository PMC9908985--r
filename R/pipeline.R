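#' Pipeline run configuration
#'
#' Collects every input path, threshold set and toggle for an end-to-end
#' run. All referenced paths must exist at run start; the configuration is
#' serialised verbatim into the output directory so any run is auditable.
#'
#' @param models_dir directory of model PDB files, named
#'   "<protein>.pdb" or "<protein>_F<k>.pdb" for fragment k.
#' @param hits_path domain-hit table (see [load_hits()]).
#' @param out_dir output directory (created).
#' @param predictions_path optional TSV: domain_id, predicted_superfamily,
#'   probability.
#' @param library_manifest optional TSV: id, superfamily, path (PDB).
#' @param pdb_unclassified_manifest optional TSV like `library_manifest`
#'   for unclassified-PDB structures used in triage.
#' @param qc_thresholds,assign_thresholds threshold lists.
#' @param cluster_cutoff similarity cutoff for clustering (TM-score scale
#'   for the built-in comparator).
#' @param overlap_tolerance residue overlap tolerated between resolved hits.
#' @param stages character subset of c("qc", "assign", "cluster").
#' @param seed integer; threaded to every stochastic component (the
#'   built-in pipeline is deterministic, but the seed is recorded and
#'   forwarded so adapter comparators can use it).
#' @export
run_config <- function(models_dir, hits_path, out_dir,
                       predictions_path = NULL, library_manifest = NULL,
                       pdb_unclassified_manifest = NULL,
                       qc_thresholds = default_thresholds(),
                       assign_thresholds = assignment_thresholds(),
                       cluster_cutoff = 0.5,
                       overlap_tolerance = 10L,
                       stages = c("qc", "assign", "cluster"),
                       seed = 1L) {
  for (p in c(models_dir, hits_path, predictions_path, library_manifest,
              pdb_unclassified_manifest))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  cfg <- list(models_dir = models_dir, hits_path = hits_path,
              out_dir = out_dir, predictions_path = predictions_path,
              library_manifest = library_manifest,
              pdb_unclassified_manifest = pdb_unclassified_manifest,
              qc_thresholds = qc_thresholds,
              assign_thresholds = assign_thresholds,
              cluster_cutoff = cluster_cutoff,
              overlap_tolerance = as.integer(overlap_tolerance),
              stages = stages, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

read_library_manifest <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(tab)), function(i)
    parse_model(file.path(dirname(path), tab$path[i]), tab$id[i]))
  domain_library(models, tab$superfamily, tab$id)
}

read_predictions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  preds <- lapply(seq_len(nrow(tab)), function(i)
    prediction_record(tab$domain_id[i], tab$predicted_superfamily[i],
                      tab$probability[i]))
  names(preds) <- tab$domain_id
  preds
}

parse_models_dir <- function(models_dir) {
  files <- sort(list.files(models_dir, pattern = "\\.pdb$",
                           full.names = TRUE))
  models <- list()
  for (f in files) {
    stem <- sub("\\.pdb$", "", basename(f))
    frag <- 1L
    m <- regmatches(stem, regexec("^(.*)_F([0-9]+)$", stem))[[1]]
    pid <- stem
    if (length(m) == 3L) { pid <- m[2]; frag <- as.integer(m[3]) }
    models[[length(models) + 1L]] <- parse_model(f, pid, frag)
  }
  models
}

#' Run the full classification pipeline
#'
#' Executes, in protocol order: parse models; resolve the hit table to the
#' optimal non-overlapping domain layout per protein; choose the fragment
#' containing each selected domain and chop it; quality-filter every
#' chopped domain; assign QC-passing domains to superfamilies through the
#' comparator cascade (assigned domains join the peer library for later
#' queries); cluster the remaining unassigned domains by single linkage
#' and triage each cluster. Every excluded domain carries a
#' machine-readable reason in the audit log; summary counts are checked
#' for conservation (chopped = pass + fail; pass = assigned + unassigned;
#' unassigned = sum of cluster members) before anything is reported.
#' Reruns with an identical configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @return a `run_summary` (also written to `out_dir` with all artifact
#'   tables).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "chopped"), showWarnings = FALSE)
  saveRDS_free_config(config, file.path(out, "config.json"))
  audit <- file(file.path(out, "audit.jsonl"), "w")
  on.exit(close(audit))
  note <- function(...) {
    rec <- list(...)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 6), audit)
  }

  models <- parse_models_dir(config$models_dir)
  pids <- vapply(models, function(m) m$protein_id, "")
  hits <- load_hits(config$hits_path)
  preds <- if (!is.null(config$predictions_path))
    read_predictions(config$predictions_path) else list()
  library <- if (!is.null(config$library_manifest))
    read_library_manifest(config$library_manifest) else NULL
  pdb_unc <- if (!is.null(config$pdb_unclassified_manifest))
    read_library_manifest(config$pdb_unclassified_manifest) else NULL

  # resolve hits per protein and chop
  by_prot <- split(hits, vapply(hits, function(h) h$protein_id, ""))
  chopped <- list()
  n_unchoppable <- 0L
  for (pid in sort(names(by_prot))) {
    frag_models <- models[pids == pid]
    if (length(frag_models) == 0L) next
    ranges <- t(vapply(frag_models, function(m)
      range(m$residues$seq_index), integer(2)))
    fs <- list(protein_id = pid, protein_length = max(ranges[, 2]),
               fragment_length = NA_integer_, step = NA_integer_,
               fragments = data.frame(
                 fragment_index = vapply(frag_models, function(m)
                   m$fragment_index, 1L),
                 first_residue = ranges[, 1], last_residue = ranges[, 2]))
    class(fs) <- "fragment_set"
    layout <- resolve_hits(by_prot[[pid]], config$overlap_tolerance,
                           protein_length = max(ranges[, 2]))
    utils::write.table(layout_table(layout),
                       file.path(out, paste0("layout_", gsub("[^A-Za-z0-9_.-]", "_", pid), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (h in layout$selected) {
      reg <- tryCatch(domain_region(pid, h$segments, h$source, h$family_id),
                      error = function(e) NULL)
      if (is.null(reg)) {
        note(protein = pid, stage = "resolve", status = "excluded",
             reason = "below domain-size criterion")
        next
      }
      fidx <- tryCatch(choose_fragment(reg, fs), error = function(e) {
        if (inherits(e, "domassign_unchoppable")) NA_integer_ else stop(e)
      })
      if (is.na(fidx)) {
        n_unchoppable <- n_unchoppable + 1L
        note(protein = pid, domain = region_id(reg), stage = "chop",
             status = "excluded", reason = "unchoppable: fits no fragment")
        next
      }
      fm <- frag_models[[which(fs$fragments$fragment_index == fidx)]]
      dm <- chop(fm, reg)
      did <- region_id(reg)
      md5 <- sequence_md5(model_sequence(dm))
      write_domain(fm, reg,
                   file.path(out, "chopped",
                             paste0(domain_stem(pid, reg$segments), ".pdb")),
                   metadata = list(domain_md5 = md5,
                                   source_fragment = fidx,
                                   family = h$family_id))
      chopped[[did]] <- list(id = did, model = dm, region = reg,
                             source = h$source, family = h$family_id)
      note(protein = pid, domain = did, stage = "chop", status = "ok",
           fragment = fidx, md5 = md5)
    }
  }

  # quality control
  qc_pass <- list(); qc_fail_rules <- list()
  reports <- list()
  if ("qc" %in% config$stages) {
    for (did in sort(names(chopped))) {
      r <- qc_report(chopped[[did]]$model, config$qc_thresholds)
      r$protein_id <- did
      reports[[did]] <- r
      if (r$verdict == "pass") qc_pass[[did]] <- chopped[[did]]
      else qc_fail_rules[[did]] <- r$failed_rules
      note(domain = did, stage = "qc", status = r$verdict,
           failed_rules = r$failed_rules)
    }
    if (length(reports) > 0L)
      utils::write.table(qc_table(reports), file.path(out, "qc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    qc_pass <- chopped
  }

  # cascade assignment
  decisions <- list(); assigned <- list(); unassigned <- list()
  peer_models <- list(); peer_labels <- character(0); peer_ids <- character(0)
  if ("assign" %in% config$stages && !is.null(library)) {
    for (did in sort(names(qc_pass))) {
      d <- qc_pass[[did]]
      peers <- if (length(peer_models) > 0L)
        domain_library(peer_models, peer_labels, peer_ids) else NULL
      dec <- cascade_assign(d$model, d$region, preds[[did]], library,
                            peers = peers,
                            thresholds = config$assign_thresholds)
      dec$query_id <- did
      decisions[[did]] <- dec
      if (dec$stage != "unassigned") {
        assigned[[did]] <- dec
        peer_models[[length(peer_models) + 1L]] <- d$model
        peer_labels <- c(peer_labels, dec$assigned_superfamily)
        peer_ids <- c(peer_ids, did)
      } else {
        unassigned[[did]] <- d
      }
      note(domain = did, stage = "assign", status = dec$stage,
           superfamily = dec$assigned_superfamily)
    }
    if (length(decisions) > 0L) {
      dtab <- do.call(rbind, lapply(decisions, function(x)
        data.frame(query = x$query_id, stage = x$stage,
                   superfamily = x$assigned_superfamily,
                   score = if (is.null(x$best_hit)) NA else x$best_hit$score,
                   overlap = if (is.null(x$best_hit)) NA else
                     x$best_hit$query_overlap)))
      utils::write.table(dtab, file.path(out, "decisions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  } else {
    unassigned <- qc_pass
  }

  # clustering + triage of the unassigned
  clusters <- list()
  if ("cluster" %in% config$stages && length(unassigned) > 0L) {
    umodels <- lapply(unassigned, function(d) d$model)
    names(umodels) <- names(unassigned)
    edges <- all_vs_all(umodels, edge_threshold = config$cluster_cutoff,
                        overlap = config$assign_thresholds$overlap)
    clusters <- single_linkage(edges, config$cluster_cutoff,
                               ids = names(umodels))
    assigned_lib <- if (length(peer_models) > 0L)
      domain_library(peer_models, peer_labels, peer_ids) else NULL
    clusters <- lapply(clusters, triage_cluster, models = umodels,
                       pdb_unclassified = pdb_unc, assigned = assigned_lib,
                       thresholds = config$assign_thresholds)
    if (length(edges) > 0L)
      utils::write.table(edges, file.path(out, "edges.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (length(clusters) > 0L)
      utils::write.table(cluster_table(clusters),
                         file.path(out, "clusters.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  fail_by_rule <- table(unlist(qc_fail_rules))
  stage_counts <- table(vapply(assigned, function(d) d$stage, ""))
  triage_counts <- table(vapply(clusters, function(cl) cl$triage, ""))
  summary <- list(
    n_models = length(models),
    n_hits = length(hits),
    n_unchoppable = n_unchoppable,
    n_chopped = length(chopped),
    n_qc_pass = length(qc_pass),
    n_qc_fail = length(chopped) - length(qc_pass),
    qc_fail_by_rule = as.list(fail_by_rule),
    n_assigned = length(assigned),
    assigned_by_stage = as.list(stage_counts),
    n_unassigned = length(unassigned),
    n_clusters = length(clusters),
    cluster_members = sum(vapply(clusters, function(cl)
      length(cl$members), 1L)),
    clusters_by_triage = as.list(triage_counts),
    by_source = as.list(table(vapply(chopped, function(d) d$source, ""))))
  class(summary) <- "run_summary"
  check_conservation(summary, has_cluster = "cluster" %in% config$stages &&
                       length(unassigned) > 0L)
  jsonlite::write_json(unclass(summary), file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_text(summary), file.path(out, "summary.txt"))
  summary
}

saveRDS_free_config <- function(config, path) {
  cfg <- unclass(config)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

check_conservation <- function(summary, has_cluster = TRUE) {
  if (summary$n_chopped != summary$n_qc_pass + summary$n_qc_fail)
    stop("count conservation violated: chopped != qc_pass + qc_fail")
  if (summary$n_qc_pass != summary$n_assigned + summary$n_unassigned)
    stop("count conservation violated: qc_pass != assigned + unassigned")
  if (has_cluster && summary$n_unassigned != summary$cluster_members)
    stop("count conservation violated: unassigned != cluster members")
  invisible(TRUE)
}

report_text <- function(summary) {
  pct <- function(a, b) if (b == 0) "0.0%" else sprintf("%.1f%%", 100 * a / b)
  c(sprintf("models parsed:        %d", summary$n_models),
    sprintf("hits loaded:          %d", summary$n_hits),
    sprintf("domains chopped:      %d (unchoppable: %d)",
            summary$n_chopped, summary$n_unchoppable),
    sprintf("QC pass:              %d (%s)", summary$n_qc_pass,
            pct(summary$n_qc_pass, summary$n_chopped)),
    sprintf("QC fail:              %d", summary$n_qc_fail),
    if (length(summary$qc_fail_by_rule) > 0L)
      sprintf("  by rule:            %s",
              paste(sprintf("%s=%d", names(summary$qc_fail_by_rule),
                            unlist(summary$qc_fail_by_rule)),
                    collapse = " ")),
    sprintf("assigned:             %d (%s of QC-passing)", summary$n_assigned,
            pct(summary$n_assigned, summary$n_qc_pass)),
    if (length(summary$assigned_by_stage) > 0L)
      sprintf("  by stage:           %s",
              paste(sprintf("%s=%d", names(summary$assigned_by_stage),
                            unlist(summary$assigned_by_stage)),
                    collapse = " ")),
    sprintf("unassigned:           %d", summary$n_unassigned),
    sprintf("clusters:             %d", summary$n_clusters),
    if (length(summary$clusters_by_triage) > 0L)
      sprintf("  by triage:          %s",
              paste(sprintf("%s=%d", names(summary$clusters_by_triage),
                            unlist(summary$clusters_by_triage)),
                    collapse = " ")))
}

#' Human-readable run report
#'
#' Renders the summary with derived percentages (never stored
#' independently) after re-checking count conservation; a summary whose
#' counts do not conserve raises an error rather than printing.
#'
#' @param summary a `run_summary`.
#' @return character vector of report lines, invisibly (also printed).
#' @export
report <- function(summary) {
  stopifnot(inherits(summary, "run_summary"))
  check_conservation(summary,
                     has_cluster = summary$n_clusters > 0L ||
                       summary$n_unassigned == 0L)
  txt <- report_text(summary)
  cat(txt, sep = "\n")
  invisible(txt)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Write a complete synthetic pipeline scenario to disk
#'
#' Builds an end-to-end input set from the synthetic generators: a
#' labelled fold library (written as PDB files with a manifest), query
#' proteins that are noisy copies of library folds (with hit rows and
#' prediction records), unrelated decoy proteins, and one low-confidence
#' protein that the QC stage must remove. Ground truth (true superfamily
#' per query, planted QC failures) is returned and written as JSON.
#'
#' Because the built-in globularity metrics are implementation-coupled
#' percentiles, the scenario also calibrates the packing/SES cuts on a
#' reference battery of compact bundles and returns the resulting
#' `qc_thresholds`, mirroring how the published cuts were derived from a
#' curated domain reference.
#'
#' @param dir scenario directory (created).
#' @param seed master seed.
#' @param n_sfams,n_reps,n_queries,n_decoys,sigma forwarded to
#'   [make_assignment_benchmark()] (with sequence-correlated noise, so the
#'   perturbed copies keep realistic backbone geometry for the QC stage).
#' @return list with input paths (ready for [run_config()]),
#'   `qc_thresholds` and `ground_truth`.
#' @export
make_pipeline_scenario <- function(dir, seed = 1L, n_sfams = 6L, n_reps = 2L,
                                   n_queries = 8L, n_decoys = 3L,
                                   sigma = 0.5) {
  dir.create(file.path(dir, "models"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "library"), showWarnings = FALSE)
  bench <- make_assignment_benchmark(n_sfams, n_reps, n_queries, 0L,
                                     sigma, seed, smooth = 3L)
  # library on disk
  lib_rows <- list()
  for (e in bench$library) {
    p <- paste0(e$id, ".pdb")
    write_domain(e$model, NULL, file.path(dir, "library", p))
    lib_rows[[length(lib_rows) + 1L]] <- data.frame(
      id = e$id, superfamily = e$superfamily, path = p)
  }
  write_manifest(do.call(rbind, lib_rows),
                 file.path(dir, "library", "manifest.tsv"))
  hits <- list(); pred_rows <- list(); truth <- list()
  add_protein <- function(model, source, family, prediction = NULL,
                          true_sfam = "", planted_qc = character(0)) {
    write_domain(model, NULL,
                 file.path(dir, "models", paste0(model$protein_id, ".pdb")))
    n <- n_residues(model)
    hits[[length(hits) + 1L]] <<- domain_hit(model$protein_id, source,
                                             family, c(1L, n), 100)
    did <- sprintf("%s/1-%d", model$protein_id, n)
    if (!is.null(prediction))
      pred_rows[[length(pred_rows) + 1L]] <<- data.frame(
        domain_id = did, predicted_superfamily = prediction$predicted_superfamily,
        probability = prediction$probability)
    truth[[length(truth) + 1L]] <<- list(
      domain_id = did, true_superfamily = true_sfam,
      planted_qc_violations = planted_qc)
  }
  for (q in bench$queries)
    add_protein(q$model, "Pfam", "PF0001", q$prediction, q$true_superfamily)
  # decoys here must stay compact (QC-passing) while matching no library
  # fold: 7- and 8-helix architectures, absent from the fold vocabulary
  # (decoys may share a geometry with each other; they then simply cluster)
  compact_decoys <- list(c(7L, 11L, 9.5), c(8L, 10L, 9.5))
  for (d in seq_len(n_decoys)) {
    s <- compact_decoys[[((d - 1L) %% length(compact_decoys)) + 1L]]
    m <- perturb(make_bundle(s[1], s[2], s[3],
                             protein_id = sprintf("decoy%02d", d)),
                 0.3, seed = seed * 4000L + d, smooth = 3L)
    add_protein(m, "NewFam", "", NULL, "")
  }
  lowq <- inject_plddt(make_bundle(3L, 18L, 10, protein_id = "lowq"), 55)
  add_protein(lowq, "NewFam", "", NULL, "",
              planted_qc = c("min_mean_plddt", "max_single_lur_fraction"))
  write_hits(hits, file.path(dir, "hits.tsv"))
  if (length(pred_rows) > 0L)
    utils::write.table(do.call(rbind, pred_rows),
                       file.path(dir, "predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_ground_truth(truth, file.path(dir, "ground_truth.json"))
  # calibration reference: generic compact bundles plus the library folds
  # themselves (the curated reference role); a guard band absorbs the
  # coordinate noise of the query copies
  generic <- lapply(1:20, function(i)
    make_bundle(3L + i %% 3, 12L + (i %% 7) * 2, 9 + (i %% 4) * 0.5,
                protein_id = paste0("ref", i)))
  refs <- do.call(rbind, lapply(c(generic, lapply(bench$library,
                                                  function(e) e$model)),
                                function(b)
    data.frame(packing_density = packing_density(b),
               ses_per_volume = ses_area_volume(b)$ses_per_volume)))
  qc_thr <- calibrate_thresholds(refs, percentile = 1.0)
  qc_thr$min_packing_density <- 0.85 * qc_thr$min_packing_density
  qc_thr$max_ses_per_volume <- 1.15 * qc_thr$max_ses_per_volume
  list(qc_thresholds = qc_thr,
       models_dir = file.path(dir, "models"),
       hits_path = file.path(dir, "hits.tsv"),
       predictions_path = file.path(dir, "predictions.tsv"),
       library_manifest = file.path(dir, "library", "manifest.tsv"),
       ground_truth = truth)
}
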