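test_that("all-vs-all scores each unordered pair once in canonical order", {
  b <- make_bundle(3L, 16L, 9.5)
  single <- list(a = b)
  expect_equal(nrow(all_vs_all(single, edge_threshold = 0.5)), 0L)
  doms <- list(a = b, b = perturb(b, 0.4, 1), c = make_bundle(4L, 13L, 10))
  edges <- all_vs_all(doms, edge_threshold = 0.5)
  expect_lte(nrow(edges), 3L)
  expect_true(all(edges$id_a < edges$id_b))
  expect_true(edges$passed[edges$id_a == "a" & edges$id_b == "b"])
})

test_that("passing edges form cliques matching the generator's templates", {
  t1 <- make_bundle(3L, 18L, 9.5, protein_id = "t1")
  t2 <- make_bundle(2L, 26L, 9, protein_id = "t2")
  doms <- c(setNames(lapply(1:3, function(i) perturb(t1, 0.4, i)),
                     paste0("a", 1:3)),
            setNames(lapply(1:2, function(i) perturb(t2, 0.4, i + 10)),
                     paste0("b", 1:2)))
  edges <- all_vs_all(doms, edge_threshold = 0.5)
  passed <- edges[edges$passed, ]
  key <- function(x) substr(x, 1, 1)
  expect_true(all(key(passed$id_a) == key(passed$id_b)))
  expect_equal(nrow(passed[key(passed$id_a) == "a", ]), 3L)  # 3-clique
  expect_equal(nrow(passed[key(passed$id_a) == "b", ]), 1L)
  clusters <- single_linkage(edges, 0.5, ids = names(doms))
  expect_equal(lapply(clusters, `[[`, "members"),
               list(c("a1", "a2", "a3"), c("b1", "b2")))
})

test_that("single linkage at a cutoff equals union-find components", {
  # definition-forced chaining
  edges <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"),
                      weight = c(0.9, 0.8))
  cl <- single_linkage(edges, 0.5, ids = c("a", "b", "c"))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, c("a", "b", "c"))
  # no passing edges: all singletons
  cl0 <- single_linkage(edges, 0.95, ids = c("a", "b", "c"))
  expect_length(cl0, 3L)
  # randomized equivalence with a union-find oracle
  set.seed(13)
  for (trial in 1:500) {
    n <- sample(3:12, 1L)
    ids <- paste0("d", seq_len(n))
    m <- sample(0:(n * 2), 1L)
    ea <- sample(ids, m, replace = TRUE)
    eb <- sample(ids, m, replace = TRUE)
    keep <- ea != eb
    edges <- data.frame(id_a = ea[keep], id_b = eb[keep],
                        weight = runif(sum(keep)))
    cutoff <- runif(1)
    got <- lapply(single_linkage(edges, cutoff, ids), `[[`, "members")
    pass <- edges$weight >= cutoff
    want <- uf_components(ids, edges$id_a[pass], edges$id_b[pass])
    expect_setequal(got, want)
  }
})

test_that("raising the cutoff only refines clusters, never merges", {
  set.seed(21)
  ids <- paste0("d", 1:15)
  ea <- sample(ids, 40, replace = TRUE)
  eb <- sample(ids, 40, replace = TRUE)
  keep <- ea != eb
  edges <- data.frame(id_a = ea[keep], id_b = eb[keep],
                      weight = runif(sum(keep)))
  cuts <- c(0.2, 0.5, 0.8)
  parts <- lapply(cuts, function(ct)
    lapply(single_linkage(edges, ct, ids), `[[`, "members"))
  for (k in 1:2) {
    fine <- parts[[k + 1]]; coarse <- parts[[k]]
    for (cl in fine) {
      inside <- vapply(coarse, function(cc) all(cl %in% cc), TRUE)
      expect_equal(sum(inside), 1L)   # every finer cluster nests in one coarser
    }
  }
  # every partition covers all ids exactly once
  for (p in parts) expect_setequal(unlist(p), ids)
})

test_that("cluster triage separates PDB matches, multidomain and novel folds", {
  t_known <- make_bundle(3L, 18L, 9.5, protein_id = "known")
  t_pdb <- make_bundle(4L, 20L, 9, protein_id = "pdbfold")
  assigned <- domain_library(list(t_known), "1.10.10.10", "known1")
  pdb_unc <- domain_library(list(t_pdb), "", "pdb1")
  models <- list(
    # a near copy of the unclassified-PDB entry
    hitpdb = perturb(t_pdb, 0.3, 1),
    # two known folds concatenated: only part matches the assigned library
    multi = concat_models(perturb(t_known, 0.3, 2),
                          make_bundle(2L, 24L, 9, protein_id = "x"),
                          protein_id = "multi"),
    # geometry absent from every library
    novel = make_bundle(6L, 11L, 12, protein_id = "novel"))
  mk_cluster <- function(id) {
    cl <- list(members = id, triage = NA_character_)
    class(cl) <- "domain_cluster"
    cl
  }
  tr <- function(id) triage_cluster(mk_cluster(id), models,
                                    pdb_unclassified = pdb_unc,
                                    assigned = assigned)$triage
  expect_equal(tr("hitpdb"), "pdb_unclassified_match")
  expect_equal(tr("multi"), "multidomain")
  expect_equal(tr("novel"), "putative_new")
  # with no libraries only putative_new is possible
  expect_equal(triage_cluster(mk_cluster("hitpdb"), models)$triage,
               "putative_new")
})

test_that("triage is invariant to member order and picks the top-pLDDT representative", {
  t1 <- make_bundle(3L, 18L, 9.5)
  models <- list(m1 = inject_plddt(perturb(t1, 0.3, 1), 80),
                 m2 = inject_plddt(perturb(t1, 0.3, 2), 95),
                 m3 = inject_plddt(perturb(t1, 0.3, 3), 90))
  mk <- function(members) {
    cl <- list(members = members, triage = NA_character_)
    class(cl) <- "domain_cluster"
    cl
  }
  expect_equal(cluster_representative(mk(c("m1", "m2", "m3")), models), "m2")
  lib <- domain_library(list(t1), "1.10.10.10", "ref")
  a <- triage_cluster(mk(c("m1", "m2", "m3")), models, assigned = lib)
  b <- triage_cluster(mk(c("m3", "m1", "m2")), models, assigned = lib)
  expect_equal(a$triage, b$triage)
  expect_equal(a$representative, b$representative)
})
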