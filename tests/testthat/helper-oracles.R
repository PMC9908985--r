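# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# exhaustive run scanner for long unordered regions
brute_lurs <- function(plddt, min_len = 5L, cut = 70) {
  n <- length(plddt)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (plddt[i] < cut) {
      j <- i
      while (j < n && plddt[j + 1L] < cut) j <- j + 1L
      if (j - i + 1L >= min_len)
        runs[[length(runs) + 1L]] <- c(i, j, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(runs) == 0L)
    return(data.frame(start = integer(0), stop = integer(0),
                      length = integer(0)))
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1], stop = m[, 2], length = m[, 3])
}

# O(n^2) all-pairs packing density
brute_packing <- function(model, cutoff = 5,
                          hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C")) {
  res <- model$residues
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  nres <- nrow(res)
  counts <- integer(nres)
  for (i in seq_len(nres)) {
    ai <- xyz[at$seq_index == res$seq_index[i], , drop = FALSE]
    for (j in seq_len(nres)) {
      if (i == j) next
      aj <- xyz[at$seq_index == res$seq_index[j], , drop = FALSE]
      dmin <- min(sqrt(outer(rowSums(ai^2), rowSums(aj^2), "+") -
                       2 * tcrossprod(ai, aj)))
      if (dmin <= cutoff) counts[i] <- counts[i] + 1L
    }
  }
  mean(counts[res$aa %in% hydrophobic])
}

# union-find connected components over a thresholded edge list
uf_components <- function(ids, edges_a, edges_b) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, "")
  unname(lapply(split(ids, roots), sort))
}

# exhaustive subset enumeration for hit resolution (<= ~12 hits)
brute_resolve_score <- function(hits, tol) {
  n <- length(hits)
  sets <- lapply(hits, domassign::hit_residues)
  scores <- vapply(hits, function(h) h$score, 1.0)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    ok <- TRUE
    if (length(idx) >= 2L) {
      for (a in seq_along(idx)) {
        for (b in seq_along(idx)) {
          if (a >= b) next
          if (length(intersect(sets[[idx[a]]], sets[[idx[b]]])) > tol) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
    }
    if (ok) best <- max(best, sum(scores[idx]))
  }
  best
}

# quaternion (Horn) absolute-orientation RMSD, an independent check on the
# SVD-based superposition
quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  M <- crossprod(A0, B0)
  S <- M
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# random compact blob of CA/CB pseudo-residues for metric oracles
random_blob_model <- function(n, seed, box = 12) {
  set.seed(seed)
  aa <- sample(c("A", "V", "L", "G", "S", "K", "E", "F"), n, replace = TRUE)
  ca <- matrix(stats::runif(n * 3, 0, box), n, 3)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      seq_index = i, name = "CA", element = "C",
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3])
    rows[[length(rows) + 1L]] <- data.frame(
      seq_index = i, name = "CB", element = "C",
      x = ca[i, 1] + 0.8, y = ca[i, 2] + 0.4, z = ca[i, 3])
  }
  domassign::structure_model(
    paste0("blob", seed),
    data.frame(seq_index = seq_len(n), aa = aa, plddt = 90),
    do.call(rbind, rows))
}

# random domain-hit instances for the resolver oracle
random_hits <- function(n_hits, seed, protein_len = 120L) {
  set.seed(seed)
  hits <- list()
  for (k in seq_len(n_hits)) {
    start <- sample.int(protein_len - 45L, 1L)
    stop <- min(protein_len, start + sample(40:70, 1L))
    segs <- c(start, stop)
    if (stats::runif(1) < 0.25 && stop + 15L < protein_len) {
      s2 <- stop + sample(5:12, 1L)
      segs <- rbind(segs, c(s2, min(protein_len, s2 + sample(40:55, 1L))))
    }
    hits[[k]] <- domassign::domain_hit("P1", "Pfam", paste0("F", k), segs,
                                       score = round(stats::runif(1, 1, 100), 1))
  }
  hits
}

# canonical compact fixture for QC tests
compact_pass_model <- function(plddt = 90)
  domassign::make_bundle(4L, 16L, 9, protein_id = "compact", plddt = plddt)

# globularity thresholds calibrated once on a reference battery of compact
# bundles (the built-in metrics are implementation-coupled, so the published
# cuts do not transfer; see calibrate_thresholds)
.thr_cache <- new.env()
calibrated_thr <- function() {
  if (is.null(.thr_cache$thr)) {
    refs <- lapply(1:24, function(i) domassign::qc_report(
      domassign::make_bundle(3L + i %% 3, 14L + (i %% 4) * 2,
                             9 + (i %% 3) * 0.5,
                             protein_id = paste0("ref", i))))
    .thr_cache$thr <- domassign::calibrate_thresholds(refs, percentile = 1.0)
  }
  .thr_cache$thr
}
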