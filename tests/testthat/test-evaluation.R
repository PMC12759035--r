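test_that("PPV is the matched fraction of description features", {
  # a 25-feature description with 12 features seen in the index
  expect_equal(ppv(sprintf("T%02d", 1:25), sprintf("T%02d", 1:12)), 0.48)
  # restricted to 10 selected features of which 6 match
  expect_equal(ppv(sprintf("S%02d", 1:10), sprintf("S%02d", 1:6)), 0.6)
  expect_equal(ppv(c("A", "B"), c("C", "D")), 0)
  expect_equal(ppv(c("A", "B"), c("B", "A", "Z")), 1)
  expect_error(ppv(character(0), "A"), "undefined")
})

# Cohort of identical deletions with identical phenotypes.
identical_cohort <- function(n = 8) {
  ids <- sprintf("P%02d", seq_len(n))
  sets <- stats::setNames(rep(list(1:5), n), ids)
  universe <- c("TERM:A", "TERM:B")
  present <- stats::setNames(rep(list(universe), n), ids)
  genotypes <- genotypes_from_sets(sets)
  phenotypes <- phenotypes_from_lists(ids, universe, present)
  list(cohort = cnv_cohort(genotypes, phenotypes),
       genes = make_gene_map(5), universe = universe)
}

test_that("perfect concordance gives PPV 1 at every threshold", {
  fx <- identical_cohort(8)
  rec <- leave_one_out_sweep(fx$cohort, fx$genes, fx$universe, "6",
                             thresholds = seq(1, 0, by = -0.25))
  expect_equal(nrow(rec), 8 * 5) # every patient eligible at every threshold
  expect_true(all(rec$ppv == 1))
  expect_true(all(rec$n_connections == 7))
})

test_that("a threshold above all pairwise similarities yields no records", {
  # two clusters sharing half their HI genes: max cross-similarity 1/3,
  # within-cluster groups have only 3 connections (< 5)
  ids <- sprintf("P%02d", 1:8)
  sets <- c(stats::setNames(rep(list(c(1:2, 5:6)), 4), ids[1:4]),
            stats::setNames(rep(list(c(3:4, 5:6)), 4), ids[5:8]))
  genotypes <- genotypes_from_sets(sets)
  phenotypes <- phenotypes_from_lists(ids, "TERM:A")
  cohort <- cnv_cohort(genotypes, phenotypes)
  rec <- leave_one_out_sweep(cohort, make_gene_map(6), "TERM:A", "6",
                             thresholds = 0.9)
  expect_equal(nrow(rec), 0)
})

test_that("patients below the connection floor are skipped, not zero-filled", {
  fx <- identical_cohort(5) # 4 connections each < default floor of 5
  rec <- leave_one_out_sweep(fx$cohort, fx$genes, fx$universe, "6",
                             thresholds = 1)
  expect_equal(nrow(rec), 0)
  relaxed <- similarity_settings(min_connections_for_ppv = 4L)
  rec2 <- leave_one_out_sweep(fx$cohort, fx$genes, fx$universe, "6",
                              thresholds = 1, settings = relaxed)
  expect_equal(nrow(rec2), 5)
})

test_that("the sweep matches a brute-force enumeration on small cohorts", {
  # independent oracle: per-base gene overlap, loop-counted Jaccard,
  # hand-rolled grouping and description
  brute_sweep <- function(cohort, genes, subset, thresholds) {
    ids <- cohort$patients$patient_id
    gene_set <- function(pid) {
      rows <- cohort$genotypes[cohort$genotypes$patient_id == pid &
                                 cohort$genotypes$chromosome == "6" &
                                 cohort$genotypes$type == "deletion", ]
      hits <- character(0)
      for (k in seq_len(nrow(genes))) {
        for (r in seq_len(nrow(rows))) {
          bases_g <- genes$start[k]:genes$end[k]
          bases_a <- rows$start[r]:rows$end[r]
          if (length(intersect(bases_g, bases_a)) > 0) {
            hits <- c(hits, genes$gene_id[k])
          }
        }
      }
      unique(hits)
    }
    gsets <- lapply(stats::setNames(ids, ids), gene_set)
    hi <- lapply(gsets, function(g) g[g %in% genes$gene_id[genes$is_hi]])
    de <- lapply(gsets, function(g)
      g[g %in% genes$gene_id[genes$is_dominating_effect]])
    jac <- function(a, b) {
      u <- unique(c(a, b))
      if (length(u) == 0) return(1)
      length(unique(a[a %in% b])) / length(u)
    }
    is_present <- function(pid, term) {
      any(cohort$phenotypes$patient_id == pid &
            cohort$phenotypes$term_id == term &
            cohort$phenotypes$status == "present")
    }
    out <- list()
    for (t in thresholds) for (id in ids) {
      ok <- vapply(ids, function(o) setequal(de[[id]], de[[o]]) &&
                     jac(hi[[id]], hi[[o]]) >= t - 1e-9, logical(1))
      members <- ids[ids != id & ok]
      if (length(members) < 5) next
      need <- max(ceiling(0.2 * length(members) - 1e-9), 2)
      counts <- vapply(subset, function(term)
        sum(vapply(members, is_present, logical(1), term = term)), numeric(1))
      included <- subset[counts >= need]
      matched <- sum(vapply(included, is_present, logical(1), pid = id))
      out[[length(out) + 1]] <- data.frame(
        index_id = id, hi_threshold = t, n_connections = length(members),
        n_description_features = length(included), n_matched = matched,
        ppv = if (length(included) > 0) matched / length(included)
              else NA_real_, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }

  set.seed(71)
  ids <- sprintf("P%02d", 1:10)
  sets <- stats::setNames(lapply(1:10, function(i) {
    base <- if (i <= 6) 1:4 else 3:6
    sort(unique(c(base, sample(1:8, sample(0:2, 1)))))
  }), ids)
  universe <- sprintf("TERM:%d", 1:6)
  present <- stats::setNames(lapply(1:10, function(i)
    sample(universe, sample(2:5, 1))), ids)
  genotypes <- genotypes_from_sets(sets)
  phenotypes <- phenotypes_from_lists(ids, universe, present)
  cohort <- cnv_cohort(genotypes, phenotypes)
  genes <- make_gene_map(8, de = 4)
  thresholds <- c(1, 0.6, 0.3, 0)

  rec <- leave_one_out_sweep(cohort, genes, universe, "6", thresholds)
  oracle <- brute_sweep(cohort, genes, universe, thresholds)
  key <- function(d) d[order(d$hi_threshold, d$index_id),
                       c("index_id", "hi_threshold", "n_connections",
                         "n_description_features", "n_matched", "ppv")]
  expect_equal(key(as.data.frame(rec)), key(oracle),
               ignore_attr = TRUE)
})

test_that("sweep summaries report counts, medians and stratified tests", {
  rec <- data.frame(
    index_id = sprintf("P%02d", 1:20),
    hi_threshold = 0.5,
    n_connections = rep(c(10, 25), 10),
    n_description_features = 10L,
    n_matched = 5L,
    ppv = rep(0.5, 20),
    index_has_de = rep(c(TRUE, FALSE), each = 10)
  )
  s <- summarize_sweep(rec, size_bands = c(15L, 20L))
  expect_equal(s$thresholds$median_ppv, 0.5)
  expect_equal(s$thresholds$median_ppv_de, 0.5)
  expect_equal(s$thresholds$n_ge15, 10)
  expect_equal(s$thresholds$n_ge20, 10)
  # constant PPV: rank-sum test degenerate, flagged as NA
  expect_true(is.na(s$thresholds$p_de))

  # a clear stochastic shift gives a small p in the right direction
  set.seed(73)
  rec2 <- rec
  rec2$ppv <- ifelse(rec2$index_has_de, runif(20, 0.6, 1), runif(20, 0, 0.4))
  s2 <- summarize_sweep(rec2, size_bands = 15L)
  expect_lt(s2$thresholds$p_de, 0.01)
  expect_gt(s2$thresholds$median_ppv_de, s2$thresholds$median_ppv_no_de)

  # single record: medians defined, tests skipped
  s3 <- summarize_sweep(rec[1, ], size_bands = 15L)
  expect_equal(s3$thresholds$median_ppv, 0.5)
  expect_true(is.na(s3$thresholds$p_de))
  expect_true(is.na(s3$bands$p))
})

test_that("qualifying counts never increase with the threshold", {
  set.seed(79)
  sets <- random_sets(25, 8)
  fix <- make_set_cohort(sets, n_genes = 8, de = 2,
                         universe = sprintf("TERM:%d", 1:4))
  rec <- leave_one_out_sweep(fix$cohort, fix$genes, sprintf("TERM:%d", 1:4),
                             "6")
  if (nrow(rec) > 0) {
    s <- summarize_sweep(rec)
    thr <- s$thresholds[order(-s$thresholds$hi_threshold), ]
    for (col in c("n_eligible", "n_ge15", "n_ge20", "n_ge30")) {
      expect_true(all(diff(thr[[col]]) >= 0))
    }
  }
})
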