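# Fixture builders: cohorts whose per-patient gene content is prescribed
# exactly, so pairwise similarities are known by construction.
#
# Gene k (k = 1..n) spans [k*10000 + 1, k*10000 + 5000] on chromosome "6".
# A patient assigned gene indices {1..8, 11} receives one deletion per
# consecutive run of indices, covering exactly those genes and no others.

gene_start <- function(k) k * 10000L + 1L
gene_end <- function(k) k * 10000L + 5000L

# All genes HI by construction (pLI 0.99, HI% 1); `de` = indices flagged
# dominating-effect; `non_hi` = indices demoted to clearly benign scores.
make_gene_map <- function(n, de = integer(0), non_hi = integer(0)) {
  pli <- rep(0.99, n)
  hi_pct <- rep(1, n)
  pli[non_hi] <- 0.1
  hi_pct[non_hi] <- 80
  gene_table(
    gene_id = sprintf("g%02d", seq_len(n)),
    chromosome = "6",
    start = gene_start(seq_len(n)),
    end = gene_end(seq_len(n)),
    hi_percent = hi_pct, pli = pli, phaplo = NA_real_,
    is_dominating_effect = seq_len(n) %in% de
  )
}

# One aberration per consecutive run of gene indices.
runs_of <- function(idx) {
  idx <- sort(unique(idx))
  breaks <- c(0, which(diff(idx) != 1), length(idx))
  lapply(seq_len(length(breaks) - 1),
         function(i) idx[(breaks[i] + 1):breaks[i + 1]])
}

genotypes_from_sets <- function(sets) {
  rows <- lapply(names(sets), function(pid) {
    do.call(rbind, lapply(runs_of(sets[[pid]]), function(run) {
      data.frame(patient_id = pid, chromosome = "6",
                 start = gene_start(min(run)), end = gene_end(max(run)),
                 type = "deletion", stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

# `present`: named list patient -> character vector of present terms;
# every (patient, term in universe) pair gets an explicit status row.
phenotypes_from_lists <- function(patient_ids, universe,
                                  present = list(), cohort = "parent",
                                  unknown = list()) {
  cohort <- rep_len(cohort, length(patient_ids))
  rows <- lapply(seq_along(patient_ids), function(i) {
    pid <- patient_ids[i]
    status <- rep("absent", length(universe))
    status[universe %in% present[[pid]]] <- "present"
    status[universe %in% unknown[[pid]]] <- "unknown"
    data.frame(patient_id = pid, term_id = universe, status = status,
               cohort = cohort[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Cohort with prescribed gene sets and (optionally) phenotypes.
make_set_cohort <- function(sets, n_genes = max(unlist(sets)),
                            de = integer(0), universe = "CUST:0001",
                            present = list(), unknown = list(),
                            cohort = "parent") {
  genotypes <- genotypes_from_sets(sets)
  phenotypes <- phenotypes_from_lists(names(sets), universe, present,
                                      cohort, unknown)
  list(cohort = cnv_cohort(genotypes, phenotypes),
       genes = make_gene_map(n_genes, de = de))
}

# Random cohort over m genes for property tests (gene sets drawn directly).
random_sets <- function(n_patients, n_genes, de = integer(0)) {
  sets <- lapply(seq_len(n_patients), function(i) {
    k <- sample(1:min(8, n_genes), 1)
    sort(sample(seq_len(n_genes), k))
  })
  names(sets) <- sprintf("R%03d", seq_len(n_patients))
  # guarantee runs_of never produces an empty genotype
  sets
}
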