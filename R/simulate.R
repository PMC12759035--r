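#' Configuration for the synthetic-cohort simulator
#'
#' The simulator emulates the statistical structure a deletion
#' genotype-phenotype cohort exhibits: deletions clustered at recurrent
#' hotspot regions (so genotypically similar groups exist), gene-driven
#' penetrant phenotype features (dominating-effect genes carry highly
#' penetrant feature sets, other HI genes weaker ones), background features
#' unrelated to genotype, and a literature sub-cohort whose truly present
#' features are partially unreported (masked to `unknown`), reproducing the
#' parent-vs-literature asymmetry in feature counts.
#'
#' The defaults mirror a realistic single-chromosome deletion cohort: 452
#' patients of which about two thirds are literature cases, 600 genes on a
#' 171 Mb chromosome with about 20% HI genes (~120) of which 5 are
#' dominating-effect, log-normal deletion sizes with median ~4.5 Mb, and a
#' literature masking rate of 0.68 (literature cases report roughly a third
#' of the features parents report).
#'
#' @param seed Integer seed (mandatory; the run is fully reproducible).
#' @param n_patients Cohort size.
#' @param n_genes Genes on the simulated chromosome.
#' @param chromosome Chromosome label.
#' @param chromosome_length Chromosome length in base pairs.
#' @param hi_gene_fraction Fraction of genes that are HI.
#' @param n_de_genes Number of dominating-effect genes (flagged among HI
#'   genes).
#' @param score_missingness Probability each individual score is unknown.
#' @param features_per_de_gene,features_per_hi_gene Features linked to each
#'   DE / non-DE HI gene.
#' @param n_background_features Genotype-independent features.
#' @param de_feature_penetrance Probability a deleted DE gene's feature is
#'   present.
#' @param hi_feature_penetrance Same for non-DE HI genes.
#' @param background_feature_rate Per-patient probability of each background
#'   feature.
#' @param hotspot_regions `data.frame(start, end, weight)` of recurrent
#'   deletion regions; weights sum to the probability that a deletion centres
#'   on a hotspot (remainder uniform). `NULL` uses three default hotspots
#'   totalling 0.75.
#' @param deletion_size_meanlog,deletion_size_sdlog Log-normal deletion-size
#'   parameters (base pairs).
#' @param literature_fraction Fraction of patients labelled `literature`.
#' @param literature_masking_rate Probability a truly present feature of a
#'   literature case is recorded as `unknown`.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(
    seed,
    n_patients = 452L,
    n_genes = 600L,
    chromosome = "6",
    chromosome_length = 171115067,
    hi_gene_fraction = 0.20,
    n_de_genes = 5L,
    score_missingness = 0.20,
    features_per_de_gene = 3L,
    features_per_hi_gene = 1L,
    n_background_features = 40L,
    de_feature_penetrance = 0.90,
    hi_feature_penetrance = 0.40,
    background_feature_rate = 0.03,
    hotspot_regions = NULL,
    deletion_size_meanlog = log(4.5e6),
    deletion_size_sdlog = 1.1,
    literature_fraction = 310 / 452,
    literature_masking_rate = 0.68) {
  if (missing(seed) || !is.finite(seed)) {
    stop("simulation_config requires an integer seed", call. = FALSE)
  }
  if (is.null(hotspot_regions)) {
    hotspot_regions <- data.frame(
      start = round(chromosome_length * c(0.05, 0.45, 0.75)),
      end = round(chromosome_length * c(0.12, 0.55, 0.88)),
      weight = c(0.20, 0.25, 0.30)
    )
  }
  fracs <- c(hi_gene_fraction, score_missingness, de_feature_penetrance,
             hi_feature_penetrance, background_feature_rate,
             literature_fraction, literature_masking_rate)
  stopifnot(all(fracs >= 0), all(fracs <= 1),
            sum(hotspot_regions$weight) <= 1,
            all(hotspot_regions$weight >= 0),
            all(hotspot_regions$end <= chromosome_length),
            n_de_genes <= ceiling(n_genes * hi_gene_fraction))
  check_intervals(hotspot_regions$start, hotspot_regions$end, "hotspots")
  structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    n_genes = as.integer(n_genes), chromosome = as.character(chromosome),
    chromosome_length = chromosome_length,
    hi_gene_fraction = hi_gene_fraction, n_de_genes = as.integer(n_de_genes),
    score_missingness = score_missingness,
    features_per_de_gene = as.integer(features_per_de_gene),
    features_per_hi_gene = as.integer(features_per_hi_gene),
    n_background_features = as.integer(n_background_features),
    de_feature_penetrance = de_feature_penetrance,
    hi_feature_penetrance = hi_feature_penetrance,
    background_feature_rate = background_feature_rate,
    hotspot_regions = hotspot_regions,
    deletion_size_meanlog = deletion_size_meanlog,
    deletion_size_sdlog = deletion_size_sdlog,
    literature_fraction = literature_fraction,
    literature_masking_rate = literature_masking_rate
  ), class = "simulation_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a gene map with feature links
#'
#' Places non-overlapping gene spans along the chromosome, draws HI scores so
#' that exactly the configured fraction of genes satisfies the HI rule
#' (HI-destined genes get all three scores in the pathogenic range, the rest
#' all benign, so score missingness never flips a verdict), flags
#' `n_de_genes` HI genes as dominating-effect, and assigns each HI gene a
#' fixed set of associated feature codes (synthetic `CUST:` terms) emulating
#' curated gene-phenotype links.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_gene_map`: `genes` (a [gene_table()]),
#'   `feature_map` (`data.frame(term_id, gene_id)`, `gene_id` `NA` for
#'   background features) and `feature_universe` (all term ids).
#' @export
simulate_gene_map <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    slot <- floor(config$chromosome_length / n)
    width <- pmin(pmax(round(stats::rlnorm(n, log(3e4), 0.8)), 1e3),
                  slot - 2L)
    offset <- floor(stats::runif(n, 0, slot - width))
    start <- (seq_len(n) - 1L) * slot + offset + 1L
    end <- start + width - 1L

    n_hi <- round(n * config$hi_gene_fraction)
    is_hi_target <- seq_len(n) %in% sample.int(n, n_hi)
    hi_percent <- ifelse(is_hi_target, stats::runif(n, 0, 10),
                         stats::runif(n, 15, 95))
    pli <- ifelse(is_hi_target, stats::runif(n, 0.9, 1),
                  stats::runif(n, 0, 0.5))
    phaplo <- ifelse(is_hi_target, stats::runif(n, 0.86, 1),
                     stats::runif(n, 0, 0.5))
    drop <- matrix(stats::runif(3 * n) < config$score_missingness, n, 3)
    # keep at least one score known so HI-destined genes stay classifiable
    all_gone <- rowSums(drop) == 3
    drop[all_gone, 1] <- FALSE
    hi_percent[drop[, 1]] <- NA_real_
    pli[drop[, 2]] <- NA_real_
    phaplo[drop[, 3]] <- NA_real_

    de <- rep(FALSE, n)
    de[sample(which(is_hi_target), config$n_de_genes)] <- TRUE

    genes <- gene_table(
      gene_id = sprintf("G%04d", seq_len(n)),
      symbol = sprintf("GENE%04d", seq_len(n)),
      chromosome = config$chromosome,
      start = start, end = end,
      hi_percent = hi_percent, pli = pli, phaplo = phaplo,
      is_dominating_effect = de
    )

    hi_ids <- genes$gene_id[genes$is_hi]
    per_gene <- ifelse(genes$gene_id[genes$is_hi] %in%
                         genes$gene_id[genes$is_dominating_effect],
                       config$features_per_de_gene,
                       config$features_per_hi_gene)
    feature_map <- data.frame(
      term_id = character(0), gene_id = character(0), stringsAsFactors = FALSE)
    if (length(hi_ids) > 0) {
      feature_map <- data.frame(
        term_id = sprintf("CUST:%04d", seq_len(sum(per_gene))),
        gene_id = rep(hi_ids, per_gene), stringsAsFactors = FALSE)
    }
    if (config$n_background_features > 0) {
      bg <- data.frame(
        term_id = sprintf("CUST:9%03d", seq_len(config$n_background_features)),
        gene_id = NA_character_, stringsAsFactors = FALSE)
      feature_map <- rbind(feature_map, bg)
    }
    structure(list(genes = genes, feature_map = feature_map,
                   feature_universe = feature_map$term_id),
              class = "sim_gene_map")
  })
}

#' Simulate a patient cohort over a simulated gene map
#'
#' Draws one deletion per patient — centred on a hotspot region with the
#' configured probability, uniform elsewhere; log-normal size — then samples
#' phenotypes gene-wise: each deleted dominating-effect gene's linked features
#' are present with `de_feature_penetrance`, each deleted non-DE HI gene's
#' with `hi_feature_penetrance`, and background features with
#' `background_feature_rate`. Literature-cohort patients then have each truly
#' present feature masked to `unknown` with `literature_masking_rate`,
#' emulating under-reporting in case reports.
#'
#' @param config A [simulation_config()].
#' @param gene_map A [simulate_gene_map()] result.
#' @return A [cnv_cohort()].
#' @export
simulate_patients <- function(config, gene_map) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(gene_map, "sim_gene_map"))
  with_seed(config$seed + 1L, {
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    n_lit <- round(n * config$literature_fraction)
    cohort_label <- rep(c("literature", "parent"), c(n_lit, n - n_lit))

    hs <- config$hotspot_regions
    p_hot <- sum(hs$weight)
    size <- pmin(pmax(round(stats::rlnorm(n, config$deletion_size_meanlog,
                                          config$deletion_size_sdlog)), 5e3),
                 floor(config$chromosome_length / 4))
    u <- stats::runif(n)
    centre <- numeric(n)
    for (i in seq_len(n)) {
      if (u[i] < p_hot) {
        k <- sample.int(nrow(hs), 1, prob = hs$weight)
        centre[i] <- round(stats::runif(1, hs$start[k], hs$end[k]))
      } else {
        centre[i] <- round(stats::runif(1, 1, config$chromosome_length))
      }
    }
    start <- pmax(1, round(centre - size / 2))
    end <- pmin(config$chromosome_length, start + size - 1)
    genotypes <- genotype_table(ids, config$chromosome, start, end, "deletion")

    fm <- gene_map$feature_map
    genes <- gene_map$genes
    de_ids <- genes$gene_id[genes$is_dominating_effect]
    terms <- gene_map$feature_universe
    penetrance_of <- function(gene_id) {
      ifelse(is.na(gene_id), config$background_feature_rate,
             ifelse(gene_id %in% de_ids, config$de_feature_penetrance,
                    config$hi_feature_penetrance))
    }

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      deleted <- genes_in_aberration(config$chromosome, start[i], end[i],
                                     genes)
      active <- is.na(fm$gene_id) | fm$gene_id %in% deleted
      p <- ifelse(active, penetrance_of(fm$gene_id), 0)
      present <- stats::runif(length(terms)) < p
      status <- ifelse(present, "present", "absent")
      if (cohort_label[i] == "literature") {
        mask <- present & stats::runif(length(terms)) <
          config$literature_masking_rate
        status[mask] <- "unknown"
      }
      rows[[i]] <- data.frame(patient_id = ids[i], term_id = terms,
                              status = status, cohort = cohort_label[i],
                              stringsAsFactors = FALSE)
    }
    phenotypes <- do.call(rbind, rows)
    cnv_cohort(genotypes, phenotypes)
  })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_gene_map()] then
#' [simulate_patients()].
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_cohort`: `cohort` (a [cnv_cohort()]), `genes`,
#'   `feature_map`, `feature_universe`, `config`.
#' @export
simulate_cohort <- function(config) {
  gene_map <- simulate_gene_map(config)
  cohort <- simulate_patients(config, gene_map)
  structure(list(cohort = cohort, genes = gene_map$genes,
                 feature_map = gene_map$feature_map,
                 feature_universe = gene_map$feature_universe,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> seed ", x$config$seed, ": ", sep = "")
  print(x$cohort)
  invisible(x)
}
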