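#' Genotypic similarity settings
#'
#' Parameters controlling pairwise comparison, group formation, tier selection
#' and description generation. Defaults are the chromosome-6 deletion profile:
#' dominating-effect (DE) gene concordance is a hard gate; HI-gene similarity
#' is swept over a descending 0.1-step grid; groups of at least 20 are
#' accepted at HI-gene similarity thresholds of 0.8 and above, groups of at
#' least 15 at 0.7 and 0.6; below that a description is only produced when the
#' index deletion contains a DE gene, at the highest threshold still yielding
#' at least `de_fallback_min_group` members. Optional size/location/gene
#' Jaccard filters are disabled by default.
#'
#' @param hi_threshold_grid Descending vector of HI-gene similarity thresholds.
#' @param tier_rules `data.frame(min_hi, min_size)`, descending in `min_hi`:
#'   at grid threshold `min_hi` a group qualifies when it has at least
#'   `min_size` members.
#' @param de_fallback_min_group Minimum group size for the DE fallback tier.
#' @param prevalence_min Minimum fraction of the connected group exhibiting a
#'   feature for it to enter the description (default 0.20).
#' @param min_carrier_count Minimum absolute number of carriers (default 2),
#'   guarding small groups against single-patient features.
#' @param min_connections_for_ppv Minimum group size for a patient to enter
#'   the PPV evaluation (default 5).
#' @param min_size_jaccard,min_location_jaccard,min_gene_jaccard Optional
#'   additional filters in `[0, 1]`; `NULL` disables (the default profile).
#' @param hi_similarity_mode `"jaccard"` (symmetric Jaccard index of the two
#'   HI-gene sets, the default) or `"index_fraction"` (fraction of the index's
#'   HI genes shared with the other patient, asymmetric).
#' @param tol Absolute tolerance for threshold comparisons, so a 7/10 overlap
#'   passes a 0.7 threshold despite binary floating point.
#' @return An object of class `similarity_settings`.
#' @export
similarity_settings <- function(
    hi_threshold_grid = seq(1, 0, by = -0.1),
    tier_rules = data.frame(min_hi = c(1.0, 0.9, 0.8, 0.7, 0.6),
                            min_size = c(20L, 20L, 20L, 15L, 15L)),
    de_fallback_min_group = 15L,
    prevalence_min = 0.20,
    min_carrier_count = 2L,
    min_connections_for_ppv = 5L,
    min_size_jaccard = NULL,
    min_location_jaccard = NULL,
    min_gene_jaccard = NULL,
    hi_similarity_mode = c("jaccard", "index_fraction"),
    tol = 1e-9) {
  hi_similarity_mode <- match.arg(hi_similarity_mode)
  stopifnot(all(hi_threshold_grid >= 0), all(hi_threshold_grid <= 1),
            !is.unsorted(rev(hi_threshold_grid)),
            all(c("min_hi", "min_size") %in% names(tier_rules)),
            !is.unsorted(rev(tier_rules$min_hi)),
            prevalence_min >= 0, prevalence_min <= 1,
            min_carrier_count >= 0, min_connections_for_ppv >= 1,
            de_fallback_min_group >= 1)
  for (f in list(min_size_jaccard, min_location_jaccard, min_gene_jaccard)) {
    stopifnot(is.null(f) || (f >= 0 && f <= 1))
  }
  structure(list(
    hi_threshold_grid = as.numeric(hi_threshold_grid),
    tier_rules = data.frame(min_hi = as.numeric(tier_rules$min_hi),
                            min_size = as.integer(tier_rules$min_size)),
    de_fallback_min_group = as.integer(de_fallback_min_group),
    prevalence_min = prevalence_min,
    min_carrier_count = as.integer(min_carrier_count),
    min_connections_for_ppv = as.integer(min_connections_for_ppv),
    min_size_jaccard = min_size_jaccard,
    min_location_jaccard = min_location_jaccard,
    min_gene_jaccard = min_gene_jaccard,
    hi_similarity_mode = hi_similarity_mode,
    tol = tol
  ), class = "similarity_settings")
}

#' Jaccard index of two sets
#'
#' `|a intersect b| / |a union b|`. Two empty sets are taken as identical
#' (Jaccard 1): two deletions affecting zero HI genes are indistinguishable
#' with respect to HI-gene content. One empty set against a non-empty one
#' gives 0.
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return A fraction in `[0, 1]`.
#' @export
jaccard_set <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Base-pair Jaccard overlap of two interval sets
#'
#' Total overlapping base pairs divided by the total base pairs covered by the
#' union of both merged interval sets. Both empty gives 1 by the same
#' convention as [jaccard_set()].
#'
#' @param a,b [IRanges::IRanges] objects (merged per patient).
#' @return A fraction in `[0, 1]`.
#' @export
location_jaccard <- function(a, b) {
  total_union <- sum(IRanges::width(IRanges::union(a, b)))
  if (total_union == 0) return(1)
  sum(IRanges::width(IRanges::intersect(a, b))) / total_union
}

#' Size ratio of two genotypes
#'
#' Location-free size similarity: the smaller total affected length divided by
#' the larger, computed on merged intervals.
#'
#' @param len_a,len_b Total affected base pairs of each patient (positive).
#' @return A fraction in `(0, 1]`.
#' @export
size_jaccard <- function(len_a, len_b) {
  stopifnot(len_a > 0, len_b > 0)
  min(len_a, len_b) / max(len_a, len_b)
}

#' Dominating-effect gene concordance
#'
#' `TRUE` when the two patients' affected dominating-effect gene sets are
#' identical (both empty counts as concordant). Concordance is the hard gate
#' of genotypic similarity: discordant patients are never grouped.
#'
#' @param de_a,de_b Character vectors of affected DE gene ids.
#' @return Logical scalar.
#' @export
de_concordant <- function(de_a, de_b) {
  setequal(de_a, de_b)
}

#' Annotate a cohort for comparison on one chromosome and aberration type
#'
#' Precomputes, per patient, the merged aberration intervals of the focus
#' type on the focus chromosome and the affected gene, HI-gene and DE-gene
#' sets. Patients without such an aberration are retained but are not
#' comparable to anyone.
#'
#' @param cohort A [cnv_cohort()].
#' @param genes A gene map (see [gene_table()]).
#' @param chromosome Chromosome of interest.
#' @param type `"deletion"` (default) or `"duplication"`.
#' @return An object of class `annotated_cohort` with per-patient named lists
#'   `intervals` (merged [IRanges::IRanges]), `genes`, `hi_genes`, `de_genes`,
#'   the numeric vector `total_bp`, and logical `has_content`.
#' @export
annotate_cohort <- function(cohort, genes, chromosome, type = "deletion") {
  stopifnot(inherits(cohort, "cnv_cohort"), length(chromosome) == 1)
  type <- normalize_aberration_type(type)
  ids <- cohort$patients$patient_id
  g <- cohort$genotypes
  g <- g[g$chromosome == chromosome & g$type == type, , drop = FALSE]
  gmap <- genes[genes$chromosome == chromosome, , drop = FALSE]

  empty <- IRanges::IRanges()
  intervals <- stats::setNames(rep(list(empty), length(ids)), ids)
  gene_sets <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  hi_sets <- de_sets <- gene_sets
  total_bp <- stats::setNames(numeric(length(ids)), ids)

  if (nrow(g) > 0) {
    by_patient <- split(g, g$patient_id)
    for (pid in names(by_patient)) {
      rows <- by_patient[[pid]]
      merged <- merge_intervals(rows$start, rows$end)
      intervals[[pid]] <- merged
      total_bp[[pid]] <- sum(IRanges::width(merged))
      gs <- genes_in_aberration(chromosome, rows$start, rows$end, gmap)
      gene_sets[[pid]] <- gs
      hi_sets[[pid]] <- gs[gs %in% gmap$gene_id[gmap$is_hi]]
      de_sets[[pid]] <- gs[gs %in% gmap$gene_id[gmap$is_dominating_effect]]
    }
  }
  structure(list(
    patient_ids = ids,
    chromosome = as.character(chromosome),
    type = type,
    intervals = intervals,
    genes = gene_sets,
    hi_genes = hi_sets,
    de_genes = de_sets,
    total_bp = total_bp,
    has_content = stats::setNames(total_bp > 0, ids),
    cohort = cohort,
    gene_map = genes
  ), class = "annotated_cohort")
}

#' @export
print.annotated_cohort <- function(x, ...) {
  cat("<annotated_cohort> chromosome ", x$chromosome, " ", x$type, "s: ",
      sum(x$has_content), "/", length(x$patient_ids),
      " patients with content\n", sep = "")
  invisible(x)
}

#' Compare two patients' genotypes
#'
#' Computes the four similarity measures and DE concordance for a patient
#' pair, on their merged content of the annotation's focus type and
#' chromosome. The pair is not comparable (`comparable = FALSE`, measures
#' `NA`) when either patient lacks such an aberration — in particular a
#' deletion patient against a duplication-only patient.
#'
#' With `hi_similarity_mode = "index_fraction"`, `hi_gene_similarity` is the
#' fraction of patient `a`'s HI genes shared with `b` (asymmetric; `a` is the
#' index); the default Jaccard mode is symmetric.
#'
#' @param annotated An [annotate_cohort()] result.
#' @param id_a,id_b Patient identifiers (`id_a` is the index).
#' @param settings A [similarity_settings()].
#' @return An object of class `pairwise_comparison`: list with `patient_a`,
#'   `patient_b`, `comparable`, `de_concordant`, `hi_gene_similarity`,
#'   `gene_jaccard`, `size_jaccard`, `location_jaccard`.
#' @export
compare_patients <- function(annotated, id_a, id_b,
                             settings = similarity_settings()) {
  stopifnot(inherits(annotated, "annotated_cohort"),
            id_a %in% annotated$patient_ids, id_b %in% annotated$patient_ids)
  if (!annotated$has_content[[id_a]] || !annotated$has_content[[id_b]]) {
    return(structure(list(patient_a = id_a, patient_b = id_b,
                          comparable = FALSE, de_concordant = NA,
                          hi_gene_similarity = NA_real_,
                          gene_jaccard = NA_real_, size_jaccard = NA_real_,
                          location_jaccard = NA_real_),
                     class = "pairwise_comparison"))
  }
  hi_a <- annotated$hi_genes[[id_a]]
  hi_b <- annotated$hi_genes[[id_b]]
  hi_sim <- if (settings$hi_similarity_mode == "index_fraction") {
    if (length(hi_a) == 0) {
      if (length(hi_b) == 0) 1 else 0
    } else {
      length(intersect(hi_a, hi_b)) / length(unique(hi_a))
    }
  } else {
    jaccard_set(hi_a, hi_b)
  }
  structure(list(
    patient_a = id_a, patient_b = id_b, comparable = TRUE,
    de_concordant = de_concordant(annotated$de_genes[[id_a]],
                                  annotated$de_genes[[id_b]]),
    hi_gene_similarity = hi_sim,
    gene_jaccard = jaccard_set(annotated$genes[[id_a]],
                               annotated$genes[[id_b]]),
    size_jaccard = size_jaccard(annotated$total_bp[[id_a]],
                                annotated$total_bp[[id_b]]),
    location_jaccard = location_jaccard(annotated$intervals[[id_a]],
                                        annotated$intervals[[id_b]])
  ), class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat("<pairwise_comparison> ", x$patient_a, " vs ", x$patient_b, ": ", sep = "")
  if (!x$comparable) {
    cat("not comparable\n")
  } else {
    cat(sprintf("HI %.3f, gene %.3f, size %.3f, location %.3f, DE %s\n",
                x$hi_gene_similarity, x$gene_jaccard, x$size_jaccard,
                x$location_jaccard,
                if (x$de_concordant) "concordant" else "discordant"))
  }
  invisible(x)
}

#' All pairwise comparisons of an annotated cohort
#'
#' Runs [compare_patients()] over every ordered patient pair and returns the
#' measures as named matrices for fast repeated lookup during group building
#' and threshold sweeps. In the default Jaccard mode all matrices are
#' symmetric; in `index_fraction` mode `hi[i, j]` is taken with patient `i` as
#' the index.
#'
#' @param annotated An [annotate_cohort()] result.
#' @param settings A [similarity_settings()].
#' @return A list of matrices `comparable` (logical, diagonal `FALSE`), `de`
#'   (logical), `hi`, `gene`, `size`, `location` (numeric), with patient ids
#'   as dimnames.
#' @export
compare_all <- function(annotated, settings = similarity_settings()) {
  ids <- annotated$patient_ids
  n <- length(ids)
  dn <- list(ids, ids)
  comparable <- matrix(FALSE, n, n, dimnames = dn)
  de <- matrix(FALSE, n, n, dimnames = dn)
  hi <- gene <- size <- location <- matrix(NA_real_, n, n, dimnames = dn)
  need_loc <- !is.null(settings$min_location_jaccard)
  asym <- settings$hi_similarity_mode == "index_fraction"

  for (i in seq_len(n)) {
    if (!annotated$has_content[[ids[i]]]) next
    for (j in seq_len(n)) {
      if (j <= i || !annotated$has_content[[ids[j]]]) next
      hi_i <- annotated$hi_genes[[ids[i]]]
      hi_j <- annotated$hi_genes[[ids[j]]]
      comparable[i, j] <- comparable[j, i] <- TRUE
      de[i, j] <- de[j, i] <- de_concordant(annotated$de_genes[[ids[i]]],
                                            annotated$de_genes[[ids[j]]])
      if (asym) {
        inter <- length(intersect(hi_i, hi_j))
        hi[i, j] <- if (length(hi_i) == 0) as.numeric(length(hi_j) == 0)
                    else inter / length(unique(hi_i))
        hi[j, i] <- if (length(hi_j) == 0) as.numeric(length(hi_i) == 0)
                    else inter / length(unique(hi_j))
      } else {
        hi[i, j] <- hi[j, i] <- jaccard_set(hi_i, hi_j)
      }
      gene[i, j] <- gene[j, i] <- jaccard_set(annotated$genes[[ids[i]]],
                                              annotated$genes[[ids[j]]])
      size[i, j] <- size[j, i] <- size_jaccard(annotated$total_bp[[ids[i]]],
                                               annotated$total_bp[[ids[j]]])
      if (need_loc) {
        location[i, j] <- location[j, i] <-
          location_jaccard(annotated$intervals[[ids[i]]],
                           annotated$intervals[[ids[j]]])
      }
    }
  }
  list(comparable = comparable, de = de, hi = hi, gene = gene, size = size,
       location = location)
}
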