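#' Coordinate conventions
#'
#' All genomic coordinates in this package are 1-based and fully closed, the
#' convention used in clinical CNV reporting: an interval `[start, end]`
#' contains both endpoints and spans `end - start + 1` base pairs. A gene
#' intersects an aberration when they share at least one base pair; intervals
#' that merely touch (`[100, 200]` and `[201, 300]`) do not overlap. All
#' inputs must be on the same genome build (hg19); build conversion is
#' upstream preprocessing (e.g. UCSC LiftOver), not performed here.
#'
#' @name coordinates
#' @keywords internal
NULL

ABERRATION_TYPES <- c("deletion", "duplication")
PHENOTYPE_STATUSES <- c("present", "absent", "unknown")
COHORT_LABELS <- c("parent", "literature")
SUPPORTED_BUILD <- "hg19"

#' Length of a closed genomic interval
#'
#' @param start,end 1-based inclusive endpoints.
#' @return Integer vector of lengths, `end - start + 1`.
#' @examples
#' interval_length(100000, 200000) # 100001
#' @export
interval_length <- function(start, end) {
  check_intervals(start, end)
  as.integer(end) - as.integer(start) + 1L
}

# Stops on malformed intervals; `where` names the offending table in messages.
check_intervals <- function(start, end, where = "interval") {
  if (length(start) != length(end)) {
    stop(where, ": start and end differ in length", call. = FALSE)
  }
  bad <- which(!is.finite(start) | !is.finite(end) | start < 1 | end < start)
  if (length(bad) > 0) {
    stop(where, ": malformed interval(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (need start >= 1 and end >= start)", call. = FALSE)
  }
  invisible(TRUE)
}

normalize_aberration_type <- function(type) {
  key <- c(del = "deletion", deletion = "deletion",
           dup = "duplication", duplication = "duplication")
  out <- unname(key[tolower(trimws(as.character(type)))])
  if (anyNA(out)) {
    bad <- unique(type[is.na(out)])
    stop("unknown aberration type(s): ", paste(bad, collapse = ", "),
         " (expected deletion/DEL or duplication/DUP)", call. = FALSE)
  }
  out
}

#' Build a genotype table of aberrations
#'
#' One row per aberration; a patient with multiple deletions (e.g. a ring
#' chromosome) contributes multiple rows and their merged content is used in
#' comparisons.
#'
#' @param patient_id Character vector of patient identifiers.
#' @param chromosome Chromosome labels (character; "6", not "chr6").
#' @param start,end 1-based inclusive endpoints.
#' @param type `"deletion"` or `"duplication"` (also accepts `DEL`/`DUP`).
#' @return A `data.frame` with columns `patient_id`, `chromosome`, `start`,
#'   `end`, `type`.
#' @export
genotype_table <- function(patient_id, chromosome, start, end, type) {
  check_intervals(start, end, where = "genotypes")
  df <- data.frame(
    patient_id = as.character(patient_id),
    chromosome = as.character(chromosome),
    start = as.integer(start),
    end = as.integer(end),
    type = normalize_aberration_type(type),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df) > 0) {
    stop("genotypes: exact duplicate aberration rows present", call. = FALSE)
  }
  df
}

#' Build a phenotype table
#'
#' @param patient_id,term_id Character vectors (one row per patient-term pair).
#' @param status `"present"`, `"absent"` or `"unknown"`.
#' @param cohort `"parent"` or `"literature"`, constant within a patient.
#' @return A `data.frame` with those four columns.
#' @export
phenotype_table <- function(patient_id, term_id, status, cohort) {
  status <- match_enum(status, PHENOTYPE_STATUSES, "status")
  cohort <- match_enum(cohort, COHORT_LABELS, "cohort")
  df <- data.frame(
    patient_id = as.character(patient_id),
    term_id = as.character(term_id),
    status = status,
    cohort = cohort,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(df[c("patient_id", "term_id")])
  if (any(dup)) {
    stop("phenotypes: duplicate (patient_id, term_id) row(s), e.g. ",
         df$patient_id[dup][1], " / ", df$term_id[dup][1], call. = FALSE)
  }
  lab <- unique(df[c("patient_id", "cohort")])
  if (anyDuplicated(lab$patient_id) > 0) {
    stop("phenotypes: conflicting cohort labels for patient(s): ",
         paste(unique(lab$patient_id[duplicated(lab$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  df
}

match_enum <- function(x, levels, what) {
  x <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    stop(what, ": invalid value(s) ", paste(bad, collapse = ", "),
         " (expected ", paste(levels, collapse = "/"), ")", call. = FALSE)
  }
  x
}

#' Assemble a patient cohort
#'
#' Bundles the genotype and phenotype tables and the per-patient cohort label
#' (parent-reported vs literature case) into one validated object.
#'
#' @param genotypes Genotype table (see [genotype_table()]).
#' @param phenotypes Phenotype table (see [phenotype_table()]); may cover a
#'   superset or subset of genotyped patients.
#' @param patients Optional `data.frame(patient_id, cohort)`; defaults to the
#'   labels carried in `phenotypes`. Every genotyped patient must receive a
#'   cohort label.
#' @return An object of class `cnv_cohort`: a list with elements `genotypes`,
#'   `phenotypes`, `patients`.
#' @export
cnv_cohort <- function(genotypes, phenotypes, patients = NULL) {
  genotypes <- genotype_table(genotypes$patient_id, genotypes$chromosome,
                              genotypes$start, genotypes$end, genotypes$type)
  phenotypes <- phenotype_table(phenotypes$patient_id, phenotypes$term_id,
                                phenotypes$status, phenotypes$cohort)
  if (is.null(patients)) {
    patients <- unique(phenotypes[c("patient_id", "cohort")])
  } else {
    patients <- data.frame(patient_id = as.character(patients$patient_id),
                           cohort = match_enum(patients$cohort, COHORT_LABELS,
                                               "cohort"),
                           stringsAsFactors = FALSE)
  }
  if (anyDuplicated(patients$patient_id) > 0) {
    stop("duplicate patient_id in patient metadata", call. = FALSE)
  }
  missing <- setdiff(genotypes$patient_id, patients$patient_id)
  if (length(missing) > 0) {
    stop("no cohort label for genotyped patient(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 patients = patients),
            class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("<cnv_cohort> ", nrow(x$patients), " patients (",
      sum(x$patients$cohort == "parent"), " parent, ",
      sum(x$patients$cohort == "literature"), " literature), ",
      nrow(x$genotypes), " aberrations, ",
      length(unique(x$phenotypes$term_id)), " phenotype terms\n", sep = "")
  invisible(x)
}

#' Merge a patient's aberration intervals
#'
#' Overlapping or adjacent intervals of the same type on the same chromosome
#' are collapsed into disjoint sorted intervals; the merged content (total
#' size, gene set) is what pairwise comparisons operate on. Idempotent.
#'
#' @param start,end 1-based inclusive endpoints.
#' @return An [IRanges::IRanges] of disjoint sorted intervals.
#' @export
merge_intervals <- function(start, end) {
  if (length(start) == 0) return(IRanges::IRanges())
  check_intervals(start, end, where = "merge_intervals")
  IRanges::reduce(IRanges::IRanges(start = as.integer(start),
                                   end = as.integer(end)))
}

#' Validate a cohort against a gene map
#'
#' Re-checks structural invariants and collects non-fatal issues: aberrations
#' on chromosomes absent from the gene map, and dominating-effect flags on
#' genes that fail the HI rule (a curation inconsistency, warned not
#' rejected). Malformed intervals and duplicate rows are hard errors raised by
#' the constructors and re-raised here.
#'
#' @param cohort A [cnv_cohort()].
#' @param genes A gene map (see [gene_table()]).
#' @return An object of class `cohort_validation` with elements `n_patients`,
#'   `n_aberrations` and `warnings` (character vector, empty when clean).
#' @export
validate_cohort <- function(cohort, genes) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  check_intervals(cohort$genotypes$start, cohort$genotypes$end, "genotypes")
  if (anyDuplicated(cohort$patients$patient_id) > 0) {
    stop("duplicate patient_id", call. = FALSE)
  }
  warnings <- character(0)
  off_map <- setdiff(unique(cohort$genotypes$chromosome),
                     unique(genes$chromosome))
  if (length(off_map) > 0) {
    warnings <- c(warnings, paste0(
      "aberrations on chromosome(s) not covered by the gene map: ",
      paste(off_map, collapse = ", ")))
  }
  de_not_hi <- genes$gene_id[genes$is_dominating_effect & !genes$is_hi]
  if (length(de_not_hi) > 0) {
    warnings <- c(warnings, paste0(
      "dominating-effect gene(s) failing the HI rule: ",
      paste(de_not_hi, collapse = ", ")))
  }
  no_pheno <- setdiff(cohort$patients$patient_id,
                      unique(cohort$phenotypes$patient_id))
  if (length(no_pheno) > 0) {
    warnings <- c(warnings, paste0(length(no_pheno),
                                   " patient(s) without phenotype records"))
  }
  structure(list(n_patients = nrow(cohort$patients),
                 n_aberrations = nrow(cohort$genotypes),
                 warnings = warnings),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("<cohort_validation> ", x$n_patients, " patients, ",
      x$n_aberrations, " aberrations\n", sep = "")
  if (length(x$warnings) == 0) {
    cat("  no issues\n")
  } else {
    cat(paste0("  warning: ", x$warnings, "\n"), sep = "")
  }
  invisible(x)
}
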