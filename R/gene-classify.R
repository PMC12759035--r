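#' Criteria for calling a gene haploinsufficient
#'
#' A gene is scored by three independent predictors of haploinsufficiency:
#' the HI percentile (low = likely haploinsufficient), pLI (probability of
#' loss-of-function intolerance) and pHaplo (predicted probability of a
#' haploinsufficiency effect). A score satisfies its criterion when
#' `hi_percent` lies in `[0, hi_percent_max]` (boundaries inclusive),
#' `pli >= pli_min`, or `phaplo >= phaplo_min`.
#'
#' @param hi_percent_max Upper bound (percent) on the HI percentile; default 10.
#' @param pli_min Minimum pLI; default 0.9.
#' @param phaplo_min Minimum pHaplo; default 0.86.
#' @param single_score_classifies With only one score known, should that single
#'   satisfied criterion classify the gene as HI? Default `TRUE`, extending the
#'   majority-of-known pattern (3 known require 2, 2 known require 1) down to
#'   1 known requiring 1. `FALSE` makes one known score never sufficient.
#' @return An object of class `hi_criteria`.
#' @export
hi_criteria <- function(hi_percent_max = 10, pli_min = 0.9, phaplo_min = 0.86,
                        single_score_classifies = TRUE) {
  stopifnot(hi_percent_max >= 0, hi_percent_max <= 100,
            pli_min >= 0, pli_min <= 1, phaplo_min >= 0, phaplo_min <= 1)
  structure(list(hi_percent_max = hi_percent_max, pli_min = pli_min,
                 phaplo_min = phaplo_min,
                 single_score_classifies = isTRUE(single_score_classifies)),
            class = "hi_criteria")
}

#' Classify genes as haploinsufficient from their scores
#'
#' A gene is an HI gene when it satisfies at least two of the three criteria
#' if all three scores are known, or at least one of two criteria if only two
#' scores are known. With a single known score the default requires that one
#' criterion (see [hi_criteria()]); with no known score the gene is never HI.
#' Unknown scores are encoded as `NA`.
#'
#' @param hi_percent HI percentile in `[0, 100]` or `NA` (vectorised).
#' @param pli pLI in `[0, 1]` or `NA`.
#' @param phaplo pHaplo in `[0, 1]` or `NA`.
#' @param criteria An [hi_criteria()] object.
#' @return Logical vector: `TRUE` for HI genes.
#' @examples
#' classify_hi_gene(5, 0.95, 0.50)  # two of three satisfied -> TRUE
#' classify_hi_gene(NA, 0.92, 0.30) # one of two known -> TRUE
#' classify_hi_gene(50, 0.10, 0.90) # one of three -> FALSE
#' @export
classify_hi_gene <- function(hi_percent, pli, phaplo,
                             criteria = hi_criteria()) {
  stopifnot(inherits(criteria, "hi_criteria"))
  n <- max(length(hi_percent), length(pli), length(phaplo))
  hi_percent <- rep_len(as.numeric(hi_percent), n)
  pli <- rep_len(as.numeric(pli), n)
  phaplo <- rep_len(as.numeric(phaplo), n)
  check_score_range(hi_percent, 0, 100, "hi_percent")
  check_score_range(pli, 0, 1, "pli")
  check_score_range(phaplo, 0, 1, "phaplo")

  sat <- cbind(hi_percent >= 0 & hi_percent <= criteria$hi_percent_max,
               pli >= criteria$pli_min,
               phaplo >= criteria$phaplo_min)
  known <- rowSums(!is.na(sat))
  satisfied <- rowSums(sat, na.rm = TRUE)
  needed <- ceiling(known / 2)
  if (!criteria$single_score_classifies) needed[known == 1] <- 2
  known > 0 & satisfied >= needed
}

check_score_range <- function(x, lo, hi, what) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad) > 0) {
    stop(what, " out of range [", lo, ", ", hi, "] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a gene annotation table
#'
#' Computes the HI verdict from the scores on construction. Dominating-effect
#' (DE) genes are curated HI genes with a prominent, highly penetrant
#' phenotype; the flag is an input, and a DE flag on a gene that fails the HI
#' rule raises a warning (curation inconsistency), not an error.
#'
#' @param gene_id,symbol Character identifiers.
#' @param chromosome Chromosome label.
#' @param start,end Gene span, 1-based inclusive.
#' @param hi_percent,pli,phaplo Scores (`NA` = unknown).
#' @param is_dominating_effect Logical flag.
#' @param criteria An [hi_criteria()] object.
#' @return A `data.frame` with the input columns plus logical `is_hi`.
#' @export
gene_table <- function(gene_id, symbol = gene_id, chromosome, start, end,
                       hi_percent = NA_real_, pli = NA_real_,
                       phaplo = NA_real_, is_dominating_effect = FALSE,
                       criteria = hi_criteria()) {
  check_intervals(start, end, where = "genes")
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    symbol = rep_len(as.character(symbol), n),
    chromosome = rep_len(as.character(chromosome), n),
    start = as.integer(start),
    end = as.integer(end),
    hi_percent = rep_len(as.numeric(hi_percent), n),
    pli = rep_len(as.numeric(pli), n),
    phaplo = rep_len(as.numeric(phaplo), n),
    is_dominating_effect = rep_len(as.logical(is_dominating_effect), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id) > 0) {
    stop("genes: duplicate gene_id", call. = FALSE)
  }
  df$is_hi <- classify_hi_gene(df$hi_percent, df$pli, df$phaplo, criteria)
  de_not_hi <- df$gene_id[df$is_dominating_effect & !df$is_hi]
  if (length(de_not_hi) > 0) {
    warning("dominating-effect gene(s) failing the HI rule: ",
            paste(de_not_hi, collapse = ", "), call. = FALSE)
  }
  df
}

#' Genes intersecting an aberration
#'
#' Any-overlap rule: a gene is affected when it shares at least one base pair
#' with the aberration (closed coordinates, so `[100,200]` vs `[201,300]` is
#' adjacency, not overlap). HI- and DE-gene subsets follow by filtering on
#' `is_hi` / `is_dominating_effect`.
#'
#' @param chromosome Chromosome of the aberration.
#' @param start,end Aberration interval(s), 1-based inclusive; several
#'   intervals are treated as one multi-aberration genotype.
#' @param genes A gene map (see [gene_table()]).
#' @return Character vector of `gene_id`s, in gene-map order.
#' @export
genes_in_aberration <- function(chromosome, start, end, genes) {
  stopifnot(length(chromosome) == 1)
  check_intervals(start, end, where = "aberration")
  on_chr <- genes[genes$chromosome == chromosome, , drop = FALSE]
  if (nrow(on_chr) == 0 || length(start) == 0) return(character(0))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(as.integer(on_chr$start), as.integer(on_chr$end)),
    IRanges::IRanges(as.integer(start), as.integer(end)),
    minoverlap = 1L
  )
  on_chr$gene_id[sort(unique(S4Vectors::queryHits(hits)))]
}
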