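#' Positive predictive value of a phenotype description
#'
#' The fraction of description features that are actually present in the index
#' patient: `|description terms intersect index present terms| /
#' |description terms|`. Undefined (error) for an empty description.
#'
#' @param description_terms Character vector of term ids in the description.
#' @param index_present_terms Character vector of term ids present in the
#'   index.
#' @return A fraction in `[0, 1]`.
#' @examples
#' # a 25-feature description of which 12 are seen in the index
#' ppv(paste0("T", 1:25), paste0("T", 1:12)) # 0.48
#' @export
ppv <- function(description_terms, index_present_terms) {
  description_terms <- unique(description_terms)
  if (length(description_terms) == 0) {
    stop("PPV is undefined for an empty description", call. = FALSE)
  }
  length(intersect(description_terms, index_present_terms)) /
    length(description_terms)
}

#' Leave-one-out PPV sweep over HI-gene similarity thresholds
#'
#' For every threshold and every patient used once as index: builds the
#' connected group with [connect()] (dominating-effect concordance always
#' gating), and — when the group has at least
#' `settings$min_connections_for_ppv` members — generates the description
#' restricted to `feature_subset` and scores it against the index's own
#' present features. Patients below the connection floor are skipped, not
#' zero-filled. Unknown statuses count as not present throughout, for members
#' and index alike.
#'
#' @param cohort A [cnv_cohort()].
#' @param genes A gene map (see [gene_table()]).
#' @param feature_subset Character vector of evaluation term ids (non-empty);
#'   the curated main-feature list preventing double counting of main and
#'   sub-features.
#' @param chromosome Chromosome of interest.
#' @param thresholds Thresholds to sweep; default `settings$hi_threshold_grid`.
#' @param settings A [similarity_settings()].
#' @param type Aberration type, default `"deletion"`.
#' @return A `data.frame` of class `ppv_records` with one row per eligible
#'   (threshold, index): `index_id`, `hi_threshold`, `n_connections`,
#'   `n_description_features`, `n_matched`, `ppv` (`NA` when the description
#'   is empty), `index_has_de`.
#' @export
leave_one_out_sweep <- function(cohort, genes, feature_subset, chromosome,
                                thresholds = NULL,
                                settings = similarity_settings(),
                                type = "deletion") {
  feature_subset <- unique(as.character(feature_subset))
  if (length(feature_subset) == 0) {
    stop("feature_subset is empty; PPV evaluation requires at least one term",
         call. = FALSE)
  }
  if (is.null(thresholds)) thresholds <- settings$hi_threshold_grid
  annotated <- annotate_cohort(cohort, genes, chromosome, type)
  comparisons <- compare_all(annotated, settings)
  ids <- annotated$patient_ids
  pm <- presence_matrix(cohort$phenotypes, ids, feature_subset)

  rows <- vector("list", length(thresholds) * length(ids))
  k <- 0L
  for (thr in thresholds) {
    for (id in ids) {
      if (!annotated$has_content[[id]]) next
      members <- connect(annotated, id, thr, settings, comparisons)
      n <- length(members)
      if (n < settings$min_connections_for_ppv) next
      carriers <- colSums(pm[members, , drop = FALSE])
      included <- feature_subset[carriers >= min_carrier_count(n, settings)]
      n_feat <- length(included)
      n_matched <- sum(pm[id, included])
      k <- k + 1L
      rows[[k]] <- data.frame(
        index_id = id, hi_threshold = thr, n_connections = n,
        n_description_features = n_feat, n_matched = n_matched,
        ppv = if (n_feat > 0) n_matched / n_feat else NA_real_,
        index_has_de = length(annotated$de_genes[[id]]) > 0,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (k == 0) {
    data.frame(index_id = character(0), hi_threshold = numeric(0),
               n_connections = integer(0), n_description_features = integer(0),
               n_matched = integer(0), ppv = numeric(0),
               index_has_de = logical(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows[seq_len(k)])
  }
  class(out) <- c("ppv_records", "data.frame")
  out
}

# Two-sided rank-sum comparison; normal approximation with tie/continuity
# correction. NA (with the reason recorded by the caller) when a stratum is
# empty or the pooled values are constant.
ranksum_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  if (length(unique(c(x, y))) < 2) return(NA_real_)
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                       correct = TRUE)$p.value
  )
}

#' Summarise a PPV sweep
#'
#' Per threshold: the number of indexes whose connected group reaches each
#' size band, the overall median PPV, medians stratified by whether the index
#' deletion contains a dominating-effect gene, and medians stratified by each
#' group-size band (below vs at-least), each stratification with a two-sided
#' rank-sum p-value. Rows with an empty description (`ppv` `NA`) are excluded
#' from medians but still counted in group sizes.
#'
#' @param records A [leave_one_out_sweep()] result.
#' @param size_bands Group-size cutpoints; default `c(15, 20, 30)`.
#' @return An object of class `sweep_summary`: list with `thresholds`
#'   (`data.frame(hi_threshold, n_eligible, n_ge<band>..., median_ppv,
#'   median_ppv_de, median_ppv_no_de, p_de)`) and `bands`
#'   (`data.frame(hi_threshold, band, n_below, n_at_least, median_below,
#'   median_at_least, p)`).
#' @export
summarize_sweep <- function(records, size_bands = c(15L, 20L, 30L)) {
  stopifnot(nrow(records) > 0)
  thrs <- sort(unique(records$hi_threshold), decreasing = TRUE)

  thr_rows <- lapply(thrs, function(t) {
    r <- records[records$hi_threshold == t, , drop = FALSE]
    counts <- stats::setNames(
      lapply(size_bands, function(b) sum(r$n_connections >= b)),
      paste0("n_ge", size_bands))
    de <- r$ppv[r$index_has_de]
    nde <- r$ppv[!r$index_has_de]
    cbind(data.frame(hi_threshold = t, n_eligible = nrow(r)),
          as.data.frame(counts),
          data.frame(median_ppv = stats::median(r$ppv, na.rm = TRUE),
                     median_ppv_de = if (length(de)) stats::median(de, na.rm = TRUE) else NA_real_,
                     median_ppv_no_de = if (length(nde)) stats::median(nde, na.rm = TRUE) else NA_real_,
                     p_de = ranksum_p(de, nde)))
  })

  band_rows <- lapply(thrs, function(t) {
    r <- records[records$hi_threshold == t, , drop = FALSE]
    do.call(rbind, lapply(size_bands, function(b) {
      lo <- r$ppv[r$n_connections < b]
      hi <- r$ppv[r$n_connections >= b]
      data.frame(hi_threshold = t, band = b,
                 n_below = length(lo), n_at_least = length(hi),
                 median_below = if (length(lo)) stats::median(lo, na.rm = TRUE) else NA_real_,
                 median_at_least = if (length(hi)) stats::median(hi, na.rm = TRUE) else NA_real_,
                 p = ranksum_p(lo, hi))
    }))
  })

  structure(list(thresholds = do.call(rbind, thr_rows),
                 bands = do.call(rbind, band_rows),
                 size_bands = as.integer(size_bands)),
            class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat("<sweep_summary>\n")
  print(x$thresholds, row.names = FALSE, digits = 3)
  invisible(x)
}
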