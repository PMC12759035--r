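#' Patients connected to an index at an HI-gene similarity threshold
#'
#' A cohort patient is connected to the index when the pair is comparable
#' (both have merged content of the focus type on the focus chromosome), the
#' affected dominating-effect gene sets are identical, any enabled optional
#' size/location/gene Jaccard filters pass, and the HI-gene similarity is at
#' least `hi_threshold` (within `settings$tol`). The index itself is never a
#' member; an empty result is valid.
#'
#' @param annotated An [annotate_cohort()] result.
#' @param index_id Index patient identifier.
#' @param hi_threshold Minimum HI-gene similarity in `[0, 1]`.
#' @param settings A [similarity_settings()].
#' @param comparisons Optional precomputed [compare_all()] result; computed
#'   on the fly per pair when `NULL`.
#' @return Sorted character vector of connected patient ids.
#' @export
connect <- function(annotated, index_id, hi_threshold,
                    settings = similarity_settings(), comparisons = NULL) {
  stopifnot(inherits(annotated, "annotated_cohort"),
            index_id %in% annotated$patient_ids,
            hi_threshold >= 0, hi_threshold <= 1)
  others <- setdiff(annotated$patient_ids, index_id)
  if (!annotated$has_content[[index_id]]) return(character(0))
  tol <- settings$tol

  if (is.null(comparisons)) {
    keep <- vapply(others, function(id) {
      cp <- compare_patients(annotated, index_id, id, settings)
      pair_passes(cp$comparable, cp$de_concordant, cp$hi_gene_similarity,
                  cp$size_jaccard, cp$location_jaccard, cp$gene_jaccard,
                  hi_threshold, settings)
    }, logical(1))
  } else {
    keep <- pair_passes(comparisons$comparable[index_id, others],
                        comparisons$de[index_id, others],
                        comparisons$hi[index_id, others],
                        comparisons$size[index_id, others],
                        comparisons$location[index_id, others],
                        comparisons$gene[index_id, others],
                        hi_threshold, settings)
  }
  sort(others[keep])
}

# Vectorised gate shared by the scalar and matrix paths.
pair_passes <- function(comparable, de, hi, size, location, gene,
                        hi_threshold, settings) {
  tol <- settings$tol
  ok <- comparable & de & !is.na(hi) & hi >= hi_threshold - tol
  if (!is.null(settings$min_size_jaccard)) {
    ok <- ok & size >= settings$min_size_jaccard - tol
  }
  if (!is.null(settings$min_location_jaccard)) {
    ok <- ok & location >= settings$min_location_jaccard - tol
  }
  if (!is.null(settings$min_gene_jaccard)) {
    ok <- ok & gene >= settings$min_gene_jaccard - tol
  }
  ok & !is.na(ok)
}

#' Select the operating tier and connected group for an index
#'
#' Walks the HI-gene similarity grid from the highest threshold down. At each
#' grid threshold with a tier rule, the group from [connect()] is accepted
#' when it meets that rule's minimum size, so the description uses the highest
#' functional similarity still yielding a large enough group. Below the lowest
#' ruled threshold, a group is only formed when the index deletion contains a
#' dominating-effect gene (DE fallback): the highest remaining grid threshold
#' with at least `de_fallback_min_group` members is used. Otherwise no
#' description is produced (`tier_rule_applied = "none"`).
#'
#' @inheritParams connect
#' @return An object of class `connected_group`: list with `index_id`,
#'   `hi_threshold_used` (`NA` when none), `members` (sorted ids, index
#'   excluded), `tier_rule_applied`, `index_has_de`.
#' @export
select_tier <- function(annotated, index_id,
                        settings = similarity_settings(),
                        comparisons = NULL) {
  stopifnot(inherits(annotated, "annotated_cohort"))
  grid <- sort(unique(settings$hi_threshold_grid), decreasing = TRUE)
  rules <- settings$tier_rules
  tol <- settings$tol
  has_de <- length(annotated$de_genes[[index_id]]) > 0

  group <- function(thr, members, label) {
    structure(list(index_id = index_id, hi_threshold_used = thr,
                   members = members, tier_rule_applied = label,
                   index_has_de = has_de),
              class = "connected_group")
  }

  ruled <- grid[vapply(grid, function(t) any(abs(rules$min_hi - t) <= tol),
                       logical(1))]
  for (thr in ruled) {
    min_size <- rules$min_size[which.min(abs(rules$min_hi - thr))]
    members <- connect(annotated, index_id, thr, settings, comparisons)
    if (length(members) >= min_size) {
      return(group(thr, members,
                   sprintf("hi>=%.1f,n>=%d", thr, min_size)))
    }
  }
  if (has_de) {
    fallback <- grid[!grid %in% ruled & grid < min(rules$min_hi) - tol]
    for (thr in fallback) {
      members <- connect(annotated, index_id, thr, settings, comparisons)
      if (length(members) >= settings$de_fallback_min_group) {
        return(group(thr, members, sprintf("de_fallback(hi>=%.1f)", thr)))
      }
    }
  }
  group(NA_real_, character(0), "none")
}

#' @export
print.connected_group <- function(x, ...) {
  cat("<connected_group> index ", x$index_id, ": ", sep = "")
  if (x$tier_rule_applied == "none") {
    cat("no qualifying group\n")
  } else {
    cat(length(x$members), " members at HI-gene similarity >= ",
        format(x$hi_threshold_used), " [", x$tier_rule_applied, "]\n",
        sep = "")
  }
  invisible(x)
}
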