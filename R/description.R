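#' Minimum number of carriers for a feature to enter a description
#'
#' A feature must be present in at least `prevalence_min` of the connected
#' group (ceiling) and in at least `min_carrier_count` members. With the
#' defaults (20%, 2): a group of 17 requires 4 carriers, the minimal
#' PPV-eligible group of 5 requires 2, so no feature ever rests on a single
#' patient.
#'
#' @param group_size Number of connected patients (at least 1).
#' @param settings A [similarity_settings()].
#' @return Integer carrier threshold.
#' @examples
#' min_carrier_count(17) # 4
#' min_carrier_count(5)  # 2
#' @export
min_carrier_count <- function(group_size, settings = similarity_settings()) {
  stopifnot(all(group_size >= 1))
  # tiny slack: 0.2 * 15 exceeds 3 in binary floating point
  pmax(as.integer(ceiling(settings$prevalence_min * group_size - 1e-9)),
       settings$min_carrier_count)
}

# patients x terms logical matrix of "present" calls.
# unknown_mode "absent": unknown counts as not present (the default rule,
# matching how unreported literature features are handled); "drop": unknown
# excluded from the denominator, tracked via the companion "known" matrix.
presence_matrix <- function(phenotypes, patient_ids, terms) {
  m <- matrix(FALSE, length(patient_ids), length(terms),
              dimnames = list(patient_ids, terms))
  ph <- phenotypes[phenotypes$patient_id %in% patient_ids &
                     phenotypes$term_id %in% terms, , drop = FALSE]
  pres <- ph[ph$status == "present", , drop = FALSE]
  m[cbind(pres$patient_id, pres$term_id)] <- TRUE
  m
}

known_matrix <- function(phenotypes, patient_ids, terms) {
  m <- matrix(FALSE, length(patient_ids), length(terms),
              dimnames = list(patient_ids, terms))
  ph <- phenotypes[phenotypes$patient_id %in% patient_ids &
                     phenotypes$term_id %in% terms &
                     phenotypes$status != "unknown", , drop = FALSE]
  m[cbind(ph$patient_id, ph$term_id)] <- TRUE
  m
}

#' Generate a phenotype description for an index patient
#'
#' Counts, for every term in the feature universe, the connected-group members
#' in which the feature is present, and keeps the terms meeting
#' [min_carrier_count()]. Features are sorted by descending prevalence, ties
#' broken by term id. By default an `unknown` status counts as not present in
#' both numerator and denominator — the same rule applied to features
#' unreported in literature cases; `unknown_mode = "drop"` instead removes
#' unknowns from each feature's denominator.
#'
#' @param group A [select_tier()] / `connected_group` result with at least one
#'   member.
#' @param phenotypes Phenotype table (see [phenotype_table()]).
#' @param feature_universe Character vector of candidate term ids (non-empty);
#'   e.g. all closed-ended questionnaire features, or a curated main-feature
#'   subset.
#' @param settings A [similarity_settings()].
#' @param unknown_mode `"absent"` (default) or `"drop"`.
#' @param include_below_threshold Also report features present in the index
#'   and in at least one member but below the carrier threshold (the
#'   "index-only" annotations shown in italics in clinical description
#'   tables)? Requires the index's phenotypes.
#' @param term_labels Optional named character vector mapping term ids to
#'   human-readable labels; unmapped ids fall back to the raw code.
#' @return An object of class `phenotype_description`: list with `index_id`,
#'   `group`, `features` (`data.frame(term_id, label, carriers, group_size,
#'   prevalence)`) and `below_threshold` (same shape, or `NULL`).
#' @export
generate_description <- function(group, phenotypes, feature_universe,
                                 settings = similarity_settings(),
                                 unknown_mode = c("absent", "drop"),
                                 include_below_threshold = FALSE,
                                 term_labels = NULL) {
  stopifnot(inherits(group, "connected_group"))
  unknown_mode <- match.arg(unknown_mode)
  feature_universe <- unique(as.character(feature_universe))
  if (length(feature_universe) == 0) {
    stop("feature_universe is empty", call. = FALSE)
  }
  members <- group$members
  if (length(members) == 0) {
    stop("connected group is empty; no description can be generated",
         call. = FALSE)
  }
  pm <- presence_matrix(phenotypes, members, feature_universe)
  carriers <- colSums(pm)
  n <- length(members)
  if (unknown_mode == "drop") {
    denom <- colSums(known_matrix(phenotypes, members, feature_universe))
    need <- ifelse(denom > 0, pmax(
      as.integer(ceiling(settings$prevalence_min * pmax(denom, 1) - 1e-9)),
      settings$min_carrier_count), Inf)
    prevalence <- ifelse(denom > 0, carriers / denom, 0)
    group_size <- denom
  } else {
    need <- min_carrier_count(n, settings)
    prevalence <- carriers / n
    group_size <- rep(n, length(carriers))
  }
  keep <- carriers >= need
  features <- data.frame(
    term_id = feature_universe,
    label = label_for(feature_universe, term_labels),
    carriers = as.integer(carriers),
    group_size = as.integer(group_size),
    prevalence = prevalence,
    stringsAsFactors = FALSE
  )
  included <- features[keep, , drop = FALSE]
  included <- included[order(-included$prevalence, included$term_id), ,
                       drop = FALSE]
  rownames(included) <- NULL

  below <- NULL
  if (include_below_threshold) {
    ipm <- presence_matrix(phenotypes, group$index_id, feature_universe)
    cand <- !keep & carriers >= 1 & ipm[1, ]
    below <- features[cand, , drop = FALSE]
    below <- below[order(-below$prevalence, below$term_id), , drop = FALSE]
    rownames(below) <- NULL
  }
  structure(list(index_id = group$index_id, group = group,
                 features = included, below_threshold = below),
            class = "phenotype_description")
}

label_for <- function(term_id, term_labels) {
  if (is.null(term_labels)) return(term_id)
  out <- unname(term_labels[term_id])
  ifelse(is.na(out), term_id, out)
}

#' @export
print.phenotype_description <- function(x, ...) {
  cat("<phenotype_description> index ", x$index_id, ", group of ",
      length(x$group$members), " [", x$group$tier_rule_applied, "]: ",
      nrow(x$features), " feature(s)\n", sep = "")
  if (nrow(x$features) > 0) {
    top <- utils::head(x$features, 10)
    cat(sprintf("  %-18s %3d/%-3d %.2f  %s\n", top$term_id, top$carriers,
                top$group_size, top$prevalence, top$label), sep = "")
    if (nrow(x$features) > 10) cat("  ...\n")
  }
  if (!is.null(x$below_threshold) && nrow(x$below_threshold) > 0) {
    cat("  (+", nrow(x$below_threshold),
        " index feature(s) below the prevalence threshold)\n", sep = "")
  }
  invisible(x)
}
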