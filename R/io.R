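#' Read a genotype table
#'
#' Tab-separated with header columns `patient_id`, `chromosome`, `start`,
#' `end`, `type`, `build`. `type` accepts `deletion`/`DEL` and
#' `duplication`/`DUP`. Every row must be on build hg19; other builds are
#' rejected with a pointer to external LiftOver preprocessing. A patient with
#' several rows has a multi-aberration genotype.
#'
#' @param path File path.
#' @return A genotype `data.frame` (see [genotype_table()]).
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "chromosome", "start", "end",
                                 "type", "build"))
  bad_build <- unique(df$build[df$build != SUPPORTED_BUILD])
  if (length(bad_build) > 0) {
    stop(path, ": genome build(s) ", paste(bad_build, collapse = ", "),
         " not supported; convert coordinates to ", SUPPORTED_BUILD,
         " upstream (e.g. with UCSC LiftOver) before loading", call. = FALSE)
  }
  df$start <- check_numeric_column(df, "start", path)
  df$end <- check_numeric_column(df, "end", path)
  bad <- which(df$start < 1 | df$end < df$start)
  if (length(bad) > 0) {
    stop(path, ": malformed interval at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  genotype_table(df$patient_id, df$chromosome, df$start, df$end, df$type)
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns `gene_id`, `symbol`, `chromosome`,
#' `start`, `end`, `hi_percent`, `pli`, `phaplo`, `dominating_effect`.
#' Unknown scores are `NA`; `dominating_effect` is `TRUE`/`FALSE` or `1`/`0`.
#' HI verdicts are computed on load.
#'
#' @param path File path.
#' @param criteria An [hi_criteria()] object.
#' @return A gene `data.frame` (see [gene_table()]).
#' @export
read_genes <- function(path, criteria = hi_criteria()) {
  df <- read_tsv_checked(path, c("gene_id", "symbol", "chromosome", "start",
                                 "end", "hi_percent", "pli", "phaplo",
                                 "dominating_effect"))
  for (col in c("start", "end", "hi_percent", "pli", "phaplo")) {
    df[[col]] <- check_numeric_column(df, col, path, allow_na = col %in%
                                        c("hi_percent", "pli", "phaplo"))
  }
  gene_table(df$gene_id, df$symbol, df$chromosome, df$start, df$end,
             df$hi_percent, df$pli, df$phaplo,
             as_logical_column(df$dominating_effect, "dominating_effect",
                               path),
             criteria = criteria)
}

#' Read a phenotype table
#'
#' Tab-separated with header columns `patient_id`, `term_id`, `status`,
#' `cohort`. `status` is `present`/`absent`/`unknown`; `cohort` is
#' `parent`/`literature` and must be constant within a patient. Term ids are
#' opaque namespaced codes (`HP:`, `ICD10:`, `ORPHA:`, `CUST:` ...); no
#' ontology validation is performed.
#'
#' @param path File path.
#' @return A phenotype `data.frame` (see [phenotype_table()]).
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "term_id", "status", "cohort"))
  phenotype_table(df$patient_id, df$term_id, df$status, df$cohort)
}

#' Read a feature-subset list
#'
#' One term id per line; blank lines and `#` comments ignored. Errors when no
#' term remains (PPV evaluation needs at least one feature).
#'
#' @param path File path.
#' @return Character vector of unique term ids.
#' @export
read_feature_subset <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  terms <- unique(lines)
  if (length(terms) == 0) {
    stop(path, ": feature-subset file contains no terms", call. = FALSE)
  }
  terms
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = c("NA", ""),
                          check.names = FALSE, quote = "",
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

check_numeric_column <- function(df, col, path, allow_na = FALSE) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !(allow_na & is.na(df[[col]])))
  if (length(bad) > 0) {
    stop(path, ": non-numeric ", col, " at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  x
}

as_logical_column <- function(x, col, path) {
  key <- c("true" = TRUE, "false" = FALSE, "1" = TRUE, "0" = FALSE,
           "t" = TRUE, "f" = FALSE)
  out <- unname(key[tolower(trimws(x))])
  if (anyNA(out)) {
    stop(path, ": invalid ", col, " value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write package tables as TSV
#'
#' `write_genotypes()` adds the `build` column (always hg19); the others write
#' the documented schemas so that reading back reproduces the input.
#'
#' @param genotypes,genes,phenotypes Package tables.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  out <- genotypes[c("patient_id", "chromosome", "start", "end", "type")]
  out$build <- SUPPORTED_BUILD
  write_tsv(out, path)
}

#' @rdname write_genotypes
#' @export
write_genes <- function(genes, path) {
  out <- genes[c("gene_id", "symbol", "chromosome", "start", "end",
                 "hi_percent", "pli", "phaplo")]
  out$dominating_effect <- ifelse(genes$is_dominating_effect, "TRUE", "FALSE")
  write_tsv(out, path)
}

#' @rdname write_genotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  write_tsv(phenotypes[c("patient_id", "term_id", "status", "cohort")], path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a phenotype description report
#'
#' TSV of the included features (`term_id`, `label`, `carriers`, `group_size`,
#' `prevalence`) and, optionally, a structured JSON mirror including the
#' connected group and any below-threshold index features.
#'
#' @param description A [generate_description()] result.
#' @param path Output TSV path.
#' @param json_path Optional output JSON path.
#' @return `path`, invisibly.
#' @export
write_description <- function(description, path, json_path = NULL) {
  stopifnot(inherits(description, "phenotype_description"))
  write_tsv(description$features, path)
  if (!is.null(json_path)) {
    payload <- list(
      index_id = description$index_id,
      group = list(
        hi_threshold_used = description$group$hi_threshold_used,
        tier_rule_applied = description$group$tier_rule_applied,
        members = description$group$members
      ),
      features = description$features,
      below_threshold = description$below_threshold
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Write a sweep summary as TSV
#'
#' One row per threshold: eligible indexes, counts reaching each size band,
#' overall median PPV, the below/at-least medians per band and the rank-sum
#' p-values (the usual threshold-calibration table shape).
#'
#' @param summary A [summarize_sweep()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(summary, path) {
  stopifnot(inherits(summary, "sweep_summary"))
  wide <- summary$thresholds
  for (b in summary$size_bands) {
    bb <- summary$bands[summary$bands$band == b, , drop = FALSE]
    m <- match(wide$hi_threshold, bb$hi_threshold)
    wide[[paste0("median_lt", b)]] <- bb$median_below[m]
    wide[[paste0("median_ge", b)]] <- bb$median_at_least[m]
    wide[[paste0("p_", b)]] <- bb$p[m]
  }
  write_tsv(wide, path)
}

#' Export aberrations as BED
#'
#' Converts the 1-based closed intervals to BED's 0-based half-open
#' convention (`chromStart = start - 1`, `chromEnd = end`) for genome-browser
#' interoperability. The name field is `patient_id|type`.
#'
#' @param genotypes A genotype table.
#' @param path Output BED path.
#' @param chr_prefix Prepend `"chr"` to chromosome labels? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
export_bed <- function(genotypes, path, chr_prefix = TRUE) {
  chrom <- if (chr_prefix) paste0("chr", genotypes$chromosome)
           else genotypes$chromosome
  bed <- data.frame(chrom = chrom,
                    chromStart = genotypes$start - 1L,
                    chromEnd = genotypes$end,
                    name = paste0(genotypes$patient_id, "|", genotypes$type))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read similarity settings from a YAML profile
#'
#' Profile keys mirror [similarity_settings()] arguments; `tier_rules` is a
#' mapping from threshold to minimum group size. Missing keys keep their
#' defaults. The packaged chromosome-6 deletion profile ships as
#' `system.file("extdata", "chr6-profile.yaml", package = "cnvphen")`.
#'
#' @param path YAML file path.
#' @return A [similarity_settings()].
#' @export
read_settings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  args <- list()
  scalar_keys <- c("de_fallback_min_group", "prevalence_min",
                   "min_carrier_count", "min_connections_for_ppv",
                   "min_size_jaccard", "min_location_jaccard",
                   "min_gene_jaccard", "hi_similarity_mode")
  for (k in intersect(scalar_keys, names(raw))) args[[k]] <- raw[[k]]
  if (!is.null(raw$hi_threshold_grid)) {
    args$hi_threshold_grid <- as.numeric(raw$hi_threshold_grid)
  }
  if (!is.null(raw$tier_rules)) {
    args$tier_rules <- data.frame(
      min_hi = as.numeric(names(raw$tier_rules)),
      min_size = as.integer(unlist(raw$tier_rules))
    )
    args$tier_rules <- args$tier_rules[order(-args$tier_rules$min_hi), ]
  }
  do.call(similarity_settings, args)
}

#' Write a run-provenance record
#'
#' JSON with the settings/config used, the seed, package version and md5
#' digests of every input file, sufficient to reproduce a run.
#'
#' @param path Output JSON path.
#' @param config A named list (settings, simulation config, CLI options...).
#' @param inputs Character vector of input file paths to digest.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, inputs = character(0)) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    NULL
  }
  payload <- list(
    package = "cnvphen",
    version = as.character(utils::packageVersion("cnvphen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = digests
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
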