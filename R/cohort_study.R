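#' Build a cohort study object
#'
#' The root container of the pipeline: a set of samples, one cohort label
#' per sample, a species abundance table and (optionally) a metabolite
#' concentration table. All tables are samples-as-rows tibbles whose first
#' column, `sample_id`, carries the identifiers; they must describe exactly
#' the same samples and are stored in metadata order.
#'
#' @param abundance data frame with `sample_id` plus one nonnegative numeric
#'   column per species.
#' @param metadata data frame with columns `sample_id` and `cohort`.
#' @param metabolites optional data frame with `sample_id` plus one column
#'   per metabolite, concentrations in micromol per g stool.
#' @return an object of class `cohort_study`: a list with elements
#'   `samples` (tibble `sample_id`, `cohort`), `abundance`, `metabolites`
#'   and the logical flag `is_relative` (every abundance row sums to 1).
#' @examples
#' abund <- tibble::tibble(sample_id = c("m1", "m2", "m3"),
#'                         sp1 = c(2, 0, 1), sp2 = c(2, 3, 1))
#' meta <- tibble::tibble(sample_id = c("m1", "m2", "m3"),
#'                        cohort = c("SE", "SE", "EE"))
#' cohort_study(abund, meta)
#' @export
cohort_study <- function(abundance, metadata, metabolites = NULL) {
  metadata <- tibble::as_tibble(metadata)
  if (!all(c("sample_id", "cohort") %in% names(metadata))) {
    abort("`metadata` needs columns `sample_id` and `cohort`.")
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) {
    abort("Duplicated sample identifiers in metadata.")
  }
  if (anyNA(metadata$cohort)) abort("Every sample needs a cohort label.")

  abundance <- validate_feature_table(abundance, metadata$sample_id,
                                      what = "abundance")
  if (!is.null(metabolites)) {
    metabolites <- validate_feature_table(metabolites, metadata$sample_id,
                                          what = "metabolite")
  }

  rs <- rowSums(as_feature_matrix(abundance))
  structure(
    list(
      samples = tibble::tibble(sample_id = metadata$sample_id,
                               cohort = as.character(metadata$cohort)),
      abundance = abundance,
      metabolites = metabolites,
      is_relative = all(abs(rs - 1) <= 1e-6)
    ),
    class = "cohort_study"
  )
}

# Shared validation: sample alignment, nonnegativity, unique feature names.
validate_feature_table <- function(tbl, sample_ids, what) {
  tbl <- tibble::as_tibble(tbl)
  if (!"sample_id" %in% names(tbl)) {
    names(tbl)[1] <- "sample_id"
  }
  tbl$sample_id <- as.character(tbl$sample_id)

  missing_meta <- setdiff(tbl$sample_id, sample_ids)
  if (length(missing_meta) > 0) {
    abort(paste0("Sample(s) in ", what, " table absent from metadata: ",
                 toString(head(missing_meta, 5))))
  }
  missing_tbl <- setdiff(sample_ids, tbl$sample_id)
  if (length(missing_tbl) > 0) {
    abort(paste0("Sample(s) in metadata absent from ", what, " table: ",
                 toString(head(missing_tbl, 5))))
  }
  feats <- setdiff(names(tbl), "sample_id")
  if (anyDuplicated(feats)) {
    abort(paste0("Duplicated ", what, " feature name(s): ",
                 toString(unique(feats[duplicated(feats)]))))
  }
  m <- as_feature_matrix(tbl)
  if (anyNA(m)) abort(paste0("Missing values in ", what, " table."))
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("Negative value in %s table at sample '%s', feature '%s'.",
                  what, rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  }
  tbl[match(sample_ids, tbl$sample_id), , drop = FALSE]
}

#' @export
print.cohort_study <- function(x, ...) {
  cat("<cohort_study> ", nrow(x$samples), " samples, ",
      ncol(x$abundance) - 1L, " species",
      if (!is.null(x$metabolites)) {
        paste0(", ", ncol(x$metabolites) - 1L, " metabolites")
      } else "",
      "\n", sep = "")
  print(table(cohort = x$samples$cohort))
  invisible(x)
}

#' Extract the abundance matrix of a cohort study
#'
#' @param study a [cohort_study()].
#' @return numeric matrix, samples as rows (row names = sample ids).
#' @export
abundance_matrix <- function(study) {
  stopifnot(inherits(study, "cohort_study"))
  as_feature_matrix(study$abundance)
}

#' Extract the metabolite matrix of a cohort study
#'
#' @param study a [cohort_study()].
#' @return numeric matrix, samples as rows, or `NULL` when the study holds
#'   no metabolite table.
#' @export
metabolite_matrix <- function(study) {
  stopifnot(inherits(study, "cohort_study"))
  if (is.null(study$metabolites)) return(NULL)
  as_feature_matrix(study$metabolites)
}

#' Cohort labels of a cohort study
#'
#' @param study a [cohort_study()].
#' @return character vector named by sample id, in table order.
#' @export
cohort_labels <- function(study) {
  stopifnot(inherits(study, "cohort_study"))
  setNames(study$samples$cohort, study$samples$sample_id)
}
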