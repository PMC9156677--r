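# Internal helpers shared across modules.

#' Convert a samples-by-features tibble to a numeric matrix
#'
#' Accepts either a numeric matrix (returned as is) or a data frame whose
#' first column (or a column named `sample_id`) holds sample identifiers and
#' whose remaining columns are numeric features. Row names carry the sample
#' identifiers.
#'
#' @param x matrix or data frame.
#' @param id_col name of the identifier column, if present.
#' @return numeric matrix with sample identifiers as row names.
#' @keywords internal
#' @noRd
as_feature_matrix <- function(x, id_col = "sample_id") {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    abort("`x` must be a matrix or data frame of samples by features.")
  }
  x <- as.data.frame(x)
  if (id_col %in% names(x)) {
    ids <- as.character(x[[id_col]])
    x <- x[setdiff(names(x), id_col)]
  } else if (!is.numeric(x[[1]])) {
    ids <- as.character(x[[1]])
    x <- x[-1]
  } else {
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  bad <- names(x)[!vapply(x, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric feature column(s): ", toString(head(bad, 5))))
  }
  m <- as.matrix(x)
  rownames(m) <- ids
  m
}

# Tibble view of a samples-by-features matrix.
matrix_to_tibble <- function(m, id_col = "sample_id") {
  tibble::as_tibble(m, rownames = id_col)
}

#' Evaluate code with a locally scoped RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so seeded pipeline
#' stages do not disturb the global random stream. `seed = NULL` runs the
#' code with the ambient stream.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Row-wise softmax, guarded against overflow.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Align `groups` with the sample identifiers of a distance object or matrix.
resolve_groups <- function(groups, ids) {
  if (!is.null(names(groups)) && all(ids %in% names(groups))) {
    groups <- groups[ids]
  }
  if (length(groups) != length(ids)) {
    abort("`groups` must supply one label per sample.")
  }
  factor(as.character(groups))
}

# Two-sided p-value for a Pearson correlation via the t distribution.
pearson_p <- function(r, df) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tstat), df = df)
}
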