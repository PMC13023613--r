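#' Construct an expression matrix with a declared scale
#'
#' A thin S3 wrapper around a genes-by-samples numeric matrix that records
#' whether the values are raw read counts or already log2-normalized.
#' Downstream scoring refuses raw counts, so the scale declaration is the
#' contract that prevents silently scoring unnormalized data.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols,
#'   unique), samples in columns (colnames = sample ids, unique).
#' @param scale `"raw_counts"` or `"log2_normalized"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, scale = c("raw_counts", "log2_normalized")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  if (scale == "raw_counts" && any(values < 0)) {
    stop("raw counts must be non-negative", call. = FALSE)
  }
  structure(values, scale = scale, class = c("expression_matrix", "matrix"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, scale: %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited expression matrix
#'
#' Expects a header row and a first column of identifiers (gene symbols if
#' `orientation = "genes_in_rows"`, sample ids otherwise). The delimiter is
#' taken from the file extension (`.csv` comma, otherwise tab) unless
#' overridden. Duplicate gene symbols are collapsed by taking the
#' per-sample maximum — this keeps the dominant isoform row rather than
#' diluting it — with a message giving the number of collapsed rows.
#'
#' @param path File path.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param scale Declared scale of the values, `"raw_counts"` or
#'   `"log2_normalized"`.
#' @param delim Optional delimiter override.
#' @return An [expression_matrix()] in genes-in-rows orientation.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            scale = c("raw_counts", "log2_normalized"),
                            delim = NULL) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  df <- readr::read_delim(path, delim = delim_for(path, delim),
                          show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    stop("malformed expression file '", path, "': first problem at line ",
         prob$row[1], " (", prob$expected[1], " expected, got ",
         prob$actual[1], ")", call. = FALSE)
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop("non-numeric expression values in '", path, "'", call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  ndup <- sum(duplicated(rownames(m)))
  if (ndup > 0) {
    message("collapsed ", ndup, " duplicate gene row(s) by per-sample maximum")
    grp <- factor(rownames(m), levels = unique(rownames(m)))
    m <- do.call(rbind, lapply(split(seq_len(nrow(m)), grp), function(i) {
      apply(m[i, , drop = FALSE], 2, max)
    }))
  }
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix to a delimited file
#'
#' Genes in rows, one `gene` identifier column first; delimiter follows
#' the file extension as in [read_expression()].
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param delim Optional delimiter override.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path, delim = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- tibble::as_tibble(as.data.frame(unclass(x)), rownames = "gene")
  readr::write_delim(df, path, delim = delim_for(path, delim))
  invisible(x)
}

#' Read per-sample metadata
#'
#' Requires a `sample_id` column; the optional columns `subject_id`,
#' `group`, `timepoint`, `sex`, `sofa` and `outcome` are filled with their
#' missing markers when absent (`subject_id` defaults to `sample_id`, `sex`
#' to `"unknown"`, `outcome` to `"unknown"`, `sofa` and `timepoint` to
#' `NA`). Column headers are matched case-insensitively. SOFA values must
#' lie in 0-24 (six organ systems scored 0-4 each).
#'
#' @param path File path (TSV or CSV by extension).
#' @param delim Optional delimiter override.
#' @return A tibble with columns `sample_id`, `subject_id`, `group`,
#'   `timepoint`, `sex`, `sofa`, `outcome`.
#' @export
read_metadata <- function(path, delim = NULL) {
  df <- readr::read_delim(path, delim = delim_for(path, delim),
                          show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  if (!"sample_id" %in% names(df)) {
    stop("metadata must contain a sample_id column", call. = FALSE)
  }
  as_sample_records(df)
}

#' Validate and complete a sample-metadata table
#'
#' @param df A data frame with at least `sample_id`.
#' @return A completed, validated metadata tibble (see [read_metadata()]).
#' @export
as_sample_records <- function(df) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id  = as.character(df$sample_id),
    subject_id = if ("subject_id" %in% names(df)) as.character(df$subject_id) else as.character(df$sample_id),
    group      = if ("group" %in% names(df)) as.character(df$group) else NA_character_,
    timepoint  = if ("timepoint" %in% names(df)) as.character(df$timepoint) else NA_character_,
    sex        = if ("sex" %in% names(df)) as.character(df$sex) else "unknown",
    sofa       = if ("sofa" %in% names(df)) as.integer(df$sofa) else NA_integer_,
    outcome    = if ("outcome" %in% names(df)) as.character(df$outcome) else "unknown"
  )
  out$sex[is.na(out$sex)] <- "unknown"
  out$outcome[is.na(out$outcome)] <- "unknown"
  bad_sofa <- !is.na(out$sofa) & (out$sofa < 0L | out$sofa > 24L)
  if (any(bad_sofa)) {
    stop("SOFA score outside [0, 24] for sample(s): ",
         paste(out$sample_id[bad_sofa], collapse = ", "), call. = FALSE)
  }
  if (!all(out$sex %in% c("F", "M", "unknown"))) {
    stop("sex must be one of F, M, unknown", call. = FALSE)
  }
  if (!all(out$outcome %in% c("survivor", "non-survivor", "unknown"))) {
    stop("outcome must be one of survivor, non-survivor, unknown",
         call. = FALSE)
  }
  out
}

#' Write sample metadata to a delimited file
#'
#' @param records Metadata tibble as returned by [read_metadata()].
#' @param path Output path.
#' @param delim Optional delimiter override.
#' @return `records`, invisibly.
#' @export
write_metadata <- function(records, path, delim = NULL) {
  readr::write_delim(records, path, delim = delim_for(path, delim))
  invisible(records)
}

#' Normalize raw counts to log2 counts-per-million
#'
#' Converts each sample's counts to counts-per-million and applies
#' `log2(CPM + 1)`. The pseudocount of 1 keeps zero counts at exactly 0 on
#' the log scale. Matrices already declared log2-normalized must not be
#' passed here; they are used as-is by the scorer (no re-normalization of
#' pre-normalized inputs).
#'
#' @param x An [expression_matrix()] with scale `"raw_counts"`.
#' @return An [expression_matrix()] with scale `"log2_normalized"`.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(1023, 999999 - 1023 + 1023), nrow = 2, # arbitrary small demo
#'          dimnames = list(c("g1", "g2"), "s1")),
#'   scale = "raw_counts"
#' )
#' normalize_log2(m)
#' @export
normalize_log2 <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (attr(x, "scale") != "raw_counts") {
    stop("normalize_log2() expects raw counts; matrix is already ",
         attr(x, "scale"), call. = FALSE)
  }
  totals <- colSums(unclass(x))
  if (any(totals <= 0)) {
    stop("zero total count in sample(s): ",
         paste(colnames(x)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  cpm <- sweep(unclass(x), 2, totals, "/") * 1e6
  expression_matrix(log2(cpm + 1), scale = "log2_normalized")
}
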