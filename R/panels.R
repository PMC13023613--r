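#' Canonical marker gene panels of the sepsis host response
#'
#' Returns the five marker gene sets used throughout the package, as a long
#' tibble with one row per panel gene. Each panel carries a dysregulation
#' direction describing its behaviour in sepsis relative to healthy
#' controls: `+1` (activated), `-1` (suppressed) or `0` (bidirectional —
#' activation and suppression are both seen across patients, so no single
#' direction applies).
#'
#' The panels are:
#' \describe{
#'   \item{NDrG}{neutrophil degranulation-related genes
#'     (S100A12, CD177, HP, ANXA3, ARG1); activated in sepsis.}
#'   \item{ISGa}{type I interferon-stimulated genes
#'     (IFI27, RSAD2, IFI44L, ISG15, IFITM3); bidirectional.}
#'   \item{GBPs}{guanylate-binding protein cluster, type II interferon
#'     signaling (GBP1-GBP5); bidirectional.}
#'   \item{HLAd}{MHC class II genes
#'     (HLA-DRA, HLA-DRB1, HLA-DMA, HLA-DMB, HLA-DPA1); suppressed.}
#'   \item{LYMd}{lymphocyte and dendritic-cell markers
#'     (CD4, CD8A, CD79A, CD27, KLRF1, FCER1A); suppressed.}
#' }
#'
#' @return A tibble with columns `panel` (character, in canonical order
#'   NDrG, ISGa, GBPs, HLAd, LYMd), `gene` (HGNC symbol) and `direction`
#'   (integer in -1, 0, +1).
#' @examples
#' builtin_panels()
#' @export
builtin_panels <- function() {
  dplyr::bind_rows(
    gene_panel("NDrG", c("S100A12", "CD177", "HP", "ANXA3", "ARG1"), +1L),
    gene_panel("ISGa", c("IFI27", "RSAD2", "IFI44L", "ISG15", "IFITM3"), 0L),
    gene_panel("GBPs", c("GBP1", "GBP2", "GBP3", "GBP4", "GBP5"), 0L),
    gene_panel("HLAd", c("HLA-DRA", "HLA-DRB1", "HLA-DMA", "HLA-DMB", "HLA-DPA1"), -1L),
    gene_panel("LYMd", c("CD4", "CD8A", "CD79A", "CD27", "KLRF1", "FCER1A"), -1L)
  )
}

#' Construct a gene panel
#'
#' @param name Short panel identifier (e.g. `"NDrG"`).
#' @param genes Character vector of unique HGNC-style gene symbols.
#' @param direction Dysregulation direction in sepsis: `+1` activated,
#'   `-1` suppressed, `0` bidirectional.
#' @return A tibble with one row per gene and columns `panel`, `gene`,
#'   `direction`.
#' @examples
#' gene_panel("myPanel", c("TNF", "IL6"), +1)
#' @export
gene_panel <- function(name, genes, direction) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) == 0L) {
    stop("panel '", name, "': gene list must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("panel '", name, "': duplicate gene symbols", call. = FALSE)
  }
  direction <- as.integer(direction)
  if (!direction %in% c(-1L, 0L, 1L)) {
    stop("direction must be one of -1, 0, +1", call. = FALSE)
  }
  tibble::tibble(panel = name, gene = genes, direction = direction)
}

#' Canonical order of the built-in panels
#' @keywords internal
#' @noRd
panel_order <- function() c("NDrG", "ISGa", "GBPs", "HLAd", "LYMd")

#' Locate a panel's genes in an expression matrix
#'
#' Gene-symbol matching is exact after uppercasing both sides; no alias
#' expansion is attempted. One warning is emitted per panel symbol absent
#' from the matrix.
#'
#' @param x An [expression_matrix()].
#' @param panel A one-panel tibble as produced by [gene_panel()], or a
#'   subset of [builtin_panels()] containing a single panel.
#' @return A list with `index` (row indices of the panel genes found, in
#'   panel order), `missing` (absent symbols) and `coverage`
#'   (found / panel size).
#' @export
resolve_panel_genes <- function(x, panel) {
  stopifnot(inherits(x, "expression_matrix"))
  pname <- unique(panel$panel)
  stopifnot(length(pname) == 1L)
  symbols <- toupper(rownames(x))
  if (anyDuplicated(symbols)) {
    stop("expression matrix has duplicate gene symbols; deduplicate on read",
         call. = FALSE)
  }
  idx <- match(toupper(panel$gene), symbols)
  missing <- panel$gene[is.na(idx)]
  for (g in missing) {
    warning("panel '", pname, "': gene '", g, "' not found in matrix",
            call. = FALSE)
  }
  coverage <- sum(!is.na(idx)) / length(idx)
  if (coverage == 0) {
    stop("panel '", pname, "': none of its genes found in the matrix ",
         "(coverage 0)", call. = FALSE)
  }
  list(index = idx[!is.na(idx)], missing = missing, coverage = coverage)
}

#' Score samples against marker gene panels
#'
#' The score of a panel in a sample is the arithmetic mean of the log2
#' expression values of the panel genes present in the matrix (missing
#' members are dropped and reported through the coverage columns). The
#' composite column is the NDrG score minus the HLAd score — the
#' simplified two-set summary in which low values predict survival.
#'
#' @param x An [expression_matrix()] on the log2 scale. Raw-count matrices
#'   are rejected; normalize first with [normalize_log2()].
#' @param panels A panel tibble ([builtin_panels()] by default); may hold
#'   several panels.
#' @return A tibble with one row per sample: `sample_id`, one score column
#'   per panel, `composite` (present when both NDrG and HLAd are scored),
#'   and one `coverage_<panel>` column per panel.
#' @examples
#' m <- expression_matrix(
#'   matrix(8, nrow = 26, ncol = 2,
#'          dimnames = list(builtin_panels()$gene, c("s1", "s2"))),
#'   scale = "log2_normalized"
#' )
#' score_samples(m)
#' @export
score_samples <- function(x, panels = builtin_panels()) {
  stopifnot(inherits(x, "expression_matrix"))
  if (attr(x, "scale") != "log2_normalized") {
    stop("score_samples() requires a log2-normalized matrix; ",
         "call normalize_log2() on raw counts first", call. = FALSE)
  }
  pnames <- unique(panels$panel)
  vals <- unclass(x)
  out <- tibble::tibble(sample_id = colnames(x))
  cov <- numeric(length(pnames))
  names(cov) <- pnames
  for (p in pnames) {
    res <- resolve_panel_genes(x, panels[panels$panel == p, , drop = FALSE])
    cov[[p]] <- res$coverage
    sub <- vals[res$index, , drop = FALSE]
    out[[p]] <- unname(colMeans(sub))
  }
  if (all(c("NDrG", "HLAd") %in% pnames)) {
    out$composite <- out$NDrG - out$HLAd
  }
  for (p in pnames) out[[paste0("coverage_", p)]] <- cov[[p]]
  out
}

#' Write panel scores to a TSV file
#'
#' @param scores A score tibble from [score_samples()].
#' @param path Output file path.
#' @return `scores`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(scores, path)
  invisible(scores)
}
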