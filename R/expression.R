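# Count-matrix container, CPM normalization, expression filter, mean profiles.

#' Construct an expression matrix for one cancer type
#'
#' @param values numeric genes x samples matrix with gene ids as rownames and
#'   sample ids as colnames; no negative entries.
#' @param cancer_type cancer-type label.
#' @param unit `"raw_counts"` or `"cpm"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, cancer_type, unit = c("raw_counts", "cpm")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (any(values < 0)) stop("negative expression values", call. = FALSE)
  structure(list(cancer_type = as.character(cancer_type), unit = unit,
                 values = values), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", x$cancer_type, ": ", nrow(x$values), " genes x ",
      ncol(x$values), " samples [", x$unit, "]\n", sep = "")
  invisible(x)
}

#' Normalize raw counts to counts per million
#'
#' Divides each sample column by its library size (raw column sum) and scales
#' by 1e6. All-zero columns are passed through as zeros with a warning.
#'
#' @param x an [expr_matrix] in `raw_counts` unit.
#' @return an [expr_matrix] in `cpm` unit.
#' @export
cpm_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "raw_counts")
    stop("cpm_normalize expects raw counts", call. = FALSE)
  libs <- colSums(x$values)
  if (any(libs == 0))
    warning("all-zero library in sample(s): ",
            paste(head(colnames(x$values)[libs == 0], 3L), collapse = ", "),
            call. = FALSE)
  scale <- ifelse(libs == 0, 0, 1e6 / libs)
  expr_matrix(sweep(x$values, 2L, scale, `*`), x$cancer_type, "cpm")
}

#' Genes passing the expression filter
#'
#' A gene is retained when at least `min_samples` samples show at least
#' `min_cpm` counts per million. Applied independently per cancer type.
#'
#' @param x an [expr_matrix] in `cpm` unit.
#' @param min_cpm minimum CPM (default 1).
#' @param min_samples minimum number of samples at or above `min_cpm`
#'   (default 3).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(x, min_cpm = 1, min_samples = 3L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "cpm") stop("filter_expressed expects cpm", call. = FALSE)
  keep <- rowSums(x$values >= min_cpm) >= min_samples
  rownames(x$values)[keep]
}

#' Per-cancer-type mean CPM profiles
#'
#' Arithmetic mean CPM of each gene over all samples of each cancer type (no
#' expression filter is applied here: sub-threshold genes contribute their
#' observed mean, and a gene absent from a cancer type's matrix contributes 0).
#'
#' @param cpm_list list of [expr_matrix] objects in `cpm` unit (one per cancer
#'   type).
#' @param gene_ids genes to profile; default: union over all matrices.
#' @return numeric matrix, genes x cancer types.
#' @export
mean_profiles <- function(cpm_list, gene_ids = NULL) {
  stopifnot(length(cpm_list) >= 1L)
  for (x in cpm_list)
    if (!inherits(x, "expr_matrix") || x$unit != "cpm")
      stop("mean_profiles expects cpm expr_matrix objects", call. = FALSE)
  types <- vapply(cpm_list, `[[`, "", "cancer_type")
  if (anyDuplicated(types)) stop("duplicated cancer_type labels", call. = FALSE)
  if (is.null(gene_ids))
    gene_ids <- sort(unique(unlist(lapply(cpm_list, function(x) rownames(x$values)))))
  out <- matrix(0, nrow = length(gene_ids), ncol = length(types),
                dimnames = list(gene_ids, types))
  present <- logical(length(gene_ids))
  for (j in seq_along(cpm_list)) {
    v <- cpm_list[[j]]$values
    hit <- gene_ids %in% rownames(v)
    present <- present | hit
    out[hit, j] <- rowMeans(v[gene_ids[hit], , drop = FALSE])
  }
  if (!all(present))
    stop("gene(s) absent from every cancer type: ",
         paste(head(gene_ids[!present], 3L), collapse = ", "), call. = FALSE)
  out
}

#' Mean profile of a single gene
#'
#' @param cpm_list list of [expr_matrix] objects in `cpm` unit.
#' @param gene_id single gene id; must be present in at least one matrix.
#' @return named numeric vector of per-cancer-type mean CPM.
#' @export
mean_profile <- function(cpm_list, gene_id) {
  mean_profiles(cpm_list, gene_ids = gene_id)[1L, ]
}

#' Read a counts TSV (first column gene_id, header row of sample ids)
#'
#' @param path TSV path.
#' @param cancer_type cancer-type label for the resulting matrix.
#' @param unit matrix unit, default `"raw_counts"`.
#' @return an [expr_matrix].
#' @export
read_counts_tsv <- function(path, cancer_type, unit = "raw_counts") {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  expr_matrix(m, cancer_type, unit)
}

write_counts_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a cohort index and load its count matrices
#'
#' The index is a TSV with columns `cancer_type` and `path` (paths relative to
#' the index file's directory, or absolute).
#'
#' @param index_path cohort index TSV.
#' @return named list of `raw_counts` [expr_matrix] objects.
#' @export
read_cohort <- function(index_path) {
  idx <- read_tsv(index_path)
  if (!all(c("cancer_type", "path") %in% names(idx)))
    stop("cohort index needs columns cancer_type, path", call. = FALSE)
  base <- dirname(index_path)
  out <- lapply(seq_len(nrow(idx)), function(i) {
    p <- idx$path[i]
    if (!file.exists(p)) p <- file.path(base, idx$path[i])
    if (!file.exists(p)) stop("missing count matrix: ", idx$path[i], call. = FALSE)
    read_counts_tsv(p, idx$cancer_type[i])
  })
  names(out) <- idx$cancer_type
  out
}
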