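# Characterization: Tau specificity, exonic conservation, category enrichment,
# methylation-expression coupling, subcellular localization comparison.

#' Tau expression-specificity index
#'
#' `tau = sum(1 - x_hat) / (n - 1)` with `x_hat = x / max(x)`, computed over a
#' gene's per-group mean expression profile. 0 means identical expression in
#' every group (ubiquitous); 1 means expression restricted to a single group.
#' By default the profile is transformed with `log2(x + 1)` first, the usual
#' choice for expression data; both modes preserve the 0/1 anchor cases.
#'
#' @param profile non-negative numeric vector of per-group mean expression,
#'   length >= 2, not all zero.
#' @param log_transform apply `log2(x + 1)` before scoring (default TRUE).
#' @return tau in `[0, 1]`.
#' @export
#' @examples
#' tau(c(1, 2, 4), log_transform = FALSE)  # 0.625
tau <- function(profile, log_transform = TRUE) {
  x <- as.numeric(profile)
  if (length(x) < 2L) stop("tau needs at least 2 groups", call. = FALSE)
  if (any(x < 0)) stop("negative expression in profile", call. = FALSE)
  if (log_transform) x <- log2(x + 1)
  mx <- max(x)
  if (mx == 0) stop("all-zero profile: tau undefined", call. = FALSE)
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Tau scores for a profile matrix
#'
#' @param profiles genes x groups matrix from [mean_profiles()].
#' @param log_transform passed to [tau()].
#' @return data frame with `gene_id`, `tau`, `n_groups`; all-zero profiles —
#'   and every profile when fewer than 2 groups are present, where specificity
#'   is undefined — get `NA` tau.
#' @export
tau_table <- function(profiles, log_transform = TRUE) {
  vals <- vapply(seq_len(nrow(profiles)), function(i) {
    x <- profiles[i, ]
    if (length(x) < 2L || max(x) == 0) return(NA_real_)
    tau(x, log_transform)
  }, numeric(1L))
  data.frame(gene_id = rownames(profiles), tau = vals,
             n_groups = ncol(profiles), stringsAsFactors = FALSE)
}

#' Read a 4-column bedGraph into a per-base score table
#'
#' @param path bedGraph path (0-based half-open intervals).
#' @return data frame `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             score = gr$score, stringsAsFactors = FALSE)
}

write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", track$chrom, track$start, track$end,
                     track$score), path)
  invisible(path)
}

#' Mean conservation over a gene's exonic bases
#'
#' Averages a per-base score track over the union of the gene's exons, minus
#' an optional mask (for lncRNAs: the union of all coding exons, so that
#' shared bases do not inflate lncRNA conservation). Bases not covered by the
#' track score 0 and still count in the denominator.
#'
#' @param ann a [gene_annotation].
#' @param track score table from [read_bedgraph()].
#' @param gene_id gene to score.
#' @param mask interval matrix of bases to exclude (on the gene's chromosome),
#'   or `NULL`.
#' @return list with `gene_id`, `mean_score` (`NA` when the support is empty),
#'   `n_bases`.
#' @export
exonic_conservation <- function(ann, track, gene_id, mask = NULL) {
  g <- ann$genes[ann$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop("unknown gene_id: ", gene_id, call. = FALSE)
  support <- merge_exons(ann, gene_id)
  if (!is.null(mask) && nrow(as_interval_matrix(mask)) > 0L)
    support <- subtract_intervals(support, mask)
  n_bases <- interval_bases(support)
  if (n_bases == 0L)
    return(list(gene_id = gene_id, mean_score = NA_real_, n_bases = 0L))
  tr <- track[track$chrom == g$chrom, , drop = FALSE]
  total <- 0
  if (nrow(tr)) {
    ir_s <- ir_from_half_open(support)
    ir_t <- IRanges::IRanges(tr$start + 1L, tr$end)
    hits <- IRanges::findOverlaps(ir_s, ir_t)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- IRanges::pintersect(ir_s[qi], ir_t[si])
      total <- sum(IRanges::width(ov) * tr$score[si])
    }
  }
  list(gene_id = gene_id, mean_score = total / n_bases, n_bases = n_bases)
}

#' Conservation table for every gene in an annotation
#'
#' Coding genes are averaged over their merged exons; lncRNA genes over their
#' exons minus the union of all coding exons on the same chromosome.
#'
#' @param ann a [gene_annotation].
#' @param track score table from [read_bedgraph()].
#' @return data frame `gene_id`, `biotype`, `mean_score`, `n_bases`.
#' @export
conservation_table <- function(ann, track) {
  g <- ann$genes
  coding_ids <- g$gene_id[g$biotype == "coding"]
  cod_ex <- ann$exons[ann$exons$gene_id %in% coding_ids, , drop = FALSE]
  cod_chrom <- g$chrom[match(cod_ex$gene_id, g$gene_id)]
  mask_by_chrom <- lapply(split(cod_ex[, c("start", "end")], cod_chrom),
                          merge_intervals)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    mask <- if (g$biotype[i] == "lncRNA") mask_by_chrom[[g$chrom[i]]] else NULL
    r <- exonic_conservation(ann, track, g$gene_id[i], mask)
    data.frame(gene_id = r$gene_id, biotype = g$biotype[i],
               mean_score = r$mean_score, n_bases = r$n_bases,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-category enrichment across the four correlation sets
#'
#' For each set (LCN/LCP/CCN/CCP), computes the fraction of its unique coding
#' genes belonging to a category and a Fisher's exact test against the union
#' of the other three sets (default) or against all coding genes in the
#' summaries (`background = "all"`).
#'
#' @param summaries labeled pair table from [label_pairs()] (one window).
#' @param category_ids character vector of coding gene ids in the category.
#' @param background `"other_sets"` (default) or `"all"`.
#' @return data frame `set_label`, `n_genes`, `n_in_category`, `fraction`,
#'   `fisher_p`.
#' @export
category_enrichment <- function(summaries, category_ids,
                                background = c("other_sets", "all")) {
  background <- match.arg(background)
  sets <- c("LCN", "LCP", "CCN", "CCP")
  genes_of <- function(lab) unique(summaries$anchor_id[summaries$set_label == lab])
  all_coding <- unique(summaries$anchor_id)
  rows <- lapply(sets, function(s) {
    gs <- genes_of(s)
    n <- length(gs); hit <- sum(gs %in% category_ids)
    bg <- if (background == "other_sets")
      setdiff(unique(unlist(lapply(setdiff(sets, s), genes_of))), gs)
    else setdiff(all_coding, gs)
    bg_hit <- sum(bg %in% category_ids)
    p <- if (n > 0L && length(bg) > 0L)
      fisher_exact_2x2(hit, n - hit, bg_hit, length(bg) - bg_hit)
    else NA_real_
    data.frame(set_label = s, n_genes = n, n_in_category = hit,
               fraction = if (n > 0L) hit / n else NA_real_,
               fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an Illumina-450K-style probe manifest
#'
#' @param path TSV with columns `probe_id`, `gene_id`, `region`
#'   (`TSS200`, `TSS1500`, `Body`, ...).
#' @return the manifest data frame.
#' @export
read_probe_manifest <- function(path) {
  df <- read_tsv(path)
  need <- c("probe_id", "gene_id", "region")
  if (!all(need %in% names(df)))
    stop("probe manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Pick the representative TSS probe for a gene
#'
#' Among a gene's TSS-annotated probes (regions `TSS200`/`TSS1500`), returns
#' the one with the highest mean beta across the cancer type's samples; ties
#' break to the lexicographically smaller probe id.
#'
#' @param manifest probe manifest (see [read_probe_manifest()]).
#' @param beta probes x samples beta matrix for one cancer type.
#' @param gene_id gene whose TSS probe is sought.
#' @return probe id, or `NA_character_` when the gene has no TSS probe in the
#'   matrix.
#' @export
assign_probe_to_tss <- function(manifest, beta, gene_id) {
  probes <- manifest$probe_id[manifest$gene_id == gene_id &
                                manifest$region %in% c("TSS200", "TSS1500")]
  probes <- sort(intersect(probes, rownames(beta)))
  if (!length(probes)) return(NA_character_)
  means <- rowMeans(beta[probes, , drop = FALSE])
  probes[which.max(means)]  # which.max takes the first (smallest id) on ties
}

#' Couple lncRNA expression to coding-promoter methylation
#'
#' For each pair and cancer type, computes the Spearman correlation between
#' the lncRNA's CPM and the beta values of the coding gene's representative
#' TSS probe over the matched samples (intersection of expression and
#' methylation sample ids). BH adjustment is per cancer type. A pair is
#' flagged positively coupled when `rho_meth > 0` in the majority of its
#' testable cancer types, the pattern expected if the lncRNA represses its
#' partner through promoter methylation.
#'
#' @param pairs data frame with columns `anchor_id` (coding), `partner_id`
#'   (lncRNA) — typically the LCN rows of [label_pairs()] output.
#' @param cpm_list named list of `cpm` [expr_matrix] objects.
#' @param beta_list named list (same cancer types) of probes x samples beta
#'   matrices.
#' @param manifest probe manifest.
#' @param alpha_meth adjusted-p cutoff stored in the `significant` column
#'   (default 0.05).
#' @param min_samples_test minimum matched samples (default 10).
#' @return list with `records` (per pair x cancer type: `probe_id`,
#'   `n_samples`, `rho_meth`, `p_raw`, `p_adj`, `significant`) and `flags`
#'   (per pair: `n_testable`, `n_pos`, `positively_coupled`).
#' @export
methylation_coupling <- function(pairs, cpm_list, beta_list, manifest,
                                 alpha_meth = 0.05, min_samples_test = 10L) {
  pairs <- unique(pairs[, c("anchor_id", "partner_id")])
  rec <- list()
  for (ct in intersect(names(cpm_list), names(beta_list))) {
    ev <- cpm_list[[ct]]$values
    bv <- beta_list[[ct]]
    matched <- intersect(colnames(ev), colnames(bv))
    if (length(matched) < min_samples_test) next
    rows <- list()
    for (i in seq_len(nrow(pairs))) {
      lnc <- pairs$partner_id[i]; cod <- pairs$anchor_id[i]
      if (!lnc %in% rownames(ev)) next
      probe <- assign_probe_to_tss(manifest, bv[, matched, drop = FALSE], cod)
      if (is.na(probe)) next
      x <- ev[lnc, matched]; y <- bv[probe, matched]
      if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
      st <- spearman_test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        anchor_id = cod, partner_id = lnc, cancer_type = ct, probe_id = probe,
        n_samples = st$n, rho_meth = st$rho, p_raw = st$p,
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    df$p_adj <- bh_adjust(df$p_raw)
    df$significant <- df$p_adj < alpha_meth
    rec[[ct]] <- df
  }
  if (!length(rec)) {
    records <- data.frame(anchor_id = character(), partner_id = character(),
                          cancer_type = character(), probe_id = character(),
                          n_samples = integer(), rho_meth = numeric(),
                          p_raw = numeric(), p_adj = numeric(),
                          significant = logical(), stringsAsFactors = FALSE)
  } else {
    records <- do.call(rbind, rec)
    rownames(records) <- NULL
  }
  k <- paste(pairs$anchor_id, pairs$partner_id, sep = "\r")
  rk <- paste(records$anchor_id, records$partner_id, sep = "\r")
  idx <- factor(match(rk, k), levels = seq_along(k))
  n_testable <- as.integer(tapply(rep(TRUE, nrow(records)), idx, sum, default = 0L))
  n_pos <- as.integer(tapply(records$rho_meth > 0, idx, sum, default = 0L))
  flags <- data.frame(anchor_id = pairs$anchor_id, partner_id = pairs$partner_id,
                      n_testable = n_testable, n_pos = n_pos,
                      positively_coupled = n_testable > 0L & n_pos > n_testable / 2,
                      stringsAsFactors = FALSE)
  list(records = records, flags = flags)
}

#' Two-sample t-test with zero-variance edge handling
#'
#' Pooled-variance Student test by default (`variant = "welch"` for unequal
#' variances). Degenerate inputs: zero combined variance with equal means
#' gives `p = 1`; zero combined variance with unequal means gives the numeric
#' floor.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return list with `t` and `p` (two-sided).
#' @export
t_test_two_sample <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = .Machine$double.xmin))
  }
  ht <- t.test(a, b, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Read a cytoplasmic/nuclear RCI table
#'
#' @param path TSV with columns `gene_id`, `cell_line`, `rci`.
#' @return the data frame.
#' @export
read_rci <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "cell_line", "rci")
  if (!all(need %in% names(df)))
    stop("RCI table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$rci))) stop("non-finite RCI values", call. = FALSE)
  df
}

#' Compare subcellular localization (RCI) of LCN lncRNAs per cell line
#'
#' For each cell line, reports the median RCI of the LCN lncRNAs and Student's
#' two-sample t-tests of LCN vs the lncRNA background and LCN vs LCP. Negative
#' RCI means nuclear enrichment, the compartment where a cis-acting repressor
#' must reside. Cell lines where any compared group has fewer than 2 genes are
#' skipped.
#'
#' @param rci RCI table from [read_rci()].
#' @param lcn_ids,lcp_ids,background_ids lncRNA gene-id sets.
#' @return data frame per retained cell line: `cell_line`, `n_lcn`,
#'   `median_lcn`, `t_vs_background`, `p_vs_background`, `t_vs_lcp`,
#'   `p_vs_lcp`.
#' @export
localization_compare <- function(rci, lcn_ids, lcp_ids, background_ids) {
  rows <- lapply(sort(unique(rci$cell_line)), function(cl) {
    r <- rci[rci$cell_line == cl, ]
    a <- r$rci[r$gene_id %in% lcn_ids]
    bg <- r$rci[r$gene_id %in% background_ids]
    lp <- r$rci[r$gene_id %in% lcp_ids]
    if (length(a) < 2L || length(bg) < 2L || length(lp) < 2L) return(NULL)
    tb <- t_test_two_sample(a, bg); tl <- t_test_two_sample(a, lp)
    data.frame(cell_line = cl, n_lcn = length(a), median_lcn = median(a),
               t_vs_background = tb$t, p_vs_background = tb$p,
               t_vs_lcp = tl$t, p_vs_lcp = tl$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_line = character(), n_lcn = integer(),
                      median_lcn = numeric(), t_vs_background = numeric(),
                      p_vs_background = numeric(), t_vs_lcp = numeric(),
                      p_vs_lcp = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
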