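# End-to-end driver: pair -> screen -> label -> characterize, with a run
# manifest, stage logging and recovery evaluation against a truth manifest.

#' Configuration for an end-to-end run
#'
#' Collects the input paths and thresholds of the screen. Paths may be the
#' files written by [simulate_cohort()] or equivalently formatted real data.
#'
#' @param gtf annotation GTF path.
#' @param cohort_index cohort index TSV (columns `cancer_type`, `path`).
#' @param chrom_sizes chrom.sizes TSV, or `NULL`.
#' @param conservation bedGraph path, or `NULL` to skip conservation.
#' @param meth_index methylation index TSV, or `NULL` to skip methylation.
#' @param probe_manifest probe manifest TSV (required with `meth_index`).
#' @param rci RCI TSV, or `NULL` to skip localization.
#' @param categories named character vector of gene-list files, or `NULL`.
#' @param windows strictly increasing window sizes in bases.
#' @param apa_gap APA filter gap (bases); `NULL` disables the filter.
#' @param alpha adjusted-p cutoff for the expression screen.
#' @param enrich_p Fisher p cutoff for per-cancer-type enrichment.
#' @param alpha_meth adjusted-p cutoff for methylation coupling.
#' @param majority `"testable"` or `"all"` majority denominator.
#' @param tau_log log-transform mean profiles before Tau (default TRUE).
#' @param min_samples_test minimum samples per correlation test.
#' @param seed integer seed (used only by optional shuffle stages).
#' @param shuffle also build and screen a within-chromosome shuffled pairing
#'   null (default FALSE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(gtf, cohort_index, chrom_sizes = NULL,
                            conservation = NULL, meth_index = NULL,
                            probe_manifest = NULL, rci = NULL,
                            categories = NULL,
                            windows = c(25000L, 50000L, 100000L),
                            apa_gap = 5000L, alpha = 1e-5, enrich_p = 0.01,
                            alpha_meth = 0.05,
                            majority = "testable", tau_log = TRUE,
                            min_samples_test = 10L, seed = 1L,
                            shuffle = FALSE) {
  windows <- as.integer(windows)
  if (any(diff(windows) <= 0L))
    stop("windows must be strictly increasing", call. = FALSE)
  for (thr in c(alpha, enrich_p, alpha_meth))
    if (!(thr > 0 && thr < 1))
      stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (!is.null(meth_index) && is.null(probe_manifest))
    stop("meth_index requires probe_manifest", call. = FALSE)
  structure(list(gtf = gtf, cohort_index = cohort_index,
                 chrom_sizes = chrom_sizes, conservation = conservation,
                 meth_index = meth_index, probe_manifest = probe_manifest,
                 rci = rci, categories = categories, windows = windows,
                 apa_gap = apa_gap, alpha = alpha, enrich_p = enrich_p,
                 alpha_meth = alpha_meth, majority = majority,
                 tau_log = tau_log,
                 min_samples_test = as.integer(min_samples_test),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "pipeline_config")
}

check_inputs <- function(config) {
  paths <- c(config$gtf, config$cohort_index, config$chrom_sizes,
             config$conservation, config$meth_index, config$probe_manifest,
             config$rci, unlist(config$categories))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
}

read_beta_cohort <- function(index_path) {
  idx <- read_tsv(index_path)
  base <- dirname(index_path)
  out <- lapply(seq_len(nrow(idx)), function(i) {
    p <- idx$path[i]
    if (!file.exists(p)) p <- file.path(base, idx$path[i])
    df <- read_tsv(p)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  })
  setNames(out, idx$cancer_type)
}

#' Run the full screen
#'
#' Executes annotation reading, APA filtering, window pairing (lncRNA/coding
#' plus coding/coding controls), CPM normalization, the per-cancer-type
#' Spearman screen, cross-cancer set labeling, per-cancer-type enrichment, and
#' — when the corresponding inputs are configured — Tau specificity,
#' conservation, category enrichment, localization comparison and methylation
#' coupling. All tables are written as TSV under `out_dir`, with a JSON run
#' manifest carrying the config hash and stage-by-stage counts; re-running
#' with an identical config reproduces every file byte for byte.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory.
#' @return an object of class `cispair_run` (list of output paths, the main
#'   tables, and the funnel log).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  check_inputs(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  paths <- list()
  tables <- list()

  sizes <- if (!is.null(config$chrom_sizes)) read_chrom_sizes(config$chrom_sizes)
  ann <- read_gtf(config$gtf, chrom_sizes = sizes)
  log$n_genes <- nrow(ann$genes)
  log$n_coding <- sum(ann$genes$biotype == "coding")
  log$n_lncRNA <- sum(ann$genes$biotype == "lncRNA")

  built <- build_all_pairs(ann, windows = config$windows,
                           apa_gap = config$apa_gap)
  log$n_apa_flagged <- nrow(built$apa_flags)
  log$n_pairs <- nrow(built$pairs)
  paths$apa_flags <- file.path(out_dir, "apa_flags.tsv")
  write_tsv(built$apa_flags, paths$apa_flags)
  paths$pairs <- file.path(out_dir, "pairs.tsv")
  write_tsv(built$pairs, paths$pairs)
  tables$pairs <- built$pairs

  counts <- read_cohort(config$cohort_index)
  cpm <- lapply(counts, cpm_normalize)
  log$n_cancer_types <- length(cpm)
  log$n_samples_total <- sum(vapply(cpm, function(x) ncol(x$values), 0L))

  records <- screen_pairs(built$pairs, cpm,
                          min_samples_test = config$min_samples_test)
  log$n_records <- nrow(records)
  log$n_constant_skipped <- attr(records, "n_constant_skipped") %||% 0L
  log$n_significant <- sum(records$p_adj < config$alpha)
  paths$correlations <- file.path(out_dir, "correlations.tsv")
  write_tsv(records, paths$correlations)
  tables$records <- records

  summaries <- label_pairs(records, built$pairs, alpha = config$alpha,
                           majority = config$majority,
                           n_types_total = length(cpm))
  paths$summaries <- file.path(out_dir, "summaries.tsv")
  tables$summaries <- summaries
  # set construction reported at the widest window
  wmax <- max(config$windows)
  sets <- summaries[summaries$window_bp == wmax, , drop = FALSE]
  for (lab in c("LCN", "LCP", "CCN", "CCP"))
    log[[paste0("n_", lab)]] <- sum(sets$set_label == lab)

  enr <- pair_class_enrichment(records, alpha = config$alpha,
                               enrich_p = config$enrich_p)
  paths$enrichment <- file.path(out_dir, "enrichment_by_type.tsv")
  write_tsv(enr, paths$enrichment)
  tables$enrichment <- enr

  profiles <- mean_profiles(cpm)
  taus <- tau_table(profiles, log_transform = config$tau_log)
  taus$biotype <- ann$genes$biotype[match(taus$gene_id, ann$genes$gene_id)]
  paths$tau <- file.path(out_dir, "tau.tsv")
  write_tsv(taus, paths$tau)
  tables$tau <- taus

  cons <- NULL
  if (!is.null(config$conservation)) {
    track <- read_bedgraph(config$conservation)
    cons <- conservation_table(ann, track)
    paths$conservation <- file.path(out_dir, "conservation.tsv")
    write_tsv(cons, paths$conservation)
    tables$conservation <- cons
  }

  # Table-1-shaped summary: per-pair significance counts plus Tau and
  # conservation of both genes
  t1 <- sets
  t1$tau_coding <- taus$tau[match(t1$anchor_id, taus$gene_id)]
  t1$tau_partner <- taus$tau[match(t1$partner_id, taus$gene_id)]
  if (!is.null(cons)) {
    t1$phastcons_coding <- cons$mean_score[match(t1$anchor_id, cons$gene_id)]
    t1$phastcons_partner <- cons$mean_score[match(t1$partner_id, cons$gene_id)]
  }
  write_tsv(t1, paths$summaries)
  tables$summaries_widest <- t1

  if (!is.null(config$categories)) {
    cat_rows <- lapply(names(config$categories), function(nm) {
      ids <- readLines(config$categories[[nm]])
      ce <- category_enrichment(sets, ids)
      data.frame(category = nm, ce, stringsAsFactors = FALSE)
    })
    cat_df <- do.call(rbind, cat_rows)
    paths$category_enrichment <- file.path(out_dir, "category_enrichment.tsv")
    write_tsv(cat_df, paths$category_enrichment)
    tables$category_enrichment <- cat_df
  }

  if (!is.null(config$rci)) {
    rci <- read_rci(config$rci)
    lcn_l <- unique(sets$partner_id[sets$set_label == "LCN"])
    lcp_l <- unique(sets$partner_id[sets$set_label == "LCP"])
    all_l <- unique(ann$genes$gene_id[ann$genes$biotype == "lncRNA"])
    loc <- localization_compare(rci, lcn_l, lcp_l, setdiff(all_l, lcn_l))
    paths$localization <- file.path(out_dir, "localization.tsv")
    write_tsv(loc, paths$localization)
    tables$localization <- loc
  }

  if (!is.null(config$meth_index)) {
    beta <- read_beta_cohort(config$meth_index)
    manifest <- read_probe_manifest(config$probe_manifest)
    lcn <- sets[sets$set_label == "LCN", , drop = FALSE]
    mc <- methylation_coupling(lcn, cpm, beta, manifest,
                               alpha_meth = config$alpha_meth,
                               min_samples_test = config$min_samples_test)
    paths$methylation <- file.path(out_dir, "methylation_coupling.tsv")
    write_tsv(mc$records, paths$methylation)
    paths$coupling_flags <- file.path(out_dir, "coupling_flags.tsv")
    write_tsv(mc$flags, paths$coupling_flags)
    tables$methylation <- mc$records
    tables$coupling_flags <- mc$flags
    log$n_positively_coupled <- sum(mc$flags$positively_coupled)
  }

  if (config$shuffle) {
    shuf <- shuffle_genes(ann, seed = config$seed)
    cov_real <- proximity_coverage(ann, config$windows, config$apa_gap)
    cov_shuf <- proximity_coverage(shuf, config$windows, config$apa_gap)
    shdf <- data.frame(window_bp = as.integer(names(cov_real)),
                       frac_real = as.numeric(cov_real),
                       frac_shuffled = as.numeric(cov_shuf))
    paths$shuffle_null <- file.path(out_dir, "shuffle_null.tsv")
    write_tsv(shdf, paths$shuffle_null)
    tables$shuffle_null <- shdf
  }

  manifest_out <- list(
    package_version = as.character(utils::packageVersion("cispair")),
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    funnel = log)
  paths$run_manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest_out, paths$run_manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  structure(list(paths = paths, tables = tables, funnel = log,
                 config = config, out_dir = out_dir),
            class = "cispair_run")
}

#' @export
print.cispair_run <- function(x, ...) {
  f <- x$funnel
  cat("<cispair_run> ", x$out_dir, "\n", sep = "")
  cat("  genes: ", f$n_genes, " (", f$n_coding, " coding, ", f$n_lncRNA,
      " lncRNA); APA-flagged lncRNAs: ", f$n_apa_flagged, "\n", sep = "")
  cat("  pairs (all windows): ", f$n_pairs, "; correlation records: ",
      f$n_records, " (", f$n_significant, " significant)\n", sep = "")
  cat("  sets at widest window - LCN: ", f$n_LCN, ", LCP: ", f$n_LCP,
      ", CCN: ", f$n_CCN, ", CCP: ", f$n_CCP, "\n", sep = "")
  if (!is.null(f$n_positively_coupled))
    cat("  positively methylation-coupled LCN pairs: ",
        f$n_positively_coupled, "\n", sep = "")
  invisible(x)
}

#' Evaluate planted-pair recovery against a truth manifest
#'
#' Sensitivity is the fraction of planted repressor pairs (classes
#' `repressor` and `mediated_repressor`) among the testable ones that the
#' screen labeled LCN; the false-discovery proportion (FDP) is the fraction of
#' LCN-labeled pairs that were not planted repressors. Also returns the
#' confusion table of planted class vs assigned label.
#'
#' @param summaries labeled pair table ([label_pairs()] output restricted to
#'   one window, or a `cispair_run`'s `summaries_widest` table).
#' @param truth truth manifest (list with `pairs`), from [simulate_cohort()]
#'   or [read_truth()].
#' @return list with `sensitivity`, `fdp` (`NA` when the LCN set is empty),
#'   `n_lcn`, `confusion` (data frame class x label counts).
#' @export
evaluate_recovery <- function(summaries, truth) {
  if (inherits(summaries, "cispair_run"))
    summaries <- summaries$tables$summaries_widest
  tp <- truth$pairs
  missing_ids <- setdiff(c(tp$anchor_id, tp$partner_id),
                         c(summaries$anchor_id, summaries$partner_id))
  # planted pairs can legitimately be absent (not testable); only complain if
  # the gene universes are disjoint, which signals mismatched inputs
  if (length(missing_ids) == length(unique(c(tp$anchor_id, tp$partner_id))))
    stop("no truth gene ids found in summaries; mismatched inputs? missing: ",
         paste(head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  key <- function(a, p) paste(a, p, sep = "\r")
  sk <- key(summaries$anchor_id, summaries$partner_id)
  tk <- key(tp$anchor_id, tp$partner_id)
  planted_class <- setNames(tp$class, tk)
  cls <- planted_class[sk]
  cls[is.na(cls)] <- "unplanted"
  confusion <- as.data.frame(table(class = cls, label = summaries$set_label),
                             stringsAsFactors = FALSE)
  repressors <- tp[tp$class %in% c("repressor", "mediated_repressor"), ]
  rk <- key(repressors$anchor_id, repressors$partner_id)
  testable <- rk[rk %in% sk[summaries$n_testable > 0L]]
  hit <- rk[rk %in% sk[summaries$set_label == "LCN"]]
  lcn_k <- sk[summaries$set_label == "LCN"]
  sensitivity <- if (length(testable)) length(hit) / length(testable) else NA_real_
  fdp <- if (length(lcn_k)) sum(!lcn_k %in% rk) / length(lcn_k) else NA_real_
  list(sensitivity = sensitivity, fdp = fdp, n_lcn = length(lcn_k),
       confusion = confusion)
}
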