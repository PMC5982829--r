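# Per-cancer-type Spearman screen, BH correction, set labels, enrichment.

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of midranks; the two-sided p-value comes
#' from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' `|rho| = 1` returns the numeric floor instead of 0.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, neither constant.
#' @return list with elements `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant input: Spearman correlation undefined", call. = FALSE)
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)
  }
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; input order is preserved.
#'
#' @param p numeric vector of raw p-values in `(0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Screen gene pairs for expression correlation in each cancer type
#'
#' For every pair and every cancer type where both genes pass
#' [filter_expressed()], computes the Spearman correlation of CPM values
#' across that cancer type's samples. BH adjustment is applied within each
#' (cancer type, partner class, window) family, or one global family with
#' `family = "global"`. No threshold is applied to rho itself.
#'
#' @param pairs pair table from [build_window_pairs()]/[build_all_pairs()].
#' @param cpm_list named list of `cpm` [expr_matrix] objects, one per cancer
#'   type.
#' @param min_cpm,min_samples_expressed expression-filter parameters.
#' @param min_samples_test minimum samples for a correlation to be attempted
#'   (default 10).
#' @param family `"per_type"` (default) or `"global"` BH family.
#' @return data frame of correlation records: `anchor_id`, `partner_id`,
#'   `partner_class`, `window_bp`, `cancer_type`, `n_samples`, `rho`, `p_raw`,
#'   `p_adj`. Pairs with constant expression in a cancer type are skipped; the
#'   number skipped is reported via `attr(, "n_constant_skipped")`.
#' @export
screen_pairs <- function(pairs, cpm_list, min_cpm = 1, min_samples_expressed = 3L,
                         min_samples_test = 10L,
                         family = c("per_type", "global")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(pairs), length(cpm_list) >= 1L)
  empty <- data.frame(anchor_id = character(), partner_id = character(),
                      partner_class = character(), window_bp = integer(),
                      cancer_type = character(), n_samples = integer(),
                      rho = numeric(), p_raw = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)

  # correlations are window-independent: compute once per unique gene duo/type
  uniq <- unique(pairs[, c("anchor_id", "partner_id", "partner_class")])
  n_constant <- 0L
  rec <- list()
  for (ct in names(cpm_list)) {
    x <- cpm_list[[ct]]
    keep_genes <- filter_expressed(x, min_cpm, min_samples_expressed)
    v <- x$values
    if (ncol(v) < min_samples_test) next
    ok <- uniq$anchor_id %in% keep_genes & uniq$partner_id %in% keep_genes
    u <- uniq[ok, , drop = FALSE]
    if (nrow(u) == 0L) next
    # rank each needed gene once
    need <- unique(c(u$anchor_id, u$partner_id))
    rk <- t(apply(v[need, , drop = FALSE], 1L, rank))
    rho <- numeric(nrow(u)); p <- numeric(nrow(u)); good <- logical(nrow(u))
    for (i in seq_len(nrow(u))) {
      xa <- rk[u$anchor_id[i], ]; xp <- rk[u$partner_id[i], ]
      if (stats::sd(xa) == 0 || stats::sd(xp) == 0) { n_constant <- n_constant + 1L; next }
      r <- cor(xa, xp)
      rho[i] <- r
      if (abs(r) >= 1) {
        p[i] <- .Machine$double.xmin
      } else {
        tstat <- r * sqrt((ncol(v) - 2) / (1 - r^2))
        p[i] <- max(2 * pt(abs(tstat), df = ncol(v) - 2, lower.tail = FALSE),
                    .Machine$double.xmin)
      }
      good[i] <- TRUE
    }
    u <- u[good, , drop = FALSE]
    if (nrow(u) == 0L) next
    rec[[ct]] <- data.frame(u, cancer_type = ct,
                            n_samples = ncol(v), rho = rho[good],
                            p_raw = p[good], stringsAsFactors = FALSE)
  }
  if (!length(rec)) {
    message("screen_pairs: no testable (pair, cancer type) combinations")
    attr(empty, "n_constant_skipped") <- n_constant
    return(empty)
  }
  rec <- do.call(rbind, rec)
  # expand back to windows, then adjust within families
  out <- merge(pairs, rec, by = c("anchor_id", "partner_id", "partner_class"))
  fam <- if (family == "per_type")
    interaction(out$cancer_type, out$partner_class, out$window_bp, drop = TRUE)
  else
    interaction(out$partner_class, out$window_bp, drop = TRUE)
  out$p_adj <- NA_real_
  for (f in levels(fam)) {
    i <- which(fam == f)
    out$p_adj[i] <- bh_adjust(out$p_raw[i])
  }
  out <- out[, c("anchor_id", "partner_id", "partner_class", "window_bp",
                 "cancer_type", "n_samples", "rho", "p_raw", "p_adj")]
  out <- out[order(out$window_bp, out$cancer_type, out$anchor_id, out$partner_id), ]
  rownames(out) <- NULL
  attr(out, "n_constant_skipped") <- n_constant
  out
}

#' Aggregate correlation records across cancer types and assign set labels
#'
#' A pair is labeled `LCN` (lncRNA partner) or `CCN` (coding partner) when its
#' rho is negative in the majority of cancer types and significantly negative
#' (`p_adj < alpha`) in at least one; `LCP`/`CCP` symmetrically for positive
#' rho. Significant correlations of the opposite sign do not disqualify a
#' pair. The majority denominator is the number of testable cancer types
#' (default) or the full cohort size (`majority = "all"`).
#'
#' @param records output of [screen_pairs()].
#' @param pairs the pair table the records were computed from (pairs with no
#'   testable cancer type are carried through with label `"none"`).
#' @param alpha adjusted-p significance cutoff (default 1e-5).
#' @param majority `"testable"` (default) or `"all"`.
#' @param n_types_total cohort size; required when `majority = "all"`.
#' @return data frame with one row per (pair, window): `anchor_id`,
#'   `partner_id`, `partner_class`, `window_bp`, `n_testable`, `n_neg_rho`,
#'   `n_pos_rho`, `n_sig_neg`, `n_sig_pos`, `set_label`.
#' @export
label_pairs <- function(records, pairs, alpha = 1e-5,
                        majority = c("testable", "all"), n_types_total = NULL) {
  majority <- match.arg(majority)
  if (majority == "all" && is.null(n_types_total))
    stop("majority = 'all' needs n_types_total", call. = FALSE)
  key <- function(df) paste(df$anchor_id, df$partner_id, df$window_bp, sep = "\r")
  base <- unique(pairs[, c("anchor_id", "partner_id", "partner_class", "window_bp")])
  k <- key(base)
  n_testable <- n_neg <- n_pos <- n_sig_neg <- n_sig_pos <- integer(length(k))
  if (nrow(records)) {
    rk <- key(records)
    idx <- match(rk, k)
    add <- function(cond) as.integer(tapply(cond, factor(idx, levels = seq_along(k)),
                                            sum, default = 0L))
    n_testable <- add(rep(TRUE, nrow(records)))
    n_neg <- add(records$rho < 0)
    n_pos <- add(records$rho > 0)
    n_sig_neg <- add(records$rho < 0 & records$p_adj < alpha)
    n_sig_pos <- add(records$rho > 0 & records$p_adj < alpha)
  }
  denom <- if (majority == "testable") n_testable else rep(n_types_total, length(k))
  lab <- rep("none", length(k))
  is_l <- base$partner_class == "lncRNA"
  neg <- n_neg > denom / 2 & n_sig_neg >= 1L
  pos <- n_pos > denom / 2 & n_sig_pos >= 1L
  lab[neg & is_l] <- "LCN"; lab[pos & is_l] <- "LCP"
  lab[neg & !is_l] <- "CCN"; lab[pos & !is_l] <- "CCP"
  out <- data.frame(base, n_testable = n_testable, n_neg_rho = n_neg,
                    n_pos_rho = n_pos, n_sig_neg = n_sig_neg,
                    n_sig_pos = n_sig_pos, set_label = lab,
                    stringsAsFactors = FALSE)
  out <- out[order(out$window_bp, out$anchor_id, out$partner_id), ]
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups,
#'   columns = outcome: table `rbind(c(a, b), c(c, d))`.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  fisher.test(matrix(as.integer(counts), nrow = 2L, byrow = TRUE))$p.value
}

#' Enrichment of significant lncRNA/coding vs coding/coding pairs
#'
#' For each (cancer type, window) stratum, compares the fraction of
#' significantly correlated (either sign, `p_adj < alpha`) lncRNA/coding pairs
#' with the coding/coding control fraction by Fisher's exact test. A stratum
#' is flagged enriched when `p < enrich_p` and the lncRNA fraction exceeds the
#' control fraction.
#'
#' @param records output of [screen_pairs()] containing both partner classes.
#' @param alpha adjusted-p significance cutoff (default 1e-5).
#' @param enrich_p Fisher p cutoff for the enriched flag (default 0.01).
#' @return data frame with one row per (cancer type, window): counts,
#'   fractions (`NA` when a class has no pairs), `fisher_p`, `enriched`.
#' @export
pair_class_enrichment <- function(records, alpha = 1e-5, enrich_p = 0.01) {
  strata <- unique(records[, c("cancer_type", "window_bp")])
  strata <- strata[order(strata$window_bp, strata$cancer_type), , drop = FALSE]
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    r <- records[records$cancer_type == strata$cancer_type[i] &
                   records$window_bp == strata$window_bp[i], ]
    lc <- r[r$partner_class == "lncRNA", ]; cc <- r[r$partner_class == "coding", ]
    lc_sig <- sum(lc$p_adj < alpha); cc_sig <- sum(cc$p_adj < alpha)
    lc_frac <- if (nrow(lc)) lc_sig / nrow(lc) else NA_real_
    cc_frac <- if (nrow(cc)) cc_sig / nrow(cc) else NA_real_
    p <- if (nrow(lc) && nrow(cc))
      fisher_exact_2x2(lc_sig, nrow(lc) - lc_sig, cc_sig, nrow(cc) - cc_sig)
    else NA_real_
    data.frame(cancer_type = strata$cancer_type[i],
               window_bp = strata$window_bp[i],
               lc_n = nrow(lc), lc_sig = lc_sig, lc_frac = lc_frac,
               cc_n = nrow(cc), cc_sig = cc_sig, cc_frac = cc_frac,
               fisher_p = p,
               enriched = isTRUE(p < enrich_p && lc_frac > cc_frac),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
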