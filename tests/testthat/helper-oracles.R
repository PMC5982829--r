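# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (IRanges, stats::cor/rank, p.adjust, fisher.test) so
# that each comparison is a genuine dual-route check.

# distinct bases covered by a set of half-open intervals
oracle_bases <- function(m) {
  if (NROW(m) == 0L) return(integer())
  sort(unique(unlist(lapply(seq_len(nrow(m)), function(i)
    seq.int(m[i, 1L], m[i, 2L] - 1L)))))
}

# base-set subtraction
oracle_subtract_bases <- function(a, b) setdiff(oracle_bases(a), oracle_bases(b))

# O(n^2) all-vs-all window pairing: gap < w (overlap counts as gap 0)
oracle_window_pairs <- function(anchors, partners, w, cc = FALSE) {
  out <- list()
  for (i in seq_len(nrow(anchors))) for (j in seq_len(nrow(partners))) {
    if (anchors$gene_id[i] == partners$gene_id[j]) next
    if (cc && anchors$gene_id[i] >= partners$gene_id[j]) next
    if (anchors$chrom[i] != partners$chrom[j]) next
    gap <- max(0L, max(partners$start[j] - anchors$end[i],
                       anchors$start[i] - partners$end[j]))
    if (gap < w)
      out[[length(out) + 1L]] <- data.frame(
        anchor_id = anchors$gene_id[i], partner_id = partners$gene_id[j],
        distance_bp = gap, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(anchor_id = character(), partner_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$anchor_id, df$partner_id), , drop = FALSE]
}

# midranks without rank(): position-count definition
oracle_midrank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1L))
}

# Pearson correlation from the textbook formula
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_midrank(x), oracle_midrank(y))

# BH step-up written as a direct loop over the sorted p-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# two-sided Fisher p by exhaustive enumeration of tables with fixed margins,
# probabilities from choose() directly
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  ptab <- function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- vapply(xs, ptab, numeric(1L))
  p_obs <- ptab(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# per-base conservation average (uncovered bases score 0)
oracle_conservation <- function(support, track_df, chrom) {
  bases <- oracle_bases(support)
  if (!length(bases)) return(NA_real_)
  tr <- track_df[track_df$chrom == chrom, , drop = FALSE]
  score <- numeric(length(bases))
  for (k in seq_len(nrow(tr))) {
    hit <- bases >= tr$start[k] & bases < tr$end[k]
    score[hit] <- tr$score[k]
  }
  mean(score)
}

# pooled-variance two-sample t from the textbook formula
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, p = 2 * pt(abs(tt), df = na + nb - 2, lower.tail = FALSE))
}
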