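# Proximity pairing: orientation classes, APA filter, window pairs, shuffle null.

ORIENTATIONS <- c("antisense_overlap", "sense_overlap", "divergent",
                  "convergent", "sense_upstream", "sense_downstream")

#' Classify the orientation of a partner gene relative to a coding anchor
#'
#' Vectorized over its arguments. Overlapping spans are `antisense_overlap`
#' (opposite strand) or `sense_overlap` (same strand). Non-overlapping,
#' opposite-strand partners are `divergent` when they lie on the anchor's 5'
#' side (head-to-head promoters) and `convergent` on the 3' side
#' (tail-to-tail). Non-overlapping same-strand partners are `sense_upstream`
#' of the anchor's 5' end, otherwise `sense_downstream`.
#'
#' @param a_start,a_end,a_strand anchor span (0-based half-open) and strand.
#' @param p_start,p_end,p_strand partner span and strand.
#' @return character vector of orientation labels.
#' @export
classify_orientation <- function(a_start, a_end, a_strand, p_start, p_end,
                                 p_strand) {
  n <- length(a_start)
  overlap <- p_start < a_end & p_end > a_start
  same <- a_strand == p_strand
  # partner entirely left of anchor, in genome coordinates
  left <- p_end <= a_start
  # is "left of anchor" the anchor's 5' side?
  five_is_left <- a_strand == "+"
  on_5prime <- (left & five_is_left) | (!left & !five_is_left)
  out <- character(n)
  out[overlap & !same] <- "antisense_overlap"
  out[overlap & same] <- "sense_overlap"
  out[!overlap & !same & on_5prime] <- "divergent"
  out[!overlap & !same & !on_5prime] <- "convergent"
  out[!overlap & same & on_5prime] <- "sense_upstream"
  out[!overlap & same & !on_5prime] <- "sense_downstream"
  out
}

#' Flag lncRNAs that may be alternative-polyadenylation artifacts
#'
#' A lncRNA transcribed in sense (same strand) that overlaps a coding gene or
#' lies within `apa_gap` bases of its boundary is flagged as a potential 3'
#' extension of that gene rather than an independent transcript, and should be
#' excluded from pairing. With `side = "downstream"` only lncRNAs on the coding
#' gene's 3' side qualify.
#'
#' @param ann a [gene_annotation] containing both biotypes.
#' @param apa_gap maximum boundary gap in bases (default 5000).
#' @param side `"both"` (default) or `"downstream"`.
#' @return data frame with columns `lnc_id`, `coding_id`, `gap_bp` (one row per
#'   flagged lncRNA; the nearest qualifying coding gene is reported).
#' @export
flag_apa_candidates <- function(ann, apa_gap = 5000L, side = c("both", "downstream")) {
  side <- match.arg(side)
  g <- ann$genes
  lnc <- g[g$biotype == "lncRNA", , drop = FALSE]
  cod <- g[g$biotype == "coding", , drop = FALSE]
  if (nrow(lnc) == 0L || nrow(cod) == 0L)
    return(data.frame(lnc_id = character(), coding_id = character(),
                      gap_bp = integer(), stringsAsFactors = FALSE))
  gr_l <- GenomicRanges::GRanges(lnc$chrom,
                                 IRanges::IRanges(lnc$start + 1L, lnc$end))
  gr_c <- GenomicRanges::GRanges(cod$chrom,
                                 IRanges::IRanges(cod$start + 1L, cod$end))
  hits <- GenomicRanges::findOverlaps(gr_l, gr_c, maxgap = as.integer(apa_gap),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  keep <- lnc$strand[qi] == cod$strand[si]
  if (side == "downstream") {
    # lncRNA must sit (at least partly) past the coding gene's 3' end
    past3 <- ifelse(cod$strand[si] == "+",
                    lnc$end[qi] > cod$end[si],
                    lnc$start[qi] < cod$start[si])
    keep <- keep & past3
  }
  qi <- qi[keep]; si <- si[keep]
  if (!length(qi))
    return(data.frame(lnc_id = character(), coding_id = character(),
                      gap_bp = integer(), stringsAsFactors = FALSE))
  gap <- pmax(0L, pmax(cod$start[si] - lnc$end[qi], lnc$start[qi] - cod$end[si]))
  df <- data.frame(lnc_id = lnc$gene_id[qi], coding_id = cod$gene_id[si],
                   gap_bp = as.integer(gap), stringsAsFactors = FALSE)
  df <- df[df$gap_bp <= apa_gap, , drop = FALSE]
  # one row per lncRNA: nearest qualifying coding gene, ties by coding_id
  df <- df[order(df$lnc_id, df$gap_bp, df$coding_id), , drop = FALSE]
  df <- df[!duplicated(df$lnc_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build proximal gene pairs at a distance window
#'
#' Emits a pair for every partner whose span intersects the anchor span
#' extended by `window_bp` on both sides (half-open), i.e. whose boundary gap
#' is `< window_bp`; overlapping spans pair at distance 0. Anchors must be
#' coding genes. When `partner_class = "coding"` each unordered pair is kept
#' once with the lexicographically smaller `gene_id` as anchor.
#'
#' @param anchors data frame of coding genes (columns as in
#'   `gene_annotation$genes`).
#' @param partners data frame of partner genes; for lncRNA partners, apply
#'   [flag_apa_candidates()] filtering beforehand.
#' @param window_bp positive window size in bases.
#' @param partner_class `"lncRNA"` or `"coding"`.
#' @return data frame with columns `anchor_id`, `partner_id`, `partner_class`,
#'   `orientation`, `distance_bp`, `window_bp`.
#' @export
build_window_pairs <- function(anchors, partners, window_bp,
                               partner_class = c("lncRNA", "coding")) {
  partner_class <- match.arg(partner_class)
  if (!is.numeric(window_bp) || length(window_bp) != 1L || window_bp <= 0)
    stop("`window_bp` must be a positive number of bases", call. = FALSE)
  window_bp <- as.integer(window_bp)
  if (any(anchors$biotype != "coding"))
    stop("anchors must be coding genes", call. = FALSE)
  empty <- data.frame(anchor_id = character(), partner_id = character(),
                      partner_class = character(), orientation = character(),
                      distance_bp = integer(), window_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(anchors) == 0L || nrow(partners) == 0L) return(empty)
  gr_a <- GenomicRanges::GRanges(anchors$chrom,
                                 IRanges::IRanges(anchors$start + 1L, anchors$end))
  gr_p <- GenomicRanges::GRanges(partners$chrom,
                                 IRanges::IRanges(partners$start + 1L, partners$end))
  hits <- GenomicRanges::findOverlaps(gr_a, gr_p, maxgap = window_bp - 1L,
                                      ignore.strand = TRUE)
  ai <- S4Vectors::queryHits(hits); pi <- S4Vectors::subjectHits(hits)
  keep <- anchors$gene_id[ai] != partners$gene_id[pi]
  if (partner_class == "coding")
    keep <- keep & anchors$gene_id[ai] < partners$gene_id[pi]
  ai <- ai[keep]; pi <- pi[keep]
  if (!length(ai)) return(empty)
  dist <- GenomicRanges::distance(gr_a[ai], gr_p[pi], ignore.strand = TRUE)
  out <- data.frame(
    anchor_id = anchors$gene_id[ai],
    partner_id = partners$gene_id[pi],
    partner_class = partner_class,
    orientation = classify_orientation(anchors$start[ai], anchors$end[ai],
                                       anchors$strand[ai], partners$start[pi],
                                       partners$end[pi], partners$strand[pi]),
    distance_bp = as.integer(dist),
    window_bp = window_bp,
    stringsAsFactors = FALSE)
  out <- out[order(out$anchor_id, out$partner_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build lncRNA/coding and coding/coding pairs at several windows
#'
#' Convenience driver: APA-filters the lncRNAs, then calls
#' [build_window_pairs()] for every window with lncRNA partners and (as the
#' control set) coding partners.
#'
#' @param ann a [gene_annotation].
#' @param windows integer vector of window sizes (bases), e.g.
#'   `c(25000, 50000, 100000)`.
#' @param apa_gap passed to [flag_apa_candidates()]; use `NULL` to skip the
#'   filter.
#' @param apa_side passed to [flag_apa_candidates()].
#' @return list with elements `pairs` (row-bound pair table across windows and
#'   both partner classes) and `apa_flags` (the flagged lncRNAs).
#' @export
build_all_pairs <- function(ann, windows = c(25000L, 50000L, 100000L),
                            apa_gap = 5000L, apa_side = "both") {
  g <- ann$genes
  cod <- g[g$biotype == "coding", , drop = FALSE]
  lnc <- g[g$biotype == "lncRNA", , drop = FALSE]
  if (!is.null(apa_gap)) {
    flags <- flag_apa_candidates(ann, apa_gap = apa_gap, side = apa_side)
    lnc <- lnc[!lnc$gene_id %in% flags$lnc_id, , drop = FALSE]
  } else {
    flags <- data.frame(lnc_id = character(), coding_id = character(),
                        gap_bp = integer(), stringsAsFactors = FALSE)
  }
  pieces <- lapply(sort(as.integer(windows)), function(w) {
    rbind(build_window_pairs(cod, lnc, w, "lncRNA"),
          build_window_pairs(cod, cod, w, "coding"))
  })
  list(pairs = do.call(rbind, pieces), apa_flags = flags)
}

#' Shuffle gene placements within their chromosomes
#'
#' Draws, for each gene, a new start uniformly from `[0, chrom_len - len]`
#' keeping id, chromosome, strand and length (the `shuffleBed -chrom` null).
#' Exons are shifted rigidly with the gene. Overlaps among shuffled genes are
#' permitted by default; `allow_overlap = FALSE` rejection-samples placements
#' that overlap an already placed gene on the same chromosome.
#'
#' @param ann a [gene_annotation] with `chrom_sizes` set.
#' @param seed integer seed; the shuffle is deterministic given it.
#' @param allow_overlap permit overlapping shuffled placements (default TRUE).
#' @param max_tries rejection-sampling cap per gene when
#'   `allow_overlap = FALSE`.
#' @return a [gene_annotation] with shuffled coordinates.
#' @export
shuffle_genes <- function(ann, seed, allow_overlap = TRUE, max_tries = 1000L) {
  sizes <- ann$chrom_sizes
  if (is.null(sizes)) stop("shuffle requires chrom_sizes", call. = FALSE)
  g <- ann$genes
  len <- g$end - g$start
  if (any(len > sizes[g$chrom]))
    stop("gene longer than its chromosome: ",
         g$gene_id[which(len > sizes[g$chrom])[1L]], call. = FALSE)
  new_start <- with_seed(seed, {
    if (allow_overlap) {
      as.integer(floor(runif(nrow(g)) * (sizes[g$chrom] - len + 1L)))
    } else {
      placed <- lapply(names(sizes), function(ch) NULL)
      names(placed) <- names(sizes)
      st <- integer(nrow(g))
      for (i in seq_len(nrow(g))) {
        ch <- g$chrom[i]
        for (try in seq_len(max_tries)) {
          s <- as.integer(floor(runif(1L) * (sizes[ch] - len[i] + 1L)))
          occ <- placed[[ch]]
          if (is.null(occ) ||
              !any(s < occ[, 2L] & s + len[i] > occ[, 1L])) break
          if (try == max_tries)
            stop("could not place gene without overlap: ", g$gene_id[i],
                 call. = FALSE)
        }
        placed[[ch]] <- rbind(placed[[ch]], c(s, s + len[i]))
        st[i] <- s
      }
      st
    }
  })
  shift <- new_start - g$start
  g$start <- new_start
  g$end <- new_start + len
  e <- ann$exons
  e_shift <- shift[match(e$gene_id, ann$genes$gene_id)]
  e$start <- e$start + e_shift
  e$end <- e$end + e_shift
  gene_annotation(g, e, sizes)
}

#' Fraction of lncRNAs with a coding gene within given windows
#'
#' After optional APA filtering, computes for each window the fraction of
#' lncRNAs whose span lies within `window` bases of (or overlaps) at least one
#' coding gene. Used both to describe an annotation's pairing coverage and,
#' on a shuffled annotation, as the randomized baseline.
#'
#' @param ann a [gene_annotation].
#' @param windows integer vector of window sizes (bases).
#' @param apa_gap passed to [flag_apa_candidates()]; `NULL` to skip.
#' @return named numeric vector of fractions, one per window.
#' @export
proximity_coverage <- function(ann, windows = c(25000L, 50000L, 100000L),
                               apa_gap = 5000L) {
  g <- ann$genes
  cod <- g[g$biotype == "coding", , drop = FALSE]
  lnc <- g[g$biotype == "lncRNA", , drop = FALSE]
  if (!is.null(apa_gap)) {
    flags <- flag_apa_candidates(ann, apa_gap = apa_gap)
    lnc <- lnc[!lnc$gene_id %in% flags$lnc_id, , drop = FALSE]
  }
  out <- vapply(sort(as.integer(windows)), function(w) {
    p <- build_window_pairs(cod, lnc, w, "lncRNA")
    length(unique(p$partner_id)) / nrow(lnc)
  }, numeric(1L))
  names(out) <- as.character(sort(as.integer(windows)))
  out
}
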