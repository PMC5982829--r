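# Gene-model container and annotation I/O.
#
# A `gene_annotation` is a list with:
#   genes       data.frame(gene_id, chrom, start, end, strand, biotype)
#   exons       data.frame(gene_id, start, end)   (pooled across transcripts,
#               possibly overlapping; merge with merge_exons())
#   chrom_sizes named integer vector, or NULL
# Coordinates are 0-based half-open throughout; GTF (1-based inclusive) is
# converted on read and on write.

#' Construct a gene annotation object
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `biotype` (`"coding"`/`"lncRNA"`); coordinates
#'   0-based half-open.
#' @param exons data frame with columns `gene_id`, `start`, `end`; every
#'   `gene_id` must appear in `genes`. Exons extending beyond the gene span are
#'   clipped with a warning (the gene line is authoritative).
#' @param chrom_sizes named integer vector of chromosome lengths, or `NULL`.
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons, chrom_sizes = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(genes)))
    stop("`genes` must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  genes <- as.data.frame(genes)[, need]
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in `genes`", call. = FALSE)
  if (any(genes$start < 0L) || any(genes$start >= genes$end))
    stop("gene coordinates must satisfy 0 <= start < end", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (!all(genes$biotype %in% c("coding", "lncRNA")))
    stop("biotype must be 'coding' or 'lncRNA'", call. = FALSE)

  exons <- as.data.frame(exons)[, c("gene_id", "start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (!all(exons$gene_id %in% genes$gene_id))
    stop("exon refers to unknown gene_id: ",
         paste(head(setdiff(exons$gene_id, genes$gene_id), 3L), collapse = ", "),
         call. = FALSE)
  if (!all(genes$gene_id %in% exons$gene_id))
    stop("every gene needs at least one exon; missing for: ",
         paste(head(setdiff(genes$gene_id, exons$gene_id), 3L), collapse = ", "),
         call. = FALSE)
  if (any(exons$start >= exons$end)) stop("exon start must be < end", call. = FALSE)

  gs <- genes$start[match(exons$gene_id, genes$gene_id)]
  ge <- genes$end[match(exons$gene_id, genes$gene_id)]
  if (any(exons$start < gs | exons$end > ge)) {
    warning("exon(s) extend beyond the gene span; clipped to the gene line",
            call. = FALSE)
    exons$start <- pmax(exons$start, gs)
    exons$end <- pmin(exons$end, ge)
    exons <- exons[exons$start < exons$end, , drop = FALSE]
  }

  if (!is.null(chrom_sizes)) {
    chrom_sizes <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
    if (any(chrom_sizes <= 0L)) stop("chromosome lengths must be > 0", call. = FALSE)
    miss <- setdiff(unique(genes$chrom), names(chrom_sizes))
    if (length(miss))
      stop("chromosome(s) absent from chrom_sizes: ",
           paste(miss, collapse = ", "), call. = FALSE)
    too_long <- genes$end > chrom_sizes[genes$chrom]
    if (any(too_long))
      stop("gene(s) extend beyond chromosome end: ",
           paste(head(genes$gene_id[too_long], 3L), collapse = ", "), call. = FALSE)
  }

  rownames(genes) <- NULL; rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons, chrom_sizes = chrom_sizes),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  tab <- table(x$genes$biotype)
  cat("<gene_annotation> ", nrow(x$genes), " genes (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      "), ", nrow(x$exons), " exon records on ",
      length(unique(x$genes$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Default GENCODE biotype mapping
#'
#' Maps GENCODE v19 `gene_type` strings to the two biotypes used by the screen.
#' `protein_coding` maps to `coding`; the classical long-non-coding classes map
#' to `lncRNA`; everything else is ignored. Supply your own named vector to
#' [read_gtf()] to change the policy.
#'
#' @return named character vector with values in `c("coding", "lncRNA")`.
#' @export
default_biotype_map <- function() {
  c(protein_coding = "coding",
    lincRNA = "lncRNA", antisense = "lncRNA", processed_transcript = "lncRNA",
    sense_intronic = "lncRNA", sense_overlapping = "lncRNA",
    `3prime_overlapping_ncrna` = "lncRNA")
}

#' Read a GENCODE-dialect GTF into a gene annotation
#'
#' Parses `gene` and `exon` features, converts 1-based inclusive GTF
#' coordinates to 0-based half-open, pools exons across transcripts per gene,
#' and assigns biotypes through `biotype_map` (genes whose annotated type is
#' absent from the map are dropped).
#'
#' @param path GTF file path.
#' @param biotype_map named character vector mapping annotation `gene_type` /
#'   `gene_biotype` strings to `"coding"` or `"lncRNA"`; unmapped types are
#'   ignored.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return a [gene_annotation] object.
#' @export
read_gtf <- function(path, biotype_map = default_biotype_map(),
                     chrom_sizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty GTF: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF line ", lineno[which(nf != 9L)[1L]],
         ": expected 9 tab-separated fields, got ", nf[which(nf != 9L)[1L]],
         call. = FALSE)
  feat <- vapply(fields, `[[`, "", 3L)
  sel <- feat %in% c("gene", "exon")
  fields <- fields[sel]; feat <- feat[sel]; lineno <- lineno[sel]
  if (!length(fields)) stop("no gene/exon features in GTF: ", path, call. = FALSE)

  chrom <- vapply(fields, `[[`, "", 1L)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  strand <- vapply(fields, `[[`, "", 7L)
  attrs <- vapply(fields, `[[`, "", 9L)
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1L | end1 < start1 |
                 !strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed GTF line ", lineno[bad[1L]],
         ": bad coordinates or strand", call. = FALSE)

  gid <- sub('.*gene_id "([^"]+)".*', "\\1", attrs)
  no_gid <- !grepl('gene_id "', attrs, fixed = TRUE)
  if (any(no_gid))
    stop("malformed GTF line ", lineno[which(no_gid)[1L]],
         ": missing gene_id attribute", call. = FALSE)
  gtype <- rep(NA_character_, length(attrs))
  has_t <- grepl('gene_type "', attrs, fixed = TRUE)
  gtype[has_t] <- sub('.*gene_type "([^"]+)".*', "\\1", attrs[has_t])
  has_b <- !has_t & grepl('gene_biotype "', attrs, fixed = TRUE)
  gtype[has_b] <- sub('.*gene_biotype "([^"]+)".*', "\\1", attrs[has_b])

  is_gene <- feat == "gene"
  g <- data.frame(gene_id = gid[is_gene], chrom = chrom[is_gene],
                  start = start1[is_gene] - 1L, end = end1[is_gene],
                  strand = strand[is_gene], biotype_src = gtype[is_gene],
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$gene_id))
    stop("duplicated gene feature for gene_id: ",
         g$gene_id[duplicated(g$gene_id)][1L], call. = FALSE)
  e <- data.frame(gene_id = gid[!is_gene], start = start1[!is_gene] - 1L,
                  end = end1[!is_gene], stringsAsFactors = FALSE)
  orphan <- setdiff(e$gene_id, g$gene_id)
  if (length(orphan))
    stop("exon without a parent gene feature: ",
         paste(head(orphan, 3L), collapse = ", "), call. = FALSE)

  if (any(is.na(g$biotype_src)))
    stop("gene feature without gene_type/gene_biotype attribute: ",
         g$gene_id[is.na(g$biotype_src)][1L], call. = FALSE)
  g$biotype <- unname(biotype_map[g$biotype_src])
  g <- g[!is.na(g$biotype) & g$biotype != "ignore", , drop = FALSE]
  e <- e[e$gene_id %in% g$gene_id, , drop = FALSE]
  g$biotype_src <- NULL
  gene_annotation(g, e, chrom_sizes)
}

#' Write a gene annotation as a GENCODE-dialect GTF
#'
#' Inverse of [read_gtf()] up to exon pooling: emits one `gene` line per gene
#' and one `exon` line per stored exon interval, converting back to 1-based
#' inclusive coordinates.
#'
#' @param ann a [gene_annotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  src <- c(coding = "protein_coding", lncRNA = "lincRNA")
  g <- ann$genes
  gl <- sprintf('%s\tcispair\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_type "%s";',
                g$chrom, g$start + 1L, g$end, g$strand, g$gene_id,
                src[g$biotype])
  e <- ann$exons
  ec <- g$chrom[match(e$gene_id, g$gene_id)]
  es <- g$strand[match(e$gene_id, g$gene_id)]
  eb <- src[g$biotype[match(e$gene_id, g$gene_id)]]
  el <- sprintf('%s\tcispair\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_type "%s";',
                ec, e$start + 1L, e$end, es, e$gene_id, eb)
  ord <- order(g$chrom, g$start, g$gene_id)
  out <- unlist(lapply(ord, function(i) {
    c(gl[i], el[e$gene_id == g$gene_id[i]])
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Merge a gene's exons into disjoint intervals
#'
#' Union of the exonic bases of one gene, the support over which conservation
#' is averaged.
#'
#' @param ann a [gene_annotation].
#' @param gene_id single gene identifier.
#' @return integer interval matrix (see [merge_intervals()]).
#' @export
merge_exons <- function(ann, gene_id) {
  ex <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("gene has no exons: ", gene_id, call. = FALSE)
  merge_intervals(ex[, c("start", "end")])
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path TSV with columns (chromosome name, length), no header.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  sizes <- setNames(as.integer(df[[2L]]), df[[1L]])
  if (any(sizes <= 0L)) stop("chromosome lengths must be > 0", call. = FALSE)
  sizes
}

write_chrom_sizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), as.integer(sizes)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene spans as BED6
#'
#' @param ann a [gene_annotation].
#' @param path output path. Name field is `gene_id|biotype`.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(ann, path) {
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start), ]
  writeLines(sprintf("%s\t%d\t%d\t%s|%s\t0\t%s", g$chrom, g$start, g$end,
                     g$gene_id, g$biotype, g$strand), path)
  invisible(path)
}

#' Write gene models as BED12
#'
#' Exon chains are merged ([merge_exons()]) before writing, since BED12 blocks
#' must be disjoint. The name field encodes `gene_id|biotype` so that
#' [read_bed12()] round-trips the annotation.
#'
#' @param ann a [gene_annotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(ann, path) {
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start), ]
  lines <- vapply(seq_len(nrow(g)), function(i) {
    m <- merge_exons(ann, g$gene_id[i])
    sprintf("%s\t%d\t%d\t%s|%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            g$chrom[i], g$start[i], g$end[i], g$gene_id[i], g$biotype[i],
            g$strand[i], g$start[i], g$end[i], nrow(m),
            paste0(m[, 2L] - m[, 1L], ",", collapse = ""),
            paste0(m[, 1L] - g$start[i], ",", collapse = ""))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED12 file written by [write_bed12()]
#'
#' @param path BED12 path; names must be `gene_id|biotype`.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return a [gene_annotation] with merged exon chains.
#' @export
read_bed12 <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- strsplit(as.character(gr$name), "|", fixed = TRUE)
  if (any(lengths(nm) != 2L))
    stop("BED12 name field must be 'gene_id|biotype'", call. = FALSE)
  genes <- data.frame(
    gene_id = vapply(nm, `[[`, "", 1L),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    biotype = vapply(nm, `[[`, "", 2L),
    stringsAsFactors = FALSE)
  blocks <- gr$blocks
  exons <- do.call(rbind, lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    data.frame(gene_id = genes$gene_id[i],
               start = genes$start[i] + BiocGenerics::start(b) - 1L,
               end = genes$start[i] + BiocGenerics::end(b),
               stringsAsFactors = FALSE)
  }))
  gene_annotation(genes, exons, chrom_sizes)
}

# Transcription start site of a gene (0-based position of the first
# transcribed base): span start on '+', span end - 1 on '-'.
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}
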