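# Small in-code fixtures shared across test files.

# minimal two-gene annotation on one chromosome
tiny_annotation <- function() {
  genes <- data.frame(
    gene_id = c("CODA", "LNCA"),
    chrom = "chr1",
    start = c(1000L, 2500L), end = c(2000L, 3000L),
    strand = c("+", "-"),
    biotype = c("coding", "lncRNA"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("CODA", "CODA", "LNCA"),
    start = c(1000L, 1600L, 2500L), end = c(1400L, 2000L, 3000L),
    stringsAsFactors = FALSE)
  gene_annotation(genes, exons, c(chr1 = 100000L))
}

# random annotation for property tests: n genes on a few chromosomes
random_annotation <- function(n, seed, chrom_len = 500000L, n_chrom = 2L) {
  set.seed(seed)
  chrom <- sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE)
  len <- sample(500:5000, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(chrom_len - l, 1L), 1L)
  genes <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n)), chrom = chrom,
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = sample(c("coding", "lncRNA"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                      end = genes$end, stringsAsFactors = FALSE)
  sizes <- setNames(rep(chrom_len, n_chrom), sprintf("chr%d", seq_len(n_chrom)))
  gene_annotation(genes, exons, sizes)
}

# write a small GENCODE-dialect GTF (1-based inclusive)
write_tiny_gtf <- function(path) {
  lines <- c(
    "#!genome-build test",
    paste0("chr1\ttest\tgene\t101\t200\t.\t+\t.\t",
           'gene_id "G1"; gene_type "protein_coding";'),
    paste0("chr1\ttest\texon\t101\t150\t.\t+\t.\t",
           'gene_id "G1"; gene_type "protein_coding";'),
    paste0("chr1\ttest\texon\t141\t200\t.\t+\t.\t",
           'gene_id "G1"; gene_type "protein_coding";'),
    # second transcript re-uses the first exon
    paste0("chr1\ttest\texon\t101\t150\t.\t+\t.\t",
           'gene_id "G1"; gene_type "protein_coding";'),
    paste0("chr1\ttest\tgene\t501\t800\t.\t-\t.\t",
           'gene_id "G2"; gene_type "antisense";'),
    paste0("chr1\ttest\texon\t501\t800\t.\t-\t.\t",
           'gene_id "G2"; gene_type "antisense";'),
    paste0("chr1\ttest\tgene\t901\t950\t.\t+\t.\t",
           'gene_id "G3"; gene_type "miRNA";'),
    paste0("chr1\ttest\texon\t901\t950\t.\t+\t.\t",
           'gene_id "G3"; gene_type "miRNA";'))
  writeLines(lines, path)
  path
}

# expression matrix from a plain matrix with auto ids
make_expr <- function(m, cancer_type = "CT01", unit = "raw_counts") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%d", seq_len(ncol(m)))
  expr_matrix(m, cancer_type, unit)
}

# small simulated cohort shared by the heavier tests (generated once per run)
small_sim_config <- function(seed = 7L, ...) {
  args <- list(seed = seed, n_coding = 60L, n_lnc = 60L, n_repressor = 12L,
               n_shared = 10L, n_apa = 6L, n_distal = 3L, n_single_cancer = 8L,
               n_lnc_high_cons = 6L, n_types = 2L, samples_per_type = 120L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}
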