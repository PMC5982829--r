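# Tau, conservation, categories, methylation coupling, localization, t-test.

test_that("tau anchors and direct arithmetic", {
  expect_equal(tau(c(5, 5, 5, 5)), 0)
  expect_equal(tau(c(0, 7, 0)), 1)
  expect_equal(tau(c(1, 2, 4), log_transform = FALSE), 0.625)
  expect_equal(tau(c(5, 5), log_transform = FALSE), 0)
  expect_error(tau(c(0, 0, 0)), "all-zero")
  expect_error(tau(5), "2 groups")
  expect_error(tau(c(-1, 2)), "negative")
})

test_that("tau is scale-invariant and increases under concentration", {
  set.seed(17)
  for (rep in 1:20) {
    x <- rexp(sample(3:8, 1L))
    expect_equal(tau(x, FALSE), tau(runif(1, 0.1, 10) * x, FALSE))
  }
  # moving mass from a low entry onto the max (same max after renorm) never
  # lowers tau: compare profile against a majorizing one
  x <- c(4, 3, 2, 1)
  y <- c(4, 3.5, 1.5, 1)   # same max, more concentrated
  expect_gte(tau(y, FALSE), tau(x, FALSE) - 1e-12)
})

test_that("tau_table scores all genes and leaves all-zero profiles NA", {
  prof <- rbind(flat = c(3, 3, 3), single = c(0, 9, 0), zero = c(0, 0, 0))
  tt <- tau_table(prof, log_transform = FALSE)
  expect_equal(tt$tau[tt$gene_id == "flat"], 0)
  expect_equal(tt$tau[tt$gene_id == "single"], 1)
  expect_true(is.na(tt$tau[tt$gene_id == "zero"]))
})

cons_fixture <- function() {
  genes <- data.frame(
    gene_id = c("COD", "LNC", "LNCIN"), chrom = "chr1",
    start = c(100L, 400L, 150L), end = c(300L, 600L, 250L),
    strand = c("+", "-", "-"),
    biotype = c("coding", "lncRNA", "lncRNA"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("COD", "COD", "LNC", "LNC", "LNCIN"),
    start = c(100L, 200L, 400L, 500L, 150L),
    end = c(180L, 300L, 480L, 580L, 250L))
  gene_annotation(genes, exons)
}

test_that("exonic conservation averages the track over merged exons", {
  ann <- cons_fixture()
  # constant track over everything
  tr <- data.frame(chrom = "chr1", start = 0L, end = 1000L, score = 0.8)
  expect_equal(exonic_conservation(ann, tr, "COD")$mean_score, 0.8)
  # two equal-length exons over 0.2 and 0.6 average to 0.4
  tr2 <- data.frame(chrom = "chr1", start = c(0L, 450L), end = c(450L, 1000L),
                    score = c(0.2, 0.6))
  got <- exonic_conservation(ann, tr2, "LNC")
  expect_equal(got$n_bases, 160L)
  expect_equal(got$mean_score, (50 * 0.2 + 30 * 0.6 + 80 * 0.6) / 160,
               tolerance = 1e-12)
  expect_equal(got$mean_score,
               oracle_conservation(merge_exons(ann, "LNC"), tr2, "chr1"))
})

test_that("coding-exon mask removes shared bases; full overlap empties support", {
  ann <- cons_fixture()
  tr <- data.frame(chrom = "chr1", start = 0L, end = 1000L, score = 0.8)
  ct <- conservation_table(ann, tr)
  # LNCIN [150,250) sits inside COD exons [100,180)+[200,300): only the
  # intronic slice [180,200) survives masking
  lncin <- ct[ct$gene_id == "LNCIN", ]
  expect_equal(lncin$n_bases, 20L)
  # a lncRNA fully inside coding exons would have empty support
  sub <- subtract_intervals(rbind(c(150L, 180L)), merge_exons(ann, "COD"))
  expect_equal(nrow(sub), 0L)
  r <- exonic_conservation(ann, tr, "LNCIN", mask = rbind(c(0L, 1000L)))
  expect_equal(r$n_bases, 0L)
  expect_true(is.na(r$mean_score))
})

test_that("exonic conservation equals the per-base loop on random layouts", {
  set.seed(23)
  ann <- random_annotation(20, seed = 23, chrom_len = 10000L, n_chrom = 1L)
  breaks <- sort(sample(0:9999, 30L))
  tr <- data.frame(chrom = "chr1", start = c(0L, breaks),
                   end = c(breaks, 10000L),
                   score = round(runif(31), 3))
  tr <- tr[tr$start < tr$end, ]
  for (g in ann$genes$gene_id[1:10]) {
    got <- exonic_conservation(ann, tr, g)
    expect_equal(got$mean_score,
                 oracle_conservation(merge_exons(ann, g), tr, "chr1"),
                 tolerance = 1e-12)
  }
})

test_that("category enrichment saturates, detects planted excess, handles empties", {
  summ <- data.frame(
    anchor_id = sprintf("C%03d", 1:120),
    partner_id = sprintf("L%03d", 1:120),
    partner_class = "lncRNA", window_bp = 100000L,
    n_testable = 4L, n_neg_rho = 3L, n_pos_rho = 1L, n_sig_neg = 1L,
    n_sig_pos = 0L,
    set_label = rep(c("LCN", "LCP", "CCN", "CCP"), each = 30L),
    stringsAsFactors = FALSE)
  all_cat <- category_enrichment(summ, summ$anchor_id)
  expect_true(all(all_cat$fraction == 1))
  expect_true(all(all_cat$fisher_p == 1))
  empty_cat <- category_enrichment(summ, character())
  expect_true(all(empty_cat$fraction == 0))
  # planted 10x enrichment in LCN
  cat10 <- c(sprintf("C%03d", 1:20), sprintf("C%03d", seq(31, 120, by = 15)))
  enr <- category_enrichment(summ, cat10)
  lcn <- enr[enr$set_label == "LCN", ]
  expect_gt(lcn$fraction, 0.5)
  expect_lt(lcn$fisher_p, 0.01)
  expect_equal(lcn$fisher_p,
               oracle_fisher(lcn$n_in_category, lcn$n_genes - lcn$n_in_category,
                             sum(cat10 %in% summ$anchor_id) - lcn$n_in_category,
                             90L - (sum(cat10 %in% summ$anchor_id) - lcn$n_in_category)),
               tolerance = 1e-7)
})

test_that("TSS probe assignment takes the max-mean probe with lexicographic ties", {
  manifest <- data.frame(
    probe_id = c("cg_b", "cg_a", "cg_c", "cg_body"),
    gene_id = "G1",
    region = c("TSS200", "TSS1500", "TSS200", "Body"), stringsAsFactors = FALSE)
  beta <- rbind(cg_b = c(0.2, 0.2), cg_a = c(0.7, 0.7), cg_c = c(0.7, 0.7),
                cg_body = c(0.99, 0.99))
  colnames(beta) <- c("S1", "S2")
  # body probe ignored; cg_a and cg_c tie at 0.7 -> lexicographically smaller
  expect_equal(assign_probe_to_tss(manifest, beta, "G1"), "cg_a")
  expect_equal(assign_probe_to_tss(manifest, beta[c("cg_b", "cg_c", "cg_body"), ], "G1"),
               "cg_c")
  expect_true(is.na(assign_probe_to_tss(manifest, beta, "G2")))
})

test_that("methylation coupling recovers a planted mediated repressor", {
  set.seed(41)
  n <- 120L
  mk <- function(ct) {
    z <- rnorm(n)
    lnc <- 50 * exp(0.8 * z + rnorm(n, 0, 0.3))
    beta <- plogis(qlogis(0.2) + 1.0 * z + rnorm(n, 0, 0.4))
    beta_null <- plogis(qlogis(0.2) + rnorm(n, 0, 0.4))
    samples <- sprintf("%s_%03d", ct, 1:n)
    cpm <- make_expr(rbind(LNC1 = lnc, LNC2 = 50 * exp(rnorm(n, 0, 0.5))),
                     ct, unit = "cpm")
    colnames(cpm$values) <- samples
    beta_m <- rbind(cg_C1_1 = beta, cg_C2_1 = beta_null)
    colnames(beta_m) <- samples
    list(cpm = cpm, beta = beta_m)
  }
  parts <- lapply(c("CTA", "CTB"), mk)
  cpm <- setNames(lapply(parts, `[[`, "cpm"), c("CTA", "CTB"))
  beta <- setNames(lapply(parts, `[[`, "beta"), c("CTA", "CTB"))
  manifest <- data.frame(probe_id = c("cg_C1_1", "cg_C2_1"),
                         gene_id = c("C1", "C2"), region = "TSS200",
                         stringsAsFactors = FALSE)
  pairs <- data.frame(anchor_id = c("C1", "C2"), partner_id = c("LNC1", "LNC2"),
                      stringsAsFactors = FALSE)
  mc <- methylation_coupling(pairs, cpm, beta, manifest)
  fl <- mc$flags
  expect_true(fl$positively_coupled[fl$anchor_id == "C1"])
  planted <- mc$records[mc$records$anchor_id == "C1", ]
  expect_true(all(planted$rho_meth > 0))
  expect_true(all(planted$significant))
  # zero matched samples -> no records
  beta_mis <- lapply(beta, function(b) { colnames(b) <- paste0("x", colnames(b)); b })
  mc0 <- methylation_coupling(pairs, cpm, beta_mis, manifest)
  expect_equal(nrow(mc0$records), 0L)
  expect_true(all(!mc0$flags$positively_coupled))
})

test_that("two-sample t matches the pooled-variance formula and its edges", {
  set.seed(3)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  got <- t_test_two_sample(a, b)
  want <- oracle_student_t(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(t_test_two_sample(a, a)$p, 1, tolerance = 1e-12)
  expect_equal(t_test_two_sample(c(1, 1), c(1, 1))$p, 1)
  expect_lt(t_test_two_sample(c(0, 0, 0), c(1, 1, 1))$p, 1e-200)
  w <- t_test_two_sample(a, b, variant = "welch")
  expect_equal(w$p, t.test(a, b)$p.value)
})

test_that("localization comparison separates a nuclear-shifted group", {
  set.seed(9)
  lines <- sprintf("CL%02d", 1:5)
  rci <- do.call(rbind, lapply(lines, function(cl) data.frame(
    gene_id = sprintf("L%03d", 1:100), cell_line = cl,
    rci = c(rnorm(30, -1), rnorm(70, 0)), stringsAsFactors = FALSE)))
  lcn <- sprintf("L%03d", 1:30)
  lcp <- sprintf("L%03d", 31:60)
  bg <- sprintf("L%03d", 31:100)
  loc <- localization_compare(rci, lcn, lcp, bg)
  expect_equal(nrow(loc), 5L)
  expect_true(all(loc$median_lcn < 0))
  expect_true(all(loc$p_vs_background < 0.05))
  # identical groups give t = 0, p = 1
  same <- localization_compare(rci, bg, bg, bg)
  expect_true(all(same$t_vs_background == 0))
  expect_true(all(same$p_vs_background == 1))
  # too-small groups are skipped
  skipped <- localization_compare(rci, "L001", lcp, bg)
  expect_equal(nrow(skipped), 0L)
})
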