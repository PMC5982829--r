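# Synthetic-cohort generator: determinism, planted geometry, effect sizes.

test_that("same seed gives byte-identical cohort files", {
  cfg <- small_sim_config(seed = 3L, samples_per_type = 30L)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted geometry: APA decoys are flagged, pair distances respected", {
  cfg <- small_sim_config(seed = 11L)
  gen <- generate_genome(cfg)
  fl <- flag_apa_candidates(gen$annotation, apa_gap = cfg$apa_gap)
  # exactly the planted decoys are flagged
  expect_setequal(fl$lnc_id, gen$truth$apa$lnc_id)
  expect_equal(nrow(gen$truth$apa), cfg$n_apa)
  # planted pairs appear at every window that covers their distance
  cod <- gen$annotation$genes[gen$annotation$genes$biotype == "coding", ]
  lnc_ids <- setdiff(
    gen$annotation$genes$gene_id[gen$annotation$genes$biotype == "lncRNA"],
    fl$lnc_id)
  lnc <- gen$annotation$genes[gen$annotation$genes$gene_id %in% lnc_ids, ]
  for (w in c(25000L, 50000L, 100000L)) {
    p <- build_window_pairs(cod, lnc, w, "lncRNA")
    k <- paste(p$anchor_id, p$partner_id)
    tp <- gen$truth$pairs
    should <- tp$distance_bp < w
    expect_equal(paste(tp$anchor_id, tp$partner_id) %in% k, should,
                 label = sprintf("window %d", w))
  }
  # recorded distances match the pairing computation
  p100 <- build_window_pairs(cod, lnc, 100000L, "lncRNA")
  m <- merge(gen$truth$pairs, p100, by = c("anchor_id", "partner_id"))
  expect_equal(m$distance_bp.x, m$distance_bp.y)
  expect_equal(m$orientation.x, m$orientation.y)
  # distal controls pair with nothing at 100 kb
  distal <- gen$truth$genes$gene_id[gen$truth$genes$sim_class == "distal_control"]
  expect_false(any(p100$partner_id %in% distal))
})

test_that("planted effect sizes land near their targets", {
  cfg <- small_sim_config(seed = 19L, samples_per_type = 200L)
  gen <- generate_genome(cfg)
  cpm <- lapply(generate_expression(gen, cfg), cpm_normalize)
  v <- cpm[[1L]]$values
  tp <- gen$truth$pairs
  rho_of <- function(rows) vapply(seq_len(nrow(rows)), function(i)
    cor(rank(v[rows$anchor_id[i], ]), rank(v[rows$partner_id[i], ])),
    numeric(1L))
  rep_rho <- rho_of(tp[tp$class %in% c("repressor", "mediated_repressor"), ])
  expect_true(all(rep_rho < -0.25))
  expect_lt(abs(median(rep_rho) - cfg$rho_target), 0.12)
  ind_rho <- rho_of(tp[tp$class == "independent", ])
  expect_true(all(abs(ind_rho) < 0.25))
  expect_lt(abs(median(ind_rho)), 0.06)
  sh_rho <- rho_of(tp[tp$class == "shared_domain_positive", ])
  expect_true(all(sh_rho > 0.25))
})

test_that("the stored gamma calibration curve reproduces under re-simulation", {
  cal <- read.table(system.file("extdata", "gamma_calibration.tsv",
                                package = "cispair"),
                    header = TRUE, sep = "\t")
  expect_true(all(diff(cal$median_spearman) < 0))  # monotone in gamma
  g <- 0.6
  cfg <- sim_config(seed = 2L, n_coding = 60L, n_lnc = 60L, n_repressor = 20L,
                    n_shared = 10L, n_apa = 5L, n_distal = 3L,
                    n_single_cancer = 5L, n_types = 1L,
                    samples_per_type = 200L, gamma = g)
  gen <- generate_genome(cfg)
  v <- cpm_normalize(generate_expression(gen, cfg)[[1L]])$values
  tp <- gen$truth$pairs[gen$truth$pairs$class %in%
                          c("repressor", "mediated_repressor"), ]
  med <- median(vapply(seq_len(nrow(tp)), function(i)
    cor(rank(v[tp$anchor_id[i], ]), rank(v[tp$partner_id[i], ])), numeric(1L)))
  expect_lt(abs(med - cal$median_spearman[cal$gamma == g]), 0.1)
})

test_that("single-cancer genes are highly specific; betas stay inside (0,1)", {
  cfg <- small_sim_config(seed = 23L, n_types = 4L, samples_per_type = 60L)
  gen <- generate_genome(cfg)
  cpm <- lapply(generate_expression(gen, cfg), cpm_normalize)
  prof <- mean_profiles(cpm)
  single <- gen$truth$genes$gene_id[gen$truth$genes$specificity == "single_cancer"]
  taus <- vapply(single, function(g) tau(prof[g, ]), numeric(1L))
  expect_true(all(taus > 0.9))
  ubiq <- gen$truth$genes$gene_id[gen$truth$genes$specificity == "ubiquitous"]
  expect_lt(median(vapply(ubiq, function(g) tau(prof[g, ]), numeric(1L))), 0.5)

  meth <- generate_methylation(gen, cfg)
  for (ct_i in names(meth$beta)) {
    b <- meth$beta[[ct_i]]
    expect_true(all(b > 0 & b < 1))
    # sample ids align with the same cancer type's expression matrix
    expect_equal(colnames(b), colnames(cpm[[ct_i]]$values))
  }
  # mediated pairs couple lncRNA expression to promoter methylation
  tp <- gen$truth$pairs
  med_p <- tp[tp$class == "mediated_repressor", ]
  ct <- gen$truth$cancer_types[1L]
  rho_m <- vapply(seq_len(nrow(med_p)), function(i) {
    probe <- assign_probe_to_tss(meth$manifest, meth$beta[[ct]],
                                 med_p$anchor_id[i])
    cor(rank(cpm[[ct]]$values[med_p$partner_id[i], ]),
        rank(meth$beta[[ct]][probe, ]))
  }, numeric(1L))
  expect_true(all(rho_m > 0.1))
  # plain repressors show no systematic coupling
  rep_p <- tp[tp$class == "repressor", ]
  rho_r <- vapply(seq_len(nrow(rep_p)), function(i) {
    probe <- assign_probe_to_tss(meth$manifest, meth$beta[[ct]],
                                 rep_p$anchor_id[i])
    cor(rank(cpm[[ct]]$values[rep_p$partner_id[i], ]),
        rank(meth$beta[[ct]][probe, ]))
  }, numeric(1L))
  expect_lt(abs(median(rho_r)), 0.15)
})

test_that("conservation track separates gene classes and stays in [0,1]", {
  cfg <- small_sim_config(seed = 29L, samples_per_type = 20L)
  gen <- generate_genome(cfg)
  track <- generate_conservation_track(gen, cfg)
  expect_true(all(track$score >= 0 & track$score <= 1))
  # non-overlapping, each chromosome fully covered
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, ]
    t <- t[order(t$start), ]
    expect_true(all(t$start[-1L] >= t$end[-nrow(t)]))
    expect_equal(sum(t$end - t$start),
                 unname(gen$annotation$chrom_sizes[[ch]]))
  }
  ct <- conservation_table(gen$annotation, track)
  cls <- gen$truth$genes$conservation_class[match(ct$gene_id,
                                                  gen$truth$genes$gene_id)]
  hi <- ct$mean_score[cls == "high" & ct$n_bases > 0]
  lo <- ct$mean_score[cls == "low" & ct$n_bases > 0]
  expect_gt(min(hi, na.rm = TRUE), 0.5)
  expect_lt(median(lo, na.rm = TRUE), 0.2)
  # intergenic query scores the background
  probe_ann <- gene_annotation(
    data.frame(gene_id = "Q", chrom = "chr1", start = 9500000L,
               end = 9501000L, strand = "+", biotype = "coding"),
    data.frame(gene_id = "Q", start = 9500000L, end = 9501000L))
  q <- exonic_conservation(probe_ann, track, "Q")
  expect_equal(q$mean_score, 0.02, tolerance = 1e-9)
})

test_that("RCI table shifts planted repressor lncRNAs toward the nucleus", {
  cfg <- small_sim_config(seed = 31L, samples_per_type = 20L)
  gen <- generate_genome(cfg)
  rci <- generate_rci(gen, cfg)
  expect_equal(length(unique(rci$cell_line)), cfg$n_cell_lines)
  rep_l <- gen$truth$pairs$partner_id[gen$truth$pairs$class %in%
                                        c("repressor", "mediated_repressor")]
  other <- setdiff(unique(rci$gene_id), rep_l)
  loc <- localization_compare(rci, rep_l,
                              lcp_ids = other, background_ids = other)
  expect_gt(mean(loc$median_lcn < 0), 0.8)
  expect_gte(mean(loc$p_vs_background < 0.05), 0.8)
})
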