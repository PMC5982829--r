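# Synthetic-cohort generator: miniature genome, counts, methylation,
# conservation and localization data with a ground-truth manifest.
#
# The generator emulates the shape of the screen's real inputs (GENCODE-style
# annotation, per-cancer-type TCGA count matrices, 450K beta matrices,
# phastCons track, LncAtlas RCI table) at desk scale, planting four pair
# classes: `repressor` (negative expression coupling), `mediated_repressor`
# (negative expression coupling plus positive lncRNA-expression/promoter-
# methylation coupling), `shared_domain_positive` (positive coupling through a
# shared latent domain activity) and `independent`.

#' Configuration for the synthetic cohort
#'
#' Defaults define the standard desk-scale study: 3 chromosomes of 10 Mb,
#' 300 coding and 300 lncRNA genes, 4 cancer types of 200 samples, 40 planted
#' repressor pairs (half methylation-mediated) at a target population Spearman
#' of -0.5, 60 shared-domain positive pairs, 20 alternative-polyadenylation
#' decoys and 10 distal negative-control lncRNAs. Effect-size parameters
#' (`gamma`, `shared_a`, `meth_delta`) were calibrated once by simulation so
#' the realized pair correlations match the targets (see the package
#' vignette).
#'
#' @param seed integer seed (mandatory); all outputs are deterministic given
#'   it.
#' @param n_chrom,chrom_len chromosome count and length (bases).
#' @param n_coding,n_lnc gene counts.
#' @param n_types,samples_per_type cohort shape.
#' @param n_repressor planted repressor pairs; `frac_mediated` of them also
#'   get methylation coupling.
#' @param frac_mediated fraction of repressors that are methylation-mediated.
#' @param n_shared planted shared-domain positive pairs.
#' @param n_apa same-strand lncRNAs planted within `apa_gap` of a coding gene.
#' @param n_distal lncRNAs planted just beyond 100 kb of any coding gene.
#' @param n_single_cancer genes (unpaired) expressed in exactly one cancer
#'   type.
#' @param n_lnc_high_cons lncRNAs drawn from the high-conservation class.
#' @param apa_gap APA decoy gap ceiling (bases).
#' @param rho_target target population Spearman for repressor pairs.
#' @param gamma repressor latent-activity loading (log scale), calibrated to
#'   `rho_target`.
#' @param shared_a shared-domain latent loading (log scale).
#' @param meth_delta methylation latent loading (logit scale) for mediated
#'   pairs.
#' @param meth_noise_sd logit-scale probe noise.
#' @param dispersion_range negative-binomial gene dispersion range.
#' @param lib_sdlog log-normal sd of per-sample library factors.
#' @param base_mean_range per-gene baseline mean count range (log-uniform).
#' @param n_cell_lines,rci_shift,rci_sd RCI table shape; repressor lncRNAs are
#'   shifted by `rci_shift` (nuclear when negative).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chrom = 3L, chrom_len = 10e6,
                       n_coding = 300L, n_lnc = 300L,
                       n_types = 4L, samples_per_type = 200L,
                       n_repressor = 40L, frac_mediated = 0.5,
                       n_shared = 60L, n_apa = 20L, n_distal = 10L,
                       n_single_cancer = 40L, n_lnc_high_cons = 15L,
                       apa_gap = 5000L,
                       rho_target = -0.5, gamma = 0.57,
                       shared_a = 0.57, meth_delta = 0.5,
                       meth_noise_sd = 0.6,
                       dispersion_range = c(0.1, 0.4),
                       lib_sdlog = 0.3,
                       base_mean_range = c(20, 500),
                       n_cell_lines = 15L, rci_shift = -1, rci_sd = 1) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_len = as.integer(chrom_len),
              n_coding = as.integer(n_coding), n_lnc = as.integer(n_lnc),
              n_types = as.integer(n_types),
              samples_per_type = as.integer(samples_per_type),
              n_repressor = as.integer(n_repressor),
              frac_mediated = frac_mediated,
              n_shared = as.integer(n_shared), n_apa = as.integer(n_apa),
              n_distal = as.integer(n_distal),
              n_single_cancer = as.integer(n_single_cancer),
              n_lnc_high_cons = as.integer(n_lnc_high_cons),
              apa_gap = as.integer(apa_gap),
              rho_target = rho_target, gamma = gamma, shared_a = shared_a,
              meth_delta = meth_delta, meth_noise_sd = meth_noise_sd,
              dispersion_range = dispersion_range, lib_sdlog = lib_sdlog,
              base_mean_range = base_mean_range,
              n_cell_lines = as.integer(n_cell_lines),
              rci_shift = rci_shift, rci_sd = rci_sd)
  stopifnot(cfg$n_chrom > 0L, cfg$chrom_len > 0L, cfg$n_coding > 0L,
            cfg$n_lnc >= cfg$n_repressor + cfg$n_shared + cfg$n_apa + cfg$n_distal,
            cfg$n_types >= 1L, cfg$samples_per_type > 0L,
            cfg$n_repressor <= cfg$n_coding, cfg$frac_mediated >= 0,
            cfg$frac_mediated <= 1)
  structure(cfg, class = "sim_config")
}

sim_type_labels <- function(config) sprintf("CT%02d", seq_len(config$n_types))

# Exon chain for one gene: k chunks, one exon in each; first exon starts at
# the gene start and the last one ends at the gene end.
sim_exons <- function(start, end, k) {
  len <- end - start
  if (k == 1L) return(cbind(start = start, end = end))
  chunk <- len / k
  u <- runif(k, 0.3, 0.8)
  ex_start <- as.integer(floor(start + (seq_len(k) - 1L) * chunk))
  ex_len <- pmax(50L, as.integer(floor(chunk * u)))
  ex_end <- pmin(ex_start + ex_len, end)
  ex_start[1L] <- start
  ex_start[k] <- end - ex_len[k]
  ex_end[k] <- end
  cbind(start = as.integer(ex_start), end = as.integer(ex_end))
}

#' Generate the synthetic genome and truth manifest
#'
#' Coding genes are placed non-overlapping on a regular grid within the first
#' 80% of each chromosome; the remaining telomeric region holds the distal
#' negative-control lncRNAs (> 100 kb from any coding gene). Each planted
#' pair's lncRNA is placed at a drawn orientation and boundary distance
#' relative to its coding anchor; APA decoys are same-strand lncRNAs within
#' `apa_gap` of their anchor.
#'
#' @param config a [sim_config].
#' @return list with `annotation` (a [gene_annotation]) and `truth` (lists
#'   `pairs`, `genes`, `apa` — the manifest).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "genome"), {
    chroms <- sprintf("chr%d", seq_len(config$n_chrom))
    sizes <- setNames(rep(config$chrom_len, config$n_chrom), chroms)
    zone <- as.integer(config$chrom_len * 0.8)

    # --- coding genes on a grid ---
    per_chrom <- ceiling(config$n_coding / config$n_chrom)
    slot <- as.integer((zone - 200000L) / per_chrom)
    cod_len <- as.integer(round(runif(config$n_coding, 5000, 20000)))
    ci <- seq_len(config$n_coding) - 1L
    cod <- data.frame(
      gene_id = sprintf("CG%04d", seq_len(config$n_coding)),
      chrom = chroms[(ci %% config$n_chrom) + 1L],
      start = 100000L + (ci %/% config$n_chrom) * slot,
      end = 100000L + (ci %/% config$n_chrom) * slot + cod_len,
      strand = sample(c("+", "-"), config$n_coding, replace = TRUE),
      biotype = "coding", stringsAsFactors = FALSE)

    # --- planted pairs: draw anchors without replacement ---
    n_med <- as.integer(round(config$n_repressor * config$frac_mediated))
    classes <- c(rep("mediated_repressor", n_med),
                 rep("repressor", config$n_repressor - n_med),
                 rep("shared_domain_positive", config$n_shared),
                 rep("apa_decoy", config$n_apa))
    n_attached <- config$n_lnc - config$n_distal
    n_indep <- n_attached - length(classes)
    stopifnot(n_indep >= 0L)
    classes <- c(classes, rep("independent", n_indep))
    anchors <- sample(config$n_coding, length(classes),
                      replace = length(classes) > config$n_coding)
    # anchors for planted effect classes must be unique so latents don't mix
    stopifnot(!anyDuplicated(anchors[classes != "independent"]) ||
                length(classes) <= config$n_coding)

    lnc_len <- as.integer(round(runif(length(classes), 2000, 6000)))
    orient_pool <- c("antisense_overlap", "divergent", "convergent",
                     "sense_downstream")
    orientation <- sample(orient_pool, length(classes), replace = TRUE)
    # a few shared pairs at 30 kb exercise window nesting (in 50/100 not 25 kb)
    far <- which(classes == "shared_domain_positive")[1:4]
    lnc <- data.frame(gene_id = sprintf("LNC%04d", seq_along(classes)),
                      chrom = "", start = 0L, end = 0L, strand = "+",
                      biotype = "lncRNA", stringsAsFactors = FALSE)
    dist_bp <- integer(length(classes))
    for (i in seq_along(classes)) {
      a <- cod[anchors[i], ]
      len <- lnc_len[i]
      if (classes[i] == "apa_decoy") {
        ori <- "sense_downstream"; gap <- as.integer(round(runif(1, 500, 4500)))
      } else {
        ori <- orientation[i]
        gap <- switch(ori,
          antisense_overlap = 0L,
          divergent = as.integer(round(runif(1, 200, 800))),
          convergent = as.integer(round(runif(1, 1000, 20000))),
          sense_downstream = as.integer(round(runif(1, 6000, 20000))))
        if (!is.na(match(i, far)) && ori != "antisense_overlap") gap <- 30000L
      }
      if (ori == "antisense_overlap") {
        st <- a$start + (a$end - a$start) %/% 2L
        lnc[i, c("start", "end")] <- c(st, st + len)
        lnc$strand[i] <- if (a$strand == "+") "-" else "+"
        dist_bp[i] <- 0L
      } else {
        side3 <- ori %in% c("convergent", "sense_downstream")
        # genomic side: 3' side of a '+' anchor is right, of a '-' anchor left
        right <- (side3 & a$strand == "+") | (!side3 & a$strand == "-")
        if (right) {
          st <- a$end + gap
        } else {
          st <- a$start - gap - len
        }
        lnc[i, c("start", "end")] <- c(st, st + len)
        lnc$strand[i] <- if (ori %in% c("divergent", "convergent")) {
          if (a$strand == "+") "-" else "+"
        } else a$strand
        dist_bp[i] <- gap
        orientation[i] <- ori
      }
      lnc$chrom[i] <- a$chrom
    }

    # --- distal negative controls: > 100 kb beyond the last coding gene ---
    if (config$n_distal > 0L) {
      dl <- as.integer(round(runif(config$n_distal, 2000, 6000)))
      di <- seq_len(config$n_distal) - 1L
      dchrom <- chroms[(di %% config$n_chrom) + 1L]
      dstart <- integer(config$n_distal)
      for (i in seq_len(config$n_distal)) {
        last_end <- max(cod$end[cod$chrom == dchrom[i]])
        dstart[i] <- as.integer(last_end + 101000L + (di[i] %/% config$n_chrom) * 50000L)
      }
      stopifnot(all(dstart + dl <= config$chrom_len))
      distal <- data.frame(
        gene_id = sprintf("LNC%04d", length(classes) + seq_len(config$n_distal)),
        chrom = dchrom, start = dstart, end = dstart + dl,
        strand = sample(c("+", "-"), config$n_distal, replace = TRUE),
        biotype = "lncRNA", stringsAsFactors = FALSE)
      lnc <- rbind(lnc, distal)
      classes <- c(classes, rep("distal_control", config$n_distal))
    }

    genes <- rbind(cod, lnc)
    n_ex <- ifelse(genes$biotype == "coding", sample(2:5, nrow(genes), TRUE),
                   sample(1:3, nrow(genes), TRUE))
    exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      m <- sim_exons(genes$start[i], genes$end[i], n_ex[i])
      data.frame(gene_id = genes$gene_id[i], start = m[, 1L], end = m[, 2L],
                 stringsAsFactors = FALSE)
    }))
    ann <- gene_annotation(genes, exons, sizes)

    # --- per-gene truth: specificity, conservation, localization ---
    pair_classes <- c("repressor", "mediated_repressor",
                      "shared_domain_positive", "independent")
    is_pair <- classes %in% pair_classes
    pair_idx <- which(is_pair)
    pairs <- data.frame(
      pair_id = seq_along(pair_idx),
      anchor_id = cod$gene_id[anchors[pair_idx]],
      partner_id = lnc$gene_id[pair_idx],
      class = classes[pair_idx],
      effect = ifelse(classes[pair_idx] %in% c("repressor", "mediated_repressor"),
                      config$rho_target,
                      ifelse(classes[pair_idx] == "shared_domain_positive",
                             abs(config$rho_target), 0)),
      meth_delta = ifelse(classes[pair_idx] == "mediated_repressor",
                          config$meth_delta, 0),
      orientation = orientation[pair_idx],
      distance_bp = dist_bp[pair_idx],
      stringsAsFactors = FALSE)

    types <- sim_type_labels(config)
    involved <- unique(c(pairs$anchor_id, pairs$partner_id))
    free <- setdiff(genes$gene_id, involved)
    single <- sample(free, min(config$n_single_cancer, length(free)))
    spec_type <- setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
    spec_type[single] <- sample(types, length(single), replace = TRUE)

    lnc_ids <- lnc$gene_id
    high_lnc <- sample(lnc_ids, min(config$n_lnc_high_cons, length(lnc_ids)))
    cons_class <- ifelse(genes$biotype == "coding", "high",
                         ifelse(genes$gene_id %in% high_lnc, "high", "low"))
    rep_lnc <- pairs$partner_id[pairs$class %in% c("repressor", "mediated_repressor")]
    loc_shift <- ifelse(genes$gene_id %in% rep_lnc, config$rci_shift, 0)

    gene_truth <- data.frame(
      gene_id = genes$gene_id, biotype = genes$biotype,
      specificity = ifelse(is.na(spec_type), "ubiquitous", "single_cancer"),
      specific_type = spec_type,
      conservation_class = cons_class,
      localization_shift = loc_shift,
      sim_class = c(rep("coding", nrow(cod)), classes),
      stringsAsFactors = FALSE)
    rownames(gene_truth) <- NULL

    apa <- data.frame(lnc_id = lnc$gene_id[classes == "apa_decoy"],
                      coding_id = cod$gene_id[anchors[classes == "apa_decoy"]],
                      gap_bp = dist_bp[classes == "apa_decoy"],
                      stringsAsFactors = FALSE)

    list(annotation = ann,
         truth = list(pairs = pairs, genes = gene_truth, apa = apa,
                      cancer_types = types))
  })
}

# Latent activities shared between expression and methylation: one n_pairs x
# n_samples matrix per cancer type, deterministic given the config seed.
sim_latents <- function(config, n_pairs) {
  with_seed(child_seed(config$seed, "latents"), {
    lapply(sim_type_labels(config), function(ct) {
      matrix(rnorm(n_pairs * config$samples_per_type), nrow = n_pairs)
    }) |> setNames(sim_type_labels(config))
  })
}

# Fixed per-gene expression parameters (baseline, dispersion), seeded.
sim_gene_params <- function(config, truth) {
  with_seed(child_seed(config$seed, "geneparams"), {
    g <- truth$genes
    n <- nrow(g)
    base <- exp(runif(n, log(config$base_mean_range[1L]),
                      log(config$base_mean_range[2L])))
    disp <- runif(n, config$dispersion_range[1L], config$dispersion_range[2L])
    list(base_mean = setNames(base, g$gene_id),
         dispersion = setNames(disp, g$gene_id))
  })
}

#' Generate per-cancer-type raw count matrices
#'
#' Counts are negative binomial with mean
#' `L_s * exp(b_g + a*u_p(s) -/+ gamma*z_p(s) + specificity boost)`: `L_s` is a
#' log-normal library factor, `z_p` a per-sample latent activity loading
#' positively on a repressor pair's lncRNA and negatively on its coding gene,
#' `u_p` a latent domain activity loading positively on both genes of a
#' shared-domain pair. Single-cancer genes have their baseline elevated in
#' exactly one cancer type and suppressed elsewhere.
#'
#' @param genome output of [generate_genome()].
#' @param config the [sim_config] used to generate it.
#' @return named list of `raw_counts` [expr_matrix] objects, one per cancer
#'   type.
#' @export
generate_expression <- function(genome, config) {
  truth <- genome$truth
  pars <- sim_gene_params(config, truth)
  lat <- sim_latents(config, nrow(truth$pairs))
  types <- truth$cancer_types
  g <- truth$genes
  gid <- g$gene_id
  with_seed(child_seed(config$seed, "expression"), {
    out <- lapply(seq_along(types), function(d) {
      ct <- types[d]
      ns <- config$samples_per_type
      L <- rlnorm(ns, 0, config$lib_sdlog)
      b <- log(pars$base_mean[gid])
      # single-cancer specificity: high in its own type, near-silent elsewhere
      sc <- g$specificity == "single_cancer"
      b[sc & g$specific_type == ct] <- log(200)
      b[sc & g$specific_type != ct] <- log(0.01)
      logmu <- matrix(b, nrow = length(gid), ncol = ns)
      z <- lat[[ct]]
      for (p in seq_len(nrow(truth$pairs))) {
        pr <- truth$pairs[p, ]
        ia <- match(pr$anchor_id, gid); il <- match(pr$partner_id, gid)
        if (pr$class %in% c("repressor", "mediated_repressor")) {
          logmu[il, ] <- logmu[il, ] + config$gamma * z[p, ]
          logmu[ia, ] <- logmu[ia, ] - config$gamma * z[p, ]
        } else if (pr$class == "shared_domain_positive") {
          logmu[il, ] <- logmu[il, ] + config$shared_a * z[p, ]
          logmu[ia, ] <- logmu[ia, ] + config$shared_a * z[p, ]
        }
      }
      mu <- sweep(exp(logmu), 2L, L, `*`)
      counts <- matrix(rnbinom(length(mu), mu = mu,
                               size = rep(1 / pars$dispersion[gid], ns)),
                       nrow = length(gid))
      dimnames(counts) <- list(gid, sprintf("%s_S%03d", ct, seq_len(ns)))
      expr_matrix(counts, ct, "raw_counts")
    })
    setNames(out, types)
  })
}

#' Generate methylation beta matrices and a probe manifest
#'
#' Every coding gene gets 1-3 TSS probes (`TSS200`/`TSS1500`) and one `Body`
#' decoy probe. For mediated-repressor pairs the coding gene's TSS probes
#' track the pair's latent activity on the logit scale
#' (`beta = plogis(logit(b0) + delta * z_p(s) + noise)`), so lncRNA expression
#' and promoter methylation rise together while the coding gene falls; all
#' other probes are logit-normal noise. Sample ids match the expression
#' matrices.
#'
#' @param genome output of [generate_genome()].
#' @param config the [sim_config].
#' @return list with `beta` (named list of probes x samples matrices) and
#'   `manifest` (probe manifest data frame).
#' @export
generate_methylation <- function(genome, config) {
  truth <- genome$truth
  lat <- sim_latents(config, nrow(truth$pairs))
  types <- truth$cancer_types
  cod <- truth$genes$gene_id[truth$genes$biotype == "coding"]
  with_seed(child_seed(config$seed, "methylation"), {
    n_tss <- sample(1:3, length(cod), replace = TRUE)
    manifest <- do.call(rbind, lapply(seq_along(cod), function(i) {
      data.frame(
        probe_id = sprintf("cg_%s_%d", cod[i], seq_len(n_tss[i] + 1L)),
        gene_id = cod[i],
        region = c(rep(c("TSS200", "TSS1500"), length.out = n_tss[i]), "Body"),
        stringsAsFactors = FALSE)
    }))
    base <- setNames(runif(nrow(manifest), 0.1, 0.4), manifest$probe_id)
    med <- truth$pairs[truth$pairs$class == "mediated_repressor", , drop = FALSE]
    med_pair_of <- setNames(med$pair_id, med$anchor_id)
    beta <- lapply(types, function(ct) {
      ns <- config$samples_per_type
      z <- lat[[ct]]
      m <- matrix(NA_real_, nrow = nrow(manifest), ncol = ns,
                  dimnames = list(manifest$probe_id,
                                  sprintf("%s_S%03d", ct, seq_len(ns))))
      for (i in seq_len(nrow(manifest))) {
        lg <- qlogis(base[i]) + rnorm(ns, 0, config$meth_noise_sd)
        pid <- med_pair_of[manifest$gene_id[i]]
        if (!is.na(pid) && manifest$region[i] != "Body")
          lg <- lg + config$meth_delta * z[pid, ]
        m[i, ] <- plogis(lg)
      }
      m
    })
    list(beta = setNames(beta, types), manifest = manifest)
  })
}

#' Generate a per-base conservation track (bedGraph)
#'
#' Exonic bases of high-conservation-class genes score around 0.8, low-class
#' around 0.05, and everything else (the genomic background) 0.02; values are
#' clipped to `[0, 1]`. Where exons of several genes overlap, the highest
#' class wins.
#'
#' @param genome output of [generate_genome()].
#' @param config the [sim_config].
#' @return bedGraph-shaped data frame (`chrom`, `start`, `end`, `score`).
#' @export
generate_conservation_track <- function(genome, config) {
  ann <- genome$annotation
  truth <- genome$truth
  with_seed(child_seed(config$seed, "conservation"), {
    cls <- setNames(truth$genes$conservation_class, truth$genes$gene_id)
    mean_of <- c(high = 0.8, low = 0.05)
    gene_score <- pmin(1, pmax(0, rnorm(nrow(truth$genes),
                                        mean_of[cls], 0.03)))
    names(gene_score) <- truth$genes$gene_id
    rows <- lapply(names(ann$chrom_sizes), function(ch) {
      gids <- ann$genes$gene_id[ann$genes$chrom == ch]
      ex <- ann$exons[ann$exons$gene_id %in% gids, , drop = FALSE]
      if (nrow(ex) == 0L)
        return(data.frame(chrom = ch, start = 0L,
                          end = ann$chrom_sizes[[ch]], score = 0.02,
                          stringsAsFactors = FALSE))
      ir <- IRanges::IRanges(ex$start + 1L, ex$end)
      dj <- IRanges::disjoin(ir)
      hits <- IRanges::findOverlaps(dj, ir)
      sc <- tapply(gene_score[ex$gene_id[S4Vectors::subjectHits(hits)]],
                   factor(S4Vectors::queryHits(hits), levels = seq_along(dj)),
                   max)
      m <- half_open_from_ir(dj)
      seg <- data.frame(chrom = ch, start = m[, 1L], end = m[, 2L],
                        score = round(as.numeric(sc), 4L),
                        stringsAsFactors = FALSE)
      # fill the complement with background
      gaps <- subtract_intervals(cbind(0L, ann$chrom_sizes[[ch]]),
                                 m)
      bg <- data.frame(chrom = ch, start = gaps[, 1L], end = gaps[, 2L],
                       score = 0.02, stringsAsFactors = FALSE)
      out <- rbind(seg, bg)
      out[order(out$start), ]
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic cytoplasmic/nuclear RCI table
#'
#' Each lncRNA gets one RCI value per cell line, drawn from a normal centred
#' on its planted localization shift (negative = nuclear-shifted, as planted
#' for repressor lncRNAs) with sd `rci_sd`.
#'
#' @param genome output of [generate_genome()].
#' @param config the [sim_config].
#' @return data frame `gene_id`, `cell_line`, `rci`.
#' @export
generate_rci <- function(genome, config) {
  truth <- genome$truth
  lnc <- truth$genes[truth$genes$biotype == "lncRNA", , drop = FALSE]
  lines <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  with_seed(child_seed(config$seed, "rci"), {
    out <- expand.grid(gene_id = lnc$gene_id, cell_line = lines,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    shift <- lnc$localization_shift[match(out$gene_id, lnc$gene_id)]
    out$rci <- rnorm(nrow(out), mean = shift, sd = config$rci_sd)
    out[order(out$cell_line, out$gene_id), ] -> out
    rownames(out) <- NULL
    out
  })
}

# Category lists with a planted enrichment: "cancer_census" holds 80% of the
# repressor anchors plus 5% of the other coding genes; "imprinted" is a flat
# 5% random draw (no enrichment).
generate_categories <- function(genome, config) {
  truth <- genome$truth
  cod <- truth$genes$gene_id[truth$genes$biotype == "coding"]
  rep_anchor <- truth$pairs$anchor_id[truth$pairs$class %in%
                                        c("repressor", "mediated_repressor")]
  with_seed(child_seed(config$seed, "categories"), {
    census <- sort(unique(c(
      sample(rep_anchor, max(1L, round(0.8 * length(rep_anchor)))),
      sample(setdiff(cod, rep_anchor),
             max(1L, round(0.05 * length(setdiff(cod, rep_anchor))))))))
    imprinted <- sort(sample(cod, max(1L, round(0.05 * length(cod)))))
    list(cancer_census = census, imprinted = imprinted)
  })
}

#' Generate and write a full synthetic cohort
#'
#' Emits every file the pipeline consumes — GTF annotation, chrom.sizes,
#' per-cancer-type count TSVs with a cohort index, beta TSVs with a
#' methylation index and probe manifest, a conservation bedGraph, an RCI
#' table, category gene lists — plus the truth manifest as JSON. Byte-identical
#' across runs with the same config.
#'
#' @param config a [sim_config].
#' @param out_dir output directory (created if missing).
#' @return an object of class `cispair_cohort`: list with `paths`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(config)
  expr <- generate_expression(genome, config)
  meth <- generate_methylation(genome, config)
  track <- generate_conservation_track(genome, config)
  rci <- generate_rci(genome, config)
  cats <- generate_categories(genome, config)

  p <- list()
  p$gtf <- file.path(out_dir, "annotation.gtf")
  write_gtf(genome$annotation, p$gtf)
  p$chrom_sizes <- file.path(out_dir, "chrom.sizes")
  write_chrom_sizes(genome$annotation$chrom_sizes, p$chrom_sizes)

  types <- genome$truth$cancer_types
  count_paths <- file.path(out_dir, sprintf("counts_%s.tsv", types))
  for (i in seq_along(types)) write_counts_tsv(expr[[i]], count_paths[i])
  p$cohort_index <- file.path(out_dir, "cohort_index.tsv")
  write_tsv(data.frame(cancer_type = types, path = basename(count_paths)),
            p$cohort_index)

  beta_paths <- file.path(out_dir, sprintf("meth_%s.tsv", types))
  for (i in seq_along(types)) {
    bm <- meth$beta[[i]]
    write_tsv(data.frame(probe_id = rownames(bm), signif(bm, 6L),
                         check.names = FALSE), beta_paths[i])
  }
  p$meth_index <- file.path(out_dir, "meth_index.tsv")
  write_tsv(data.frame(cancer_type = types, path = basename(beta_paths)),
            p$meth_index)
  p$probe_manifest <- file.path(out_dir, "probe_manifest.tsv")
  write_tsv(meth$manifest, p$probe_manifest)

  p$conservation <- file.path(out_dir, "conservation.bedgraph")
  write_bedgraph(track, p$conservation)
  p$rci <- file.path(out_dir, "rci.tsv")
  write_tsv(data.frame(gene_id = rci$gene_id, cell_line = rci$cell_line,
                       rci = signif(rci$rci, 6L)), p$rci)

  dir.create(file.path(out_dir, "categories"), showWarnings = FALSE)
  p$categories <- vapply(names(cats), function(nm) {
    f <- file.path(out_dir, "categories", paste0(nm, ".txt"))
    writeLines(cats[[nm]], f)
    f
  }, character(1L))

  p$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(genome$truth, p$truth, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")

  structure(list(paths = p, truth = genome$truth, config = config),
            class = "cispair_cohort")
}

#' @export
print.cispair_cohort <- function(x, ...) {
  tp <- table(x$truth$pairs$class)
  cat("<cispair_cohort> seed ", x$config$seed, ": ",
      nrow(x$truth$genes), " genes, ", x$config$n_types, " cancer types x ",
      x$config$samples_per_type, " samples\n  planted pairs: ",
      paste(sprintf("%s: %d", names(tp), as.integer(tp)), collapse = ", "),
      "\n  files under ", dirname(x$paths$gtf), "\n", sep = "")
  invisible(x)
}

#' Read a truth manifest written by [simulate_cohort()]
#'
#' @param path truth.json path.
#' @return the truth list (`pairs`, `genes`, `apa`, `cancer_types`).
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$pairs <- as.data.frame(tr$pairs, stringsAsFactors = FALSE)
  tr$genes <- as.data.frame(tr$genes, stringsAsFactors = FALSE)
  tr$apa <- as.data.frame(tr$apa, stringsAsFactors = FALSE)
  tr
}
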