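# Spearman screen, BH adjustment, labels, Fisher enrichment.

test_that("spearman_test matches the midrank Pearson oracle and cor.test", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(5:40, 1L)
    x <- sample(round(rexp(n) * 10), n)   # ties likely
    y <- round(rnorm(n), 1)
    got <- spearman_test(x, y)
    expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)
  }
  # p-value agrees with cor.test's t-approximation
  x <- c(1, 2, 3, 4, 5); y <- c(3, 1, 2, 5, 4)
  got <- spearman_test(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(got$rho, unname(ct$estimate))
  expect_equal(got$p, ct$p.value, tolerance = 1e-10)
})

test_that("spearman handles perfect monotone and degenerate inputs", {
  x <- c(2, 5, 9, 11)
  expect_equal(spearman_test(x, x^3)$rho, 1)
  expect_equal(spearman_test(x, rev(x))$rho, -1)
  expect_gt(spearman_test(x, x^3)$p, 0)      # floor, not zero
  expect_error(spearman_test(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rexp(50); y <- rexp(50)
  expect_equal(spearman_test(x, y)$rho,
               spearman_test(log2(x + 1), y)$rho)
  expect_equal(spearman_test(x, y)$rho,
               spearman_test(x, log2(y + 1))$rho)
})

test_that("bh_adjust equals the independent step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(8)
  p <- runif(20)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("fisher_exact_2x2 matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(10, 10, 10, 10), 1)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), oracle_fisher(5, 0, 0, 5),
               tolerance = 1e-9)
  set.seed(12)
  for (rep in 1:25) {
    cells <- as.integer(sample(0:15, 4L, replace = TRUE))
    if (sum(cells) == 0L) next
    p1 <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p1, oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-7)
    # symmetric under simultaneous row and column swap
    expect_equal(p1, fisher_exact_2x2(cells[4], cells[3], cells[2], cells[1]))
  }
})

make_screen_fixture <- function(seed = 2L, n = 120L, rho_pairs = 3L) {
  # two cancer types; first `rho_pairs` pairs get strong negative coupling
  set.seed(seed)
  genes <- sprintf("G%02d", 1:10)
  pairs <- data.frame(anchor_id = genes[1:5], partner_id = genes[6:10],
                      partner_class = "lncRNA", orientation = "divergent",
                      distance_bp = 1000L, window_bp = 100000L,
                      stringsAsFactors = FALSE)
  cpm <- lapply(c("CTA", "CTB"), function(ct) {
    z <- matrix(rnorm(5 * n), nrow = 5)
    base <- matrix(rexp(10 * n, 0.01), nrow = 10, dimnames = list(genes, NULL))
    for (i in seq_len(rho_pairs)) {
      base[i, ] <- 100 * exp(-1.2 * z[i, ] + rnorm(n, 0, 0.4))
      base[i + 5, ] <- 100 * exp(1.2 * z[i, ] + rnorm(n, 0, 0.4))
    }
    colnames(base) <- sprintf("%s_%03d", ct, 1:n)
    make_expr(base, ct, unit = "cpm")
  })
  names(cpm) <- c("CTA", "CTB")
  list(pairs = pairs, cpm = cpm)
}

test_that("screen_pairs recovers planted negative couplings and labels them", {
  fx <- make_screen_fixture()
  rec <- screen_pairs(fx$pairs, fx$cpm)
  expect_true(all(rec$p_adj >= rec$p_raw - 1e-15))
  expect_true(all(abs(rec$rho) <= 1))
  planted <- rec[rec$anchor_id %in% sprintf("G%02d", 1:3), ]
  expect_true(all(planted$rho < 0))
  expect_true(all(planted$p_adj < 1e-5))
  lab <- label_pairs(rec, fx$pairs)
  got <- lab$set_label[lab$anchor_id %in% sprintf("G%02d", 1:3)]
  expect_true(all(got == "LCN"))
  # non-planted pairs stay unlabeled
  expect_true(all(lab$set_label[lab$anchor_id %in% c("G04", "G05")] == "none"))
})

test_that("labels follow the majority + at-least-one-significant rule", {
  # counts shaped like published per-pair tallies: a pair with 0 significant
  # positive and 3 significant negative types is LCN; 2 positive / 5 negative
  # significances still LCN (positives do not veto)
  mk_rec <- function(rhos, sig) data.frame(
    anchor_id = "C", partner_id = "L", partner_class = "lncRNA",
    window_bp = 100000L, cancer_type = sprintf("T%02d", seq_along(rhos)),
    n_samples = 100L, rho = rhos,
    p_raw = ifelse(sig, 1e-9, 0.5), p_adj = ifelse(sig, 1e-9, 0.5),
    stringsAsFactors = FALSE)
  pair <- data.frame(anchor_id = "C", partner_id = "L",
                     partner_class = "lncRNA", orientation = "divergent",
                     distance_bp = 0L, window_bp = 100000L,
                     stringsAsFactors = FALSE)
  dicer_like <- mk_rec(c(-.3, -.4, -.5, -.1, -.2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(label_pairs(dicer_like, pair)$set_label, "LCN")
  rhoh_like <- mk_rec(c(-.3, -.4, -.5, -.2, -.25, .3, .4, -.1),
                      c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(label_pairs(rhoh_like, pair)$set_label, "LCN")
  # no significant type -> none, even with a negative majority
  none_like <- mk_rec(c(-.3, -.2, -.1), c(FALSE, FALSE, FALSE))
  expect_equal(label_pairs(none_like, pair)$set_label, "none")
  # negative in exactly half of testable types is not a majority
  half <- mk_rec(c(-.5, -.4, .4, .5), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(label_pairs(half, pair)$set_label, "none")
  # coding partner gets the CC labels
  pair_cc <- transform(pair, partner_class = "coding")
  rec_cc <- transform(dicer_like, partner_class = "coding")
  expect_equal(label_pairs(rec_cc, pair_cc)$set_label, "CCN")
  # pair absent from records -> none with zero testable types
  lab0 <- label_pairs(dicer_like[0, ], pair)
  expect_equal(lab0$set_label, "none")
  expect_equal(lab0$n_testable, 0L)
})

test_that("every pair gets exactly one label and LCN excludes LCP", {
  fx <- make_screen_fixture(seed = 4L)
  rec <- screen_pairs(fx$pairs, fx$cpm)
  lab <- label_pairs(rec, fx$pairs)
  expect_equal(nrow(lab), nrow(fx$pairs))
  expect_true(all(lab$set_label %in% c("LCN", "LCP", "CCN", "CCP", "none")))
  expect_true(all(lab$n_sig_neg <= lab$n_neg_rho))
  expect_true(all(lab$n_neg_rho <= lab$n_testable))
})

test_that("pair_class_enrichment flags lncRNA excess over the coding control", {
  rec <- data.frame(
    anchor_id = sprintf("A%03d", 1:200), partner_id = sprintf("P%03d", 1:200),
    partner_class = rep(c("lncRNA", "coding"), each = 100L),
    window_bp = 25000L, cancer_type = "CTA", n_samples = 50L,
    rho = 0.5, p_raw = 0.5,
    p_adj = c(rep(1e-7, 50), rep(0.5, 50), rep(1e-7, 10), rep(0.5, 90)),
    stringsAsFactors = FALSE)
  e <- pair_class_enrichment(rec)
  expect_equal(e$lc_frac, 0.5)
  expect_equal(e$cc_frac, 0.1)
  expect_true(e$enriched)
  expect_equal(e$fisher_p, oracle_fisher(50, 50, 10, 90), tolerance = 1e-7)
  # identical fractions are never enriched
  rec$p_adj <- rep(c(1e-7, 0.5), 100)
  expect_false(pair_class_enrichment(rec)$enriched)
  # a stratum with no lncRNA pairs reports NA fraction and FALSE flag
  cc_only <- rec[rec$partner_class == "coding", ]
  e2 <- pair_class_enrichment(cc_only)
  expect_true(is.na(e2$lc_frac))
  expect_false(e2$enriched)
})
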