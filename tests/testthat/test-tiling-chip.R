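test_that("locus p-values equal the brute-force sign-enumeration oracle at n = 5, 8, 11", {
  set.seed(42)
  for (n in c(5L, 8L, 11L)) {
    for (rep in 1:8) {
      x <- round(rnorm(n, mean = 0.3, sd = 1), 2) # rounding induces some ties
      cl <- call_locus(x)
      orc <- oracle_signed_rank(x)
      expect_equal(cl$p_up, orc$p_up, tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d (upper)", n, rep))
      expect_equal(cl$p_down, orc$p_down, tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d (lower)", n, rep))
    }
  }
})

test_that("tie-free locus p-values agree with the exact Wilcoxon signed-rank test", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(11)
    cl <- call_locus(x)
    ref_up <- stats::wilcox.test(x, alternative = "greater",
                                 exact = TRUE)$p.value
    ref_down <- stats::wilcox.test(x, alternative = "less",
                                   exact = TRUE)$p.value
    expect_equal(cl$p_up, ref_up, tolerance = 1e-12)
    expect_equal(cl$p_down, ref_down, tolerance = 1e-12)
  }
})

test_that("locus calling handles the degenerate and boundary cases", {
  up <- call_locus(rep(1, 11))
  expect_equal(up$p_up, 1 / 2048, tolerance = 1e-12)
  expect_identical(up$status, "positive")
  expect_equal(up$log2_ratio, 1)

  down <- call_locus(rep(-1, 11))
  expect_equal(down$p_down, 1 / 2048, tolerance = 1e-12)
  expect_identical(down$status, "negative")

  expect_identical(call_locus(rep(0, 11))$status, "not_significant")
  expect_error(call_locus(c(1, 2, 3)), "at least 5")
})

test_that("track calling preserves locus metadata, sorts, and rejects duplicates", {
  pt <- make_probe_table(c(1.5, 0, -1.5), sd = 0.01, seed = 5)
  pt <- pt[rev(seq_len(nrow(pt))), ] # shuffled input still sorts
  tr <- call_track(pt, factor_label = "A")
  expect_s3_class(tr, "binding_track")
  expect_identical(tr$status, c("positive", "not_significant", "negative"))
  expect_identical(tr$start, c(0L, 300L, 600L))
  expect_true(all(tr$resolution == 300L))
  expect_identical(attr(tr, "factor_label"), "A")

  expect_identical(nrow(call_track(pt[0, ])), 0L)

  dup <- pt
  dup$locus_id <- "same"
  expect_error(call_track(dup), "duplicate locus ids")
})

test_that("track calling recovers a planted landscape with high sensitivity", {
  cs <- data.frame(chrom = "c1", length = 300L * 2000L)
  sim <- simulate_tiling(tiling_sim_config(cs, bound_fraction_a = 0.3,
                                           effect_log2 = 1.5, noise_sd = 0.5,
                                           seed = 31L))
  tr <- call_track(sim$probes_a)
  called <- tr$locus_id[tr$status == "positive"]
  sens <- mean(sim$truth$a %in% called)
  expect_gt(sens, 0.95)
})

test_that("clusters are maximal runs of contiguous positive loci, at least two long", {
  # positives at grid indices 5,6,7 and an isolated one at 12
  status <- rep(FALSE, 15)
  status[c(5, 6, 7, 12)] <- TRUE
  tr <- make_track(status, log2 = seq(0.1, 1.5, length.out = 15))
  cl <- find_clusters(tr)
  expect_identical(nrow(cl), 1L)
  expect_equal(cl$start, 4L * 300L)
  expect_equal(cl$end, 7L * 300L)
  expect_identical(cl$n_loci, 3L)
  expect_equal(cl$peak_log2, max(tr$log2_ratio[5:7]))

  expect_identical(nrow(find_clusters(make_track(rep(FALSE, 6)))), 0L)

  # runs do not merge across chromosomes or across grid gaps
  tr2 <- make_track(c(TRUE, TRUE), chrom = c("c1", "c2"))
  expect_identical(nrow(find_clusters(tr2)), 0L)
  tr3 <- make_track(rep(TRUE, 3))
  tr3$start[3] <- tr3$start[3] + 600L # gap before third locus
  tr3$end[3] <- tr3$end[3] + 600L
  cl3 <- find_clusters(tr3)
  expect_identical(cl3$n_loci, 2L)
})

test_that("top peaks rank clusters by peak signal and apply the log-ratio floor", {
  status <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  log2 <- c(1.2, 1.0, 0, 0.9, 0.7, 0, 0.5, 0.6)
  tr <- make_track(status, log2 = log2)
  pk <- top_peaks(tr, k = 1)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$peak_log2, 1.2)
  pk2 <- top_peaks(tr, k = 10)
  expect_equal(pk2$peak_log2, c(1.2, 0.9)) # 0.6-peak cluster fails > 0.8
  expect_identical(nrow(top_peaks(make_track(rep(FALSE, 4)))), 0L)
})

test_that("coincidence counts are conserved and percentages recompute from the counts", {
  a <- make_track(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                  chrom = rep(c("c1", "c2"), each = 3))
  b <- make_track(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
                  chrom = rep(c("c1", "c2"), each = 3))
  ct <- coincidence_table(a, b)
  tot <- ct[ct$chrom == "Total", ]
  per <- ct[ct$chrom != "Total", ]
  expect_equal(tot$detectable, sum(per$detectable))
  expect_equal(tot$a_positive, sum(per$a_positive))
  expect_equal(tot$a_and_b, sum(per$a_and_b))
  expect_true(all(ct$a_and_b <= ct$a_positive))
  expect_true(all(ct$a_positive <= ct$detectable))
  expect_equal(ct$a_positive_pct,
               as.integer(floor(100 * ct$a_positive / ct$detectable + 0.5)))
  expect_equal(tot$a_and_b_pct,
               as.integer(floor(100 * tot$a_and_b / tot$a_positive + 0.5)))

  expect_equal(coincidence_table(a, a)$a_and_b_pct[3], 100L)
  disjoint <- make_track(c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
                         chrom = rep(c("c1", "c2"), each = 3))
  expect_equal(coincidence_table(a, disjoint)$a_and_b_pct[3], 0L)

  shifted <- make_track(rep(TRUE, 6), chrom = rep(c("c1", "c2"), each = 3),
                        start0 = 100L)
  expect_error(coincidence_table(a, shifted), "shared locus grid")
})

test_that("100-bp loci map into their containing 300-bp locus before comparison", {
  a <- make_track(c(TRUE, FALSE), size = 300L) # [0,300) positive
  b100 <- make_track(c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE), size = 100L)
  ct <- coincidence_table(a, b100)
  tot <- ct[ct$chrom == "Total", ]
  expect_equal(tot$detectable, 2L)
  # b's positive 100-bp locus [100,200) lands in a's positive [0,300)
  expect_equal(tot$a_and_b, 1L)
})

test_that("track correlation is perfect on self and restricted to the stated subset", {
  set.seed(99)
  a <- make_track(sample(c(TRUE, FALSE), 50, replace = TRUE),
                  log2 = rnorm(50))
  expect_equal(correlate_tracks(a, a)$spearman_rho, 1.0)
  expect_identical(nrow(correlate_tracks(a, a, subset = "a_positive")$pairs),
                   sum(a$status == "positive"))
  none <- make_track(rep(FALSE, 50), log2 = rnorm(50))
  expect_error(correlate_tracks(none, a, subset = "a_positive"), "empty")
})

test_that("track correlation is near zero for independent tracks and positive under planted overlap", {
  cs <- data.frame(chrom = "c1", length = 300L * 3000L)
  sim <- simulate_tiling(tiling_sim_config(cs, bound_fraction_a = 0.3,
                                           cond_overlap_b_given_a = 0.3,
                                           marginal_b = 0.3, seed = 55L))
  ta <- call_track(sim$probes_a)
  tb <- call_track(sim$probes_b)
  # under conditional overlap equal to the marginal, B is independent of A
  rho_null <- correlate_tracks(ta, tb, subset = "all")$spearman_rho
  expect_lt(abs(rho_null), 3 / sqrt(nrow(ta)))

  sim2 <- simulate_tiling(tiling_sim_config(cs, bound_fraction_a = 0.3,
                                            cond_overlap_b_given_a = 0.76,
                                            seed = 56L))
  rho <- correlate_tracks(call_track(sim2$probes_a),
                          call_track(sim2$probes_b))$spearman_rho
  expect_gt(rho, 0.1)
})

test_that("subtelomere zones count positive loci intersecting the terminal 10 kb", {
  cs <- data.frame(chrom = "c1", length = 200000L)
  # positive at [0,300) and one centred locus
  n <- 200000L %/% 300L
  status <- rep(FALSE, n)
  status[c(1, 333)] <- TRUE # locus 333 starts at 99600, mid-chromosome
  tr <- make_track(status, chrom = "c1")
  rep_ <- subtelomere_presence(tr, cs)
  left <- rep_[rep_$end_side == "left", ]
  right <- rep_[rep_$end_side == "right", ]
  expect_equal(left$positive_loci, 1L)
  expect_equal(right$positive_loci, 0L)
  expect_error(subtelomere_presence(tr, data.frame(chrom = "cX",
                                                   length = 1e6)),
               "absent from sizes")
})

test_that("planted subtelomeric positives are all recovered", {
  cs <- data.frame(chrom = "c1", length = 120000L)
  n <- 120000L %/% 300L
  means <- rep(0, n)
  sub_idx <- c(2, 10, n - 5, n) # inside the terminal 10 kb on each side
  means[sub_idx] <- 2
  pt <- make_probe_table(means, sd = 0.3, chrom = "c1", seed = 8)
  tr <- call_track(pt)
  rep_ <- subtelomere_presence(tr, cs)
  expect_equal(sum(rep_$positive_loci), length(sub_idx))
})

test_that("genomic context labels follow divergent > promoter > ORF precedence", {
  # layout on one chromosome:
  #   gA: [1000,2000) on '-'  and gB: [2600,3600) on '+'  (divergent pair,
  #   intergenic [2000,2600)); gC: [10000,12000) on '+'
  genes <- make_genes("c1", c(1000, 2600, 10000), c(2000, 3600, 12000),
                      c("-", "+", "+"))
  tr <- make_track(rep(TRUE, 4), chrom = "c1")
  tr$start <- c(2100L, 9700L, 10500L, 20000L)
  tr$end <- tr$start + 300L
  tr$locus_id <- paste0("c1:", tr$start)
  out <- classify_context(tr, genes)
  expect_identical(out$context, c("divergent_promoter", "single_promoter",
                                  "ORF_internal", "intergenic_other"))
  bad <- genes
  bad$strand[2] <- "*"
  expect_error(classify_context(tr, bad), "strandless")
})
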