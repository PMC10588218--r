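test_that("size factors follow the median-of-ratios convention", {
  set.seed(131)
  m <- matrix(rpois(400, 50), 100, 4)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(size_factors(same)), c(1, 1, 1))

  scaled <- cbind(a = m[, 1], b = m[, 1] * 2L)
  sf <- size_factors(scaled)
  expect_equal(unname(sf[2] / sf[1]), 2)

  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "nonzero")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(137)
  m <- matrix(rnbinom(300 * 6, mu = 80, size = 10), 300, 6)
  m[, 4:6] <- matrix(rnbinom(300 * 3, mu = 240, size = 10), 300, 3)
  got <- unname(size_factors(m))
  want <- unname(DESeq2::estimateSizeFactorsForMatrix(m))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("enrichment test recovers planted targets and stays finite", {
  g <- gen_counts(count_sim_params(n_genes = 800, dispersion = 0.05,
                                   enriched_set = 1:60,
                                   enriched_log2fc = 3, seed = 139))
  et <- enrichment_test(g$counts, g$condition)
  cand <- candidate_filter(et)
  expect_gte(mean(sprintf("gene%05d", 1:60) %in% cand), 0.95)
  expect_lte(sum(!cand %in% sprintf("gene%05d", 1:60)), 3)

  # zero-input gene stays finite through the pseudo-count
  cz <- g$counts
  cz[5, g$condition == "input"] <- 0L
  etz <- enrichment_test(cz, g$condition)
  expect_true(is.finite(etz$log2FC[5]))

  # all-zero gene is excluded from testing with a message
  cz[7, ] <- 0L
  expect_message(etz2 <- enrichment_test(cz, g$condition), "all-zero")
  expect_false(etz2$tested[7])
  expect_true(is.na(etz2$p[7]))

  expect_error(enrichment_test(g$counts[, c(1, 4, 5, 6)],
                               g$condition[c(1, 4, 5, 6)]),
               "two replicates")
})

test_that("YFP subtraction is exact, flag-aware and order-independent", {
  tdp <- data.frame(gene_id = c("g1", "g2", "g3"),
                    log2FC = c(2.5, 1.2, 0.4))
  expect_equal(yfp_subtract(tdp, tdp)$adjusted_log2FC, c(0, 0, 0))

  yfp <- data.frame(gene_id = c("g2", "g1"), log2FC = c(0.2, 1.0))
  out <- yfp_subtract(tdp, yfp)
  expect_equal(out$adjusted_log2FC, c(1.5, 1.0, 0.4))
  expect_equal(out$yfp_missing, c(FALSE, FALSE, TRUE))
  expect_equal(out$yfp_log2FC[3], 0)
})

test_that("candidate filter is strict at the printed thresholds and monotone", {
  rec <- data.frame(gene_id = c("at", "above", "sig_padj", "good"),
                    log2FC = c(1, 1.5, 2, 2),
                    padj = c(0.01, 0.01, 0.05, 0.049))
  got <- candidate_filter(rec)
  expect_false("at" %in% got)        # log2FC exactly 1 excluded
  expect_false("sig_padj" %in% got)  # padj exactly 0.05 excluded
  expect_setequal(got, c("above", "good"))
  expect_length(candidate_filter(rec[0, ]), 0L)

  set.seed(149)
  rec2 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     log2FC = rnorm(200, 1, 1),
                     padj = runif(200))
  for (th in c(0.5, 1, 1.5, 2)) {
    lo <- candidate_filter(rec2, log2fc_min = th)
    hi <- candidate_filter(rec2, log2fc_min = th + 0.5)
    expect_true(all(hi %in% lo))
  }
})

test_that("overlap bookkeeping is exact set algebra", {
  rep1 <- overlap_report(c("a", "b", "c"), c("c", "d"))
  expect_equal(rep1$shared, 1)
  expect_equal(rep1$union, 4)

  dis <- overlap_report(c("a", "b"), c("c", "d"))
  expect_equal(dis$shared, 0)
  expect_equal(dis$union, dis$size_a + dis$size_b)

  sub <- overlap_report(c("a", "b"), c("a", "b", "c"))
  expect_equal(sub$unique_a, 0)

  set.seed(151)
  for (i in 1:300) {
    a <- sample(letters, sample(1:20, 1))
    b <- sample(letters, sample(1:20, 1))
    r <- overlap_report(a, b)
    expect_lte(r$shared, min(r$size_a, r$size_b))
    expect_equal(r$union, r$size_a + r$size_b - r$shared)
    expect_equal(r$unique_a, r$size_a - r$shared)
    expect_equal(r$unique_b, r$size_b - r$shared)
    expect_equal(r$pct_shared_of_a, 100 * r$shared / r$size_a)
  }
  expect_error(overlap_report(10, 20, shared = 15), "exceed")
})

test_that("delta-delta-Ct identities hold exactly", {
  flat <- ddct_fold_change(20, 18, 22, 20)
  expect_equal(flat$delta_delta_ct, 0)
  expect_equal(flat$fold_change, 1)

  up <- ddct_fold_change(19, 18, 22, 20)  # ddCt = -1
  expect_equal(up$fold_change, 2)

  # triplicate wells are averaged before differencing
  trip <- ddct_fold_change(c(19.8, 20.0, 20.2), c(18.1, 17.9, 18.0),
                           c(22.0, 21.9, 22.1), 20)
  expect_equal(trip$delta_ct_ip, 2)
  expect_equal(trip$delta_delta_ct, 0)

  # multiplicativity and exact log identity
  set.seed(157)
  for (i in 1:20) {
    d1 <- runif(1, -3, 3); d2 <- runif(1, -3, 3)
    f1 <- ddct_fold_change(20 + d1, 20, 20, 20)$fold_change
    f2 <- ddct_fold_change(20 + d2, 20, 20, 20)$fold_change
    f12 <- ddct_fold_change(20 + d1 + d2, 20, 20, 20)$fold_change
    expect_equal(f12, f1 * f2)
    expect_equal(log2(f1), -d1)
  }
  expect_error(ddct_fold_change(Inf, 20, 20, 20), "finite")
})

test_that("ortholog joins preserve multiplicity and unmapped genes", {
  fly <- data.frame(gene_id = c("dlp", "futsch", "orphan"),
                    log2FC = c(2, 1.8, 1.2))
  map <- data.frame(fly_id = c("dlp", "dlp", "futsch"),
                    human_id = c("GPC6", "GPC4", "MAP1B"),
                    score = c(11, 4, 9))
  expect_message(j <- ortholog_join(fly, map), "multiple orthologs")
  expect_equal(nrow(j), 4L)
  expect_true(is.na(j$human_id[j$gene_id == "orphan"]))

  best <- suppressMessages(ortholog_join(fly, map, best_score_only = TRUE))
  expect_equal(best$human_id[best$gene_id == "dlp"], "GPC6")

  one <- data.frame(fly_id = "futsch", human_id = "MAP1B", score = 9)
  rt <- ortholog_join(fly[2, , drop = FALSE], one)
  expect_equal(rt$human_id, "MAP1B")
  expect_equal(nrow(rt), 1L)
})

test_that("cryptic-vs-canonical comparison is signed, calibrated and powered", {
  d0 <- data.frame(group = rep(c("cryptic", "canonical"), each = 5),
                   expr = rep(c(1, 2, 3, 4, 5), 2))
  r0 <- cryptic_group_compare(d0)
  expect_equal(r0$test$statistic, 0)
  expect_equal(r0$test$p_value, 1)

  d1 <- gen_nucleus_expression(seed = 163)
  r1 <- cryptic_group_compare(d1)
  d1s <- d1[order(d1$group != "canonical"), ]  # canonical appears first
  r2 <- cryptic_group_compare(d1s)
  expect_equal(r2$test$statistic, -r1$test$statistic)
  expect_equal(r2$test$p_value, r1$test$p_value)

  # power >= 0.8 at the study group sizes for a 0.3 shift, sd 0.8
  hits <- vapply(1:100, function(s) {
    d <- gen_nucleus_expression(mean_cryptic = 1.65, mean_canonical = 1.35,
                                sd = 0.8, seed = 5000 + s)
    cryptic_group_compare(d)$test$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)

  expect_error(cryptic_group_compare(data.frame(group = "cryptic",
                                                expr = 1)), "two groups")
})
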