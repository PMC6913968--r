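test_that("length filter keeps the inclusive 313-319 window", {
  seqs <- vapply(c(312, 313, 316, 319, 320), function(n)
    paste(rep("A", n), collapse = ""), character(1))
  kept <- filterByLength(seqs)
  expect_equal(nchar(kept), c(313, 316, 319))
  expect_length(filterByLength(character(0)), 0)
  ## exhaustive check against the inclusive-window predicate
  set.seed(1)
  lens <- sample(300:330, 1000, replace = TRUE)
  rnd <- vapply(lens, function(n) paste(rep("T", n), collapse = ""),
                character(1))
  expect_equal(length(filterByLength(rnd)), sum(lens >= 313 & lens <= 319))
})

test_that("length filter works on DNAStringSet input", {
  ss <- Biostrings::DNAStringSet(c(paste(rep("A", 312), collapse = ""),
                                   paste(rep("A", 316), collapse = "")))
  expect_equal(length(filterByLength(ss)), 1L)
})

test_that("dereplication groups exact duplicates and drops singletons", {
  d <- dereplicate(c("AAA", "AAA", "CCC"))
  expect_equal(d, data.frame(sequence = "AAA", abundance = 2L))
  expect_equal(nrow(dereplicate(c("A", "C", "G"))), 0L)
  ## random multiset vs counting oracle, with stable ordering
  set.seed(2)
  pool <- randomDNA(8, len = 20)
  s <- sample(pool, 400, replace = TRUE)
  d <- dereplicate(s)
  tab <- table(s)
  expect_equal(sort(d$abundance, decreasing = TRUE), d$abundance)
  for (i in seq_len(nrow(d)))
    expect_equal(d$abundance[i], unname(tab[d$sequence[i]]))
  ## ties broken by first occurrence
  d2 <- dereplicate(c("GG", "TT", "GG", "TT"))
  expect_equal(d2$sequence, c("GG", "TT"))
})

test_that("greedy clustering follows identity arithmetic", {
  s <- paste(rep("ACGT", 79), collapse = "")  # 316 bp
  expect_equal(nrow(greedyCluster(
    data.frame(sequence = c(s, s), abundance = c(5L, 3L)))$centroids), 1L)
  ## 10 substitutions in 316 bp: identity 306/316 = 96.8% < 98% -> two MOTUs
  set.seed(3)
  s10 <- mutateSeq(s, 10)
  cl <- greedyCluster(data.frame(sequence = c(s, s10),
                                 abundance = c(5L, 3L)))
  expect_equal(nrow(cl$centroids), 2L)
  ## 4 substitutions: 312/316 = 98.7% -> joins the centroid
  s4 <- mutateSeq(s, 4)
  cl2 <- greedyCluster(data.frame(sequence = c(s, s4),
                                  abundance = c(5L, 3L)))
  expect_equal(nrow(cl2$centroids), 1L)
  expect_equal(cl2$centroids$abundance, 8L)
})

test_that("greedy clustering matches an independent implementation", {
  set.seed(4)
  for (rep in 1:5) {
    base <- randomDNA(3, len = 120)
    seqs <- c(base, vapply(sample(base, 12, replace = TRUE), function(b)
      mutateSeq(b, sample(0:6, 1)), character(1)))
    ab <- sort(sample(2:50, length(seqs)), decreasing = TRUE)
    derep <- data.frame(sequence = seqs, abundance = ab)
    got <- greedyCluster(derep)
    expect_equal(got$clusters$motu, greedyOracle(seqs, 0.98))
  }
})

test_that("cluster count does not increase when identity is relaxed", {
  set.seed(5)
  base <- randomDNA(2, len = 100)
  seqs <- c(base, vapply(sample(base, 10, replace = TRUE), function(b)
    mutateSeq(b, sample(0:5, 1)), character(1)))
  derep <- data.frame(sequence = seqs,
                      abundance = seq(2 * length(seqs), 2, by = -2))
  n98 <- nrow(greedyCluster(derep, qcConfig(cluster_identity = 0.98))$centroids)
  n95 <- nrow(greedyCluster(derep, qcConfig(cluster_identity = 0.95))$centroids)
  expect_lte(n95, n98)
})

test_that("contamination threshold is the maximum offending relative abundance", {
  cnt <- matrix(0L, 3, 3,
                dimnames = list(c("aic", "m1", "m2"),
                                c("S1_r1", "S2_r1", "C1_r1")))
  cnt["m1", 1:2] <- c(39991L, 20000L)
  cnt["aic", 1] <- 9L              # 9 / 40000 in a regular replicate
  cnt["aic", 3] <- 30000L
  me <- makeMe(cnt, isControl = c(FALSE, FALSE, TRUE))
  expect_equal(contaminationThreshold(me), 9 / 40000)
  ## clean table -> 0
  cnt2 <- cnt; cnt2["aic", 1] <- 0L
  expect_equal(contaminationThreshold(makeMe(cnt2, isControl = c(FALSE, FALSE, TRUE))), 0)
  ## no controls -> error
  expect_error(contaminationThreshold(makeMe(cnt)), "control")
})

test_that("contamination threshold equals the max-scan oracle under random injections", {
  set.seed(6)
  for (rep in 1:25) {
    n <- 12; k <- 8
    cnt <- matrix(rpois(n * k, 500), n, k)
    ctrl <- c(rep(FALSE, k - 2), TRUE, TRUE)
    aic <- c(TRUE, rep(FALSE, n - 1))
    cnt[1, !ctrl] <- rbinom(sum(!ctrl), 1, 0.5) * sample(0:20, sum(!ctrl), TRUE)
    cnt[1, ctrl] <- sample(4000:9000, sum(ctrl))
    cnt[-1, ctrl] <- rbinom((n - 1) * sum(ctrl), 1, 0.1) *
      sample(0:15, (n - 1) * sum(ctrl), TRUE)
    dimnames(cnt) <- list(sprintf("m%02d", 1:n),
                          sprintf("S%02d_r1", 1:k))
    me <- makeMe(cnt, isControl = ctrl, isAic = aic)
    t <- contaminationThreshold(me)
    expect_equal(t, thresholdOracle(cnt, ctrl, aic))
    ## filtering at the derived threshold removes all cross-contamination
    f <- motuCounts(filterLowAbundance(me, t))
    expect_true(all(f[aic, !ctrl] == 0))
    expect_true(all(f[!aic, ctrl] == 0))
  }
})

test_that("abundance filter removes at-threshold MOTUs and keeps strictly-above", {
  cnt <- matrix(c(10L, 11L, 39979L), 3, 1,
                dimnames = list(c("m1", "m2", "m3"), "S1_r1"))
  me <- makeMe(cnt, isAic = rep(FALSE, 3))
  f <- motuCounts(filterLowAbundance(me, 0.00025))
  expect_equal(unname(f[, 1]), c(0L, 11L, 39979L))
  ## threshold 0 leaves every positive count in place
  f0 <- motuCounts(filterLowAbundance(me, 0))
  expect_equal(f0, cnt)
})

test_that("abundance filter equals the element-wise oracle with pre-filter totals", {
  set.seed(8)
  for (rep in 1:10) {
    cnt <- matrix(rpois(60, 40), 10, 6,
                  dimnames = list(sprintf("m%02d", 1:10),
                                  sprintf("S%d_r1", 1:6)))
    thr <- runif(1, 0, 0.2)
    me <- makeMe(cnt, isAic = rep(FALSE, 10))
    f <- motuCounts(filterLowAbundance(me, thr))
    tot <- colSums(cnt)
    exp <- cnt
    for (j in 1:6) exp[cnt[, j] / tot[j] <= thr, j] <- 0L
    expect_equal(f, exp)
  }
})

test_that("shallow replicates are discarded and survivors combined additively", {
  cnt <- matrix(0L, 3, 3,
                dimnames = list(c("m1", "m2", "m3"),
                                c("L1_A_r1", "L1_A_r2", "L2_A_r1")))
  cnt[, 1] <- c(4000L, 100L, 0L)
  cnt[, 2] <- c(3000L, 5L, 7L)     # 3012 reads < 4000 -> discarded
  cnt[, 3] <- c(3999L, 0L, 0L)     # 3999 < 4000 -> sample L2_A fails
  me <- makeMe(cnt, isAic = rep(FALSE, 3),
               sample = c("L1_A", "L1_A", "L2_A"))
  out <- discardAndCombine(me)
  expect_equal(colnames(motuCounts(out)), "L1_A")
  expect_equal(unname(motuCounts(out)[, 1]), c(4000L, 100L, 0L))
  expect_equal(S4Vectors::metadata(out)$failed$sample, "L2_A")
  ## at exactly 4000 reads the replicate is retained
  cnt[, 3] <- c(4000L, 0L, 0L)
  out2 <- discardAndCombine(makeMe(cnt, isAic = rep(FALSE, 3),
                                   sample = c("L1_A", "L1_A", "L2_A")))
  expect_true("L2_A" %in% colnames(motuCounts(out2)))
})

test_that("additive combination unions MOTUs and sums reads", {
  cnt <- matrix(c(5000L, 100L, 0L,
                  4200L, 0L, 70L), 3, 2,
                dimnames = list(c("m1", "m2", "m3"), c("L1_A_r1", "L1_A_r2")))
  out <- discardAndCombine(makeMe(cnt, isAic = rep(FALSE, 3)))
  expect_equal(unname(motuCounts(out)[, "L1_A"]), c(9200L, 100L, 70L))
  ## merging conserves the total reads of surviving replicates
  expect_equal(sum(motuCounts(out)), sum(cnt))
})

test_that("rarefaction subsamples without replacement, deterministically", {
  x <- c(a = 3L, b = 1L)
  expect_equal(rarefyCounts(x, 4, seed = 1), x)
  expect_error(rarefyCounts(x, 5, seed = 1), "depth")
  r1 <- rarefyCounts(c(a = 100L, b = 40L, c = 5L), 50, seed = 9)
  r2 <- rarefyCounts(c(a = 100L, b = 40L, c = 5L), 50, seed = 9)
  expect_identical(r1, r2)
  expect_equal(sum(r1), 50L)
  ## hypergeometric expectation: from {a:3, b:1} draw 2 -> E[a] = 1.5
  draws <- vapply(1:400, function(s) rarefyCounts(x, 2, seed = s)[["a"]],
                  numeric(1))
  expect_equal(mean(draws), 1.5, tolerance = 0.05)
  ## richness never increases
  y <- c(a = 500L, b = 30L, c = 2L, d = 1L)
  for (s in 1:20)
    expect_lte(sum(rarefyCounts(y, 40, seed = s) > 0), sum(y > 0))
})
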