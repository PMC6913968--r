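tree <- makeTestTree()
allSp <- tree@lineage$name[tree@lineage$rank == "species"]
refdb <- allSp  # full coverage unless a test narrows it

test_that("the six categories classify the worked examples", {
  m1 <- data.frame(taxon = "Genus01 sp1")
  expect_equal(classifyComparison(m1, m1, refdb, tree)$category, "found")
  ## cross-rank lineage match
  e2 <- classifyComparison(data.frame(taxon = "Genus01 sp1"),
                           data.frame(taxon = "Genus01"), refdb, tree)
  expect_equal(e2$category, "different_level")
  ## congeneric pair = putative misidentification
  e3 <- classifyComparison(data.frame(taxon = "Genus01 sp1"),
                           data.frame(taxon = "Genus01 sp2"), refdb, tree)
  expect_equal(e3$category, "putative_misid")
  ## morphology species without reference coverage
  e4 <- classifyComparison(data.frame(taxon = "Genus05 sp1"),
                           data.frame(taxon = character(0)),
                           setdiff(refdb, "Genus05 sp1"), tree)
  expect_equal(e4$category, "missing_in_reference")
  ## covered but not recovered / DNA-only
  e5 <- classifyComparison(data.frame(taxon = "Genus05 sp1"),
                           data.frame(taxon = "Genus06 sp1"), refdb, tree)
  expect_setequal(e5$category, c("not_found", "extra"))
  expect_error(classifyComparison(data.frame(taxon = "Nullius nomen"),
                                  m1, refdb, tree), "unmatched")
})

test_that("exact matches are consumed before cross-rank and congeneric pairing", {
  m <- data.frame(taxon = c("Genus01 sp1", "Genus01 sp2"))
  d <- data.frame(taxon = c("Genus01 sp1", "Genus01"))
  e <- classifyComparison(m, d, refdb, tree)
  expect_equal(e$category[e$taxon_morph == "Genus01 sp1"], "found")
  expect_equal(e$category[e$taxon_morph == "Genus01 sp2"], "different_level")
})

test_that("a species complex containing the morphology species counts as found", {
  e <- classifyComparison(data.frame(taxon = "Genus01 sp1"),
                          data.frame(taxon = "Genus01 sp1/Genus01 sp2"),
                          refdb, tree)
  expect_equal(e$category, "found")
})

test_that("classification partitions random lists and fractions sum to one", {
  set.seed(12)
  gens <- unique(sub(" .*", "", allSp))
  for (rep in 1:40) {
    m <- data.frame(taxon = sample(c(allSp, gens), sample(1:12, 1)))
    m <- m[!duplicated(m$taxon), , drop = FALSE]
    d <- data.frame(taxon = sample(c(allSp, gens), sample(1:12, 1)))
    d <- d[!duplicated(d$taxon), , drop = FALSE]
    m <- removeRedundant(tree, m); d <- removeRedundant(tree, d)
    cov <- sample(allSp, length(allSp) * 0.8)
    e <- classifyComparison(m, d, cov, tree)
    ## partition: every occurrence appears exactly once
    expect_setequal(stats::na.omit(e$taxon_morph), m$taxon)
    expect_setequal(stats::na.omit(e$taxon_dna), d$taxon)
    expect_equal(sum(!is.na(e$taxon_morph)), nrow(m))
    expect_equal(sum(!is.na(e$taxon_dna)), nrow(d))
    fr <- overlapFractions(e)
    expect_equal(fr$overlap + fr$morph_only + fr$dna_only, 1,
                 tolerance = 1e-9)
    ## permutation invariance of the category counts
    e2 <- classifyComparison(m[rev(seq_len(nrow(m))), , drop = FALSE],
                             d[rev(seq_len(nrow(d))), , drop = FALSE],
                             cov, tree)
    expect_equal(table(e$category), table(e2$category))
  }
})

test_that("overlap fractions group categories as in the field convention", {
  e <- data.frame(taxon_morph = NA, taxon_dna = NA,
                  category = rep(c("found", "different_level",
                                   "putative_misid", "missing_in_reference",
                                   "not_found", "extra"),
                                 c(4, 2, 1, 1, 1, 1)))
  fr <- overlapFractions(e)
  expect_equal(fr$overlap, 0.7)
  expect_equal(fr$morph_only, 0.2)
  expect_equal(fr$dna_only, 0.1)
  expect_true(all(unlist(overlapFractions(e[e$category == "found", ])[
    c("overlap", "morph_only", "dna_only")]) == c(1, 0, 0)))
  expect_true(is.na(overlapFractions(e[0, ])$overlap))
})

test_that("failed-sample exclusion removes the affected morphology entries", {
  morph <- data.frame(location = c("L1", "L1", "L2"),
                      group = c("MOLL", "CRUS", "MOLL"),
                      taxon = c("Genus01 sp1", "Genus02 sp1", "Genus03 sp1"))
  failed <- data.frame(location = "L1", group = "MOLL")
  kept <- excludeFailed(morph, failed)
  expect_equal(nrow(kept), 2L)
  expect_false(any(kept$location == "L1" & kept$group == "MOLL"))
  expect_equal(unname(attr(kept, "removed")["MOLL"]), 1L)
  expect_identical(excludeFailed(morph, failed[0, ]), morph)
})

test_that("summaries average per-unit fractions unweighted", {
  fr <- data.frame(unit = c("a", "b"), group = c("CRUS", "CRUS"),
                   overlap = c(0.4, 0.6), morph_only = c(0.5, 0.2),
                   dna_only = c(0.1, 0.2))
  s <- summarizeComparison(fr)
  expect_equal(unname(s$overall$overlap["mean"]), 0.5)
  expect_equal(unname(s$overall$overlap[c("min", "max")]), c(0.4, 0.6))
  expect_equal(s$per_group$overlap, 0.5)
  expect_equal(s$counts$dna_gt_morph, 0L)
  s1 <- summarizeComparison(fr[1, ])
  expect_equal(unname(s1$overall$overlap["mean"]), 0.4)
})

test_that("richness statistics match the closed-form definitions", {
  expect_equal(richnessStats(1:5, 2 * (1:5))$r, 1)
  rs <- richnessStats(c(1, 2, 3), c(2, 4, 6))
  expect_equal(rs$mean_ratio, 2)
  expect_equal(rs$ratio_of_means, 2)
  ## textbook-formula oracle
  set.seed(13)
  for (rep in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    rr <- richnessStats(x, y)$r
    mx <- mean(x); my <- mean(y)
    oracle <- sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
    expect_equal(rr, oracle, tolerance = 1e-12)
  }
  expect_true(is.na(richnessStats(rep(3, 5), 1:5)$r))
})

test_that("within-overlap shares are the fractions of the three match kinds", {
  sh <- withinOverlapShares(c(found = 3, different_level = 1,
                              putative_misid = 1))
  expect_equal(unname(sh), c(0.6, 0.2, 0.2))
})
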