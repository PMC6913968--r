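tree <- makeTestTree()

hit <- function(motu = "m1", taxon = "Genus01 sp1", rank = "species",
                pident = 99.5, qcovs = 100, bitscore = 570,
                db = "wfd_custom", lineage = "") {
  data.frame(motu = motu, taxon = taxon, rank = rank, pident = pident,
             qcovs = qcovs, bitscore = bitscore, db = db, lineage = lineage,
             stringsAsFactors = FALSE)
}

test_that("direct hits require identity strictly above 98 at full coverage", {
  h <- rbind(hit(pident = 98.0), hit(taxon = "Genus01 sp2", pident = 99.1),
             hit(taxon = "Genus01 sp3", pident = 99.5, qcovs = 98),
             hit(taxon = "Genus02 sp1", pident = 99.9, db = "genbank"))
  expect_equal(findDirectHits(h), "Genus01 sp2")
  ## predicate-scan oracle on random tables
  set.seed(10)
  for (rep in 1:20) {
    h <- hit(taxon = sprintf("T%02d", 1:30),
             pident = round(runif(30, 95, 100), 1),
             qcovs = sample(c(100, 99, 100, 100), 30, replace = TRUE))
    expect_setequal(findDirectHits(h),
                    unique(h$taxon[h$pident > 98 & h$qcovs == 100]))
  }
})

test_that("resolution rules fire in order on direct-hit names", {
  ## rule 1: non-register species dropped
  r <- resolveDirect(c("Genus01 sp1", "Genus03 exoticus"), hit(), tree)
  expect_equal(r$taxa$name, "Genus01 sp1")
  expect_true(1L %in% r$rules)
  ## rule 2 + dedup: synonym and its canonical collapse to one taxon
  r2 <- resolveDirect(c("Vetus nomen", "Genus01 sp1"), hit(), tree)
  expect_equal(r2$taxa$name, "Genus01 sp1")
  expect_true(2L %in% r2$rules)
  ## rule 3: subspecies set to species level
  r3 <- resolveDirect("Genus02 sp1 minor", hit(), tree)
  expect_equal(r3$taxa, data.frame(name = "Genus02 sp1", rank = "species"))
  expect_true(3L %in% r3$rules)
  ## rule 4: genus-level name loses to conspecific species-level name
  r4 <- resolveDirect(c("Genus01", "Genus01 sp1"), hit(), tree)
  expect_equal(r4$taxa$name, "Genus01 sp1")
  expect_true(4L %in% r4$rules)
  ## rule 5: blocklist
  r5 <- resolveDirect(c("Genus01 sp1", "Genus01 sp2"), hit(),
                      tree, resolutionConfig(blocklist = "Genus01 sp2"))
  expect_equal(r5$taxa$name, "Genus01 sp1")
  expect_true(5L %in% r5$rules)
})

test_that("consistency margin separates rules 6 and 7", {
  h <- rbind(hit(taxon = "Genus01 sp1", pident = 99.8),
             hit(taxon = "Genus01 sp2", pident = 98.4))
  names2 <- c("Genus01 sp1", "Genus01 sp2")
  r6 <- resolveDirect(names2, h, tree, resolutionConfig(consistency_margin = 1))
  expect_equal(r6$taxa$name, "Genus01 sp1")
  expect_true(6L %in% r6$rules)
  ## margin 2 > 1.4 difference: both retained as a species complex
  r7 <- resolveDirect(names2, h, tree, resolutionConfig(consistency_margin = 2))
  expect_setequal(r7$taxa$name, names2)
  expect_true(7L %in% r7$rules)
})

test_that("LCA assignment applies the top-percent band and the genus cap", {
  h <- rbind(hit(taxon = "Genus01 sp1", pident = 92, bitscore = 400),
             hit(taxon = "Genus01 sp2", pident = 91, bitscore = 392),
             hit(taxon = "Genus02 sp1", pident = 85, bitscore = 310))
  ## candidates are those with bit-score >= 0.95 * 400 = 380 -> one genus
  expect_equal(lcaAssign(h, tree), list(name = "Genus01", rank = "genus"))
  ## bit-score 170 itself fails the strict > 170 filter
  expect_null(lcaAssign(hit(pident = 92, bitscore = 170), tree))
  expect_equal(lcaAssign(hit(pident = 92, bitscore = 171), tree)$rank,
               "genus")
  ## a single-species candidate set is capped at genus
  expect_equal(lcaAssign(hit(pident = 92, bitscore = 400), tree),
               list(name = "Genus01", rank = "genus"))
  ## identity / coverage minima
  expect_null(lcaAssign(hit(pident = 79.9, bitscore = 400), tree))
  expect_null(lcaAssign(hit(pident = 92, qcovs = 79, bitscore = 400), tree))
})

test_that("taxa sharing nothing above order give no LCA", {
  ## Genus01 (Famia01/Ordo01) vs Genus03 (Famia03/Ordo03): different orders
  h <- rbind(hit(taxon = "Genus01 sp1", pident = 92, bitscore = 400),
             hit(taxon = "Genus03 sp1", pident = 92, bitscore = 399))
  expect_null(lcaAssign(h, tree))
})

test_that("contaminant screening uses the register's orders as target set", {
  wfd <- hit(pident = 82, bitscore = 300)
  gbHuman <- hit(taxon = "Homo sapiens", bitscore = 580, db = "genbank",
                 lineage = "Primates/Hominidae/Homo/Homo sapiens")
  expect_equal(screenContaminants(wfd, gbHuman, tree)$keep, FALSE)
  ## no general-database hits -> keep
  expect_true(screenContaminants(wfd, gbHuman[0, ], tree)$keep)
  ## an in-register order outscoring the curated hit is still kept
  gbTarget <- hit(taxon = "Genus01 sp1", bitscore = 600, db = "genbank",
                  lineage = "Ordo01/Famia01/Genus01/Genus01 sp1")
  expect_true(screenContaminants(wfd, gbTarget, tree)$keep)
  ## weaker non-target hit does not discard
  gbWeak <- gbHuman; gbWeak$bitscore <- 100
  expect_true(screenContaminants(wfd, gbWeak, tree)$keep)
})

test_that("assignAll aggregates conspecific MOTUs and reports the unidentified", {
  cnt <- matrix(c(100L, 50L, 30L), 3, 1,
                dimnames = list(c("m1", "m2", "m3"), "L1_CRUS"))
  me <- MotuExperiment(cnt,
    data.frame(sample = "L1_CRUS", location = "L1", group = "CRUS",
               replicate = 1, is_control = FALSE),
    data.frame(is_aic = rep(FALSE, 3)))
  h <- rbind(hit(motu = "m1"), hit(motu = "m2", pident = 98.7))
  res <- assignAll(me, h, tree)
  expect_equal(res$results$method[match(c("m1", "m2", "m3"),
                                        res$results$motu)],
               c("direct", "direct", "unidentified"))
  ## one taxon entry with the summed reads
  expect_equal(nrow(res$taxa), 1L)
  expect_equal(res$taxa$reads, 150L)
  expect_equal(res$taxa$taxon, "Genus01 sp1")
})

test_that("direct and LCA paths are mutually exclusive and ranks respect caps", {
  cnt <- matrix(c(10L, 10L), 2, 1,
                dimnames = list(c("m1", "m2"), "L1_CRUS"))
  me <- MotuExperiment(cnt,
    data.frame(sample = "L1_CRUS", location = "L1", group = "CRUS",
               replicate = 1, is_control = FALSE),
    data.frame(is_aic = c(FALSE, FALSE)))
  h <- rbind(hit(motu = "m1", pident = 99.9),                  # direct
             hit(motu = "m2", pident = 92, bitscore = 400))    # lca
  res <- assignAll(me, h, tree)$results
  expect_equal(res$rank[res$motu == "m1"], "species")
  expect_equal(res$method[res$motu == "m2"], "lca")
  expect_equal(res$rank[res$motu == "m2"], "genus")
})
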