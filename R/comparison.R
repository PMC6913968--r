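## Morphology-vs-DNA concordance: six-category classification, overlap
## fractions, failed-sample exclusion, summaries, richness statistics.

.lineageFor <- function(tree, taxon) {
  ## species complexes "A/B" borrow the lineage of their first component
  first <- strsplit(taxon, "/", fixed = TRUE)[[1]][1]
  i <- match(first, tree@lineage$name)
  if (is.na(i)) return(NULL)
  list(rank = tree@lineage$rank[i],
       lineage = unlist(tree@lineage[i, .RANKS[1:4]]))
}

.isAncestor <- function(a, b) {
  ## is taxon a (rank/lineage list) a strict ancestor of b?
  da <- .rankDepth(a$rank); db <- .rankDepth(b$rank)
  da < db && !is.na(b$lineage[a$rank]) &&
    b$lineage[[a$rank]] == a$lineage[[a$rank]]
}

#' Classify a combined morphology/DNA taxon list into six categories
#'
#' Deterministic matching in priority order on one comparison unit (a sample
#' or a pooled location), both lists already register-matched and
#' redundancy-removed: exact taxon matches are `found`; remaining cross-rank
#' lineage matches (an entry on one list is an ancestor of an entry on the
#' other) are `different_level`; remaining congeneric species pairs (one per
#' list, same genus, different species; alphabetical pairing on ties) are
#' `putative_misid`; remaining morphology-only species absent from the
#' reference database are `missing_in_reference`; remaining morphology-only
#' entries are `not_found`; remaining DNA-only entries are `extra`.
#' Every occurrence on either list lands in exactly one entry.
#'
#' @param morph,dna data.frames with a `taxon` column of canonical names
#'   (DNA species complexes may be written `"A/B"`).
#' @param refdbSpecies character vector of species covered by the DNA
#'   reference database.
#' @param tree a [TaxonomyTree-class].
#' @return data.frame `taxon_morph`, `taxon_dna`, `category`.
#' @export
classifyComparison <- function(morph, dna, refdbSpecies, tree) {
  mt <- sort(unique(morph$taxon))
  dt <- sort(unique(dna$taxon))
  mi <- lapply(mt, .lineageFor, tree = tree)
  di <- lapply(dt, .lineageFor, tree = tree)
  bad <- c(mt[vapply(mi, is.null, TRUE)], dt[vapply(di, is.null, TRUE)])
  if (length(bad))
    stop("unmatched names in comparison lists: ", paste(bad, collapse = ", "))
  usedM <- logical(length(mt)); usedD <- logical(length(dt))
  rows <- list()
  add <- function(m, d, cat)
    rows[[length(rows) + 1L]] <<- data.frame(
      taxon_morph = m, taxon_dna = d, category = cat,
      stringsAsFactors = FALSE)
  dComponents <- strsplit(dt, "/", fixed = TRUE)
  ## 1: exact matches (a complex containing the morphology species counts)
  for (a in seq_along(mt)) {
    j <- which(!usedD & vapply(seq_along(dt), function(b)
      dt[b] == mt[a] || mt[a] %in% dComponents[[b]], TRUE))
    if (length(j)) {
      usedM[a] <- TRUE; usedD[j[1L]] <- TRUE
      add(mt[a], dt[j[1L]], "found")
    }
  }
  ## 2: cross-rank lineage matches
  for (a in which(!usedM)) {
    j <- which(!usedD & vapply(seq_along(dt), function(b)
      .isAncestor(mi[[a]], di[[b]]) || .isAncestor(di[[b]], mi[[a]]), TRUE))
    if (length(j)) {
      usedM[a] <- TRUE; usedD[j[1L]] <- TRUE
      add(mt[a], dt[j[1L]], "different_level")
    }
  }
  ## 3: congeneric species pairs, alphabetical
  for (a in which(!usedM)) {
    if (mi[[a]]$rank != "species") next
    g <- mi[[a]]$lineage[["genus"]]
    j <- which(!usedD & vapply(seq_along(dt), function(b)
      di[[b]]$rank == "species" &&
        identical(di[[b]]$lineage[["genus"]], g), TRUE))
    if (length(j)) {
      usedM[a] <- TRUE; usedD[j[1L]] <- TRUE
      add(mt[a], dt[j[1L]], "putative_misid")
    }
  }
  ## 4/5: remaining morphology-only
  for (a in which(!usedM)) {
    cat <- if (mi[[a]]$rank == "species" && !(mt[a] %in% refdbSpecies))
      "missing_in_reference" else "not_found"
    add(mt[a], NA_character_, cat)
  }
  ## 6: remaining DNA-only
  for (b in which(!usedD)) add(NA_character_, dt[b], "extra")
  if (length(rows)) do.call(rbind, rows)
  else data.frame(taxon_morph = character(0), taxon_dna = character(0),
                  category = character(0))
}

#' Overlap fractions of a classified comparison
#'
#' The first three categories count as found on both lists; taxa missing
#' from the reference count towards the morphology-only fraction.
#'
#' @param entries output of [classifyComparison()] for one unit.
#' @return list with `overlap`, `morph_only`, `dna_only` (summing to 1),
#'   `counts` (per category) and `n`; fractions are `NA` when the unit is
#'   empty.
#' @export
overlapFractions <- function(entries) {
  cnt <- table(factor(entries$category, levels = .CATEGORIES))
  n <- nrow(entries)
  if (n == 0L)
    return(list(overlap = NA_real_, morph_only = NA_real_,
                dna_only = NA_real_, counts = cnt, n = 0L))
  list(overlap = unname(cnt["found"] + cnt["different_level"] +
                          cnt["putative_misid"]) / n,
       morph_only = unname(cnt["missing_in_reference"] + cnt["not_found"]) / n,
       dna_only = unname(cnt["extra"]) / n,
       counts = cnt, n = n)
}

#' Shares of the three within-overlap categories
#'
#' Fractions of exact matches, different-level matches and putative
#' misidentifications among the entries counted as overlap.
#'
#' @param counts named numeric vector (or table) with elements `found`,
#'   `different_level`, `putative_misid`.
#' @return named numeric vector of the three shares (fractions of their sum).
#' @export
withinOverlapShares <- function(counts) {
  k <- c("found", "different_level", "putative_misid")
  v <- as.numeric(counts[k])
  stats::setNames(v / sum(v), k)
}

#' Exclude morphology entries from failed samples
#'
#' Taxa from samples that failed to amplify can only count towards the
#' morphology-only fraction, so they are removed before the comparison.
#'
#' @param morph data.frame with `location` and `group` columns.
#' @param failed data.frame of failed samples with `location` and `group`.
#' @return `morph` without rows from failed (location, group) units; the
#'   number removed per group is attached as attribute `"removed"`.
#' @export
excludeFailed <- function(morph, failed) {
  if (nrow(failed) == 0L) return(morph)
  key <- paste(morph$location, morph$group)
  bad <- key %in% paste(failed$location, failed$group)
  out <- morph[!bad, , drop = FALSE]
  attr(out, "removed") <- table(morph$group[bad])
  out
}

#' Summarise per-unit overlap fractions
#'
#' Unweighted means and ranges of the per-unit fractions, overall and per
#' group, plus counts of units where the DNA-only fraction exceeds the
#' morphology-only fraction and vice versa.
#'
#' @param fracs data.frame with columns `unit`, `group`, `overlap`,
#'   `morph_only`, `dna_only` (one row per comparison unit).
#' @return list with `overall` (means and ranges), `per_group` (data.frame)
#'   and `counts`.
#' @export
summarizeComparison <- function(fracs) {
  fr <- fracs[!is.na(fracs$overlap), , drop = FALSE]
  mr <- function(v) c(mean = mean(v), min = min(v), max = max(v))
  overall <- list(overlap = mr(fr$overlap), morph_only = mr(fr$morph_only),
                  dna_only = mr(fr$dna_only), n_units = nrow(fr))
  perGroup <- do.call(rbind, lapply(split(fr, fr$group), function(g)
    data.frame(group = g$group[1L], n = nrow(g),
               overlap = mean(g$overlap), morph_only = mean(g$morph_only),
               dna_only = mean(g$dna_only), stringsAsFactors = FALSE)))
  rownames(perGroup) <- NULL
  list(overall = overall, per_group = perGroup,
       counts = list(dna_gt_morph = sum(fr$dna_only > fr$morph_only),
                     morph_gt_overlap = sum(fr$morph_only > fr$overlap)))
}

#' Richness statistics for paired morphology/DNA samples
#'
#' @param morph,dna paired per-sample richness vectors.
#' @return list with the Pearson correlation `r` (`NA` when undefined),
#'   `mean_ratio` (mean of per-sample dna/morph ratios), `ratio_of_means`,
#'   and per-list means and ranges. Both ratio variants are reported because
#'   "x times as many taxa" summaries are ambiguous between them.
#' @export
richnessStats <- function(morph, dna) {
  stopifnot(length(morph) == length(dna))
  r <- NA_real_
  if (length(morph) >= 3L && stats::sd(morph) > 0 && stats::sd(dna) > 0)
    r <- stats::cor(morph, dna)
  ok <- morph > 0
  list(r = r,
       mean_ratio = mean(dna[ok] / morph[ok]),
       ratio_of_means = mean(dna) / mean(morph),
       morph = c(mean = mean(morph), min = min(morph), max = max(morph)),
       dna = c(mean = mean(dna), min = min(dna), max = max(dna)))
}
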