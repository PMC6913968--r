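## Per-MOTU taxonomic assignment from dual-database BLAST-style hit tables.

#' Assignment configuration
#'
#' Defaults are the study conditions: direct hits require identity strictly
#' above 98% at 100% coverage; the LCA path uses hits with bit-score
#' strictly above 170, identity and coverage at least 80%, restricted to the
#' top 5% of the best candidate bit-score (MEGAN-style top-percent filter),
#' capped at genus rank; assignments shallower than order are discarded.
#'
#' @param direct_min_identity,direct_coverage direct-hit thresholds (%).
#' @param lca_top_fraction keep candidates with bit-score `>= (1 -
#'   fraction) * best`.
#' @param lca_min_bitscore,lca_min_identity,lca_min_coverage LCA candidate
#'   filters.
#' @param lca_rank_cap deepest rank an LCA result may take.
#' @param min_accept_rank shallowest acceptable final rank.
#' @export
assignConfig <- function(direct_min_identity = 98, direct_coverage = 100,
                         lca_top_fraction = 0.05, lca_min_bitscore = 170,
                         lca_min_identity = 80, lca_min_coverage = 80,
                         lca_rank_cap = "genus", min_accept_rank = "order") {
  stopifnot(lca_top_fraction > 0, lca_top_fraction < 1,
            lca_rank_cap %in% .RANKS, min_accept_rank %in% .RANKS)
  list(direct_min_identity = direct_min_identity,
       direct_coverage = direct_coverage,
       lca_top_fraction = lca_top_fraction,
       lca_min_bitscore = lca_min_bitscore,
       lca_min_identity = lca_min_identity,
       lca_min_coverage = lca_min_coverage,
       lca_rank_cap = lca_rank_cap,
       min_accept_rank = min_accept_rank)
}

#' Name-resolution configuration
#'
#' @param blocklist taxon names treated as putative misidentifications or
#'   reference contaminations and removed (rule 5); an explicit, versioned
#'   stand-in for the expert curation step. Empty by default.
#' @param consistency_margin identity difference (percentage points) above
#'   which one species counts as having "matched consistently higher" than
#'   the others (rule 6).
#' @export
resolutionConfig <- function(blocklist = character(0),
                             consistency_margin = 0.5) {
  stopifnot(consistency_margin >= 0)
  list(blocklist = blocklist, consistency_margin = consistency_margin)
}

.checkHits <- function(hits) {
  req <- c("motu", "taxon", "rank", "pident", "qcovs", "bitscore", "db")
  if (!all(req %in% names(hits)))
    stop("hit table must have columns: ", paste(req, collapse = ", "))
  invisible(hits)
}

#' Direct reference hits for one MOTU
#'
#' @param hits hit rows for one MOTU (columns `taxon`, `pident`, `qcovs`,
#'   `db`); only `wfd_custom` rows are considered.
#' @param cfg an [assignConfig()].
#' @return distinct taxon names with identity strictly above the direct
#'   threshold at full coverage (possibly empty).
#' @export
findDirectHits <- function(hits, cfg = assignConfig()) {
  h <- hits[hits$db == "wfd_custom" &
            hits$pident > cfg$direct_min_identity &
            hits$qcovs >= cfg$direct_coverage, , drop = FALSE]
  unique(h$taxon)
}

#' Rule-based resolution of multiple direct-hit names
#'
#' Applies, in order: (1) drop names not on the national register, (2)
#' resolve synonyms, (3) collapse subspecies to species, (4) when both a
#' genus-level name and species of that genus are present keep the species,
#' (5) drop blocklisted names, (6) when one species' best hit identity
#' exceeds every other's by at least the consistency margin keep only it,
#' (7) otherwise keep all remaining names (unresolvable species complex).
#'
#' @param names taxon names from [findDirectHits()].
#' @param hits the MOTU's hit rows (used for best identities in rule 6).
#' @param tree a [TaxonomyTree-class].
#' @param res a [resolutionConfig()].
#' @return list with `taxa` (data.frame `name`, `rank`; zero rows when all
#'   names were eliminated, in which case the caller falls through to the
#'   LCA path) and `rules` (integer ids of the rules that fired).
#' @export
resolveDirect <- function(names, hits, tree, res = resolutionConfig()) {
  stopifnot(length(names) > 0L)
  rules <- integer(0)
  m <- matchNames(tree, names)
  ## (1) non-register (incl. unmatched) names removed
  keep <- !is.na(m$taxon) & m$in_register
  if (any(!keep)) rules <- c(rules, 1L)
  m <- m[keep, , drop = FALSE]
  if (any(m$status == "synonym")) rules <- c(rules, 2L)
  if (any(m$status == "subspecies_collapsed")) rules <- c(rules, 3L)
  canon <- m[!duplicated(m$taxon), c("input", "taxon", "rank")]
  ## (4) genus-level names beaten by conspecific species-level names
  if (nrow(canon) > 1L && any(canon$rank == "genus")) {
    spGenus <- vapply(canon$taxon[canon$rank %in% c("species")],
                      function(t) unname(lineageOf(tree, t)["genus"]), "")
    dropG <- canon$rank == "genus" & canon$taxon %in% spGenus
    if (any(dropG)) {
      rules <- c(rules, 4L)
      canon <- canon[!dropG, , drop = FALSE]
    }
  }
  ## (5) blocklist
  blocked <- canon$taxon %in% res$blocklist
  if (any(blocked)) {
    rules <- c(rules, 5L)
    canon <- canon[!blocked, , drop = FALSE]
  }
  ## (6) consistently-higher match wins
  if (nrow(canon) > 1L) {
    best <- vapply(canon$input, function(nm)
      max(hits$pident[hits$taxon == nm], -Inf), numeric(1))
    top <- which.max(best)
    if (all(best[top] - best[-top] >= res$consistency_margin)) {
      rules <- c(rules, 6L)
      canon <- canon[top, , drop = FALSE]
    } else {
      rules <- c(rules, 7L)
    }
  }
  list(taxa = data.frame(name = canon$taxon, rank = canon$rank,
                         stringsAsFactors = FALSE),
       rules = rules)
}

#' Genus-capped LCA assignment for one MOTU
#'
#' Candidate hits must pass the minimum identity/coverage filters, have
#' bit-score strictly above the minimum, and lie within the top-percent band
#' of the best candidate bit-score. The lowest common ancestor of the
#' candidate taxa is returned, never deeper than the rank cap.
#'
#' @param hits hit rows for one MOTU; only `wfd_custom` rows are used.
#' @param tree a [TaxonomyTree-class].
#' @param cfg an [assignConfig()].
#' @return list (`name`, `rank`) or `NULL` when no candidate survives or no
#'   order-level ancestor is shared.
#' @export
lcaAssign <- function(hits, tree, cfg = assignConfig()) {
  h <- hits[hits$db == "wfd_custom" &
            hits$pident >= cfg$lca_min_identity &
            hits$qcovs >= cfg$lca_min_coverage &
            hits$bitscore > cfg$lca_min_bitscore, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h <- h[h$bitscore >= (1 - cfg$lca_top_fraction) * max(h$bitscore), ,
         drop = FALSE]
  m <- matchNames(tree, unique(h$taxon))
  taxa <- unique(m$taxon[!is.na(m$taxon)])
  if (length(taxa) == 0L) return(NULL)
  lowestCommonAncestor(tree, taxa, maxDepth = cfg$lca_rank_cap)
}

#' Screen a MOTU against the second reference library
#'
#' A MOTU is discarded as non-target when its best GenBank-style hit
#' outscores its best curated-reference hit and that hit's order is not on
#' the register (e.g. human or endosymbiont contamination of the reference
#' data). The target set is defined by the register's orders, not
#' hard-coded.
#'
#' @param wfdHits,gbHits hit rows for one MOTU from the curated and the
#'   general reference library (either may have zero rows). `gbHits` must
#'   carry a slash-delimited `lineage` column whose first element is the
#'   order.
#' @param tree a [TaxonomyTree-class].
#' @return list with `keep` (logical) and `reason` (`NA` or `"non-target"`).
#' @export
screenContaminants <- function(wfdHits, gbHits, tree) {
  if (nrow(gbHits) == 0L) return(list(keep = TRUE, reason = NA_character_))
  bestW <- if (nrow(wfdHits)) max(wfdHits$bitscore) else -Inf
  gbest <- gbHits[which.max(gbHits$bitscore), ]
  if (gbest$bitscore > bestW) {
    ord <- strsplit(gbest$lineage, "/", fixed = TRUE)[[1]][1]
    registerOrders <- tree@nodes$name[tree@nodes$rank == "order" &
                                      tree@nodes$in_register]
    if (!(ord %in% registerOrders))
      return(list(keep = FALSE, reason = "non-target"))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Assign every MOTU and aggregate into taxon lists
#'
#' Per MOTU: contaminant screening, then the direct-hit path (accumulated
#' names resolved through rules 1-7) or, failing that, the genus-capped LCA
#' path; assignments shallower than order are discarded. MOTUs with the same
#' final taxon are aggregated per sample (summed reads); the direct and LCA
#' paths are mutually exclusive.
#'
#' @param x a sample-level [MotuExperiment-class] (from
#'   [discardAndCombine()]).
#' @param hits hit table covering both databases (`db` column
#'   `wfd_custom` / `genbank`).
#' @param tree a [TaxonomyTree-class].
#' @param cfg an [assignConfig()].
#' @param res a [resolutionConfig()].
#' @return list with `results` (per-MOTU data.frame: `motu`, `method`
#'   (`direct`/`lca`/`discarded`/`unidentified`), `taxon`, `rank`, `rules`,
#'   `reason`, `reads`) and `taxa` (long data.frame `sample`, `location`,
#'   `group`, `taxon`, `rank`, `reads` of aggregated assignments).
#' @export
assignAll <- function(x, hits, tree, cfg = assignConfig(),
                      res = resolutionConfig()) {
  .checkHits(hits)
  cnt <- motuCounts(x)
  cd <- as.data.frame(colData(x))
  motus <- rownames(cnt)
  byMotu <- split(seq_len(nrow(hits)), hits$motu)
  out <- data.frame(motu = motus, method = "unidentified",
                    taxon = NA_character_, rank = NA_character_,
                    rules = "", reason = NA_character_,
                    reads = as.integer(rowSums(cnt)),
                    stringsAsFactors = FALSE)
  minDepth <- .rankDepth(cfg$min_accept_rank)
  for (k in seq_along(motus)) {
    idx <- byMotu[[motus[k]]]
    if (is.null(idx)) next
    h <- hits[idx, , drop = FALSE]
    wfd <- h[h$db == "wfd_custom", , drop = FALSE]
    gb <- h[h$db == "genbank", , drop = FALSE]
    scr <- screenContaminants(wfd, gb, tree)
    if (!scr$keep) {
      out$method[k] <- "discarded"; out$reason[k] <- scr$reason
      next
    }
    direct <- findDirectHits(h, cfg)
    assigned <- FALSE
    if (length(direct)) {
      r <- resolveDirect(direct, wfd, tree, res)
      if (nrow(r$taxa)) {
        out$method[k] <- "direct"
        out$taxon[k] <- paste(sort(r$taxa$name), collapse = "/")
        out$rank[k] <- if (nrow(r$taxa) == 1L) r$taxa$rank else "species"
        out$rules[k] <- paste(r$rules, collapse = ",")
        assigned <- TRUE
      }
    }
    if (!assigned) {
      l <- lcaAssign(h, tree, cfg)
      if (is.null(l)) {
        out$method[k] <- "discarded"; out$reason[k] <- "above order"
      } else if (.rankDepth(l$rank) < minDepth) {
        out$method[k] <- "discarded"; out$reason[k] <- "above order"
      } else {
        out$method[k] <- "lca"
        out$taxon[k] <- l$name
        out$rank[k] <- l$rank
      }
    }
  }
  ok <- out$method %in% c("direct", "lca")
  taxa <- NULL
  if (any(ok)) {
    sub <- cnt[ok, , drop = FALSE]
    key <- paste(out$taxon[ok], out$rank[ok], sep = "\r")
    agg <- rowsum(sub, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    long <- lapply(seq_len(ncol(agg)), function(j) {
      nz <- agg[, j] > 0
      if (!any(nz)) return(NULL)
      data.frame(sample = colnames(agg)[j],
                 location = cd$location[j], group = cd$group[j],
                 taxon = vapply(parts[nz], `[`, "", 1L),
                 rank = vapply(parts[nz], `[`, "", 2L),
                 reads = as.integer(agg[nz, j]),
                 stringsAsFactors = FALSE)
    })
    taxa <- do.call(rbind, long)
    rownames(taxa) <- NULL
  } else {
    taxa <- data.frame(sample = character(0), location = character(0),
                       group = character(0), taxon = character(0),
                       rank = character(0), reads = integer(0))
  }
  list(results = out, taxa = taxa)
}
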