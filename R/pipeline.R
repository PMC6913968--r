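## End-to-end orchestration: simulate -> contamination threshold -> abundance
## filter -> replicate discard/merge -> assignment -> taxon lists ->
## morphology comparison -> summaries, with optional artifact writing.

.compareUnit <- function(morphTaxa, dnaTaxa, refdb, tree) {
  m <- removeRedundant(tree, morphTaxa)
  d <- removeRedundant(tree, dnaTaxa)
  entries <- classifyComparison(m, d, refdb, tree)
  list(morph = m, dna = d, entries = entries,
       fractions = overlapFractions(entries))
}

.aggTaxa <- function(df) {
  ## collapse duplicate taxon rows (summing reads/counts) within one unit
  if (nrow(df) == 0L) return(df)
  num <- intersect(c("reads", "count"), names(df))[1]
  out <- stats::aggregate(df[[num]], list(taxon = df$taxon, rank = df$rank),
                          sum)
  names(out)[3] <- num
  out[order(out$taxon), , drop = FALSE]
}

#' Run the full pipeline on a simulated study
#'
#' Executes the fixed stage order: simulation, contamination-threshold
#' derivation from the internal controls, per-replicate low-abundance MOTU
#' filtering, shallow-replicate discard and additive combination, dual-
#' database taxonomic assignment, register matching and redundancy removal
#' of the morphological and DNA taxon lists, failed-sample exclusion,
#' six-category comparison (per sorted sample, per location, and for the
#' pools), and summary statistics including rarefaction.
#'
#' @param cfg a [simConfig()] (or an already-generated [simulateStudy()]
#'   result, in which case it is used as-is).
#' @param filterCfg a [filterConfig()]; its threshold is the one applied
#'   (the control-derived threshold is reported alongside).
#' @param assignCfg an [assignConfig()].
#' @param resCfg a [resolutionConfig()].
#' @param outDir optional directory; when given, comparison reports, the
#'   assignment table, a presence/absence export and a run manifest are
#'   written there.
#' @param rarefy logical; compute the rarefaction summary (pools to 15,000
#'   reads, sorted samples to 2,500).
#' @return a list with the simulation, intermediate tables, per-unit
#'   comparisons and a `summary` list of headline numbers.
#' @export
runPipeline <- function(cfg, filterCfg = filterConfig(),
                        assignCfg = assignConfig(),
                        resCfg = resolutionConfig(),
                        outDir = NULL, rarefy = TRUE) {
  t0 <- Sys.time()
  sim <- if (inherits(cfg, "simConfig")) simulateStudy(cfg) else cfg
  tree <- sim$tree
  timings <- c(simulate = as.numeric(Sys.time() - t0, units = "secs"))

  t0 <- Sys.time()
  thrDerived <- contaminationThreshold(sim$me)
  thr <- filterCfg$motu_rel_abundance_threshold
  if (thrDerived > thr)
    warning("control-derived threshold (", signif(thrDerived, 3),
            ") exceeds the configured threshold (", thr, ")")
  filt <- filterLowAbundance(sim$me, thr)
  sl <- discardAndCombine(filt, filterCfg)
  failed <- metadata(sl)$failed
  timings["filter"] <- as.numeric(Sys.time() - t0, units = "secs")

  t0 <- Sys.time()
  asn <- assignAll(sl, sim$hits, tree, assignCfg, resCfg)
  timings["assign"] <- as.numeric(Sys.time() - t0, units = "secs")

  t0 <- Sys.time()
  ## morphology: register matching, then aggregation per unit
  mm <- matchNames(tree, sim$morphology$taxon)
  unmatched <- unique(sim$morphology$taxon[mm$status == "unmatched"])
  morph <- data.frame(location = sim$morphology$location,
                      group = sim$morphology$group,
                      taxon = mm$taxon, rank = mm$rank,
                      count = sim$morphology$count,
                      stringsAsFactors = FALSE)
  morph <- morph[!is.na(morph$taxon), , drop = FALSE]
  failedSorted <- failed[failed$group != "POOL", , drop = FALSE]
  morphKept <- excludeFailed(morph, failedSorted)

  dnaSorted <- asn$taxa[asn$taxa$group != "POOL", , drop = FALSE]
  dnaPooled <- asn$taxa[asn$taxa$group == "POOL", , drop = FALSE]
  locs <- sort(unique(sim$morphology$location))
  refdb <- sim$refdbSpecies

  sortedUnits <- list(); sortedLocs <- list(); pooledLocs <- list()
  fracRow <- function(unit, group, fr)
    data.frame(unit = unit, group = group, overlap = fr$overlap,
               morph_only = fr$morph_only, dna_only = fr$dna_only,
               n = fr$n, stringsAsFactors = FALSE)
  unitFracs <- list(); locFracsSorted <- list(); locFracsPooled <- list()
  sortedCounts <- stats::setNames(numeric(length(.CATEGORIES)), .CATEGORIES)

  for (loc in locs) {
    mLoc <- morphKept[morphKept$location == loc, , drop = FALSE]
    dLoc <- dnaSorted[dnaSorted$location == loc, , drop = FALSE]
    ## per (location, group) sorted units
    for (g in unique(c(mLoc$group, dLoc$group))) {
      key <- paste(loc, g, sep = "_")
      cu <- .compareUnit(.aggTaxa(mLoc[mLoc$group == g, , drop = FALSE]),
                         .aggTaxa(dLoc[dLoc$group == g, , drop = FALSE]),
                         refdb, tree)
      sortedUnits[[key]] <- cu
      unitFracs[[key]] <- fracRow(key, g, cu$fractions)
    }
    ## location level, sorted samples added together
    if (nrow(dLoc) > 0L) {
      cl <- .compareUnit(.aggTaxa(mLoc), .aggTaxa(dLoc), refdb, tree)
      sortedLocs[[loc]] <- cl
      locFracsSorted[[loc]] <- fracRow(loc, "ALL", cl$fractions)
      sortedCounts <- sortedCounts + as.numeric(cl$fractions$counts)
    }
    ## pooled sample vs full morphology list
    pLoc <- dnaPooled[dnaPooled$location == loc, , drop = FALSE]
    poolFailed <- any(failed$group == "POOL" & failed$location == loc)
    if (nrow(pLoc) > 0L && !poolFailed) {
      mAll <- morph[morph$location == loc, , drop = FALSE]
      cp <- .compareUnit(.aggTaxa(mAll), .aggTaxa(pLoc), refdb, tree)
      pooledLocs[[loc]] <- cp
      locFracsPooled[[loc]] <- fracRow(loc, "ALL", cp$fractions)
    }
  }
  unitFracs <- do.call(rbind, unitFracs)
  locFracsSorted <- do.call(rbind, locFracsSorted)
  locFracsPooled <- do.call(rbind, locFracsPooled)

  ## richness (redundancy retained, the headline metric) per location
  richSorted <- vapply(locs, function(l)
    nrow(.aggTaxa(dnaSorted[dnaSorted$location == l, , drop = FALSE])),
    integer(1))
  richPooled <- vapply(locs, function(l)
    nrow(.aggTaxa(dnaPooled[dnaPooled$location == l, , drop = FALSE])),
    integer(1))
  richMorph <- vapply(locs, function(l)
    nrow(.aggTaxa(morph[morph$location == l, , drop = FALSE])), integer(1))
  both <- richSorted > 0 & richPooled > 0
  gain <- 100 * (mean(richSorted[both]) / mean(richPooled[both]) - 1)

  ## sequencing depth per location
  slTot <- replicateTotals(sl)
  cd <- as.data.frame(colData(sl))
  depthSorted <- vapply(locs, function(l)
    sum(slTot[cd$location == l & cd$group != "POOL"]), numeric(1))
  depthPooled <- vapply(locs, function(l)
    sum(slTot[cd$location == l & cd$group == "POOL"]), numeric(1))
  okD <- depthSorted > 0 & depthPooled > 0
  depthRatio <- mean(depthSorted[okD]) / mean(depthPooled[okD])

  rare <- NULL
  if (rarefy) rare <- .rarefactionSummary(sl, asn$results, cfg = sim$config)

  summary <- list(
    threshold_derived = thrDerived,
    threshold_applied = thr,
    retained_motus = sum(rowSums(motuCounts(sl)) > 0),
    n_failed_samples = nrow(failed),
    richness_gain_pct = gain,
    mean_richness_sorted = mean(richSorted[both]),
    mean_richness_pooled = mean(richPooled[both]),
    depth_ratio = depthRatio,
    sorted = summarizeComparison(locFracsSorted),
    pooled = summarizeComparison(locFracsPooled),
    per_group = summarizeComparison(unitFracs),
    within_overlap_shares = withinOverlapShares(sortedCounts),
    category_counts = sortedCounts,
    richness_sorted = richnessStats(richMorph[both], richSorted[both]),
    richness_pooled = richnessStats(richMorph[both], richPooled[both]),
    rarefaction = rare,
    unmatched_names = unmatched)
  timings["compare"] <- as.numeric(Sys.time() - t0, units = "secs")

  run <- list(sim = sim, sampleTable = sl, failed = failed,
              assignment = asn$results, taxa = asn$taxa,
              morphology = morph, morphologyKept = morphKept,
              units = list(sorted_units = sortedUnits,
                           sorted_locations = sortedLocs,
                           pooled_locations = pooledLocs),
              fractions = list(per_unit = unitFracs,
                               sorted = locFracsSorted,
                               pooled = locFracsPooled),
              summary = summary, timings = timings)
  if (!is.null(outDir)) .writeRunArtifacts(run, outDir)
  run
}

.rarefactionSummary <- function(sl, results, cfg,
                                pooledDepth = 15000L, sortedDepth = 2500L) {
  cnt <- motuCounts(sl)
  cd <- as.data.frame(colData(sl))
  taxonOf <- stats::setNames(results$taxon, results$motu)
  rareOne <- function(col, depth, seed) {
    v <- cnt[, col]
    if (sum(v) < depth) return(NULL)
    r <- rarefyCounts(v, depth, seed)
    list(motus = sum(r > 0),
         taxa = length(unique(stats::na.omit(taxonOf[names(r)[r > 0]]))))
  }
  locs <- unique(cd$location)
  rows <- list()
  for (i in seq_len(ncol(cnt))) {
    depth <- if (cd$group[i] == "POOL") pooledDepth else sortedDepth
    r <- rareOne(i, depth, cfg$seed + i)
    if (is.null(r)) next
    rows[[colnames(cnt)[i]]] <- data.frame(
      sample = colnames(cnt)[i], location = cd$location[i],
      group = cd$group[i], motus = r$motus, taxa = r$taxa,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  if (is.null(per)) return(NULL)
  sortedLoc <- stats::aggregate(cbind(motus, taxa) ~ location,
                                per[per$group != "POOL", ], sum)
  pooledLoc <- per[per$group == "POOL", c("location", "motus", "taxa")]
  m <- merge(sortedLoc, pooledLoc, by = "location",
             suffixes = c("_sorted", "_pooled"))
  list(per_sample = per,
       motu_ratio = mean(m$motus_sorted) / mean(m$motus_pooled),
       taxon_ratio = mean(m$taxa_sorted) / mean(m$taxa_pooled),
       n_locations = nrow(m))
}

#' Read a structured pipeline configuration file
#'
#' A YAML file with optional sections `simulation`, `filter`, `assignment`
#' and `resolution`; each key overrides the corresponding constructor
#' default ([simConfig()], [filterConfig()], [assignConfig()],
#' [resolutionConfig()]), so an empty section yields the study defaults.
#' The simulation section must provide `seed`.
#'
#' @param path YAML file path.
#' @return list with elements `sim`, `filter`, `assign`, `resolution`,
#'   ready to pass to [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sec <- function(name) if (is.null(y[[name]])) list() else y[[name]]
  simArgs <- sec("simulation")
  vecFields <- c("poolSizes", "refCoverage", "meanRichness", "failureProb",
                 "contamRelRange", "failedDepthRange", "contamMotuRelRange")
  for (f in intersect(names(simArgs), vecFields))
    simArgs[[f]] <- unlist(simArgs[[f]])
  list(sim = do.call(simConfig, simArgs),
       filter = do.call(filterConfig, sec("filter")),
       assign = do.call(assignConfig, sec("assignment")),
       resolution = do.call(resolutionConfig, sec("resolution")))
}

#' Evaluate pipeline output against the generator's ground truth
#'
#' @param run output of [runPipeline()].
#' @param truth the `truth` element of the underlying [simulateStudy()]
#'   result (taken from `run` when omitted).
#' @return list with `false_taxa` (species-level DNA assignments absent
#'   from the location's true community), `recovery` (per location and
#'   origin: true species, recovered species), `swaps` (injected congeneric
#'   swaps: eligible pairs surviving filtering and how many were classified
#'   `putative_misid`), `uncovered` (category table of morphology species
#'   lacking reference coverage) and `screening` (contaminant-MOTU
#'   disposition).
#' @export
truthEvaluate <- function(run, truth = run$sim$truth) {
  res <- run$assignment
  known <- c(truth$motuMap$motu, truth$contaminantMotus, truth$aicMotu)
  if (!all(res$motu %in% known))
    stop("assignment contains MOTU ids absent from the ground truth")
  comm <- truth$community

  splitTaxa <- function(x) unlist(strsplit(x, "/", fixed = TRUE))
  ## false taxa + recovery per location and origin
  recRows <- list(); falseTaxa <- list()
  for (origin in c("sorted", "pooled")) {
    lists <- if (origin == "sorted")
      run$taxa[run$taxa$group != "POOL", , drop = FALSE]
    else run$taxa[run$taxa$group == "POOL", , drop = FALSE]
    for (loc in unique(comm$location)) {
      trueSp <- comm$species[comm$location == loc]
      dl <- lists[lists$location == loc, , drop = FALSE]
      if (nrow(dl) == 0L) next
      spAssigned <- unique(splitTaxa(dl$taxon[dl$rank == "species"]))
      fp <- setdiff(spAssigned, trueSp)
      ## a complex counts as recovered/true when any component is true
      cplx <- dl$taxon[dl$rank == "species" & grepl("/", dl$taxon, fixed = TRUE)]
      for (cx in cplx)
        if (any(splitTaxa(cx) %in% trueSp))
          fp <- setdiff(fp, splitTaxa(cx))
      if (length(fp))
        falseTaxa[[length(falseTaxa) + 1L]] <- data.frame(
          location = loc, origin = origin, taxon = fp,
          stringsAsFactors = FALSE)
      recRows[[length(recRows) + 1L]] <- data.frame(
        location = loc, origin = origin, n_true = length(trueSp),
        n_recovered = sum(trueSp %in% spAssigned),
        richness = nrow(.aggTaxa(dl)), stringsAsFactors = FALSE)
    }
  }
  recovery <- do.call(rbind, recRows)
  falseTaxa <- if (length(falseTaxa)) do.call(rbind, falseTaxa) else
    data.frame(location = character(0), origin = character(0),
               taxon = character(0))

  ## injected congeneric swaps
  swaps <- truth$swaps
  swapRows <- list()
  if (nrow(swaps)) for (i in seq_len(nrow(swaps))) {
    key <- paste(swaps$location[i], swaps$group[i], sep = "_")
    u <- run$units$sorted_units[[key]]
    if (is.null(u)) next
    X <- swaps$true_species[i]; Y <- swaps$recorded[i]
    dnaSp <- unique(splitTaxa(u$dna$taxon[u$dna$rank == "species"]))
    morphSp <- u$morph$taxon
    eligible <- (X %in% dnaSp) && (Y %in% morphSp) &&
      !(X %in% morphSp) && !(Y %in% dnaSp)
    ## with several surplus congeners the alphabetical pairing may couple
    ## the swap partners to other members of the genus, so credit any
    ## putative-misidentification entry within the swap's genus
    gX <- sub(" .*", "", X)
    e3 <- u$entries[u$entries$category == "putative_misid", , drop = FALSE]
    hit <- eligible && any(sub(" .*", "", e3$taxon_morph) == gX)
    swapRows[[i]] <- data.frame(location = swaps$location[i],
                                group = swaps$group[i], true_species = X,
                                recorded = Y, eligible = eligible,
                                recovered_cat3 = hit,
                                stringsAsFactors = FALSE)
  }
  swapTab <- if (length(swapRows)) do.call(rbind, swapRows) else
    data.frame(eligible = logical(0), recovered_cat3 = logical(0))

  ## morphology species without reference coverage: their categories
  uncovCat <- character(0)
  for (loc in names(run$units$sorted_locations)) {
    u <- run$units$sorted_locations[[loc]]
    e <- u$entries
    mo <- e$taxon_morph[!is.na(e$taxon_morph)]
    uncovM <- mo[mo %in% comm$species & !(mo %in% truth$covered)]
    uncovCat <- c(uncovCat,
                  e$category[!is.na(e$taxon_morph) &
                             e$taxon_morph %in% uncovM])
  }

  contamRes <- res[res$motu %in% truth$contaminantMotus, , drop = FALSE]
  targetMotus <- truth$motuMap$motu[truth$motuMap$type == "haplotype"]
  screening <- list(
    contaminants_discarded = sum(contamRes$method == "discarded" &
                                 contamRes$reason == "non-target"),
    contaminants_present = nrow(contamRes),
    target_discarded_nontarget = sum(res$method == "discarded" &
                                     res$reason == "non-target" &
                                     res$motu %in% targetMotus))
  list(false_taxa = falseTaxa, recovery = recovery, swaps = swapTab,
       uncovered = table(uncovCat), screening = screening)
}

#' Export a presence/absence matrix
#'
#' Writes a location x taxon 0/1 CSV (register naming) suitable for
#' external ecological-quality-ratio tools.
#'
#' @param taxa long data.frame with `location` and `taxon` columns.
#' @param path output CSV path.
#' @return the matrix, invisibly.
#' @export
exportPresenceAbsence <- function(taxa, path) {
  tab <- table(taxa$location, taxa$taxon)
  m <- as.data.frame.matrix((tab > 0) + 0L)
  utils::write.csv(cbind(location = rownames(m), m), path,
                   row.names = FALSE)
  invisible(m)
}

.writeRunArtifacts <- function(run, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  entries <- do.call(rbind, lapply(names(run$units$sorted_units), function(k) {
    e <- run$units$sorted_units[[k]]$entries
    if (nrow(e) == 0L) return(NULL)
    cbind(unit = k, e)
  }))
  utils::write.csv(entries, file.path(outDir, "comparison_entries.csv"),
                   row.names = FALSE)
  utils::write.csv(run$fractions$per_unit,
                   file.path(outDir, "comparison_fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary$per_group$per_group,
                   file.path(outDir, "group_summary.csv"), row.names = FALSE)
  utils::write.table(run$assignment,
                     file.path(outDir, "assignments.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  exportPresenceAbsence(run$taxa[run$taxa$group != "POOL", ],
                        file.path(outDir, "presence_absence_sorted.csv"))
  manifest <- list(
    seed = run$sim$config$seed,
    config = unclass(run$sim$config),
    threshold_derived = run$summary$threshold_derived,
    threshold_applied = run$summary$threshold_applied,
    package_version = as.character(utils::packageVersion("MetabarComp")),
    r_version = R.version.string,
    timings_sec = as.list(round(run$timings, 3)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
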