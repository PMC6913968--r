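## Synthetic study generator: taxonomy + register, reference databases with
## coverage gaps, morphological lists with identification noise, sorted and
## pooled MOTU tables with preferential amplification, haplotype splitting,
## pseudogenes, spike-in cross-contamination and failed samples -- with full
## ground truth.

.GROUPS <- c("ANNE", "CRUS", "HECO", "MOLL", "TOE", "REST")

#' Simulation configuration
#'
#' Defaults emulate the monitoring-study conditions: 25 locations sorted
#' into six taxon groups, two PCR replicates per sample, reference-database
#' coverage lowest for annelids (63.5%) and highest for the
#' Trichoptera/Odonata/Ephemeroptera group (96.5%), mollusc samples failing
#' to amplify more than half the time, lognormal biomass, group-level
#' preferential amplification in the pools (producing single-taxon
#' dominance), haplotype splitting of species into several MOTUs,
#' low-abundance pseudogene MOTUs, and spike-in (AIC) cross-contamination
#' below the 0.025% filtering level.
#'
#' @param seed integer seed; every output is bit-reproducible given it.
#' @param nLocations number of sampling locations.
#' @param poolSizes named integer vector: regional species pool per group.
#' @param refCoverage named fractions: share of each group's pool with
#'   reference sequences.
#' @param meanRichness named Poisson means: species per (location, group).
#' @param failureProb named per-group probability that a sorted sample
#'   fails to amplify; `pooledFailureProb` is the analogue for pools.
#' @param biomassSigma lognormal sd of per-species biomass.
#' @param dominanceSigma lognormal sd of the group-level amplification
#'   factor applied in the pools (the dominance dial; 0 disables it).
#' @param speciesAmpSigma lognormal sd of per-species amplification jitter.
#' @param haplotypeLambda Poisson rate for extra haplotype MOTUs per species.
#' @param pseudogeneRate,pseudogeneDepletion probability that a species
#'   carries a pseudogene MOTU, and its relative read weight.
#' @param aicContamProb,contamRelRange probability that a regular replicate
#'   receives AIC reads, and the relative-abundance range of such carry-over.
#' @param controlForeignProb probability that a control replicate receives
#'   foreign (non-AIC) reads.
#' @param nControls number of AIC control samples (two replicates each).
#' @param depthMeanLog,depthSdLog,depthMin,depthMax replicate depth model.
#' @param failedDepthRange read-depth range of failed replicates.
#' @param misidRate probability a morphological record is a congeneric
#'   misidentification.
#' @param genusLevelRate probability a morphological record stops at genus.
#' @param morphMissRate probability a species present in the bulk sample is
#'   overlooked in the morphological assessment (it can still be detected by
#'   DNA, feeding the DNA-only fraction).
#' @param synonymRate share of species that carry a register synonym;
#'   `synonymUseRate` is the chance a record (or reference entry) uses it.
#' @param subspeciesRate share of species carrying a subspecies name.
#' @param nonRegisterRate share of extra non-register species per genus
#'   pool; `nonRegisterHitRate` the chance one shows up as a direct hit.
#' @param genusRefHitRate chance of a genus-level reference direct hit.
#' @param nContaminantMotus,contamMotuProb,contamMotuRelRange non-target
#'   contaminant MOTUs (e.g. human) and their occurrence model.
#' @param pooledFailureProb probability a pooled sample fails.
#' @return a named list of class `simConfig`.
#' @export
simConfig <- function(seed,
    nLocations = 25L,
    poolSizes = c(ANNE = 85L, CRUS = 60L, HECO = 150L, MOLL = 70L,
                  TOE = 283L, REST = 300L),
    refCoverage = c(ANNE = 0.635, CRUS = 0.95, HECO = 0.95, MOLL = 0.90,
                    TOE = 0.965, REST = 0.92),
    meanRichness = c(ANNE = 6, CRUS = 4, HECO = 8, MOLL = 6, TOE = 8,
                     REST = 14),
    failureProb = c(ANNE = 0.16, CRUS = 0.04, HECO = 0.12, MOLL = 0.54,
                    TOE = 0.04, REST = 0),
    biomassSigma = 2.0, dominanceSigma = 2.0, speciesAmpSigma = 1.5,
    haplotypeLambda = 0.6, pseudogeneRate = 0.15, pseudogeneDepletion = 0.01,
    aicContamProb = 0.3, contamRelRange = c(2e-05, 2.4e-04),
    controlForeignProb = 0.5, nControls = 2L,
    depthMeanLog = log(28000), depthSdLog = 0.35,
    depthMin = 4200, depthMax = 70000, failedDepthRange = c(200, 3900),
    misidRate = 0.05, genusLevelRate = 0.10, morphMissRate = 0.15,
    synonymRate = 0.05, synonymUseRate = 0.05, subspeciesRate = 0.02,
    nonRegisterRate = 0.05, nonRegisterHitRate = 0.05,
    genusRefHitRate = 0.08,
    nContaminantMotus = 3L, contamMotuProb = 0.15,
    contamMotuRelRange = c(5e-04, 5e-03),
    pooledFailureProb = 0.04) {
  stopifnot(!missing(seed), all(refCoverage >= 0 & refCoverage <= 1),
            all(failureProb >= 0 & failureProb <= 1))
  cfg <- as.list(environment())
  class(cfg) <- "simConfig"
  cfg
}

.simTaxonomy <- function(cfg) {
  rows <- list()
  prefix <- c(ANNE = "Anne", CRUS = "Crus", HECO = "Heco", MOLL = "Moll",
              TOE = "Toe", REST = "Rest")
  for (g in .GROUPS) {
    pool <- cfg$poolSizes[[g]]
    nGen <- max(2L, ceiling(pool / 3))
    nFam <- max(2L, ceiling(nGen / 4))
    nOrd <- max(2L, ceiling(nFam / 3))
    p <- prefix[[g]]
    ords <- sprintf("%sformes%02d", p, seq_len(nOrd))
    fams <- sprintf("%sidae%02d", p, seq_len(nFam))
    gens <- sprintf("%sgen%03d", p, seq_len(nGen))
    famOrd <- ords[1L + (seq_len(nFam) - 1L) %% nOrd]
    genFam <- fams[1L + (seq_len(nGen) - 1L) %% nFam]
    nsp <- rep(1L, nGen)
    if (pool > nGen)
      nsp <- nsp + tabulate(sample.int(nGen, pool - nGen, replace = TRUE),
                            nGen)
    rows[[length(rows) + 1L]] <- data.frame(
      name = ords, rank = "order", parent = NA_character_,
      canonical_name = NA_character_, in_register = TRUE, group = g)
    rows[[length(rows) + 1L]] <- data.frame(
      name = fams, rank = "family", parent = famOrd,
      canonical_name = NA_character_, in_register = TRUE,
      group = NA_character_)
    rows[[length(rows) + 1L]] <- data.frame(
      name = gens, rank = "genus", parent = genFam,
      canonical_name = NA_character_, in_register = TRUE,
      group = NA_character_)
    sp <- unlist(lapply(seq_len(nGen), function(i)
      sprintf("%s sp%d", gens[i], seq_len(nsp[i]))))
    spGen <- rep(gens, nsp)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sp, rank = "species", parent = spGen,
      canonical_name = NA_character_, in_register = TRUE,
      group = NA_character_)
    ## non-register (foreign) congeners occasionally present in reference data
    nNR <- ceiling(cfg$nonRegisterRate * pool)
    nrGen <- gens[sample.int(nGen, nNR, replace = TRUE)]
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("%s foreign%d", nrGen, seq_len(nNR)), rank = "species",
      parent = nrGen, canonical_name = NA_character_, in_register = FALSE,
      group = NA_character_)
    ## synonyms and subspecies for a share of register species
    hasSyn <- sp[stats::runif(length(sp)) < cfg$synonymRate]
    if (length(hasSyn))
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(hasSyn, " olim"), rank = "species",
        parent = NA_character_, canonical_name = hasSyn,
        in_register = FALSE, group = NA_character_)
    hasSsp <- sp[stats::runif(length(sp)) < cfg$subspeciesRate]
    if (length(hasSsp))
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(hasSsp, "sspA"), rank = "subspecies", parent = hasSsp,
        canonical_name = NA_character_, in_register = TRUE,
        group = NA_character_)
  }
  taxonomyTree(do.call(rbind, rows))
}

.lineageString <- function(tree, taxon) {
  i <- match(taxon, tree@lineage$name)
  v <- unlist(tree@lineage[i, .RANKS[1:4]])
  paste(v[!is.na(v)][seq_len(.rankDepth(tree@lineage$rank[i]))],
        collapse = "/")
}

.bits <- function(pident, qcovs = 100) round(5.8 * pident * qcovs / 100)

#' Simulate a full metabarcoding study
#'
#' Generates, from one seed: the taxonomy/register, a reference database
#' with per-group coverage gaps, per-location communities sorted into six
#' groups, morphological taxon lists with congeneric misidentifications and
#' resolution noise, sorted and pooled MOTU read tables (two PCR replicates
#' per sample, plus AIC control replicates) with haplotype splitting,
#' pseudogene MOTUs, non-target contaminant MOTUs and AIC cross-
#' contamination, dual-database hit tables, and the complete ground truth.
#'
#' @param cfg a [simConfig()].
#' @return list with elements `tree` ([TaxonomyTree-class]), `me`
#'   (replicate-level [MotuExperiment-class] including controls), `hits`
#'   (dual-database hit table), `morphology` (data.frame `location`,
#'   `group`, `taxon`, `count`), `refdbSpecies`, `truth` (list: `community`,
#'   `motuMap`, `swaps`, `failures`, `groupAmp`, `covered`) and `config`.
#' @export
simulateStudy <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  tree <- .simTaxonomy(cfg)
  nodes <- tree@nodes
  regAll <- nodes$name[nodes$rank == "species" & nodes$in_register &
                       is.na(nodes$canonical_name)]
  regSpecies <- split(regAll, groupOf(tree, regAll))
  nrSpecies <- nodes$name[nodes$rank == "species" & !nodes$in_register &
                          is.na(nodes$canonical_name)]
  synOf <- stats::setNames(nodes$name[!is.na(nodes$canonical_name)],
                           nodes$canonical_name[!is.na(nodes$canonical_name)])
  sspOf <- stats::setNames(nodes$name[nodes$rank == "subspecies"],
                           nodes$parent[nodes$rank == "subspecies"])
  genusOfSp <- stats::setNames(nodes$parent[nodes$rank == "species"],
                               nodes$name[nodes$rank == "species"])

  ## reference coverage per group
  covered <- unlist(lapply(.GROUPS, function(g) {
    sp <- regSpecies[[g]]
    sp[sample.int(length(sp), round(cfg$refCoverage[[g]] * length(sp)))]
  }), use.names = FALSE)

  locs <- sprintf("L%02d", seq_len(cfg$nLocations))

  ## communities
  comm <- list()
  for (loc in locs) for (g in .GROUPS) {
    pool <- regSpecies[[g]]
    rich <- min(stats::rpois(1L, cfg$meanRichness[[g]]), length(pool))
    if (rich == 0L) next
    sp <- pool[sample.int(length(pool), rich)]
    comm[[length(comm) + 1L]] <- data.frame(
      location = loc, group = g, species = sp,
      biomass = stats::rlnorm(rich, 0, cfg$biomassSigma),
      stringsAsFactors = FALSE)
  }
  community <- do.call(rbind, comm)

  allSpecies <- sort(unique(community$species))
  speciesAmp <- stats::setNames(
    stats::rlnorm(length(allSpecies), 0, cfg$speciesAmpSigma), allSpecies)

  ## MOTUs: haplotypes + pseudogenes per species, one AIC, some contaminants
  nHap <- 1L + stats::rpois(length(allSpecies), cfg$haplotypeLambda)
  hasPseudo <- stats::runif(length(allSpecies)) < cfg$pseudogeneRate
  hapIdx <- unlist(lapply(nHap, seq_len))
  motuMap <- data.frame(taxon = rep(allSpecies, nHap), type = "haplotype",
                        hap = hapIdx, weight = 0.3 ^ (hapIdx - 1L),
                        stringsAsFactors = FALSE)
  if (any(hasPseudo))
    motuMap <- rbind(motuMap, data.frame(
      taxon = allSpecies[hasPseudo], type = "pseudogene", hap = 0L,
      weight = cfg$pseudogeneDepletion, stringsAsFactors = FALSE))
  motuMap <- motuMap[order(motuMap$taxon, -motuMap$weight), , drop = FALSE]
  rownames(motuMap) <- NULL
  motuMap$motu <- sprintf("motu%05d", seq_len(nrow(motuMap)))
  contamSpecies <- list(
    c("Homo sapiens", "Primates/Hominidae/Homo/Homo sapiens"),
    c("Wolbachia pipientis",
      "Rickettsiales/Anaplasmataceae/Wolbachia/Wolbachia pipientis"),
    c("Penicillium chrysogenum",
      "Eurotiales/Aspergillaceae/Penicillium/Penicillium chrysogenum"))
  nCM <- min(cfg$nContaminantMotus, length(contamSpecies))
  contamMotus <- if (nCM > 0L) sprintf("motuCNT%02d", seq_len(nCM))
                 else character(0)
  aicMotu <- "motuAIC"
  allMotus <- c(motuMap$motu, contamMotus, aicMotu)
  motuOfSp <- split(seq_len(nrow(motuMap)), motuMap$taxon)

  groupAmp <- matrix(stats::rlnorm(length(locs) * length(.GROUPS), 0,
                                   cfg$dominanceSigma),
                     length(locs), length(.GROUPS),
                     dimnames = list(locs, .GROUPS))

  drawDepth <- function() as.integer(round(min(max(
    stats::rlnorm(1L, cfg$depthMeanLog, cfg$depthSdLog),
    cfg$depthMin), cfg$depthMax)))

  counts <- list(); failures <- list()
  cm <- list(sample = character(0), location = character(0),
             group = character(0), replicate = integer(0),
             is_control = logical(0))
  .emit <- function(name, vec, sample, location, group, repIdx, ctrl) {
    counts[[name]] <<- vec
    cm$sample <<- c(cm$sample, sample)
    cm$location <<- c(cm$location, location)
    cm$group <<- c(cm$group, group)
    cm$replicate <<- c(cm$replicate, repIdx)
    cm$is_control <<- c(cm$is_control, ctrl)
  }
  .replicate <- function(unitIdx, ampVec, depth) {
    ## unitIdx: rows of motuMap active in this unit, ampVec: per-row weight
    x <- stats::rmultinom(1L, depth, ampVec)[, 1L]
    v <- integer(length(allMotus))
    names(v) <- allMotus
    v[motuMap$motu[unitIdx]] <- x
    ## AIC carry-over (proportional; vanishes in shallow replicates)
    if (stats::runif(1L) < cfg$aicContamProb)
      v[aicMotu] <- as.integer(floor(
        depth * stats::runif(1L, cfg$contamRelRange[1], cfg$contamRelRange[2])))
    ## non-target contaminant MOTUs
    if (nCM > 0L && stats::runif(1L) < cfg$contamMotuProb) {
      cm <- contamMotus[sample.int(nCM, 1L)]
      v[cm] <- as.integer(round(depth * stats::runif(
        1L, cfg$contamMotuRelRange[1], cfg$contamMotuRelRange[2])))
    }
    v
  }
  unitWeights <- function(sp, biomass, gAmp = NULL) {
    idx <- unlist(motuOfSp[sp], use.names = FALSE)
    spw <- stats::setNames(biomass * speciesAmp[sp], sp)
    if (!is.null(gAmp)) spw <- spw * gAmp[sp]
    w <- spw[motuMap$taxon[idx]] * motuMap$weight[idx]
    list(idx = idx, w = unname(w))
  }

  for (loc in locs) {
    cu <- community[community$location == loc, , drop = FALSE]
    ## sorted samples
    for (g in unique(cu$group)) {
      sub <- cu[cu$group == g, , drop = FALSE]
      uw <- unitWeights(sub$species, sub$biomass)
      smp <- paste(loc, g, sep = "_")
      fail <- stats::runif(1L) < cfg$failureProb[[g]]
      if (fail)
        failures[[length(failures) + 1L]] <- data.frame(
          location = loc, group = g, origin = "sorted",
          stringsAsFactors = FALSE)
      for (r in 1:2) {
        depth <- if (fail)
          as.integer(round(stats::runif(1L, cfg$failedDepthRange[1],
                                        cfg$failedDepthRange[2])))
          else drawDepth()
        .emit(paste0(smp, "_r", r), .replicate(uw$idx, uw$w, depth),
              smp, loc, g, r, FALSE)
      }
    }
    ## pooled sample: group-level amplification factors compound here
    gAmp <- stats::setNames(groupAmp[loc, cu$group], cu$species)
    uw <- unitWeights(cu$species, cu$biomass, gAmp)
    smp <- paste(loc, "POOL", sep = "_")
    fail <- stats::runif(1L) < cfg$pooledFailureProb
    if (fail)
      failures[[length(failures) + 1L]] <- data.frame(
        location = loc, group = "POOL", origin = "pooled",
        stringsAsFactors = FALSE)
    for (r in 1:2) {
      depth <- if (fail)
        as.integer(round(stats::runif(1L, cfg$failedDepthRange[1],
                                      cfg$failedDepthRange[2])))
        else drawDepth()
      .emit(paste0(smp, "_r", r), .replicate(uw$idx, uw$w, depth),
            smp, loc, "POOL", r, FALSE)
    }
  }
  ## AIC control samples
  for (i in seq_len(cfg$nControls)) for (r in 1:2) {
    depth <- drawDepth()
    v <- integer(length(allMotus)); names(v) <- allMotus
    v[aicMotu] <- depth
    if (stats::runif(1L) < cfg$controlForeignProb) {
      fm <- motuMap$motu[sample.int(nrow(motuMap), 1L)]
      v[fm] <- as.integer(floor(depth * stats::runif(
        1L, cfg$contamRelRange[1], cfg$contamRelRange[2])))
    }
    smp <- sprintf("CTRL%02d", i)
    .emit(paste0(smp, "_r", r), v, smp, "CTRL", "CTRL", r, TRUE)
  }

  cnt <- do.call(cbind, counts)
  rownames(cnt) <- allMotus
  me <- MotuExperiment(cnt, as.data.frame(cm, stringsAsFactors = FALSE),
                       data.frame(is_aic = allMotus == aicMotu,
                                  row.names = allMotus))

  ## hit tables
  coveredByGenus <- split(covered, genusOfSp[covered])
  coveredByFamily <- split(covered, vapply(covered, function(s)
    unname(lineageOf(tree, s)["family"]), ""))
  hc <- list(motu = character(0), taxon = character(0), rank = character(0),
             pident = numeric(0), qcovs = numeric(0), bitscore = numeric(0),
             db = character(0), lineage = character(0))
  addHit <- function(motu, taxon, rank, pident, qcovs, bits, db, lineage) {
    hc$motu <<- c(hc$motu, motu); hc$taxon <<- c(hc$taxon, taxon)
    hc$rank <<- c(hc$rank, rank)
    hc$pident <<- c(hc$pident, round(pident, 1))
    hc$qcovs <<- c(hc$qcovs, round(qcovs, 1))
    hc$bitscore <<- c(hc$bitscore, bits)
    hc$db <<- c(hc$db, db); hc$lineage <<- c(hc$lineage, lineage)
  }
  runifn <- function(a, b) stats::runif(1L, a, b)
  for (k in seq_len(nrow(motuMap))) {
    m <- motuMap$motu[k]; s <- motuMap$taxon[k]
    g <- genusOfSp[[s]]
    isCov <- s %in% covered
    congen <- setdiff(coveredByGenus[[g]], s)
    if (motuMap$type[k] == "haplotype" && isCov) {
      p0 <- if (motuMap$hap[k] == 1L) runifn(98.6, 100) else runifn(98.05, 99.6)
      addHit(m, s, "species", p0, 100, .bits(p0), "wfd_custom",
             .lineageString(tree, s))
      if (!is.na(synOf[s]) && stats::runif(1L) < cfg$synonymUseRate)
        addHit(m, synOf[[s]], "species", p0 - runifn(0, 0.3), 100,
               .bits(p0) - 2L, "wfd_custom", .lineageString(tree, s))
      if (stats::runif(1L) < cfg$genusRefHitRate)
        addHit(m, g, "genus", runifn(98.1, 99.2), 100, .bits(98.5),
               "wfd_custom", .lineageString(tree, g))
      nrCon <- nrSpecies[genusOfSp[nrSpecies] == g]
      if (length(nrCon) && stats::runif(1L) < cfg$nonRegisterHitRate)
        addHit(m, nrCon[1L], "species", runifn(98.1, 99.0), 100, .bits(98.4),
               "wfd_custom", .lineageString(tree, nrCon[1L]))
      for (cs in utils::head(congen, 3L)) {
        p <- runifn(85, 95)
        addHit(m, cs, "species", p, runifn(92, 100), .bits(p), "wfd_custom",
               .lineageString(tree, cs))
      }
      addHit(m, s, "species", p0 - runifn(0, 0.5), 100,
             .bits(p0) - sample(5:40, 1L), "genbank",
             .lineageString(tree, s))
    } else if (motuMap$type[k] == "pseudogene") {
      p0 <- runifn(90, 96)
      if (isCov)
        addHit(m, s, "species", p0, runifn(90, 100), .bits(p0), "wfd_custom",
               .lineageString(tree, s))
      for (cs in utils::head(congen, 2L)) {
        p <- runifn(84, 92)
        addHit(m, cs, "species", p, runifn(90, 100), .bits(p), "wfd_custom",
               .lineageString(tree, cs))
      }
      if (isCov)
        addHit(m, s, "species", p0 - runifn(0, 0.5), runifn(90, 100),
               .bits(p0) - sample(5:40, 1L), "genbank",
               .lineageString(tree, s))
    } else {
      ## uncovered species: only congeneric / confamilial reference entries
      if (length(congen)) {
        for (cs in utils::head(congen, 4L)) {
          p <- runifn(85, 95)
          addHit(m, cs, "species", p, runifn(90, 100), .bits(p),
                 "wfd_custom", .lineageString(tree, cs))
        }
      } else {
        fam <- unname(lineageOf(tree, s)["family"])
        rel <- setdiff(coveredByFamily[[fam]], s)
        for (cs in utils::head(rel, 3L)) {
          p <- runifn(80, 88)
          addHit(m, cs, "species", p, runifn(90, 100), .bits(p),
                 "wfd_custom", .lineageString(tree, cs))
        }
      }
    }
  }
  for (i in seq_len(nCM)) {
    rs <- allSpecies[sample.int(length(allSpecies), 1L)]
    p <- runifn(80, 83)
    addHit(contamMotus[i], rs, "species", p, runifn(80, 95),
           round(2.0 * p), "wfd_custom", .lineageString(tree, rs))
    addHit(contamMotus[i], contamSpecies[[i]][1], "species", runifn(99, 100),
           100, 600L, "genbank", contamSpecies[[i]][2])
  }
  addHit(aicMotu, "Muntiacus reevesi", "species", 100, 100, 600L, "genbank",
         "Artiodactyla/Cervidae/Muntiacus/Muntiacus reevesi")
  hits <- as.data.frame(hc, stringsAsFactors = FALSE)

  ## morphology with identification noise
  congenersOf <- lapply(stats::setNames(nm = allSpecies), function(s)
    setdiff(regAll[genusOfSp[regAll] == genusOfSp[[s]]], s))
  n <- nrow(community)
  rec <- community$species
  u <- stats::runif(n)
  missed <- stats::runif(n) < cfg$morphMissRate
  swaps <- list()
  for (i in seq_len(n)) {
    if (missed[i]) next
    s <- community$species[i]
    pool <- congenersOf[[s]]
    if (u[i] < cfg$misidRate && length(pool)) {
      rec[i] <- pool[sample.int(length(pool), 1L)]
      swaps[[length(swaps) + 1L]] <- data.frame(
        location = community$location[i], group = community$group[i],
        true_species = s, recorded = rec[i], stringsAsFactors = FALSE)
    } else if (u[i] < cfg$misidRate + cfg$genusLevelRate) {
      rec[i] <- genusOfSp[[s]]
    } else if (!is.na(synOf[s]) &&
               u[i] < cfg$misidRate + cfg$genusLevelRate + cfg$synonymUseRate) {
      rec[i] <- synOf[[s]]
    } else if (!is.na(sspOf[s]) &&
               u[i] < cfg$misidRate + cfg$genusLevelRate + cfg$synonymUseRate +
                      cfg$subspeciesRate) {
      rec[i] <- sspOf[[s]]
    }
  }
  morphology <- data.frame(location = community$location,
                           group = community$group, taxon = rec,
                           count = 1L + stats::rpois(n, 5),
                           stringsAsFactors = FALSE)[!missed, , drop = FALSE]
  morphology <- stats::aggregate(count ~ location + group + taxon,
                                 morphology, sum)
  morphology <- morphology[order(morphology$location, morphology$group,
                                 morphology$taxon), ]
  rownames(morphology) <- NULL

  truth <- list(
    community = community,
    morph_missed = community[missed, c("location", "group", "species")],
    motuMap = motuMap[, c("motu", "taxon", "type", "hap", "weight")],
    swaps = if (length(swaps)) do.call(rbind, swaps) else
      data.frame(location = character(0), group = character(0),
                 true_species = character(0), recorded = character(0)),
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(location = character(0), group = character(0),
                 origin = character(0)),
    groupAmp = groupAmp,
    covered = covered,
    contaminantMotus = contamMotus,
    aicMotu = aicMotu)
  list(tree = tree, me = me, hits = hits, morphology = morphology,
       refdbSpecies = covered, truth = truth, config = cfg)
}
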