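## Sequence QC stand-ins and MOTU-table processing.

#' Quality-control configuration
#'
#' Defaults follow the study conditions for the 316 bp COI fragment: reads
#' outside 313-319 bp discarded, dereplication minimum abundance 2,
#' clustering identity 98%.
#'
#' @param len_min,len_max inclusive length window (bp).
#' @param min_derep_abundance minimum abundance retained after dereplication.
#' @param cluster_identity pairwise identity fraction for greedy clustering.
#' @export
qcConfig <- function(len_min = 313L, len_max = 319L,
                     min_derep_abundance = 2L, cluster_identity = 0.98) {
  stopifnot(len_min <= len_max, cluster_identity > 0, cluster_identity <= 1)
  list(len_min = len_min, len_max = len_max,
       min_derep_abundance = min_derep_abundance,
       cluster_identity = cluster_identity)
}

#' MOTU-table filtering configuration
#'
#' @param motu_rel_abundance_threshold per-replicate relative-abundance
#'   threshold; MOTUs at or below it are zeroed (strictly-above retained).
#' @param min_replicate_reads replicates with fewer reads are discarded.
#' @param replicate_combination only `"additive"` is implemented: surviving
#'   replicates are summed, counting every MOTU irrespective of how many
#'   replicates it occurred in.
#' @export
filterConfig <- function(motu_rel_abundance_threshold = 0.00025,
                         min_replicate_reads = 4000L,
                         replicate_combination = "additive") {
  stopifnot(motu_rel_abundance_threshold >= 0,
            motu_rel_abundance_threshold < 1,
            replicate_combination == "additive")
  list(motu_rel_abundance_threshold = motu_rel_abundance_threshold,
       min_replicate_reads = min_replicate_reads,
       replicate_combination = replicate_combination)
}

#' Length-filter sequences
#'
#' Retains sequences with length inside the inclusive `[len_min, len_max]`
#' window.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet].
#' @param cfg a [qcConfig()].
#' @return the retained subset of `seqs`.
#' @export
filterByLength <- function(seqs, cfg = qcConfig()) {
  len <- if (inherits(seqs, "XStringSet")) Biostrings::width(seqs)
         else nchar(seqs)
  seqs[len >= cfg$len_min & len <= cfg$len_max]
}

#' Dereplicate sequences
#'
#' Exact-identity grouping; groups below `min_derep_abundance` are dropped;
#' output is sorted by abundance descending with ties broken by first
#' occurrence.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet] of reads.
#' @param cfg a [qcConfig()].
#' @return data.frame with columns `sequence`, `abundance`.
#' @export
dereplicate <- function(seqs, cfg = qcConfig()) {
  s <- as.character(seqs)
  u <- s[!duplicated(s)]
  ab <- as.integer(table(factor(s, levels = u)))
  keep <- ab >= cfg$min_derep_abundance
  u <- u[keep]; ab <- ab[keep]
  o <- order(-ab, seq_along(ab))
  data.frame(sequence = u[o], abundance = ab[o], stringsAsFactors = FALSE)
}

.pairIdentity <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = 4, gapExtension = 2)
  ## identity = matches / alignment length (gapped columns included)
  alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / alnLen
}

#' Greedy centroid clustering
#'
#' Abundance-ordered greedy clustering: each sequence joins the first
#' existing centroid whose global-alignment identity (matches / alignment
#' length) is at least `cluster_identity`, otherwise it founds a new
#' centroid. A simplified desk-scale analogue of abundance-sorted centroid
#' clustering as used by OTU pickers.
#'
#' @param derep data.frame from [dereplicate()] (abundance-descending).
#' @param cfg a [qcConfig()].
#' @return list with `clusters` (input plus `motu` column) and `centroids`
#'   (data.frame `motu`, `sequence`, `abundance` = member total).
#' @export
greedyCluster <- function(derep, cfg = qcConfig()) {
  n <- nrow(derep)
  motu <- integer(n)
  centSeq <- character(0)
  for (i in seq_len(n)) {
    s <- derep$sequence[i]
    hit <- 0L
    for (j in seq_along(centSeq)) {
      if (.pairIdentity(s, centSeq[j]) >= cfg$cluster_identity) { hit <- j; break }
    }
    if (hit == 0L) {
      centSeq <- c(centSeq, s)
      hit <- length(centSeq)
    }
    motu[i] <- hit
  }
  clusters <- cbind(derep, motu = motu)
  centroids <- data.frame(
    motu = seq_along(centSeq), sequence = centSeq,
    abundance = as.integer(tapply(derep$abundance, motu, sum)),
    stringsAsFactors = FALSE)
  list(clusters = clusters, centroids = centroids)
}

#' Contamination threshold from the internal control
#'
#' The artificial internal control (AIC) is amplified in dedicated control
#' replicates; AIC reads observed in regular replicates, and foreign reads
#' observed in control replicates, measure cross-contamination. This returns
#' the smallest relative-abundance threshold `t` such that zeroing, per
#' replicate, every MOTU with relative abundance `<= t` removes all AIC
#' reads from non-control replicates and all non-AIC MOTUs from control
#' replicates -- i.e. the maximum offending relative abundance, or 0 when no
#' cross-contamination exists.
#'
#' @param x a [MotuExperiment-class] containing at least one control
#'   replicate with the AIC MOTU flagged.
#' @return a fraction in `[0, 1)`.
#' @export
contaminationThreshold <- function(x) {
  ctrl <- isControl(x)
  if (!any(ctrl)) stop("no control replicates in the table")
  aic <- isAic(x)
  cnt <- motuCounts(x)
  tot <- colSums(cnt)
  rel <- sweep(cnt, 2, pmax(tot, 1L), "/")
  off <- c(rel[aic, !ctrl, drop = FALSE][cnt[aic, !ctrl, drop = FALSE] > 0],
           rel[!aic, ctrl, drop = FALSE][cnt[!aic, ctrl, drop = FALSE] > 0])
  if (length(off) == 0L) 0 else max(off)
}

#' Per-replicate low-abundance MOTU filter
#'
#' Zeroes every count whose relative abundance within its replicate is at or
#' below `threshold` (strictly-above retained). Denominators are the
#' replicate totals before filtering.
#'
#' @param x a [MotuExperiment-class].
#' @param threshold relative-abundance threshold (fraction); defaults to the
#'   configured study value of 0.025%.
#' @return the filtered [MotuExperiment-class]; the threshold is recorded in
#'   `metadata(x)$abundance_threshold`.
#' @export
filterLowAbundance <- function(x, threshold = filterConfig()$motu_rel_abundance_threshold) {
  cnt <- motuCounts(x)
  tot <- colSums(cnt)
  rel <- sweep(cnt, 2, pmax(tot, 1L), "/")
  cnt[rel <= threshold] <- 0L
  assays(x)$counts <- cnt
  metadata(x)$abundance_threshold <- threshold
  x
}

#' Discard shallow replicates and combine the rest additively
#'
#' Replicates whose (post-filter) total is strictly below
#' `min_replicate_reads` are discarded. Surviving replicates of each
#' non-control sample are merged by summing counts (union of MOTUs). Samples
#' that lose all replicates are recorded as failed. Control replicates are
#' dropped from the merged table.
#'
#' @param x a [MotuExperiment-class] at replicate level.
#' @param cfg a [filterConfig()].
#' @return a [MotuExperiment-class] with one column per surviving sample;
#'   `metadata()$failed` holds a data.frame (`sample`, `location`, `group`)
#'   of failed samples and `metadata()$discarded_replicates` the discarded
#'   replicate names.
#' @export
discardAndCombine <- function(x, cfg = filterConfig()) {
  cnt <- motuCounts(x)
  cd <- as.data.frame(colData(x))
  tot <- colSums(cnt)
  keep <- tot >= cfg$min_replicate_reads & !cd$is_control
  samples <- unique(cd$sample[!cd$is_control])
  merged <- matrix(0L, nrow(cnt), 0L)
  info <- list(); failed <- list()
  for (s in samples) {
    cols <- which(cd$sample == s & keep)
    meta <- cd[cd$sample == s, , drop = FALSE][1L, ]
    if (length(cols) == 0L) {
      failed[[s]] <- data.frame(sample = s, location = meta$location,
                                group = meta$group, stringsAsFactors = FALSE)
      next
    }
    merged <- cbind(merged, as.integer(rowSums(cnt[, cols, drop = FALSE])))
    info[[s]] <- data.frame(sample = s, location = meta$location,
                            group = meta$group, replicate = length(cols),
                            is_control = FALSE, stringsAsFactors = FALSE)
  }
  colnames(merged) <- names(info)
  rownames(merged) <- rownames(cnt)
  out <- MotuExperiment(merged, do.call(rbind, info),
                        as.data.frame(rowData(x)))
  metadata(out) <- metadata(x)
  metadata(out)$failed <- if (length(failed)) do.call(rbind, failed)
    else data.frame(sample = character(0), location = character(0),
                    group = character(0))
  metadata(out)$discarded_replicates <-
    colnames(cnt)[!keep & !cd$is_control]
  out
}

#' Rarefy a count vector to fixed depth
#'
#' Uniform subsampling of reads without replacement (multivariate
#' hypergeometric), deterministic under the supplied seed.
#'
#' @param counts named non-negative integer vector (reads per MOTU or taxon).
#' @param depth target read depth; must not exceed `sum(counts)`.
#' @param seed integer seed.
#' @return rarefied counts, same names and order.
#' @export
rarefyCounts <- function(counts, depth, seed) {
  if (sum(counts) < depth)
    stop("total reads (", sum(counts), ") below rarefaction depth ", depth)
  set.seed(seed)
  ## rrarefy warns when the smallest nonzero count exceeds 1; our inputs are
  ## genuine read counts, so that heuristic does not apply
  out <- as.integer(suppressWarnings(vegan::rrarefy(counts, depth)))
  names(out) <- names(counts)
  out
}
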