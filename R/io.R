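## Plain-text interchange: MOTU table TSV + replicate sidecar CSV,
## BLAST-tabular-style hit TSVs with lineage column, register CSV,
## morphology CSV, truth JSON.

#' Write / read a MOTU read-count table
#'
#' The table is a TSV whose first column is the MOTU id and remaining
#' columns are replicates; replicate annotations (sample, location, group,
#' replicate index, control flag) travel in a sidecar CSV; the AIC flag per
#' MOTU goes in a second sidecar.
#'
#' @param x a [MotuExperiment-class].
#' @param path TSV path; sidecars are written next to it as
#'   `<path>.replicates.csv` and `<path>.motus.csv`.
#' @export
writeMotuTable <- function(x, path) {
  cnt <- motuCounts(x)
  utils::write.table(cbind(motu = rownames(cnt), as.data.frame(cnt)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(replicate_id = colnames(cnt),
                         as.data.frame(colData(x))),
                   paste0(path, ".replicates.csv"), row.names = FALSE)
  utils::write.csv(cbind(motu = rownames(cnt),
                         as.data.frame(rowData(x))),
                   paste0(path, ".motus.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeMotuTable
#' @param path TSV path written by [writeMotuTable()].
#' @return a [MotuExperiment-class].
#' @export
readMotuTable <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  cnt <- as.matrix(tab[, -1, drop = FALSE])
  rownames(cnt) <- tab[[1]]
  reps <- utils::read.csv(paste0(path, ".replicates.csv"),
                          stringsAsFactors = FALSE)
  stopifnot(identical(reps$replicate_id, colnames(cnt)))
  motus <- utils::read.csv(paste0(path, ".motus.csv"),
                           stringsAsFactors = FALSE)
  stopifnot(identical(motus$motu, rownames(cnt)))
  MotuExperiment(cnt, reps[, setdiff(names(reps), "replicate_id")],
                 motus[, setdiff(names(motus), "motu"), drop = FALSE])
}

#' Write / read a hit table
#'
#' BLAST outfmt-6-like TSV with columns `qseqid`, `sseqid`, `pident`,
#' `qcovs`, `bitscore` and a slash-delimited `lineage`
#' (`order/family/genus[/species]`); the subject taxon and its rank are
#' recovered from the lineage. One file per reference database.
#'
#' @param hits hit data.frame (internal layout, see [assignAll()]).
#' @param path TSV path.
#' @param db database label to stamp on read (`wfd_custom` or `genbank`).
#' @export
writeHitTable <- function(hits, path) {
  out <- data.frame(qseqid = hits$motu, sseqid = hits$taxon,
                    pident = hits$pident, qcovs = hits$qcovs,
                    bitscore = hits$bitscore, lineage = hits$lineage)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHitTable
#' @export
readHitTable <- function(path, db) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parts <- strsplit(tab$lineage, "/", fixed = TRUE)
  data.frame(motu = tab$qseqid, taxon = tab$sseqid,
             rank = .RANKS[lengths(parts)],
             pident = tab$pident, qcovs = tab$qcovs,
             bitscore = tab$bitscore, db = db, lineage = tab$lineage,
             stringsAsFactors = FALSE)
}

#' Write a simulated study to disk
#'
#' Emits exactly the formats the pipeline consumes: register CSV, MOTU TSV
#' with sidecars, one hit TSV per database, morphology CSV, and the ground
#' truth as JSON.
#'
#' @param sim a [simulateStudy()] result.
#' @param dir output directory (created if needed).
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$tree@nodes, file.path(dir, "register.csv"),
                   row.names = FALSE, na = "")
  writeMotuTable(sim$me, file.path(dir, "motu_table.tsv"))
  writeHitTable(sim$hits[sim$hits$db == "wfd_custom", ],
                file.path(dir, "hits_wfd.tsv"))
  writeHitTable(sim$hits[sim$hits$db == "genbank", ],
                file.path(dir, "hits_genbank.tsv"))
  utils::write.csv(sim$morphology, file.path(dir, "morphology.csv"),
                   row.names = FALSE)
  writeLines(sim$refdbSpecies, file.path(dir, "refdb_species.txt"))
  truth <- sim$truth
  truth$groupAmp <- as.data.frame(truth$groupAmp)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
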