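#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- colData rowData
NULL

## Ranks recognised by the package, shallowest first. Intermediate ranks
## (tribe, subfamily) are flattened at ingest.
.RANKS <- c("order", "family", "genus", "species", "subspecies")

.CATEGORIES <- c("found", "different_level", "putative_misid",
                 "missing_in_reference", "not_found", "extra")

#' Ranked taxonomic backbone
#'
#' Holds the register of canonical taxa (order, family, genus, species,
#' subspecies), their parent links, synonym rows pointing at canonical names,
#' register membership and, for order-rank rows, the coarse sorting group the
#' order belongs to. A pre-computed lineage table (order/family/genus/species
#' columns per canonical node) backs lowest-common-ancestor queries and
#' redundancy removal.
#'
#' @slot nodes data.frame with columns `name`, `rank`, `parent`,
#'   `canonical_name` (`NA` for canonical rows, otherwise the canonical name
#'   the row is a synonym of), `in_register`, `group`.
#' @slot lineage data.frame with one row per canonical node and columns
#'   `name`, `rank`, `order`, `family`, `genus`, `species`.
#' @export
setClass("TaxonomyTree",
         representation(nodes = "data.frame", lineage = "data.frame"))

setValidity("TaxonomyTree", function(object) {
  n <- object@nodes
  msg <- character(0)
  req <- c("name", "rank", "parent", "canonical_name", "in_register")
  if (!all(req %in% names(n)))
    return(paste("nodes must have columns:", paste(req, collapse = ", ")))
  if (anyDuplicated(n$name))
    msg <- c(msg, "duplicated node names")
  if (!all(n$rank %in% .RANKS))
    msg <- c(msg, "invalid rank(s)")
  syn <- !is.na(n$canonical_name)
  if (any(syn)) {
    tgt <- match(n$canonical_name[syn], n$name)
    if (anyNA(tgt))
      msg <- c(msg, "synonym target(s) missing from the tree")
    else {
      if (any(!is.na(n$canonical_name[tgt])))
        msg <- c(msg, "synonym chains are not allowed (targets must be canonical)")
      if (any(!n$in_register[tgt]))
        msg <- c(msg, "synonym targets must be register members")
    }
  }
  canon <- n[!syn, , drop = FALSE]
  notTop <- canon$rank != "order"
  if (any(notTop)) {
    pi <- match(canon$parent[notTop], canon$name)
    if (anyNA(pi))
      msg <- c(msg, "parent(s) missing from the tree")
    else {
      expect <- .RANKS[match(canon$rank[notTop], .RANKS) - 1L]
      if (any(canon$rank[pi] != expect))
        msg <- c(msg, "parent rank must be exactly one level shallower")
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' MOTU read-count experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `counts` assay (MOTUs in rows, PCR replicates or merged samples in
#' columns). Column metadata carries `sample`, `location`, `group` (one of
#' the six sorting groups, `POOL` for location pools, or `CTRL`),
#' `replicate` and `is_control`; row metadata carries `is_aic`, flagging the
#' artificial-internal-control construct used to gauge cross-contamination.
#'
#' @export
setClass("MotuExperiment", contains = "SummarizedExperiment")

setValidity("MotuExperiment", function(object) {
  msg <- character(0)
  if (!"counts" %in% names(assays(object)))
    return("a 'counts' assay is required")
  cnt <- assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  cd <- colData(object)
  reqC <- c("sample", "location", "group", "replicate", "is_control")
  if (!all(reqC %in% names(cd)))
    msg <- c(msg, paste("colData must have:", paste(reqC, collapse = ", ")))
  if (!"is_aic" %in% names(rowData(object)))
    msg <- c(msg, "rowData must have an 'is_aic' column")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @importFrom SummarizedExperiment assays
#' @describeIn MotuExperiment-class Constructor.
#' @param counts integer matrix, MOTUs x replicates, with dimnames.
#' @param replicates data.frame of column metadata (`sample`, `location`,
#'   `group`, `replicate`, `is_control`), one row per column of `counts`.
#' @param motus data.frame of row metadata (at least `is_aic`), one row per
#'   row of `counts`.
#' @export
MotuExperiment <- function(counts, replicates, motus = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(motus))
    motus <- data.frame(is_aic = rep(FALSE, nrow(counts)))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(replicates, row.names = colnames(counts)),
    rowData = DataFrame(motus, row.names = rownames(counts)))
  new("MotuExperiment", se)
}

#' @describeIn MotuExperiment-class Access the read-count matrix.
#' @param x a `MotuExperiment`.
#' @export
motuCounts <- function(x) assay(x, "counts")

#' @describeIn MotuExperiment-class Logical vector: is each column a control?
#' @export
isControl <- function(x) colData(x)$is_control

#' @describeIn MotuExperiment-class Logical vector: is each MOTU the AIC?
#' @export
isAic <- function(x) rowData(x)$is_aic

#' @describeIn MotuExperiment-class Per-column read totals.
#' @export
replicateTotals <- function(x) colSums(motuCounts(x))

setMethod("show", "MotuExperiment", function(object) {
  cat("MotuExperiment:", nrow(object), "MOTUs x", ncol(object),
      "replicates/samples\n")
  cat("  controls:", sum(isControl(object)),
      "| AIC MOTUs:", sum(isAic(object)), "\n")
  thr <- metadata(object)$abundance_threshold
  if (!is.null(thr)) cat("  abundance threshold applied:", thr, "\n")
  invisible(callNextMethod())
})
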