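## Taxonomic backbone: construction, name matching against the national
## species register, lineage queries, genus-capped LCA, redundancy removal.

.rankDepth <- function(rank) match(rank, .RANKS)

#' Build a TaxonomyTree from a node table
#'
#' @param nodes data.frame with columns `name`, `rank`, `parent`,
#'   `canonical_name` (empty or `NA` on canonical rows), `in_register` and
#'   optionally `group` (coarse sorting group, meaningful on order rows).
#' @return A [TaxonomyTree-class] object.
#' @export
taxonomyTree <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"group" %in% names(nodes)) nodes$group <- NA_character_
  nodes$canonical_name[!is.na(nodes$canonical_name) &
                       nodes$canonical_name == ""] <- NA_character_
  nodes$parent[!is.na(nodes$parent) & nodes$parent == ""] <- NA_character_
  nodes$in_register <- as.logical(nodes$in_register)
  obj <- new("TaxonomyTree", nodes = nodes, lineage = .buildLineage(nodes))
  validObject(obj)
  obj
}

#' Read a species register / synonym file
#'
#' Expects a CSV with columns `name`, `rank`, `parent`, `canonical_name`
#' (empty when the row is canonical) and `in_register`; an optional `group`
#' column labels order rows with their sorting group.
#'
#' @param path path to the CSV file.
#' @return A [TaxonomyTree-class].
#' @export
readRegister <- function(path) {
  taxonomyTree(utils::read.csv(path, stringsAsFactors = FALSE,
                               na.strings = c("NA", "")))
}

.buildLineage <- function(nodes) {
  canon <- nodes[is.na(nodes$canonical_name), , drop = FALSE]
  lin <- matrix(NA_character_, nrow(canon), 4L,
                dimnames = list(canon$name, .RANKS[1:4]))
  curName <- canon$name
  curRank <- canon$rank
  ## subspecies contribute their parent species to the lineage table
  ss <- curRank == "subspecies"
  if (any(ss)) {
    i <- match(curName[ss], canon$name)
    curName[ss] <- canon$parent[i]
    curRank[ss] <- "species"
  }
  repeat {
    ok <- !is.na(curName)
    if (!any(ok)) break
    lin[cbind(which(ok), .rankDepth(curRank[ok]))] <- curName[ok]
    i <- match(curName, canon$name)
    d <- .rankDepth(curRank)
    nxt <- ifelse(ok & d > 1L, canon$parent[i], NA_character_)
    curName <- nxt
    curRank <- .RANKS[pmax(d - 1L, 1L)]
  }
  data.frame(name = canon$name, rank = canon$rank,
             as.data.frame(lin, stringsAsFactors = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Match raw names against the register
#'
#' Resolves each raw name to its canonical register taxon: exact matches are
#' returned as-is, synonyms are mapped to their canonical target, and
#' subspecies (explicit rows or unrecognised trinomials whose first two words
#' form a known species) are collapsed to species level. Names that cannot be
#' resolved are flagged `unmatched`, never dropped.
#'
#' @param tree a [TaxonomyTree-class].
#' @param x character vector of raw names.
#' @return data.frame with columns `input`, `taxon`, `rank`, `in_register`,
#'   `status` (one of `matched`, `synonym`, `subspecies_collapsed`,
#'   `unmatched`).
#' @export
matchNames <- function(tree, x) {
  if (nrow(tree@nodes) == 0L) stop("empty register")
  stopifnot(is.character(x), all(nzchar(x)))
  n <- tree@nodes
  res <- data.frame(input = x, taxon = NA_character_, rank = NA_character_,
                    in_register = NA, status = "unmatched",
                    stringsAsFactors = FALSE)
  .resolve <- function(raw) {
    i <- match(raw, n$name)
    status <- "matched"
    if (is.na(i)) {
      ## trinomial fallback: "Genus species infra" -> "Genus species"
      words <- strsplit(raw, " +")[[1]]
      if (length(words) >= 3L) {
        i <- match(paste(words[1:2], collapse = " "), n$name)
        if (!is.na(i)) status <- "subspecies_collapsed"
      }
      if (is.na(i)) return(NULL)
    }
    if (!is.na(n$canonical_name[i])) {
      i <- match(n$canonical_name[i], n$name)
      status <- "synonym"
    }
    if (n$rank[i] == "subspecies") {
      i <- match(n$parent[i], n$name)
      status <- "subspecies_collapsed"
    }
    list(i = i, status = status)
  }
  for (k in seq_along(x)) {
    r <- .resolve(x[k])
    if (is.null(r)) next
    res$taxon[k] <- n$name[r$i]
    res$rank[k] <- n$rank[r$i]
    res$in_register[k] <- n$in_register[r$i]
    res$status[k] <- r$status
  }
  res
}

#' Lineage of a canonical taxon
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxon a canonical taxon name.
#' @return named character vector (order, family, genus, species), `NA`
#'   where the taxon is shallower than the rank.
#' @export
lineageOf <- function(tree, taxon) {
  i <- match(taxon, tree@lineage$name)
  if (is.na(i)) stop("taxon not in tree: ", taxon)
  unlist(tree@lineage[i, .RANKS[1:4]])
}

#' Sorting group of a taxon
#'
#' Looks up the coarse sorting group via the taxon's order.
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxon canonical taxon name(s); species complexes written
#'   `"A/B"` are resolved through their first component.
#' @return character vector of group labels (`NA` when unknown).
#' @export
groupOf <- function(tree, taxon) {
  first <- vapply(strsplit(taxon, "/", fixed = TRUE), `[`, "", 1L)
  ord <- tree@lineage$order[match(first, tree@lineage$name)]
  tree@nodes$group[match(ord, tree@nodes$name)]
}

#' Lowest common ancestor with a rank cap
#'
#' Returns the deepest lineage node shared by all input taxa, never deeper
#' than `maxDepth` (so a single species, or a set of conspecific inputs,
#' yields its genus under the default cap). Returns `NULL` when the taxa do
#' not even share an order.
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxa character vector of canonical taxon names (length >= 1).
#' @param maxDepth deepest rank the result may take (default `"genus"`).
#' @return list with `name` and `rank`, or `NULL`.
#' @export
lowestCommonAncestor <- function(tree, taxa, maxDepth = "genus") {
  if (length(taxa) == 0L) stop("empty taxon set")
  stopifnot(maxDepth %in% .RANKS)
  i <- match(taxa, tree@lineage$name)
  if (anyNA(i)) stop("taxa not in tree: ",
                     paste(taxa[is.na(i)], collapse = ", "))
  cap <- min(.rankDepth(maxDepth), 4L)
  res <- NULL
  for (d in seq_len(cap)) {
    v <- tree@lineage[[.RANKS[d]]][i]
    if (anyNA(v) || length(unique(v)) != 1L) break
    res <- list(name = v[1L], rank = .RANKS[d])
  }
  res
}

#' Remove redundant higher-rank entries from a taxon list
#'
#' An entry whose taxon is a strict ancestor of another entry's taxon on the
#' same list is dropped (e.g. a genus-level identification is omitted when a
#' species of that genus is also listed). With `mode = "lineage"` (default)
#' this is applied along the whole lineage (a family entry is removed when a
#' contained genus or species is present); `mode = "genus"` restricts
#' removal to the genus-vs-species case.
#'
#' @param tree a [TaxonomyTree-class].
#' @param entries data.frame with (at least) a `taxon` column of canonical
#'   names; one taxon list (one sample or unit) per call.
#' @param mode `"lineage"` or `"genus"`.
#' @return `entries` with redundant rows removed.
#' @export
removeRedundant <- function(tree, entries, mode = c("lineage", "genus")) {
  mode <- match.arg(mode)
  if (nrow(entries) == 0L) return(entries)
  li <- match(entries$taxon, tree@lineage$name)
  if (anyNA(li)) stop("unmatched taxa in list: ",
                      paste(unique(entries$taxon[is.na(li)]), collapse = ", "))
  rk <- tree@lineage$rank[li]
  ## strict ancestors contributed by each entry
  ancestors <- unlist(lapply(seq_len(nrow(entries)), function(k) {
    d <- min(.rankDepth(rk[k]), 5L)
    if (d <= 1L) return(character(0))
    up <- unlist(tree@lineage[li[k], .RANKS[seq_len(min(d, 4L) - (d <= 4L))]])
    ## for species (d=4): ancestors are order..genus; subspecies (d=5): order..species
    up <- up[!is.na(up) & up != entries$taxon[k]]
    if (mode == "genus") up <- up[names(up) == "genus" & rk[k] %in% c("species", "subspecies")]
    up
  }), use.names = FALSE)
  drop <- entries$taxon %in% ancestors
  if (mode == "genus") drop <- drop & rk == "genus"
  entries[!drop, , drop = FALSE]
}
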