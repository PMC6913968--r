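## Shared fixtures and independent oracles, built in code.

## A small hand-rolled ranked tree: nGenera genera spread over families and
## orders, spPerGenus species each; built directly as a node table,
## independently of the package's simulation module.
makeTestTree <- function(nGenera = 17, spPerGenus = 3, nFamilies = 6,
                         nOrders = 3, synonyms = TRUE) {
  ords <- sprintf("Ordo%02d", seq_len(nOrders))
  fams <- sprintf("Famia%02d", seq_len(nFamilies))
  gens <- sprintf("Genus%02d", seq_len(nGenera))
  famOrd <- ords[1 + (seq_len(nFamilies) - 1) %% nOrders]
  genFam <- fams[1 + (seq_len(nGenera) - 1) %% nFamilies]
  sp <- as.vector(outer(gens, seq_len(spPerGenus),
                        function(g, k) sprintf("%s sp%d", g, k)))
  spGen <- rep(gens, spPerGenus)
  nodes <- rbind(
    data.frame(name = ords, rank = "order", parent = NA,
               canonical_name = NA, in_register = TRUE,
               group = rep(c("ANNE", "CRUS", "MOLL"), length.out = nOrders)),
    data.frame(name = fams, rank = "family", parent = famOrd,
               canonical_name = NA, in_register = TRUE, group = NA),
    data.frame(name = gens, rank = "genus", parent = genFam,
               canonical_name = NA, in_register = TRUE, group = NA),
    data.frame(name = sp, rank = "species", parent = spGen,
               canonical_name = NA, in_register = TRUE, group = NA))
  if (synonyms) {
    nodes <- rbind(nodes,
      data.frame(name = "Vetus nomen", rank = "species", parent = NA,
                 canonical_name = "Genus01 sp1", in_register = FALSE,
                 group = NA),
      data.frame(name = "Genus02 sp1 minor", rank = "subspecies",
                 parent = "Genus02 sp1", canonical_name = NA,
                 in_register = TRUE, group = NA),
      data.frame(name = "Genus03 exoticus", rank = "species",
                 parent = "Genus03", canonical_name = NA,
                 in_register = FALSE, group = NA))
  }
  taxonomyTree(nodes)
}

## Brute-force LCA: walk parent pointers on the raw node table, intersect
## the full ancestor paths (self included), return the deepest common node
## not deeper than the cap.
bruteLCA <- function(tree, taxa, cap = "genus") {
  nodes <- tree@nodes
  rankNum <- c(order = 1, family = 2, genus = 3, species = 4, subspecies = 5)
  path <- function(t) {
    out <- character(0)
    while (!is.na(t)) {
      i <- match(t, nodes$name)
      out <- c(out, t)
      t <- nodes$parent[i]
    }
    out
  }
  common <- Reduce(intersect, lapply(taxa, path))
  if (length(common) == 0) return(NULL)
  depth <- rankNum[nodes$rank[match(common, nodes$name)]]
  keep <- depth <= rankNum[cap]
  if (!any(keep)) return(NULL)
  best <- common[keep][which.max(depth[keep])]
  list(name = best, rank = nodes$rank[match(best, nodes$name)])
}

## Brute-force redundancy removal: drop an entry when any other entry's
## ancestor path (parent walking) contains its taxon.
bruteRemoveRedundant <- function(tree, entries) {
  nodes <- tree@nodes
  path <- function(t) {
    out <- character(0)
    t <- nodes$parent[match(t, nodes$name)]
    while (!is.na(t)) {
      out <- c(out, t)
      t <- nodes$parent[match(t, nodes$name)]
    }
    out
  }
  ancestors <- unlist(lapply(entries$taxon, path))
  entries[!(entries$taxon %in% ancestors), , drop = FALSE]
}

## Ungapped identity for equal-length sequences (substitution-only cases).
hammingIdentity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  mean(av == bv)
}

## Independent greedy clustering on equal-length sequences.
greedyOracle <- function(seqs, identity) {
  cent <- character(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0
    for (j in seq_along(cent))
      if (hammingIdentity(seqs[i], cent[j]) >= identity) { hit <- j; break }
    if (hit == 0) { cent <- c(cent, seqs[i]); hit <- length(cent) }
    assign[i] <- hit
  }
  assign
}

## Max-scan oracle for the contamination threshold.
thresholdOracle <- function(counts, isControl, isAic) {
  best <- 0
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    if (tot == 0) next
    for (i in seq_len(nrow(counts))) {
      offending <- if (isControl[j]) !isAic[i] else isAic[i]
      if (offending && counts[i, j] > 0)
        best <- max(best, counts[i, j] / tot)
    }
  }
  best
}

## Tiny MotuExperiment builder.
makeMe <- function(counts, isControl = rep(FALSE, ncol(counts)),
                   isAic = c(TRUE, rep(FALSE, nrow(counts) - 1)),
                   group = rep("CRUS", ncol(counts)),
                   sample = sub("_r[0-9]+$", "", colnames(counts))) {
  MotuExperiment(counts,
    data.frame(sample = sample,
               location = sub("_.*", "", sample),
               group = ifelse(isControl, "CTRL", group),
               replicate = seq_len(ncol(counts)),
               is_control = isControl),
    data.frame(is_aic = isAic, row.names = rownames(counts)))
}

randomDNA <- function(n, len = 316) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

mutateSeq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}
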