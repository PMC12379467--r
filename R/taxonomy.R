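## Peptide-centric taxonomy: taxonomy tree, digested-reference peptide
## index, lowest common ancestor assignment, GO-slim rollup and grouped RIA
## statistics.

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
            "species")

#' Canonical taxonomic ranks, domain to species
#' @return Character vector of the 7-rank ladder.
#' @export
taxRanks <- function() .RANKS

#' TaxonomyTree: rooted taxonomy with canonical ranks
#'
#' Nodes carry an id, name, rank (one of the 7-rank ladder, or "no rank"
#' for unranked intermediates) and parent id; a single root is its own
#' parent or has parent \code{NA}.
#'
#' @slot nodes data.frame with columns \code{id}, \code{name}, \code{rank},
#'   \code{parent}.
#' @export
setClass("TaxonomyTree", representation(nodes = "data.frame"),
         validity = function(object) {
           n <- object@nodes
           if (!all(c("id", "name", "rank", "parent") %in% names(n)))
             return("nodes need columns id, name, rank, parent")
           if (anyDuplicated(n$id)) return("duplicate node ids")
           root <- is.na(n$parent) | n$parent == n$id
           if (sum(root) != 1L) return("tree must have exactly one root")
           if (!all(n$parent[!root] %in% n$id))
             return("dangling parent reference")
           TRUE
         })

#' Construct a TaxonomyTree from a node table
#'
#' @param nodes data.frame with columns \code{id}, \code{name}, \code{rank},
#'   \code{parent} (NCBI-taxonomy-dump compatible subset; the root points to
#'   itself or has parent NA).
#' @return A \code{TaxonomyTree}.
#' @export
taxonomyTree <- function(nodes) {
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  new("TaxonomyTree", nodes = nodes)
}

#' Read a taxonomy table from TSV
#' @param path TSV with columns \code{taxon_id}, \code{parent_id},
#'   \code{rank}, \code{name}.
#' @return A \code{TaxonomyTree}.
#' @export
readTaxonomy <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  taxonomyTree(data.frame(id = d$taxon_id, name = d$name, rank = d$rank,
                          parent = d$parent_id, stringsAsFactors = FALSE))
}

#' @describeIn TaxonomyTree node table accessor
#' @param x,object A \code{TaxonomyTree}.
#' @export
taxNodes <- function(x) x@nodes

setMethod("show", "TaxonomyTree", function(object) {
  cat(sprintf("TaxonomyTree: %d nodes (%s)\n", nrow(object@nodes),
              paste(names(table(object@nodes$rank)),
                    table(object@nodes$rank), sep = "=", collapse = ", ")))
})

## Path from a node up to the root, node first.
.rootPath <- function(tree, id) {
  n <- taxNodes(tree)
  parent <- setNames(n$parent, n$id)
  path <- character(0)
  cur <- as.character(id)
  while (!is.na(cur) && !cur %in% path) {
    path <- c(path, cur)
    nxt <- parent[[cur]]
    if (is.na(nxt) || identical(nxt, cur)) break
    cur <- nxt
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxon,
#' computed by pairwise depth-aligned walking toward the root.
#'
#' @param taxa Character vector of taxon ids (non-empty).
#' @param tree A \code{TaxonomyTree}.
#' @return A taxon id, or \code{NA_character_} for an empty input
#'   (no assignment).
#' @export
taxLca <- function(taxa, tree) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) return(NA_character_)
  n <- taxNodes(tree)
  bad <- setdiff(taxa, n$id)
  if (length(bad)) stop("unknown taxon id(s): ", paste(bad, collapse = ", "))
  parent <- setNames(n$parent, n$id)
  depth <- function(id) length(.rootPath(tree, id)) - 1L
  up <- function(id) {
    p <- parent[[id]]
    if (is.na(p) || identical(p, id)) id else p
  }
  cur <- taxa[1]
  for (other in taxa[-1]) {
    a <- cur; b <- other
    da <- depth(a); db <- depth(b)
    while (da > db) { a <- up(a); da <- da - 1L }
    while (db > da) { b <- up(b); db <- db - 1L }
    while (!identical(a, b)) { a <- up(a); b <- up(b) }
    cur <- a
  }
  cur
}

## ---- PeptideTaxonIndex --------------------------------------------------

#' PeptideTaxonIndex: digested-reference lookup for peptide taxonomy
#'
#' Maps I/L-collapsed tryptic peptide keys to the set of taxa whose
#' reference proteins contain them, and to the GO terms annotated on those
#' proteins. The local, deterministic replacement for a web taxonomy
#' service.
#'
#' @slot peptideTaxa Named list: collapsed peptide key -> character vector
#'   of taxon ids.
#' @slot peptideGo Named list: collapsed peptide key -> character vector of
#'   GO term ids (with multiplicity, one entry per annotated source
#'   protein).
#' @slot params Digestion parameters used to build the index.
#' @export
setClass("PeptideTaxonIndex",
         representation(peptideTaxa = "list", peptideGo = "list",
                        params = "list"))

setMethod("show", "PeptideTaxonIndex", function(object) {
  cat(sprintf("PeptideTaxonIndex: %d peptide keys\n",
              length(object@peptideTaxa)))
})

setMethod("length", "PeptideTaxonIndex",
          function(x) length(x@peptideTaxa))

#' Collapse isoleucine to leucine in peptide keys
#'
#' I and L are isobaric and indistinguishable by mass spectrometry; all
#' index lookups use collapsed keys.
#'
#' @param x Character vector of peptides.
#' @return Collapsed keys.
#' @export
collapseIL <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Build a peptide-taxon index from a reference proteome
#'
#' Digests every reference protein into fully tryptic peptides under
#' \code{params} and indexes them by I/L-collapsed key. GO annotations of a
#' protein propagate to all its peptides.
#'
#' @param proteins Named character vector (or AAStringSet) of protein
#'   sequences.
#' @param taxonIds Character vector, one taxon id per protein.
#' @param goTerms Optional list parallel to \code{proteins}: GO term ids
#'   annotated on each protein.
#' @param tree A \code{TaxonomyTree}; every taxon id must exist in it.
#' @param params \code{\link{digestionParams}} (default: trypsin, 2 missed
#'   cleavages, length 6-100).
#' @return A \code{PeptideTaxonIndex}.
#' @export
buildPeptideIndex <- function(proteins, taxonIds, goTerms = NULL, tree,
                              params = digestionParams()) {
  prot <- as.character(proteins)
  if (length(prot) != length(taxonIds))
    stop("need one taxon id per protein")
  if (any(is.na(taxonIds) | !nzchar(taxonIds)))
    stop("protein record without taxon id")
  bad <- setdiff(unique(as.character(taxonIds)), taxNodes(tree)$id)
  if (length(bad)) stop("unknown taxon id(s): ", paste(bad, collapse = ", "))
  taxMap <- new.env(parent = emptyenv())
  goMap <- new.env(parent = emptyenv())
  for (i in seq_along(prot)) {
    peps <- unique(collapseIL(digestProtein(prot[i], params)))
    for (p in peps) {
      taxMap[[p]] <- c(taxMap[[p]], as.character(taxonIds[i]))
      if (!is.null(goTerms) && length(goTerms[[i]]))
        goMap[[p]] <- c(goMap[[p]], goTerms[[i]])
    }
  }
  keys <- ls(taxMap)
  new("PeptideTaxonIndex",
      peptideTaxa = setNames(lapply(keys, function(k) unique(taxMap[[k]])),
                             keys),
      peptideGo = setNames(lapply(keys, function(k)
        if (is.null(goMap[[k]])) character(0) else goMap[[k]]), keys),
      params = list(digestion = params))
}

#' Assign a peptide to a taxon (LCA) and GO terms
#'
#' Exact I/L-collapsed lookup against the index; when the peptide is absent
#' and missed-cleavage handling is enabled, it is split at internal K/R
#' sites and assigned the LCA over taxa matching every fully tryptic
#' sub-peptide (the advanced missed-cleavage rule). Peptides matching
#' nothing return an NA taxon — unassigned is a value, not an error.
#'
#' @param peptide Query peptide string.
#' @param index A \code{\link{PeptideTaxonIndex}}.
#' @param tree The \code{TaxonomyTree} the index was built against.
#' @param handleMissedCleavage Split unmatched peptides at K/R and require
#'   all fragments to match (default TRUE).
#' @return List with \code{taxon} (id or NA) and \code{go} (character
#'   vector with multiplicity).
#' @export
assignPeptide <- function(peptide, index, tree,
                          handleMissedCleavage = TRUE) {
  key <- collapseIL(peptide)
  taxa <- index@peptideTaxa[[key]]
  go <- index@peptideGo[[key]]
  if (is.null(taxa) && handleMissedCleavage) {
    parts <- digestProtein(peptide,
                           digestionParams(missedCleavages = 0L,
                                           lengthBounds = c(1L, nchar(peptide))))
    parts <- collapseIL(parts)
    if (length(parts) > 1L) {
      hits <- lapply(parts, function(p) index@peptideTaxa[[p]])
      if (!any(vapply(hits, is.null, logical(1)))) {
        common <- Reduce(intersect, hits)
        taxa <- if (length(common)) common else
          vapply(hits, function(h) taxLca(h, tree), character(1))
        go <- unlist(lapply(parts, function(p) index@peptideGo[[p]]),
                     use.names = FALSE)
      }
    }
  }
  if (is.null(taxa))
    return(list(taxon = NA_character_, go = character(0)))
  list(taxon = taxLca(taxa, tree),
       go = if (is.null(go)) character(0) else go)
}

## ---- GO ontology --------------------------------------------------------

#' Read a minimal GO ontology from OBO
#'
#' Parses \code{[Term]} stanzas for \code{id}, \code{name}, \code{is_a}
#' parents and the \code{is_obsolete} flag — the subset GO-slim rollup
#' needs.
#'
#' @param path OBO file.
#' @return List with \code{parents} (named list: term -> is_a parents) and
#'   \code{names} (named character).
#' @export
readObo <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\[Term\\]", lines)
  bounds <- c(starts, length(lines) + 1L)
  parents <- list(); nm <- character(0)
  for (i in seq_along(starts)) {
    block <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    if (any(grepl("^is_obsolete: true", block))) next
    id <- sub("^id: ", "", grep("^id: ", block, value = TRUE)[1])
    if (is.na(id)) next
    name <- sub("^name: ", "", grep("^name: ", block, value = TRUE)[1])
    isa <- sub("^is_a: (\\S+).*", "\\1", grep("^is_a: ", block, value = TRUE))
    parents[[id]] <- isa
    nm[id] <- if (is.na(name)) id else name
  }
  list(parents = parents, names = nm)
}

#' Roll GO terms up to a slim subset
#'
#' Each term maps to the set of its ancestors-or-self contained in the
#' slim; terms with no slim ancestor are dropped (their count is reported
#' via a message). A term contributing through two slim ancestors appears
#' under both.
#'
#' @param terms Character vector of GO term ids (multiset: repeats count).
#' @param ontology List from \code{\link{readObo}}.
#' @param slim Character vector of slim term ids.
#' @return Named integer vector: slim term id -> count.
#' @export
goslimRollup <- function(terms, ontology, slim) {
  parents <- ontology$parents
  ancCache <- new.env(parent = emptyenv())
  ancestors <- function(t) {
    if (!is.null(ancCache[[t]])) return(ancCache[[t]])
    seen <- character(0)
    frontier <- t
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(parents[frontier], use.names = FALSE), seen)
    }
    ancCache[[t]] <- seen
    seen
  }
  counts <- integer(0)
  dropped <- 0L
  unknown <- 0L
  for (t in terms) {
    if (!t %in% names(parents) && !t %in% slim) { unknown <- unknown + 1L; next }
    hits <- intersect(ancestors(t), slim)
    if (length(hits) == 0L) { dropped <- dropped + 1L; next }
    for (h in hits) counts[h] <- if (is.na(counts[h])) 1L else counts[h] + 1L
  }
  if (unknown) message(unknown, " unknown GO term(s) skipped")
  if (dropped) message(dropped, " term(s) without slim ancestor dropped")
  counts
}

## ---- grouped RIA statistics --------------------------------------------

#' Filter RIA groups by peptide and sample support
#'
#' Keeps groups (taxon or GO term) with at least \code{minPeptides}
#' peptides, each peptide passing the \code{minSamples} reproducibility
#' rule.
#'
#' @param groups data.frame with columns \code{group}, \code{peptide},
#'   \code{ria} and \code{nSamples} (distinct samples the peptide was seen
#'   in).
#' @param minPeptides Minimum peptides per group (default 3).
#' @param minSamples Minimum samples per peptide (default 2).
#' @return Filtered data.frame.
#' @export
groupFilter <- function(groups, minPeptides = 3L, minSamples = 2L) {
  g <- groups[groups$nSamples >= minSamples, , drop = FALSE]
  sizes <- table(g$group)
  keep <- names(sizes)[sizes >= minPeptides]
  out <- g[g$group %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare RIA between two groups (pooled-variance t-test)
#'
#' Two-sided two-sample Student t-test for independent groups with pooled
#' variance, with significance stars at p < 0.05 (*), < 0.01 (**) and
#' < 0.001 (***).
#'
#' @param a,b Numeric vectors of per-peptide RIA values.
#' @return List with \code{statistic}, \code{pValue}, \code{stars}
#'   (\code{""} when not significant, \code{NA} when the test is
#'   undefined).
#' @export
compareGroups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    return(list(statistic = NA_real_, pValue = NA_real_,
                stars = NA_character_))
  if (sd(a) == 0 && sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(statistic = 0, pValue = 1, stars = ""))
    return(list(statistic = NA_real_, pValue = NA_real_,
                stars = NA_character_))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  p <- tt$p.value
  stars <- if (is.na(p)) NA_character_
  else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
  list(statistic = unname(tt$statistic), pValue = p, stars = stars)
}

#' Summarize per-peptide RIA by taxon at a given rank
#'
#' Rolls peptide assignments up to the requested rank by ancestor lookup;
#' peptides whose LCA is shallower than the rank are excluded from that
#' rank's table.
#'
#' @param assignments data.frame with columns \code{peptide}, \code{taxon}
#'   (LCA id), \code{ria}, \code{labeled}.
#' @param tree A \code{TaxonomyTree}.
#' @param rank One of \code{taxRanks()}.
#' @return data.frame: \code{taxon}, \code{name}, \code{nPeptides},
#'   \code{medianRia}, \code{meanRia}, \code{nLabeled}.
#' @export
summarizeTaxa <- function(assignments, tree, rank = "species") {
  if (!rank %in% .RANKS) stop("unknown rank: ", rank)
  n <- taxNodes(tree)
  rankOf <- setNames(n$rank, n$id)
  nameOf <- setNames(n$name, n$id)
  atRank <- vapply(assignments$taxon, function(id) {
    if (is.na(id)) return(NA_character_)
    path <- .rootPath(tree, id)
    hit <- path[rankOf[path] == rank]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  d <- assignments[!is.na(atRank), , drop = FALSE]
  d$atRank <- atRank[!is.na(atRank)]
  if (nrow(d) == 0L)
    return(data.frame(taxon = character(0), name = character(0),
                      nPeptides = integer(0), medianRia = numeric(0),
                      meanRia = numeric(0), nLabeled = integer(0)))
  out <- do.call(rbind, lapply(split(d, d$atRank), function(g)
    data.frame(taxon = g$atRank[1], name = unname(nameOf[g$atRank[1]]),
               nPeptides = nrow(g), medianRia = median(g$ria),
               meanRia = mean(g$ria), nLabeled = sum(g$labeled),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
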