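## In silico digestion, theoretical vs observed taxonomy drop-off profiles,
## sequence-randomization control, and BLAST export/import adapters for
## unassigned peptides.

#' Digestion parameters
#'
#' @param enzyme Only \code{"trypsin"} is implemented: cleavage C-terminal
#'   of K or R; with \code{nroP = TRUE} (default) not before proline.
#' @param missedCleavages Maximum missed cleavage sites (default 2).
#' @param lengthBounds Inclusive peptide length bounds (default 6-100).
#' @param nroP Suppress cleavage before proline (default TRUE).
#' @return List of class \code{DigestionParams}.
#' @export
digestionParams <- function(enzyme = "trypsin", missedCleavages = 2L,
                            lengthBounds = c(6L, 100L), nroP = TRUE) {
  if (missedCleavages < 0L) stop("missedCleavages must be >= 0")
  if (lengthBounds[1] > lengthBounds[2]) stop("invalid length bounds")
  structure(list(enzyme = enzyme, missedCleavages = as.integer(missedCleavages),
                 lengthBounds = as.integer(lengthBounds), nroP = nroP),
            class = "DigestionParams")
}

#' In silico tryptic digestion
#'
#' Cleaves C-terminal of K/R (not before P by default) and returns every
#' product with at most \code{missedCleavages} internal cleavage sites and
#' within the length bounds, including the terminal peptides. A sequence
#' without any cleavage site is its own (only) product when within bounds.
#'
#' @param sequence Protein (or peptide) string.
#' @param params \code{\link{digestionParams}}.
#' @return Character vector of peptides, in N-to-C order of their start
#'   position.
#' @examples
#' digestProtein("AAAKBBBRCCC", digestionParams(missedCleavages = 0,
#'                                              lengthBounds = c(3, 10)))
#' @export
digestProtein <- function(sequence, params = digestionParams()) {
  if (!nzchar(sequence)) stop("empty sequence")
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  ## cleavage after position i
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n]
  if (params$nroP) cut <- cut[res[cut + 1L] != "P"]
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  nseg <- length(starts)
  out <- character(0)
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + params$missedCleavages)) {
      len <- ends[j] - starts[i] + 1L
      if (len >= params$lengthBounds[1] && len <= params$lengthBounds[2])
        out <- c(out, substr(sequence, starts[i], ends[j]))
    }
  }
  out
}

#' DropoffProfile: taxon-specific peptide counts along a lineage
#'
#' Per rank (domain to species) on a focal lineage: the count of peptides
#' whose LCA sits exactly at that rank's node, and the fraction of peptides
#' specific at that rank or deeper relative to the domain-level total.
#' Drop-off rates describe how taxon-specific peptide counts decline from
#' general to specific ranks; comparing observed against theoretical
#' profiles flags hidden labeled populations.
#'
#' @slot lineage Named character vector: rank -> taxon id on the focal
#'   lineage.
#' @slot counts Named integer vector: rank -> peptides with LCA exactly at
#'   that rank.
#' @slot fractions Named numeric vector: rank -> cumulative-from-species
#'   fraction of the domain-level total.
#' @export
setClass("DropoffProfile",
         representation(lineage = "character", counts = "integer",
                        fractions = "numeric"))

setMethod("show", "DropoffProfile", function(object) {
  cat("DropoffProfile:\n")
  print(data.frame(rank = names(object@counts), taxon = object@lineage,
                   count = object@counts,
                   fraction = round(object@fractions, 4),
                   row.names = NULL))
})

#' @describeIn DropoffProfile profile as a data.frame
#' @param x,object A \code{DropoffProfile}.
#' @export
dropoffTable <- function(x)
  data.frame(rank = names(x@counts), taxon = unname(x@lineage),
             count = unname(x@counts), fraction = unname(x@fractions),
             stringsAsFactors = FALSE)

## Shared core: count LCA hits along the focal lineage and derive
## non-increasing fractions (peptides specific at rank r or deeper, over
## the domain-level total).
.dropoffFromLca <- function(lcas, lineage) {
  ranks <- intersect(.RANKS, names(lineage))
  counts <- setNames(integer(length(ranks)), ranks)
  for (r in ranks)
    counts[r] <- sum(!is.na(lcas) & lcas == lineage[[r]])
  atOrBelow <- rev(cumsum(rev(counts)))
  total <- atOrBelow[1]
  fractions <- if (total > 0) atOrBelow / total else
    setNames(numeric(length(ranks)), ranks)
  new("DropoffProfile", lineage = lineage[ranks], counts = counts,
      fractions = fractions)
}

#' Focal lineage of a taxon
#'
#' @param tree A \code{TaxonomyTree}.
#' @param taxon Focal taxon id (usually a species).
#' @return Named character vector rank -> taxon id along the root path.
#' @export
taxLineage <- function(tree, taxon) {
  n <- taxNodes(tree)
  rankOf <- setNames(n$rank, n$id)
  path <- .rootPath(tree, taxon)
  keep <- path[rankOf[path] %in% .RANKS]
  setNames(keep, rankOf[keep])[intersect(.RANKS, rankOf[keep])]
}

#' Theoretical taxonomy drop-off profile
#'
#' Digests the expressed proteins of the focal taxon into tryptic peptides
#' of 7-15 residues, applies the detectability predicate, draws a seeded
#' sample of \code{nSample} peptides (3,500 by default), assigns each via
#' the peptide-taxon index and counts LCA hits along the focal lineage.
#'
#' @param proteome Named character vector of the focal taxon's proteins.
#' @param expressed Optional character vector of protein names restricting
#'   the digestion to expressed proteins.
#' @param detectability Predicate \code{function(peptide) -> logical};
#'   default accepts everything. See \code{\link{naiveDetectability}} for a
#'   bundled heuristic.
#' @param index A \code{\link{PeptideTaxonIndex}} over the full reference.
#' @param tree The \code{TaxonomyTree}.
#' @param focalTaxon Focal taxon id.
#' @param nSample Number of peptides to sample (default 3500); if the
#'   detectable pool is smaller, all of it is used with a warning.
#' @param seed Sampling seed.
#' @param digestion Digestion parameters (default: 7-15 residues, 0 missed
#'   cleavages).
#' @return A \code{\link{DropoffProfile}}.
#' @export
theoreticalDropoff <- function(proteome, expressed = NULL,
                               detectability = NULL, index, tree, focalTaxon,
                               nSample = 3500L, seed = 1L,
                               digestion = digestionParams(
                                 missedCleavages = 0L,
                                 lengthBounds = c(7L, 15L))) {
  prot <- as.character(proteome)
  if (!is.null(expressed)) prot <- prot[names(proteome) %in% expressed]
  if (length(prot) == 0L) stop("no expressed proteins to digest")
  pool <- unique(unlist(lapply(prot, digestProtein, params = digestion),
                        use.names = FALSE))
  if (!is.null(detectability))
    pool <- pool[vapply(pool, detectability, logical(1))]
  if (length(pool) == 0L) stop("empty detectable peptide pool")
  if (length(pool) < nSample) {
    warning("detectable pool (", length(pool),
            ") smaller than requested sample (", nSample, "): using all")
    sampled <- sort(pool)
  } else {
    rng <- .seededRng(seed)
    sampled <- sort(sample_rng(rng, pool, size = nSample))
  }
  lcas <- vapply(sampled, function(p)
    assignPeptide(p, index, tree)$taxon, character(1))
  .dropoffFromLca(lcas, taxLineage(tree, focalTaxon))
}

#' Observed taxonomy drop-off profile of labeled peptides
#'
#' @param assignments data.frame with columns \code{peptide} and
#'   \code{taxon} (LCA ids) for labeled peptides.
#' @param tree The \code{TaxonomyTree}.
#' @param focalTaxon Focal taxon id.
#' @return A \code{\link{DropoffProfile}} counting labeled peptides whose
#'   LCA equals each rank of the focal lineage.
#' @export
observedDropoff <- function(assignments, tree, focalTaxon) {
  .dropoffFromLca(assignments$taxon, taxLineage(tree, focalTaxon))
}

#' Compare theoretical and observed drop-off profiles
#'
#' Per-rank deviation is the absolute difference of the fractions, in
#' percentage points; the maximum over ranks is the headline statistic.
#'
#' @param theoretical,observed \code{\link{DropoffProfile}}s on the same
#'   lineage.
#' @return List with \code{perRank} (data.frame: rank, theoretical,
#'   observed, deviation in points) and \code{maxDeviation}.
#' @export
compareDropoff <- function(theoretical, observed) {
  if (!identical(theoretical@lineage, observed@lineage))
    stop("profiles are on different lineages")
  dev <- abs(observed@fractions - theoretical@fractions) * 100
  list(perRank = data.frame(rank = names(dev),
                            theoretical = unname(theoretical@fractions),
                            observed = unname(observed@fractions),
                            deviation = unname(dev),
                            stringsAsFactors = FALSE),
       maxDeviation = max(dev))
}

#' Sequence-randomization control for false-positive assignments
#'
#' Shuffles the residues within each peptide (preserving length and
#' composition), reassigns the shuffled peptides against the index, and
#' tallies per-rank assignment counts; the mean across rounds estimates the
#' false-positive assignment expectation at each rank.
#'
#' @param peptides Character vector of peptides.
#' @param index A \code{\link{PeptideTaxonIndex}}.
#' @param tree The \code{TaxonomyTree}.
#' @param seed Seed.
#' @param nRounds Shuffling rounds (default 10).
#' @return Named numeric vector: rank -> mean assigned count per round
#'   (plus \code{"unassigned"}).
#' @export
randomizationControl <- function(peptides, index, tree, seed = 1L,
                                 nRounds = 10L) {
  if (length(peptides) == 0L) stop("no peptides")
  n <- taxNodes(tree)
  rankOf <- setNames(n$rank, n$id)
  rng <- .seededRng(seed)
  tallies <- matrix(0, nrow = nRounds, ncol = length(.RANKS) + 1L,
                    dimnames = list(NULL, c(.RANKS, "unassigned")))
  for (round in seq_len(nRounds)) {
    shuffled <- vapply(peptides, function(p) {
      r <- strsplit(p, "")[[1]]
      if (length(r) > 1L) paste(sample_rng(rng, r), collapse = "") else p
    }, character(1))
    lcas <- vapply(shuffled, function(p)
      assignPeptide(p, index, tree, handleMissedCleavage = FALSE)$taxon,
      character(1))
    for (t in lcas) {
      col <- if (is.na(t)) "unassigned" else {
        rk <- rankOf[[t]]
        if (rk %in% .RANKS) rk else "unassigned"
      }
      tallies[round, col] <- tallies[round, col] + 1
    }
  }
  colMeans(tallies)
}

#' Bundled naive detectability heuristic
#'
#' Accepts peptides of 7-25 residues whose fraction of strongly hydrophobic
#' residues (AILMFWV) lies in [0.1, 0.7] — a demonstration stand-in for an
#' external detectability predictor, pluggable via the
#' \code{detectability} argument of \code{\link{theoreticalDropoff}}.
#'
#' @param peptide Peptide string.
#' @return Logical.
#' @export
naiveDetectability <- function(peptide) {
  len <- nchar(peptide)
  if (len < 7L || len > 25L) return(FALSE)
  hyd <- sum(strsplit(peptide, "")[[1]] %in%
               c("A", "I", "L", "M", "F", "W", "V")) / len
  hyd >= 0.1 && hyd <= 0.7
}

#' Export unassigned peptides to FASTA
#'
#' @param peptides Character vector (possibly empty) of unassigned
#'   peptides.
#' @param path Output FASTA.
#' @return \code{path}, invisibly.
#' @export
exportUnassigned <- function(peptides, path) {
  x <- Biostrings::AAStringSet(peptides)
  if (length(x)) names(x) <- sprintf("unassigned%05d", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Import and filter BLAST tabular output
#'
#' Reads outfmt-6-style tabular output, keeps hits with e-value strictly
#' below \code{eCutoff} (hits at or above it are removed), then drops
#' organisms with fewer than \code{minHitsPerOrganism} surviving hits.
#'
#' @param path BLAST tabular file (no header).
#' @param columns Column names, by default the standard 12 outfmt-6 fields
#'   plus \code{stitle}; must include \code{qseqid}, \code{evalue} and the
#'   organism column.
#' @param organismColumn Column holding the organism label (default
#'   \code{"stitle"}).
#' @param eCutoff E-value cutoff (default 0.001).
#' @param minHitsPerOrganism Minimum surviving hits per organism
#'   (default 2).
#' @return List with \code{hits} (filtered table) and \code{organisms}
#'   (data.frame organism/nHits, sorted by count).
#' @export
importBlastTabular <- function(path,
                               columns = c("qseqid", "sseqid", "pident",
                                           "length", "mismatch", "gapopen",
                                           "qstart", "qend", "sstart",
                                           "send", "evalue", "bitscore",
                                           "stitle"),
                               organismColumn = "stitle", eCutoff = 0.001,
                               minHitsPerOrganism = 2L) {
  d <- tryCatch(read.delim(path, header = FALSE, stringsAsFactors = FALSE),
                error = function(e) stop("cannot read BLAST tabular: ", path))
  if (ncol(d) < length(columns))
    columns <- columns[seq_len(ncol(d))]
  names(d)[seq_along(columns)] <- columns
  d$evalue <- suppressWarnings(as.numeric(d$evalue))
  bad <- is.na(d$evalue) | is.na(d[[organismColumn]])
  if (any(bad)) {
    message(sum(bad), " malformed BLAST row(s) skipped")
    d <- d[!bad, , drop = FALSE]
  }
  d <- d[d$evalue < eCutoff, , drop = FALSE]
  counts <- table(d[[organismColumn]])
  keep <- names(counts)[counts >= minHitsPerOrganism]
  d <- d[d[[organismColumn]] %in% keep, , drop = FALSE]
  rownames(d) <- NULL
  cnt <- sort(table(d[[organismColumn]]), decreasing = TRUE)
  org <- data.frame(organism = names(cnt), nHits = as.integer(cnt),
                    stringsAsFactors = FALSE)
  list(hits = d, organisms = org)
}
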