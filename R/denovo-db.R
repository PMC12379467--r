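## De novo sequencing output -> filtered, merged, non-redundant peptide FASTA.

#' Parse de novo sequencing output
#'
#' Reads peptide lists produced by de novo sequencing engines. Two dialects
#' are supported: a generic TSV with columns \code{run}, \code{spectrum},
#' \code{sequence}, \code{score}, and an mzTab-style PSM section (lines
#' starting \code{PSM} with a \code{PSH} header carrying \code{sequence} and
#' \code{search_engine_score[1]} columns, as Casanovo writes).
#'
#' Modification annotations embedded in the sequence (e.g.
#' \code{"PEPT+15.995IDER"} or \code{"M(ox)"}) are preserved verbatim in
#' \code{sequence} and stripped to bare residues in \code{peptide}.
#'
#' @param path Input file.
#' @param dialect \code{"tsv"} or \code{"mztab"}.
#' @param run Run identifier used when the dialect carries none (mzTab);
#'   defaults to the file name.
#' @return data.frame with columns \code{run}, \code{spectrum},
#'   \code{sequence} (verbatim), \code{peptide} (stripped), \code{score},
#'   \code{engine}. Malformed rows are skipped with a message.
#' @export
parseDenovo <- function(path, dialect = c("tsv", "mztab"), run = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("run", "spectrum", "sequence", "score")
    if (!all(need %in% names(d)))
      stop("generic TSV dialect needs columns: ", paste(need, collapse = ", "))
    if (nrow(d) == 0L) stop("zero parseable rows in ", path)
    rec <- data.frame(run = as.character(d$run),
                      spectrum = as.character(d$spectrum),
                      sequence = as.character(d$sequence),
                      score = suppressWarnings(as.numeric(d$score)),
                      engine = if ("engine" %in% names(d))
                        as.character(d$engine) else "denovo",
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    psh <- grep("^PSH\\t", lines, value = TRUE)
    psm <- grep("^PSM\\t", lines, value = TRUE)
    if (length(psh) == 0L || length(psm) == 0L)
      stop("no PSH/PSM section found in mzTab-style input")
    hdr <- strsplit(psh[1], "\t", fixed = TRUE)[[1]]
    seqcol <- match("sequence", hdr)
    scorecol <- grep("^search_engine_score", hdr)[1]
    speccol <- match("spectra_ref", hdr)
    if (is.na(seqcol) || is.na(scorecol))
      stop("mzTab PSH header lacks sequence/search_engine_score columns")
    fields <- strsplit(psm, "\t", fixed = TRUE)
    rec <- data.frame(
      run = if (is.null(run)) basename(path) else run,
      spectrum = vapply(fields, function(f)
        if (!is.na(speccol) && length(f) >= speccol) f[speccol] else NA_character_,
        character(1)),
      sequence = vapply(fields, function(f)
        if (length(f) >= seqcol) f[seqcol] else NA_character_, character(1)),
      score = suppressWarnings(as.numeric(vapply(fields, function(f)
        if (length(f) >= scorecol) f[scorecol] else NA_character_,
        character(1)))),
      engine = "denovo", stringsAsFactors = FALSE)
  }
  rec$peptide <- stripModifications(rec$sequence)
  bad <- is.na(rec$score) | !is.finite(rec$score) | is.na(rec$peptide) |
    nchar(rec$peptide) == 0L
  if (any(bad))
    message(sum(bad), " malformed row(s) skipped")
  rec <- rec[!bad, c("run", "spectrum", "sequence", "peptide", "score",
                     "engine")]
  if (nrow(rec) == 0L) stop("zero parseable rows in ", path)
  rownames(rec) <- NULL
  rec
}

#' Strip modification annotations from peptide strings
#'
#' Removes bracketed annotations (\code{(...)}, \code{[...]}), inline mass
#' deltas (\code{+15.995}, \code{-17.027}) and any other non-letter
#' characters, then uppercases. \code{"PEPT+15.995IDER"} becomes
#' \code{"PEPTIDER"}.
#'
#' @param x Character vector of annotated sequences.
#' @return Character vector of bare residue strings.
#' @export
stripModifications <- function(x) {
  x <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", x)
  x <- gsub("[+-]?[0-9]+\\.?[0-9]*", "", x)
  toupper(gsub("[^A-Za-z]", "", x))
}

#' Filter de novo records by quality score
#'
#' Keeps records whose score is strictly greater than the threshold
#' (matching the "CS > 0.99" convention; the boundary value itself is
#' dropped). Negative scores are legal input.
#'
#' @param records data.frame from \code{\link{parseDenovo}}.
#' @param threshold Finite numeric; use \code{-Inf} for the unfiltered
#'   database.
#' @return Filtered data.frame.
#' @export
filterByScore <- function(records, threshold = 0.99) {
  if (is.na(threshold)) stop("threshold must be numeric")
  records[records$score > threshold, , drop = FALSE]
}

## ---- PeptideDatabase ----------------------------------------------------

#' PeptideDatabase: non-redundant peptide sequence database
#'
#' Ordered unique peptide strings with per-peptide provenance (observation
#' count, contributing runs, maximum quality score) and the creation
#' parameters, plus target/decoy/entrapment flags when augmented.
#'
#' @slot peptides Character vector of unique bare peptide strings.
#' @slot provenance data.frame aligned with \code{peptides}: columns
#'   \code{count}, \code{runs}, \code{maxScore}, \code{kind}
#'   ("target", "decoy" or "entrapment").
#' @slot params List of creation parameters (threshold, length bounds, ...).
#' @export
setClass("PeptideDatabase",
         representation(peptides = "character", provenance = "data.frame",
                        params = "list"),
         validity = function(object) {
           if (anyDuplicated(object@peptides))
             return("duplicate peptide sequences in database")
           if (nrow(object@provenance) != length(object@peptides))
             return("provenance rows must match peptide count")
           TRUE
         })

#' @describeIn PeptideDatabase peptide strings accessor
#' @param x,object A \code{PeptideDatabase}.
#' @export
peptides <- function(x) x@peptides

#' @describeIn PeptideDatabase provenance table accessor
#' @export
provenance <- function(x) x@provenance

#' @describeIn PeptideDatabase creation parameters accessor
#' @export
dbParams <- function(x) x@params

setMethod("length", "PeptideDatabase", function(x) length(x@peptides))

setMethod("show", "PeptideDatabase", function(object) {
  kinds <- table(object@provenance$kind)
  cat(sprintf("PeptideDatabase: %d peptides (%s)\n", length(object@peptides),
              paste(names(kinds), kinds, sep = "=", collapse = ", ")))
  if (length(object@params))
    cat(" params:", paste(names(object@params),
                          vapply(object@params, function(p)
                            paste(format(p), collapse = ","), character(1)),
                          sep = "=", collapse = " "), "\n")
})

#' Assemble a non-redundant peptide database
#'
#' Strips modification annotations, drops sequences with ambiguous residues
#' (B, J, Z, X, U, O — no elemental composition) or outside the length
#' bounds, deduplicates by exact string, and aggregates provenance. I and L
#' are kept distinct here; they are collapsed only during taxonomy matching.
#'
#' @param records data.frame from \code{\link{parseDenovo}} (ideally already
#'   score-filtered; the threshold used is recorded, not enforced).
#' @param lengthBounds Integer pair, inclusive peptide length bounds
#'   (default 6-100).
#' @param threshold Score threshold recorded in the creation parameters.
#' @return A \code{\link{PeptideDatabase}}.
#' @export
assembleDatabase <- function(records, lengthBounds = c(6L, 100L),
                             threshold = NA_real_) {
  pep <- stripModifications(records$sequence)
  ambiguous <- grepl("[BJZXUO]", pep)
  len <- nchar(pep)
  short <- len < lengthBounds[1] | len > lengthBounds[2]
  keep <- !ambiguous & !short
  if (!any(keep))
    stop("all records dropped (ambiguous residues: ", sum(ambiguous),
         ", outside length bounds: ", sum(short & !ambiguous), ")")
  if (any(!keep))
    message("dropped ", sum(ambiguous), " record(s) with ambiguous residues, ",
            sum(short & !ambiguous), " outside length bounds")
  d <- records[keep, , drop = FALSE]
  d$peptide <- pep[keep]
  grp <- split(d, d$peptide)
  uniq <- names(grp)[order(match(names(grp), d$peptide))]  # first-seen order
  prov <- do.call(rbind, lapply(grp[uniq], function(g)
    data.frame(count = nrow(g),
               runs = paste(sort(unique(g$run)), collapse = ";"),
               maxScore = max(g$score), kind = "target",
               stringsAsFactors = FALSE)))
  rownames(prov) <- NULL
  new("PeptideDatabase", peptides = uniq, provenance = prov,
      params = list(threshold = threshold, lengthBounds = lengthBounds))
}

#' Write a peptide database to FASTA
#'
#' One entry per peptide; headers carry a stable id plus key=value
#' provenance fields so a round trip through
#' \code{\link{readPeptideFasta}} restores the database.
#'
#' @param db A \code{PeptideDatabase}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writePeptideFasta <- function(db, path) {
  if (length(db) == 0L) stop("refusing to write an empty database")
  prov <- provenance(db)
  hdr <- sprintf("pep%06d kind=%s count=%d runs=%s max_score=%s",
                 seq_along(peptides(db)), prov$kind, prov$count,
                 ifelse(nzchar(prov$runs), prov$runs, "."),
                 format(prov$maxScore, trim = TRUE))
  x <- Biostrings::AAStringSet(peptides(db))
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a peptide database from FASTA
#'
#' Inverse of \code{\link{writePeptideFasta}}. Plain FASTA without
#' provenance fields is accepted; duplicate sequences are collapsed with a
#' warning.
#'
#' @param path FASTA file.
#' @return A \code{PeptideDatabase}.
#' @export
readPeptideFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA: ", path)
  seqs <- as.character(x)
  hdr <- names(x)
  field <- function(key, default) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    out <- rep(default, length(hdr))
    hit <- grepl(paste0(key, "="), hdr)
    out[hit] <- sub(paste0(key, "="), "", m)
    out
  }
  prov <- data.frame(count = as.integer(field("count", "1")),
                     runs = {r <- field("runs", ""); ifelse(r == ".", "", r)},
                     maxScore = as.numeric(field("max_score", NA_character_)),
                     kind = field("kind", "target"),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(seqs)) {
    warning("duplicate sequences in FASTA collapsed")
    first <- !duplicated(seqs)
    agg <- tapply(prov$count, seqs, sum)
    prov <- prov[first, , drop = FALSE]
    seqs <- seqs[first]
    prov$count <- as.integer(agg[seqs])
  }
  rownames(prov) <- NULL
  new("PeptideDatabase", peptides = unname(seqs), provenance = prov,
      params = list(source = path))
}
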