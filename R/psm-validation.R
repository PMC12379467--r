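## Target-decoy FDR, entrapment database construction and the
## entrapment-based false discovery proportion estimator.

#' Generate decoy peptides for a database
#'
#' Default method is full sequence reversal (entries are peptides, not
#' proteins, so no enzymatic terminus is preserved). A decoy colliding with
#' any target string — palindromes, notably — is re-drawn by seeded
#' residue shuffling until collision-free (or flagged after
#' \code{maxTries}).
#'
#' @param db A \code{\link{PeptideDatabase}} of targets.
#' @param method \code{"reverse"} or \code{"shuffle"}.
#' @param seed Seed for the shuffle fallback.
#' @param maxTries Shuffle attempts per colliding decoy.
#' @return A \code{PeptideDatabase} with targets followed by an equal number
#'   of decoys (\code{kind == "decoy"}).
#' @export
generateDecoys <- function(db, method = c("reverse", "shuffle"), seed = 1L,
                           maxTries = 25L) {
  method <- match.arg(method)
  targets <- peptides(db)
  if (length(targets) == 0L) stop("empty target database")
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  rng <- .seededRng(seed)
  decoys <- character(length(targets))
  tset <- targets
  for (i in seq_along(targets)) {
    d <- if (method == "reverse") revstr(targets[i]) else
      paste(sample_rng(rng, strsplit(targets[i], "")[[1]]), collapse = "")
    tries <- 0L
    while (d %in% tset && tries < maxTries) {
      d <- paste(sample_rng(rng, strsplit(targets[i], "")[[1]]),
                 collapse = "")
      tries <- tries + 1L
    }
    if (d %in% tset)
      warning("could not derive a collision-free decoy for ", targets[i])
    decoys[i] <- d
  }
  prov <- rbind(provenance(db),
                data.frame(count = 1L, runs = "", maxScore = NA_real_,
                           kind = "decoy", stringsAsFactors = FALSE,
                           row.names = NULL)[rep(1L, length(decoys)), ])
  ## decoys that still collide with targets (or each other) are dropped from
  ## the unique-sequence container rather than silently duplicated
  all <- c(targets, decoys)
  dup <- duplicated(all)
  new("PeptideDatabase", peptides = all[!dup],
      provenance = {p <- prov[!dup, , drop = FALSE]; rownames(p) <- NULL; p},
      params = c(dbParams(db), list(decoyMethod = method, decoySeed = seed)))
}

## Small local RNG wrapper: keeps decoy/entrapment sampling reproducible
## without touching the global .Random.seed.
.seededRng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    s
  })
  env
}

sample_rng <- function(rng, x, size = length(x), replace = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- sample(x, size = size, replace = replace)
  rng$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

#' Target-decoy FDR and q-values for a PSM table
#'
#' At each score threshold the FDR estimate is the number of decoys divided
#' by the number of targets among PSMs passing it; the q-value is the
#' running minimum of that estimate from the strictest threshold to the
#' loosest. Ties between a decoy and a target are broken decoy-first
#' (conservative).
#'
#' @param psms data.frame with columns \code{score} and logical
#'   \code{isDecoy} (plus anything else, carried through).
#' @param scoreOrientation \code{"higher"} if larger scores are better,
#'   \code{"lower"} otherwise (e.g. E-values).
#' @param correction \code{0} for the plain #decoys/#targets estimator
#'   (default), \code{1} for the +1-corrected variant.
#' @return The input with columns \code{fdr} and \code{qvalue} appended,
#'   sorted best score first.
#' @export
computeFdr <- function(psms, scoreOrientation = c("higher", "lower"),
                       correction = 0) {
  scoreOrientation <- match.arg(scoreOrientation)
  if (!any(psms$isDecoy)) stop("no decoy PSMs: FDR is undefined")
  s <- if (scoreOrientation == "higher") -psms$score else psms$score
  ord <- order(s, !psms$isDecoy)  # ties: decoys first
  d <- psms[ord, , drop = FALSE]
  cumD <- cumsum(d$isDecoy)
  cumT <- cumsum(!d$isDecoy)
  fdr <- (cumD + correction) / pmax(cumT, 1L)
  d$fdr <- fdr
  d$qvalue <- rev(cummin(rev(fdr)))
  attr(d, "fdrCorrection") <- correction
  rownames(d) <- NULL
  d
}

#' Filter targets at a q-value threshold
#'
#' @param psms Output of \code{\link{computeFdr}}.
#' @param alpha PSM-level FDR threshold (default 0.01).
#' @return Target PSMs with \code{qvalue <= alpha}.
#' @export
filterFdr <- function(psms, alpha = 0.01) {
  psms[!psms$isDecoy & psms$qvalue <= alpha, , drop = FALSE]
}

#' Augment a target database with entrapment sequences
#'
#' For peptide-kind databases the entrapment proteome is digested into fully
#' tryptic peptides of 6-100 residues with up to two missed cleavages,
#' peptides colliding with any target are removed, and
#' \code{ceiling(r * n_targets)} peptides are sampled with a seeded draw.
#' For protein-kind databases whole entrapment records are appended.
#'
#' @param db Target \code{\link{PeptideDatabase}}.
#' @param entrapmentProteins Named character vector (or AAStringSet) of
#'   entrapment protein sequences, foreign to the sample.
#' @param r Entrapment-to-target sequence ratio (> 0).
#' @param kind \code{"peptide"} or \code{"protein"}.
#' @param seed Sampling seed.
#' @param digestion \code{\link{digestionParams}} for peptide-kind
#'   augmentation.
#' @return Augmented \code{PeptideDatabase}; new entries have
#'   \code{kind == "entrapment"}.
#' @export
buildEntrapmentDb <- function(db, entrapmentProteins, r = 1, kind = c("peptide",
                              "protein"), seed = 1L,
                              digestion = digestionParams(missedCleavages = 2L,
                                                          lengthBounds = c(6L, 100L))) {
  kind <- match.arg(kind)
  if (r <= 0) stop("entrapment ratio r must be positive")
  prot <- as.character(entrapmentProteins)
  if (length(prot) == 0L) stop("empty entrapment proteome")
  targets <- peptides(db)
  if (kind == "peptide") {
    pool <- unique(unlist(lapply(prot, digestProtein, params = digestion),
                          use.names = FALSE))
    pool <- setdiff(pool, targets)
    n <- ceiling(r * length(targets))
    if (length(pool) < n)
      stop("entrapment pool (", length(pool),
           ") smaller than requested sample (", n, ")")
    rng <- .seededRng(seed)
    entr <- sort(sample_rng(rng, pool, size = n))
  } else {
    entr <- setdiff(unique(prot), targets)
  }
  prov <- rbind(provenance(db),
                data.frame(count = 1L, runs = "", maxScore = NA_real_,
                           kind = "entrapment", stringsAsFactors = FALSE,
                           row.names = NULL)[rep(1L, length(entr)), ])
  rownames(prov) <- NULL
  new("PeptideDatabase", peptides = c(targets, entr), provenance = prov,
      params = c(dbParams(db),
                 list(entrapmentRatio = r, entrapmentKind = kind,
                      entrapmentSeed = seed)))
}

#' Entrapment-based false discovery proportion estimate
#'
#' \deqn{\widehat{FDP} = \frac{N_E (1 + 1/r)}{N_T + N_E}}
#' where \eqn{N_E} is the number of identified entrapment peptides (known
#' false positives), \eqn{N_T} the number of identified original-target
#' peptides and \eqn{r} the entrapment-to-target sequence ratio of the
#' database. The \eqn{N_E/r} term extrapolates the false positives expected
#' from the target portion, making this a conservative upper-bound estimate
#' of the false discovery proportion among target identifications.
#'
#' @param nEntrapment \eqn{N_E}.
#' @param nTarget \eqn{N_T}.
#' @param r Entrapment-to-target ratio (> 0).
#' @return Estimated FDP as a fraction.
#' @examples
#' estimateFdp(10, 990, r = 1)  # 0.02
#' @export
estimateFdp <- function(nEntrapment, nTarget, r) {
  if (r <= 0) stop("r must be positive")
  if (nEntrapment < 0 || nTarget < 0) stop("counts must be non-negative")
  if (nEntrapment + nTarget == 0) stop("no identifications: FDP undefined")
  nEntrapment * (1 + 1 / r) / (nTarget + nEntrapment)
}

#' Keep items observed in a minimum number of samples
#'
#' Reproducibility filter used throughout the workflow ("detected in at
#' least two samples").
#'
#' @param items data.frame with at least the key column and a \code{sample}
#'   column.
#' @param key Column identifying the item (default \code{"peptide"}).
#' @param minSamples Minimum distinct samples (default 2).
#' @return Rows whose key occurs in at least \code{minSamples} distinct
#'   samples.
#' @export
minSampleFilter <- function(items, key = "peptide", minSamples = 2L) {
  if (minSamples <= 1L) return(items)
  nsamp <- tapply(items$sample, items[[key]],
                  function(s) length(unique(s)))
  keep <- names(nsamp)[nsamp >= minSamples]
  items[items[[key]] %in% keep, , drop = FALSE]
}
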