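#' @import methods
#' @importFrom stats median rnorm runif rlnorm setNames cor sd t.test rbeta
#' @importFrom utils read.delim write.table head tail
NULL

## Package-level caches for the chemistry tables. Loaded lazily from
## inst/extdata so users can override them (see loadIsotopeTable).
.pepSIPenv <- new.env(parent = emptyenv())

#' Load an element isotope table
#'
#' Reads a tab-separated table of isotope masses and natural fractional
#' abundances. The packaged default covers C, H, N, O and S with one
#' designated heavy "label" isotope for each labelable element
#' (2H, 13C, 18O; 15N carried for completeness).
#'
#' @param path Path to a TSV with columns \code{element}, \code{isotope_mass}
#'   (Da), \code{abundance} (fraction) and \code{label} (0/1 flag marking the
#'   isotope whose abundance is replaced when simulating label incorporation).
#'   Defaults to the packaged table.
#' @return A named list, one entry per element, each a data.frame with
#'   columns \code{mass}, \code{abundance}, \code{shift} (nominal mass shift
#'   relative to the lightest isotope) and \code{label}.
#' @export
loadIsotopeTable <- function(path = system.file("extdata", "isotopes.tsv",
                                                package = "pepSIP")) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  tab <- lapply(split(raw, raw$element), function(d) {
    d <- d[order(d$isotope_mass), , drop = FALSE]
    if (abs(sum(d$abundance) - 1) > 1e-9)
      stop("isotope abundances for ", d$element[1], " do not sum to 1")
    if (any(diff(d$isotope_mass) <= 0))
      stop("isotope masses for ", d$element[1], " not strictly ascending")
    data.frame(mass = d$isotope_mass,
               abundance = d$abundance,
               shift = as.integer(round(d$isotope_mass - d$isotope_mass[1])),
               label = as.logical(d$label))
  })
  tab
}

.isotopeTable <- function() {
  if (is.null(.pepSIPenv$isotopes))
    .pepSIPenv$isotopes <- loadIsotopeTable()
  .pepSIPenv$isotopes
}

.aminoAcidTable <- function() {
  if (is.null(.pepSIPenv$aa)) {
    path <- system.file("extdata", "amino_acids.tsv", package = "pepSIP")
    aa <- read.delim(path, stringsAsFactors = FALSE)
    rownames(aa) <- aa$residue
    .pepSIPenv$aa <- aa[, c("C", "H", "N", "O", "S")]
  }
  .pepSIPenv$aa
}

#' Natural abundance of the label isotope of an element
#'
#' @param element Element symbol ("C", "H", "O" or "N").
#' @return Natural abundance of the designated heavy isotope, in atom percent
#'   (e.g. 1.07 for carbon-13).
#' @export
naturalAbundance <- function(element) {
  tab <- .isotopeTable()
  if (!element %in% names(tab)) stop("unknown element: ", element)
  d <- tab[[element]]
  if (!any(d$label)) stop("element ", element, " has no designated label isotope")
  100 * d$abundance[d$label][1]
}

## ---- ElementalComposition ----------------------------------------------
## Represented as a named integer vector (element -> atom count); a tiny
## value class keeps validity checking and arithmetic in one place.

#' Elemental composition constructor
#'
#' @param ... Named atom counts, e.g. \code{elementalComposition(C = 2, H = 5,
#'   N = 1, O = 2)}, or a single named numeric vector.
#' @return A named integer vector of class \code{ElementalComposition}.
#' @export
elementalComposition <- function(...) {
  args <- list(...)
  x <- if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]])))
    args[[1]] else unlist(args)
  x <- round(x)
  if (any(x < 0)) stop("atom counts must be non-negative")
  storage.mode(x) <- "integer"
  x <- x[x > 0]
  class(x) <- "ElementalComposition"
  x
}

#' @export
`+.ElementalComposition` <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  out <- setNames(integer(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  class(out) <- "ElementalComposition"
  out
}

#' @export
print.ElementalComposition <- function(x, ...) {
  cat(paste0(names(x), unclass(x), collapse = " "), "\n")
  invisible(x)
}

#' Elemental composition of a peptide
#'
#' Sums residue compositions over the sequence and adds one water for the
#' termini. Fixed cysteine carbamidomethylation (+C2H3NO per C residue, the
#' standard iodoacetamide adduct) can be applied, and arbitrary modification
#' deltas supplied as compositions.
#'
#' @param seq Peptide string over the 20 canonical one-letter codes
#'   (uppercase).
#' @param carbamidomethyl Apply fixed carbamidomethylation to cysteines
#'   (default \code{FALSE}: the sequence string is assumed to reflect the
#'   composition used for quantification).
#' @param modifications Optional list of \code{ElementalComposition} deltas
#'   added to the total.
#' @return An \code{ElementalComposition}.
#' @examples
#' peptideComposition("G")   # C2 H5 N1 O2, glycine plus water
#' @export
peptideComposition <- function(seq, carbamidomethyl = FALSE,
                               modifications = NULL) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L)
    stop("peptide sequence must be a single non-empty string")
  aa <- .aminoAcidTable()
  res <- strsplit(seq, "")[[1]]
  bad <- which(!res %in% rownames(aa))
  if (length(bad))
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
  counts <- colSums(aa[res, , drop = FALSE])
  comp <- elementalComposition(counts) +
    elementalComposition(H = 2, O = 1)  # terminal water
  if (carbamidomethyl) {
    nC <- sum(res == "C")
    if (nC > 0)
      comp <- comp + elementalComposition(C = 2 * nC, H = 3 * nC,
                                          N = nC, O = nC)
  }
  if (!is.null(modifications))
    for (m in modifications) comp <- comp + m
  comp
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp An \code{ElementalComposition} (or named count vector).
#' @return Mass in Da: sum of count times lightest-isotope mass. An empty
#'   composition has mass 0.
#' @export
monoisotopicMass <- function(comp) {
  if (length(comp) == 0L) return(0)
  tab <- .isotopeTable()
  missing <- setdiff(names(comp), names(tab))
  if (length(missing))
    stop("element(s) missing from isotope table: ",
         paste(missing, collapse = ", "))
  sum(vapply(names(comp),
             function(el) comp[[el]] * tab[[el]]$mass[1], numeric(1)))
}

## ---- IsotopeEnvelope ----------------------------------------------------

#' IsotopeEnvelope: probabilities over nominal mass-shift isotopologues
#'
#' Ordered probabilities \eqn{p_0 \ldots p_K} for nominal mass shifts
#' +0 ... +K relative to the monoisotopic peak, together with the reference
#' monoisotopic mass, the label element and the relative isotope abundance
#' (RIA, atom percent) used for that element.
#'
#' @slot probs Numeric vector of isotopologue probabilities.
#' @slot monoMass Monoisotopic mass of the composition in Da.
#' @slot labelElement Element whose heavy isotope abundance was set.
#' @slot ria RIA of the label isotope used, in atom percent.
#' @export
setClass("IsotopeEnvelope",
         representation(probs = "numeric", monoMass = "numeric",
                        labelElement = "character", ria = "numeric"),
         validity = function(object) {
           if (any(object@probs < -1e-12))
             return("envelope probabilities must be non-negative")
           if (sum(object@probs) > 1 + 1e-9)
             return("envelope probabilities sum to more than 1")
           TRUE
         })

#' @describeIn IsotopeEnvelope probabilities accessor
#' @param x,object An \code{IsotopeEnvelope}.
#' @export
envelopeProbs <- function(x) x@probs

#' @describeIn IsotopeEnvelope monoisotopic mass (Da) accessor
#' @export
envelopeMonoMass <- function(x) x@monoMass

#' @describeIn IsotopeEnvelope RIA (atom percent) accessor
#' @export
envelopeRia <- function(x) x@ria

setMethod("show", "IsotopeEnvelope", function(object) {
  cat(sprintf("IsotopeEnvelope: %d peaks, mono %.5f Da, %s at %.2f atom%%\n",
              length(object@probs), object@monoMass,
              object@labelElement, object@ria))
  p <- round(object@probs, 4)
  cat(" p:", paste(p[seq_len(min(8, length(p)))], collapse = " "),
      if (length(p) > 8) "...\n" else "\n")
})

## Direct (non-FFT) linear convolution: keeps probabilities exact to
## floating round-off, which the enumeration-equivalence guarantee needs.
.conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  idx <- seq_along(b) - 1L
  for (i in seq_along(a)) out[i + idx] <- out[i + idx] + a[i] * b
  out
}

## Distribution of nominal shifts contributed by n atoms of one element.
## Binary-exponentiation of the single-atom shift distribution by
## convolution; exact for any n.
.elementShiftDist <- function(abund, shifts, n) {
  one <- numeric(max(shifts) + 1L)
  one[shifts + 1L] <- abund
  out <- 1
  base <- one
  while (n > 0) {
    if (n %% 2L == 1L) out <- .conv(out, base)
    n <- n %/% 2L
    if (n > 0) base <- .conv(base, base)
  }
  out
}

#' Isotopologue envelope of a composition at a given label abundance
#'
#' Convolves per-element isotope distributions in nominal mass-shift space.
#' For the label element, the designated heavy isotope's abundance is set to
#' \code{ria/100} and the remaining isotopes are rescaled proportionally so
#' abundances still sum to one. At \code{ria} equal to the natural abundance
#' the result is the natural envelope.
#'
#' @param comp \code{ElementalComposition}.
#' @param labelElement Element being labeled ("C", "H", "O" or "N"). If the
#'   composition lacks this element the natural envelope is returned.
#' @param ria Relative isotope abundance of the label isotope, atom percent
#'   in [0, 100]. Defaults to the natural abundance.
#' @param truncationTol Trailing peaks are dropped once cumulative
#'   probability reaches \code{1 - truncationTol}.
#' @return An \code{IsotopeEnvelope}.
#' @examples
#' env <- isotopeEnvelope(peptideComposition("PEPTIDER"), "C", ria = 50)
#' envelopeCentroid(env)
#' @export
isotopeEnvelope <- function(comp, labelElement = "C",
                            ria = naturalAbundance(labelElement),
                            truncationTol = 1e-6) {
  if (ria < 0 || ria > 100) stop("ria must lie in [0, 100]")
  if (truncationTol < 0) stop("truncationTol must be non-negative")
  tab <- .isotopeTable()
  missing <- setdiff(names(comp), names(tab))
  if (length(missing))
    stop("element(s) missing from isotope table: ",
         paste(missing, collapse = ", "))
  dist <- 1
  for (el in names(comp)) {
    d <- tab[[el]]
    ab <- d$abundance
    if (el == labelElement && any(d$label)) {
      p <- ria / 100
      rest <- !d$label
      ab[d$label] <- p
      ab[rest] <- d$abundance[rest] / sum(d$abundance[rest]) * (1 - p)
    }
    eldist <- .elementShiftDist(ab, d$shift, comp[[el]])
    dist <- .conv(dist, eldist)
  }
  cum <- cumsum(dist)
  keep <- which(cum < 1 - truncationTol)
  k <- if (length(keep)) min(max(keep) + 1L, length(dist)) else 1L
  probs <- dist[seq_len(k)]
  new("IsotopeEnvelope", probs = probs, monoMass = monoisotopicMass(comp),
      labelElement = labelElement, ria = ria)
}

#' Centroid mass shift of an envelope
#'
#' Intensity-weighted mean nominal shift, \eqn{\sum k p_k / \sum p_k}. For a
#' pure binomial envelope (carbon-only composition) this equals n times the
#' heavy-isotope fraction, which makes it a cheap independent oracle for RIA
#' recovery.
#'
#' @param env An \code{IsotopeEnvelope}.
#' @return Centroid in nominal-shift units.
#' @export
envelopeCentroid <- function(env) {
  p <- envelopeProbs(env)
  s <- sum(p)
  if (s <= 0) stop("all-zero envelope has no centroid")
  sum((seq_along(p) - 1) * p) / s
}
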