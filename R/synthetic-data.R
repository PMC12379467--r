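## Seeded simulator of a mock labeled community: taxonomy, proteomes,
## isotope-envelope features with known true RIA, error-bearing de novo
## reads with correlated scores, and target/decoy PSM score sets.

## Average-proteome residue frequencies (rounded, renormalized at use).
.AA_FREQ <- c(A = 0.083, R = 0.055, N = 0.041, D = 0.054, C = 0.014,
              Q = 0.039, E = 0.062, G = 0.072, H = 0.022, I = 0.057,
              L = 0.096, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
              S = 0.066, T = 0.054, W = 0.011, Y = 0.029, V = 0.068)

#' Specification of a simulated labeled community
#'
#' Defaults emulate a five-species mock community with two labeled members:
#' one heavily labeled (95.7 atom percent carbon-13, the near-complete
#' labeling seen after long incubation on a fully labeled substrate) and
#' one intermediately labeled (50 atom percent); the remaining three stay
#' at natural abundance. Sister taxa share a configurable fraction of
#' orthologous proteins verbatim, which creates genus/family-level
#' non-specific peptides.
#'
#' @param taxa Character vector of species names.
#' @param abundances Relative abundances (sum to 1).
#' @param trueRia Per-taxon true RIA, atom percent of the label isotope.
#' @param labeledFraction Per-taxon fraction of features drawn at the
#'   labeled RIA (the rest at natural abundance).
#' @param labelElement Label element (default "C").
#' @param orthologFraction Fraction of proteins shared verbatim between
#'   sister taxa (default 0.3).
#' @param proteinsPerTaxon Proteins simulated per taxon (default 30).
#' @param seed Master seed; every downstream draw derives from it.
#' @return List of class \code{CommunitySpec}.
#' @export
communitySpec <- function(taxa = c("Taxon_A", "Taxon_B", "Taxon_C",
                                   "Taxon_D", "Taxon_E"),
                          abundances = rep(1 / length(taxa), length(taxa)),
                          trueRia = c(95.7, 50, NA, NA, NA)[seq_along(taxa)],
                          labeledFraction = ifelse(is.na(trueRia), 0, 1),
                          labelElement = "C",
                          orthologFraction = 0.3,
                          proteinsPerTaxon = 30L, seed = 1L) {
  if (length(taxa) < 2L) stop("need at least two taxa")
  if (abs(sum(abundances) - 1) > 1e-6) stop("abundances must sum to 1")
  nat <- naturalAbundance(labelElement)
  ria <- ifelse(is.na(trueRia), nat, trueRia)
  if (any(ria < nat - 1e-9 | ria > 100)) stop("true RIA outside [natural, 100]")
  if (any(labeledFraction < 0 | labeledFraction > 1))
    stop("labeledFraction outside [0, 1]")
  structure(list(taxa = taxa, abundances = abundances, trueRia = ria,
                 labeledFraction = labeledFraction,
                 labelElement = labelElement,
                 orthologFraction = orthologFraction,
                 proteinsPerTaxon = as.integer(proteinsPerTaxon),
                 seed = as.integer(seed)),
            class = "CommunitySpec")
}

.randomProtein <- function(rng, meanLog = log(250), sdLog = 0.3) {
  len <- max(30L, round(exp(rnorm_rng(rng, 1, meanLog, sdLog))))
  paste(sample_prob_rng(rng, names(.AA_FREQ), size = len, replace = TRUE,
                        prob = .AA_FREQ / sum(.AA_FREQ)), collapse = "")
}

## rng-scoped wrappers around the stats RNG (same mechanism as sample_rng)
rnorm_rng <- function(rng, n, mean = 0, sd = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- rnorm(n, mean, sd)
  rng$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

runif_rng <- function(rng, n, min = 0, max = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- runif(n, min, max)
  rng$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

## sample with prob support (extends sample_rng signature)
sample_prob_rng <- function(rng, x, size, replace = FALSE, prob = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- sample(x, size = size, replace = replace, prob = prob)
  rng$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

#' Generate a mock community: taxonomy, proteomes, ortholog truth
#'
#' Builds a 7-rank taxonomy in which the first two taxa are sister species
#' in one genus, the next two share a family (distinct genera), and any
#' remaining taxa branch at class level under one phylum and domain.
#' Protein sequences are random with average-proteome residue frequencies
#' and log-normal lengths; sister taxa share \code{orthologFraction} of
#' their proteins verbatim. Fully deterministic under the spec seed.
#'
#' @param spec A \code{\link{communitySpec}}.
#' @return List with \code{tree} (\code{TaxonomyTree}), \code{proteomes}
#'   (named list: taxon name -> named character vector of proteins),
#'   \code{taxonIds} (species name -> taxon id) and \code{orthologs}
#'   (data.frame of shared protein pairs).
#' @export
generateCommunity <- function(spec) {
  rng <- .seededRng(spec$seed)
  k <- length(spec$taxa)
  nodes <- data.frame(
    id = c("d1", "p1", "c1", "c2", "o1", "o2", "f1", "f2", "g1", "g2"),
    name = c("Bacteria_sim", "Phylum_1", "Class_1", "Class_2", "Order_1",
             "Order_2", "Family_1", "Family_2", "Genus_1", "Genus_2"),
    rank = c("domain", "phylum", "class", "class", "order", "order",
             "family", "family", "genus", "genus"),
    parent = c("d1", "d1", "p1", "p1", "c1", "c2", "o1", "o1", "f1", "f1"),
    stringsAsFactors = FALSE)
  ## species placement: taxa 1,2 -> g1 (sisters); 3,4 -> g2 and f2;
  ## extra taxa -> their own genera under o2/c2
  speciesParent <- character(k)
  speciesParent[1:min(2, k)] <- "g1"
  if (k >= 3) speciesParent[3] <- "g2"
  if (k >= 4) speciesParent[4] <- "f2"
  if (k >= 5) for (i in 5:k) {
    gid <- paste0("gx", i)
    nodes <- rbind(nodes, data.frame(id = gid, name = paste0("Genus_x", i),
                                     rank = "genus", parent = "o2",
                                     stringsAsFactors = FALSE))
    speciesParent[i] <- gid
  }
  spIds <- paste0("s", seq_len(k))
  nodes <- rbind(nodes, data.frame(id = spIds, name = spec$taxa,
                                   rank = "species",
                                   parent = speciesParent,
                                   stringsAsFactors = FALSE))
  ## f2 hangs directly under o1 but species 4 needs a genus for a full
  ## lineage; give it one
  if (k >= 4) {
    nodes <- rbind(nodes, data.frame(id = "g3", name = "Genus_3",
                                     rank = "genus", parent = "f2",
                                     stringsAsFactors = FALSE))
    nodes$parent[nodes$id == spIds[4]] <- "g3"
  }
  tree <- taxonomyTree(nodes)
  proteomes <- vector("list", k)
  names(proteomes) <- spec$taxa
  for (i in seq_len(k)) {
    prot <- vapply(seq_len(spec$proteinsPerTaxon), function(j)
      .randomProtein(rng), character(1))
    names(prot) <- sprintf("%s_prot%03d", spec$taxa[i],
                           seq_len(spec$proteinsPerTaxon))
    proteomes[[i]] <- prot
  }
  ## sisters (taxa 1 and 2) share orthologFraction of proteins verbatim
  orthologs <- data.frame(from = character(0), to = character(0),
                          protein = character(0), stringsAsFactors = FALSE)
  if (k >= 2 && spec$orthologFraction > 0) {
    nShared <- round(spec$orthologFraction * spec$proteinsPerTaxon)
    if (nShared > 0) {
      idx <- seq_len(nShared)
      proteomes[[2]][idx] <- proteomes[[1]][idx]
      orthologs <- data.frame(from = names(proteomes[[1]])[idx],
                              to = names(proteomes[[2]])[idx],
                              protein = unname(proteomes[[1]][idx]),
                              stringsAsFactors = FALSE)
    }
  }
  list(tree = tree, proteomes = proteomes,
       taxonIds = setNames(spIds, spec$taxa), orthologs = orthologs)
}

#' Generate noisy peptide features with known true RIA
#'
#' Samples tryptic peptides (7-30 residues) from each taxon's digested
#' proteome, computes their isotope envelopes at the taxon's true RIA (or a
#' two-component natural/labeled mixture when \code{mixtureShare} is set),
#' and corrupts them with multiplicative log-normal peak noise, an additive
#' uniform baseline and dropout of peaks below a relative-intensity floor.
#'
#' @param community Output of \code{\link{generateCommunity}}.
#' @param spec The \code{\link{communitySpec}} used.
#' @param nPerTaxon Features per taxon per sample (default 20).
#' @param samples Sample ids (default \code{c("s1","s2","s3")}).
#' @param noiseSigma Log-normal noise sigma as a fraction (default 0.02,
#'   i.e. 2 percent).
#' @param baseline Additive uniform baseline as a fraction of the summed
#'   intensity (default 0.001).
#' @param dropoutFloor Peaks below this relative intensity may be dropped
#'   (default 1e-4).
#' @param mixtureShare When non-NULL, labeled taxa emit two-component
#'   features: this share at the labeled RIA and the rest at natural
#'   abundance.
#' @param seed Seed (defaults to \code{spec$seed + 1}).
#' @return List with \code{features} (data.frame: peptide, charge, sample,
#'   taxon, intensities as comma-joined strings) and \code{truth}
#'   (data.frame: peptide, sample, taxon, trueRia, trueShare).
#' @export
generateFeatures <- function(community, spec, nPerTaxon = 20L,
                             samples = c("s1", "s2", "s3"),
                             noiseSigma = 0.02, baseline = 0.001,
                             dropoutFloor = 1e-4, mixtureShare = NULL,
                             seed = spec$seed + 1L) {
  rng <- .seededRng(seed)
  nat <- naturalAbundance(spec$labelElement)
  digestion <- digestionParams(missedCleavages = 0L,
                               lengthBounds = c(7L, 30L))
  feats <- list(); truths <- list()
  for (i in seq_along(spec$taxa)) {
    taxon <- spec$taxa[i]
    peps <- unique(unlist(lapply(community$proteomes[[taxon]],
                                 digestProtein, params = digestion),
                          use.names = FALSE))
    if (length(peps) == 0L) stop("taxon ", taxon,
                                 " has no peptides in length range")
    chosen <- sample_rng(rng, peps,
                         size = min(nPerTaxon, length(peps)))
    isLabeled <- runif_rng(rng, length(chosen)) < spec$labeledFraction[i]
    for (smp in samples) {
      for (j in seq_along(chosen)) {
        pep <- chosen[j]
        comp <- peptideComposition(pep)
        riaTrue <- if (isLabeled[j]) spec$trueRia[i] else nat
        if (!is.null(mixtureShare) && isLabeled[j]) {
          pNat <- envelopeProbs(isotopeEnvelope(comp, spec$labelElement,
                                                ria = nat))
          pLab <- envelopeProbs(isotopeEnvelope(comp, spec$labelElement,
                                                ria = spec$trueRia[i]))
          kmax <- max(length(pNat), length(pLab))
          length(pNat) <- kmax; length(pLab) <- kmax
          pNat[is.na(pNat)] <- 0; pLab[is.na(pLab)] <- 0
          probs <- (1 - mixtureShare) * pNat + mixtureShare * pLab
          trueShare <- mixtureShare
        } else {
          probs <- envelopeProbs(isotopeEnvelope(comp, spec$labelElement,
                                                 ria = riaTrue))
          trueShare <- 1
        }
        noisy <- probs * exp(rnorm_rng(rng, length(probs), 0, noiseSigma)) +
          runif_rng(rng, length(probs), 0, baseline)
        drop <- noisy / max(noisy) < dropoutFloor &
          runif_rng(rng, length(noisy)) < 0.5
        noisy[drop] <- 0
        feats[[length(feats) + 1L]] <- data.frame(
          peptide = pep, charge = 2L, sample = smp, taxon = taxon,
          intensities = paste(format(noisy, digits = 10, trim = TRUE,
                                     scientific = FALSE),
                              collapse = ","),
          stringsAsFactors = FALSE)
        truths[[length(truths) + 1L]] <- data.frame(
          peptide = pep, sample = smp, taxon = taxon, trueRia = riaTrue,
          trueShare = trueShare, stringsAsFactors = FALSE)
      }
    }
  }
  list(features = do.call(rbind, feats), truth = do.call(rbind, truths))
}

#' Generate error-bearing de novo reads with quality scores
#'
#' Each feature yields one read; each residue is substituted independently
#' with the given error rate, preferring mass-plausible swaps (I/L, K/Q,
#' N/D, E/Q classes). Scores are drawn from a high-mean Beta component for
#' error-free reads and a lower-mean component otherwise, so thresholding
#' on the score enriches correct reads.
#'
#' @param features Feature table from \code{\link{generateFeatures}}.
#' @param errorRate Per-residue substitution probability (default 0.05).
#' @param seed Seed.
#' @return List with \code{reads} (data.frame: run, spectrum, sequence,
#'   score, engine) and \code{truth} (data.frame: spectrum, truePeptide,
#'   correct).
#' @export
generateDenovoReads <- function(features, errorRate = 0.05, seed = 1L) {
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0, 1)")
  rng <- .seededRng(seed)
  swaps <- list(I = "L", L = "I", K = "Q", Q = "K", N = "D", D = "N",
                E = "Q")
  reads <- vector("list", nrow(features))
  truth <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    pep <- strsplit(features$peptide[i], "")[[1]]
    hit <- runif_rng(rng, length(pep)) < errorRate
    out <- pep
    for (j in which(hit)) {
      out[j] <- if (!is.null(swaps[[pep[j]]])) swaps[[pep[j]]] else
        sample_rng(rng, setdiff(names(.AA_FREQ), pep[j]), size = 1L)
    }
    correct <- !any(hit)
    score <- if (correct) rbeta_rng(rng, 1, 60, 0.6) else
      rbeta_rng(rng, 1, 4, 2)
    reads[[i]] <- data.frame(run = features$sample[i],
                             spectrum = sprintf("scan=%d", i),
                             sequence = paste(out, collapse = ""),
                             score = score, engine = "sim",
                             stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(spectrum = sprintf("scan=%d", i),
                             truePeptide = features$peptide[i],
                             correct = correct, stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
}

rbeta_rng <- function(rng, n, shape1, shape2) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- rbeta(n, shape1, shape2)
  rng$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

#' Generate a synthetic PSM score set with decoys and planted truth
#'
#' True-target scores come from a high-mean normal component; false-target
#' and decoy scores are i.i.d. draws from the null component (the
#' equal-null assumption of target-decoy competition), with one decoy per
#' null target.
#'
#' @param nTrue Number of true target PSMs.
#' @param nFalse Number of false target PSMs (and of decoys).
#' @param separation Mean separation between the true and null score
#'   components, in null standard deviations (default 3.5).
#' @param seed Seed.
#' @return data.frame: \code{spectrum}, \code{peptide}, \code{score},
#'   \code{isDecoy}, \code{isTrue} (planted truth; decoys are FALSE),
#'   \code{sample}.
#' @export
generatePsmScores <- function(nTrue, nFalse, separation = 3.5, seed = 1L) {
  if (nTrue <= 0 || nFalse <= 0) stop("counts must be positive")
  rng <- .seededRng(seed)
  scoreT <- rnorm_rng(rng, nTrue, separation, 1)
  scoreF <- rnorm_rng(rng, nFalse, 0, 1)
  scoreD <- rnorm_rng(rng, nFalse, 0, 1)
  n <- nTrue + 2L * nFalse
  data.frame(spectrum = sprintf("spec%06d", seq_len(n)),
             peptide = sprintf("PEP%06d", seq_len(n)),
             score = c(scoreT, scoreF, scoreD),
             isDecoy = rep(c(FALSE, FALSE, TRUE), c(nTrue, nFalse, nFalse)),
             isTrue = rep(c(TRUE, FALSE, FALSE), c(nTrue, nFalse, nFalse)),
             sample = "sim", stringsAsFactors = FALSE)
}
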