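## Independent oracles used across the suite. These deliberately avoid the
## package's convolution/LCA code paths.

## Exhaustive multinomial enumeration of the isotopologue distribution in
## nominal-shift space. Per element, every partition of its atoms over its
## isotopes is enumerated with dmultinom; elements are combined by an outer
## cartesian walk. Feasible for compositions of a few dozen atoms.
enumEnvelopeOracle <- function(comp, labelElement = "C", ria = NULL) {
  iso <- loadIsotopeTable()
  perElement <- lapply(names(comp), function(el) {
    d <- iso[[el]]
    ab <- d$abundance
    if (el == labelElement && any(d$label) && !is.null(ria)) {
      p <- ria / 100
      rest <- !d$label
      ab[d$label] <- p
      ab[rest] <- d$abundance[rest] / sum(d$abundance[rest]) * (1 - p)
    }
    n <- comp[[el]]
    m <- length(ab)
    ## all compositions k_1..k_m with sum n
    combos <- if (m == 1L) matrix(n, 1, 1) else {
      grid <- do.call(expand.grid, rep(list(0:n), m - 1L))
      last <- n - rowSums(grid)
      ok <- last >= 0
      as.matrix(cbind(grid[ok, , drop = FALSE], last[ok]))
    }
    probs <- apply(combos, 1, function(k) dmultinom(k, prob = ab))
    shifts <- as.vector(combos %*% d$shift)
    agg <- tapply(probs, shifts, sum)
    list(shift = as.integer(names(agg)), prob = as.numeric(agg))
  })
  ## combine elements by outer walk
  acc <- data.frame(shift = 0L, prob = 1)
  for (pe in perElement) {
    shift <- as.vector(outer(acc$shift, pe$shift, `+`))
    prob <- as.vector(outer(acc$prob, pe$prob, `*`))
    agg <- tapply(prob, shift, sum)
    acc <- data.frame(shift = as.integer(names(agg)),
                      prob = as.numeric(agg))
  }
  out <- numeric(max(acc$shift) + 1L)
  out[acc$shift + 1L] <- acc$prob
  out
}

## Brute-force LCA: intersection of root paths, deepest common node.
lcaOracle <- function(taxa, nodesDf) {
  parent <- setNames(nodesDf$parent, nodesDf$id)
  pathOf <- function(id) {
    p <- character(0)
    cur <- id
    while (!is.na(cur) && !cur %in% p) {
      p <- c(p, cur)
      nxt <- parent[[cur]]
      if (is.na(nxt) || identical(nxt, cur)) break
      cur <- nxt
    }
    p
  }
  paths <- lapply(unique(as.character(taxa)), pathOf)
  common <- Reduce(intersect, paths)
  common[1]  # paths are node-first, so first common entry is deepest
}

## Random rooted tree over n nodes with ids t1..tn; t1 is the root.
randomTreeDf <- function(n, seed) {
  set.seed(seed)
  ids <- paste0("t", seq_len(n))
  parent <- c(ids[1], vapply(2:n, function(i)
    ids[sample.int(i - 1L, 1L)], character(1)))
  data.frame(id = ids, name = ids, rank = "no rank", parent = parent,
             stringsAsFactors = FALSE)
}

## Residue-sum peptide mass, independent of ElementalComposition math.
RESIDUE_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
                  V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
                  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
                  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
                  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
residueSumMass <- function(pep)
  sum(RESIDUE_MONO[strsplit(pep, "")[[1]]]) + 18.0105646

## Noisy natural-abundance feature for a peptide (multiplicative
## log-normal peak noise).
noisyNaturalFeature <- function(pep, sigma = 0.02) {
  p <- envelopeProbs(isotopeEnvelope(peptideComposition(pep), "C"))
  p * exp(rnorm(length(p), 0, sigma))
}
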