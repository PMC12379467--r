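test_that("tryptic digestion follows the K/R rule with the proline exception", {
  p0 <- digestionParams(missedCleavages = 0L, lengthBounds = c(3L, 10L))
  expect_equal(digestProtein("AAAKEEERCCC", p0), c("AAAK", "EEER", "CCC"))
  ## K before P is not cleaved
  expect_equal(digestProtein("AAAKPEEE", digestionParams(
    missedCleavages = 0L, lengthBounds = c(3L, 10L))), "AAAKPEEE")
  ## the exception is toggleable
  expect_equal(digestProtein("AAAKPEEE", digestionParams(
    missedCleavages = 0L, lengthBounds = c(3L, 10L), nroP = FALSE)),
    c("AAAK", "PEEE"))
  ## no cleavage site: the sequence itself iff within bounds
  expect_equal(digestProtein("AAAA", p0), "AAAA")
  expect_equal(digestProtein("AA", p0), character(0))
})

test_that("missed cleavages enumerate contiguous segment joins", {
  p2 <- digestionParams(missedCleavages = 2L, lengthBounds = c(1L, 100L))
  out <- digestProtein("AAKBBKCCK", p2)
  expect_setequal(out, c("AAK", "BBK", "CCK", "AAKBBK", "BBKCCK",
                         "AAKBBKCCK"))
  ## every product is a contiguous substring of the source
  expect_true(all(vapply(out, function(p)
    grepl(p, "AAKBBKCCK", fixed = TRUE), logical(1))))
  ## 0-missed-cleavage products concatenate back to the source
  p0 <- digestionParams(missedCleavages = 0L, lengthBounds = c(1L, 100L))
  expect_equal(paste(digestProtein("AAKBBKCCK", p0), collapse = ""),
               "AAKBBKCCK")
})

dropoffFixture <- function(sharedFraction = 0.5, nPep = 20) {
  ## two sister species sharing a configurable fraction of peptides
  tree <- taxonomyTree(data.frame(
    id = c("d", "p", "c", "o", "f", "g", "s1", "s2"),
    name = c("Bacteria", "P", "C", "O", "F", "G", "SpA", "SpB"),
    rank = c("domain", "phylum", "class", "order", "family", "genus",
             "species", "species"),
    parent = c("d", "d", "p", "c", "o", "f", "g", "g"),
    stringsAsFactors = FALSE))
  set.seed(31)
  mk <- function() paste(c(sample(c("A", "G", "S", "T", "V", "E", "D",
                                    "F", "W", "Y", "H", "M", "N", "Q"),
                                  9, replace = TRUE), "K"), collapse = "")
  peps <- unique(replicate(nPep * 3, mk()))[seq_len(nPep)]
  nShared <- round(sharedFraction * nPep)
  protA <- paste(peps, collapse = "")
  protB <- paste(c(peps[seq_len(nShared)],
                   unique(replicate(nPep * 3, mk()))[seq_len(nPep - nShared)]),
                 collapse = "")
  idx <- buildPeptideIndex(c(a = protA, b = protB), c("s1", "s2"),
                           tree = tree,
                           params = digestionParams(missedCleavages = 0L,
                                                    lengthBounds = c(7L, 15L)))
  list(tree = tree, protA = protA, protB = protB, idx = idx, peps = peps)
}

test_that("theoretical drop-off reflects peptide sharing between sisters", {
  fx <- dropoffFixture(sharedFraction = 0.5)
  prof <- theoreticalDropoff(c(a = fx$protA), index = fx$idx,
                             tree = fx$tree, focalTaxon = "s1",
                             nSample = 20L, seed = 5)
  tab <- dropoffTable(prof)
  expect_equal(tab$fraction[tab$rank == "domain"], 1)
  expect_true(all(diff(tab$fraction) <= 0))        # non-increasing
  expect_equal(tab$fraction[tab$rank == "genus"], 1)   # all within genus
  expect_equal(tab$fraction[tab$rank == "species"], 0.5, tolerance = 0.15)

  ## fully species-specific proteome -> flat profile at 1
  fx0 <- dropoffFixture(sharedFraction = 0)
  prof0 <- theoreticalDropoff(c(a = fx0$protA), index = fx0$idx,
                              tree = fx0$tree, focalTaxon = "s1",
                              nSample = 20L, seed = 5)
  expect_true(all(dropoffTable(prof0)$fraction == 1))

  ## seeded determinism
  prof2 <- theoreticalDropoff(c(a = fx$protA), index = fx$idx,
                              tree = fx$tree, focalTaxon = "s1",
                              nSample = 20L, seed = 5)
  expect_identical(dropoffTable(prof), dropoffTable(prof2))

  expect_warning(theoreticalDropoff(c(a = fx$protA), index = fx$idx,
                                    tree = fx$tree, focalTaxon = "s1",
                                    nSample = 10000L, seed = 5),
                 "smaller than requested")
})

test_that("observed drop-off tallies labeled LCAs per rank", {
  fx <- dropoffFixture()
  asg <- data.frame(peptide = paste0("p", 1:10),
                    taxon = c(rep("s1", 6), rep("f", 3), "g"))
  prof <- observedDropoff(asg, fx$tree, "s1")
  tab <- dropoffTable(prof)
  expect_equal(tab$count[tab$rank == "species"], 6L)
  expect_equal(tab$count[tab$rank == "family"], 3L)
  expect_equal(tab$count[tab$rank == "genus"], 1L)
  expect_equal(tab$fraction[tab$rank == "domain"], 1)
  ## no labeled peptides on the lineage -> all-zero profile
  zero <- observedDropoff(data.frame(peptide = "p", taxon = NA_character_),
                          fx$tree, "s1")
  expect_true(all(dropoffTable(zero)$count == 0L))
})

test_that("drop-off comparison reports deviations in percentage points", {
  fx <- dropoffFixture()
  asg <- data.frame(peptide = paste0("p", 1:10), taxon = rep("s1", 10))
  prof <- observedDropoff(asg, fx$tree, "s1")
  same <- compareDropoff(prof, prof)
  expect_equal(same$maxDeviation, 0)
  ## engineered 6-point gap at species level
  other <- observedDropoff(
    data.frame(peptide = paste0("q", 1:50),
               taxon = c(rep("s1", 37), rep("d", 13))), fx$tree, "s1")
  dev <- compareDropoff(prof, other)
  expect_equal(dev$maxDeviation,
               max(abs(dropoffTable(other)$fraction -
                         dropoffTable(prof)$fraction)) * 100)
})

test_that("randomized peptides rarely hit species-specific assignments", {
  fx <- dropoffFixture(sharedFraction = 0)
  set.seed(77)
  random12 <- replicate(30, paste(sample(names(pepSIP:::.AA_FREQ), 12,
                                         replace = TRUE), collapse = ""))
  ctl <- randomizationControl(random12, fx$idx, fx$tree, seed = 3,
                              nRounds = 3)
  expect_lt(ctl[["species"]], 1)
  ## single-residue peptides shuffle to themselves
  one <- randomizationControl(c("K", "A"), fx$idx, fx$tree, seed = 3,
                              nRounds = 2)
  expect_equal(sum(one), 2)
  expect_equal(unname(one[["unassigned"]]), 2)
  ## determinism
  ctl2 <- randomizationControl(random12, fx$idx, fx$tree, seed = 3,
                               nRounds = 3)
  expect_identical(ctl, ctl2)
})

test_that("BLAST import keeps e-value < cutoff and multi-hit organisms", {
  f <- tempfile(fileext = ".tsv")
  rows <- c(
    "q1\ts1\t98\t10\t0\t0\t1\t10\t1\t10\t1e-05\t50\tOrganism A",
    "q2\ts2\t97\t10\t0\t0\t1\t10\t1\t10\t0.001\t40\tOrganism A",
    "q3\ts3\t96\t10\t0\t0\t1\t10\t1\t10\t1e-04\t45\tOrganism A",
    "q4\ts4\t95\t10\t0\t0\t1\t10\t1\t10\t1e-06\t60\tOrganism B")
  writeLines(rows, f)
  out <- importBlastTabular(f)
  ## the e-value == 0.001 hit is removed (strict <); Organism B has a
  ## single surviving hit and is dropped
  expect_equal(nrow(out$hits), 2L)
  expect_setequal(out$hits$qseqid, c("q1", "q3"))
  expect_equal(out$organisms$organism, "Organism A")
  expect_equal(out$organisms$nHits, 2L)
})

test_that("unassigned export writes one FASTA entry per peptide", {
  f <- tempfile(fileext = ".fasta")
  exportUnassigned(c("PEPTIDER", "AAAAGGGG"), f)
  x <- Biostrings::readAAStringSet(f)
  expect_equal(length(x), 2L)
  expect_equal(as.character(x[[1]]), "PEPTIDER")
  ## zero peptides: empty FASTA, no error
  f0 <- tempfile(fileext = ".fasta")
  expect_no_error(exportUnassigned(character(0), f0))
  expect_equal(length(Biostrings::readAAStringSet(f0)), 0L)
})
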