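## Small reference community reused across taxonomy tests: two
## Enterobacteriaceae-style sister species plus a fungus-like outgroup.
toyTree <- function() {
  taxonomyTree(data.frame(
    id     = c("root", "bac", "fun", "pro", "gam", "ent", "esc", "sal",
               "eco", "sen", "asc", "sac", "sce"),
    name   = c("cellular", "Bacteria", "Fungi", "Pseudomonadota",
               "Gammaproteobacteria", "Enterobacteriaceae", "Escherichia",
               "Salmonella", "E_coli_like", "S_enterica_like", "Ascomycota",
               "Saccharomyces", "S_cerevisiae_like"),
    rank   = c("no rank", "domain", "domain", "phylum", "class", "family",
               "genus", "genus", "species", "species", "phylum", "genus",
               "species"),
    parent = c("root", "root", "root", "bac", "pro", "gam", "ent", "ent",
               "esc", "sal", "fun", "asc", "sac"),
    stringsAsFactors = FALSE))
}

toyIndex <- function(tree = toyTree()) {
  proteins <- c(eco1 = "AAAGGGKTEPTIDERVVVK",
                eco2 = "AAAGGGKTTTTTTK",
                sen1 = "AAAGGGKTEPTLDERVVVK",
                sce1 = "WWWYYYKFFFFFFR")
  buildPeptideIndex(proteins, c("eco", "eco", "sen", "sce"), tree = tree,
                    params = digestionParams(missedCleavages = 1L,
                                             lengthBounds = c(5L, 30L)))
}

test_that("LCA resolves singletons, sisters and cross-domain sets", {
  tree <- toyTree()
  expect_equal(taxLca("eco", tree), "eco")
  expect_equal(taxLca(c("eco", "sen"), tree), "ent")  # family level
  expect_equal(taxLca(c("eco", "sce"), tree), "root")
  expect_equal(taxLca(character(0), tree), NA_character_)
  expect_error(taxLca("nope", tree), "unknown taxon")
})

test_that("LCA agrees with the root-path-intersection oracle", {
  df <- randomTreeDf(60, seed = 9)
  tree <- taxonomyTree(df)
  set.seed(10)
  for (i in 1:150) {
    taxa <- sample(df$id, sample(1:5, 1))
    expect_identical(taxLca(taxa, tree), lcaOracle(taxa, df))
  }
})

test_that("the index collapses I/L and maps shared peptides to both taxa", {
  tree <- toyTree()
  idx <- toyIndex(tree)
  ## AAAGGGK occurs in eco and sen proteins -> both taxa
  expect_setequal(idx@peptideTaxa[["AAAGGGK"]], c("eco", "sen"))
  ## PEPTIDER (eco) and PEPTLDER (sen) collapse to one key
  expect_setequal(idx@peptideTaxa[["TEPTLDER"]], c("eco", "sen"))
  expect_null(idx@peptideTaxa[["TEPTIDER"]])   # only collapsed keys exist
})

test_that("peptide assignment uses LCA and I/L-invariant lookups", {
  tree <- toyTree()
  idx <- toyIndex(tree)
  expect_equal(assignPeptide("TTTTTTK", idx, tree)$taxon, "eco")
  expect_equal(assignPeptide("AAAGGGK", idx, tree)$taxon, "ent")
  expect_equal(assignPeptide("TEPTIDER", idx, tree)$taxon, "ent")
  expect_equal(assignPeptide("TEPTLDER", idx, tree)$taxon, "ent")
  expect_true(is.na(assignPeptide("MISSINGPEPK", idx, tree)$taxon))
})

test_that("missed-cleavage handling assigns via all tryptic fragments", {
  tree <- toyTree()
  proteins <- c(p1 = "AAAATTKGGGGSSR")   # fragments AAAATTK + GGGGSSR
  idx <- buildPeptideIndex(proteins, "eco", tree = tree,
                           params = digestionParams(missedCleavages = 0L,
                                                    lengthBounds = c(5L, 10L)))
  ## the full missed-cleavage peptide is absent from the 0-MC index but
  ## both halves map to eco
  expect_null(idx@peptideTaxa[["AAAATTKGGGGSSR"]])
  expect_equal(assignPeptide("AAAATTKGGGGSSR", idx, tree)$taxon, "eco")
  expect_true(is.na(assignPeptide("AAAATTKGGGGSSR", idx, tree,
                                  handleMissedCleavage = FALSE)$taxon))
})

test_that("replacing I with L never changes an assignment", {
  tree <- toyTree()
  idx <- toyIndex(tree)
  queries <- c("TEPTIDER", "TTTTTTK", "AAAGGGK")
  for (q in queries) {
    swapped <- gsub("I", "L", q)
    expect_identical(assignPeptide(q, idx, tree)$taxon,
                     assignPeptide(swapped, idx, tree)$taxon)
  }
})

test_that("GO slim rollup maps terms to slim ancestors", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0001", "name: biological_process", "",
    "[Term]", "id: GO:0002", "name: metabolism", "is_a: GO:0001 ! bp", "",
    "[Term]", "id: GO:0003", "name: transport", "is_a: GO:0001 ! bp", "",
    "[Term]", "id: GO:0004", "name: sugar metabolism",
    "is_a: GO:0002 ! metabolism", "",
    "[Term]", "id: GO:0005", "name: sugar transport",
    "is_a: GO:0002 ! metabolism", "is_a: GO:0003 ! transport", "",
    "[Term]", "id: GO:0006", "name: gone", "is_obsolete: true"), obo)
  ont <- readObo(obo)
  expect_false("GO:0006" %in% names(ont$parents))
  slim <- c("GO:0002", "GO:0003")
  expect_equal(goslimRollup("GO:0002", ont, slim), c("GO:0002" = 1L))
  expect_equal(goslimRollup("GO:0004", ont, slim), c("GO:0002" = 1L))
  r <- goslimRollup("GO:0005", ont, slim)   # child of two slim ancestors
  expect_setequal(names(r), slim)
  expect_true(all(r == 1L))
  ## rollup of slim terms is idempotent and never emits non-slim terms
  twice <- goslimRollup(names(r), ont, slim)
  expect_setequal(names(twice), names(r))
  expect_true(all(names(goslimRollup(c("GO:0004", "GO:0005"), ont, slim))
                  %in% slim))
  expect_message(goslimRollup("GO:9999", ont, slim), "unknown")
})

test_that("group filtering enforces peptide and sample support", {
  g <- data.frame(group = c("t1", "t1", "t1", "t2", "t2", "t1"),
                  peptide = c("a", "b", "c", "d", "e", "f"),
                  ria = c(10, 11, 12, 9, 8, 10),
                  nSamples = c(3, 2, 2, 2, 2, 1))
  out <- groupFilter(g, minPeptides = 3, minSamples = 2)
  expect_setequal(unique(out$group), "t1")
  expect_equal(nrow(out), 3L)   # the 1-sample peptide is gone
  expect_identical(groupFilter(g, minPeptides = 1, minSamples = 1), g)
})

test_that("group comparison is a pooled-variance t-test with stars", {
  same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$pValue, 1)
  expect_equal(same$stars, "")

  set.seed(2)
  a <- rnorm(30, 1.07, 1); b <- rnorm(30, 50, 1)
  res <- compareGroups(a, b)
  ## closed-form pooled t computed independently
  sp <- sqrt(((29) * var(a) + (29) * var(b)) / 58)
  tManual <- (mean(a) - mean(b)) / (sp * sqrt(1 / 30 + 1 / 30))
  expect_equal(res$statistic, tManual, tolerance = 1e-12)
  expect_lt(res$pValue, 0.001)
  expect_equal(res$stars, "***")

  undef <- compareGroups(c(1), c(2, 3))
  expect_true(is.na(undef$pValue))
  zeroVar <- compareGroups(c(5, 5), c(7, 7))
  expect_true(is.na(zeroVar$pValue))
})

test_that("rank summaries roll peptides up along the lineage", {
  tree <- toyTree()
  asg <- data.frame(peptide = c("p1", "p2", "p3", "p4", "p5"),
                    taxon = c("eco", "eco", "eco", "ent", "sen"),
                    ria = c(8, 9, 10, 50, 12),
                    labeled = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  sp <- summarizeTaxa(asg, tree, "species")
  eco <- sp[sp$taxon == "eco", ]
  expect_equal(eco$nPeptides, 3L)
  expect_equal(eco$medianRia, 9)
  expect_equal(eco$nLabeled, 2L)
  ## family-level peptide appears at family rank, not species
  expect_false("ent" %in% sp$taxon)
  fam <- summarizeTaxa(asg, tree, "family")
  expect_equal(fam$nPeptides[fam$taxon == "ent"], 5L)  # all on the lineage
  expect_error(summarizeTaxa(asg, tree, "tribe"), "unknown rank")
})

test_that("rank rollup conserves counts monotonically", {
  tree <- toyTree()
  set.seed(4)
  asg <- data.frame(peptide = paste0("p", 1:30),
                    taxon = sample(c("eco", "sen", "esc", "ent", "gam"),
                                   30, replace = TRUE),
                    ria = runif(30, 1, 99), labeled = TRUE)
  counts <- vapply(c("phylum", "class", "family", "genus", "species"),
                   function(r) sum(summarizeTaxa(asg, tree, r)$nPeptides),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})
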