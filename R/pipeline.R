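## End-to-end orchestration: single config, staged outputs, manifest with
## full parameter provenance, resume of completed stages.

#' Default pipeline configuration
#'
#' Flat key set, one namespace per stage. Paths are resolved against the
#' run directory. Thresholds default to the workflow's standard values:
#' quality score > 0.99, PSM-level FDR 1 percent, carbon-13 label with a
#' ±5 atom percent merge window and 0.5 atom percent grid step, peptides in
#' at least 2 samples and taxa with at least 3 peptides.
#'
#' @param ... Overrides of default keys.
#' @return Named list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    denovo_path = NULL, denovo_dialect = "tsv",
    score_threshold = 0.99, min_length = 6L, max_length = 100L,
    psm_path = NULL, fdr_alpha = 0.01, score_orientation = "higher",
    features_path = NULL, label_element = "C",
    grid_step = NULL, min_correlation = 0.7,
    min_samples = 2L, min_peptides = 3L,
    reference_fasta = NULL, taxonomy_path = NULL,
    missed_cleavages = 2L, focal_taxon = NULL, dropoff_n_sample = 3500L,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config Named list (see \code{\link{defaultConfig}}).
#' @param stages Stages intended to run.
#' @return Character vector of violations (empty when runnable), each
#'   naming the offending key.
#' @export
validateConfig <- function(config,
                           stages = c("build_db", "validate", "quantify",
                                      "profile", "dropoff")) {
  v <- character(0)
  chk <- function(cond, msg) if (cond) v <<- c(v, msg)
  chk(!is.null(config$fdr_alpha) &&
        (config$fdr_alpha <= 0 || config$fdr_alpha > 1),
      "fdr_alpha: must lie in (0, 1]")
  chk(!is.null(config$score_threshold) && !is.finite(config$score_threshold) &&
        config$score_threshold != -Inf,
      "score_threshold: must be finite or -Inf")
  chk(!is.null(config$min_length) && !is.null(config$max_length) &&
        config$min_length > config$max_length,
      "min_length/max_length: min exceeds max")
  chk(!is.null(config$min_correlation) &&
        (config$min_correlation < -1 || config$min_correlation > 1),
      "min_correlation: must lie in [-1, 1]")
  chk(!is.null(config$label_element) &&
        !config$label_element %in% c("C", "H", "O"),
      "label_element: must be C, H or O")
  if ("build_db" %in% stages)
    chk(is.null(config$denovo_path), "denovo_path: required for build_db")
  if ("validate" %in% stages)
    chk(is.null(config$psm_path), "psm_path: required for validate")
  if ("quantify" %in% stages)
    chk(is.null(config$features_path), "features_path: required for quantify")
  if ("profile" %in% stages) {
    chk(is.null(config$reference_fasta),
        "reference_fasta: required for profile")
    chk(is.null(config$taxonomy_path), "taxonomy_path: required for profile")
  }
  if ("dropoff" %in% stages)
    chk(is.null(config$focal_taxon), "focal_taxon: required for dropoff")
  v
}

.writeTsv <- function(d, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(paste0("# ", names(params), "=",
                      vapply(params, function(p)
                        paste(format(p), collapse = ","), character(1))),
               con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.readTsv <- function(path) read.delim(path, comment.char = "#",
                                      stringsAsFactors = FALSE)

#' Run the workflow end-to-end
#'
#' Executes build_db, validate, quantify, profile and dropoff in order, writing each
#' stage's TSV outputs plus a JSON manifest (parameters, input digests,
#' completed stages) into \code{runDir}. A rerun with identical config and
#' inputs skips stages whose outputs are already up to date.
#'
#' @param config Named list (see \code{\link{defaultConfig}} /
#'   \code{\link{validateConfig}}).
#' @param runDir Output directory (created if needed).
#' @param stages Stages to run, in pipeline order.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, runDir,
                        stages = c("build_db", "validate", "quantify",
                                   "profile", "dropoff")) {
  violations <- validateConfig(config, stages)
  if (length(violations))
    stop("invalid config:\n  ", paste(violations, collapse = "\n  "))
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(runDir, "manifest.json")
  digest <- function(path) if (!is.null(path) && file.exists(path))
    unname(tools::md5sum(path)) else NA_character_
  manifest <- list(package = "pepSIP",
                   version = as.character(utils::packageVersion("pepSIP")),
                   config = config,
                   inputs = list(denovo = digest(config$denovo_path),
                                 psms = digest(config$psm_path),
                                 features = digest(config$features_path),
                                 reference = digest(config$reference_fasta),
                                 taxonomy = digest(config$taxonomy_path)),
                   stages = list())
  prev <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else NULL
  upToDate <- function(stage, outputs) {
    !is.null(prev) && stage %in% names(prev$stages) &&
      identical(prev$inputs, lapply(manifest$inputs, identity)[names(prev$inputs)]) &&
      all(file.exists(file.path(runDir, outputs)))
  }
  runStage <- function(stage, outputs, fn) {
    if (upToDate(stage, outputs)) {
      message("stage ", stage, ": up to date, skipped")
      manifest$stages[[stage]] <<- prev$stages[[stage]]
      return(invisible())
    }
    message("stage ", stage, ": running")
    counts <- tryCatch(fn(), error = function(e)
      stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[stage]] <<- list(outputs = outputs, counts = counts,
                                      completed = TRUE)
    invisible()
  }

  if ("build_db" %in% stages) runStage("build_db", "database.fasta", function() {
    rec <- parseDenovo(config$denovo_path, config$denovo_dialect)
    filt <- filterByScore(rec, config$score_threshold)
    db <- assembleDatabase(filt, c(config$min_length, config$max_length),
                           threshold = config$score_threshold)
    writePeptideFasta(db, file.path(runDir, "database.fasta"))
    list(records_in = nrow(rec), records_filtered = nrow(filt),
         peptides_out = length(db))
  })

  if ("validate" %in% stages) runStage("validate", "psms_filtered.tsv", function() {
    psms <- .readTsv(config$psm_path)
    if (!"isDecoy" %in% names(psms)) {
      db <- readPeptideFasta(file.path(runDir, "database.fasta"))
      ddb <- generateDecoys(db, seed = config$seed)
      decoySet <- peptides(ddb)[provenance(ddb)$kind == "decoy"]
      psms$isDecoy <- psms$peptide %in% decoySet
    }
    scored <- computeFdr(psms, config$score_orientation)
    kept <- filterFdr(scored, config$fdr_alpha)
    kept <- minSampleFilter(kept, minSamples = config$min_samples)
    .writeTsv(kept, file.path(runDir, "psms_filtered.tsv"),
              params = list(fdr_alpha = config$fdr_alpha,
                            min_samples = config$min_samples))
    list(psms_in = nrow(psms), psms_kept = nrow(kept))
  })

  if ("quantify" %in% stages) runStage("quantify",
                                       c("weights.tsv", "peptides.tsv"),
                                       function() {
    feats <- .readTsv(config$features_path)
    el <- config$label_element
    step <- if (is.null(config$grid_step)) isotopeDefaults(el)$gridStep else
      config$grid_step
    res <- quantifyFeatures(feats, el, gridStep = step,
                            minCorrelation = config$min_correlation)
    .writeTsv(res, file.path(runDir, "weights.tsv"),
              params = list(label_element = el, grid_step = step,
                            min_correlation = config$min_correlation,
                            merge_window = isotopeDefaults(el)$mergeWindow))
    summ <- summarizePeptides(res, el, minSamples = config$min_samples)
    .writeTsv(summ, file.path(runDir, "peptides.tsv"),
              params = list(min_samples = config$min_samples))
    list(features_in = nrow(feats),
         features_assigned = sum(!is.na(res$ria[!duplicated(
           paste(res$peptide, res$sample))])),
         peptides_out = nrow(summ), peptides_labeled = sum(summ$labeled))
  })

  if ("profile" %in% stages) runStage("profile",
                                      c("assignments.tsv", "taxa_species.tsv"),
                                      function() {
    tree <- readTaxonomy(config$taxonomy_path)
    ref <- Biostrings::readAAStringSet(config$reference_fasta)
    taxonIds <- sub(".*taxon=([^ ]+).*", "\\1", names(ref))
    index <- buildPeptideIndex(ref, taxonIds, tree = tree,
                               params = digestionParams(
                                 missedCleavages = config$missed_cleavages))
    summ <- .readTsv(file.path(runDir, "peptides.tsv"))
    asg <- do.call(rbind, lapply(seq_len(nrow(summ)), function(i) {
      a <- assignPeptide(summ$peptide[i], index, tree)
      data.frame(peptide = summ$peptide[i], taxon = a$taxon,
                 ria = summ$ria[i], labeled = summ$labeled[i],
                 nSamples = summ$nSamples[i], stringsAsFactors = FALSE)
    }))
    .writeTsv(asg, file.path(runDir, "assignments.tsv"))
    ok <- asg[!is.na(asg$taxon) & !is.na(asg$ria), , drop = FALSE]
    tab <- summarizeTaxa(ok, tree, "species")
    .writeTsv(tab, file.path(runDir, "taxa_species.tsv"),
              params = list(rank = "species",
                            min_peptides = config$min_peptides,
                            min_samples = config$min_samples))
    list(peptides_in = nrow(summ), assigned = sum(!is.na(asg$taxon)),
         species_reported = nrow(tab))
  })

  if ("dropoff" %in% stages) runStage("dropoff", "dropoff.tsv", function() {
    tree <- readTaxonomy(config$taxonomy_path)
    ref <- Biostrings::readAAStringSet(config$reference_fasta)
    taxonIds <- sub(".*taxon=([^ ]+).*", "\\1", names(ref))
    index <- buildPeptideIndex(ref, taxonIds, tree = tree,
                               params = digestionParams(
                                 missedCleavages = 0L,
                                 lengthBounds = c(7L, 15L)))
    focal <- config$focal_taxon
    proteome <- setNames(as.character(ref), names(ref))
    focalProt <- proteome[taxonIds == focal]
    theo <- theoreticalDropoff(focalProt, index = index, tree = tree,
                               focalTaxon = focal,
                               nSample = config$dropoff_n_sample,
                               seed = config$seed)
    asg <- .readTsv(file.path(runDir, "assignments.tsv"))
    lab <- asg[!is.na(asg$labeled) & asg$labeled, , drop = FALSE]
    obs <- observedDropoff(lab, tree, focal)
    cmpd <- compareDropoff(theo, obs)
    .writeTsv(cmpd$perRank, file.path(runDir, "dropoff.tsv"),
              params = list(focal_taxon = focal,
                            n_sample = config$dropoff_n_sample,
                            max_deviation = cmpd$maxDeviation))
    list(labeled_peptides = nrow(lab),
         max_deviation = cmpd$maxDeviation)
  })

  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(manifest)
}
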