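# End-to-end workflow: simulate a train/test benchmark, detect and
# featurise overlaps, train on the labelled training side, classify the
# test side, filter, assemble corrected and uncorrected, and evaluate.

#' Standard benchmark configuration
#'
#' The default desk-scale study conditions: a 200 kb genome carrying a
#' 1.5 kb x 6-copy repeat family at 1% divergence and a 400 bp x 10-copy
#' exact family, 10x coverage of 400 +/- 40 bp reads with 1% substitution
#' and 0.3% indel errors, and a two-genome related panel at 8% and 9%
#' divergence (roughly 92% and 91% identity).
#'
#' @param seed Integer seed.
#' @return A [simConfig()] object.
#' @export
standardBenchmarkConfig <- function(seed = 1L) {
  cfg <- simConfig(
    genome_length = 200000L,
    repeat_specs = data.frame(unit_length = c(1500L, 400L),
                              copy_number = c(6L, 10L),
                              divergence = c(0.01, 0)),
    related_divergence = c(0.08, 0.09),
    coverage = 10,
    read_length_mean = 400,
    read_length_sd = 40,
    substitution_rate = 0.01,
    indel_rate = 0.003,
    seed = seed)
  cfg
}

make_dataset <- function(config, prefix) {
  sim <- simulateGenome(config)
  rd <- simulateReads(sim$genome, config, prefix = prefix)
  panel <- NULL
  if (length(config$related_divergence)) {
    panel <- lapply(seq_along(config$related_divergence), function(i) {
      deriveRelatedGenome(sim$genome, config$related_divergence[i],
                          seed = child_seed(config$seed, 10L + i),
                          name = sprintf("%s_panel%d", names(sim$genome), i))
    })
  }
  list(genome = sim$genome, repeats = sim$repeats, reads = rd$reads,
       placements = rd$placements, panel = panel)
}

#' Generate a matched train/test benchmark
#'
#' Two independently simulated genomes (sharing no sequence) under the
#' same configuration, each with reads, true placements and a related-
#' genome panel, mirroring a train-on-one-organism, assemble-another
#' design.
#'
#' @param seed Integer seed.
#' @param config Base configuration from [standardBenchmarkConfig()] (its
#'   seed is overridden by `seed`).
#' @param dir Optional directory; when given, FASTA/TSV files for both
#'   datasets are written there.
#' @return A list with `train` and `test` datasets, each holding `genome,
#'   repeats, reads, placements, panel`.
#' @export
makeBenchmark <- function(seed = 1L, config = standardBenchmarkConfig(),
                          dir = NULL) {
  cfg_train <- config
  cfg_train$seed <- as.integer(child_seed(seed, 101L))
  cfg_test <- config
  cfg_test$seed <- as.integer(child_seed(seed, 202L))
  train <- make_dataset(cfg_train, prefix = "trn")
  test <- make_dataset(cfg_test, prefix = "tst")
  out <- list(train = train, test = test, seed = as.integer(seed))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (side in c("train", "test")) {
      ds <- out[[side]]
      writeFasta(ds$genome, file.path(dir, paste0(side, "_genome.fa")))
      writeFasta(ds$reads, file.path(dir, paste0(side, "_reads.fa")))
      writePlacements(ds$placements,
                      file.path(dir, paste0(side, "_placements.tsv")))
      for (i in seq_along(ds$panel))
        writeFasta(ds$panel[[i]],
                   file.path(dir, sprintf("%s_panel%d.fa", side, i)))
    }
  }
  out
}

#' Full overlap feature table for one dataset
#'
#' Detects candidate overlaps (unless supplied) and binds the requested
#' feature families; with ground-truth placements, labels are attached.
#'
#' @param reads Named DNAStringSet.
#' @param featureFamilies Subset of `c("noncomparative", "comparative")`.
#' @param panel Related-genome panel (list of length-1 DNAStringSets);
#'   required for the comparative family.
#' @param placements Optional named GRanges of true placements; adds a
#'   `label` column.
#' @param candidates Optional precomputed overlap table.
#' @param k Feature k-mer size (default 16).
#' @param coverage Expected coverage for k-mer normalisation (estimated
#'   from the reads when `NULL`).
#' @param minOverlap,maxError Overlapper thresholds.
#' @param tolerance Comparative combination tolerance (bp).
#' @return A list with `candidates` and `features` (data.frame).
#' @export
overlapFeatureTable <- function(reads, featureFamilies = c("noncomparative",
                                                           "comparative"),
                                panel = NULL, placements = NULL,
                                candidates = NULL, k = 16L, coverage = NULL,
                                minOverlap = 30L, maxError = 0.06,
                                tolerance = 30L) {
  featureFamilies <- match.arg(featureFamilies,
                               c("noncomparative", "comparative"),
                               several.ok = TRUE)
  if ("comparative" %in% featureFamilies && is.null(panel))
    stop("comparative features need a genome panel", call. = FALSE)
  if (is.null(candidates))
    candidates <- findOverlapCandidates(reads, minOverlap = minOverlap,
                                        maxError = maxError)
  feats <- candidates[c("readA", "readB", "orientation")]
  if ("noncomparative" %in% featureFamilies) {
    model <- buildKmerModel(reads, k = k, expectedCoverage = coverage)
    nc <- noncompFeatures(candidates, reads, model)
    feats <- cbind(feats, nc[setdiff(names(nc), names(feats))])
    feats$n_kmers <- NULL
  }
  if ("comparative" %in% featureFamilies) {
    ce <- comparativeEvidence(candidates, reads, panel,
                              tolerance = tolerance)
    feats$comp_score <- ce$comp_score
  }
  if (!is.null(placements)) {
    lab <- labelOverlaps(candidates, placements, minTrueOverlap = minOverlap)
    feats$label <- lab$label
  }
  list(candidates = candidates, features = feats)
}

#' Run the overlap-correction pipeline on a benchmark
#'
#' Trains a classifier on the labelled training dataset, classifies the
#' test dataset's overlaps, removes the predicted-false ones, assembles
#' both the corrected and the uncorrected (control) overlap sets and
#' evaluates them against the test genome.  Classification metrics on the
#' test side use its ground-truth labels.
#'
#' @param benchmark A benchmark from [makeBenchmark()].
#' @param algorithm Classifier algorithm (see [trainClassifier()]).  The
#'   default random forest gives the lowest false-negative and
#'   false-positive rates on the standard benchmark and therefore the
#'   cleanest filtered overlap set; `"decision_tree"` reproduces the
#'   classical C4.5-style setup.
#' @param featureFamilies Feature arms: `"noncomparative"`,
#'   `"comparative"` or both.
#' @param seed Integer training seed.
#' @param coverage Expected coverage for k-mer normalisation (the
#'   configured coverage of the benchmark, if known).
#' @param verbose Log stage progress via `message()`.
#' @return A list with `metrics` (occMetrics), `corrected` and
#'   `uncorrected` ([AssemblyReport-class]), `model`, `train` and `test`
#'   feature tables.
#' @export
runPipeline <- function(benchmark, algorithm = "random_forest",
                        featureFamilies = c("noncomparative", "comparative"),
                        seed = 1L, coverage = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(what) say("[%s] %.1fs elapsed", what,
                              as.numeric(Sys.time() - t0, units = "secs"))
  tr <- benchmark$train
  te <- benchmark$test
  say("pipeline: %d training reads, %d test reads, features: %s",
      length(tr$reads), length(te$reads),
      paste(featureFamilies, collapse = "+"))
  trainTab <- overlapFeatureTable(tr$reads, featureFamilies, tr$panel,
                                  tr$placements, coverage = coverage)
  stage(sprintf("train features: %d candidates", nrow(trainTab$features)))
  testTab <- overlapFeatureTable(te$reads, featureFamilies, te$panel,
                                 te$placements, coverage = coverage)
  stage(sprintf("test features: %d candidates", nrow(testTab$features)))
  model <- trainClassifier(trainTab$features, algorithm = algorithm,
                           seed = seed)
  pred <- predictLabels(model, testTab$features[setdiff(
    names(testTab$features), "label")])
  metrics <- evaluateClassification(pred, testTab$features$label)
  stage(sprintf("classified: accuracy %.4f", metrics$accuracy))
  retained <- filterOverlaps(testTab$candidates, pred)
  say("retained %d of %d test candidates", nrow(retained),
      nrow(testTab$candidates))
  uncorrected <- evaluateAssembly(te$reads, testTab$candidates, te$genome)
  stage(sprintf("uncorrected assembly: N50 %.0f, %.2f%% matched",
                uncorrected@n50, uncorrected@pctMatched))
  corrected <- evaluateAssembly(te$reads, retained, te$genome)
  stage(sprintf("corrected assembly: N50 %.0f, %.2f%% matched",
                corrected@n50, corrected@pctMatched))
  list(metrics = metrics, corrected = corrected, uncorrected = uncorrected,
       model = model, train = trainTab, test = testTab,
       predictions = pred)
}
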