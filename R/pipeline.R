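#' End-to-end pipeline with manifest-based provenance
#'
#' Orchestrates simulate -> dataset -> train -> call -> link ->
#' characterize from one configuration. Every stage writes its outputs
#' under `outdir` and appends a manifest entry (parameters and md5
#' checksums of outputs), so a finished run is a pure function of
#' (config, inputs, seed) and re-running with the same config is a no-op
#' unless forced.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param outdir Output directory.
#' @param synthetic A [synthetic_config()] (the pipeline starts from the
#'   generator; point `dataset_dir` at an existing dataset to skip it).
#' @param induction An [induction_config()].
#' @param calling A [calling_config()].
#' @param train_n Bins sampled for training ([sample_training_set()]).
#' @param test_fraction Held-out fraction of the sample.
#' @param proximal_distance Promoter-proximity cutoff (bp).
#' @param ratio_threshold Contact enrichment cutoff.
#' @param expression_threshold FPKM above which a gene counts as expressed.
#' @param seed Master seed propagated to every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            synthetic = synthetic_config(),
                            induction = induction_config(),
                            calling = calling_config(),
                            train_n = 2e5, test_fraction = 0.3,
                            proximal_distance = 5000,
                            ratio_threshold = 2,
                            expression_threshold = 1,
                            seed = 1) {
  synthetic$seed <- .derive_seed(seed, 1L)
  induction$seed <- .derive_seed(seed, 2L)
  structure(list(outdir = outdir, synthetic = synthetic,
                 induction = induction, calling = calling,
                 train_n = train_n, test_fraction = test_fraction,
                 proximal_distance = proximal_distance,
                 ratio_threshold = ratio_threshold,
                 expression_threshold = expression_threshold, seed = seed),
            class = "pipeline_config")
}

.manifest_path <- function(outdir) file.path(outdir, "manifest.json")

.read_manifest <- function(outdir) {
  mp <- .manifest_path(outdir)
  if (file.exists(mp)) jsonlite::read_json(mp, simplifyVector = TRUE)
  else list()
}

.record_stage <- function(outdir, stage, params, outputs) {
  manifest <- .read_manifest(outdir)
  sums <- tools::md5sum(outputs[file.exists(outputs)])
  manifest[[stage]] <- list(params = params,
                            outputs = as.list(sums))
  jsonlite::write_json(manifest, .manifest_path(outdir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

.stage_done <- function(outdir, stage, outputs) {
  manifest <- .read_manifest(outdir)
  if (is.null(manifest[[stage]])) return(FALSE)
  all(file.exists(outputs))
}

#' Run the pipeline
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of
#'   `c("simulate", "dataset", "train", "call", "link", "characterize")`;
#'   stages always run in dependency order. A requested stage whose inputs
#'   are missing is an error naming the stage to run first.
#' @param force Re-run stages whose outputs already exist.
#' @return The manifest (invisibly).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "dataset", "train", "call",
                                    "link", "characterize"),
                         force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "dataset", "train", "call", "link",
                  "characterize")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sim_dir <- file.path(outdir, "simulated")
  ds_dir <- file.path(outdir, "dataset")
  model_path <- file.path(outdir, "model.json")
  report_path <- file.path(outdir, "report.tsv")
  calls_path <- file.path(outdir, "calls.bed")
  linkage_path <- file.path(outdir, "linkage.tsv")
  char_dir <- file.path(outdir, "characterization")

  need <- function(path, stage) {
    if (!all(file.exists(path)))
      .stopf("missing %s; run stage '%s' first", paste(path, collapse = ", "),
             stage)
  }

  if ("simulate" %in% stages) {
    outs <- file.path(sim_dir, c("chrom.sizes", "true_enhancers.bed",
                                 "annotation.gff3", "contacts.tsv",
                                 "expression.tsv", "ground_truth.json"))
    if (force || !.stage_done(outdir, "simulate", outs)) {
      sim <- simulate_enhancer_genome(config$synthetic)
      write_synthetic_data(sim, sim_dir)
      .record_stage(outdir, "simulate",
                    list(seed = config$synthetic$seed),
                    list.files(sim_dir, full.names = TRUE))
    }
  }

  if ("dataset" %in% stages) {
    need(file.path(sim_dir, "chrom.sizes"), "simulate")
    outs <- file.path(ds_dir, c("dataset.tsv", "dataset.json"))
    if (force || !.stage_done(outdir, "dataset", outs)) {
      sizes <- read_chrom_sizes(file.path(sim_dir, "chrom.sizes"))
      marks <- .default_mark_names(config$synthetic$n_marks)
      track_files <- setNames(
        file.path(sim_dir, paste0(marks, ".bedGraph")), marks)
      bins <- tile_genome(sizes, width = config$synthetic$bin_width)
      tracks <- lapply(names(track_files), function(mk) {
        rec <- read_signal_track(track_files[[mk]])
        minmax_normalize(map_signal_to_bins(rec, bins, mark = mk))
      })
      names(tracks) <- names(track_files)
      peaks <- read_peaks(file.path(sim_dir, "true_enhancers.bed"))
      regions <- expand_peaks(peaks, target_width = 400, chrom_sizes = sizes)
      dataset <- bin_dataset(bins, tracks, label_bins(bins, regions))
      write_bin_dataset(dataset, ds_dir)
      .record_stage(outdir, "dataset", list(bin_width = bins$width),
                    outs)
    }
  }

  if ("train" %in% stages) {
    need(file.path(ds_dir, "dataset.tsv"), "dataset")
    outs <- c(model_path, report_path)
    if (force || !.stage_done(outdir, "train", outs)) {
      dataset <- read_bin_dataset(ds_dir)
      split <- sample_training_set(dataset, n = config$train_n,
                                   test_fraction = config$test_fraction,
                                   seed = .derive_seed(config$seed, 3L))
      rb <- induce_rulebase(split$train, config$induction)
      ev <- evaluate_rulebase(rb, split$test)
      write_rulebase(rb, model_path,
                     txt_path = file.path(outdir, "rules.txt"))
      rep_df <- data.frame(metric = names(ev$report),
                           value = unlist(ev$report))
      write.table(rep_df, report_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      .record_stage(outdir, "train", list(seed = config$induction$seed), outs)
    }
  }

  if ("call" %in% stages) {
    need(model_path, "train")
    need(file.path(ds_dir, "dataset.tsv"), "dataset")
    if (force || !.stage_done(outdir, "call", calls_path)) {
      dataset <- read_bin_dataset(ds_dir)
      rb <- read_rulebase(model_path)
      reference <- read_peaks(file.path(sim_dir, "true_enhancers.bed"))
      calls <- call_enhancers(rb, dataset, config$calling,
                              reference = reference)
      write_calls(calls, calls_path)
      .record_stage(outdir, "call",
                    list(threshold = config$calling$threshold,
                         merge_gap = config$calling$merge_gap), calls_path)
    }
  }

  if ("link" %in% stages) {
    need(calls_path, "call")
    if (force || !.stage_done(outdir, "link", linkage_path)) {
      sizes <- read_chrom_sizes(file.path(sim_dir, "chrom.sizes"))
      calls <- read_peaks(calls_path)
      ann <- read_annotation(file.path(sim_dir, "annotation.gff3"))
      genes <- ann[ann$type == "gene"]
      promoters <- promoter_intervals(genes, sizes)
      contacts <- flag_enriched_contacts(
        read_contacts(file.path(sim_dir, "contacts.tsv")),
        config$ratio_threshold)
      fpkm <- read_fpkm(file.path(sim_dir, "expression.tsv"))
      linkage <- link_enhancers_to_promoters(
        calls, promoters, contacts, config$proximal_distance)
      linkage <- linked_expression(linkage, fpkm,
                                   config$expression_threshold)
      write_linkage(linkage, linkage_path)
      .record_stage(outdir, "link",
                    list(proximal_distance = config$proximal_distance),
                    linkage_path)
    }
  }

  if ("characterize" %in% stages) {
    need(calls_path, "call")
    need(file.path(ds_dir, "dataset.tsv"), "dataset")
    outs <- file.path(char_dir, c("directionality.tsv",
                                  "signal_enrichment.tsv",
                                  "feature_enrichment.tsv"))
    if (force || !.stage_done(outdir, "characterize", outs)) {
      dir.create(char_dir, showWarnings = FALSE, recursive = TRUE)
      sizes <- read_chrom_sizes(file.path(sim_dir, "chrom.sizes"))
      dataset <- read_bin_dataset(ds_dir)
      calls <- read_peaks(calls_path)
      plus <- map_signal_to_bins(
        read_signal_track(file.path(sim_dir, "nascent_plus.bedGraph")),
        dataset$bins, mark = "plus")$values
      minus <- map_signal_to_bins(
        read_signal_track(file.path(sim_dir, "nascent_minus.bedGraph")),
        dataset$bins, mark = "minus")$values
      dir_df <- directionality_score(plus, minus, dataset$bins, calls)
      write.table(dir_df, file.path(char_dir, "directionality.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      enr <- do.call(rbind, lapply(dataset$feature_order, function(mk) {
        e <- obs_exp_signal_enrichment(dataset$features[, mk], calls,
                                       dataset$bins)
        data.frame(mark = mk, observed = e$observed, expected = e$expected,
                   log2_ratio = e$log2_ratio)
      }))
      write.table(enr, file.path(char_dir, "signal_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ann <- read_annotation(file.path(sim_dir, "annotation.gff3"))
      cats <- annotation_categories(ann, sizes)
      fe <- feature_overlap_enrichment(calls, cats, sizes)
      write.table(fe, file.path(char_dir, "feature_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      .record_stage(outdir, "characterize", list(), outs)
    }
  }

  invisible(.read_manifest(outdir))
}
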