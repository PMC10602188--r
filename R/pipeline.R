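# End-to-end orchestration: generate (or load) a raw variant table, curate
# it into the strict and extended datasets, annotate substitutions, run the
# threshold-calibrated evaluation (per-predictor and ensemble AUC, optimal
# cutoffs, balanced resampling, stratified tables), fit the two-feature
# classifiers, and drive a saturation scan. Every stage writes its artifact
# into the run directory so any number in a report can be recomputed from
# the intermediate files; a manifest records the configuration, seed and
# package version. Outputs contain no timestamps, so two runs with the same
# configuration and seed are byte-identical.

#' Pipeline run configuration
#'
#' @param generator A [generator_config()] for the all-synthetic mode.
#' @param raw_table Optional path to a raw variant TSV; when given it is
#'   curated instead of generating one.
#' @param stages Character subset of
#'   `c("curate", "evaluate", "classify", "saturate")`.
#' @param predictors ddG predictor column names.
#' @param ensembles Named list of predictor-column vectors to average.
#' @param cutoffs `"optimize"` (MCC-optimal per score) or a named numeric
#'   vector of fixed thresholds.
#' @param rsa_cutoff Fixed RSA threshold used when `cutoffs` is numeric;
#'   with `"optimize"` the RSA cutoff is calibrated too.
#' @param resampling_repeats Balanced resampling repeats, default 100.
#' @param min_group Strict group-size threshold for stratified AUC tables.
#' @param protocol A [split_protocol()] for the classifier stage.
#' @param classifier_datasets Which curated datasets to fit classifiers on.
#' @param saturation List with n_proteins, min_len, max_len, cutoff for the
#'   scan.
#' @param seed Run seed; overrides `generator$seed`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       raw_table = NULL,
                       stages = c("curate", "evaluate", "classify", "saturate"),
                       predictors = c("ddg_p1", "ddg_p2", "ddg_p3"),
                       ensembles = list(avg_p1_p2 = c("ddg_p1", "ddg_p2"),
                                        avg_p1_p3 = c("ddg_p1", "ddg_p3"),
                                        avg_all = c("ddg_p1", "ddg_p2", "ddg_p3")),
                       cutoffs = "optimize",
                       rsa_cutoff = 0.35,
                       resampling_repeats = 100,
                       min_group = 100,
                       protocol = split_protocol(),
                       classifier_datasets = "dataset1",
                       saturation = list(n_proteins = 5, min_len = 80, max_len = 200,
                                         cutoff = -1.1),
                       seed = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(seed)) {
    generator$seed <- as.integer(seed)
    protocol$seed <- as.integer(seed)
  }
  structure(list(generator = generator, raw_table = raw_table, stages = stages,
                 predictors = predictors, ensembles = ensembles,
                 cutoffs = cutoffs, rsa_cutoff = rsa_cutoff,
                 resampling_repeats = resampling_repeats,
                 min_group = min_group, protocol = protocol,
                 classifier_datasets = classifier_datasets,
                 saturation = saturation, seed = generator$seed),
            class = "run_config")
}

.score_columns <- function(data, config) {
  scores <- list()
  for (p in config$predictors) scores[[p]] <- data[[p]]
  for (nm in names(config$ensembles)) {
    scores[[nm]] <- ensemble_ddg(data, config$ensembles[[nm]])
  }
  scores$rsa <- data$rsa
  scores
}

.evaluate_dataset <- function(data, config) {
  miss <- setdiff(c(config$predictors, "rsa", "label"), names(data))
  if (length(miss)) {
    stop(sprintf("evaluation input lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  scores <- .score_columns(data, config)
  labels <- data$label
  per_score <- list()
  for (nm in names(scores)) {
    s <- scores[[nm]]
    if (identical(config$cutoffs, "optimize")) {
      opt <- optimal_threshold(s, labels, "pathogenic_if_le")
    } else {
      fixed <- if (nm == "rsa") config$rsa_cutoff else config$cutoffs[[nm]]
      if (is.null(fixed) || is.na(fixed)) {
        stop(sprintf("no fixed cutoff supplied for score '%s'", nm), call. = FALSE)
      }
      opt <- list(threshold = fixed,
                  mcc = mcc(confusion_counts(s, labels, fixed, "pathogenic_if_le")))
    }
    res <- balanced_resample_evaluate(as.integer(s <= opt$threshold), labels,
                                      n_repeats = config$resampling_repeats,
                                      seed = config$seed + 31L)
    per_score[[nm]] <- list(
      auc = auc_concordance(s, labels),
      cutoff = opt$threshold,
      mcc_at_cutoff = opt$mcc,
      resampling = list(n_repeats = attr(res, "n_repeats"),
                        n_per_class = attr(res, "n_per_class"),
                        mean = as.list(setNames(res$mean, res$metric)),
                        sd = as.list(setNames(res$sd, res$metric))))
  }
  strat <- list()
  strat_score <- names(config$ensembles)[1] %||% config$predictors[1]
  s <- scores[[strat_score]]
  tmp <- data
  tmp$.score <- s
  for (axis in c("cat_hydropathy", "cat_size", "cat_aromatic", "cat_charge",
                 "functional_class")) {
    if (!axis %in% names(tmp)) next
    strat[[axis]] <- stratified_auc(tmp, axis, ".score",
                                    min_count = config$min_group)
  }
  list(n = nrow(data), n_benign = sum(labels == 0), n_pathogenic = sum(labels == 1),
       stratified_score = strat_score, scores = per_score, stratified = strat)
}

.classifier_report <- function(data, config) {
  specs <- c(as.list(setNames(config$predictors, config$predictors)),
             config$ensembles)
  rows <- list()
  for (nm in names(specs)) {
    fit <- fit_pathogenicity(data, ddg = specs[[nm]], rsa = TRUE,
                             protocol = config$protocol)
    m <- fit$metrics
    rows[[nm]] <- list(features = paste(c(unlist(specs[[nm]]), "rsa"), collapse = "+"),
                       c = fit$c,
                       train_auc = m$auc[m$portion == "train"],
                       train_mcc = m$mcc[m$portion == "train"],
                       test_auc = m$auc[m$portion == "test"],
                       test_mcc = m$mcc[m$portion == "test"])
  }
  rows
}

#' Run the pipeline end to end
#'
#' @param config A [run_config()] (or path handled by [read_run_config()]).
#' @param out_dir Run directory; created if needed.
#' @return Invisibly, a list with the in-memory artifacts (curation result,
#'   evaluation and classifier reports, saturation summary, file paths).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  artifacts <- list()

  raw <- if (!is.null(config$raw_table)) read_variant_table(config$raw_table)
  else generate_raw_variants(config$generator)
  write_variant_table(raw, pth("raw_variants.tsv"))
  message(sprintf("[synth] %d raw variant records", nrow(raw)))

  if ("curate" %in% config$stages) {
    cur <- build_datasets(raw)
    artifacts$curation <- cur
    ann1 <- annotate_variants(cur$dataset1)
    ann2 <- annotate_variants(cur$dataset2)
    write_variant_table(ann1, pth("dataset1_annotated.tsv"))
    write_variant_table(ann2, pth("dataset2_annotated.tsv"))
    .write_json(cur$report[setdiff(names(cur$report), "per_gene")],
                pth("curation_report.json"))
    write_variant_table(cur$report$per_gene, pth("curation_per_gene.tsv"))
    message(sprintf("[curate] dataset1 %d rows, dataset2 %d rows",
                    nrow(ann1), nrow(ann2)))

    if ("evaluate" %in% config$stages) {
      ev <- list(dataset1 = .evaluate_dataset(ann1, config),
                 dataset2 = .evaluate_dataset(ann2, config))
      artifacts$evaluation <- ev
      .write_json(ev, pth("evaluation_report.json"))
      for (ds in names(ev)) {
        strat_score <- ev[[ds]]$stratified_score
        dat <- if (ds == "dataset1") ann1 else ann2
        rc <- roc_curve(ensemble_ddg(dat, config$ensembles[[strat_score]] %||%
                                       strat_score), dat$label)
        write_variant_table(rc$points, pth(sprintf("roc_%s_%s.tsv", ds, strat_score)))
      }
      message("[evaluate] evaluation report written")
    }

    if ("classify" %in% config$stages) {
      cls <- list()
      for (ds in config$classifier_datasets) {
        dat <- if (ds == "dataset1") ann1 else ann2
        cls[[ds]] <- .classifier_report(dat, config)
      }
      artifacts$classifier <- cls
      .write_json(cls, pth("classifier_report.json"))
      message("[classify] classifier report written")
    }
  }

  if ("saturate" %in% config$stages) {
    sat_cfg <- config$saturation
    seqs <- generate_sequences(config$generator, sat_cfg$n_proteins,
                               sat_cfg$min_len, sat_cfg$max_len)
    write_fasta(seqs, pth("sequences.fasta"))
    scan <- scan_fasta(seqs, scorer = synthetic_scorer(config$seed),
                       cutoff = sat_cfg$cutoff %||% -1.1,
                       out_tsv = pth("saturation_scan.tsv"), keep_tables = FALSE)
    artifacts$saturation <- scan$summary
    .write_json(scan$summary, pth("saturation_summary.json"))
    message(sprintf("[saturate] %d substitutions scored, %d flagged",
                    scan$summary$total_mutations, scan$summary$total_pathogenic))
  }

  manifest <- list(
    package = "stabvar",
    version = as.character(utils::packageVersion("stabvar")),
    seed = config$seed,
    stages = config$stages,
    generator = config$generator[setdiff(names(config$generator), "aa_bias")],
    aa_bias = as.list(config$generator$aa_bias),
    protocol = unclass(config$protocol),
    cutoffs = config$cutoffs,
    resampling_repeats = config$resampling_repeats)
  .write_json(manifest, pth("manifest.json"))
  artifacts$out_dir <- out_dir
  invisible(artifacts)
}
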