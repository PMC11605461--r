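#' Read and validate a run configuration
#'
#' A single JSON file with per-stage sections; unspecified values take the
#' study defaults (36-month lookback with the immediate month trimmed,
#' minimum 10 curated codes, 70/30 split, 600-pathway evaluation set,
#' fine-tuning batch 8 for 4 epochs, threshold grid 0.40-0.70, k = 6).
#' All randomness is routed through named seeds derived from the single
#' run seed, and every stage records its seeds in its manifest.
#'
#' @param path JSON file path, or a list to validate directly.
#' @return a `run_config` list.
#' @export
readRunConfig <- function(path) {
  user <- if (is.list(path)) path
          else jsonlite::read_json(path, simplifyVector = TRUE)
  def <- list(
    output_dir = "codepaths_run",
    seed = 1L,
    paths = list(),
    synth = list(n_patients = 2000L, case_fraction = 0.444,
                 signal_mode = "marginal_shift",
                 mean_pathway_length = 170, vocab_size = 450L),
    pathway = list(lookback_months = 36L, trim_months = 1L,
                   min_codes = 10L, max_len = 512L),
    cohort = list(train_fraction = 0.7, eval_size = 600L,
                  validation_sample_size = NULL, quotas = NULL),
    model = list(preset = "desk", dropout = 0, classifier_bias = TRUE),
    pretrain = list(batch_size = 2L, epochs = 2L, lr = 1e-3),
    finetune = list(batch_size = 8L, epochs = 4L, lr = 1e-3, restarts = 2L),
    evaluate = list(threshold = 0.4, n_boot = 200L,
                    thresholds = seq(0.40, 0.70, by = 0.05)),
    interpret = list(k = 6L, n_init = 10L, perplexity = 30))
  cfg <- utils::modifyList(def, user)
  if (cfg$pathway$trim_months >= cfg$pathway$lookback_months)
    stop("trim_months must be smaller than lookback_months")
  class(cfg) <- "run_config"
  cfg
}

stageFile <- function(cfg, ...) file.path(cfg$output_dir, ...)

requireArtifact <- function(cfg, file, producer) {
  p <- stageFile(cfg, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run stage '", producer, "' first")
  p
}

writeManifest <- function(cfg, stage, inputs, seeds) {
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  man <- list(
    stage = stage,
    config_hash = unname(tools::md5sum(tmp)),
    seeds = seeds,
    inputs = as.list(vapply(inputs, function(f)
      unname(tools::md5sum(stageFile(cfg, f))), character(1))),
    package_version = as.character(utils::packageVersion("codepaths")))
  unlink(tmp)
  jsonlite::write_json(man, stageFile(cfg, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

#' Run one pipeline stage
#'
#' Stages, in order: `synth` (or external input files), `curate`,
#' `pathways`, `cohort`, `pretrain`, `finetune`, `baseline`, `evaluate`,
#' `interpret`. Each stage reads the upstream artifacts from
#' `config$output_dir`, writes its own outputs there, and records a
#' manifest (config hash, seeds, input hashes, package version) enabling
#' an exact rerun. Running a stage before its inputs exist raises an
#' error naming the stage to run first.
#'
#' @param stage stage name.
#' @param config a `run_config` (see [readRunConfig()]).
#' @return the stage's main output, invisibly.
#' @export
runStage <- function(stage, config) {
  stage <- match.arg(stage, c("synth", "curate", "pathways", "cohort",
                              "pretrain", "finetune", "baseline",
                              "evaluate", "interpret"))
  cfg <- if (inherits(config, "run_config")) config else readRunConfig(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         synth = stageSynth(cfg), curate = stageCurate(cfg),
         pathways = stagePathways(cfg), cohort = stageCohort(cfg),
         pretrain = stagePretrain(cfg), finetune = stageFinetune(cfg),
         baseline = stageBaseline(cfg), evaluate = stageEvaluate(cfg),
         interpret = stageInterpret(cfg))
}

#' @rdname runStage
#' @param stages stage names to run in order (default: the full pipeline).
#' @export
runPipeline <- function(config, stages = c("synth", "curate", "pathways",
                                           "cohort", "pretrain", "finetune",
                                           "baseline", "evaluate",
                                           "interpret")) {
  for (s in stages) runStage(s, config)
  invisible(stages)
}

stageSynth <- function(cfg) {
  seed <- deriveSeed(cfg$seed, "synth")
  sc <- synthConfig(n_patients = cfg$synth$n_patients,
                    case_fraction = cfg$synth$case_fraction,
                    vocab_size = cfg$synth$vocab_size,
                    mean_pathway_length = cfg$synth$mean_pathway_length,
                    signal_mode = cfg$synth$signal_mode, seed = seed)
  coh <- generateCohort(sc)
  writePatients(coh$patients, stageFile(cfg, "patients.csv"))
  writeEvents(coh$events, stageFile(cfg, "events.csv"))
  writeCodeMap(coh$code_map, stageFile(cfg, "codemap.csv"))
  for (nm in names(coh$code_lists))
    writeCodeList(coh$code_lists[[nm]], stageFile(cfg, paste0(nm, "_codes.txt")))
  utils::write.csv(coh$truth, stageFile(cfg, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  writeManifest(cfg, "synth", character(0), list(synth = seed))
  invisible(coh)
}

# resolve an input either from cfg$paths or from the synth stage outputs
resolveInput <- function(cfg, key, file, producer = "synth") {
  p <- cfg$paths[[key]]
  if (!is.null(p)) { if (!file.exists(p)) stop("file not found: ", p); return(p) }
  requireArtifact(cfg, file, producer)
}

readLists <- function(cfg) {
  list(lung = readCodeList(resolveInput(cfg, "lung_codes", "lung_codes.txt")),
       other_cancer = readCodeList(
         resolveInput(cfg, "other_cancer_codes", "other_cancer_codes.txt")),
       respiratory = readCodeList(
         resolveInput(cfg, "respiratory_codes", "respiratory_codes.txt")),
       diagnostic = readCodeList(
         resolveInput(cfg, "diagnostic_codes", "diagnostic_codes.txt")))
}

stageCurate <- function(cfg) {
  events <- readEvents(resolveInput(cfg, "events", "events.csv"))
  cm <- loadCodeMap(resolveInput(cfg, "codemap", "codemap.csv"), quiet = TRUE)
  cur <- curateEvents(events, cm)
  utils::write.csv(data.frame(patient_id = cur$patient_id,
                              event_date = format(cur$event_date),
                              group_id = cur$group_id),
                   stageFile(cfg, "curated_events.csv"),
                   row.names = FALSE, quote = FALSE)
  writeManifest(cfg, "curate", character(0), list())
  invisible(cur)
}

readCurated <- function(cfg) {
  p <- requireArtifact(cfg, "curated_events.csv", "curate")
  df <- utils::read.csv(p, colClasses = "character")
  df$event_date <- as.Date(df$event_date)
  df
}

stagePathways <- function(cfg) {
  cur <- readCurated(cfg)
  lists <- readLists(cfg)
  pw <- cfg$pathway
  mk <- function(append) {
    p <- buildPathways(cur, lists$lung, lists$other_cancer,
                       lists$respiratory, diagnostic_codes = lists$diagnostic,
                       lookback_months = pw$lookback_months,
                       trim_months = pw$trim_months,
                       append_index_code = append)
    filterMinCodes(p, pw$min_codes)
  }
  pretrain_pw <- mk(TRUE)   # keeps the endpoint diagnostic code
  model_pw <- stripLabelCodes(mk(FALSE), lists$lung, lists$other_cancer)
  vocab <- buildVocabulary(groupIds(loadCodeMap(
    resolveInput(cfg, "codemap", "codemap.csv"), quiet = TRUE)))
  saveRDS(list(pretrain = pretrain_pw, model = model_pw, vocab = vocab),
          stageFile(cfg, "pathways.rds"))
  writeManifest(cfg, "pathways", "curated_events.csv",
                list())
  invisible(model_pw)
}

stageCohort <- function(cfg) {
  pw <- readRDS(requireArtifact(cfg, "pathways.rds", "pathways"))
  seed <- deriveSeed(cfg$seed, "cohort")
  ids <- pathwayInfo(pw$model)$patient_id
  split <- splitPopulation(ids, cfg$cohort$train_fraction, seed = seed,
                           eval_size = cfg$cohort$eval_size,
                           validation_sample_size =
                             cfg$cohort$validation_sample_size)
  train_pw <- pw$model[which(ids %in% split$training)]
  if (!is.null(cfg$cohort$quotas)) {
    cc <- buildCaseControl(train_pw, unlist(cfg$cohort$quotas), seed = seed)
    split$case_control <- pathwayInfo(cc$pathways)$patient_id
    utils::write.csv(cc$composition, stageFile(cfg, "composition.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    split$case_control <- pathwayInfo(train_pw)$patient_id
  }
  jsonlite::write_json(split, stageFile(cfg, "cohort.json"),
                       auto_unbox = FALSE)
  writeManifest(cfg, "cohort", "pathways.rds", list(cohort = seed))
  invisible(split)
}

modelFromCfg <- function(cfg, vocab) {
  seqModelConfig(preset = cfg$model$preset, vocab_size = vocabSize(vocab),
                 dropout = cfg$model$dropout,
                 classifier_bias = cfg$model$classifier_bias)
}

stagePretrain <- function(cfg) {
  pw <- readRDS(requireArtifact(cfg, "pathways.rds", "pathways"))
  split <- jsonlite::read_json(requireArtifact(cfg, "cohort.json", "cohort"),
                               simplifyVector = TRUE)
  seed <- deriveSeed(cfg$seed, "pretrain")
  mcfg <- modelFromCfg(cfg, pw$vocab)
  tr_pw <- pw$pretrain[which(pathwayInfo(pw$pretrain)$patient_id %in%
                               split$case_control)]
  ids <- tokenizePathways(tr_pw, pw$vocab,
                          max_len = min(cfg$pathway$max_len, mcfg$max_len))
  model <- initSeqModel(mcfg, seed = seed)
  plan <- trainPlan(batch_size = cfg$pretrain$batch_size,
                    epochs = cfg$pretrain$epochs, lr = cfg$pretrain$lr,
                    seed = seed)
  out <- pretrainModel(model, ids, plan)
  saveModel(out$model, stageFile(cfg, "model_pretrained.rds"))
  utils::write.csv(data.frame(step = seq_along(out$loss_trace),
                              loss = out$loss_trace),
                   stageFile(cfg, "pretrain_trace.csv"), row.names = FALSE)
  writeManifest(cfg, "pretrain", c("pathways.rds", "cohort.json"),
                list(pretrain = seed))
  invisible(out)
}

stageFinetune <- function(cfg) {
  pw <- readRDS(requireArtifact(cfg, "pathways.rds", "pathways"))
  split <- jsonlite::read_json(requireArtifact(cfg, "cohort.json", "cohort"),
                               simplifyVector = TRUE)
  model <- loadModel(requireArtifact(cfg, "model_pretrained.rds", "pretrain"))
  seed <- deriveSeed(cfg$seed, "finetune")
  info <- pathwayInfo(pw$model)
  train_ids <- setdiff(split$case_control, split$evaluation)
  tr <- pw$model[which(info$patient_id %in% train_ids)]
  ev <- pw$model[which(info$patient_id %in% split$evaluation)]
  if (!length(ev)) { ev <- tr[seq_len(min(100L, length(tr)))] }
  enc <- function(p) tokenizePathways(p, pw$vocab,
                                      max_len = min(cfg$pathway$max_len,
                                                    model@config$max_len))
  plan <- trainPlan(batch_size = cfg$finetune$batch_size,
                    epochs = cfg$finetune$epochs, lr = cfg$finetune$lr,
                    seed = seed, restarts = cfg$finetune$restarts)
  out <- finetuneModel(model, enc(tr), pathwayLabels(tr), plan,
                       enc(ev), pathwayLabels(ev))
  saveModel(out$model, stageFile(cfg, "model_finetuned.rds"))
  utils::write.csv(out$restart_report, stageFile(cfg, "restart_report.csv"),
                   row.names = FALSE)
  writeManifest(cfg, "finetune",
                c("pathways.rds", "cohort.json", "model_pretrained.rds"),
                list(finetune = seed))
  invisible(out)
}

stageBaseline <- function(cfg) {
  pw <- readRDS(requireArtifact(cfg, "pathways.rds", "pathways"))
  split <- jsonlite::read_json(requireArtifact(cfg, "cohort.json", "cohort"),
                               simplifyVector = TRUE)
  seed <- deriveSeed(cfg$seed, "baseline")
  info <- pathwayInfo(pw$model)
  tr <- pw$model[which(info$patient_id %in% split$case_control)]
  X <- featurizeCounts(tr, pw$vocab)
  fit <- trainCountsBaseline(X, pathwayLabels(tr), seed = seed)
  saveRDS(fit, stageFile(cfg, "baseline.rds"))
  writeManifest(cfg, "baseline", c("pathways.rds", "cohort.json"),
                list(baseline = seed))
  invisible(fit)
}

stageEvaluate <- function(cfg) {
  pw <- readRDS(requireArtifact(cfg, "pathways.rds", "pathways"))
  split <- jsonlite::read_json(requireArtifact(cfg, "cohort.json", "cohort"),
                               simplifyVector = TRUE)
  model <- loadModel(requireArtifact(cfg, "model_finetuned.rds", "finetune"))
  baseline <- readRDS(requireArtifact(cfg, "baseline.rds", "baseline"))
  seed <- deriveSeed(cfg$seed, "evaluate")
  info <- pathwayInfo(pw$model)
  va <- pw$model[which(info$patient_id %in% split$validation_sample)]
  ids <- tokenizePathways(va, pw$vocab,
                          max_len = min(cfg$pathway$max_len,
                                        model@config$max_len))
  y <- pathwayLabels(va)
  s_deep <- scorePathways(model, ids)
  s_lr <- predictCountsBaseline(baseline, featurizeCounts(va, pw$vocab))
  rep_deep <- metricsReport(s_deep, y, threshold = cfg$evaluate$threshold,
                            n_boot = cfg$evaluate$n_boot, seed = seed)
  rep_lr <- metricsReport(s_lr, y, threshold = cfg$evaluate$threshold,
                          n_boot = cfg$evaluate$n_boot, seed = seed)
  cmp <- delongTest(s_deep, s_lr, y)
  sweep <- thresholdSweep(s_deep, y, cfg$evaluate$thresholds)
  utils::write.csv(sweep, stageFile(cfg, "threshold_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(patient_id = pathwayInfo(va)$patient_id,
                              label = y, score_deep = s_deep,
                              score_lr = s_lr),
                   stageFile(cfg, "validation_scores.csv"), row.names = FALSE)
  res <- list(deep = rep_deep, baseline = rep_lr, delong = cmp)
  jsonlite::write_json(res, stageFile(cfg, "metrics.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeMetricsMarkdown(res, sweep, stageFile(cfg, "metrics.md"))
  writeManifest(cfg, "evaluate",
                c("pathways.rds", "cohort.json", "model_finetuned.rds",
                  "baseline.rds"), list(evaluate = seed))
  invisible(res)
}

writeMetricsMarkdown <- function(res, sweep, path) {
  f <- function(x) ifelse(is.na(x), "n/a", sprintf("%.1f%%", 100 * x))
  lines <- c(
    "# Model performance", "",
    "| model | class | precision | recall | F1 | AUROC |",
    "|---|---|---|---|---|---|",
    sprintf("| sequence model | lung | %s | %s | %s | %.3f |",
            f(res$deep$positive$precision), f(res$deep$positive$recall),
            f(res$deep$positive$f1), res$deep$auroc),
    sprintf("| sequence model | not lung | %s | %s | %s | |",
            f(res$deep$negative$precision), f(res$deep$negative$recall),
            f(res$deep$negative$f1)),
    sprintf("| count LR | lung | %s | %s | %s | %.3f |",
            f(res$baseline$positive$precision), f(res$baseline$positive$recall),
            f(res$baseline$positive$f1), res$baseline$auroc),
    sprintf("| count LR | not lung | %s | %s | %s | |",
            f(res$baseline$negative$precision), f(res$baseline$negative$recall),
            f(res$baseline$negative$f1)),
    "",
    sprintf("DeLong comparison: difference %.4f, p = %.3g",
            res$delong$difference, res$delong$p_value),
    "", "## Threshold sweep", "",
    "| threshold | n predicted | n correct | positives | sensitivity | PPV |",
    "|---|---|---|---|---|---|",
    sprintf("| %.2f | %d | %d | %d | %s | %s |", sweep$threshold,
            sweep$n_predicted_positive, sweep$n_true_positive,
            sweep$n_positives, f(sweep$sensitivity), f(sweep$ppv)))
  writeLines(lines, path)
}

stageInterpret <- function(cfg) {
  pw <- readRDS(requireArtifact(cfg, "pathways.rds", "pathways"))
  split <- jsonlite::read_json(requireArtifact(cfg, "cohort.json", "cohort"),
                               simplifyVector = TRUE)
  model <- loadModel(requireArtifact(cfg, "model_finetuned.rds", "finetune"))
  seed <- deriveSeed(cfg$seed, "interpret")
  info <- pathwayInfo(pw$model)
  keep <- which(info$patient_id %in% split$validation_sample &
                  pathwayLabels(pw$model) == 1L)
  if (length(keep) < 10L) keep <- which(pathwayLabels(pw$model) == 1L)
  sub <- pw$model[keep]
  ids <- tokenizePathways(sub, pw$vocab,
                          max_len = min(cfg$pathway$max_len,
                                        model@config$max_len))
  emb <- clsEmbedding(model, ids)
  k <- min(cfg$interpret$k, nrow(emb) - 1L)
  cl <- clusterPathways(emb, k = k, seed = seed,
                        n_init = cfg$interpret$n_init)
  prof <- lapply(ids, function(s)
    attentionProfileTokens(model, s, pw$vocab))
  summ <- clusterCodeSummary(cl$assignments, sub, prof)
  xy <- embed2d(emb, seed = seed, perplexity = cfg$interpret$perplexity)
  utils::write.csv(data.frame(patient_id = pathwayInfo(sub)$patient_id,
                              cluster = cl$assignments, xy),
                   stageFile(cfg, "clusters.csv"), row.names = FALSE)
  top <- do.call(rbind, lapply(names(summ), function(nm) {
    s <- summ[[nm]]
    data.frame(cluster = nm, n = s$n,
               top_codes = paste(utils::head(s$prevalence$group_id, 5L),
                                 collapse = ";"),
               top_attended = paste(utils::head(s$attention$group_id, 5L),
                                    collapse = ";"))
  }))
  utils::write.csv(top, stageFile(cfg, "cluster_summary.csv"),
                   row.names = FALSE)
  writeManifest(cfg, "interpret",
                c("pathways.rds", "model_finetuned.rds"),
                list(interpret = seed))
  invisible(list(clusters = cl, summary = summ))
}
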