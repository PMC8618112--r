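# End-to-end workflow: curation -> descriptors -> split -> variable
# selection -> tuning -> training -> error model -> AD grid -> evaluation,
# plus model persistence and a prediction entry point.

#' Validate a pipeline configuration
#'
#' A configuration must name the endpoint (endpoint, species,
#' trophic_level), provide the input records (`records` data.frame or
#' `input_csv` path) and an explicit master `seed`; every stage seed is
#' derived from it deterministically. Optional fields override stage
#' defaults: selection_method ("vsurf", "ga" or "both"), rf_grid (list of
#' [rfConfig()] argument lists), tune_B, cv_folds, ad_grid, coverage_floor,
#' split_frac, split_seed, ga, vsurf (config lists), algal_ionization,
#' outdir.
#'
#' @param config list or YAML file path.
#' @return normalized config list (invisibly errors otherwise).
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  need <- c("endpoint", "species", "trophic_level", "seed")
  miss <- need[!vapply(need, function(f) !is.null(config[[f]]), logical(1L))]
  if (length(miss))
    stop("config lacks required field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(config$records) && is.null(config$input_csv))
    stop("config needs 'records' or 'input_csv'", call. = FALSE)
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    stop("'seed' must be a single integer", call. = FALSE)
  if (!config$trophic_level %in% c("alga", "daphnid", "fish"))
    stop("trophic_level must be alga, daphnid or fish", call. = FALSE)
  config$selection_method <- config$selection_method %||% "vsurf"
  if (!config$selection_method %in% c("vsurf", "ga", "both"))
    stop("selection_method must be vsurf, ga or both", call. = FALSE)
  config$split_frac <- config$split_frac %||% 0.8
  config$tune_B <- config$tune_B %||% 100L
  config$cv_folds <- config$cv_folds %||% 10L
  config$coverage_floor <- config$coverage_floor %||% 0.75
  config
}

.stageSeed <- function(master, stage) {
  offs <- c(curate = 11L, split = 23L, select = 37L, tune = 41L,
            train = 53L, cv = 67L, ad = 79L)
  (as.integer(master) * 101L + offs[[stage]]) %% 2147480000L
}

#' Run the full QSAR modelling pipeline
#'
#' Executes curation, descriptor computation and pruning, the
#' dissimilarity 80:20 split, variable selection, bootstrap tuning, model
#' training, the error model, the 32-combination applicability-domain
#' grid, and evaluation (training and validation, with and without AD).
#' Reruns with the same configuration are deterministic.
#'
#' @param config see [validatePipelineConfig()].
#' @return list with dataset, descriptors, split, selection, tuning,
#'   bundle, adTable, reports, seeds and (when `config$outdir` is set) the
#'   artifact paths.
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  records <- config$records %||% readToxicityRecords(config$input_csv)
  seeds <- vapply(c("curate", "split", "select", "tune", "train", "cv",
                    "ad"),
                  function(s) .stageSeed(config$seed, s), numeric(1L))

  cur <- curateRecords(records, endpoint = config$endpoint,
                       species = config$species,
                       trophicLevel = config$trophic_level)
  cp <- retainedCompounds(cur$dataset)

  desc <- computeDescriptors(cp$neutralized_smiles, ids = cp$cas)
  dropped <- desc$dropped
  dm <- pruneConstant(desc$matrix)
  okIds <- compoundIds(dm)
  y <- stats::setNames(cp$response_transformed, cp$cas)[okIds]

  pca <- pcaScores(dm)
  dmModel <- pruneCorrelated(dm)
  split <- dissimilaritySplit(pca$scores, y, frac = config$split_frac,
                              seed = config$split_seed %||% seeds[["split"]])
  Xtr <- descriptorValues(dmModel)[split$train_idx, , drop = FALSE]
  Xva <- descriptorValues(dmModel)[split$valid_idx, , drop = FALSE]
  ytr <- y[split$train_idx]; yva <- y[split$valid_idx]

  sel <- .selectFeatures(Xtr, ytr, config, seeds[["select"]])
  Xtr <- Xtr[, sel$selected_names, drop = FALSE]
  Xva <- Xva[, sel$selected_names, drop = FALSE]

  grid <- if (is.null(config$rf_grid)) defaultTuningGrid() else
    lapply(config$rf_grid, function(g) do.call(rfConfig, g))
  tuned <- tuneForest(Xtr, ytr, grid = grid, B = config$tune_B,
                      seed = seeds[["tune"]])
  cfg <- tuned$best
  cfg$seed <- as.integer(seeds[["train"]])
  bundle <- trainForest(Xtr, ytr, config = cfg,
                        transform = cur$dataset@transform)
  bundle <- trainErrorModel(bundle, seed = seeds[["cv"]],
                            cvFolds = config$cv_folds)
  adSel <- selectAdConfig(bundle,
                          grid = config$ad_grid %||% defaultAdGrid(),
                          cvFolds = config$cv_folds,
                          seed = seeds[["ad"]],
                          coverageFloor = config$coverage_floor)
  bundle <- adSel$bundle

  reports <- list(
    train = evaluateWithAd(bundle, Xtr, ytr, applyAd = FALSE,
                           subset = "train"),
    train_ad = evaluateWithAd(bundle, Xtr, ytr, applyAd = TRUE,
                              isTraining = TRUE, subset = "train"),
    validation = evaluateWithAd(bundle, Xva, yva, applyAd = FALSE),
    validation_ad = evaluateWithAd(bundle, Xva, yva, applyAd = TRUE))

  out <- list(dataset = cur$dataset, audit = cur$audit,
              descriptors = dmModel, descriptorDropped = dropped,
              pca = pca, split = split, selection = sel, tuning = tuned,
              bundle = bundle, adTable = adSel$table, reports = reports,
              seeds = as.list(seeds), config = config)
  if (!is.null(config$outdir)) out$paths <- .writeArtifacts(out, config$outdir)
  out
}

.selectFeatures <- function(Xtr, ytr, config, seed) {
  method <- config$selection_method
  runGa <- function() gaSelect(Xtr, ytr,
                               cfg = do.call(gaConfig, config$ga %||% list()),
                               seed = seed)
  runVs <- function() {
    s <- vsurfSelect(Xtr, ytr,
                     cfg = do.call(vsurfConfig, config$vsurf %||% list()),
                     seed = seed)
    # models keep the interpretation set by default; the sparser
    # prediction set is available via config$vsurf_set = "prediction"
    if (!identical(config$vsurf_set, "prediction")) {
      s$prediction_names <- s$selected_names
      s$selected_names <- s$interpretation_names
    }
    s
  }
  if (method == "ga") return(runGa())
  if (method == "vsurf") return(runVs())
  a <- runGa(); b <- runVs()
  score <- function(s) {
    cv <- cvAbsErrors(Xtr[, s$selected_names, drop = FALSE], ytr,
                      config = rfConfig(n_trees = 100L), k = 10L,
                      seed = seed + 3L)
    regressionMetrics(ytr, cv$predictions)$r2
  }
  ra <- score(a); rb <- score(b)
  winner <- if (ra >= rb) a else b
  winner$competition <- data.frame(method = c("ga", "vsurf"),
                                   cv_r2 = c(ra, rb))
  winner
}

.writeArtifacts <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  writeCuratedDataset(list(dataset = out$dataset, audit = out$audit),
                      p("curated.csv"), p("curation_audit.json"))
  jsonlite::write_json(out$split[c("train_ids", "valid_ids", "seed",
                                   "metric", "scoring")],
                       p("split.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$selection[c("method", "selected_names", "seed")],
                       p("selection.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(out$adTable, p("ad_grid.csv"), row.names = FALSE)
  jsonlite::write_json(out$reports, p("evaluation.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  saveModelBundle(out$bundle, p("model"))
  log <- c(sprintf("endpoint: %s %s (%s)", out$dataset@species,
                   out$dataset@endpoint, out$dataset@trophicLevel),
           sprintf("master seed: %s", out$config$seed),
           sprintf("stage seeds: %s",
                   paste(names(out$seeds), unlist(out$seeds), sep = "=",
                         collapse = " ")),
           sprintf("selected descriptors (%d): %s",
                   length(out$selection$selected_names),
                   paste(out$selection$selected_names, collapse = ", ")))
  writeLines(log, p("run_log.txt"))
  c(curated = p("curated.csv"), audit = p("curation_audit.json"),
    split = p("split.json"), selection = p("selection.json"),
    ad_grid = p("ad_grid.csv"), evaluation = p("evaluation.json"),
    model = p("model"), log = p("run_log.txt"))
}

#' Persist a trained model bundle
#'
#' Writes the fitted forests as RDS and a JSON metadata sidecar (config,
#' descriptor names, transform, AD thresholds, seeds).
#'
#' @param bundle a \linkS4class{ToxModelBundle}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
saveModelBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(bundle, file.path(dir, "bundle.rds"))
  ad <- bundle@ad
  meta <- list(config = bundle@config,
               selected_descriptors = bundle@selectedDescriptors,
               transform = list(lambda = bundle@transform@lambda,
                                mean_t = bundle@transform@meanT,
                                sd_t = bundle@transform@sdT),
               ad = list(metric = ad@metric, k = ad@k,
                         td_percentile = ad@tdPercentile,
                         td_value = ad@tdValue,
                         te_percentile = ad@tePercentile,
                         te_value = ad@teValue),
               n_train = nrow(bundle@trainX))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a persisted model bundle
#'
#' @param dir directory written by [saveModelBundle()].
#' @return a \linkS4class{ToxModelBundle}.
#' @export
loadModelBundle <- function(dir) {
  readRDS(file.path(dir, "bundle.rds"))
}

#' Predict toxicity for new structures
#'
#' Standardizes each SMILES, computes descriptors, predicts the
#' transformed response with its per-tree spread, back-transforms to
#' mmol/L and mg/L, and reports the applicability-domain decision, the
#' six AD metrics and the leverage flag. Unparsable rows carry an error
#' message; the remaining rows proceed.
#'
#' @param bundle a \linkS4class{ToxModelBundle} (or directory path).
#' @param smiles character vector of SMILES.
#' @param neutralize passed to [standardizeStructure()].
#' @return data.frame, one row per input.
#' @export
predictToxicity <- function(bundle, smiles, neutralize = TRUE) {
  if (is.character(bundle)) bundle <- loadModelBundle(bundle)
  n <- length(smiles)
  out <- data.frame(smiles = smiles, error = NA_character_,
                    prediction_transformed = NA_real_,
                    prediction_mmol = NA_real_, prediction_mg_l = NA_real_,
                    tree_sd = NA_real_, inside_ad = NA,
                    distance_check = NA, error_check = NA,
                    mean_knn_distance = NA_real_, predicted_error = NA_real_,
                    wrms1 = NA_real_, wrms2 = NA_real_,
                    sim_nearest1 = NA_real_, sim_nearest5 = NA_real_,
                    high_leverage = NA, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    std <- tryCatch(standardizeStructure(smiles[i], neutralize = neutralize),
                    error = function(e) conditionMessage(e))
    if (is.character(std)) { out$error[i] <- std; next }
    desc <- tryCatch(computeDescriptors(std$neutralized_smiles, ids = "q"),
                     error = function(e) conditionMessage(e))
    if (is.character(desc)) { out$error[i] <- desc; next }
    have <- descriptorNames(desc$matrix)
    missing <- setdiff(bundle@selectedDescriptors, have)
    if (length(missing)) {
      out$error[i] <- paste("descriptors unavailable:",
                            paste(missing, collapse = ","))
      next
    }
    x <- descriptorValues(desc$matrix)[1L, bundle@selectedDescriptors,
                                       drop = FALSE]
    pr <- predictWithSpread(bundle, x)
    met <- adMetrics(x, bundle)
    dec <- assessAD(x, bundle)
    mmol <- boxCoxInvert(pr$prediction, bundle@transform@lambda)
    mw <- tryCatch(.molecularWeight(std$neutralized_smiles),
                   error = function(e) NA_real_)
    lev <- leverageFlags(bundle@trainX, x)
    out$prediction_transformed[i] <- pr$prediction
    out$prediction_mmol[i] <- mmol
    out$prediction_mg_l[i] <- mmol * mw
    out$tree_sd[i] <- pr$tree_sd
    out$inside_ad[i] <- dec$inside
    out$distance_check[i] <- dec$distance_check
    out$error_check[i] <- dec$error_check
    out$mean_knn_distance[i] <- dec$mean_knn_distance
    out$predicted_error[i] <- dec$predicted_error
    out$wrms1[i] <- met$wrms1; out$wrms2[i] <- met$wrms2
    out$sim_nearest1[i] <- met$sim_nearest1
    out$sim_nearest5[i] <- met$sim_nearest5
    out$high_leverage[i] <- lev$high_leverage[1L]
  }
  out
}
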