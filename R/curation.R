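# Record-level filtering and compound-level curation: one consolidated,
# Box-Cox-transformed response per retained chemical.

.RECORD_COLUMNS <- c("cas", "name", "smiles", "endpoint", "species",
                     "duration_h", "value_mg_l", "qualifier", "ph_adjusted",
                     "solubility_mg_l", "source")

.QUALIFIERS <- c("exact", "greater_than", "less_than", "range", "approximate")

#' Read raw toxicity records from CSV
#'
#' Expected header: cas,name,smiles,endpoint,species,duration_h,value_mg_l,
#' qualifier,ph_adjusted,solubility_mg_l,source. Extra columns (e.g. doses,
#' purity, exposure_type, metadata exclusion flags) are carried through.
#'
#' @param path CSV file path.
#' @return data.frame of raw records.
#' @export
readToxicityRecords <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.RECORD_COLUMNS, names(rec))
  if (length(missing))
    stop("record CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rec$ph_adjusted <- as.logical(rec$ph_adjusted)
  rec
}

#' Default record-filter criteria for a trophic level
#'
#' Exact-value qualifiers only; guideline exposure-duration windows in
#' hours per trophic level and endpoint (alga 72 h, daphnid 48 h acute and
#' 21 d chronic, fish 96 h acute and 28-90 d early-life-stage chronic);
#' pH-adjusted records dropped for daphnid and fish data.
#'
#' @param trophicLevel "alga", "daphnid" or "fish".
#' @return list of criteria consumed by [filterValueRecords()].
#' @export
defaultFilterCriteria <- function(trophicLevel = c("alga", "daphnid", "fish")) {
  trophicLevel <- match.arg(trophicLevel)
  windows <- switch(trophicLevel,
    alga = list(EC50 = c(72, 72), NOEC = c(72, 72)),
    daphnid = list(EC50 = c(48, 48), NOEC = c(504, 504)),
    fish = list(LC50 = c(96, 96), NOEC = c(672, 2160)))
  list(qualifiers = "exact",
       durationWindows = windows,
       durationTolerance = 1e-6,
       dropPhAdjusted = trophicLevel %in% c("daphnid", "fish"),
       minDoses = NULL, minPurity = NULL, allowedExposureTypes = NULL)
}

#' Filter raw toxicity records
#'
#' Keeps records that satisfy all criteria: allowed qualifier (censored,
#' range and approximate values are dropped), guideline duration window for
#' the record's endpoint, pH-adjustment policy, and optional study-quality
#' criteria (minimum dose count, minimum purity, allowed exposure types)
#' when those columns are present. Every dropped record receives exactly
#' one primary reason, checked in that order.
#'
#' @param records data.frame of raw records.
#' @param criteria list as from [defaultFilterCriteria()].
#' @return list with `kept` (data.frame) and `audit` (data.frame with
#'   columns row, cas, reason for dropped records).
#' @export
filterValueRecords <- function(records, criteria) {
  stopifnot(is.data.frame(records))
  known <- names(criteria$durationWindows)
  bad <- setdiff(unique(records$endpoint), known)
  if (length(bad))
    stop("no duration window configured for endpoint(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!all(records$qualifier %in% .QUALIFIERS))
    stop("unknown qualifier label(s): ",
         paste(setdiff(records$qualifier, .QUALIFIERS), collapse = ", "),
         call. = FALSE)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  tol <- criteria$durationTolerance %||% 1e-6
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (!(r$qualifier %in% criteria$qualifiers)) { reason[i] <- "censored"; next }
    if (!is.finite(r$value_mg_l) || r$value_mg_l <= 0) {
      reason[i] <- "missing_value"; next }
    w <- criteria$durationWindows[[r$endpoint]]
    if (r$duration_h < w[1] - tol || r$duration_h > w[2] + tol) {
      reason[i] <- "duration"; next }
    if (isTRUE(criteria$dropPhAdjusted) && isTRUE(r$ph_adjusted)) {
      reason[i] <- "ph_adjusted"; next }
    if (!is.null(criteria$minDoses) && "doses" %in% names(records) &&
        is.finite(r$doses) && r$doses < criteria$minDoses) {
      reason[i] <- "doses"; next }
    if (!is.null(criteria$minPurity) && "purity" %in% names(records) &&
        is.finite(r$purity) && r$purity < criteria$minPurity) {
      reason[i] <- "purity"; next }
    if (!is.null(criteria$allowedExposureTypes) &&
        "exposure_type" %in% names(records) &&
        !(r$exposure_type %in% criteria$allowedExposureTypes)) {
      reason[i] <- "exposure_type"; next }
    if ("manual_outlier" %in% names(records) && isTRUE(r$manual_outlier)) {
      reason[i] <- "manual_override"; next }
  }
  dropped <- which(!is.na(reason))
  list(kept = records[is.na(reason), , drop = FALSE],
       audit = data.frame(row = dropped, cas = records$cas[dropped],
                          reason = reason[dropped],
                          stringsAsFactors = FALSE))
}

#' Convert a concentration from mg/L to mmol/L
#'
#' @param value concentration in mg/L (> 0).
#' @param mw molecular weight in g/mol (> 0).
#' @return value / mw, in mmol/L.
#' @export
toMillimolar <- function(value, mw) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("'value' must be positive and finite", call. = FALSE)
  if (any(!is.finite(mw)) || any(mw <= 0))
    stop("'mw' must be positive and finite", call. = FALSE)
  value / mw
}

#' Consolidate replicate measurements for one compound
#'
#' Replicates are acceptable when the largest and smallest value agree
#' within a factor of 10 (one log unit; the boundary ratio passes, with
#' multiplicative tolerance 1 + 1e-9). Acceptable sets are consolidated by
#' their geometric mean; the median and arithmetic mean are also returned
#' for the audit trail. Singleton lists pass through unchanged.
#'
#' @param values positive replicate values (mmol/L).
#' @param maxFactor largest admissible max/min ratio (default 10).
#' @param enforceSpread set FALSE to force aggregation regardless of spread.
#' @return list with `ok` (logical), `value` (geometric mean when ok),
#'   `ratio` (max/min), `median`, `arithmetic_mean`.
#' @export
consolidateReplicates <- function(values, maxFactor = 10,
                                  enforceSpread = TRUE) {
  if (!length(values)) stop("no replicate values", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("replicate values must be positive and finite", call. = FALSE)
  ratio <- max(values) / min(values)
  ok <- !enforceSpread || ratio <= maxFactor * (1 + 1e-9)
  list(ok = ok,
       value = if (ok) geometricMean(values) else NA_real_,
       ratio = ratio, median = stats::median(values),
       arithmetic_mean = mean(values))
}

#' Water-solubility screen
#'
#' A consolidated toxicity value above the compound's water solubility is
#' physically suspect (the nominal test concentration cannot have been in
#' solution) and the compound is dropped. Missing solubility keeps the
#' compound with a warning flag.
#'
#' @param response consolidated response (mmol/L).
#' @param solubility water solubility (mmol/L) or NA.
#' @return list with `keep` (logical) and `warning` (TRUE when solubility
#'   was unavailable).
#' @export
solubilityScreen <- function(response, solubility) {
  stopifnot(is.finite(response), response > 0)
  if (is.na(solubility)) return(list(keep = TRUE, warning = TRUE))
  list(keep = response <= solubility, warning = FALSE)
}

#' Curate raw toxicity records into an endpoint dataset
#'
#' Runs the full curation cascade for one species/endpoint dataset:
#' record-level filtering (qualifiers, duration, pH adjustment, optional
#' study criteria), structure standardization (canonical SMILES, salt
#' stripping, neutralization - kept ionized for algal data), structural
#' exclusion taxonomy, mg/L to mmol/L conversion, factor-of-10 replicate
#' consolidation by geometric mean, water-solubility screen, the
#' pH-microspecies screen (algal datasets only), Box-Cox normalization
#' with profile-likelihood lambda, and the single-pass +/- 3 SD outlier
#' exclusion.
#'
#' @param records data.frame of raw records (one endpoint).
#' @param endpoint endpoint label ("EC50", "LC50" or "NOEC").
#' @param species species label.
#' @param trophicLevel "alga", "daphnid" or "fish".
#' @param criteria record-filter criteria; default
#'   [defaultFilterCriteria()] for the trophic level.
#' @param neutralize neutralize charges; default FALSE for algal datasets
#'   (ionized form kept, pH being critical for algae), TRUE otherwise.
#' @param microspecies run the pH 7.5/8.1 microspecies screen; default
#'   TRUE for algal datasets only.
#' @param pkaTable pKa plugin table for the microspecies screen.
#' @param lambdaInterval Box-Cox lambda search interval.
#' @param maxFactor replicate-spread factor (default 10).
#' @return list with `dataset` (an \linkS4class{EndpointDataset}) and
#'   `audit` (record-level drops, per-compound decisions, transform
#'   parameters).
#' @export
curateRecords <- function(records, endpoint, species, trophicLevel,
                          criteria = defaultFilterCriteria(trophicLevel),
                          neutralize = !identical(trophicLevel, "alga"),
                          microspecies = identical(trophicLevel, "alga"),
                          pkaTable = defaultPkaTable(),
                          lambdaInterval = c(-2, 2), maxFactor = 10) {
  stopifnot(trophicLevel %in% c("alga", "daphnid", "fish"))
  flt <- filterValueRecords(records, criteria)
  kept <- flt$kept

  casList <- sort(unique(records$cas))
  cp <- data.frame(cas = casList, smiles = NA_character_,
                   neutralized_smiles = NA_character_, mw = NA_real_,
                   response_mmol = NA_real_,
                   response_transformed = NA_real_, retained = FALSE,
                   exclusion = NA_character_, n_replicates = 0L,
                   replicate_ratio = NA_real_,
                   median_mmol = NA_real_, arithmetic_mean_mmol = NA_real_,
                   solubility_warning = FALSE, stringsAsFactors = FALSE)
  rownames(cp) <- casList

  metaCols <- intersect(c("uvcb", "isomer_mixture", "nonionic_surfactant",
                          "name_cas_mismatch"), names(records))
  for (cas in casList) {
    recAll <- records[records$cas == cas, , drop = FALSE]
    recKept <- kept[kept$cas == cas, , drop = FALSE]
    # order-invariant structure choice: lexicographic minimum SMILES
    smis <- recAll$smiles[nzchar(recAll$smiles) & !is.na(recAll$smiles)]
    if (!length(smis)) { cp[cas, "exclusion"] <- "missing_structure"; next }
    smi <- min(smis)
    std <- tryCatch(standardizeStructure(smi, neutralize = neutralize),
                    error = function(e) NULL)
    if (is.null(std)) { cp[cas, "exclusion"] <- "unparsable"; next }
    cp[cas, "smiles"] <- std$normalized_smiles
    cp[cas, "neutralized_smiles"] <- std$neutralized_smiles
    md <- lapply(stats::setNames(metaCols, metaCols),
                 function(cl) any(as.logical(recAll[[cl]])))
    cls <- classifyStructure(std$neutralized_smiles, metadata = md)
    if (!cls$keep) { cp[cas, "exclusion"] <- cls$reason; next }
    mw <- tryCatch(.molecularWeight(std$neutralized_smiles),
                   error = function(e) NA_real_)
    if (!is.finite(mw) || mw <= 0) {
      cp[cas, "exclusion"] <- "no_molecular_weight"; next }
    cp[cas, "mw"] <- mw
    if (nrow(recKept) == 0L) { cp[cas, "exclusion"] <- "no_valid_records"; next }
    mmol <- toMillimolar(recKept$value_mg_l, mw)
    cp[cas, "n_replicates"] <- length(mmol)
    cons <- consolidateReplicates(mmol, maxFactor = maxFactor)
    cp[cas, "replicate_ratio"] <- cons$ratio
    cp[cas, "median_mmol"] <- cons$median
    cp[cas, "arithmetic_mean_mmol"] <- cons$arithmetic_mean
    if (!cons$ok) { cp[cas, "exclusion"] <- "replicate_spread"; next }
    sols <- recKept$solubility_mg_l
    sol <- if (all(is.na(sols))) NA_real_ else
      toMillimolar(min(sols, na.rm = TRUE), mw)
    scr <- solubilityScreen(cons$value, sol)
    cp[cas, "solubility_warning"] <- scr$warning
    if (!scr$keep) { cp[cas, "exclusion"] <- "above_solubility"; next }
    if (microspecies) {
      ms <- microspeciesPhScreen(std$neutralized_smiles, pkaTable = pkaTable)
      if (ms == "unstable") { cp[cas, "exclusion"] <- "microspecies_ph"; next }
    }
    cp[cas, "response_mmol"] <- cons$value
  }

  ok <- which(is.na(cp$exclusion) & is.finite(cp$response_mmol))
  if (length(ok) < 3L)
    stop("fewer than 3 compounds survive curation; cannot fit Box-Cox",
         call. = FALSE)
  bc <- fitBoxCox(cp$response_mmol[ok], interval = lambdaInterval)
  keepIdx <- excludeOutliers(bc$transformed, bc$transform)
  outIdx <- setdiff(seq_along(ok), keepIdx)
  cp$exclusion[ok[outIdx]] <- "outlier_3sd"
  cp$response_transformed[ok[keepIdx]] <- bc$transformed[keepIdx]
  cp$retained[ok[keepIdx]] <- TRUE

  # refresh transform statistics on the retained set (values unchanged;
  # meanT/sdT describe the final dataset, lambda stays as fitted)
  dataset <- new("EndpointDataset", endpoint = endpoint, species = species,
                 trophicLevel = trophicLevel, compounds = cp,
                 transform = bc$transform)
  audit <- list(
    records = flt$audit,
    compounds = cp[, c("cas", "exclusion", "n_replicates", "replicate_ratio",
                       "median_mmol", "arithmetic_mean_mmol",
                       "solubility_warning")],
    transform = list(lambda = bc$transform@lambda,
                     mean_t = bc$transform@meanT, sd_t = bc$transform@sdT))
  list(dataset = dataset, audit = audit)
}

# molecular weight via OpenBabel property calculator
.molecularWeight <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)
  ChemmineR::cid(sdf) <- "q"
  p <- ChemmineR::propOB(sdf)
  as.numeric(p$MW[1L])
}

#' Write a curated dataset and its audit trail
#'
#' @param curated result of [curateRecords()].
#' @param csvPath output CSV (cas, smiles, response_mmol,
#'   response_transformed) for retained compounds.
#' @param auditPath optional JSON audit path.
#' @return invisibly, the paths written.
#' @export
writeCuratedDataset <- function(curated, csvPath, auditPath = NULL) {
  cp <- retainedCompounds(curated$dataset)
  utils::write.csv(cp[, c("cas", "smiles", "response_mmol",
                          "response_transformed")],
                   csvPath, row.names = FALSE)
  if (!is.null(auditPath))
    jsonlite::write_json(curated$audit, auditPath, auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(c(csvPath, auditPath))
}
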