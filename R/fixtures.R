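# Seeded synthetic fixtures: a compound library with controlled fractions
# of salts, ionizable structures and excludable structures; replicate
# toxicity records in the multi-source record shape the curation stage
# reads; and plain regression benchmarks with known informative variables.

# deterministic pools of valid, descriptor-computable SMILES ------------

.neutralPool <- function() {
  subst <- c("C", "CC", "CCC", "CCCC", "C(C)C", "O", "OC", "OCC", "N",
             "NC", "N(C)C", "Cl", "Br", "F", "I", "C=O", "C(=O)C",
             "C(=O)OC", "C#N", "OC(=O)C", "CO", "CCO", "C=C")
  mono <- sprintf("c1ccc(%s)cc1", subst)
  pairs <- expand.grid(a = c("C", "O", "Cl", "OC", "N", "C#N", "F"),
                       b = c("C", "CC", "Cl", "Br", "OC", "C=O"),
                       stringsAsFactors = FALSE)
  di <- sprintf("c1cc(%s)ccc1%s", pairs$a, pairs$b)
  chains <- vapply(2:8, function(k) strrep("C", k), character(1L))
  ali <- c(paste0(chains, "O"),                     # alcohols
           paste0(chains, "C(=O)C"),                # ketones
           paste0(chains, "OC(=O)C"),               # esters
           paste0(chains, "Cl"), paste0(chains, "Br"),
           paste0(chains, "C#N"),
           paste0(chains, "OCC"),                   # ethers
           paste0(chains, "C=C"))
  het <- c("c1ccncc1", "Cc1ccncc1", "CCc1ccncc1", "c1ccoc1", "Cc1ccco1",
           "c1ccsc1", "Cc1cccs1", "c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1",
           "C1CCCCC1", "C1CCCCC1O", "C1CCCCC1N", "CC1CCCCC1",
           "C1CCOC1", "C1CCNC1")
  unique(c(mono, di, ali, het))
}

.ionizablePool <- function() {
  ringSub <- c("C", "CC", "CCC", "CCCC", "Cl", "Br", "F", "OC", "C=O")
  phenols <- c("Oc1ccccc1", "Oc1ccccc1C",
               sprintf("Oc1ccc(%s)cc1", ringSub))
  acids <- c(paste0(vapply(1:8, function(k) strrep("C", k), character(1L)),
                    "C(=O)O"),
             "OC(=O)c1ccccc1", "OC(=O)Cc1ccccc1",
             sprintf("OC(=O)c1ccc(%s)cc1", ringSub))
  amines <- c(paste0(vapply(2:8, function(k) strrep("C", k), character(1L)),
                     "N"),
              "NCc1ccccc1", "CNCc1ccccc1", "Nc1ccccc1",
              sprintf("Nc1ccc(%s)cc1", c("C", "CC", "Cl", "OC", "F")),
              sprintf("NCc1ccc(%s)cc1", c("C", "Cl", "OC")),
              c("CNC", "CNCC", "CNCCC", "CNCCCC"))
  thiols <- c("CCS", "CCCS", "CCCCS", "CCCCCS")
  unique(c(phenols, acids, amines, thiols))
}

# neutral parent -> ionized salt form (carboxylates and amines)
.saltForm <- function(parent) {
  if (startsWith(parent, "OC(=O)"))
    return(paste0(sub("^OC\\(=O\\)", "[O-]C(=O)", parent), ".[Na+]"))
  if (grepl("C(=O)O", parent, fixed = TRUE))
    return(paste0(sub("C\\(=O\\)O", "C(=O)[O-]", parent), ".[Na+]"))
  if (endsWith(parent, "N"))
    return(paste0(sub("N$", "[NH3+]", parent), ".[Cl-]"))
  if (startsWith(parent, "Nc") || startsWith(parent, "NC"))
    return(paste0(sub("^N", "[NH3+]", parent), ".[Cl-]"))
  if (startsWith(parent, "Oc"))
    return(paste0(sub("^O", "[O-]", parent), ".[Na+]"))
  paste0(parent, ".[Na+].[Cl-]")   # inert co-crystal fallback
}

.excludablePool <- function() {
  inorg <- c("[Na+].[Cl-]", "[K+].[Br-]", "[K+].[I-]", "[Li+].[Cl-]",
             "[Mg+2].[Cl-].[Cl-]", "[Ca+2].[Cl-].[Cl-]",
             "O=S(=O)(O)O", "O=[N+]([O-])O", "NO", "O=P(O)(O)O",
             "[Na+].[OH-]", "[NH4+].[Cl-]")
  metal <- c("CC[Sn](CC)CC", "CCCC[Sn](CCCC)CCCC", "CC[Pb](CC)(CC)CC",
             "Cl[Hg]c1ccccc1", "C[Hg]Cl", "CC(=O)O[Sn](C)(C)C",
             "CC(=O)O[Pb]OC(=O)C", "CCCC[Sn](CCCC)(CCCC)Cl",
             "C[Al](C)C", "CC[Al](CC)CC")
  mixA <- c("CCO", "CCCO", "CCCCO", "CCOCC", "CC(=O)C")
  mixB <- c("CCCCCC", "c1ccccc1C", "CCCCCCO", "CCCCC(=O)C")
  mixtures <- as.vector(outer(mixA, mixB, function(a, b) paste0(a, ".", b)))
  list(inorganic = inorg, metal_complex = metal, mixture = mixtures)
}

#' Fixture generator settings
#'
#' Defaults emulate a multi-source replicate-record collection at desk
#' scale: a few replicates per compound with sub-log spread, moderate
#' fractions of censored records, salts, ionizable and excludable
#' structures, and small fractions of deliberately broken compounds
#' (inflated replicate spread, solubility violations, gross outliers).
#'
#' @param n_compounds compounds in the library.
#' @param replicate_lambda Poisson mean of extra replicates per compound
#'   (each compound gets 1 + Poisson(replicate_lambda) records).
#' @param replicate_spread maximum log10 spread among a compound's clean
#'   replicates (must stay below 1 so clean compounds pass the
#'   factor-of-10 rule).
#' @param censored_fraction probability that a replicate carries a
#'   non-exact qualifier (a compound whose replicates are all censored or
#'   pH-adjusted is lost downstream).
#' @param ph_adjusted_fraction probability that a non-censored replicate
#'   is pH-adjusted.
#' @param salt_fraction fraction of compounds emitted as salts.
#' @param excludable_fraction fraction of structurally excludable
#'   compounds (inorganics, metal complexes, mixtures).
#' @param ionizable_fraction fraction of ionizable (neutral) compounds.
#' @param inflated_fraction fraction of compounds whose replicate spread
#'   exceeds one log unit (must be rejected downstream).
#' @param solubility_violation_fraction fraction of compounds whose
#'   consolidated value exceeds their stated water solubility.
#' @param outlier_fraction fraction of compounds with a gross response
#'   shift (targets of the +/- 3 SD rule).
#' @param noise_sd response noise on the transformed scale.
#' @param true_lambda Box-Cox lambda of the simulated response scale
#'   (0 = log).
#' @return spec list.
#' @export
fixtureSpec <- function(n_compounds = 200L, replicate_lambda = 1.5,
                        replicate_spread = 0.6, censored_fraction = 0.10,
                        ph_adjusted_fraction = 0.03, salt_fraction = 0.10,
                        excludable_fraction = 0.10,
                        ionizable_fraction = 0.15,
                        inflated_fraction = 0.05,
                        solubility_violation_fraction = 0.05,
                        outlier_fraction = 0.02, noise_sd = 0.8,
                        true_lambda = 0) {
  spec <- as.list(environment())
  fr <- c(spec$salt_fraction, spec$excludable_fraction,
          spec$ionizable_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("role fractions must be in [0,1] and sum to at most 1",
         call. = FALSE)
  if (spec$replicate_spread < 0) stop("replicate_spread must be >= 0",
                                      call. = FALSE)
  spec
}

#' Generate a synthetic compound library
#'
#' Draws `n_compounds` SMILES from deterministic template pools with the
#' spec's fractions of salts, ionizable compounds and excludable
#' structures (inorganics, metal complexes, mixtures), each within one
#' compound of the nominal count. All emitted SMILES parse.
#'
#' @param spec from [fixtureSpec()].
#' @param seed RNG seed.
#' @return data.frame: cas, smiles, role ("normal", "ionizable", "salt",
#'   "excludable"), excl_reason (NA unless excludable), parent_smiles
#'   (the neutral parent used for response simulation).
#' @export
generateCompoundLibrary <- function(spec = fixtureSpec(), seed = 1L) {
  n <- spec$n_compounds
  nSalt <- round(spec$salt_fraction * n)
  nExcl <- round(spec$excludable_fraction * n)
  nIon <- round(spec$ionizable_fraction * n)
  nNorm <- n - nSalt - nExcl - nIon
  withSeed(seed, {
    neuPool <- .neutralPool()
    ionPool <- .ionizablePool()
    exclPool <- .excludablePool()
    if (nNorm > length(neuPool) || nIon + nSalt > length(ionPool))
      stop("requested library larger than the template pools support",
           call. = FALSE)
    norm <- sample(neuPool, nNorm)
    ionAll <- sample(ionPool, min(nIon + nSalt, length(ionPool)))
    ion <- ionAll[seq_len(nIon)]
    saltParents <- if (nSalt > 0) {
      base <- if (length(ionAll) > nIon)
        ionAll[(nIon + 1L):length(ionAll)] else character(0)
      short <- nSalt - length(base)
      c(base, if (short > 0) sample(ionPool, short, replace = TRUE))
    } else character(0)
    salts <- vapply(saltParents, .saltForm, character(1L))
    exclKinds <- sample(rep_len(names(exclPool), nExcl))
    excl <- vapply(seq_len(nExcl), function(i) {
      pool <- exclPool[[exclKinds[i]]]
      pool[((i - 1L) %% length(pool)) + 1L]
    }, character(1L))
    lib <- data.frame(
      smiles = c(norm, ion, salts, excl),
      role = c(rep("normal", nNorm), rep("ionizable", nIon),
               rep("salt", nSalt), rep("excludable", nExcl)),
      excl_reason = c(rep(NA_character_, nNorm + nIon + nSalt), exclKinds),
      parent_smiles = c(norm, ion, saltParents, rep(NA_character_, nExcl)),
      stringsAsFactors = FALSE)
    ord <- sample.int(nrow(lib))
    lib <- lib[ord, , drop = FALSE]
    lib$cas <- sprintf("JP-%05d", seq_len(nrow(lib)))
    rownames(lib) <- lib$cas
    lib[, c("cas", "smiles", "role", "excl_reason", "parent_smiles")]
  })
}

#' Generate synthetic replicate toxicity records
#'
#' Simulates a curated-input record table: a true response per compound
#' (linear in computed descriptors on the transformed scale, plus noise),
#' inverse-Box-Cox mapped to mmol/L and scaled by molecular weight to
#' mg/L; 1 + Poisson(replicate_lambda) replicates per compound with
#' controlled multiplicative spread; censored and pH-adjusted qualifiers
#' on replicates beyond the first; and the spec's sub-fractions of
#' inflated-spread, solubility-violating and gross-outlier compounds.
#' Bookkeeping (which records/compounds were broken how) is emitted so
#' downstream filter decisions can be verified against ground truth.
#'
#' @param library from [generateCompoundLibrary()].
#' @param spec from [fixtureSpec()].
#' @param seed RNG seed.
#' @param endpoint,species,trophic_level,duration_h record metadata
#'   (defaults: daphnid immobilization EC50 at 48 h).
#' @param truth optional list(descriptors, coefficients, intercept)
#'   defining the response surface; default uses ALOGP, MW and TPSA.
#' @return list with `records` (raw record data.frame), `truth`,
#'   `bookkeeping` (record- and compound-level ground truth) and
#'   `descriptors` (the parent descriptor matrix used for simulation).
#' @export
generateToxicityRecords <- function(library, spec = fixtureSpec(),
                                    seed = 1L, endpoint = "EC50",
                                    species = "Daphnia magna",
                                    trophic_level = "daphnid",
                                    duration_h = 48,
                                    truth = NULL) {
  if (spec$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (is.null(truth))
    truth <- list(descriptors = c("ALOGP", "MW", "TPSA"),
                  coefficients = c(-1.2, -0.6, 0.4), intercept = 0.5)
  modeled <- library[library$role != "excludable", , drop = FALSE]
  parents <- unname(vapply(modeled$parent_smiles, function(s)
    standardizeStructure(s, neutralize = TRUE)$neutralized_smiles,
    character(1L)))
  desc <- computeDescriptors(parents, ids = modeled$cas)
  dm <- descriptorValues(desc$matrix)
  stopifnot(all(truth$descriptors %in% colnames(dm)),
            all(modeled$cas %in% rownames(dm)))
  dm <- dm[modeled$cas, , drop = FALSE]
  Z <- scale(dm[, truth$descriptors, drop = FALSE])
  Z[!is.finite(Z)] <- 0
  mws <- unname(vapply(parents, .molecularWeight, numeric(1L)))

  withSeed(seed, {
    nM <- nrow(modeled)
    yT <- truth$intercept + as.numeric(Z %*% truth$coefficients) +
      stats::rnorm(nM, 0, spec$noise_sd)
    mmol <- boxCoxInvert(yT, spec$true_lambda)
    bad <- !is.finite(mmol) | mmol <= 0
    mmol[bad] <- 1e-6   # inverse undefined at extreme draws; floor it

    # disjoint value-level categories among modeled compounds
    cats <- rep("clean", nM)
    nInf <- round(spec$inflated_fraction * nM)
    nSol <- round(spec$solubility_violation_fraction * nM)
    nOut <- round(spec$outlier_fraction * nM)
    pickable <- sample.int(nM)
    cats[pickable[seq_len(nInf)]] <- "inflated"
    cats[pickable[nInf + seq_len(nSol)]] <- "sol_violation"
    cats[pickable[nInf + nSol + seq_len(nOut)]] <- "outlier"
    mmol[cats == "outlier"] <- mmol[cats == "outlier"] * 1e6

    recs <- list(); bookRec <- list()
    compBook <- data.frame(cas = modeled$cas, category = cats,
                           true_mmol = mmol, mw = mws,
                           consolidated_mmol = NA_real_,
                           stringsAsFactors = FALSE)
    for (i in seq_len(nM)) {
      k <- 1L + stats::rpois(1L, spec$replicate_lambda)
      if (cats[i] == "inflated") k <- max(k, 2L)
      u <- stats::runif(k, -spec$replicate_spread / 2,
                        spec$replicate_spread / 2)
      vals <- mmol[i] * 10^u
      if (cats[i] == "inflated") vals[k] <- vals[k] * 10^1.5
      censored <- stats::runif(k) < spec$censored_fraction
      phadj <- !censored & stats::runif(k) < spec$ph_adjusted_fraction
      keptVals <- vals[!censored & !phadj]
      cons <- if (length(keptVals)) geometricMean(keptVals) else NA_real_
      compBook$consolidated_mmol[i] <- cons
      sol <- if (is.na(cons)) NA_real_
        else if (cats[i] == "sol_violation") cons * 0.5
        else if (stats::runif(1L) < 0.5) cons * 100 else NA_real_
      qualifier <- ifelse(censored,
                          sample(c("greater_than", "less_than",
                                   "approximate"), k, replace = TRUE),
                          "exact")
      recs[[i]] <- data.frame(
        cas = modeled$cas[i], name = paste0("cmpd-", modeled$cas[i]),
        smiles = modeled$smiles[i], endpoint = endpoint,
        species = species, duration_h = duration_h,
        value_mg_l = vals * mws[i], qualifier = qualifier,
        ph_adjusted = phadj,
        solubility_mg_l = if (is.na(sol)) NA_real_ else sol * mws[i],
        source = "synthetic", stringsAsFactors = FALSE)
      bookRec[[i]] <- data.frame(cas = modeled$cas[i],
                                 replicate = seq_len(k),
                                 censored = censored, ph_adjusted = phadj,
                                 mmol = vals, stringsAsFactors = FALSE)
    }
    # records for excludable compounds (clean values; structure must fail)
    excl <- library[library$role == "excludable", , drop = FALSE]
    if (nrow(excl)) {
      exclRecs <- data.frame(
        cas = excl$cas, name = paste0("cmpd-", excl$cas),
        smiles = excl$smiles, endpoint = endpoint, species = species,
        duration_h = duration_h,
        value_mg_l = stats::rlnorm(nrow(excl), 1, 1),
        qualifier = "exact", ph_adjusted = FALSE,
        solubility_mg_l = NA_real_, source = "synthetic",
        stringsAsFactors = FALSE)
      recs[[length(recs) + 1L]] <- exclRecs
    }
    records <- do.call(rbind, recs)
    records <- records[order(records$cas), , drop = FALSE]
    rownames(records) <- NULL
    list(records = records, truth = truth,
         bookkeeping = list(records = do.call(rbind, bookRec),
                            compounds = compBook,
                            excludable = excl$cas),
         descriptors = desc$matrix)
  })
}

#' Generate a regression benchmark with known informative variables
#'
#' X is standard normal (optionally with an AR(1)-correlated block); the
#' response is linear in `p_informative` columns plus Gaussian noise. The
#' returned truth names the informative columns for recovery tests.
#'
#' @param n rows.
#' @param p columns.
#' @param p_informative number of informative columns (named inf01...).
#' @param noise_sd noise standard deviation.
#' @param seed RNG seed.
#' @param rho optional AR(1) correlation within the noise block.
#' @param coefficients optional coefficient vector (default magnitudes
#'   drawn in [0.5, 1.5] with random signs).
#' @return list with X (matrix), y, truth (informative_names,
#'   coefficients, noise_sd).
#' @export
generateRegressionBenchmark <- function(n, p, p_informative, noise_sd,
                                        seed = 1L, rho = 0,
                                        coefficients = NULL) {
  stopifnot(p_informative <= p)
  withSeed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0 && p > p_informative + 1L) {
      for (j in (p_informative + 2L):p)
        X[, j] <- rho * X[, j - 1L] + sqrt(1 - rho^2) * X[, j]
    }
    colnames(X) <- c(sprintf("inf%02d", seq_len(p_informative)),
                     sprintf("noise%03d", seq_len(p - p_informative)))
    beta <- coefficients %||%
      (stats::runif(p_informative, 0.5, 1.5) *
         sample(c(-1, 1), p_informative, replace = TRUE))
    y <- as.numeric(X[, seq_len(p_informative), drop = FALSE] %*% beta) +
      stats::rnorm(n, 0, noise_sd)
    list(X = X, y = y,
         truth = list(informative_names = colnames(X)[seq_len(p_informative)],
                      coefficients = beta, noise_sd = noise_sd))
  })
}
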