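# Structure standardization: canonical SMILES, counter-ion stripping,
# charge neutralization, structural exclusion taxonomy, and the
# pH-microspecies stability screen used for algal datasets.

.METALS <- c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba",
             "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
             "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
             "La", "Ce", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au",
             "Hg", "Al", "Ga", "In", "Tl", "Sn", "Pb", "Bi")

.ELEMENT_WHITELIST <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                        "B", "Si", "Se")

# one call to OpenBabel for a vector of SMILES; returns canonical SMILES
# (NA where OpenBabel produced nothing)
.obCanonical <- function(smiles, neutralize = FALSE) {
  stopifnot(is.character(smiles))
  ids <- sprintf("m%06d", seq_along(smiles))
  src <- paste0(paste(smiles, ids), "\n", collapse = "")
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else
    data.frame(names = character(0), args = character(0))
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = src, options = opts),
    error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- stats::setNames(rep(NA_character_, length(smiles)), ids)
  for (p in parts) {
    if (length(p) >= 2L) {
      id <- trimws(p[2L])
      if (id %in% ids) res[id] <- trimws(p[1L])
    }
  }
  unname(res)
}

.heavyAtomCount <- function(smiles) {
  el <- smilesElements(smiles)
  sum(el != "H")
}

#' Standardize a chemical structure
#'
#' Canonicalizes a SMILES string, strips disconnected counter-ion and
#' carbon-free fragments (keeping the largest organic component), and
#' neutralizes residual formal charges where valence allows. Algal
#' datasets, where the ionized form at assay pH is the relevant species,
#' can switch neutralization off via `neutralize = FALSE`.
#'
#' @param smiles single SMILES string.
#' @param stripSalts remove counter-ion/solvent fragments (default TRUE).
#' @param neutralize neutralize residual formal charges (default TRUE).
#' @return list with `normalized_smiles` (canonical form of the input),
#'   `neutralized_smiles` (canonical form after stripping/neutralization),
#'   and `flags` (character subset of {"salt_stripped", "neutralized"}).
#' @details Fragments are removed only when at least one component contains
#'   carbon; the parent is the component with the most heavy atoms (ties:
#'   more carbons, then lexicographic). Non-parent components are dropped
#'   when charged or carbon-free; residual neutral organic components are
#'   kept (the compound is later excluded as a mixture). Throws a
#'   structured parse error (class `aquatox_parse_error`) on malformed
#'   input.
#' @export
standardizeStructure <- function(smiles, stripSalts = TRUE, neutralize = TRUE) {
  validateSmiles(smiles)
  normalized <- .obCanonical(smiles)
  if (is.na(normalized) || !nzchar(normalized))
    smilesParseError(smiles, "toolkit could not interpret structure")
  flags <- character(0)
  comps <- smilesComponents(normalized)
  hasC <- vapply(comps, function(s) "C" %in% smilesElements(s), logical(1L))
  work <- normalized
  if (stripSalts && length(comps) > 1L && any(hasC)) {
    heavy <- vapply(comps, .heavyAtomCount, numeric(1L))
    ncarb <- vapply(comps, function(s) sum(smilesElements(s) == "C"),
                    numeric(1L))
    ord <- order(-heavy, -ncarb, comps)
    parent <- ord[1L]
    keep <- rep(FALSE, length(comps))
    keep[parent] <- TRUE
    for (i in seq_along(comps)) {
      if (i == parent) next
      charged <- smilesNetCharge(comps[i]) != 0L
      keep[i] <- !charged && hasC[i]   # neutral organics stay (mixtures)
    }
    if (any(!keep)) flags <- c(flags, "salt_stripped")
    work <- paste(comps[keep], collapse = ".")
  }
  canonStripped <- .obCanonical(work)
  if (is.na(canonStripped)) canonStripped <- work
  neutralized <- canonStripped
  if (neutralize) {
    neu <- .obCanonical(work, neutralize = TRUE)
    if (!is.na(neu) && nzchar(neu)) {
      if (!identical(neu, canonStripped)) flags <- c(flags, "neutralized")
      neutralized <- neu
    }
  }
  list(normalized_smiles = normalized, neutralized_smiles = neutralized,
       flags = flags)
}

#' Classify a standardized structure for QSAR eligibility
#'
#' Applies the structural exclusion taxonomy used when pruning toxicity
#' datasets before descriptor calculation: metal complexes, inorganics,
#' mixtures/disconnected structures, ambiguous structures, and elements
#' outside the supported organic set. Dataset-level categories that cannot
#' be read off a structure (UVCBs, isomer mixtures, non-ionic surfactants,
#' name/CAS mismatches) enter through metadata flags.
#'
#' @param neutralizedSmiles standardized (stripped/neutralized) SMILES.
#' @param metadata optional named logical vector/list with any of
#'   `uvcb`, `isomer_mixture`, `nonionic_surfactant`, `name_cas_mismatch`.
#' @return list with `keep` (logical) and `reason` (NA when kept; one of
#'   "uvcb", "isomer_mixture", "nonionic_surfactant", "name_cas_mismatch",
#'   "ambiguous", "metal_complex", "inorganic", "mixture",
#'   "unsupported_element").
#' @export
classifyStructure <- function(neutralizedSmiles, metadata = list()) {
  md <- function(key) isTRUE(metadata[[key]])
  for (key in c("uvcb", "isomer_mixture", "nonionic_surfactant",
                "name_cas_mismatch"))
    if (md(key)) return(list(keep = FALSE, reason = key))
  el <- smilesElements(neutralizedSmiles)
  if ("*" %in% el) return(list(keep = FALSE, reason = "ambiguous"))
  if (!("C" %in% el)) return(list(keep = FALSE, reason = "inorganic"))
  if (any(el %in% .METALS))
    return(list(keep = FALSE, reason = "metal_complex"))
  if (length(smilesComponents(neutralizedSmiles)) > 1L)
    return(list(keep = FALSE, reason = "mixture"))
  if (any(!el %in% .ELEMENT_WHITELIST))
    return(list(keep = FALSE, reason = "unsupported_element"))
  list(keep = TRUE, reason = NA_character_)
}

#' Default pKa lookup table for the microspecies screen
#'
#' SMARTS-group heuristic standing behind the pluggable pKa interface.
#' Each row assigns one ionizable group class a representative pKa; `type`
#' says whether the group loses ("acid") or gains ("base") a proton.
#'
#' @return data.frame with columns group, smarts, type, pka.
#' @export
defaultPkaTable <- function() {
  data.frame(
    group = c("sulfonic_acid", "carboxylic_acid", "phenol", "thiol",
              "aliphatic_amine", "aniline", "pyridine"),
    smarts = c("[SX4](=O)(=O)[OX2H1]",
               "[CX3](=O)[OX2H1]",
               "[OX2H1][cX3]",
               "[SX2H1]",
               "[NX3;!$([NX3][CX3]=[OX1]);!$([NX3]c);!$([NX3]=*)]",
               "[NX3;!$([NX3][CX3]=[OX1])]c",
               "[nX2]"),
    type = c("acid", "acid", "acid", "acid", "base", "base", "base"),
    pka = c(-1.0, 4.2, 9.9, 10.5, 10.0, 4.6, 5.2),
    stringsAsFactors = FALSE)
}

#' Screen a structure for pH-dependent microspecies changes
#'
#' Predicts, for every ionizable group found by the pKa plugin, the major
#' microspecies at two pH values (Henderson-Hasselbalch majority rule: an
#' acid group is deprotonated iff pH > pKa, a base group protonated iff
#' pH < pKa). A compound is "unstable" when any group changes state
#' between the two pH values, i.e. its dominant SMILES depends on the
#' growth medium. Applied to algal datasets, where either of two media
#' (pH 7.5 and pH 8.1) may have been used.
#'
#' @param smiles standardized SMILES string.
#' @param pkaTable plugin table as from [defaultPkaTable()].
#' @param phLow,phHigh the two growth-medium pH values (7.5 and 8.1).
#' @param onFailure what to do when the plugin fails: "unknown" (default),
#'   "stable" or "unstable".
#' @return one of "stable", "unstable", "unknown".
#' @export
microspeciesPhScreen <- function(smiles, pkaTable = defaultPkaTable(),
                                 phLow = 7.5, phHigh = 8.1,
                                 onFailure = c("unknown", "stable",
                                               "unstable")) {
  onFailure <- match.arg(onFailure)
  res <- tryCatch({
    sdf <- ChemmineR::smiles2sdf(smiles)
    ChemmineR::cid(sdf) <- "query"
    unstable <- FALSE
    for (i in seq_len(nrow(pkaTable))) {
      hits <- ChemmineR::smartsSearchOB(sdf, pkaTable$smarts[i],
                                         uniqueMatches = FALSE)
      if (hits[1L] > 0) {
        pka <- pkaTable$pka[i]
        if (pkaTable$type[i] == "acid") {
          # deprotonated iff pH > pKa; state differs iff pKa in [lo, hi)
          if (pka >= phLow && pka < phHigh) unstable <- TRUE
        } else {
          # protonated iff pH < pKa; state differs iff pKa in (lo, hi]
          if (pka > phLow && pka <= phHigh) unstable <- TRUE
        }
      }
    }
    if (unstable) "unstable" else "stable"
  }, error = function(e) NA_character_)
  if (is.na(res)) return(switch(onFailure, unknown = "unknown",
                                stable = "stable", unstable = "unstable"))
  res
}
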