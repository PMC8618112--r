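# Open 2D descriptor engine (OpenBabel-backed) and the two pruning rules
# (zero variance, pairwise |r| > 0.95).

.CRIPPEN_ELEMENTS <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I")

.SMARTS_DESCRIPTORS <- c(
  nAmide   = "[NX3][CX3](=[OX1])",
  nNitro   = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
  nSulfonyl = "[SX4](=[OX1])(=[OX1])",
  nPhenolOH = "[OX2H1][cX3]",
  nAromN   = "[nX2]",
  nRotB    = "[!D1;!$(*#*)]-!@[!D1;!$(*#*)]"
)

# element counts from a molecular formula string like "C7H8N2O"
.parseFormula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1L]]
  toks <- regmatches(formula, list(m))[[1L]]
  out <- integer(0)
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- sub("^[A-Za-z]+", "", t)
    prev <- if (el %in% names(out)) out[[el]] else 0L
    out[el] <- prev + (if (nzchar(n)) as.integer(n) else 1L)
  }
  out
}

# graph indices from a bond-order adjacency matrix (heavy atoms)
.graphIndices <- function(con) {
  nA <- nrow(con)
  adj <- (con > 0) * 1L
  deg <- rowSums(adj)
  nB <- sum(adj) / 2
  nDouble <- sum(con == 2) / 2
  nTriple <- sum(con == 3) / 2
  zagreb1 <- sum(deg^2)
  edges <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  zagreb2 <- if (nrow(edges)) sum(deg[edges[, 1]] * deg[edges[, 2]]) else 0
  chi0 <- sum(ifelse(deg > 0, 1 / sqrt(deg), 0))
  chi1 <- if (nrow(edges))
    sum(1 / sqrt(deg[edges[, 1]] * deg[edges[, 2]])) else 0
  # all-pairs shortest paths by BFS per atom (molecules are small)
  wiener <- 0; diam <- 0
  if (nA > 1 && nB > 0) {
    nbr <- apply(adj == 1L, 1L, which, simplify = FALSE)
    for (s in seq_len(nA)) {
      distv <- rep(NA_integer_, nA); distv[s] <- 0L
      frontier <- s; d <- 0L
      while (length(frontier)) {
        d <- d + 1L
        nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
        nxt <- nxt[is.na(distv[nxt])]
        distv[nxt] <- d
        frontier <- nxt
      }
      distv[is.na(distv)] <- 0L   # disconnected pairs contribute 0
      wiener <- wiener + sum(distv)
      diam <- max(diam, max(distv))
    }
    wiener <- wiener / 2
  }
  c(nBonds = nB, nDouble = nDouble, nTriple = nTriple,
    meanDeg = if (nA) mean(deg) else 0, maxDeg = if (nA) max(deg) else 0,
    nBranch = sum(deg >= 3), Zagreb1 = zagreb1, Zagreb2 = zagreb2,
    Chi0 = chi0, Chi1 = chi1, Wiener = wiener, Diameter = diam)
}

#' Compute 2D molecular descriptors
#'
#' Computes a conformation-free 2D descriptor block per compound:
#' physicochemical properties from the OpenBabel toolkit (Ghose-Crippen
#' style logP, molar refractivity, TPSA, H-bond acceptor/donor counts),
#' constitutional counts from the molecular formula, functional-group and
#' SMARTS-pattern counts, and topological indices (Zagreb, Randic
#' connectivity, Wiener, diameter) from the heavy-atom graph.
#'
#' Compounds whose logP descriptor cannot be computed - including any with
#' elements outside the Crippen parameterization - are dropped and listed,
#' mirroring the role of logP as the descriptor most closely tied to
#' aquatic toxicity. Columns with non-finite values for any retained
#' compound are removed.
#'
#' @param smiles character vector of standardized SMILES.
#' @param ids compound identifiers (default names of `smiles` or
#'   cmp00001-style).
#' @return list with `matrix` (a \linkS4class{DescriptorMatrix}) and
#'   `dropped` (data.frame id/reason).
#' @export
computeDescriptors <- function(smiles, ids = NULL) {
  if (!length(smiles)) stop("no compounds supplied", call. = FALSE)
  if (is.null(ids)) ids <- names(smiles) %||% sprintf("cmp%05d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))

  dropped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(id, reason)
    rbind(dropped, data.frame(id = id, reason = reason,
                              stringsAsFactors = FALSE))

  rows <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    smi <- smiles[i]
    row <- tryCatch(.describeOne(smi), error = function(e) NULL)
    if (is.null(row)) { dropped <- drop(ids[i], "invalid_structure"); next }
    if (!is.finite(row[["ALOGP"]])) {
      dropped <- drop(ids[i], "alogp_not_computable"); next }
    rows[[i]] <- row
  }
  keep <- !vapply(rows, is.null, logical(1L))
  if (!any(keep))
    stop("no compound yielded a descriptor row", call. = FALSE)
  m <- do.call(rbind, rows[keep])
  rownames(m) <- ids[keep]
  # drop columns that are non-finite for any retained compound
  badCols <- colnames(m)[apply(m, 2L, function(cl) any(!is.finite(cl)))]
  if (length(badCols)) m <- m[, setdiff(colnames(m), badCols), drop = FALSE]
  dm <- new("DescriptorMatrix", values = m,
            provenance = paste0("aquatox-2d/openbabel-",
                                utils::packageVersion("ChemmineOB")),
            pruneLog = if (length(badCols))
              paste("removed non-finite columns:",
                    paste(badCols, collapse = ",")) else character(0))
  list(matrix = dm, dropped = dropped)
}

# descriptor vector for a single standardized SMILES
.describeOne <- function(smi) {
  el <- smilesElements(smi)
  sdf <- ChemmineR::smiles2sdf(smi)
  ChemmineR::cid(sdf) <- "q"
  if (!ChemmineR::validSDF(sdf)) stop("invalid structure")
  p <- ChemmineR::propOB(sdf)
  logP <- as.numeric(p$logP[1L])
  if (any(!el %in% .CRIPPEN_ELEMENTS)) logP <- NA_real_
  fl <- .parseFormula(as.character(p$formula[1L]))
  cnt <- function(e) if (e %in% names(fl)) as.numeric(fl[[e]]) else 0
  nHeavy <- sum(fl[setdiff(names(fl), "H")])
  nHal <- cnt("F") + cnt("Cl") + cnt("Br") + cnt("I")
  mw <- as.numeric(p$MW[1L])
  base <- c(ALOGP = logP, MR = as.numeric(p$MR[1L]),
            TPSA = as.numeric(p$TPSA[1L]),
            HBA1 = as.numeric(p$HBA1[1L]), HBA2 = as.numeric(p$HBA2[1L]),
            HBD = as.numeric(p$HBD[1L]),
            MW = mw, AMW = mw / max(nHeavy, 1),
            nC = cnt("C"), nH = cnt("H"), nN = cnt("N"), nO = cnt("O"),
            nS = cnt("S"), nP = cnt("P"), nF = cnt("F"), nCl = cnt("Cl"),
            nBr = cnt("Br"), nI = cnt("I"), nHeavy = nHeavy, nHal = nHal,
            HeteroFrac = (nHeavy - cnt("C")) / max(nHeavy, 1),
            HperC = cnt("H") / max(cnt("C"), 1))
  rng <- tryCatch(ChemmineR::rings(sdf, type = "count", arom = TRUE),
                  error = function(e) c(RINGS = 0, AROMATIC = 0))
  if (is.matrix(rng) || is.data.frame(rng)) rng <- unlist(rng[1L, ])
  ringc <- c(nRings = as.numeric(rng[["RINGS"]]),
             nAromRings = as.numeric(rng[["AROMATIC"]]))
  grp <- tryCatch(ChemmineR::groups(sdf, groups = "fctgroup",
                                    type = "countMA"),
                  error = function(e) NULL)
  gr <- if (is.null(grp)) stats::setNames(rep(0, 12),
    c("RNH2", "R2NH", "R3N", "ROPO3", "ROH", "RCHO", "RCOR", "RCOOH",
      "RCOOR", "ROR", "RCCH", "RCN")) else {
    v <- as.numeric(grp[1L, ]); names(v) <- colnames(grp); v }
  sm <- vapply(.SMARTS_DESCRIPTORS, function(pat)
    tryCatch(as.numeric(ChemmineR::smartsSearchOB(sdf, pat,
                                                  uniqueMatches = FALSE)[1L]),
             error = function(e) 0), numeric(1L))
  con <- tryCatch(ChemmineR::conMA(sdf)[[1L]],
                  error = function(e) matrix(0, 1, 1))
  if (is.null(con) || !is.matrix(con)) con <- matrix(0, 1, 1)
  gi <- .graphIndices(con)
  c(base, ringc, gr, sm, gi)
}

#' Remove constant descriptors
#'
#' Eliminates every column whose variance is (numerically) zero; variances
#' below 1e-12 count as zero to avoid downstream blowups.
#'
#' @param m a \linkS4class{DescriptorMatrix}.
#' @return pruned \linkS4class{DescriptorMatrix} (values of surviving
#'   columns untouched). All-constant input yields an empty matrix with a
#'   warning.
#' @export
pruneConstant <- function(m) {
  stopifnot(is(m, "DescriptorMatrix"))
  v <- m@values
  vars <- apply(v, 2L, stats::var)
  keep <- which(vars > 1e-12)
  if (!length(keep))
    warning("all descriptors constant; returning empty matrix")
  removed <- setdiff(colnames(v), colnames(v)[keep])
  new("DescriptorMatrix", values = v[, keep, drop = FALSE],
      provenance = m@provenance,
      pruneLog = c(m@pruneLog,
                   sprintf("constant pruning removed %d columns%s",
                           length(removed),
                           if (length(removed))
                             paste0(": ", paste(removed, collapse = ","))
                           else "")))
}

#' Remove highly correlated descriptors
#'
#' Iteratively removes the column with the most partners at |Pearson r| >
#' `rMax` until no pair violates the bound. Ties are broken by the higher
#' mean |r| over violating partners, then by lexicographic name, making
#' the removal deterministic and close to minimal.
#'
#' @param m a \linkS4class{DescriptorMatrix} without constant columns.
#' @param rMax correlation bound (default 0.95).
#' @return pruned \linkS4class{DescriptorMatrix}.
#' @export
pruneCorrelated <- function(m, rMax = 0.95) {
  stopifnot(is(m, "DescriptorMatrix"))
  v <- m@values
  if (ncol(v) < 2L) return(m)
  cm <- abs(stats::cor(v))
  diag(cm) <- 0
  removed <- character(0)
  repeat {
    viol <- cm > rMax
    counts <- rowSums(viol)
    if (!any(counts > 0)) break
    mx <- max(counts)
    cand <- names(counts)[counts == mx]
    if (length(cand) > 1L) {
      mr <- vapply(cand, function(nm) mean(cm[nm, viol[nm, ]]), numeric(1L))
      cand <- cand[mr == max(mr)]
      cand <- sort(cand)
    }
    out <- cand[1L]
    removed <- c(removed, out)
    keep <- setdiff(rownames(cm), out)
    cm <- cm[keep, keep, drop = FALSE]
  }
  new("DescriptorMatrix",
      values = v[, setdiff(colnames(v), removed), drop = FALSE],
      provenance = m@provenance,
      pruneLog = c(m@pruneLog,
                   sprintf("correlation pruning (|r| > %g) removed %d columns",
                           rMax, length(removed))))
}
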