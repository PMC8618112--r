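# Light SMILES tokenizer used for validation, component splitting and
# element extraction. This is deliberately not a full SMILES parser: ring
# and bond semantics are delegated to OpenBabel, which however accepts (and
# silently repairs) some malformed strings, so strict validation has to
# happen here before any toolkit call.

.ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "S", "P", "F", "I",
                     "b", "c", "n", "o", "s", "p")

.SMILES_TOKEN_RE <- paste0(
  "\\[[^\\[\\]]+\\]",          # bracket atom
  "|Cl|Br",                    # two-letter organic subset
  "|[BCNOSPFI]",               # one-letter organic subset
  "|[bcnosp]",                 # aromatic subset
  "|%[0-9]{2}|[0-9]",          # ring bond closures
  "|[-=#$:/\\\\().+@]"         # bonds, branches, dot, stereo leftovers
)

.BRACKET_ELEMENT_RE <- "^\\[([0-9]*)([A-Z][a-z]?|[bcnops]|\\*)"

#' Validate a SMILES string
#'
#' Checks token grammar, balanced parentheses and brackets, and paired ring
#' closures. Returns `TRUE` invisibly or throws a structured parse error
#' (condition class `aquatox_parse_error`) carrying the offending input.
#'
#' @param smiles single SMILES string.
#' @return `TRUE` (invisibly) when valid.
#' @export
validateSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    smilesParseError(smiles, "empty or non-character SMILES")
  toks <- .tokenizeSmiles(smiles)
  if (is.null(toks))
    smilesParseError(smiles, "unrecognized token")
  depth <- 0L
  for (t in toks) {
    if (t == "(") depth <- depth + 1L
    if (t == ")") { depth <- depth - 1L
      if (depth < 0L) smilesParseError(smiles, "unbalanced ')'") }
  }
  if (depth != 0L) smilesParseError(smiles, "unbalanced '('")
  ring <- toks[grepl("^%[0-9]{2}$|^[0-9]$", toks)]
  if (length(ring)) {
    cnt <- table(ring)
    if (any(cnt %% 2L != 0L))
      smilesParseError(smiles, "unpaired ring-bond closure")
  }
  atoms <- toks[.isAtomToken(toks)]
  if (!length(atoms)) smilesParseError(smiles, "no atoms")
  invisible(TRUE)
}

smilesParseError <- function(smiles, reason) {
  stop(structure(class = c("aquatox_parse_error", "error", "condition"),
                 list(message = sprintf("cannot parse SMILES '%s': %s",
                                        as.character(smiles)[1L], reason),
                      call = NULL, smiles = smiles, reason = reason)))
}

.tokenizeSmiles <- function(smiles) {
  m <- gregexpr(.SMILES_TOKEN_RE, smiles, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(NULL)
  toks <- regmatches(smiles, list(m))[[1L]]
  if (sum(nchar(toks)) != nchar(smiles)) return(NULL)
  toks
}

.isAtomToken <- function(toks) {
  grepl("^\\[", toks) | toks %in% .ORGANIC_SUBSET
}

#' Extract element symbols from a SMILES string
#'
#' @param smiles single SMILES string (assumed valid).
#' @return character vector of element symbols, one per atom, in order.
#' @export
smilesElements <- function(smiles) {
  toks <- .tokenizeSmiles(smiles)
  if (is.null(toks)) smilesParseError(smiles, "unrecognized token")
  atoms <- toks[.isAtomToken(toks)]
  vapply(atoms, function(a) {
    if (startsWith(a, "[")) {
      el <- regmatches(a, regexec(.BRACKET_ELEMENT_RE, a))[[1L]][3L]
      if (is.na(el) || el == "*") return("*")
      # aromatic bracket atoms (e.g. [nH]) are lower case
      if (el %in% c("b", "c", "n", "o", "p", "s")) el <- toupper(el)
      el
    } else if (a %in% c("b", "c", "n", "o", "p", "s")) {
      toupper(a)
    } else a
  }, character(1L), USE.NAMES = FALSE)
}

# split a SMILES into dot-separated components (dots never occur inside
# brackets, so a character scan suffices)
smilesComponents <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  out <- character(0); buf <- character(0); inBracket <- FALSE
  for (ch in chars) {
    if (ch == "[") inBracket <- TRUE
    if (ch == "]") inBracket <- FALSE
    if (ch == "." && !inBracket) { out <- c(out, paste(buf, collapse = ""))
      buf <- character(0) } else buf <- c(buf, ch)
  }
  c(out, paste(buf, collapse = ""))
}

# net formal charge read off bracket atoms
smilesNetCharge <- function(smiles) {
  toks <- .tokenizeSmiles(smiles)
  if (is.null(toks)) smilesParseError(smiles, "unrecognized token")
  br <- toks[startsWith(toks, "[")]
  if (!length(br)) return(0L)
  chg <- vapply(br, function(a) {
    body <- sub("^\\[", "", sub("\\]$", "", a))
    m <- regmatches(body, gregexpr("[+-][0-9]*", body))[[1L]]
    if (!length(m)) return(0L)
    sum(vapply(m, function(s) {
      sign <- if (startsWith(s, "+")) 1L else -1L
      num <- sub("^[+-]", "", s)
      sign * (if (nzchar(num)) as.integer(num) else 1L)
    }, integer(1L)))
  }, integer(1L))
  sum(chg)
}
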