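# internal helpers shared across modules

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package functions do
#' not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @export
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# linear-interpolated percentile; p = 1 returns the maximum
percentile <- function(x, p) {
  stopifnot(length(x) >= 1L, all(is.finite(x)), p >= 0, p <= 1)
  unname(stats::quantile(x, probs = p, type = 7))
}

# round-half-up (R's round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

geometricMean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# column autoscaling with frozen statistics; zero-SD columns scaled by 1
scaleBy <- function(m, center, sdev) {
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  sweep(sweep(m, 2L, center, "-"), 2L, sdev, "/")
}

colStats <- function(m) {
  list(center = colMeans(m), sdev = apply(m, 2L, stats::sd))
}

# pairwise distances from rows of `a` to rows of `b`
rowDistances <- function(a, b, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  a <- as.matrix(a); b <- as.matrix(b)
  out <- matrix(0, nrow(a), nrow(b))
  if (metric == "euclidean") {
    for (j in seq_len(nrow(b)))
      out[, j] <- sqrt(rowSums(sweep(a, 2L, b[j, ], "-")^2))
  } else {
    for (j in seq_len(nrow(b)))
      out[, j] <- rowSums(abs(sweep(a, 2L, b[j, ], "-")))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
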