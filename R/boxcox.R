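# Box-Cox response normalization: profile-likelihood lambda fit by
# golden-section search, forward/inverse transform, +/- 3 SD outlier rule.

#' Box-Cox transform values at a given lambda
#'
#' (x^lambda - 1)/lambda for lambda != 0, ln(x) for lambda = 0. To keep the
#' map continuous in lambda, |lambda| below 1e-10 is treated as 0.
#'
#' @param x positive numeric vector.
#' @param lambda power parameter.
#' @return transformed values.
#' @export
boxCoxApply <- function(x, lambda) {
  stopifnot(all(x > 0))
  if (abs(lambda) < 1e-10) log(x) else (x^lambda - 1) / lambda
}

#' Invert the Box-Cox transform
#'
#' @param t transformed values.
#' @param lambda power parameter.
#' @return original-scale values; NA where the inverse is undefined
#'   (lambda * t + 1 <= 0).
#' @export
boxCoxInvert <- function(t, lambda) {
  if (abs(lambda) < 1e-10) return(exp(t))
  base <- lambda * t + 1
  out <- rep(NA_real_, length(t))
  ok <- base > 0
  out[ok] <- base[ok]^(1 / lambda)
  out
}

# profile log-likelihood of the normal Box-Cox model at lambda
.boxCoxLogLik <- function(x, lambda) {
  n <- length(x)
  t <- boxCoxApply(x, lambda)
  s2 <- stats::var(t) * (n - 1) / n        # MLE variance
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

#' Fit a Box-Cox transform by profile likelihood
#'
#' Finds the lambda maximizing the profile log-likelihood of the normal
#' Box-Cox model over `interval` by golden-section search, then records the
#' mean and sample standard deviation (n - 1 denominator) of the
#' transformed values, which drive the +/- 3 SD outlier rule.
#'
#' @param values positive responses (mmol/L), n >= 3.
#' @param interval lambda search interval (default c(-2, 2)).
#' @param tol golden-section convergence tolerance on lambda.
#' @return list with `transform` (a \linkS4class{BoxCoxTransform}) and
#'   `transformed` (the transformed values).
#' @export
fitBoxCox <- function(values, interval = c(-2, 2), tol = 1e-6) {
  if (length(values) < 3L)
    stop("Box-Cox fitting needs at least 3 values", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("Box-Cox fitting needs positive finite values", call. = FALSE)
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  f <- function(l) .boxCoxLogLik(values, l)
  phi <- (sqrt(5) - 1) / 2
  a <- interval[1]; b <- interval[2]
  c1 <- b - phi * (b - a); d1 <- a + phi * (b - a)
  fc <- f(c1); fd <- f(d1)
  while (b - a > tol) {
    if (fc >= fd) { b <- d1; d1 <- c1; fd <- fc
      c1 <- b - phi * (b - a); fc <- f(c1)
    } else { a <- c1; c1 <- d1; fc <- fd
      d1 <- a + phi * (b - a); fd <- f(d1) }
  }
  lambda <- (a + b) / 2
  t <- boxCoxApply(values, lambda)
  tr <- new("BoxCoxTransform", lambda = lambda, meanT = mean(t),
            sdT = stats::sd(t), interval = interval)
  list(transform = tr, transformed = t)
}

#' Apply the +/- 3 SD outlier rule on the transformed scale
#'
#' Retains index i iff |t_i - mean_t| <= 3 * sd_t, with mean_t and sd_t
#' frozen in the transform (single pass, never recomputed iteratively;
#' boundary values are retained). With sd_t = 0 every value is retained.
#'
#' @param transformed transformed responses.
#' @param transform fitted \linkS4class{BoxCoxTransform}.
#' @param nSd multiple of sd_t defining the band (default 3).
#' @return integer indices of retained values.
#' @export
excludeOutliers <- function(transformed, transform, nSd = 3) {
  stopifnot(is(transform, "BoxCoxTransform"))
  dev <- abs(transformed - transform@meanT)
  which(dev <= nSd * transform@sdT)
}
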