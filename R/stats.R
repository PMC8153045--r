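#' Pearson correlation with t-based p-value
#'
#' Two-sided p-value from the t transform \code{t = r sqrt((n - 2) / (1 -
#' r^2))} with \code{n - 2} degrees of freedom. With \code{nBoot > 0} a
#' percentile bootstrap 95\% CI over resampled observation pairs is added.
#' A perfect correlation (|r| = 1) is reported with p = 0.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both non-constant.
#' @param nBoot Bootstrap replicates for the CI (0 = no CI).
#' @param seed Optional integer seed for the bootstrap.
#' @return List with elements \code{r}, \code{p}, \code{ci95} (NULL or
#'   length-2 numeric), \code{n}.
#' @examples
#' pearsonTest(c(1, 2, 3, 4), c(2, 1, 4, 3))  # r = 0.6
#' @export
pearsonTest <- function(x, y, nBoot = 0, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  keep <- is.finite(x) & is.finite(y)
  if (!all(keep)) stop("x and y must be finite")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (!(sd(x) > 0) || !(sd(y) > 0)) stop("zero variance in x or y")
  r <- cor(x, y)
  p <- if (1 - r^2 <= 0) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  ci <- NULL
  if (nBoot > 0) {
    ci <- bootstrapCI(function(d) cor(d[, 1], d[, 2]), cbind(x, y),
                      nBoot = nBoot, seed = seed)
  }
  list(r = r, p = p, ci95 = ci, n = n)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (or elements, for a vector) of \code{data} with
#' replacement, applies \code{statistic}, and returns the 2.5/97.5 percentile
#' bounds (linear interpolation between order statistics). A resample on
#' which the statistic fails or is non-finite is redrawn with a warning; the
#' interval is deterministic under a fixed seed.
#'
#' @param statistic Function of one argument returning a numeric scalar.
#' @param data Vector, matrix or data.frame; rows are the resampling unit.
#' @param nBoot Number of bootstrap samples (default 1000).
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Numeric length-2 vector (low, high).
#' @export
bootstrapCI <- function(statistic, data, nBoot = 1000, seed = NULL,
                        conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 1L) stop("empty data")
  take <- if (is.null(dim(data))) function(i) data[i] else
    function(i) data[i, , drop = FALSE]
  out <- numeric(nBoot)
  warned <- FALSE
  for (b in seq_len(nBoot)) {
    val <- NA_real_
    tries <- 0L
    while (!is.finite(val)) {
      if (tries >= 100L) stop("statistic failed on 100 consecutive resamples")
      val <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                      error = function(e) NA_real_)
      if (!is.finite(val) && !warned) {
        warning("statistic failed on a bootstrap resample; redrawing")
        warned <- TRUE
      }
      tries <- tries + 1L
    }
    out[b] <- val
  }
  alpha <- (1 - conf) / 2
  unname(quantile(out, c(alpha, 1 - alpha), type = 7))
}

#' Benjamini-Hochberg FDR adjustment with rejection flags
#'
#' Step-up false discovery rate control: wraps \code{p.adjust(method = "BH")}
#' and flags hypotheses whose adjusted p-value is at most \code{q}.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with \code{adjusted} (monotone in the raw p) and
#'   \code{reject} (logical).
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))$reject  # all TRUE at q = 0.05
#' @export
bhAdjust <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}
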