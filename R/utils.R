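# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed from a root seed and a label
#'
#' Stages and per-cluster tests draw from independent RNG substreams so
#' that results do not depend on execution order.  The substream seed is
#' a polynomial string hash (base 31, modulus 2^31 - 1) of the root seed
#' together with the labels, e.g. `derive_seed(seed, "avoidance", cluster)`.
#'
#' @param seed Integer root seed.
#' @param ... Character or numeric labels identifying the substream.
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "/")
  m <- 2147483647
  h <- as.numeric(abs(as.integer(seed)) %% m)
  for (code in utf8ToInt(lab)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 2)) + 1L
}

#' Library-size log-normalization
#'
#' Scales every cell to a common library size and applies `log1p`, the
#' usual normalization on which expression correlations are computed.
#'
#' @param values genes x cells non-negative matrix.
#' @param scale_factor Target library size (default 1e4).
#' @return A dense matrix of the same shape.
#' @export
log_normalize <- function(values, scale_factor = 1e4) {
  values <- as.matrix(values)
  cs <- colSums(values)
  cs[cs == 0] <- 1
  log1p(sweep(values, 2, cs, "/") * scale_factor)
}

# Standardize matrix rows to mean 0, population sd 1 over the given
# columns; zero-variance rows become all-zero (flagged in an attribute).
standardize_rows <- function(values, cols = seq_len(ncol(values))) {
  x <- as.matrix(values[, cols, drop = FALSE])
  mu <- rowMeans(x)
  x <- x - mu
  sd_pop <- sqrt(rowMeans(x^2))
  degenerate <- sd_pop == 0
  sd_pop[degenerate] <- 1
  z <- x / sd_pop
  z[degenerate, ] <- 0
  attr(z, "degenerate") <- rownames(x)[degenerate]
  z
}

# Empirical permutation p-value from null replicates and an observed value.
# smooth = TRUE: (1 + #{null >= obs}) / (B + 1)  (add-one, ties count)
# smooth = FALSE, strict = TRUE:  #{null > obs} / B   (literal, avoidance)
# smooth = FALSE, strict = FALSE: #{null >= obs} / B  (literal, SFFL)
permutation_pvalue <- function(null_values, observed, smooth = TRUE, strict = FALSE) {
  B <- length(null_values)
  if (smooth) {
    (1 + sum(null_values >= observed, na.rm = TRUE) +
       sum(is.na(null_values))) / (B + 1)
  } else if (strict) {
    sum(null_values > observed, na.rm = TRUE) / B
  } else {
    sum(null_values >= observed, na.rm = TRUE) / B
  }
}

# Kolmogorov-Smirnov distance of a sample to Uniform(0, 1).
ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
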