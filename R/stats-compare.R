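# Distribution summaries, binned Kullback-Leibler divergence with bootstrap
# p-values, density peaks, and junction-level Pearson comparison.

# adjusted (bias-corrected) Fisher-Pearson skewness
.skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  g1 <- mean((x - mean(x))^3) / (mean((x - mean(x))^2))^(3 / 2)
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Summary of an asymmetry or angle distribution
#'
#' Mean, sample standard deviation and adjusted Fisher-Pearson skewness,
#' each with a standard error: SE(mean) = sd/sqrt(n) analytically, SE(sd)
#' and SE(skewness) by seeded nonparametric bootstrap.
#'
#' @param values numeric sample, n >= 3.
#' @param B bootstrap replicates for the sd/skewness standard errors.
#' @param seed integer seed for the bootstrap.
#' @return list of class `distribution_summary`: `n`, `mean`, `se_mean`,
#'   `sd`, `se_sd`, `skewness`, `se_skewness`, `degenerate` (TRUE for a
#'   constant sample, whose skewness is undefined).
#' @export
summarize_distribution <- function(values, B = 1000L, seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  s <- stats::sd(values)
  if (s == 0) {
    return(structure(list(n = n, mean = mean(values), se_mean = 0,
                          sd = 0, se_sd = 0, skewness = NA_real_,
                          se_skewness = NA_real_, degenerate = TRUE),
                     class = "distribution_summary"))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  boots <- matrix(sample(values, n * B, replace = TRUE), nrow = B)
  bsd <- apply(boots, 1L, stats::sd)
  bskew <- apply(boots, 1L, .skewness)
  structure(list(n = n, mean = mean(values), se_mean = s / sqrt(n),
                 sd = s, se_sd = stats::sd(bsd),
                 skewness = .skewness(values),
                 se_skewness = stats::sd(bskew, na.rm = TRUE),
                 degenerate = FALSE),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("n = %d  mean %.3f +/- %.3f  sd %.3f +/- %.3f  skew %.3f +/- %.3f\n",
              x$n, x$mean, x$se_mean, x$sd, x$se_sd, x$skewness, x$se_skewness))
  invisible(x)
}

#' Histogram binning specification
#'
#' Fixed, shared binning so KL comparisons are reproducible. Defaults:
#' 20 equal bins on [0, 1] for asymmetry ratios; use `angle_bins()` for
#' angles (30 bins on [0, pi]).
#'
#' @param n_bins number of equal-width bins.
#' @param range lower/upper edge of the binned range; values outside are
#'   clamped into the edge bins.
#' @return list of class `histogram_spec`.
#' @export
histogram_spec <- function(n_bins = 20L, range = c(0, 1)) {
  stopifnot(n_bins >= 2L, range[2L] > range[1L])
  structure(list(n_bins = as.integer(n_bins), range = as.numeric(range)),
            class = "histogram_spec")
}

#' @rdname histogram_spec
#' @export
angle_bins <- function() histogram_spec(30L, c(0, pi))

.binned_probs <- function(x, spec, pseudo = 0.5) {
  edges <- seq(spec$range[1L], spec$range[2L], length.out = spec$n_bins + 1L)
  x <- pmin(pmax(x, spec$range[1L]), spec$range[2L])
  cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = spec$n_bins)
  p <- cnt + pseudo
  p / sum(p)
}

#' Binned Kullback-Leibler divergence between two samples
#'
#' Discrete KL(P || Q) over a shared binning with a Jeffreys-style half
#' pseudo-count per bin before normalization (keeps the divergence finite
#' for disjoint supports). By convention P is the model sample and Q the
#' reference (real) sample; the divergence is asymmetric.
#'
#' @param p_sample,q_sample non-empty numeric samples.
#' @param bins a [histogram_spec()].
#' @return non-negative scalar.
#' @export
kl_divergence <- function(p_sample, q_sample, bins = histogram_spec()) {
  if (length(p_sample) == 0L || length(q_sample) == 0L)
    stop("samples must be non-empty")
  p <- .binned_probs(p_sample, bins)
  q <- .binned_probs(q_sample, bins)
  sum(p * log(p / q))
}

#' Bootstrap p-value for a KL comparison
#'
#' Null distribution: the KL divergence between a with-replacement resample
#' of the real sample of size floor(n/2) and the full real sample, repeated
#' B times — i.e. the divergence expected from sampling noise alone when the
#' model is the real distribution ("bootstrap samples up to half the size of
#' the real data"). The observed statistic is KL(model || real); the
#' p-value is the fraction of null draws at least as large, with a
#' +1/(B+1) continuity correction. A model identical to the real data gives
#' a large p-value; disjoint distributions give p <= 1/(B+1).
#'
#' @param real_sample reference sample.
#' @param model_sample sample to compare against the reference.
#' @param B number of bootstrap replicates (>= 100).
#' @param bins a [histogram_spec()].
#' @param seed integer seed.
#' @return list of class `kl_comparison`: `kl`, `p_value`, `n_bootstrap`,
#'   `bin_count`, `seed`.
#' @export
kl_bootstrap_pvalue <- function(real_sample, model_sample, B = 1000L,
                                bins = histogram_spec(), seed = 1L) {
  stopifnot(B >= 100L)
  if (length(real_sample) < 10L)
    warning("real sample has fewer than 10 values; p-value is unreliable")
  obs <- kl_divergence(model_sample, real_sample, bins)
  m <- max(2L, floor(length(real_sample) / 2))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  null <- vapply(seq_len(B), function(b) {
    kl_divergence(sample(real_sample, m, replace = TRUE), real_sample, bins)
  }, numeric(1L))
  p <- (sum(null >= obs) + 1) / (B + 1)
  structure(list(kl = obs, p_value = p, n_bootstrap = B,
                 bin_count = bins$n_bins, seed = seed),
            class = "kl_comparison")
}

#' @export
print.kl_comparison <- function(x, ...) {
  cat(sprintf("KL(model || real) = %.4f, bootstrap p = %.3f (B = %d, %d bins)\n",
              x$kl, x$p_value, x$n_bootstrap, x$bin_count))
  invisible(x)
}

#' Mode (peak) of a distribution
#'
#' Location of the sample mode: the argmax of a Gaussian kernel density
#' estimate on a 512-point grid (default bandwidth: Silverman's
#' rule-of-thumb, R's `bw.nrd0`), or the midpoint of the fullest histogram
#' bin. For multimodal samples the higher mode is returned.
#'
#' @param values numeric sample, n >= 30.
#' @param method `"density"` or `"histogram"`.
#' @param bins a [histogram_spec()] for the histogram method.
#' @return scalar peak location.
#' @export
peak_estimate <- function(values, method = c("density", "histogram"),
                          bins = histogram_spec()) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 30L) stop("need at least 30 values for a peak estimate")
  if (method == "density") {
    d <- stats::density(values, n = 512L)
    d$x[which.max(d$y)]
  } else {
    edges <- seq(bins$range[1L], bins$range[2L], length.out = bins$n_bins + 1L)
    cnt <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = bins$n_bins)
    (edges[which.max(cnt)] + edges[which.max(cnt) + 1L]) / 2
  }
}

#' Junction-level Pearson comparison of predicted vs actual angles
#'
#' Standard Pearson correlation with a two-sided p-value over paired
#' per-junction values (pairs with a missing prediction — degenerate
#' junctions — are dropped).
#'
#' @param actual,predicted paired numeric vectors.
#' @return list: `r`, `p_value`, `n`.
#' @export
pearson_junction_correlation <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  keep <- is.finite(actual) & is.finite(predicted)
  a <- actual[keep]; p <- predicted[keep]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(p) == 0)
    stop("zero variance in one of the vectors")
  ct <- stats::cor.test(a, p, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}
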