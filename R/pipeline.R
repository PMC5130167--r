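# Full-study orchestration: geometry -> MC optimization -> random ensembles
# -> statistical comparison, assembled into a Table-1-shaped report.

.study_row <- function(label, lambda_l, lambda_theta, real_l, real_theta,
                       B, seed, bins) {
  sl <- summarize_distribution(lambda_l, B = B, seed = seed)
  st <- summarize_distribution(lambda_theta, B = B, seed = seed + 1L)
  kl_l <- kl_bootstrap_pvalue(real_l, lambda_l, B = B, bins = bins,
                              seed = seed + 2L)
  kl_t <- kl_bootstrap_pvalue(real_theta, lambda_theta, B = B, bins = bins,
                              seed = seed + 3L)
  data.frame(source = label, n = sl$n,
             lambda_l_mean = sl$mean, lambda_l_se = sl$se_mean,
             lambda_l_sd = sl$sd, lambda_l_sd_se = sl$se_sd,
             lambda_l_skew = sl$skewness, lambda_l_skew_se = sl$se_skewness,
             lambda_l_kl_p = kl_l$p_value,
             lambda_theta_mean = st$mean, lambda_theta_se = st$se_mean,
             lambda_theta_sd = st$sd, lambda_theta_sd_se = st$se_sd,
             lambda_theta_skew = st$skewness,
             lambda_theta_skew_se = st$se_skewness,
             lambda_theta_kl_p = kl_t$p_value,
             stringsAsFactors = FALSE)
}

#' Run the full branching-asymmetry study on one network
#'
#' Orchestrates the complete analysis: junction geometry of the real
#' network, material-cost optimal predictions (per mode, with degeneracy
#' fractions and junction-level Pearson comparison), constrained-random
#' ensembles (per scheme), and a Table-1-shaped statistical comparison of
#' the length- and angle-asymmetry distributions (moments with SEs and
#' binned-KL bootstrap p-values against the real network). Deterministic
#' given `seed`.
#'
#' @param network a `vascular_network`, or a path to an angicart-style CSV.
#' @param modes material-cost modes to run (subset of `"surface_area"`,
#'   `"volume"`).
#' @param schemes random-simulation schemes to run (subset of `"local"`,
#'   `"intermediate1"`, `"intermediate2"`, `"global"`); empty to skip.
#' @param n_realizations realizations per scheme.
#' @param seed master integer seed for every stochastic stage.
#' @param B bootstrap replicates for SEs and KL p-values.
#' @param bins a [histogram_spec()] for the asymmetry-ratio KL binning.
#' @param output_dir optional directory; when given, the component tables
#'   are written as CSV and the summary as JSON.
#' @return list of class `vascbranch_study`: `geometry` (real per-junction
#'   table), `mc` (named list of per-mode tables), `degenerate_fraction`
#'   (per mode), `pearson` (per-mode junction-level angle correlation),
#'   `ensembles` (named list of [run_ensemble()] results), `table1`
#'   (comparison table), `peaks` (theta0 and theta1&2 density peaks, real
#'   and per mode), `provenance` (settings and seeds).
#' @export
run_study <- function(network,
                      modes = c("surface_area", "volume"),
                      schemes = c("local", "intermediate1", "intermediate2",
                                  "global"),
                      n_realizations = 100L, seed = 1L, B = 1000L,
                      bins = histogram_spec(), output_dir = NULL) {
  if (is.character(network)) network <- read_network(network)
  stopifnot(inherits(network, "vascular_network"))
  modes <- match.arg(modes, several.ok = TRUE)
  if (length(schemes) > 0L)
    schemes <- match.arg(schemes, c("local", "intermediate1", "intermediate2",
                                    "global"), several.ok = TRUE)
  geo <- junction_geometry(network)
  if (nrow(geo) < 3L) stop("stage geometry: need at least 3 bifurcations")
  safe_peak <- function(x) if (length(x) >= 30L) peak_estimate(x) else NA_real_
  peaks <- list(real = list(
    theta0 = safe_peak(geo$theta0),
    theta12 = safe_peak(c(geo$theta1, geo$theta2))))
  mc <- list(); degfrac <- list(); pearson <- list()
  for (mode in modes) {
    tab <- mc_optimize_network(network, mode)
    mc[[mode]] <- tab
    degfrac[[mode]] <- mean(tab$classification != "interior")
    ok <- tab$classification == "interior"
    if (sum(ok) >= 3L) {
      actual <- c(geo$theta0[ok], geo$theta1[ok], geo$theta2[ok])
      predicted <- c(tab$theta0_opt[ok], tab$theta1_opt[ok], tab$theta2_opt[ok])
      pearson[[mode]] <- pearson_junction_correlation(actual, predicted)
      peaks[[mode]] <- list(
        theta0 = safe_peak(tab$theta0_opt[ok]),
        theta12 = safe_peak(c(tab$theta1_opt[ok], tab$theta2_opt[ok])))
    }
  }
  ensembles <- list()
  for (sc in schemes)
    ensembles[[sc]] <- run_ensemble(network, sc, n_realizations, seed)
  rows <- list(.study_row("real", geo$lambda_l, geo$lambda_theta,
                          geo$lambda_l, geo$lambda_theta, B, seed, bins))
  for (mode in modes) {
    tab <- mc[[mode]]
    ok <- tab$classification == "interior"
    if (sum(ok) >= 3L)
      rows[[length(rows) + 1L]] <-
        .study_row(paste0("mc_", mode), tab$lambda_l_opt[ok],
                   tab$lambda_theta_opt[ok], geo$lambda_l, geo$lambda_theta,
                   B, seed, bins)
  }
  for (sc in schemes) {
    m <- ensembles[[sc]]$measurements
    rows[[length(rows) + 1L]] <-
      .study_row(sc, m$lambda_l, m$lambda_theta, geo$lambda_l,
                 geo$lambda_theta, B, seed, bins)
  }
  table1 <- do.call(rbind, rows)
  rownames(table1) <- NULL
  provenance <- list(seed = seed, n_realizations = n_realizations, B = B,
                     modes = modes, schemes = schemes,
                     bins = unclass(bins),
                     n_junctions = nrow(geo),
                     n_skipped = attr(geo, "n_skipped"),
                     package_version = as.character(utils::packageVersion("vascbranch")))
  out <- structure(list(geometry = geo, mc = mc,
                        degenerate_fraction = degfrac, pearson = pearson,
                        ensembles = ensembles, table1 = table1, peaks = peaks,
                        provenance = provenance),
                   class = "vascbranch_study")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(geo, file.path(output_dir, "geometry.csv"),
                     row.names = FALSE)
    for (mode in modes)
      utils::write.csv(mc[[mode]], file.path(output_dir,
                                             paste0("mc_", mode, ".csv")),
                       row.names = FALSE)
    for (sc in schemes)
      utils::write.csv(ensembles[[sc]]$measurements,
                       file.path(output_dir, paste0("ensemble_", sc, ".csv")),
                       row.names = FALSE)
    utils::write.csv(table1, file.path(output_dir, "table1.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(provenance = provenance,
                              degenerate_fraction = degfrac,
                              pearson = pearson, peaks = peaks),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.vascbranch_study <- function(x, ...) {
  cat("Branching-asymmetry study: ", x$provenance$n_junctions,
      " junctions\n", sep = "")
  cat("Comparison table (lambda_l / lambda_theta means):\n")
  print(x$table1[, c("source", "n", "lambda_l_mean", "lambda_l_kl_p",
                     "lambda_theta_mean", "lambda_theta_kl_p")],
        digits = 3L)
  invisible(x)
}
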