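## Pointwise bootstrap t-test between two cohorts of experiment-averaged
## time series, with tiered significance coding.

welch_t <- function(mA, vA, nA, mB, vB, nB) {
  denom <- sqrt(vA / nA + vB / nB)
  t <- (mA - mB) / denom
  t[denom == 0 & (mA - mB) == 0] <- 0
  t
}

#' Pointwise bootstrap t-test between two cohorts of time series
#'
#' For each of the shared time points, computes the Welch t statistic
#' between the columns (experiments) of `groupA` and `groupB`, and a
#' two-sided bootstrap p-value. The null distribution is built by the
#' shift method: each group's columns are re-centred on the pooled mean,
#' then experiments (whole columns — the resampling unit is the
#' experiment, preserving within-series autocorrelation) are resampled
#' with replacement within each group; one resample per iteration is
#' shared across all time points. `p = (1 + #{|t*| >= |t_obs|}) /
#' (n_iter + 1)`.
#'
#' An alternative null (`null = "pooled"`) resamples from the pooled,
#' uncentred columns.
#'
#' @param groupA,groupB Numeric matrices, time points x experiments
#'   (equal row counts; >= 2 columns each).
#' @param n_iter Bootstrap iterations (default 10000).
#' @param seed Integer seed for the resampling (required for
#'   reproducibility).
#' @param null `"shift"` (default) or `"pooled"`.
#' @param chunk Iterations per vectorized block (memory/speed knob).
#' @return A `group_comparison`: `t_obs`, `p_values`, `sig_tier`,
#'   `mean_A`, `mean_B`, `sd_A`, `sd_B`, `n_A`, `n_B`, `n_iterations`.
#'   Time points where the statistic is undefined (NaN) get `p = NA`
#'   and tier `ns`, with a warning.
#' @export
bootstrap_ttest_series <- function(groupA, groupB, n_iter = 10000,
                                   seed = 1L, null = c("shift", "pooled"),
                                   chunk = 500L) {
  null <- match.arg(null)
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (nrow(groupA) != nrow(groupB)) stop("time bases differ between groups")
  nA <- ncol(groupA); nB <- ncol(groupB)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 experiments")
  if (n_iter < 1) stop("n_iter must be a positive integer")
  nt <- nrow(groupA)

  mA <- rowMeans(groupA); mB <- rowMeans(groupB)
  vA <- rowSums((groupA - mA)^2) / (nA - 1)
  vB <- rowSums((groupB - mB)^2) / (nB - 1)
  t_obs <- welch_t(mA, vA, nA, mB, vB, nB)
  bad <- !is.finite(t_obs)
  if (any(bad)) {
    warning(sum(bad), " time point(s) with undefined statistic; reported as ns",
            call. = FALSE)
  }

  if (null == "shift") {
    pooled <- (nA * mA + nB * mB) / (nA + nB)
    A0 <- groupA - mA + pooled
    B0 <- groupB - mB + pooled
  } else {
    A0 <- cbind(groupA, groupB)
    B0 <- A0
  }
  srcA <- ncol(A0); srcB <- ncol(B0)
  A0sq <- A0^2; B0sq <- B0^2

  abs_obs <- abs(t_obs)
  exceed <- numeric(nt)
  set.seed(as.integer(seed))
  # the full index streams are drawn up-front so that the chunk size is a
  # pure compute-blocking knob with no effect on the result
  iA_all <- sample.int(srcA, nA * n_iter, replace = TRUE)
  iB_all <- sample.int(srcB, nB * n_iter, replace = TRUE)
  done <- 0L
  while (done < n_iter) {
    m <- min(chunk, n_iter - done)
    WA <- matrix(0, srcA, m)
    WB <- matrix(0, srcB, m)
    for (j in seq_len(m)) {
      WA[, j] <- tabulate(iA_all[(done + j - 1) * nA + seq_len(nA)], srcA)
      WB[, j] <- tabulate(iB_all[(done + j - 1) * nB + seq_len(nB)], srcB)
    }
    mAs <- (A0 %*% WA) / nA
    mBs <- (B0 %*% WB) / nB
    vAs <- pmax((A0sq %*% WA) - nA * mAs^2, 0) / (nA - 1)
    vBs <- pmax((B0sq %*% WB) - nB * mBs^2, 0) / (nB - 1)
    ts <- welch_t(mAs, vAs, nA, mBs, vBs, nB)
    exceed <- exceed + rowSums(abs(ts) >= abs_obs)
    done <- done + m
  }
  p <- (1 + exceed) / (n_iter + 1)
  p[bad] <- NA_real_
  structure(list(t_obs = t_obs, p_values = p,
                 sig_tier = tier_significance(p),
                 mean_A = mA, mean_B = mB,
                 sd_A = sqrt(vA), sd_B = sqrt(vB),
                 n_A = nA, n_B = nB, n_iterations = n_iter,
                 null = null, seed = as.integer(seed)),
            class = "group_comparison")
}

#' Tiered significance coding of p-values
#'
#' Strict-inequality binning into the five display tiers used on the
#' comparison plots: `ns` (p >= 0.05), `p05` (p < 0.05), `p01`
#' (p < 0.01), `p001` (p < 0.001), `p0001` (p < 0.0001). `NA` p-values
#' map to `ns`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Factor with levels `ns, p05, p01, p001, p0001`.
#' @export
tier_significance <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  tier <- rep("ns", length(p))
  tier[!is.na(p) & p < 0.05] <- "p05"
  tier[!is.na(p) & p < 0.01] <- "p01"
  tier[!is.na(p) & p < 0.001] <- "p001"
  tier[!is.na(p) & p < 0.0001] <- "p0001"
  factor(tier, levels = c("ns", "p05", "p01", "p001", "p0001"))
}

#' Plot a group comparison with colour-coded significance bands
#'
#' Mean +/- SD traces for both cohorts with the light epoch shaded and a
#' significance band beneath the records (green p < 0.05, yellow
#' p < 0.01, orange p < 0.001, red p < 0.0001).
#'
#' @param cmp A [bootstrap_ttest_series()] result.
#' @param time_axis_s Time axis (seconds); default index-based.
#' @param light_window Light epoch `[on, off)` s for the shaded
#'   rectangle (default `c(55, 115)`).
#' @param ylab Y label.
#' @param file Optional output path (PNG/PDF via [ggplot2::ggsave()]).
#' @return The ggplot object, invisibly if written to file.
#' @export
render_comparison <- function(cmp, time_axis_s = NULL,
                              light_window = c(55, 115),
                              ylab = "change", file = NULL) {
  stopifnot(inherits(cmp, "group_comparison"))
  if (length(cmp$p_values) == 0) stop("empty comparison")
  t <- time_axis_s %||% seq_along(cmp$p_values)
  df <- data.frame(t = t, mA = cmp$mean_A, mB = cmp$mean_B,
                   loA = cmp$mean_A - cmp$sd_A, hiA = cmp$mean_A + cmp$sd_A,
                   loB = cmp$mean_B - cmp$sd_B, hiB = cmp$mean_B + cmp$sd_B,
                   tier = cmp$sig_tier)
  tier_cols <- c(ns = NA, p05 = "#2ca02c", p01 = "#ffd500",
                 p001 = "#ff7f0e", p0001 = "#d62728")
  band_y <- min(df$loA, df$loB, na.rm = TRUE)
  band_h <- 0.04 * (max(df$hiA, df$hiB, na.rm = TRUE) - band_y + 1e-12)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = t)) +
    ggplot2::annotate("rect", xmin = light_window[1], xmax = light_window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.12,
                      fill = "darkgreen") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = loA, ymax = hiA),
                         fill = "grey40", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = loB, ymax = hiB),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = mA), colour = "grey20") +
    ggplot2::geom_line(ggplot2::aes(y = mB), colour = "steelblue4") +
    ggplot2::geom_tile(data = df[df$tier != "ns", ],
                       ggplot2::aes(y = band_y - band_h, fill = tier),
                       height = band_h) +
    ggplot2::scale_fill_manual(values = tier_cols[-1], drop = FALSE,
                               name = "bootstrap t-test") +
    ggplot2::labs(x = "time (s)", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 3.5, dpi = 150)
    return(invisible(p))
  }
  p
}
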