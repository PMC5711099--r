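#' Conformity index (Jaccard overlap) of two masks
#'
#' Intersection volume divided by union volume. Symmetric, in [0,1], equal
#' to 1 only for identical non-empty masks. The masks must share a grid;
#' resample one explicitly (\code{\link{resample_mask}}) before comparing
#' masks across grids.
#'
#' @param a,b \code{\link{binary_mask}} objects on the same grid.
#' @return Scalar in [0,1].
#' @export
conformity_index <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_grid(a$grid, b$grid))
    stop("masks are on different grids; resample one explicitly first")
  inter <- sum(a$member & b$member)
  uni <- sum(a$member | b$member)
  if (uni == 0L) stop("conformity index undefined: both masks empty")
  inter / uni
}

#' Summarize conformity indices over a case series
#'
#' Descriptive statistics of per-case conformity indices for one method
#' pair, plus one-sample tests of the hypothesis that the mean CI equals 1
#' (paired Student t and Wilcoxon signed-rank). When every CI equals 1 the
#' tests are degenerate and reported as exact agreement (\code{p = NA},
#' \code{exact_agreement = TRUE}).
#'
#' @param ci numeric vector of per-case conformity indices, or a list of
#'   mask pairs (\code{list(list(a=, b=), ...)}) from which they are
#'   computed.
#' @param pair label for the method pair.
#' @return An object of class \code{ci_stats}: n, mean, sd, se, min, max,
#'   t_p, wilcoxon_p, exact_agreement.
#' @export
ci_summary <- function(ci, pair = "pair") {
  if (is.list(ci)) {
    ci <- vapply(ci, function(p) conformity_index(p$a, p$b), numeric(1))
  }
  stopifnot(is.numeric(ci), length(ci) >= 1L, all(ci >= 0 & ci <= 1))
  n <- length(ci)
  s <- stats::sd(ci)
  if (is.na(s)) s <- 0
  exact <- all(ci == 1)
  if (exact || s == 0) {
    t_p <- if (exact) NA_real_ else 0
    w_p <- if (exact) NA_real_ else 0
    # constant CIs != 1 differ from 1 with zero variance: report p = 0
  } else {
    t_p <- stats::t.test(ci, mu = 1)$p.value
    w_p <- suppressWarnings(stats::wilcox.test(ci - 1)$p.value)
  }
  structure(list(pair = pair, n = n, mean = mean(ci), sd = s,
                 se = s / sqrt(n), min = min(ci), max = max(ci),
                 t_p = t_p, wilcoxon_p = w_p, exact_agreement = exact),
            class = "ci_stats")
}

#' @export
print.ci_stats <- function(x, ...) {
  cat(sprintf("<ci_stats> %s: n=%d mean=%.3f sd=%.3f se=%.3f min=%.2f max=%.2f%s\n",
              x$pair, x$n, x$mean, x$sd, x$se, x$min, x$max,
              if (x$exact_agreement) " (exact agreement)" else ""))
  invisible(x)
}

#' Intraclass correlation ICC(2,1) with 95 percent lower limit
#'
#' Two-way random effects, absolute agreement, single rater: the agreement
#' statistic used to compare per-case volumes across delineation methods.
#' The 95 percent lower confidence limit uses the F-based interval
#' (McGraw & Wong).
#'
#' @param volumes numeric matrix, cases in rows, methods in columns
#'   (complete, >= 2 rows and >= 2 columns).
#' @return An object of class \code{icc_result}: \code{icc},
#'   \code{ci95_lower}, plus the mean squares.
#' @export
icc_agreement <- function(volumes) {
  volumes <- as.matrix(volumes)
  ns <- nrow(volumes); nr <- ncol(volumes)
  if (ns < 2L || nr < 2L) stop("need >= 2 cases and >= 2 methods")
  if (anyNA(volumes)) stop("volume matrix must be complete")
  if (stats::var(as.vector(volumes)) == 0) stop("constant matrix: zero variance")
  gm <- mean(volumes)
  rm_ <- rowMeans(volumes); cm_ <- colMeans(volumes)
  SSR <- nr * sum((rm_ - gm)^2)
  SSC <- ns * sum((cm_ - gm)^2)
  SST <- sum((volumes - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (ns - 1); MSC <- SSC / (nr - 1); MSE <- SSE / ((ns - 1) * (nr - 1))
  icc <- (MSR - MSE) / (MSR + (nr - 1) * MSE + (nr / ns) * (MSC - MSE))
  # F-based lower limit (two-sided 95% interval)
  alpha <- 0.05
  a <- (nr * icc) / (ns * (1 - icc))
  b <- 1 + (nr * icc * (ns - 1)) / (ns * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (nr - 1) + (b * MSE)^2 / ((ns - 1) * (nr - 1)))
  FL <- stats::qf(1 - alpha / 2, ns - 1, v)
  lower <- ns * (MSR - FL * MSE) /
    (FL * (nr * MSC + (nr * ns - nr - ns) * MSE) + ns * MSR)
  # perfect agreement (zero residual and column variance) degenerates the
  # F interval; the lower limit then coincides with the estimate
  if (!is.finite(lower)) lower <- icc
  structure(list(icc = icc, ci95_lower = min(lower, icc),
                 MSR = MSR, MSC = MSC, MSE = MSE, n = ns, k = nr),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.3f (95%% lower limit %.3f), n = %d cases x %d methods\n",
              x$icc, x$ci95_lower, x$n, x$k))
  invisible(x)
}

#' Paired tests on per-case measurements
#'
#' Two-sided paired Student t and Wilcoxon signed-rank tests. Zero
#' differences are dropped from the Wilcoxon statistic (standard
#' convention); if all differences are zero, \code{wilcoxon_p = 1}. A
#' non-zero constant difference makes the t statistic undefined and raises
#' an error.
#'
#' @param x,y numeric vectors of equal length (per-case measurements).
#' @return List with \code{t_p} and \code{wilcoxon_p}.
#' @export
paired_tests <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (all(d == 0)) return(list(t_p = 1, wilcoxon_p = 1))
  if (stats::sd(d) == 0)
    stop("constant non-zero paired difference: t statistic undefined")
  t_p <- stats::t.test(x, y, paired = TRUE)$p.value
  w_p <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
  list(t_p = t_p, wilcoxon_p = w_p)
}

#' Friedman test across methods with Holm-corrected post-hoc Wilcoxon
#'
#' Nonparametric repeated-measures comparison of the per-case volumes from
#' three or more delineation methods, followed by pairwise Wilcoxon
#' signed-rank tests with Holm correction.
#'
#' @param volumes numeric matrix, cases in rows, methods (>= 3) in columns.
#' @return List with \code{p} (Friedman), \code{statistic}, and
#'   \code{posthoc} (data frame: pair, p_raw, p_holm).
#' @export
friedman_volumes <- function(volumes) {
  volumes <- as.matrix(volumes)
  if (ncol(volumes) < 3L)
    stop("Friedman test needs >= 3 methods; use paired_tests for 2")
  if (all(volumes == volumes[, 1])) {
    # identical methods: all within-case ranks tie, statistic 0 by definition
    ft <- list(statistic = c(chisq = 0), p.value = 1)
  } else {
    ft <- stats::friedman.test(volumes)
  }
  cn <- colnames(volumes)
  if (is.null(cn)) cn <- paste0("m", seq_len(ncol(volumes)))
  pairs <- utils::combn(ncol(volumes), 2)
  praw <- apply(pairs, 2, function(pp) {
    d <- volumes[, pp[1]] - volumes[, pp[2]]
    if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(volumes[, pp[1]], volumes[, pp[2]],
                                          paired = TRUE)$p.value)
  })
  posthoc <- data.frame(pair = apply(pairs, 2, function(pp) paste(cn[pp], collapse = " vs ")),
                        p_raw = praw,
                        p_holm = stats::p.adjust(praw, "holm"),
                        stringsAsFactors = FALSE)
  list(p = ft$p.value, statistic = unname(ft$statistic), posthoc = posthoc)
}

#' Bland-Altman agreement statistics
#'
#' Mean difference, SD of differences, and 1.96-SD limits of agreement for
#' per-case volumes before and after an operation (e.g. a DICOM-RT
#' transfer), plus the per-case (mean, difference) pairs for plotting.
#'
#' @param before,after numeric vectors (ml), equal length.
#' @return An object of class \code{bland_altman}.
#' @export
bland_altman <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 1L)
  d <- after - before
  m <- (after + before) / 2
  sdd <- stats::sd(d)
  if (is.na(sdd)) sdd <- 0
  structure(list(mean_diff = mean(d), sd_diff = sdd,
                 limits = mean(d) + c(-1.96, 1.96) * sdd,
                 cases = data.frame(mean = m, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> mean diff %.3f ml, SD %.3f, limits [%.3f, %.3f]\n",
              x$mean_diff, x$sd_diff, x$limits[1], x$limits[2]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$cases$mean, x$cases$diff,
                 xlab = "mean of before/after (ml)",
                 ylab = "difference after - before (ml)", ...)
  graphics::abline(h = c(x$mean_diff, x$limits), lty = c(1, 2, 2))
  invisible(x)
}

#' Relative volume variation in percent
#'
#' \code{100 * |v_new - v_ref| / v_ref}; the resampling experiment's
#' headline measure of how much a delineated volume moves when the PET grid
#' changes.
#'
#' @param v_ref reference volume (ml), must be > 0.
#' @param v_new comparison volume (ml).
#' @return Percent variation (>= 0).
#' @export
relative_volume_variation <- function(v_ref, v_new) {
  if (any(v_ref <= 0)) stop("reference volume must be > 0")
  100 * abs(v_new - v_ref) / v_ref
}
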