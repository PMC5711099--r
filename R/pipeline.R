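#' Study configuration
#'
#' Bundles the synthetic cohort conditions, the delineation arms, the
#' planning-CT grid kind for the resampling experiment, and the contour
#' transfer scenarios for the round-trip experiment.
#'
#' @param n cohort size (default 31).
#' @param ranges cohort parameter ranges (\code{\link{cohort_ranges}}).
#' @param seed master seed controlling the whole study.
#' @param arms named list of \code{\link{seg_config}} (>= 2); default the
#'   six study arms (\code{\link{default_arms}}).
#' @param ct_grid \code{"fine"} (0.59 x 0.59 x 3 mm) or \code{"coarse"}
#'   (1.17 x 1.17 x 3 mm).
#' @param scenarios list of transfer scenarios, each
#'   \code{list(dialect=, rule=)}; defaults mirror the shrinking
#'   (center-dialect export re-rasterized by centers) and expanding
#'   (edge-dialect export re-rasterized by overlap) conventions.
#' @return An object of class \code{study_config}.
#' @export
study_config <- function(n = 31, ranges = cohort_ranges(), seed = 1L,
                         arms = default_arms(ranges$psf_fwhm),
                         ct_grid = c("fine", "coarse"),
                         scenarios = list(
                           list(dialect = "voxel_center", rule = "center_inside"),
                           list(dialect = "voxel_edge", rule = "any_overlap"))) {
  ct_grid <- match.arg(ct_grid)
  stopifnot(n >= 2, length(arms) >= 2)
  structure(list(n = n, ranges = ranges, seed = as.integer(seed), arms = arms,
                 ct_grid = ct_grid, scenarios = scenarios),
            class = "study_config")
}

## run every arm on every case; one failed case/arm is recorded, not fatal
segment_cohort <- function(cohort, arms) {
  lapply(seq_along(cohort), function(ci) {
    cs <- cohort[[ci]]
    res <- lapply(arms, function(cfg) {
      tryCatch(run_segmentation(cs$pet, cs$roi, cfg),
               error = function(e) {
                 warning(sprintf("case %d arm %s failed: %s", ci, cfg$label,
                                 conditionMessage(e)), call. = FALSE)
                 NULL
               })
    })
    names(res) <- names(arms)
    res
  })
}

#' Segmentation comparison experiment
#'
#' Runs every delineation arm on every cohort case and summarizes: per-case
#' volumes and SUV statistics, pairwise conformity indices between arms and
#' against the ground truth, ICC over the volume matrix (overall, and per
#' pair including the truth column), and the Friedman test with
#' Holm-corrected pairwise Wilcoxon post-hocs.
#'
#' @param cohort a \code{phantom_cohort} from \code{\link{generate_cohort}}.
#' @param arms named list of \code{\link{seg_config}}.
#' @param seg optional precomputed output of the internal per-case
#'   segmentation (reused by \code{\link{run_study}}).
#' @return List with \code{volumes} (data frame), \code{ci_table}
#'   (data frame, one row per pair incl. truth pairs), \code{icc_overall},
#'   \code{icc_pairs}, \code{friedman}.
#' @export
run_segmentation_comparison <- function(cohort, arms = default_arms(), seg = NULL) {
  if (is.null(seg)) seg <- segment_cohort(cohort, arms)
  labs <- vapply(arms, `[[`, character(1), "label")
  nA <- length(arms)
  vol_rows <- list()
  for (ci in seq_along(cohort)) {
    for (ai in seq_len(nA)) {
      r <- seg[[ci]][[ai]]
      if (is.null(r)) next
      vol_rows[[length(vol_rows) + 1L]] <- data.frame(
        case = ci, arm = labs[ai], volume_ml = r$volume_ml,
        suv_max = r$suv_max, suv_mean = r$suv_mean,
        truth_ml = mask_volume_ml(cohort[[ci]]$truth))
    }
  }
  volumes <- do.call(rbind, vol_rows)

  # conformity indices: truth vs each arm, then arms two by two
  all_labels <- c("TRUTH", labs)
  ci_rows <- list()
  get_mask <- function(ci, who) {
    if (who == "TRUTH") cohort[[ci]]$truth else seg[[ci]][[match(who, labs)]]$mask
  }
  for (i in seq_len(length(all_labels) - 1L)) {
    for (j in seq((i + 1L), length(all_labels))) {
      a <- all_labels[i]; b <- all_labels[j]
      cis <- vapply(seq_along(cohort), function(ci) {
        ma <- get_mask(ci, a); mb <- get_mask(ci, b)
        if (is.null(ma) || is.null(mb)) return(NA_real_)
        tryCatch(conformity_index(ma, mb), error = function(e) NA_real_)
      }, numeric(1))
      cis <- cis[!is.na(cis)]
      if (length(cis) == 0L) next
      st <- ci_summary(cis, pair = paste(a, "vs", b))
      ci_rows[[length(ci_rows) + 1L]] <- data.frame(
        pair = st$pair, n = st$n, mean = st$mean, sd = st$sd, se = st$se,
        min = st$min, max = st$max, t_p = st$t_p, wilcoxon_p = st$wilcoxon_p)
    }
  }
  ci_table <- do.call(rbind, ci_rows)

  vmat <- matrix(NA_real_, length(cohort), nA + 1L,
                 dimnames = list(NULL, all_labels))
  vmat[, 1] <- vapply(cohort, function(cs) mask_volume_ml(cs$truth), numeric(1))
  for (ci in seq_along(cohort)) for (ai in seq_len(nA)) {
    r <- seg[[ci]][[ai]]
    if (!is.null(r)) vmat[ci, ai + 1L] <- r$volume_ml
  }
  complete <- stats::complete.cases(vmat)
  vm <- vmat[complete, , drop = FALSE]
  icc_overall <- icc_agreement(vm)
  icc_pairs <- list()
  for (i in seq_len(ncol(vm) - 1L)) for (j in seq((i + 1L), ncol(vm))) {
    key <- paste(colnames(vm)[i], "vs", colnames(vm)[j])
    icc_pairs[[key]] <- tryCatch(icc_agreement(vm[, c(i, j)]),
                                 error = function(e) NULL)
  }
  fr <- friedman_volumes(vm[, -1L, drop = FALSE])
  list(volumes = volumes, ci_table = ci_table, icc_overall = icc_overall,
       icc_pairs = icc_pairs, friedman = fr, volume_matrix = vmat)
}

#' PET resampling experiment
#'
#' For each case, the threshold-based arms are run on the native PET grid
#' and again after trilinear resampling onto the planning-CT grid
#' (restricted to the analysis region); emits per-case relative volume
#' variations and paired comparisons of volumes and reference SUV values
#' per dialect.
#'
#' @param cohort a \code{phantom_cohort}.
#' @param arms named list of \code{\link{seg_config}}; non-threshold arms
#'   are ignored.
#' @param ct_grid \code{"fine"} or \code{"coarse"}.
#' @return List with \code{cases} (data frame: case, arm, native and
#'   resampled volume, reference SUV before/after, relative variation) and
#'   \code{tests} (per-arm paired test p-values).
#' @export
run_resampling_study <- function(cohort, arms = default_arms(),
                                 ct_grid = c("fine", "coarse")) {
  ct_grid <- match.arg(ct_grid)
  thr <- Filter(function(a) a$method %in% c("fixed_threshold", "relative_threshold"), arms)
  rows <- list()
  for (ci in seq_along(cohort)) {
    cs <- cohort[[ci]]
    ext <- list(lo = cs$roi$lo, hi = cs$roi$hi)
    tgt <- make_ct_grid(ct_grid, ext)
    pet_ct <- resample_suv(cs$pet, tgt)
    for (cfg in thr) {
      r0 <- tryCatch(run_segmentation(cs$pet, cs$roi, cfg), error = function(e) NULL)
      r1 <- tryCatch(run_segmentation(pet_ct, cs$roi, cfg), error = function(e) NULL)
      if (is.null(r0) || is.null(r1)) next
      ref0 <- reference_uptake(cs$pet, cs$roi, cfg$dialect)
      ref1 <- reference_uptake(pet_ct, cs$roi, cfg$dialect)
      rows[[length(rows) + 1L]] <- data.frame(
        case = ci, arm = cfg$label,
        volume_native_ml = r0$volume_ml, volume_ct_ml = r1$volume_ml,
        ref_suv_native = ref0, ref_suv_ct = ref1,
        rel_variation_pct = if (r0$volume_ml > 0)
          relative_volume_variation(r0$volume_ml, r1$volume_ml) else NA_real_)
    }
  }
  cases <- do.call(rbind, rows)
  tests <- lapply(split(cases, cases$arm), function(df) {
    if (nrow(df) < 2L) return(NULL)
    vt <- tryCatch(paired_tests(df$volume_native_ml, df$volume_ct_ml),
                   error = function(e) list(t_p = NA_real_, wilcoxon_p = NA_real_))
    st <- tryCatch(paired_tests(df$ref_suv_native, df$ref_suv_ct),
                   error = function(e) list(t_p = NA_real_, wilcoxon_p = NA_real_))
    data.frame(arm = df$arm[1],
               mean_rel_variation_pct = mean(df$rel_variation_pct, na.rm = TRUE),
               volume_t_p = vt$t_p, volume_wilcoxon_p = vt$wilcoxon_p,
               ref_suv_t_p = st$t_p, ref_suv_wilcoxon_p = st$wilcoxon_p)
  })
  list(cases = cases, tests = do.call(rbind, tests))
}

#' Contour transfer experiment
#'
#' For each case, arm, and transfer scenario (boundary dialect at export,
#' rasterization rule at import), computes the round-trip volume change and
#' summarizes each scenario with Bland-Altman statistics.
#'
#' @param cohort a \code{phantom_cohort}.
#' @param arms named list of \code{\link{seg_config}}.
#' @param scenarios list of \code{list(dialect=, rule=)}.
#' @param seg optional precomputed segmentation results.
#' @return List with \code{cases} (data frame) and \code{bland_altman}
#'   (per scenario, over all arms pooled).
#' @export
run_transfer_study <- function(cohort, arms = default_arms(),
                               scenarios = list(
                                 list(dialect = "voxel_center", rule = "center_inside"),
                                 list(dialect = "voxel_edge", rule = "any_overlap")),
                               seg = NULL) {
  if (is.null(seg)) seg <- segment_cohort(cohort, arms)
  labs <- vapply(arms, `[[`, character(1), "label")
  rows <- list()
  for (ci in seq_along(cohort)) {
    for (ai in seq_along(arms)) {
      r <- seg[[ci]][[ai]]
      if (is.null(r) || !any(r$mask$member)) next
      for (sc in scenarios) {
        rt <- tryCatch(round_trip_volume_change(r$mask, sc$dialect, sc$rule),
                       error = function(e) NULL)
        if (is.null(rt)) next
        rows[[length(rows) + 1L]] <- data.frame(
          case = ci, arm = labs[ai], dialect = sc$dialect, rule = sc$rule,
          v_before = rt$v_before, v_after = rt$v_after, delta = rt$delta)
      }
    }
  }
  cases <- do.call(rbind, rows)
  ba <- lapply(split(cases, paste(cases$dialect, cases$rule, sep = "+")),
               function(df) bland_altman(df$v_before, df$v_after))
  list(cases = cases, bland_altman = ba)
}

#' Run the full comparison study
#'
#' Generates the synthetic cohort, runs all three experiments (segmentation
#' comparison, PET resampling, contour transfer), and returns the combined
#' report. Fully deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{study_config}}.
#' @return An object of class \code{comparison_report}.
#' @export
run_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  cohort <- generate_cohort(cfg$n, cfg$ranges, cfg$seed)
  seg <- segment_cohort(cohort, cfg$arms)
  comparison <- run_segmentation_comparison(cohort, cfg$arms, seg = seg)
  resampling <- run_resampling_study(cohort, cfg$arms, cfg$ct_grid)
  transfer <- run_transfer_study(cohort, cfg$arms, cfg$scenarios, seg = seg)
  structure(list(config = cfg, cohort = cohort,
                 comparison = comparison, resampling = resampling,
                 transfer = transfer),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d cases, %d arms\n",
              length(x$cohort), length(x$config$arms)))
  cat(sprintf("  overall ICC(2,1) %.3f (95%% lower %.3f); Friedman p %.3g\n",
              x$comparison$icc_overall$icc, x$comparison$icc_overall$ci95_lower,
              x$comparison$friedman$p))
  for (nm in names(x$transfer$bland_altman)) {
    ba <- x$transfer$bland_altman[[nm]]
    cat(sprintf("  transfer %s: mean delta %+.3f ml (SD %.3f)\n",
                nm, ba$mean_diff, ba$sd_diff))
  }
  invisible(x)
}

#' Write the report tables to disk
#'
#' Emits the report as CSV tables (per-case volumes, conformity-index
#' summary, ICC table, Friedman post-hocs, resampling and transfer tables)
#' plus a JSON run manifest carrying the seed and configuration summary.
#' Re-running the same configuration reproduces byte-identical CSVs.
#'
#' @param report a \code{comparison_report} from \code{\link{run_study}}.
#' @param outdir output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "comparison_report"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(format(df, digits = 10, trim = TRUE), p, row.names = FALSE)
    p
  }
  files <- c(
    wr(report$comparison$volumes, "volumes.csv"),
    wr(report$comparison$ci_table, "ci_pairs.csv"),
    wr(icc_table_df(report$comparison), "icc.csv"),
    wr(report$comparison$friedman$posthoc, "friedman_posthoc.csv"),
    wr(report$resampling$cases, "resampling.csv"),
    wr(report$resampling$tests, "resampling_tests.csv"),
    wr(report$transfer$cases, "transfer.csv"))
  manifest <- list(
    n_cases = length(report$cohort),
    seed = report$config$seed,
    arms = vapply(report$config$arms, `[[`, character(1), "label"),
    ct_grid = report$config$ct_grid,
    friedman_p = report$comparison$friedman$p,
    icc_overall = report$comparison$icc_overall$icc)
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = 10)
  invisible(c(files, mf))
}

icc_table_df <- function(comparison) {
  rows <- list(data.frame(pair = "Overall",
                          icc = comparison$icc_overall$icc,
                          ci95_lower = comparison$icc_overall$ci95_lower))
  for (nm in names(comparison$icc_pairs)) {
    ic <- comparison$icc_pairs[[nm]]
    if (is.null(ic)) next
    rows[[length(rows) + 1L]] <- data.frame(pair = nm, icc = ic$icc,
                                            ci95_lower = ic$ci95_lower)
  }
  do.call(rbind, rows)
}
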