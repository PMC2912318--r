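# Group-level aggregation and the end-to-end pipeline: per-slice ApEn by
# condition, means +/- SEM, paired two-tailed t (primary) and Wilcoxon
# signed-rank (distribution-free companion). No multiple-testing correction
# is applied across the three pairwise comparisons; all raw p-values are
# reported so the reader can correct if desired.

#' Summarize one condition's per-slice ApEn values
#'
#' @param values numeric per-slice ApEn values (n >= 2).
#' @param condition condition label.
#' @return a `condition_summary`: `condition`, `values`, `mean`,
#'   `sem` (sample-SD / sqrt(n)), `n`.
#' @export
summarize_condition <- function(values, condition) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 slices (SEM undefined for n < 2)", call. = FALSE)
  structure(
    list(condition = as.character(condition), values = values,
         mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n),
    class = "condition_summary"
  )
}

#' Paired comparison of two conditions
#'
#' Paired two-tailed t-test on the per-slice differences (primary p-value)
#' plus the paired Wilcoxon signed-rank test. Differences follow the sign
#' convention `a - b`. Zero-variance differences are reported with a
#' `degenerate` flag instead of a numerical error: p = 1 when all
#' differences are exactly zero, p = NA for a constant nonzero shift.
#'
#' @param a,b numeric per-slice values, same slice order.
#' @param slice_ids identifiers; `a[i]`, `b[i]` must belong to slice
#'   `slice_ids[i]` in both conditions.
#' @param labels length-2 character, names of the two conditions.
#' @return a list: `comparison`, `n`, `mean_diff`, `t`, `p_t`, `p_wilcoxon`,
#'   `degenerate`, `direction`.
#' @export
paired_comparison <- function(a, b, slice_ids, labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) != length(slice_ids)) {
    stop("a, b and slice_ids must have matching lengths", call. = FALSE)
  }
  if (anyDuplicated(slice_ids)) {
    stop("duplicate slice_ids in paired comparison", call. = FALSE)
  }
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired slices", call. = FALSE)
  d <- a - b
  comparison <- paste0(labels[1], "_vs_", labels[2])
  direction <- if (mean(d) > 0) {
    sprintf("%s > %s", labels[1], labels[2])
  } else if (mean(d) < 0) {
    sprintf("%s < %s", labels[1], labels[2])
  } else "no difference"
  # zero variance up to floating point (a - b constant): degenerate pairing
  if (stats::sd(d) <= 1e-10 * max(abs(d), 1e-300)) {
    p_t <- if (all(d == 0)) 1.0 else NA_real_
    return(list(comparison = comparison, n = n, mean_diff = mean(d),
                t = NA_real_, p_t = p_t, p_wilcoxon = p_t,
                degenerate = TRUE, direction = direction))
  }
  tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE,
                                            correct = TRUE))
  list(comparison = comparison, n = n, mean_diff = mean(d),
       t = unname(tt$statistic), p_t = tt$p.value,
       p_wilcoxon = wt$p.value, degenerate = FALSE, direction = direction)
}

# analyze one preprocessed-ready recording; returns a one-row data.frame
analyze_recording <- function(rec, cfg) {
  pp <- preprocess(rec, cfg)
  seg <- isolate_gamma_segment(pp$recording, cfg$gamma_window_ms)
  ps <- power_spectrum(seg)
  dom <- dominant_frequency(ps, search_band = c(30, 120))
  gd <- is_gamma_dominant(ps, gamma_band = c(30, 120), margin = 2,
                          extent = cfg$band)
  res <- approximate_entropy(seg, apen_params(m = cfg$apen_m,
                                              r_coeff = cfg$apen_r_coeff))
  data.frame(slice_id = rec$slice_id, condition = rec$condition,
             n = res$n, r_used = res$r_used,
             phi_m = res$phi_m, phi_m1 = res$phi_m1, apen = res$apen,
             degenerate = res$degenerate,
             dominant_freq_hz = dom, gamma_dominant = gd$dominant,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' For every recording: preprocess, isolate the gamma window, verify spectral
#' content, compute ApEn; then per-condition summaries and the three pairwise
#' paired comparisons (nicotine vs control, nicotine vs washout, control vs
#' washout). Recordings failing the gamma-dominance QC are flagged but still
#' analyzed, matching the study's analyze-all-slices design.
#'
#' @param cfg an `lfp_config`.
#' @param input either a [cohort_spec()] (simulation mode), a list of
#'   `lfp_recording`s, or a directory containing `<name>.csv` /
#'   `<name>.json` pairs in the native format.
#' @return an `lfp_comparison_report`: `per_slice` (data.frame),
#'   `summaries`, `pairwise`, `n_slices`, `n_gamma_qc_fail`, `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), input) {
  recs <- if (inherits(input, "cohort_spec")) {
    generate_cohort(input)
  } else if (is.character(input) && length(input) == 1L && dir.exists(input)) {
    metas <- sort(list.files(input, pattern = "\\.json$", full.names = TRUE))
    metas <- metas[file.exists(sub("\\.json$", ".csv", metas))]
    if (length(metas) == 0L) stop("no recording pairs found in ", input, call. = FALSE)
    lapply(metas, function(mj) read_recording(sub("\\.json$", ".csv", mj), mj))
  } else if (is.list(input) && all(vapply(input, inherits, TRUE, "lfp_recording"))) {
    input
  } else {
    stop("input must be a cohort_spec, a list of recordings, or a directory",
         call. = FALSE)
  }

  per_slice <- do.call(rbind, lapply(recs, analyze_recording, cfg = cfg))
  per_slice <- per_slice[order(per_slice$condition, per_slice$slice_id), ]
  rownames(per_slice) <- NULL

  counts <- table(per_slice$condition)
  if (any(counts < 2L)) {
    stop("every condition needs at least 2 slices", call. = FALSE)
  }
  summaries <- lapply(CONDITIONS, function(cond) {
    summarize_condition(per_slice$apen[per_slice$condition == cond], cond)
  })
  names(summaries) <- CONDITIONS

  pairs <- list(c("nicotine", "control"), c("nicotine", "washout"),
                c("control", "washout"))
  pairwise <- lapply(pairs, function(pr) {
    da <- per_slice[per_slice$condition == pr[1], ]
    db <- per_slice[per_slice$condition == pr[2], ]
    common <- intersect(da$slice_id, db$slice_id)
    da <- da[match(common, da$slice_id), ]
    db <- db[match(common, db$slice_id), ]
    if (length(common) < 3L) {
      # too few pairs for any test: report the effect, flag as degenerate
      return(list(comparison = paste0(pr[1], "_vs_", pr[2]),
                  n = length(common), mean_diff = mean(da$apen - db$apen),
                  t = NA_real_, p_t = NA_real_, p_wilcoxon = NA_real_,
                  degenerate = TRUE, direction = "insufficient n"))
    }
    paired_comparison(da$apen, db$apen, common, labels = pr)
  })
  names(pairwise) <- vapply(pairwise, `[[`, "", "comparison")

  structure(
    list(per_slice = per_slice, summaries = summaries, pairwise = pairwise,
         n_slices = length(unique(per_slice$slice_id)),
         n_gamma_qc_fail = sum(!per_slice$gamma_dominant),
         config = cfg),
    class = "lfp_comparison_report"
  )
}

#' @export
print.lfp_comparison_report <- function(x, ...) {
  cat(sprintf("<lfp_comparison_report> %d slices x %d conditions\n",
              x$n_slices, length(x$summaries)))
  for (s in x$summaries) {
    cat(sprintf("  %-9s ApEn = %.3f +/- %.3f (SEM, n = %d)\n",
                s$condition, s$mean, s$sem, s$n))
  }
  for (p in x$pairwise) {
    cat(sprintf("  %-22s mean diff %+0.4f, t = %s, p_t = %s, p_wilcoxon = %s%s\n",
                p$comparison, p$mean_diff,
                if (is.na(p$t)) "NA" else sprintf("%.3f", p$t),
                if (is.na(p$p_t)) "NA" else format.pval(p$p_t, digits = 3),
                if (is.na(p$p_wilcoxon)) "NA" else format.pval(p$p_wilcoxon, digits = 3),
                if (p$degenerate) " [degenerate]" else ""))
  }
  if (x$n_gamma_qc_fail > 0) {
    cat(sprintf("  QC: %d segment(s) failed the gamma-dominance check (still analyzed)\n",
                x$n_gamma_qc_fail))
  }
  invisible(x)
}

#' Write a comparison report to JSON (and optionally the per-slice CSV)
#'
#' @param report an `lfp_comparison_report`.
#' @param path_json output JSON path.
#' @param path_csv optional per-slice CSV path (columns slice_id, condition,
#'   n, r_used, phi_m, phi_m1, apen, degenerate, dominant_freq_hz,
#'   gamma_dominant).
#' @return invisibly, `path_json`.
#' @export
write_report <- function(report, path_json, path_csv = NULL) {
  stopifnot(inherits(report, "lfp_comparison_report"))
  payload <- list(
    summaries = lapply(report$summaries, unclass),
    pairwise = report$pairwise,
    n_slices = report$n_slices,
    n_gamma_qc_fail = report$n_gamma_qc_fail,
    per_slice = report$per_slice,
    config = unclass(report$config),
    software = list(package = "apenlfp",
                    version = as.character(utils::packageVersion("apenlfp")))
  )
  jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  if (!is.null(path_csv)) {
    data.table::fwrite(report$per_slice, path_csv)
  }
  invisible(path_json)
}
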