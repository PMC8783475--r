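#' Decision thresholds for the strandedness verdict
#'
#' @param stranded_min Stranded proportion above which the library is called
#'   stranded (default 0.9; strictly "over", so exactly 0.9 is
#'   inconclusive).
#' @param unstranded_max Proportion below which the library is called
#'   unstranded (default 0.6; strictly "under").
#' @param low_align_warn Aligned fraction below which a low-alignment
#'   warning is raised (default 0.1).
#' @param min_determined_pairs Determinable-pair count below which a
#'   low-evidence warning is raised (default 1000; warning only, never a
#'   hard stop).
#' @return A `strand_thresholds` list.
#' @export
strand_thresholds <- function(stranded_min = 0.9, unstranded_max = 0.6,
                              low_align_warn = 0.1,
                              min_determined_pairs = 1000) {
  if (!(0.5 < unstranded_max && unstranded_max < stranded_min &&
        stranded_min <= 1))
    stop("need 0.5 < unstranded_max < stranded_min <= 1", call. = FALSE)
  structure(list(stranded_min = stranded_min,
                 unstranded_max = unstranded_max,
                 low_align_warn = low_align_warn,
                 min_determined_pairs = as.integer(min_determined_pairs)),
            class = "strand_thresholds")
}

#' Stranded proportion
#'
#' The fraction of determinable pairs explained by the dominant layout:
#' `max(n_fr, n_rf) / (n_fr + n_rf)`. Stranded libraries sit near 1,
#' unstranded libraries near 0.5; the value is always in `[0.5, 1]`.
#'
#' @param counts An `orientation_counts` object (or any list with `n_fr`
#'   and `n_rf`).
#' @return A fraction in `[0.5, 1]`.
#' @export
stranded_proportion <- function(counts) {
  det <- counts$n_fr + counts$n_rf
  if (det == 0)
    stop("stranded proportion undefined: no read pair orientation could ",
         "be determined", call. = FALSE)
  max(counts$n_fr, counts$n_rf) / det
}

#' Binomial confidence interval for the stranded proportion
#'
#' Two-sided Clopper-Pearson (exact) interval for the true proportion of
#' major-layout pairs. Used only for reporting; verdicts depend on the
#' point estimate and thresholds alone.
#'
#' @param n_major Pairs explained by the dominant layout.
#' @param n_determined Determinable pairs (`n_fr + n_rf`).
#' @param level Confidence level (default 0.99).
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
binomial_interval <- function(n_major, n_determined, level = 0.99) {
  stopifnot(n_determined > 0, n_major >= 0, n_major <= n_determined)
  ci <- stats::binom.test(n_major, n_determined,
                          conf.level = level)$conf.int
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Verdict from the stranded proportion
#'
#' Applies the decision thresholds: proportion strictly above
#' `stranded_min` calls the dominant layout (`FR_STRANDED` or
#' `RF_STRANDED`); strictly below `unstranded_max` calls `UNSTRANDED`;
#' anything between (thresholds included) is `INCONCLUSIVE`, which in
#' practice often indicates contamination (genomic DNA, incompletely
#' depleted small RNAs) rather than a genuinely intermediate protocol.
#'
#' @param proportion Stranded proportion (see [stranded_proportion()]).
#' @param dominant `"FR"` or `"RF"`, whichever layout dominates.
#' @param aligned_frac Fraction of sampled pairs with at least one mate
#'   assigned.
#' @param n_determined Determinable-pair count.
#' @param failed_frac Fraction of sampled pairs classified `FAILED`.
#' @param thresholds A [strand_thresholds()] object.
#' @return A list with `verdict` (one of `FR_STRANDED`, `RF_STRANDED`,
#'   `UNSTRANDED`, `INCONCLUSIVE`) and `warnings` (character vector).
#' @export
decide <- function(proportion, dominant, aligned_frac, n_determined,
                   failed_frac = 0, thresholds = strand_thresholds()) {
  stopifnot(dominant %in% c("FR", "RF"))
  warnings <- character()
  verdict <- if (proportion > thresholds$stranded_min) {
    paste0(dominant, "_STRANDED")
  } else if (proportion < thresholds$unstranded_max) {
    "UNSTRANDED"
  } else {
    warnings <- c(warnings, sprintf(
      paste0("stranded proportion %.4f is between the unstranded (%.2f) ",
             "and stranded (%.2f) thresholds; possible contamination ",
             "(genomic DNA, small RNAs) or a mixed library"),
      proportion, thresholds$unstranded_max, thresholds$stranded_min))
    "INCONCLUSIVE"
  }
  if (aligned_frac < thresholds$low_align_warn)
    warnings <- c(warnings, sprintf(
      paste0("only %.1f%% of sampled read pairs aligned to the ",
             "transcriptome (< %.0f%%); verdict unreliable - wrong or ",
             "unrelated transcriptome?"),
      100 * aligned_frac, 100 * thresholds$low_align_warn))
  if (n_determined < thresholds$min_determined_pairs)
    warnings <- c(warnings, sprintf(
      "only %d determinable pair(s) (< %d); low evidence",
      n_determined, thresholds$min_determined_pairs))
  if (failed_frac > 0.2)
    warnings <- c(warnings, sprintf(
      "%.1f%% of sampled pairs FAILED orientation classification (> 20%%)",
      100 * failed_frac))
  list(verdict = verdict, warnings = warnings)
}

#' Build a strandedness report from orientation counts
#'
#' Computes the layout fractions, the stranded proportion with its binomial
#' confidence interval, and the verdict with QC warnings. By default the
#' proportion's denominator is the determinable pairs only
#' (`n_fr + n_rf`): `FAILED` pairs reflect mapping quality, and letting
#' them dilute the proportion would let poor mapping masquerade as
#' unstrandedness; the failed fraction is reported separately (with a
#' warning above 20%). `denominator = "total"` instead divides by all
#' sampled pairs.
#'
#' @param counts An `orientation_counts` object from [tally()].
#' @param thresholds A [strand_thresholds()] object.
#' @param ci_level Confidence level for the reported interval (default
#'   0.99).
#' @param denominator `"determined"` (default) or `"total"`.
#' @return A `strandedness` object; see [print.strandedness()],
#'   [coef.strandedness()], [as.data.frame.strandedness()].
#' @export
strandedness_report <- function(counts, thresholds = strand_thresholds(),
                                ci_level = 0.99,
                                denominator = c("determined", "total")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(counts, "orientation_counts") ||
            all(c("n_total", "n_fr", "n_rf", "n_failed", "n_unmapped") %in%
                names(counts)))
  n_total <- counts$n_total
  det <- counts$n_fr + counts$n_rf
  aligned_frac <- if (n_total > 0) (n_total - counts$n_unmapped) / n_total
                  else 0
  if (det == 0) {
    msg <- paste0("stranded proportion undefined: no read pair ",
                  "orientation could be determined")
    if (aligned_frac < thresholds$low_align_warn)
      msg <- paste0(msg, sprintf(
        "; only %.1f%% of sampled read pairs aligned to the transcriptome",
        100 * aligned_frac))
    stop(msg, call. = FALSE)
  }
  den <- if (denominator == "determined") det else n_total
  frac_fr <- counts$n_fr / den
  frac_rf <- counts$n_rf / den
  failed_frac <- counts$n_failed / n_total
  sp <- max(frac_fr, frac_rf)
  dominant <- if (counts$n_fr >= counts$n_rf) "FR" else "RF"
  ci <- binomial_interval(max(counts$n_fr, counts$n_rf), den, ci_level)
  d <- decide(sp, dominant, aligned_frac, det, failed_frac, thresholds)
  structure(list(
    counts = counts,
    frac_fr = frac_fr, frac_rf = frac_rf,
    failed_frac = failed_frac, aligned_frac = aligned_frac,
    stranded_proportion = sp, percent_stranded = 100 * sp,
    dominant = dominant,
    ci_low = unname(ci[1]), ci_high = unname(ci[2]), ci_level = ci_level,
    verdict = d$verdict, warnings = d$warnings,
    thresholds = thresholds, denominator = denominator),
    class = "strandedness")
}

#' @describeIn strandedness_report Human-readable report (fractions to 4
#'   decimals, verdict line, warnings).
#' @param x,object A `strandedness` object.
#' @param ... Unused.
#' @export
print.strandedness <- function(x, ...) {
  c_ <- x$counts
  cat("Strandedness check\n")
  cat(sprintf("  read pairs sampled:         %d\n", c_$n_total))
  cat(sprintf("  aligned fraction:           %.4f\n", x$aligned_frac))
  cat(sprintf("  unmapped / failed pairs:    %d / %d\n",
              c_$n_unmapped, c_$n_failed))
  cat(sprintf("  fraction FR (%s): %.4f\n",
              rseqc_layout_code("FR"), x$frac_fr))
  cat(sprintf("  fraction RF (%s): %.4f\n",
              rseqc_layout_code("RF"), x$frac_rf))
  cat(sprintf("  stranded proportion:        %.4f  (%d%% CI %.4f-%.4f)\n",
              x$stranded_proportion, round(100 * x$ci_level),
              x$ci_low, x$ci_high))
  cat(sprintf("  verdict:                    %s\n", x$verdict))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @describeIn strandedness_report One-row summary data frame.
#' @export
summary.strandedness <- function(object, ...) {
  as.data.frame(object)
}

#' @describeIn strandedness_report Named estimates: `frac_fr`, `frac_rf`,
#'   `stranded_proportion`.
#' @export
coef.strandedness <- function(object, ...) {
  c(frac_fr = object$frac_fr, frac_rf = object$frac_rf,
    stranded_proportion = object$stranded_proportion)
}

#' @describeIn strandedness_report Confidence interval on the stranded
#'   proportion (as computed at report time).
#' @param parm,level Ignored; the interval is fixed at report time.
#' @export
confint.strandedness <- function(object, parm, level, ...) {
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("stranded_proportion",
                              c("lower", "upper")))
  attr(m, "level") <- object$ci_level
  m
}

#' @describeIn strandedness_report Barplot of the orientation category
#'   fractions.
#' @export
plot.strandedness <- function(x, ...) {
  c_ <- x$counts
  h <- c(FR = c_$n_fr, RF = c_$n_rf, FAILED = c_$n_failed,
         UNMAPPED = c_$n_unmapped) / max(1, c_$n_total)
  graphics::barplot(h, ylab = "fraction of sampled pairs",
                    main = sprintf("%s (stranded proportion %.3f)",
                                   x$verdict, x$stranded_proportion), ...)
  invisible(x)
}

#' @describeIn strandedness_report Machine-readable single-row data frame.
#' @param row.names,optional Passed through (unused).
#' @export
as.data.frame.strandedness <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  c_ <- x$counts
  data.frame(
    n_sampled = c_$n_total, n_unmapped = c_$n_unmapped,
    n_failed = c_$n_failed, n_fr = c_$n_fr, n_rf = c_$n_rf,
    aligned_frac = x$aligned_frac, frac_fr = x$frac_fr,
    frac_rf = x$frac_rf, stranded_proportion = x$stranded_proportion,
    percent_stranded = x$percent_stranded,
    ci_low = x$ci_low, ci_high = x$ci_high,
    verdict = x$verdict,
    warnings = paste(x$warnings, collapse = "; "),
    stringsAsFactors = FALSE)
}

#' Simulate orientation counts from a fitted report
#'
#' Draws `nsim` multinomial replicates of the orientation category counts at
#' the report's fitted fractions — a quick parametric check of how variable
#' the stranded proportion would be at this sample size.
#'
#' @param object A `strandedness` object.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data frame with one row per replicate: counts and the
#'   recomputed stranded proportion.
#' @export
simulate.strandedness <- function(object, nsim = 1, seed = NULL, ...) {
  c_ <- object$counts
  pr <- c(c_$n_fr, c_$n_rf, c_$n_failed, c_$n_unmapped) / c_$n_total
  draws <- with_seed(seed, stats::rmultinom(nsim, c_$n_total, pr))
  sp <- apply(draws, 2, function(v)
    if (v[1] + v[2] == 0) NA_real_ else max(v[1], v[2]) / (v[1] + v[2]))
  data.frame(n_fr = draws[1, ], n_rf = draws[2, ], n_failed = draws[3, ],
             n_unmapped = draws[4, ], stranded_proportion = sp)
}

#' Write machine-readable report files
#'
#' Writes `<prefix>.tsv` (single row, tab-separated) and `<prefix>.json`.
#'
#' @param x A `strandedness` object.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(x, prefix) {
  stopifnot(inherits(x, "strandedness"))
  df <- as.data.frame(x)
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  lst <- as.list(df[1, , drop = TRUE])
  lst$warnings <- x$warnings
  jsonlite::write_json(lst, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv, json))
}
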