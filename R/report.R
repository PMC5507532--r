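# Concordance against truth sets, exact binomial confidence intervals,
# sample-throughput projection and library-size arithmetic.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval from the beta-quantile closed form:
#' lower = `qbeta(alpha/2, x, n - x + 1)`, upper =
#' `qbeta(1 - alpha/2, x + 1, n - x)`, with the conventional endpoints at
#' x = 0 and x = n (for x = n the lower bound is `(alpha/2)^(1/n)`).
#'
#' @param successes,trials Counts, `0 <= successes <= trials`, `trials >= 1`.
#' @param confidence Coverage, default 0.95.
#' @return One-row tibble with `lower` and `upper` in percent.
#' @export
#' @examples
#' exact_binomial_ci(409, 409)  # lower 99.10
exact_binomial_ci <- function(successes, trials, confidence = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials) {
    stop("need 0 <= successes <= trials and trials >= 1", call. = FALSE)
  }
  a <- 1 - confidence
  lower <- if (successes == 0) 0 else stats::qbeta(a / 2, successes,
                                                   trials - successes + 1)
  upper <- if (successes == trials) 1 else stats::qbeta(1 - a / 2,
                                                        successes + 1,
                                                        trials - successes)
  tibble::tibble(lower = 100 * lower, upper = 100 * upper)
}

classify_variant <- function(ref, alt, zygosity) {
  dplyr::case_when(
    nchar(ref) != nchar(alt) ~ "indel",
    zygosity == "hom" ~ "hom_snv",
    TRUE ~ "het_snv"
  )
}

#' Variant detection concordance against a truth set
#'
#' Calls and truth are matched exactly on (sample, contig, position,
#' ref, alt); both must be normalised identically (left-aligned anchored
#' representation). True positives are categorised into heterozygous SNVs,
#' homozygous SNVs and indels by the truth zygosity. True negatives follow
#' the reference-base bookkeeping `TN = roi_size x n_samples - total TP`.
#' Sensitivity and specificity carry exact binomial confidence intervals.
#'
#' @param calls Tibble of calls with columns `sample`, `contig`, `pos`,
#'   `ref`, `alt` (rows with a `filter` column are restricted to `PASS`).
#' @param truth Tibble with `sample`, `contig`, `pos`, `ref`, `alt`,
#'   `zygosity`.
#' @param roi_size Region-of-interest size in bp (> 0).
#' @param n_samples Number of samples; defaults to the distinct samples in
#'   `truth` and `calls`.
#' @param confidence CI coverage, default 0.95.
#' @return A `slim_concordance` list; see [tidy.slim_concordance()] and
#'   [glance.slim_concordance()].
#' @export
concordance <- function(calls, truth, roi_size, n_samples = NULL,
                        confidence = 0.95) {
  if (roi_size <= 0) stop("roi_size must be positive", call. = FALSE)
  calls <- tibble::as_tibble(calls)
  truth <- tibble::as_tibble(truth)
  if ("filter" %in% names(calls)) {
    calls <- calls[calls$filter == "PASS", , drop = FALSE]
  }
  if (is.null(n_samples)) {
    n_samples <- length(unique(c(calls$sample, truth$sample)))
  }
  key <- function(d) paste(d$sample, d$contig, d$pos, d$ref, d$alt, sep = "\r")
  truth$matched <- key(truth) %in% key(calls)
  fp <- sum(!(key(calls) %in% key(truth)))
  truth$class <- classify_variant(truth$ref, truth$alt, truth$zygosity)
  tp_by <- table(factor(truth$class[truth$matched],
                        levels = c("het_snv", "hom_snv", "indel")))
  tp <- sum(truth$matched)
  fn <- sum(!truth$matched)
  tn <- roi_size * n_samples - tp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- tn / (tn + fp)
  sens_ci <- if (tp + fn > 0) exact_binomial_ci(tp, tp + fn, confidence) else
    tibble::tibble(lower = NA_real_, upper = NA_real_)
  spec_ci <- exact_binomial_ci(tn, tn + fp, confidence)
  structure(
    list(tp = tp, tp_het_snv = unname(tp_by[["het_snv"]]),
         tp_hom_snv = unname(tp_by[["hom_snv"]]),
         tp_indel = unname(tp_by[["indel"]]),
         fp = fp, fn = fn, tn = tn,
         roi_size = roi_size, n_samples = n_samples,
         sensitivity = sens, sensitivity_ci = sens_ci,
         specificity = spec, specificity_ci = spec_ci,
         confidence = confidence),
    class = "slim_concordance"
  )
}

#' @export
print.slim_concordance <- function(x, ...) {
  cat(sprintf(
    "<slim_concordance> TP %d (het SNV %d, hom SNV %d, indel %d); FP %d; FN %d; TN %d\n",
    x$tp, x$tp_het_snv, x$tp_hom_snv, x$tp_indel, x$fp, x$fn, x$tn
  ))
  if (!is.na(x$sensitivity)) {
    cat(sprintf("  sensitivity %.2f%% (%.0f%% CI: %.2f%%-%.2f%%)\n",
                100 * x$sensitivity, 100 * x$confidence,
                x$sensitivity_ci$lower, x$sensitivity_ci$upper))
  } else {
    cat("  sensitivity not applicable (no truth variants)\n")
  }
  cat(sprintf("  specificity %.2f%% (%.0f%% CI: %.2f%%-%.2f%%)\n",
              100 * x$specificity, 100 * x$confidence,
              x$specificity_ci$lower, x$specificity_ci$upper))
  invisible(x)
}

#' Tidy a concordance summary
#'
#' @param x A `slim_concordance`.
#' @param ... Unused.
#' @return `tidy()` returns one row per tally; `glance()` a one-row summary.
#' @export
tidy.slim_concordance <- function(x, ...) {
  tibble::tibble(
    metric = c("tp", "tp_het_snv", "tp_hom_snv", "tp_indel", "fp", "fn", "tn"),
    count = c(x$tp, x$tp_het_snv, x$tp_hom_snv, x$tp_indel, x$fp, x$fn, x$tn)
  )
}

#' @rdname tidy.slim_concordance
#' @export
glance.slim_concordance <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
    sensitivity = x$sensitivity,
    sensitivity_lower = x$sensitivity_ci$lower,
    sensitivity_upper = x$sensitivity_ci$upper,
    specificity = x$specificity,
    specificity_lower = x$specificity_ci$lower,
    specificity_upper = x$specificity_ci$upper
  )
}

#' Project per-library amplicon coverage from kit throughput
#'
#' Uses the observed scaling constant that one library needs
#' `reads_for_500x` raw paired-end reads for a 500x mean amplicon coverage.
#' The projected mean is rounded down to the nearest `round_to`; the
#' projected minimum is 0.2x of the mean (the uniformity floor).
#'
#' @param kit_reads Raw paired-end reads produced by the kit.
#' @param libraries Number of pooled libraries (>= 1).
#' @param reads_for_500x Scaling constant, default 91500.
#' @param round_to Rounding granularity, default 100.
#' @return One-row tibble: `kit_reads`, `libraries`, `reads_per_library`,
#'   `mean_coverage`, `min_coverage`.
#' @export
#' @examples
#' project_throughput(30e6, 96)  # 1700x mean, 340x minimum
project_throughput <- function(kit_reads, libraries, reads_for_500x = 91500,
                               round_to = 100) {
  stopifnot(libraries >= 1, kit_reads > 0)
  per_lib <- kit_reads / libraries
  mean_exact <- per_lib / reads_for_500x * 500
  mean_cov <- floor(mean_exact / round_to) * round_to
  tibble::tibble(
    kit_reads = kit_reads, libraries = libraries,
    reads_per_library = per_lib,
    mean_coverage = mean_cov, min_coverage = 0.2 * mean_cov
  )
}

#' Library size arithmetic
#'
#' Average fragment sizes through library preparation: the gene-specific
#' insert gains the two universal tags, then the indexing PCR adds the
#' index/adapter bases.
#'
#' @param insert_mean Mean gene-specific insert size, bp.
#' @param tag_total Total tag bases added (both ends); default the summed
#'   lengths of the configured tags (41 for the defaults).
#' @param index_addition Bases added by indexing, bp (94 for the dual-index
#'   chemistry modelled here).
#' @return One-row tibble: `tagged_size`, `indexed_size`.
#' @export
#' @examples
#' library_size(331)  # 372 tagged, 466 indexed
library_size <- function(insert_mean, tag_total = NULL, index_addition = 94) {
  if (is.null(tag_total)) tag_total <- sum(nchar(slim_tags()))
  stopifnot(insert_mean >= 0, tag_total >= 0, index_addition >= 0)
  tibble::tibble(tagged_size = insert_mean + tag_total,
                 indexed_size = insert_mean + tag_total + index_addition)
}
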