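# Coverage statistics over the region of interest, and VCF output.

#' Coverage and specificity report
#'
#' Per-base depth over the region of interest is taken from merged,
#' pair-collapsed reads (forward/reverse mates on the same position count as
#' one coverage). The threshold table reports the fraction of targeted bases
#' with depth at least `k` times the mean for the conventional ladder of
#' `k`; uniformity is the 0.2x row. Per-amplicon coverage is measured on
#' each amplicon's non-overlapping region.
#'
#' @param pileups List of per-amplicon pileups (from [call_pairs()]).
#' @param panel The panel.
#' @param tallies Assignment tallies tibble (`total_pairs`,
#'   `assigned_pairs`, `mapping_rate`).
#' @return A `slim_coverage` list: `depth` (per-base tibble), `mean_depth`,
#'   `median_depth`, `min_depth`, `max_depth`, `thresholds` (tibble `k`,
#'   `fraction`), `uniformity`, `mapping_rate`, `on_target_rate`,
#'   `per_amplicon`.
#' @export
coverage_report <- function(pileups, panel,
                            tallies = tibble::tibble(total_pairs = NA_integer_,
                                                     assigned_pairs = NA_integer_,
                                                     mapping_rate = NA_real_)) {
  amps <- panel$amplicons
  depth_all <- purrr::map_dfr(pileups, function(p) {
    if (!nrow(p$depth)) return(NULL)
    tibble::tibble(contig = amps$contig[match(p$amplicon, amps$id)],
                   gpos0 = p$depth$gpos0, reads = p$depth$reads)
  })
  if (nrow(depth_all)) {
    depth_all <- dplyr::summarise(
      dplyr::group_by(depth_all, .data$contig, .data$gpos0),
      reads = sum(.data$reads), .groups = "drop"
    )
  }
  roi_pos <- purrr::pmap_dfr(panel$roi, function(contig, start, end) {
    tibble::tibble(contig = contig, gpos0 = start:(end - 1L))
  })
  roi_depth <- dplyr::left_join(roi_pos, depth_all, by = c("contig", "gpos0"))
  roi_depth$reads[is.na(roi_depth$reads)] <- 0L
  mean_d <- mean(roi_depth$reads)
  ks <- c(0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.75, 1.0)
  thresholds <- tibble::tibble(
    k = ks,
    fraction = vapply(ks, function(k) mean(roi_depth$reads >= k * mean_d),
                      numeric(1))
  )
  on_target <- if (nrow(depth_all) && sum(depth_all$reads) > 0) {
    sum(roi_depth$reads) / sum(depth_all$reads)
  } else {
    NA_real_
  }
  per_amp <- purrr::map_dfr(pileups, function(p) {
    a <- amps[match(p$amplicon, amps$id), ]
    lo <- a$start + nchar(a$fwd_gene)
    hi <- a$end - nchar(a$rev_gene)  # clipped interior, 0-based half-open
    jn <- panel$junctions
    jn <- jn[jn$left_id == a$id | jn$right_id == a$id, , drop = FALSE]
    pos <- lo:(hi - 1L)
    if (nrow(jn)) {
      for (j in seq_len(nrow(jn))) {
        pos <- pos[pos < jn$ov_start[j] | pos >= jn$ov_end[j]]
      }
    }
    d <- p$depth$reads[match(pos, p$depth$gpos0)]
    d[is.na(d)] <- 0L
    tibble::tibble(amplicon = a$id, contig = a$contig,
                   n_pos = length(pos), mean_cov = mean(d))
  })
  structure(
    list(depth = roi_depth, mean_depth = mean_d,
         median_depth = stats::median(roi_depth$reads),
         min_depth = min(roi_depth$reads), max_depth = max(roi_depth$reads),
         thresholds = thresholds,
         uniformity = thresholds$fraction[thresholds$k == 0.2],
         mapping_rate = tallies$mapping_rate,
         on_target_rate = on_target,
         per_amplicon = per_amp),
    class = "slim_coverage"
  )
}

coverage_as_list <- function(cov) {
  list(mean_depth = cov$mean_depth, median_depth = cov$median_depth,
       min_depth = cov$min_depth, max_depth = cov$max_depth,
       uniformity = cov$uniformity, mapping_rate = cov$mapping_rate,
       on_target_rate = cov$on_target_rate,
       thresholds = as.list(stats::setNames(cov$thresholds$fraction,
                                            paste0(cov$thresholds$k, "x"))))
}

#' @export
print.slim_coverage <- function(x, ...) {
  cat(sprintf(
    "<slim_coverage> mean %.0fx (min %d, max %d); uniformity (>=0.2x mean) %.2f%%\n",
    x$mean_depth, x$min_depth, x$max_depth, 100 * x$uniformity
  ))
  invisible(x)
}

#' @export
tidy.slim_coverage <- function(x, ...) x$thresholds

#' @export
glance.slim_coverage <- function(x, ...) {
  tibble::tibble(mean_depth = x$mean_depth, median_depth = x$median_depth,
                 min_depth = x$min_depth, max_depth = x$max_depth,
                 uniformity = x$uniformity, mapping_rate = x$mapping_rate,
                 on_target_rate = x$on_target_rate)
}

#' @export
autoplot.slim_coverage <- function(object, ...) {
  ggplot2::ggplot(object$per_amplicon,
                  ggplot2::aes(x = .data$amplicon, y = .data$mean_cov)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.2 * mean(object$per_amplicon$mean_cov),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "mean coverage (non-overlap region)",
                  title = "Per-amplicon coverage; dashed line = 0.2x of mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Write variant calls as VCF 4.2
#'
#' One record per call; 1-based positions, left-aligned anchored indels.
#' FILTER carries `PASS`, `low_support`, `low_frequency` or `below_noise`;
#' INFO carries the quality-weighted frequency (`QWF`), segment noise
#' (`NOISE_MU`, `NOISE_SD`), source amplicon and depth/support.
#'
#' @param calls Calls tibble (as from [call_pairs()]).
#' @param path Output path.
#' @param contig_lengths Named integer vector for the header.
#' @param noise Optional noise tibble to annotate per-amplicon noise.
#' @return The path, invisibly.
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL, noise = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=slimamp",
    "##FILTER=<ID=low_support,Description=\"Fewer than the minimum supporting reads\">",
    "##FILTER=<ID=low_frequency,Description=\"Below the minimum allele frequency\">",
    "##FILTER=<ID=below_noise,Description=\"Below the segment noise gate\">",
    "##INFO=<ID=QWF,Number=1,Type=Float,Description=\"Quality-weighted allele frequency\">",
    "##INFO=<ID=NOISE_MU,Number=1,Type=Float,Description=\"Segment noise mean\">",
    "##INFO=<ID=NOISE_SD,Number=1,Type=Float,Description=\"Segment noise SD\">",
    "##INFO=<ID=AMPLICON,Number=1,Type=String,Description=\"Source amplicon\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Merged-read depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Supporting merged reads\">"
  )
  if (!is.null(contig_lengths)) {
    lines <- c(lines, sprintf("##contig=<ID=%s,length=%d>",
                              names(contig_lengths), contig_lengths))
  }
  lines <- c(lines, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (!is.null(calls) && nrow(calls)) {
    mu <- sd <- rep(NA_real_, nrow(calls))
    if (!is.null(noise) && "amplicon" %in% names(calls)) {
      m <- match(calls$amplicon, noise$amplicon)
      mu <- noise$mu_noise[m]; sd <- noise$sd_noise[m]
    }
    info <- sprintf("QWF=%.6g;NOISE_MU=%.6g;NOISE_SD=%.6g;AMPLICON=%s;DP=%d;AD=%d",
                    calls$qwf, ifelse(is.na(mu), 0, mu), ifelse(is.na(sd), 0, sd),
                    if ("amplicon" %in% names(calls)) calls$amplicon else ".",
                    calls$depth, calls$support)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                              calls$contig, calls$pos, calls$ref, calls$alt,
                              calls$filter, info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into a calls tibble
#'
#' Uses an independent VCF parser (vcfR) so the package writer is checked by
#' a third-party reader in round-trip tests.
#'
#' @param path VCF path.
#' @return Tibble `contig`, `pos`, `ref`, `alt`, `filter`, `qwf`, `support`,
#'   `depth` (INFO fields `NA` when absent).
#' @export
read_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fx)) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          filter = character(), qwf = numeric(),
                          support = integer(), depth = integer()))
  }
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    suppressWarnings(as.numeric(x))
  }
  tibble::tibble(
    contig = fx$CHROM, pos = as.integer(fx$POS), ref = fx$REF, alt = fx$ALT,
    filter = fx$FILTER,
    qwf = info_num("QWF"),
    support = as.integer(info_num("AD")),
    depth = as.integer(info_num("DP"))
  )
}

#' Read a truth/variant VCF into a variant-spec table
#'
#' @param path VCF path (e.g. from [write_truth_vcf()]).
#' @return A [variant_spec()] tibble.
#' @export
read_variant_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fx)) {
    return(variant_spec(character(), integer(), character(), character()))
  }
  zyg <- vcfR::extract.info(v, element = "ZYG")
  vaf <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "VAF")))
  zyg[is.na(zyg)] <- "het"
  variant_spec(fx$CHROM, as.integer(fx$POS), fx$REF, fx$ALT, zyg,
               vaf = ifelse(is.na(vaf), ifelse(zyg == "hom", 1, 0.5), vaf))
}

#' Split variant specs into two haplotypes by zygosity
#'
#' Homozygous specs are applied to both haplotypes, heterozygous specs to
#' one; sampling the two haplotypes at equal fractions then realises the
#' target allele fractions (0.5 het, 1.0 hom).
#'
#' @param reference Named character vector of reference sequences.
#' @param specs A [variant_spec()] table.
#' @return List: `haplotypes` (named list of two references), `fractions`,
#'   `truth` (left-aligned truth tibble).
#' @export
build_haplotypes <- function(reference, specs) {
  specs <- tibble::as_tibble(specs)
  hom <- specs[specs$zygosity == "hom", , drop = FALSE]
  a <- apply_variants(reference, specs)
  b <- apply_variants(reference, hom)
  list(haplotypes = list(hapA = a$haplotype, hapB = b$haplotype),
       fractions = c(0.5, 0.5),
       truth = a$truth)
}
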