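# The bulk analysis pipeline: FASTQ pair -> amplicon assignment -> banded
# realignment -> pair merging -> primer clipping -> per-segment pileups ->
# noise estimation -> variant calls + coverage report.
#
# For throughput, reads are processed in groups sharing an identical
# alignment structure (same CIGAR and start for both mates): within a group
# the merge geometry is constant and the phred-weighted consensus reduces to
# vectorised column operations. The per-pair rules are identical to
# merge_pair(); a property test asserts agreement between the two paths.

qual_matrix <- function(quals) {
  # rows = read positions, cols = reads (all equal width)
  matrix(unlist(lapply(quals, function(q) utf8ToInt(q) - 33L)),
         ncol = length(quals))
}

char_matrix <- function(reads) {
  matrix(unlist(strsplit(reads, "", fixed = TRUE)), ncol = length(reads))
}

fast_hamming <- function(reads, refchunk) {
  # mismatches of each read against one reference chunk of equal width
  M <- char_matrix(reads)
  colSums(M != strsplit(refchunk, "", fixed = TRUE)[[1]])
}

empty_pileup <- function(amplicon) {
  list(amplicon = amplicon,
       alleles = tibble::tibble(gpos0 = integer(), allele = character(),
                                weight = numeric(), count = integer()),
       depth = tibble::tibble(gpos0 = integer(), reads = integer()),
       events = tibble::tibble(gpos0 = integer(), ref = character(),
                               alt = character(), type = character(),
                               count = integer(), weight = numeric()),
       n_pairs = 0L, n_dropped = 0L)
}

# Build the per-segment pileup for one amplicon from its assigned pairs.
amplicon_pileup <- function(read1, read2, qual1, qual2, amp, ampref,
                            reference, params) {
  n <- length(read1)
  out <- empty_pileup(amp$id)
  out$n_pairs <- n
  if (!n) return(out)
  ampref <- toupper(ampref)
  read1 <- toupper(read1); read2 <- toupper(read2)
  amplen <- nchar(ampref)
  clip_lo <- nchar(amp$fwd_oligo) + 1L
  clip_hi <- amplen - nchar(amp$rev_oligo)
  gmap <- function(p) amp$start + nchar(amp$fwd_gene) + (p - clip_lo)

  rc2 <- reverse_complement(read2)
  q2r <- stringi::stri_reverse(qual2)
  l1 <- nchar(read1[1]); l2 <- nchar(rc2[1])
  # fast path: reads that are pure substitution copies of the reference
  mm1 <- fast_hamming(read1, substr(ampref, 1L, l1))
  mm2 <- fast_hamming(rc2, substr(ampref, amplen - l2 + 1L, amplen))
  fast_cap <- max(8L, ceiling(0.06 * l1))
  fast <- mm1 <= fast_cap & mm2 <= fast_cap
  aln_key <- character(n)
  aln1 <- vector("list", n); aln2 <- vector("list", n)
  fast_a1 <- list(score = 2L * l1, ref_start = 1L, ref_end = l1,
                  read_start = 1L, read_end = l1, cigar = paste0(l1, "M"))
  fast_a2 <- list(score = 2L * l2, ref_start = amplen - l2 + 1L,
                  ref_end = amplen, read_start = 1L, read_end = l2,
                  cigar = paste0(l2, "M"))
  for (i in seq_len(n)) {
    if (fast[i]) {
      aln1[[i]] <- fast_a1; aln2[[i]] <- fast_a2
    } else {
      aln1[[i]] <- as.list(realign_local(read1[i], ampref, band = params$band,
                                         diag_offset = 0L))
      aln2[[i]] <- as.list(realign_local(rc2[i], ampref, band = params$band,
                                         diag_offset = amplen - l2))
    }
    aln_key[i] <- paste(aln1[[i]]$ref_start, aln1[[i]]$cigar,
                        aln2[[i]]$ref_start, aln2[[i]]$cigar, sep = "|")
  }

  acc_w <- list(); acc_c <- list(); acc_d <- integer(0)
  pos_universe <- clip_lo:clip_hi
  np <- length(pos_universe)
  alleles <- c("A", "C", "G", "T", "-")
  W <- matrix(0, nrow = np, ncol = 5L, dimnames = list(NULL, alleles))
  CNT <- matrix(0L, nrow = np, ncol = 5L, dimnames = list(NULL, alleles))
  DEP <- integer(np)
  events <- list()

  for (key in unique(aln_key)) {
    sel <- which(aln_key == key)
    m <- length(sel)
    a1 <- aln1[[sel[1]]]; a2 <- aln2[[sel[1]]]
    m1 <- alignment_map(a1); m2 <- alignment_map(a2)
    # incompatible indel structure between mates inside their overlap
    ov_lo <- max(m1$ref_start, m2$ref_start)
    ov_hi <- min(m1$ref_end, m2$ref_end)
    if (ov_lo <= ov_hi) {
      d1 <- m1$src[(ov_lo:ov_hi) - m1$ref_start + 1L] < 0
      d2 <- m2$src[(ov_lo:ov_hi) - m2$ref_start + 1L] < 0
      ins_in <- function(mm) {
        ii <- mm$insertions
        ii[ii$after_ref >= ov_lo - 1L & ii$after_ref < ov_hi, , drop = FALSE]
      }
      ii1 <- ins_in(m1); ii2 <- ins_in(m2)
      if (!identical(d1, d2) ||
          !identical(sort(paste(ii1$after_ref, ii1$read_len)),
                     sort(paste(ii2$after_ref, ii2$read_len)))) {
        out$n_dropped <- out$n_dropped + m
        next
      }
    }
    M1 <- char_matrix(read1[sel]); Q1 <- qual_matrix(qual1[sel])
    M2 <- char_matrix(rc2[sel]); Q2 <- qual_matrix(q2r[sel])
    span_lo <- max(min(m1$ref_start, m2$ref_start), clip_lo)
    span_hi <- min(max(m1$ref_end, m2$ref_end), clip_hi)
    if (span_lo > span_hi) next
    for (p in span_lo:span_hi) {
      in1 <- p >= m1$ref_start && p <= m1$ref_end
      in2 <- p >= m2$ref_start && p <= m2$ref_end
      if (in1) {
        s1 <- m1$src[p - m1$ref_start + 1L]
        c1 <- if (s1 > 0) M1[s1, ] else rep("-", m)
        y1 <- Q1[abs(s1), ]
      }
      if (in2) {
        s2 <- m2$src[p - m2$ref_start + 1L]
        c2 <- if (s2 > 0) M2[s2, ] else rep("-", m)
        y2 <- Q2[abs(s2), ]
      }
      if (in1 && in2) {
        agree <- c1 == c2
        cons <- ifelse(agree, c1, ifelse(y1 >= y2, c1, c2))
        cq <- ifelse(agree, pmin(y1 + y2, 60L), pmax(abs(y1 - y2), 2L))
      } else if (in1) {
        cons <- c1; cq <- y1
      } else if (in2) {
        cons <- c2; cq <- y2
      } else {
        next
      }
      cq <- pmin(pmax(cq, 2L), 60L)
      w <- phred_weight(cq)
      k <- p - clip_lo + 1L
      DEP[k] <- DEP[k] + m
      for (al in alleles) {
        hit <- cons == al
        if (any(hit)) {
          W[k, al] <- W[k, al] + sum(w[hit])
          CNT[k, al] <- CNT[k, al] + sum(hit)
        }
      }
    }
    # deletion events (from the shared alignment structure)
    del_ref <- sort(unique(c(
      (m1$ref_start:m1$ref_end)[m1$src < 0],
      (m2$ref_start:m2$ref_end)[m2$src < 0]
    )))
    del_ref <- del_ref[del_ref >= clip_lo & del_ref <= clip_hi]
    if (length(del_ref)) {
      runs <- split(del_ref, cumsum(c(1L, diff(del_ref) != 1L)))
      for (run in runs) {
        g0 <- gmap(run[1]) - 1L  # anchor: genomic base before the run
        glen <- length(run)
        refseq <- reference[[amp$contig]]
        refal <- toupper(substr(refseq, g0 + 1L, g0 + 1L + glen))
        altal <- substr(refal, 1L, 1L)
        la <- left_align_variant(refseq, g0 + 1L, refal, altal)
        events[[length(events) + 1L]] <- tibble::tibble(
          gpos0 = la$pos - 1L, ref = la$ref, alt = la$alt, type = "del",
          count = m, weight = NA_real_,
          wpos0 = gmap(run[1])  # '-' allele weight is looked up here later
        )
      }
    }
    # insertion events
    ii <- m1$insertions
    if (nrow(m2$insertions)) {
      extra <- m2$insertions[!paste(m2$insertions$after_ref) %in%
                               paste(ii$after_ref), , drop = FALSE]
      ii <- dplyr::bind_rows(ii, extra)
    }
    if (nrow(ii)) {
      for (z in seq_len(nrow(ii))) {
        ar <- ii$after_ref[z]
        if (ar < clip_lo || ar >= clip_hi) next
        use1 <- z <= nrow(m1$insertions)
        MM <- if (use1) M1 else M2
        QQ <- if (use1) Q1 else Q2
        rows <- ii$read_from[z]:(ii$read_from[z] + ii$read_len[z] - 1L)
        strs <- apply(MM[rows, , drop = FALSE], 2, paste, collapse = "")
        wmin <- phred_weight(apply(QQ[rows, , drop = FALSE], 2, min))
        g0 <- gmap(ar)
        refseq <- reference[[amp$contig]]
        refal <- toupper(substr(refseq, g0 + 1L, g0 + 1L))
        for (s in unique(strs)) {
          hit <- strs == s
          la <- left_align_variant(refseq, g0 + 1L, refal,
                                   paste0(refal, toupper(s)))
          events[[length(events) + 1L]] <- tibble::tibble(
            gpos0 = la$pos - 1L, ref = la$ref, alt = la$alt, type = "ins",
            count = sum(hit), weight = sum(wmin[hit]), wpos0 = NA_integer_
          )
        }
      }
    }
  }
  keep <- DEP > 0L
  gpos <- gmap(pos_universe)
  al_tbl <- tibble::tibble(
    gpos0 = rep(gpos, 5L),
    allele = rep(alleles, each = np),
    weight = as.vector(W),
    count = as.vector(CNT)
  )
  al_tbl <- al_tbl[al_tbl$gpos0 %in% gpos[keep], ]
  out$alleles <- al_tbl[al_tbl$count > 0 | al_tbl$weight > 0 |
                          al_tbl$allele != "-", ]
  out$depth <- tibble::tibble(gpos0 = gpos[keep], reads = DEP[keep])
  if (length(events)) {
    ev <- dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(events),
                      .data$gpos0, .data$ref, .data$alt, .data$type),
      count = sum(.data$count), weight = sum(.data$weight),
      wpos0 = dplyr::first(.data$wpos0), .groups = "drop"
    )
    # deletion event weight: the '-' allele weight accumulated at the first
    # aligned deleted position (already summed over groups in the pileup)
    del <- is.na(ev$weight)
    if (any(del)) {
      dw <- al_tbl[al_tbl$allele == "-", ]
      wrow <- dw$weight[match(ev$wpos0[del], dw$gpos0)]
      ev$weight[del] <- ifelse(is.na(wrow), 0, wrow)
    }
    out$events <- ev[setdiff(names(ev), "wpos0")]
  }
  out
}

#' Per-segment quality-weighted noise statistics
#'
#' For every (position, non-reference base) pair in the segment whose
#' quality-weighted frequency sits below the candidate-exclusion ceiling,
#' the frequency joins the noise collection; the segment noise is the mean
#' and standard deviation of that collection. Observations at or above the
#' ceiling are treated as candidate variants, not noise, so true variants do
#' not inflate the gate.
#'
#' @param pileup One amplicon pileup (element of [segment_pileups()]).
#' @param reference Named character vector of reference sequences.
#' @param contig Contig of the segment.
#' @param candidate_exclusion Ceiling, default 0.05.
#' @return One-row tibble: `amplicon`, `mu_noise`, `sd_noise`, `n_obs`,
#'   `flagged` (`TRUE` for a zero-coverage segment).
#' @export
estimate_noise <- function(pileup, reference, contig,
                           candidate_exclusion = 0.05) {
  if (!nrow(pileup$depth)) {
    return(tibble::tibble(amplicon = pileup$amplicon, mu_noise = NA_real_,
                          sd_noise = NA_real_, n_obs = 0L, flagged = TRUE))
  }
  al <- pileup$alleles
  tot <- stats::aggregate(weight ~ gpos0, al, sum)
  wtot <- stats::setNames(tot$weight, tot$gpos0)
  refseq <- reference[[contig]]
  refbase <- toupper(substr(rep(refseq, nrow(al)), al$gpos0 + 1L, al$gpos0 + 1L))
  sub <- al[al$allele != "-" & al$allele != refbase, , drop = FALSE]
  qwf <- sub$weight / wtot[as.character(sub$gpos0)]
  qwf[!is.finite(qwf)] <- 0
  qwf <- qwf[qwf < candidate_exclusion]
  if (!length(qwf)) {
    return(tibble::tibble(amplicon = pileup$amplicon, mu_noise = 0,
                          sd_noise = 0, n_obs = 0L, flagged = FALSE))
  }
  tibble::tibble(amplicon = pileup$amplicon, mu_noise = mean(qwf),
                 sd_noise = if (length(qwf) > 1L) stats::sd(qwf) else 0,
                 n_obs = length(qwf), flagged = FALSE)
}

#' Call variants from a segment pileup under the noise gate
#'
#' Candidates are alleles whose quality-weighted frequency exceeds
#' `mu + sd_mult * sd` of the segment noise (a configurable absolute floor
#' replaces the gate when the segment SD is exactly zero). Candidates pass
#' when supported by at least `min_support` merged reads and at least
#' `min_freq` allele frequency; failing candidates are retained with filter
#' `low_support` or `low_frequency`. Indels enter as left-aligned anchored
#' alleles aggregated from the realignment edit paths.
#'
#' @param pileup One amplicon pileup.
#' @param noise The matching [estimate_noise()] row.
#' @param reference,contig Reference sequences and the segment's contig.
#' @param params [slim_call_params()].
#' @return Tibble of variant calls (possibly empty): `contig`, `pos`
#'   (1-based), `ref`, `alt`, `qwf`, `support`, `depth`, `freq`, `filter`,
#'   `amplicon`.
#' @export
call_variants <- function(pileup, noise, reference, contig,
                          params = slim_call_params()) {
  empty <- tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          qwf = numeric(), support = integer(),
                          depth = integer(), freq = numeric(),
                          filter = character(), amplicon = character())
  if (!nrow(pileup$depth) || isTRUE(noise$flagged)) return(empty)
  gate <- if (noise$sd_noise > 0) {
    noise$mu_noise + params$sd_mult * noise$sd_noise
  } else {
    max(noise$mu_noise, params$zero_sigma_floor)
  }
  al <- pileup$alleles
  tot <- stats::aggregate(weight ~ gpos0, al, sum)
  wtot <- stats::setNames(tot$weight, tot$gpos0)
  dep <- stats::setNames(pileup$depth$reads, pileup$depth$gpos0)
  refseq <- reference[[contig]]
  refbase <- toupper(substr(rep(refseq, nrow(al)), al$gpos0 + 1L, al$gpos0 + 1L))
  snv <- al[al$allele != "-" & al$allele != refbase & al$count > 0, , drop = FALSE]
  snv_ref <- refbase[al$allele != "-" & al$allele != refbase & al$count > 0]
  rows <- list()
  if (nrow(snv)) {
    qwf <- snv$weight / wtot[as.character(snv$gpos0)]
    keep <- qwf > gate
    if (any(keep)) {
      rows[[1]] <- tibble::tibble(
        contig = contig, pos = snv$gpos0[keep] + 1L, ref = snv_ref[keep],
        alt = snv$allele[keep], qwf = qwf[keep],
        support = snv$count[keep],
        depth = as.integer(dep[as.character(snv$gpos0[keep])])
      )
    }
  }
  ev <- pileup$events
  if (nrow(ev)) {
    anchor_dep <- as.integer(dep[as.character(ev$gpos0)])
    anchor_w <- wtot[as.character(ev$gpos0)]
    qwf <- ev$weight / anchor_w
    qwf[!is.finite(qwf)] <- 0
    keep <- qwf > gate
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        contig = contig, pos = ev$gpos0[keep] + 1L, ref = ev$ref[keep],
        alt = ev$alt[keep], qwf = pmin(qwf[keep], 1),
        support = ev$count[keep], depth = anchor_dep[keep]
      )
    }
  }
  if (!length(rows)) return(empty)
  calls <- dplyr::bind_rows(rows)
  calls$freq <- calls$support / pmax(calls$depth, 1L)
  calls$filter <- dplyr::case_when(
    calls$support < params$min_support ~ "low_support",
    calls$freq < params$min_freq ~ "low_frequency",
    TRUE ~ "PASS"
  )
  calls$amplicon <- pileup$amplicon
  dplyr::arrange(calls, .data$pos)
}

#' Run the full calling pipeline on a simulated or real read-pair table
#'
#' @param pairs Tibble with `read1`, `read2`, `qual1`, `qual2` (as returned
#'   by [simulate_reads()] or read from FASTQ via [call_pipeline()]).
#' @param panel A complete `slim_panel`.
#' @param reference Named character vector of reference sequences.
#' @param params [slim_call_params()].
#' @return A `slim_callset`: list with `calls` (deduplicated across
#'   overlapping amplicons), `segment_calls`, `noise`, `coverage`
#'   (see [coverage_report()]), `tallies` and `pileups`.
#' @export
call_pairs <- function(pairs, panel, reference, params = slim_call_params()) {
  pairs <- assign_amplicon(pairs, panel, params$max_mismatch)
  n_total <- nrow(pairs)
  assigned <- pairs[!is.na(pairs$amplicon), , drop = FALSE]
  amprefs <- amplicon_seqs(panel, reference)
  amps <- panel$amplicons
  pileups <- vector("list", nrow(amps))
  names(pileups) <- amps$id
  for (i in seq_len(nrow(amps))) {
    sub <- assigned[assigned$amplicon == amps$id[i], , drop = FALSE]
    pileups[[i]] <- amplicon_pileup(sub$read1, sub$read2, sub$qual1, sub$qual2,
                                    amps[i, ], amprefs[[amps$id[i]]],
                                    reference, params)
  }
  noise <- purrr::map_dfr(pileups, function(p) {
    ctg <- amps$contig[match(p$amplicon, amps$id)]
    estimate_noise(p, reference, ctg, params$noise_exclusion)
  })
  seg_calls <- purrr::map_dfr(pileups, function(p) {
    ctg <- amps$contig[match(p$amplicon, amps$id)]
    call_variants(p, noise[noise$amplicon == p$amplicon, ], reference, ctg,
                  params)
  })
  calls <- seg_calls
  if (nrow(calls)) {
    calls <- dplyr::slice_max(
      dplyr::group_by(calls, .data$contig, .data$pos, .data$ref, .data$alt),
      order_by = .data$depth, n = 1L, with_ties = FALSE
    )
    calls <- dplyr::arrange(dplyr::ungroup(calls), .data$contig, .data$pos)
  }
  tallies <- tibble::tibble(
    total_pairs = n_total, assigned_pairs = nrow(assigned),
    dropped_pairs = sum(purrr::map_int(pileups, "n_dropped")),
    mapping_rate = nrow(assigned) / max(n_total, 1L)
  )
  coverage <- coverage_report(pileups, panel, tallies)
  structure(list(calls = calls, segment_calls = seg_calls, noise = noise,
                 coverage = coverage, tallies = tallies, pileups = pileups),
            class = "slim_callset")
}

#' @rdname call_pairs
#' @param fastq1,fastq2 Paths to the two FASTQ mate files.
#' @param out_dir Optional directory; when given, writes `calls.vcf`,
#'   `coverage.json` and `coverage.tsv` there.
#' @export
call_pipeline <- function(fastq1, fastq2, panel, reference,
                          params = slim_call_params(), out_dir = NULL) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  stopifnot(nrow(r1) == nrow(r2))
  pairs <- tibble::tibble(read1 = r1$seq, read2 = r2$seq,
                          qual1 = r1$qual, qual2 = r2$qual)
  res <- call_pairs(pairs, panel, reference, params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(res$calls, file.path(out_dir, "calls.vcf"),
              contig_lengths = stats::setNames(nchar(reference), names(reference)),
              noise = res$noise)
    jsonlite::write_json(coverage_as_list(res$coverage),
                         file.path(out_dir, "coverage.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_tsv(res$coverage$thresholds,
                     file.path(out_dir, "coverage.tsv"))
  }
  res
}

#' @export
print.slim_callset <- function(x, ...) {
  cat(sprintf(
    "<slim_callset> %d call(s) (%d PASS); mapping rate %.2f%%; mean depth %.0fx; uniformity %.2f%%\n",
    nrow(x$calls), sum(x$calls$filter == "PASS"),
    100 * x$tallies$mapping_rate, x$coverage$mean_depth,
    100 * x$coverage$uniformity
  ))
  invisible(x)
}

#' @export
tidy.slim_callset <- function(x, ...) x$calls

#' @export
glance.slim_callset <- function(x, ...) {
  tibble::tibble(
    n_calls = nrow(x$calls), n_pass = sum(x$calls$filter == "PASS"),
    mapping_rate = x$tallies$mapping_rate,
    on_target_rate = x$coverage$on_target_rate,
    mean_depth = x$coverage$mean_depth,
    uniformity = x$coverage$uniformity
  )
}
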