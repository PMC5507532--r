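# Panel-aware amplicon variant calling.
#
# Read pairs are assigned to amplicons by their primer prefixes (the panel is
# known, so no genome-wide mapping is needed), locally realigned against the
# expected tagged amplicon sequence with a banded affine-gap Smith-Waterman,
# merged into phred-weighted consensus reads, soft-clipped of primer/tag
# bases, and piled up per amplicon segment. Variants must exceed a
# per-segment quality-weighted noise gate (mean + 6 SD of background
# non-reference allele frequencies) and survive supporting-read and
# frequency filters.

#' Variant-calling thresholds
#'
#' @param sd_mult Noise gate multiplier: candidates need a quality-weighted
#'   frequency above `mean + sd_mult * sd` of the segment noise. Default 6.
#' @param min_support Minimum supporting merged reads for PASS. Default 20.
#' @param min_freq Minimum allele frequency (supporting/depth) for PASS.
#'   Default 0.20.
#' @param noise_exclusion Quality-weighted frequency ceiling above which an
#'   observation is treated as a candidate variant and excluded from the
#'   noise estimate. Default 0.05.
#' @param zero_sigma_floor Minimum quality-weighted frequency required when a
#'   segment's noise SD is exactly zero. Default 0.005.
#' @param max_mismatch Maximum substitutions tolerated per primer prefix
#'   during pair assignment. Default 2.
#' @param band Diagonal band half-width for realignment. Default 96.
#' @return List of class `slim_call_params`.
#' @export
slim_call_params <- function(sd_mult = 6, min_support = 20L, min_freq = 0.20,
                             noise_exclusion = 0.05, zero_sigma_floor = 0.005,
                             max_mismatch = 2L, band = 96L) {
  structure(list(sd_mult = sd_mult, min_support = as.integer(min_support),
                 min_freq = min_freq, noise_exclusion = noise_exclusion,
                 zero_sigma_floor = zero_sigma_floor,
                 max_mismatch = as.integer(max_mismatch),
                 band = as.integer(band)),
            class = "slim_call_params")
}

phred_weight <- function(q) 1 - 10^(-q / 10)

#' Assign read pairs to panel amplicons by primer prefixes
#'
#' A pair belongs to the unique amplicon whose full forward oligo matches the
#' start of read 1 and whose full reverse oligo matches the start of read 2,
#' each within `max_mismatch` substitutions. Pairs matching no amplicon or
#' more than one are unassigned. Assumes panel oligo prefixes are mutually
#' distinct beyond the mismatch tolerance (true for any panel whose
#' gene-specific primers differ, as tags are shared by design).
#'
#' @param pairs Tibble with columns `read1`, `read2` (and anything else,
#'   carried through).
#' @param panel A complete `slim_panel`.
#' @param max_mismatch Per-primer substitution tolerance. Default 2.
#' @return `pairs` with an `amplicon` column (`NA` for unassigned).
#' @export
assign_amplicon <- function(pairs, panel, max_mismatch = 2L) {
  amps <- panel$amplicons
  idx <- .assign_pairs_cpp(pairs$read1, pairs$read2,
                           amps$fwd_oligo, amps$rev_oligo,
                           as.integer(max_mismatch))
  pairs$amplicon <- ifelse(idx > 0L, amps$id[pmax(idx, 1L)], NA_character_)
  pairs
}

#' Banded local realignment of a read against an amplicon reference
#'
#' Affine-gap Smith-Waterman restricted to a diagonal band. With a band at
#' least twice the largest true indel (plus alignment slack) the result
#' equals the unbanded optimum. Scoring defaults: match +2, mismatch -4, gap
#' open -6, gap extend -1 (a gap of length L costs 6 + L).
#'
#' @param read,ref Character scalars.
#' @param band Band half-width in nt; 0 disables banding (full DP).
#' @param diag_offset Expected `ref_start - read_start` offset of the band
#'   centre (use the expected start of the read on the reference).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A one-row tibble: `score`, `ref_start`, `ref_end`, `read_start`,
#'   `read_end` (1-based inclusive) and `cigar` (`M`/`I`/`D`, soft clips
#'   implicit).
#' @export
realign_local <- function(read, ref, band = 0L, diag_offset = 0L,
                          match = 2L, mismatch = -4L,
                          gap_open = 6L, gap_extend = 1L) {
  if (!nzchar(read)) stop("empty read", call. = FALSE)
  res <- .sw_banded_cpp(read, ref, match, mismatch, gap_open, gap_extend,
                        as.integer(band), as.integer(diag_offset))
  tibble::as_tibble(res)
}

cigar_ops <- function(cigar) {
  if (!nzchar(cigar)) return(tibble::tibble(len = integer(), op = character()))
  lens <- as.integer(stringr::str_extract_all(cigar, "\\d+")[[1]])
  ops <- stringr::str_extract_all(cigar, "[MID]")[[1]]
  tibble::tibble(len = lens, op = ops)
}

# Per-reference-position view of one aligned mate. `src` holds, for every
# reference offset in [ref_start, ref_end), the 1-based read position
# providing the base, or -(read position of the base preceding a deletion).
alignment_map <- function(aln) {
  ops <- cigar_ops(aln$cigar)
  n_ref <- aln$ref_end - aln$ref_start + 1L
  src <- integer(n_ref)
  ins <- list()
  r <- aln$read_start
  p <- 1L
  for (i in seq_len(nrow(ops))) {
    L <- ops$len[i]
    if (ops$op[i] == "M") {
      src[p:(p + L - 1L)] <- r:(r + L - 1L)
      r <- r + L; p <- p + L
    } else if (ops$op[i] == "D") {
      src[p:(p + L - 1L)] <- -(r - 1L)
      p <- p + L
    } else {
      ins[[length(ins) + 1L]] <- tibble::tibble(
        after_ref = aln$ref_start + p - 2L,  # 1-based ref pos preceding insert
        read_from = r, read_len = L
      )
      r <- r + L
    }
  }
  ins <- if (length(ins)) {
    dplyr::bind_rows(ins)
  } else {
    tibble::tibble(after_ref = integer(), read_from = integer(),
                   read_len = integer())
  }
  list(ref_start = aln$ref_start, ref_end = aln$ref_end, src = src,
       insertions = ins)
}

#' Merge an aligned read pair into a phred-weighted consensus
#'
#' Positions covered by one mate are copied through. Where both mates cover
#' a position: agreeing bases keep the base with quality `min(Q1 + Q2, 60)`;
#' conflicting bases keep the higher-quality base with quality
#' `max(|Q1 - Q2|, 2)`. Pairs whose insertion/deletion structure differs
#' inside the overlap are dropped (`NULL` is returned): their indel evidence
#' is internally inconsistent.
#'
#' @param aln1,aln2 Lists describing each aligned mate: `amplicon`, `read`,
#'   `qual` (character), and the fields returned by [realign_local()]
#'   (`ref_start`, `ref_end`, `cigar`, `read_start`, `read_end`).
#' @return A `slim_merged` list: `amplicon`, `ref_start` (1-based),
#'   `bases` (per reference position; `"-"` marks deletion), `quals`,
#'   `origin` (`"mate1"`, `"mate2"`, `"both-agree"`, `"both-conflict"`),
#'   `insertions` tibble (`after_ref`, `seq`, `qual`); or `NULL` when the
#'   pair is dropped.
#' @export
merge_pair <- function(aln1, aln2) {
  if (!identical(aln1$amplicon, aln2$amplicon)) {
    stop("mates aligned to different amplicons", call. = FALSE)
  }
  m1 <- alignment_map(aln1)
  m2 <- alignment_map(aln2)
  b1 <- strsplit(aln1$read, "")[[1]]
  q1 <- utf8ToInt(aln1$qual) - 33L
  b2 <- strsplit(aln2$read, "")[[1]]
  q2 <- utf8ToInt(aln2$qual) - 33L
  lo <- min(m1$ref_start, m2$ref_start)
  hi <- max(m1$ref_end, m2$ref_end)
  n <- hi - lo + 1L
  base_at <- function(m, b, pos) {
    off <- pos - m$ref_start + 1L
    s <- m$src[off]
    ifelse(s > 0, b[abs(s)], "-")
  }
  qual_at <- function(m, q, pos) {
    off <- pos - m$ref_start + 1L
    q[abs(m$src[off])]
  }
  ov_lo <- max(m1$ref_start, m2$ref_start)
  ov_hi <- min(m1$ref_end, m2$ref_end)
  if (ov_lo <= ov_hi) {
    d1 <- m1$src[(ov_lo:ov_hi) - m1$ref_start + 1L] < 0
    d2 <- m2$src[(ov_lo:ov_hi) - m2$ref_start + 1L] < 0
    i1 <- m1$insertions[m1$insertions$after_ref >= ov_lo - 1L &
                          m1$insertions$after_ref < ov_hi, , drop = FALSE]
    i2 <- m2$insertions[m2$insertions$after_ref >= ov_lo - 1L &
                          m2$insertions$after_ref < ov_hi, , drop = FALSE]
    ins_sig <- function(ii, b) {
      if (!nrow(ii)) return(character(0))
      sprintf("%d:%s", ii$after_ref,
              vapply(seq_len(nrow(ii)), function(k) {
                paste(b[ii$read_from[k]:(ii$read_from[k] + ii$read_len[k] - 1L)],
                      collapse = "")
              }, character(1)))
    }
    if (!identical(d1, d2) ||
        !identical(sort(ins_sig(i1, b1)), sort(ins_sig(i2, b2)))) {
      return(NULL)
    }
  }
  bases <- character(n); quals <- integer(n); origin <- character(n)
  for (pos in lo:hi) {
    k <- pos - lo + 1L
    in1 <- pos >= m1$ref_start && pos <= m1$ref_end
    in2 <- pos >= m2$ref_start && pos <= m2$ref_end
    if (in1 && in2) {
      x1 <- base_at(m1, b1, pos); x2 <- base_at(m2, b2, pos)
      y1 <- qual_at(m1, q1, pos); y2 <- qual_at(m2, q2, pos)
      if (x1 == x2) {
        bases[k] <- x1; quals[k] <- min(y1 + y2, 60L); origin[k] <- "both-agree"
      } else if (y1 >= y2) {
        bases[k] <- x1; quals[k] <- max(abs(y1 - y2), 2L); origin[k] <- "both-conflict"
      } else {
        bases[k] <- x2; quals[k] <- max(abs(y1 - y2), 2L); origin[k] <- "both-conflict"
      }
    } else if (in1) {
      bases[k] <- base_at(m1, b1, pos); quals[k] <- qual_at(m1, q1, pos)
      origin[k] <- "mate1"
    } else if (in2) {
      bases[k] <- base_at(m2, b2, pos); quals[k] <- qual_at(m2, q2, pos)
      origin[k] <- "mate2"
    } else {
      # internal gap between non-overlapping mates: no evidence here
      bases[k] <- "N"; quals[k] <- NA_integer_; origin[k] <- "gap"
    }
  }
  covered <- origin != "gap"
  quals[covered] <- pmin(pmax(quals[covered], 2L), 60L)
  ins_all <- dplyr::bind_rows(
    if (nrow(m1$insertions)) dplyr::mutate(
      m1$insertions,
      seq = vapply(seq_len(nrow(m1$insertions)), function(k) {
        paste(b1[.data$read_from[k]:(.data$read_from[k] + .data$read_len[k] - 1L)],
              collapse = "")
      }, character(1)),
      qual = vapply(seq_len(nrow(m1$insertions)), function(k) {
        min(q1[.data$read_from[k]:(.data$read_from[k] + .data$read_len[k] - 1L)])
      }, numeric(1))
    ),
    if (nrow(m2$insertions)) dplyr::mutate(
      m2$insertions,
      seq = vapply(seq_len(nrow(m2$insertions)), function(k) {
        paste(b2[.data$read_from[k]:(.data$read_from[k] + .data$read_len[k] - 1L)],
              collapse = "")
      }, character(1)),
      qual = vapply(seq_len(nrow(m2$insertions)), function(k) {
        min(q2[.data$read_from[k]:(.data$read_from[k] + .data$read_len[k] - 1L)])
      }, numeric(1))
    )
  )
  if (!is.null(ins_all) && nrow(ins_all)) {
    ins_all <- dplyr::distinct(ins_all[c("after_ref", "seq", "qual")],
                               .data$after_ref, .data$seq, .keep_all = TRUE)
  } else {
    ins_all <- tibble::tibble(after_ref = integer(), seq = character(),
                              qual = numeric())
  }
  structure(list(amplicon = aln1$amplicon, ref_start = lo, bases = bases,
                 quals = quals, origin = origin, insertions = ins_all),
            class = "slim_merged")
}

#' Soft-clip primer and tag bases from a merged read
#'
#' Restricts a merged consensus to the amplicon's interior: contributions
#' start after the forward gene-specific primer's 3' end and stop before the
#' reverse primer's 3' end. On the tagged amplicon reference that interior
#' is exactly the region between the two full oligos.
#'
#' @param merged A `slim_merged` from [merge_pair()].
#' @param panel The panel.
#' @return The clipped `slim_merged` with a `gpos0` field (0-based genomic
#'   position of the first retained base), or `NULL` if nothing remains.
#' @export
clip_primers <- function(merged, panel) {
  amps <- panel$amplicons
  a <- amps[match(merged$amplicon, amps$id), ]
  stopifnot(nrow(a) == 1L, !is.na(a$id))
  clip_lo <- nchar(a$fwd_oligo) + 1L                       # 1-based ampref
  amplen <- (a$end - a$start) +
    (nchar(a$fwd_oligo) - nchar(a$fwd_gene)) +
    (nchar(a$rev_oligo) - nchar(a$rev_gene))
  clip_hi <- amplen - nchar(a$rev_oligo)
  lo <- max(merged$ref_start, clip_lo)
  hi <- min(merged$ref_start + length(merged$bases) - 1L, clip_hi)
  if (lo > hi) return(NULL)
  keep <- (lo:hi) - merged$ref_start + 1L
  ins <- merged$insertions
  ins <- ins[ins$after_ref >= lo & ins$after_ref < hi, , drop = FALSE]
  out <- merged
  out$ref_start <- lo
  out$bases <- merged$bases[keep]
  out$quals <- merged$quals[keep]
  out$origin <- merged$origin[keep]
  out$insertions <- ins
  out$gpos0 <- a$start + nchar(a$fwd_gene) + (lo - clip_lo)
  out
}
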