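# Tiled amplicon panel design with stem-loop inhibition oligos.
#
# A panel is an ordered set of amplicons along a reference, where adjacent
# amplicons overlap and the two "inner" primers of every junction (the reverse
# primer of the left amplicon and the forward primer of the right one, the
# pair that would amplify the unwanted short overlap product) carry the SAME
# universal tag, and one of them additionally carries a short 5' prefix of the
# other's gene-specific sequence. The overlap product then folds into a
# terminal stem that sequesters its own primer-binding site.
#
# Coordinates are 0-based half-open everywhere (BED convention); only VCF
# output is 1-based.

new_slim_panel <- function(amplicons, junctions, roi, tags = slim_tags(),
                           params = list()) {
  structure(
    list(amplicons = amplicons, junctions = junctions, roi = roi,
         tags = tags, params = params),
    class = "slim_panel"
  )
}

#' @export
print.slim_panel <- function(x, ...) {
  cat(sprintf(
    "<slim_panel> %d amplicon(s), %d junction(s), %d roi interval(s)\n",
    nrow(x$amplicons), nrow(x$junctions), nrow(x$roi)
  ))
  if (nrow(x$amplicons)) {
    sizes <- x$amplicons$end - x$amplicons$start
    cat(sprintf("  insert sizes %d-%d bp", min(sizes), max(sizes)))
    if (nrow(x$junctions)) {
      ov <- x$junctions$ov_end - x$junctions$ov_start
      cat(sprintf(", overlaps %d-%d bp", min(ov), max(ov)))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
tidy.slim_panel <- function(x, ...) x$amplicons

empty_junctions <- function() {
  tibble::tibble(
    junction = integer(), contig = character(),
    left_id = character(), right_id = character(),
    ov_start = integer(), ov_end = integer(),
    shared_tag_id = character(), insert_len = integer(),
    insert_side = character()
  )
}

as_roi_tbl <- function(roi) {
  roi <- tibble::as_tibble(roi)
  stopifnot(all(c("contig", "start", "end") %in% names(roi)))
  dplyr::mutate(roi[c("contig", "start", "end")],
                start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Tile a region of interest with overlapping amplicons
#'
#' Lays out amplicon insert intervals (primer binding sites included) that
#' cover each target interval. The layout extends `primer_margin` bp beyond
#' each interval so that outermost primer sites sit outside the region of
#' interest, and chains of overlapping amplicons guarantee that every
#' junction primer site inside the region is covered by the neighbouring
#' amplicon's insert. Amplicon count for a long interval is chosen to keep
#' inserts near `target_len` with overlaps near `target_overlap`, then insert
#' length is equalised across the chain. Deterministic: identical inputs give
#' identical layouts.
#'
#' @param roi Data frame with columns `contig`, `start`, `end`
#'   (0-based half-open target intervals).
#' @param reference Named character vector of reference sequences
#'   (as from [read_fasta()]).
#' @param size_bounds Allowed insert length range in bp. Default `c(263, 380)`.
#' @param overlap_bounds Allowed junction overlap range in bp.
#'   Default `c(49, 193)`.
#' @param target_len,target_overlap Preferred insert length and overlap used
#'   to pick the amplicon count. Defaults 331 and 100 bp.
#' @param primer_margin Margin in bp added on each side of an interval so
#'   outer primers fall outside it. Default 30.
#' @return A `slim_panel` with amplicon intervals and junction bookkeeping;
#'   primers and tags are not yet assigned (see [slim_select_primers()],
#'   [assign_tags()], [build_slimamp_oligos()] or the one-shot
#'   [design_panel()]).
#' @export
tile_roi <- function(roi, reference, size_bounds = c(263L, 380L),
                     overlap_bounds = c(49L, 193L), target_len = 331L,
                     target_overlap = 100L, primer_margin = 30L) {
  roi <- as_roi_tbl(roi)
  stopifnot(all(roi$contig %in% names(reference)), all(roi$end > roi$start))
  amps <- list()
  juncs <- list()
  chain <- 0L
  n_amp <- 0L
  jn <- 0L
  for (i in seq_len(nrow(roi))) {
    chain <- chain + 1L
    ctg <- roi$contig[i]
    reflen <- nchar(reference[[ctg]])
    gs <- max(0L, roi$start[i] - primer_margin)
    ge <- min(reflen, roi$end[i] + primer_margin)
    layout <- tile_interval(gs, ge, reflen, size_bounds, overlap_bounds,
                            target_len, target_overlap,
                            label = sprintf("%s:%d-%d", ctg, roi$start[i], roi$end[i]))
    k <- nrow(layout)
    ids <- sprintf("amp%03d", n_amp + seq_len(k))
    n_amp <- n_amp + k
    amps[[chain]] <- tibble::tibble(
      id = ids, contig = ctg, start = layout$start, end = layout$end,
      chain = chain
    )
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        jn <- jn + 1L
        juncs[[jn]] <- tibble::tibble(
          junction = jn, contig = ctg,
          left_id = ids[j], right_id = ids[j + 1L],
          ov_start = layout$start[j + 1L], ov_end = layout$end[j],
          shared_tag_id = NA_character_, insert_len = NA_integer_,
          insert_side = NA_character_
        )
      }
    }
  }
  new_slim_panel(
    amplicons = dplyr::bind_rows(amps),
    junctions = if (jn) dplyr::bind_rows(juncs) else empty_junctions(),
    roi = roi,
    params = list(size_bounds = size_bounds, overlap_bounds = overlap_bounds,
                  target_len = target_len, target_overlap = target_overlap,
                  primer_margin = primer_margin)
  )
}

# Tile one margin-extended interval [gs, ge); returns tibble(start, end).
tile_interval <- function(gs, ge, reflen, size_bounds, overlap_bounds,
                          target_len, target_overlap, label) {
  G <- ge - gs
  min_len <- size_bounds[1]; max_len <- size_bounds[2]
  if (G <= max_len) {
    L <- max(G, min_len)
    if (L > reflen) {
      stop(sprintf("interval %s untileable: reference shorter than minimum insert", label),
           call. = FALSE)
    }
    s <- gs - (L - G) %/% 2L
    s <- max(0L, min(s, reflen - L))
    return(tibble::tibble(start = as.integer(s), end = as.integer(s + L)))
  }
  omin <- overlap_bounds[1]; omax <- overlap_bounds[2]
  k0 <- max(2L, as.integer(round((G - target_overlap) / (target_len - target_overlap))))
  for (dk in c(0L, unlist(lapply(1:25, function(d) c(d, -d))))) {
    k <- k0 + dk
    if (k < 2L) next
    # prefer one bp inside the overlap bounds so integer rounding of the
    # equalised layout cannot cross them
    for (pad in c(1L, 0L)) {
      lo <- max(min_len, ceiling((G + (k - 1) * (omin + pad)) / k))
      hi <- min(max_len, floor((G + (k - 1) * (omax - pad)) / k))
      if (lo > hi) next
      L <- as.integer(min(max(target_len, lo), hi))
      step <- (G - L) / (k - 1)
      starts <- gs + as.integer(round((seq_len(k) - 1L) * step))
      out <- tibble::tibble(start = starts, end = starts + L)
      ov <- out$end[-k] - out$start[-1]
      if (all(ov >= omin & ov <= omax)) return(out)
    }
  }
  stop(sprintf("interval %s untileable under size bounds [%d,%d] and overlap bounds [%d,%d]",
               label, min_len, max_len, omin, omax), call. = FALSE)
}

#' Screen a primer 3' end against known polymorphisms
#'
#' A primer is rejected when any masked variant with minor allele frequency
#' above `maf_threshold` falls under the last `window` genomic positions of
#' its 3' end (strand-aware: the right end of a forward primer, the left end
#' of a reverse primer). Polymorphism under the 3' end risks allele-specific
#' amplification failure.
#'
#' @param primer Data frame with columns `contig`, `start`, `end`,
#'   `orientation` (`"forward"`/`"reverse"`), 0-based half-open genomic
#'   footprint of the primer.
#' @param mask Data frame with columns `contig`, `pos` (0-based), `maf`;
#'   `NULL` means no masked sites.
#' @param maf_threshold Minor allele frequency above which a site disqualifies
#'   a primer. Default 0.0009 (0.09\%).
#' @param window Number of 3'-terminal bases screened. Default 10.
#' @return Logical vector, `TRUE` when the primer passes.
#' @export
check_3prime_snps <- function(primer, mask, maf_threshold = 9e-4, window = 10L) {
  primer <- tibble::as_tibble(primer)
  if (is.null(mask) || nrow(tibble::as_tibble(mask)) == 0L) {
    return(rep(TRUE, nrow(primer)))
  }
  mask <- tibble::as_tibble(mask)
  stopifnot(all(c("contig", "pos", "maf") %in% names(mask)),
            all(mask$maf >= 0 & mask$maf <= 1))
  hot <- mask[mask$maf > maf_threshold, , drop = FALSE]
  purrr::pmap_lgl(
    primer[c("contig", "start", "end", "orientation")],
    function(contig, start, end, orientation) {
      w <- min(window, end - start)
      if (orientation == "forward") {
        lo <- end - w; hi <- end
      } else {
        lo <- start; hi <- start + w
      }
      !any(hot$contig == contig & hot$pos >= lo & hot$pos < hi)
    }
  )
}

has_long_homopolymer <- function(seq, max_run = 4L) {
  stringr::str_detect(toupper(seq), sprintf("A{%d}|C{%d}|G{%d}|T{%d}",
                                            max_run + 1L, max_run + 1L,
                                            max_run + 1L, max_run + 1L))
}

#' Select a gene-specific primer pair for an amplicon window
#'
#' Enumerates candidate primers anchored at the amplicon boundaries (the
#' forward primer starting at `start`, the reverse primer ending at `end`,
#' each optionally shifted by up to `max_shift` bp in either direction, so a
#' homopolymer or masked site at the anchor can be escaped), varying primer
#' length within `length_bounds`. Candidates must fall inside the melting
#' temperature window, contain no homopolymer run longer than
#' `max_homopolymer`, and pass [check_3prime_snps()]. Ranking is by distance
#' of Tm from `tm_target`, then presence of a 3' G/C clamp, then smaller
#' genomic start, then shorter length -- a deterministic tie-break.
#'
#' @param reference Named character vector of reference sequences.
#' @param contig,start,end Amplicon insert interval (0-based half-open).
#' @param tm_window,tm_target Acceptable Tm window and preferred Tm in
#'   degrees Celsius. Defaults `c(57, 63)` and 60.
#' @param length_bounds Primer length range in nt. Default `c(18, 30)`.
#' @param mask,maf_threshold,snp_window Passed to [check_3prime_snps()].
#' @param max_shift Maximum shift of the anchor in bp (either direction).
#'   Default 0.
#' @param max_homopolymer Longest allowed single-base run. Default 4.
#' @return A two-row tibble (forward and reverse) with columns `orientation`,
#'   `gene_seq`, `start`, `end`, `tm`.
#' @export
slim_select_primers <- function(reference, contig, start, end,
                                tm_window = c(57, 63), tm_target = 60,
                                length_bounds = c(18L, 30L), mask = NULL,
                                maf_threshold = 9e-4, snp_window = 10L,
                                max_shift = 0L, max_homopolymer = 4L) {
  refseq <- reference[[contig]]
  stopifnot(!is.null(refseq), end - start >= 2L * length_bounds[1])
  pick <- function(orientation) {
    grid <- tidyr::expand_grid(shift = (-max_shift):max_shift,
                               len = length_bounds[1]:length_bounds[2])
    if (orientation == "forward") {
      s <- start - grid$shift
      e <- s + grid$len
    } else {
      e <- end + grid$shift
      s <- e - grid$len
    }
    ok <- s >= 0L & e <= nchar(refseq)
    s <- s[ok]; e <- e[ok]
    site <- substr(rep(refseq, length(s)), s + 1L, e)
    gene <- if (orientation == "forward") site else reverse_complement(site)
    cand <- tibble::tibble(orientation = orientation,
                           gene_seq = toupper(gene), start = s, end = e)
    cand$tm <- melting_temp(cand$gene_seq)
    cand$contig <- contig
    ok_tm <- cand$tm >= tm_window[1] & cand$tm <= tm_window[2]
    ok_homo <- !has_long_homopolymer(cand$gene_seq, max_homopolymer)
    ok_snp <- check_3prime_snps(cand, mask, maf_threshold, snp_window)
    keep <- cand[ok_tm & ok_homo & ok_snp, , drop = FALSE]
    if (!nrow(keep)) {
      stop(sprintf(
        "no %s primer for %s:%d-%d passes (tm window fails: %d, homopolymer fails: %d, 3'-SNP rule fails: %d of %d candidates)",
        orientation, contig, start, end,
        sum(!ok_tm), sum(!ok_homo), sum(!ok_snp), nrow(cand)
      ), call. = FALSE)
    }
    keep$clamp <- stringr::str_detect(keep$gene_seq, "[GC]$")
    keep <- keep[order(abs(keep$tm - tm_target), !keep$clamp,
                       keep$start, keep$end - keep$start), , drop = FALSE]
    keep[1L, c("orientation", "gene_seq", "start", "end", "tm")]
  }
  dplyr::bind_rows(pick("forward"), pick("reverse"))
}

#' Assign universal tags along each amplicon chain
#'
#' Two constraints drive the assignment: within an amplicon the forward and
#' reverse primers carry different tags, and at every junction the two inner
#' primers (reverse of the left amplicon, forward of the right) carry the
#' same tag. Chains are therefore 2-coloured by alternating the orientation
#' of the (t2, t1) assignment; isolated amplicons get forward = t2,
#' reverse = t1. Both constraints are re-checked after assignment.
#'
#' @param panel A `slim_panel`.
#' @param tags Named character vector of the two tag sequences.
#' @return The panel with `fwd_tag_id`/`rev_tag_id` (and tag sequences) set
#'   and junction `shared_tag_id` recorded.
#' @export
assign_tags <- function(panel, tags = slim_tags()) {
  stopifnot(inherits(panel, "slim_panel"), length(tags) == 2L)
  amps <- dplyr::arrange(panel$amplicons, .data$chain, .data$start)
  pos_in_chain <- stats::ave(seq_len(nrow(amps)), amps$chain,
                             FUN = seq_along)
  odd <- pos_in_chain %% 2L == 1L
  amps$fwd_tag_id <- ifelse(odd, names(tags)[2], names(tags)[1])
  amps$rev_tag_id <- ifelse(odd, names(tags)[1], names(tags)[2])
  amps$fwd_tag <- unname(tags[amps$fwd_tag_id])
  amps$rev_tag <- unname(tags[amps$rev_tag_id])
  stopifnot(all(amps$fwd_tag_id != amps$rev_tag_id))
  panel$amplicons <- amps
  if (nrow(panel$junctions)) {
    left <- match(panel$junctions$left_id, amps$id)
    right <- match(panel$junctions$right_id, amps$id)
    stopifnot(all(amps$rev_tag_id[left] == amps$fwd_tag_id[right]))
    panel$junctions$shared_tag_id <- amps$rev_tag_id[left]
  }
  panel$tags <- tags
  panel
}

#' Build the full tagged oligos, with stem-forming inserts at junctions
#'
#' Every primer becomes `tag + insert + gene` in 5'->3' order, where the
#' insert is empty except at junctions: there, a 5' prefix of the partner
#' inner primer's gene-specific sequence is placed between tag and gene on
#' one side of the junction, so the overlap product's two ends become exact
#' reverse complements over `tag length + insert length` bases and fold into
#' the inhibitory terminal stem.
#'
#' @param panel A `slim_panel` with primers selected and tags assigned.
#' @param insert_len Insert length in nt; scalar or one value per junction.
#'   Deployed designs use 7-14 nt; proof-of-concept studies also use
#'   4, 8, 12, 16.
#' @param insert_side `"left_rev"` (default): insert the right amplicon's
#'   forward-primer prefix (F2^) into the left amplicon's reverse primer.
#'   `"right_fwd"`: the mirrored R1^ construction.
#' @return The panel with `fwd_insert`, `rev_insert`, full `fwd_oligo`,
#'   `rev_oligo` and per-oligo `fwd_tm`/`rev_tm` (nearest-neighbor Tm of the
#'   gene-specific part) filled in.
#' @export
build_slimamp_oligos <- function(panel, insert_len = 12L,
                                 insert_side = c("left_rev", "right_fwd")) {
  insert_side <- match.arg(insert_side)
  stopifnot(inherits(panel, "slim_panel"))
  amps <- panel$amplicons
  stopifnot(!is.null(amps$fwd_gene), !is.null(amps$fwd_tag))
  jn <- panel$junctions
  n_j <- nrow(jn)
  insert_len <- as.integer(rep_len(insert_len, max(n_j, 1L)))
  amps$fwd_insert <- ""
  amps$rev_insert <- ""
  if (n_j) {
    for (j in seq_len(n_j)) {
      k <- insert_len[j]
      li <- match(jn$left_id[j], amps$id)
      ri <- match(jn$right_id[j], amps$id)
      if (insert_side == "left_rev") {
        partner <- amps$fwd_gene[ri]
        if (k > nchar(partner)) {
          stop(sprintf("junction %d: insert length %d exceeds partner primer length %d",
                       j, k, nchar(partner)), call. = FALSE)
        }
        amps$rev_insert[li] <- toupper(substr(partner, 1L, k))
      } else {
        partner <- amps$rev_gene[li]
        if (k > nchar(partner)) {
          stop(sprintf("junction %d: insert length %d exceeds partner primer length %d",
                       j, k, nchar(partner)), call. = FALSE)
        }
        amps$fwd_insert[ri] <- toupper(substr(partner, 1L, k))
      }
    }
    jn$insert_len <- insert_len
    jn$insert_side <- insert_side
  }
  amps$fwd_oligo <- paste0(tolower(amps$fwd_tag), amps$fwd_insert, toupper(amps$fwd_gene))
  amps$rev_oligo <- paste0(tolower(amps$rev_tag), amps$rev_insert, toupper(amps$rev_gene))
  amps$fwd_tm <- melting_temp(amps$fwd_gene)
  amps$rev_tm <- melting_temp(amps$rev_gene)
  col_order <- c("id", "contig", "start", "end", "chain",
                 "fwd_tag_id", "rev_tag_id", "fwd_tag", "rev_tag",
                 "fwd_gene", "rev_gene", "fwd_insert", "rev_insert",
                 "fwd_oligo", "rev_oligo", "fwd_tm", "rev_tm")
  panel$amplicons <- amps[col_order]
  panel$junctions <- jn
  panel
}

#' One-shot panel design
#'
#' [tile_roi()], per-amplicon [slim_select_primers()], [assign_tags()] and
#' [build_slimamp_oligos()] chained with shared defaults.
#'
#' @inheritParams tile_roi
#' @inheritParams slim_select_primers
#' @inheritParams build_slimamp_oligos
#' @param tags Tag sequences, default [slim_tags()].
#' @return A complete `slim_panel`.
#' @export
design_panel <- function(roi, reference, size_bounds = c(263L, 380L),
                         overlap_bounds = c(49L, 193L), target_len = 331L,
                         target_overlap = 100L, primer_margin = 30L,
                         tm_window = c(57, 63), tm_target = 60,
                         length_bounds = c(18L, 30L), mask = NULL,
                         maf_threshold = 9e-4, snp_window = 10L,
                         max_shift = 5L, insert_len = 12L,
                         insert_side = "left_rev", tags = slim_tags()) {
  panel <- tile_roi(roi, reference, size_bounds, overlap_bounds,
                    target_len, target_overlap, primer_margin)
  amps <- panel$amplicons
  prs <- purrr::pmap(amps[c("contig", "start", "end")], function(contig, start, end) {
    slim_select_primers(reference, contig, start, end, tm_window, tm_target,
                        length_bounds, mask, maf_threshold, snp_window,
                        max_shift)
  })
  amps$fwd_gene <- purrr::map_chr(prs, ~ .x$gene_seq[1])
  amps$rev_gene <- purrr::map_chr(prs, ~ .x$gene_seq[2])
  # primers may shift outward; widen the insert accordingly
  amps$start <- purrr::map_int(prs, ~ as.integer(.x$start[1]))
  amps$end <- purrr::map_int(prs, ~ as.integer(.x$end[2]))
  panel$amplicons <- amps
  if (nrow(panel$junctions)) {
    li <- match(panel$junctions$left_id, amps$id)
    ri <- match(panel$junctions$right_id, amps$id)
    panel$junctions$ov_start <- amps$start[ri]
    panel$junctions$ov_end <- amps$end[li]
  }
  panel <- assign_tags(panel, tags)
  build_slimamp_oligos(panel, insert_len, insert_side)
}

gene_len <- function(x) nchar(x)

#' Expected amplicon, overlap and spanning product sequences
#'
#' `amplicon_seqs()` returns the expected tagged product of every amplicon
#' (full forward oligo, genomic interior, reverse complement of the full
#' reverse oligo). `junction_overlap_seq()` returns the unwanted short
#' product of a junction's two inner primers -- the strand whose terminal
#' stem [find_terminal_stem()] measures -- and `junction_spanning_seq()` the
#' long product of the two outer primers.
#'
#' @param panel A complete `slim_panel`.
#' @param reference Named character vector of reference sequences.
#' @param junction Junction number (row of `panel$junctions`).
#' @return Named character vector (amplicon ids), or a single string.
#' @export
amplicon_seqs <- function(panel, reference) {
  amps <- panel$amplicons
  interior <- purrr::pmap_chr(
    amps[c("contig", "start", "end", "fwd_gene", "rev_gene")],
    function(contig, start, end, fwd_gene, rev_gene) {
      substr(reference[[contig]], start + nchar(fwd_gene) + 1L,
             end - nchar(rev_gene))
    }
  )
  out <- paste0(amps$fwd_oligo, toupper(interior),
                reverse_complement(amps$rev_oligo))
  names(out) <- amps$id
  out
}

#' @rdname amplicon_seqs
#' @export
junction_overlap_seq <- function(panel, reference, junction = 1L) {
  jn <- panel$junctions[panel$junctions$junction == junction, ]
  stopifnot(nrow(jn) == 1L)
  amps <- panel$amplicons
  rf <- amps[match(jn$right_id, amps$id), ]  # forward primer of overlap product
  lr <- amps[match(jn$left_id, amps$id), ]   # reverse primer of overlap product
  interior <- substr(reference[[jn$contig]],
                     jn$ov_start + nchar(rf$fwd_gene) + 1L,
                     jn$ov_end - nchar(lr$rev_gene))
  paste0(rf$fwd_oligo, toupper(interior), reverse_complement(lr$rev_oligo))
}

#' @rdname amplicon_seqs
#' @export
junction_spanning_seq <- function(panel, reference, junction = 1L) {
  jn <- panel$junctions[panel$junctions$junction == junction, ]
  stopifnot(nrow(jn) == 1L)
  amps <- panel$amplicons
  lf <- amps[match(jn$left_id, amps$id), ]
  rr <- amps[match(jn$right_id, amps$id), ]
  interior <- substr(reference[[jn$contig]],
                     lf$start + nchar(lf$fwd_gene) + 1L,
                     rr$end - nchar(rr$rev_gene))
  paste0(lf$fwd_oligo, toupper(interior), reverse_complement(rr$rev_oligo))
}

#' Export and re-import a panel manifest
#'
#' Writes the panel as plain-text files under `dir`: BED of insert intervals,
#' BED of primer footprints (strand-aware), a tab-separated oligo table, a
#' FASTA of expected tagged amplicon sequences, a junction manifest and the
#' region-of-interest BED. `read_panel()` reconstructs an identical
#' `slim_panel` from those files.
#'
#' @param panel A complete `slim_panel`.
#' @param reference Named character vector of reference sequences.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix, default `"panel"`.
#' @return `export_panel()` returns the vector of written paths, invisibly;
#'   `read_panel()` returns a `slim_panel`.
#' @export
export_panel <- function(panel, reference, dir, prefix = "panel") {
  stopifnot(inherits(panel, "slim_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  amps <- panel$amplicons
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  readr::write_tsv(amps[c("contig", "start", "end", "id")],
                   p("_inserts.bed"), col_names = FALSE)
  primers <- dplyr::bind_rows(
    tibble::tibble(contig = amps$contig, start = amps$start,
                   end = amps$start + nchar(amps$fwd_gene),
                   name = paste0(amps$id, "_fwd"), score = 0L, strand = "+"),
    tibble::tibble(contig = amps$contig, start = amps$end - nchar(amps$rev_gene),
                   end = amps$end, name = paste0(amps$id, "_rev"),
                   score = 0L, strand = "-")
  )
  primers <- dplyr::arrange(primers, .data$contig, .data$start, .data$name)
  readr::write_tsv(primers, p("_primers.bed"), col_names = FALSE)
  oligos <- dplyr::bind_rows(
    tibble::tibble(id = amps$id, primer = "fwd", tag_id = amps$fwd_tag_id,
                   tag_seq = amps$fwd_tag, insert_seq = amps$fwd_insert,
                   gene_seq = amps$fwd_gene, oligo = amps$fwd_oligo,
                   tm = amps$fwd_tm),
    tibble::tibble(id = amps$id, primer = "rev", tag_id = amps$rev_tag_id,
                   tag_seq = amps$rev_tag, insert_seq = amps$rev_insert,
                   gene_seq = amps$rev_gene, oligo = amps$rev_oligo,
                   tm = amps$rev_tm)
  )
  readr::write_tsv(oligos, p("_oligos.tsv"))
  write_fasta(amplicon_seqs(panel, reference), p("_amplicons.fasta"))
  readr::write_tsv(panel$junctions, p("_junctions.tsv"))
  readr::write_tsv(panel$roi, p("_roi.bed"), col_names = FALSE)
  invisible(vapply(c("_inserts.bed", "_primers.bed", "_oligos.tsv",
                     "_amplicons.fasta", "_junctions.tsv", "_roi.bed"),
                   p, character(1)))
}

#' @rdname export_panel
#' @export
read_panel <- function(dir, prefix = "panel") {
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  inserts <- readr::read_tsv(p("_inserts.bed"),
                             col_names = c("contig", "start", "end", "id"),
                             col_types = "ciic", progress = FALSE)
  oligos <- readr::read_tsv(p("_oligos.tsv"), col_types = "cccccccd",
                            progress = FALSE)
  oligos$insert_seq[is.na(oligos$insert_seq)] <- ""
  fwd <- oligos[oligos$primer == "fwd", ]
  rev <- oligos[oligos$primer == "rev", ]
  amps <- inserts
  m <- match(amps$id, fwd$id)
  amps$fwd_tag_id <- fwd$tag_id[m]; amps$fwd_tag <- fwd$tag_seq[m]
  amps$fwd_insert <- fwd$insert_seq[m]; amps$fwd_gene <- fwd$gene_seq[m]
  amps$fwd_oligo <- fwd$oligo[m]; amps$fwd_tm <- fwd$tm[m]
  m <- match(amps$id, rev$id)
  amps$rev_tag_id <- rev$tag_id[m]; amps$rev_tag <- rev$tag_seq[m]
  amps$rev_insert <- rev$insert_seq[m]; amps$rev_gene <- rev$gene_seq[m]
  amps$rev_oligo <- rev$oligo[m]; amps$rev_tm <- rev$tm[m]
  jn <- readr::read_tsv(p("_junctions.tsv"), col_types = "iccciicic",
                        progress = FALSE)
  if (!nrow(jn)) jn <- empty_junctions()
  roi <- readr::read_tsv(p("_roi.bed"), col_names = c("contig", "start", "end"),
                         col_types = "cii", progress = FALSE)
  # chains recovered from junction adjacency
  amps$chain <- NA_integer_
  chain <- 0L
  for (i in seq_len(nrow(amps))) {
    if (is.na(amps$chain[i])) {
      chain <- chain + 1L
      amps$chain[i] <- chain
      cur <- amps$id[i]
      repeat {
        nxt <- jn$right_id[jn$left_id == cur]
        if (!length(nxt)) break
        j <- match(nxt[1], amps$id)
        if (!is.na(amps$chain[j])) break
        amps$chain[j] <- chain
        cur <- nxt[1]
      }
    }
  }
  tags <- unique(oligos[c("tag_id", "tag_seq")])
  tagv <- stats::setNames(tags$tag_seq, tags$tag_id)
  tagv <- tagv[order(names(tagv))]
  col_order <- c("id", "contig", "start", "end", "chain",
                 "fwd_tag_id", "rev_tag_id", "fwd_tag", "rev_tag",
                 "fwd_gene", "rev_gene", "fwd_insert", "rev_insert",
                 "fwd_oligo", "rev_oligo", "fwd_tm", "rev_tm")
  new_slim_panel(amps[col_order], jn, roi, tags = tagv)
}
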