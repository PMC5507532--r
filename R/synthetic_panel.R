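# A synthetic full-scale panel emulating a two-gene clinical exon panel:
# eight exon-like target intervals (including one ~4.9 kb and one ~3.4 kb
# block, the sizes that require the longest tiling chains) whose default
# tiling yields 91 amplicons. Everything is generated from a seed; no
# external sequence is used.

#' Synthetic full-scale tiled panel
#'
#' Generates a random reference with eight exon-like intervals and designs a
#' complete panel over them with the default tiling and primer parameters.
#' Interval sizes are fixed so the default tiling produces a 91-amplicon
#' panel with chains of up to 21 amplicons, the scale of a two-gene coding
#' panel.
#'
#' @param seed Seed for the reference sequence.
#' @param insert_len Junction insert length, default 12.
#' @return List with `panel`, `reference` and `roi`.
#' @export
synthetic_panel <- function(seed = 7L, insert_len = 12L) {
  exon_sizes <- c(4900L, 3400L, 2150L, 2150L, 2150L, 2150L, 2150L,
                  1250L, 1250L)
  gap <- 400L
  starts <- 200L + cumsum(c(0L, utils::head(exon_sizes, -1) + gap))
  roi <- tibble::tibble(contig = "chrS", start = starts,
                        end = starts + exon_sizes)
  reflen <- max(roi$end) + 200L
  reference <- make_reference(reflen, 0.45, seed, "chrS")
  panel <- design_panel(roi, reference, max_shift = 20L,
                        insert_len = insert_len)
  list(panel = panel, reference = reference, roi = roi)
}

#' Deterministic synthetic variant set for a panel
#'
#' Places heterozygous/homozygous SNVs and indels (deletion lengths up to
#' 40 bp, 1 bp insertions) at safe positions: inside the primer-clipped
#' interior of distinct amplicons, outside junction overlaps, with padding
#' so no edit disturbs a primer binding site or crosses a segment boundary.
#'
#' @param panel,reference A designed panel and its reference.
#' @param n_het_snv,n_hom_snv SNV counts. Defaults 20 and 10.
#' @param del_lens Heterozygous deletion lengths. Default `c(1, 4, 11, 40)`.
#' @param ins_lens Heterozygous insertion lengths. Default `c(1)`.
#' @param seed Seed for position/base choices.
#' @return A [variant_spec()] tibble.
#' @export
synthetic_variant_specs <- function(panel, reference, n_het_snv = 20L,
                                    n_hom_snv = 10L,
                                    del_lens = c(1L, 4L, 11L, 40L),
                                    ins_lens = 1L, seed = 11L) {
  amps <- panel$amplicons
  jn <- panel$junctions
  pad <- 10L
  safe <- purrr::pmap(amps[c("id", "contig", "start", "end", "fwd_gene", "rev_gene")],
                      function(id, contig, start, end, fwd_gene, rev_gene) {
    lo <- start + nchar(fwd_gene) + pad
    hi <- end - nchar(rev_gene) - pad
    sub <- jn[jn$left_id == id | jn$right_id == id, , drop = FALSE]
    pos <- if (lo < hi) lo:(hi - 1L) else integer(0)
    if (nrow(sub)) {
      for (j in seq_len(nrow(sub))) {
        pos <- pos[pos < sub$ov_start[j] - pad | pos >= sub$ov_end[j] + pad]
      }
    }
    pos
  })
  names(safe) <- amps$id
  # longest contiguous safe run per amplicon (a deletion must fit in one run)
  longest_run <- function(p) {
    if (!length(p)) return(tibble::tibble(start = integer(), len = integer()))
    grp <- cumsum(c(1L, diff(p) != 1L))
    runs <- vapply(split(p, grp), length, integer(1))
    best <- which.max(runs)
    tibble::tibble(start = split(p, grp)[[best]][1], len = max(runs))
  }
  runs <- purrr::map_dfr(safe, longest_run, .id = "id")
  n_indel <- length(del_lens) + length(ins_lens)
  need <- n_het_snv + n_hom_snv + n_indel
  withr::with_seed(seed, {
    del_need <- sort(del_lens, decreasing = TRUE)
    specs <- list()
    used <- character(0)
    base_at <- function(ctg, pos1) toupper(substr(reference[[ctg]], pos1, pos1))
    other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    # deletions first: they need the longest runs
    for (L in del_need) {
      ok <- runs$id[runs$len >= L + 20L & !(runs$id %in% used)]
      if (!length(ok)) stop("no amplicon has a safe run for a deletion of ", L,
                            call. = FALSE)
      id <- sample(ok, 1L)
      used <- c(used, id)
      a <- amps[match(id, amps$id), ]
      r <- runs[runs$id == id, ]
      pos0 <- r$start + 5L
      ref <- toupper(substr(reference[[a$contig]], pos0 + 1L, pos0 + 1L + L))
      specs[[length(specs) + 1L]] <- variant_spec(
        a$contig, pos0 + 1L, ref, substr(ref, 1L, 1L), zygosity = "het"
      )
    }
    simple <- function(zyg, is_ins, L = 1L) {
      ok <- runs$id[runs$len >= 20L & !(runs$id %in% used)]
      if (!length(ok)) stop("not enough amplicons for the requested variants",
                            call. = FALSE)
      id <- sample(ok, 1L)
      used <<- c(used, id)
      a <- amps[match(id, amps$id), ]
      r <- runs[runs$id == id, ]
      pos0 <- r$start + r$len %/% 2L
      b <- base_at(a$contig, pos0 + 1L)
      alt <- if (is_ins) {
        paste0(b, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = ""))
      } else {
        other(b)
      }
      variant_spec(a$contig, pos0 + 1L, b, alt, zygosity = zyg)
    }
    for (L in ins_lens) specs[[length(specs) + 1L]] <- simple("het", TRUE, L)
    for (i in seq_len(n_het_snv)) specs[[length(specs) + 1L]] <- simple("het", FALSE)
    for (i in seq_len(n_hom_snv)) specs[[length(specs) + 1L]] <- simple("hom", FALSE)
    dplyr::arrange(dplyr::bind_rows(specs), .data$contig, .data$pos)
  })
}
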