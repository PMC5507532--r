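# The two-amplicon (2-plex) demonstration system: two overlapping amplicons
# (497 bp and 360 bp, 195 bp overlap) whose published gene-specific primers
# and tag constructions are the canonical proof-of-concept for stem-loop
# inhibition. The genomic interior between the primer sites is synthetic
# (seeded random filler); stem geometry and oligo construction depend only
# on the primer and tag sequences.

#' Gene-specific primer sequences of the 2-plex demonstration system
#'
#' @return Named character vector with `F1`, `R1` (amplicon 1) and `F2`,
#'   `R2` (amplicon 2), 5'->3'.
#' @export
twoplex_gene_primers <- function() {
  c(
    F1 = "GTGAAAGACATATTTACAGACAGTTTC",
    R1 = "CTTGTGAGCTGGTCTGAATGT",
    F2 = "AGGGAAGCTTCATAAGTCAGTC",
    R2 = "TCCTCTAACACTCCCTTAACTTTGT"
  )
}

#' Published 2-plex oligo constructions
#'
#' The full oligo set of the demonstration study: the four tagged
#' gene-specific primers, the stem-loop-inhibition (sStem) reverse primers
#' carrying 4/8/12/16 nt of the partner forward primer between tag and
#' gene-specific sequence, and the tag-only-stem (tStem) controls whose tags
#' are extended 5' by the same lengths of partner-primer sequence without
#' placing it next to the gene-specific part. Lower case marks tag sequence.
#'
#' @return Tibble with `oligo_id`, `design`, `amplicon`, `sequence`.
#' @export
twoplex_oligos <- function() {
  t <- slim_tags()
  g <- twoplex_gene_primers()
  ext <- function(k) toupper(substr(g[["F2"]], 1L, k))
  base <- tibble::tribble(
    ~oligo_id, ~design, ~amplicon, ~sequence,
    "t2_F1", "tagged", "amplicon1", paste0(t[["t2"]], g[["F1"]]),
    "t1_R1", "tagged", "amplicon1", paste0(t[["t1"]], g[["R1"]]),
    "t1_F2", "tagged", "amplicon2", paste0(t[["t1"]], g[["F2"]]),
    "t2_R2", "tagged", "amplicon2", paste0(t[["t2"]], g[["R2"]])
  )
  sstem <- purrr::map_dfr(c(4L, 8L, 12L, 16L), function(k) {
    tibble::tibble(
      oligo_id = sprintf("t1_F2^%d_R1", k), design = "sstem",
      amplicon = "amplicon1",
      sequence = paste0(t[["t1"]], ext(k), g[["R1"]])
    )
  })
  tstem <- purrr::map_dfr(c(4L, 8L, 12L, 16L), function(k) {
    tibble::tibble(
      oligo_id = sprintf("%dnt_t1_%s", k, c("R1", "F2")),
      design = "tstem", amplicon = c("amplicon1", "amplicon2"),
      sequence = paste0(tolower(ext(k)), t[["t1"]], g[c("R1", "F2")])
    )
  })
  dplyr::bind_rows(base, sstem, tstem)
}

#' Synthetic reference embedding the 2-plex primer sites
#'
#' A single contig in which the four gene-specific primer binding sites are
#' placed at the published geometry: amplicon 1 spans 497 bp, amplicon 2
#' spans 360 bp, and they share a 195 bp overlap. Filler between the sites
#' is seeded random sequence.
#'
#' @param seed Seed for the filler sequence.
#' @return Named character vector of length 1 (contig `"demo"`).
#' @export
twoplex_reference <- function(seed = 101L) {
  g <- twoplex_gene_primers()
  a1_start <- 50L
  a1_end <- a1_start + 497L    # 547
  a2_end <- a1_end - 195L + 360L  # 712
  a2_start <- a2_end - 360L    # 352
  reflen <- a2_end + 50L
  base <- strsplit(unname(make_reference(reflen, 0.5, seed, "demo")), "")[[1]]
  put <- function(base, seqs, at0) {
    s <- strsplit(seqs, "")[[1]]
    base[(at0 + 1L):(at0 + length(s))] <- s
    base
  }
  base <- put(base, g[["F1"]], a1_start)
  base <- put(base, g[["F2"]], a2_start)
  base <- put(base, reverse_complement(g[["R1"]]), a1_end - nchar(g[["R1"]]))
  base <- put(base, reverse_complement(g[["R2"]]), a2_end - nchar(g[["R2"]]))
  stats::setNames(paste(base, collapse = ""), "demo")
}

#' Build the 2-plex demonstration panel
#'
#' Constructs a `slim_panel` of the two overlapping demonstration amplicons
#' using the published gene-specific primers, in one of three primer
#' designs: `"slimamp"` (shared junction tag plus an inserted partner-primer
#' prefix of `insert_len` nt), `"tstem"` (shared junction tag extended 5' by
#' `ext_len` nt of partner-primer sequence, no insert between tag and gene)
#' or `"plain"` (shared junction tag only).
#'
#' @param design `"slimamp"`, `"tstem"` or `"plain"`.
#' @param insert_len F2^ insert length for `"slimamp"` (4, 8, 12 or 16 in
#'   the published study). Default 12.
#' @param ext_len Tag extension length for `"tstem"`. Default 12.
#' @param reference Reference from [twoplex_reference()].
#' @return A complete `slim_panel`.
#' @export
#' @examples
#' panel <- twoplex_panel("slimamp", insert_len = 16)
#' find_terminal_stem(junction_overlap_seq(panel, twoplex_reference()))
twoplex_panel <- function(design = c("slimamp", "tstem", "plain"),
                          insert_len = 12L, ext_len = 12L,
                          reference = twoplex_reference()) {
  design <- match.arg(design)
  g <- twoplex_gene_primers()
  amps <- tibble::tibble(
    id = c("amp001", "amp002"), contig = "demo",
    start = c(50L, 352L), end = c(547L, 712L), chain = 1L,
    fwd_gene = unname(g[c("F1", "F2")]),
    rev_gene = unname(g[c("R1", "R2")])
  )
  jn <- tibble::tibble(
    junction = 1L, contig = "demo", left_id = "amp001", right_id = "amp002",
    ov_start = 352L, ov_end = 547L, shared_tag_id = NA_character_,
    insert_len = NA_integer_, insert_side = NA_character_
  )
  panel <- new_slim_panel(amps, jn, tibble::tibble(
    contig = "demo", start = 80L, end = 680L
  ))
  panel <- assign_tags(panel)
  if (design == "slimamp") {
    return(build_slimamp_oligos(panel, insert_len = insert_len))
  }
  panel <- build_slimamp_oligos(panel, insert_len = 0L)
  if (design == "tstem" && ext_len > 0L) {
    ext <- tolower(substr(g[["F2"]], 1L, ext_len))
    a <- panel$amplicons
    a$rev_tag[a$id == "amp001"] <- paste0(ext, a$rev_tag[a$id == "amp001"])
    a$fwd_tag[a$id == "amp002"] <- paste0(ext, a$fwd_tag[a$id == "amp002"])
    a$fwd_oligo <- paste0(tolower(a$fwd_tag), a$fwd_insert, toupper(a$fwd_gene))
    a$rev_oligo <- paste0(tolower(a$rev_tag), a$rev_insert, toupper(a$rev_gene))
    panel$amplicons <- a
  }
  panel
}
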