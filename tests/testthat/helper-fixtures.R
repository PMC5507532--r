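# Shared fixtures, built in code. The full-scale synthetic panel is cached
# per session because several files exercise it.

fixture_env <- new.env(parent = emptyenv())

get_synth <- function() {
  if (is.null(fixture_env$synth)) {
    fixture_env$synth <- synthetic_panel(seed = 7)
  }
  fixture_env$synth
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small designed panel (3 overlapping amplicons on one chain) for pipeline
# unit tests
small_panel <- function(seed = 21L) {
  key <- paste0("small", seed)
  if (is.null(fixture_env[[key]])) {
    ref <- make_reference(1600, 0.5, seed)
    roi <- tibble::tibble(contig = "chrS", start = 250L, end = 1100L)
    panel <- design_panel(roi, ref, max_shift = 12L, insert_len = 10L)
    fixture_env[[key]] <- list(panel = panel, reference = ref, roi = roi)
  }
  fixture_env[[key]]
}

# an all-match alignment record in the shape merge_pair() expects
aln_allmatch <- function(read, qual, ref_start, amplicon = "ampX") {
  n <- nchar(read)
  list(amplicon = amplicon, read = read, qual = qual,
       score = 2L * n, ref_start = ref_start, ref_end = ref_start + n - 1L,
       read_start = 1L, read_end = n, cigar = paste0(n, "M"))
}

qchar <- function(q, n) strrep(intToUtf8(q + 33L), n)

empty_pileup_for_test <- function() slimamp:::empty_pileup("ampT")
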