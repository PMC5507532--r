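test_that("tiling handles single-amplicon and long intervals", {
  ref <- make_reference(6000, 0.5, 3)
  p300 <- tile_roi(tibble::tibble(contig = "chrS", start = 500L, end = 800L), ref)
  expect_equal(nrow(p300$amplicons), 1L)
  expect_equal(nrow(p300$junctions), 0L)

  p10 <- tile_roi(tibble::tibble(contig = "chrS", start = 500L, end = 510L), ref)
  expect_equal(nrow(p10$amplicons), 1L)
  expect_lte(p10$amplicons$start, 500L)
  expect_gte(p10$amplicons$end, 510L)
  expect_gte(p10$amplicons$end - p10$amplicons$start, 263L)

  # a ~4.9 kb exon-scale interval tiles into a 21-amplicon chain
  p49 <- tile_roi(tibble::tibble(contig = "chrS", start = 500L, end = 5400L), ref)
  expect_gte(nrow(p49$amplicons), 20L)
  expect_lte(nrow(p49$amplicons), 22L)
  expect_equal(nrow(p49$junctions), nrow(p49$amplicons) - 1L)
  sizes <- p49$amplicons$end - p49$amplicons$start
  expect_true(all(sizes >= 263 & sizes <= 380))
  ov <- p49$junctions$ov_end - p49$junctions$ov_start
  expect_true(all(ov >= 49 & ov <= 193))

  expect_error(
    tile_roi(tibble::tibble(contig = "chrS", start = 10L, end = 190L),
             make_reference(200, 0.5, 1)),
    "untileable"
  )
})

test_that("coverage and primer-shadow invariants hold (interval oracle)", {
  skip_if_not_installed("IRanges")
  ref <- make_reference(30000, 0.5, 13)
  set.seed(5)
  for (trial in 1:4) {
    n_iv <- sample(1:3, 1)
    starts <- sort(sample(seq(200L, 24000L, by = 3000L), n_iv))
    roi <- tibble::tibble(contig = "chrS", start = starts,
                          end = starts + sample(c(150L, 900L, 2600L), n_iv,
                                                replace = TRUE))
    panel <- tile_roi(roi, ref)
    amps <- panel$amplicons
    inserts <- IRanges::IRanges(amps$start + 1L, amps$end)
    roi_r <- IRanges::IRanges(roi$start + 1L, roi$end)
    # every roi base covered by at least one insert
    uncovered <- IRanges::setdiff(roi_r, IRanges::reduce(inserts))
    expect_equal(sum(IRanges::width(uncovered)), 0L)
    # primer shadowing: junction primer sites (up to 30 nt inside each
    # amplicon end at a junction) fall inside the neighbour's insert
    if (nrow(panel$junctions)) {
      for (j in seq_len(nrow(panel$junctions))) {
        jn <- panel$junctions[j, ]
        left <- amps[match(jn$left_id, amps$id), ]
        right <- amps[match(jn$right_id, amps$id), ]
        # right amplicon's fwd primer site
        expect_true(right$start >= left$start &&
                      right$start + 30L <= left$end)
        # left amplicon's rev primer site
        expect_true(left$end - 30L >= right$start && left$end <= right$end)
      }
    }
  }
})

test_that("3'-end SNP screening is strand-aware and threshold-exact", {
  primer_f <- tibble::tibble(contig = "c", start = 100L, end = 122L,
                             orientation = "forward")
  primer_r <- tibble::tibble(contig = "c", start = 100L, end = 122L,
                             orientation = "reverse")
  expect_true(check_3prime_snps(primer_f, NULL))
  # MAF 0.10% at the 3'-terminal base exceeds the 0.09% threshold
  mask <- tibble::tibble(contig = "c", pos = 121L, maf = 0.0010)
  expect_false(check_3prime_snps(primer_f, mask))
  # same site is 3'-distal for the reverse primer
  expect_true(check_3prime_snps(primer_r, mask))
  # 5% MAF at position 11 from the 3' end passes
  mask11 <- tibble::tibble(contig = "c", pos = 122L - 11L, maf = 0.05)
  expect_true(check_3prime_snps(primer_f, mask11))
  # MAF exactly at the threshold passes (strictly-above rule)
  mask_eq <- tibble::tibble(contig = "c", pos = 121L, maf = 0.0009)
  expect_true(check_3prime_snps(primer_f, mask_eq))
})

test_that("primer selection respects the Tm window and fails informatively", {
  ref <- make_reference(2000, 0.5, 17)
  pair <- slim_select_primers(ref, "chrS", 500L, 830L, max_shift = 10L)
  expect_equal(pair$orientation, c("forward", "reverse"))
  expect_true(all(pair$tm >= 57 & pair$tm <= 63))
  # deterministic
  pair2 <- slim_select_primers(ref, "chrS", 500L, 830L, max_shift = 10L)
  expect_identical(pair, pair2)
  # a common SNP under every candidate's 3' end forces a design error
  mask <- tibble::tibble(contig = "chrS", pos = 480L:870L, maf = 0.005)
  expect_error(
    slim_select_primers(ref, "chrS", 500L, 830L, max_shift = 10L, mask = mask),
    "3'-SNP"
  )
})

test_that("tag assignment 2-colours chains and matches the published layout", {
  two <- twoplex_panel("plain")
  a <- two$amplicons
  expect_equal(a$fwd_tag_id, c("t2", "t1"))
  expect_equal(a$rev_tag_id, c("t1", "t2"))
  expect_equal(two$junctions$shared_tag_id, "t1")

  ref <- make_reference(20000, 0.5, 19)
  long <- tile_roi(tibble::tibble(contig = "chrS", start = 200L, end = 12000L),
                   ref)
  long <- assign_tags(long)
  amps <- long$amplicons
  expect_gte(nrow(amps), 50L)  # chain long enough to exercise the colouring
  expect_true(all(amps$fwd_tag_id != amps$rev_tag_id))
  jl <- match(long$junctions$left_id, amps$id)
  jr <- match(long$junctions$right_id, amps$id)
  expect_true(all(amps$rev_tag_id[jl] == amps$fwd_tag_id[jr]))
  # junction shared tags alternate along the chain
  expect_equal(long$junctions$shared_tag_id[1:4], c("t1", "t2", "t1", "t2"))
})

test_that("oligo construction reproduces the published junction oligos", {
  ol <- twoplex_oligos()
  p12 <- twoplex_panel("slimamp", insert_len = 12)
  expect_equal(p12$amplicons$rev_oligo[1],
               ol$sequence[ol$oligo_id == "t1_F2^12_R1"])
  expect_equal(p12$amplicons$fwd_oligo[2],
               ol$sequence[ol$oligo_id == "t1_F2"])
  expect_equal(p12$amplicons$fwd_oligo[1],
               ol$sequence[ol$oligo_id == "t2_F1"])
  # insert 0 gives the plain tagged layout
  p0 <- twoplex_panel("plain")
  expect_equal(p0$amplicons$rev_oligo[1], ol$sequence[ol$oligo_id == "t1_R1"])
  # insert exceeding the partner primer is a design error
  expect_error(twoplex_panel("slimamp", insert_len = 23L), "exceeds")
})

test_that("junction products fold into stems of tag length + insert length", {
  ref <- twoplex_reference()
  for (k in c(4L, 8L, 12L, 16L)) {
    panel <- twoplex_panel("slimamp", insert_len = k)
    stem <- find_terminal_stem(junction_overlap_seq(panel, ref))$stem_length
    expect_equal(stem, 20L + k)
  }
  # holds across a designed multi-junction panel too; random gene sequence
  # can extend the duplex by a base or two past the designed stem
  sm <- small_panel()
  for (j in sm$panel$junctions$junction) {
    stem <- find_terminal_stem(
      junction_overlap_seq(sm$panel, sm$reference, j))$stem_length
    jn <- sm$panel$junctions[sm$panel$junctions$junction == j, ]
    tag_len <- nchar(slim_tags()[[jn$shared_tag_id]])
    expect_gte(stem, tag_len + jn$insert_len)
    expect_lte(stem, tag_len + jn$insert_len + 3L)
  }
})

test_that("panel export writes the manifest and round-trips losslessly", {
  sm <- small_panel()
  dir <- withr::local_tempdir()
  paths <- export_panel(sm$panel, sm$reference, dir)
  expect_true(all(file.exists(paths)))
  oligos <- readr::read_tsv(file.path(dir, "panel_oligos.tsv"),
                            col_types = "cccccccd", progress = FALSE)
  expect_equal(nrow(oligos), 2L * nrow(sm$panel$amplicons))
  back <- read_panel(dir)
  expect_equal(back$amplicons, sm$panel$amplicons, tolerance = 1e-9)
  expect_equal(back$junctions, sm$panel$junctions)
  expect_equal(back$roi, sm$panel$roi)
  expect_equal(back$tags, sm$panel$tags)
})

test_that("the full-scale synthetic panel has the expected shape", {
  synth <- get_synth()
  amps <- synth$panel$amplicons
  expect_equal(nrow(amps), 91L)
  dir <- withr::local_tempdir()
  export_panel(synth$panel, synth$reference, dir)
  inserts <- readr::read_tsv(file.path(dir, "panel_inserts.bed"),
                             col_names = c("contig", "start", "end", "id"),
                             col_types = "ciic", progress = FALSE)
  oligos <- readr::read_tsv(file.path(dir, "panel_oligos.tsv"),
                            col_types = "cccccccd", progress = FALSE)
  expect_equal(nrow(inserts), 91L)
  expect_equal(nrow(oligos), 182L)
  # all emitted primers inside the Tm window
  expect_true(all(amps$fwd_tm >= 57 & amps$fwd_tm <= 63))
  expect_true(all(amps$rev_tm >= 57 & amps$rev_tm <= 63))
})
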