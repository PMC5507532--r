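test_that("reference generation is seeded and GC-controlled", {
  expect_identical(make_reference(1000, 0.5, 7), make_reference(1000, 0.5, 7))
  gconly <- make_reference(500, 1.0, 1)
  expect_false(grepl("[AT]", gconly))
  big <- make_reference(100000, 0.4, 2)
  gc <- stringr::str_count(big, "[GC]") / 100000
  expect_lt(abs(gc - 0.4), 0.01)
})

test_that("variant application is position-stable and left-aligned", {
  ref <- c(chrS = paste0("AACT", strrep("G", 10), "TTACGTACGTACGT"))
  # 40 bp deletion shortens the haplotype by exactly 40
  big <- make_reference(2000, 0.5, 4)
  del40 <- variant_spec("chrS", 100L, substr(big, 100, 140),
                        substr(big, 100, 100), "het")
  out <- apply_variants(big, del40)
  expect_equal(nchar(out$haplotype[["chrS"]]), 2000L - 40L)

  # empty spec list is the identity
  none <- apply_variants(big, variant_spec(character(), integer(),
                                           character(), character())[0, ])
  expect_identical(none$haplotype, big)

  # insertion upstream does not displace a downstream SNV's truth coordinate
  b10 <- substr(big, 10, 10); b50 <- substr(big, 50, 50)
  ins_char <- setdiff(c("A", "C", "G", "T"), substr(big, 9, 10))[1]
  alt50 <- setdiff(c("A", "C", "G", "T"), b50)[1]
  specs <- variant_spec("chrS", c(10L, 50L), c(b10, b50),
                        c(paste0(b10, strrep(ins_char, 3)), alt50),
                        c("het", "het"))
  out2 <- apply_variants(big, specs)
  expect_true(all(c(10L, 50L) %in% out2$truth$pos))
  expect_equal(nchar(out2$haplotype[["chrS"]]), 2003L)

  # overlapping specs rejected
  bad <- variant_spec("chrS", c(100L, 101L), c(substr(big, 100, 102), "A"),
                      c(substr(big, 100, 100), "C"), "het")
  bad$ref[2] <- substr(big, 101, 101)
  expect_error(apply_variants(big, bad), "overlap")

  # a deletion in a homopolymer run is reported at its left-most position
  run <- apply_variants(ref, variant_spec("chrS", 8L, "GGG", "G", "het"))
  expect_equal(run$truth$pos, 4L)
  expect_equal(run$truth$ref, "TGG")
  expect_equal(run$truth$alt, "T")
})

test_that("simulated fragments carry tags and recover allele fractions", {
  sm <- small_panel()
  # constant depth profile gives exactly that many pairs per amplicon
  reads <- simulate_reads(sm$panel, list(ref = sm$reference), 1,
                          read_profile(error_rate = 0, depth_mean = 37,
                                       depth_sdlog = 0),
                          seed = 4)
  expect_true(all(table(reads$amplicon) == 37L))

  # het variant: pooled alt fraction within 3 binomial sigma of 0.5
  a <- sm$panel$amplicons[2, ]
  pos0 <- a$start + 60L
  b <- toupper(substr(sm$reference[["chrS"]], pos0 + 1, pos0 + 1))
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  h <- build_haplotypes(sm$reference,
                        variant_spec("chrS", pos0 + 1L, b, alt, "het"))
  rr <- simulate_reads(sm$panel, h$haplotypes, h$fractions,
                       read_profile(error_rate = 0, depth_mean = 400,
                                    depth_sdlog = 0),
                       seed = 6)
  p_alt <- mean(rr$haplotype == "hapA")
  n <- nrow(rr)
  expect_lt(abs(p_alt - 0.5), 3 * sqrt(0.25 / n))
})

test_that("a 331 bp insert with both tags yields a 372 bp fragment", {
  ref <- make_reference(900, 0.5, 23)
  roi <- tibble::tibble(contig = "chrS", start = 300L, end = 571L)
  panel <- design_panel(roi, ref, max_shift = 0L)  # margins: insert exactly 331
  expect_equal(panel$amplicons$end - panel$amplicons$start, 331L)
  reads <- simulate_reads(panel, list(ref = ref), 1,
                          read_profile(error_rate = 0, depth_mean = 2,
                                       depth_sdlog = 0, read_len = 400L),
                          seed = 1)
  expect_equal(unique(nchar(reads$read1)), 331L + 41L)
})

test_that("identical seeds give byte-identical FASTQ", {
  sm <- small_panel()
  f <- file.path(withr::local_tempdir(), paste0("r", 1:4, ".fastq"))
  simulate_reads(sm$panel, list(ref = sm$reference), 1,
                 read_profile(depth_mean = 10, depth_sdlog = 0.2), seed = 3,
                 fastq1 = f[1], fastq2 = f[2])
  simulate_reads(sm$panel, list(ref = sm$reference), 1,
                 read_profile(depth_mean = 10, depth_sdlog = 0.2), seed = 3,
                 fastq1 = f[3], fastq2 = f[4])
  expect_identical(readLines(f[1]), readLines(f[3]))
  expect_identical(readLines(f[2]), readLines(f[4]))
})
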