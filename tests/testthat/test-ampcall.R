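test_that("pair assignment recovers the true amplicon and rejects noise", {
  sm <- small_panel()
  reads <- simulate_reads(sm$panel, list(ref = sm$reference), 1,
                          read_profile(error_rate = 0, depth_mean = 5,
                                       depth_sdlog = 0), seed = 8)
  got <- assign_amplicon(reads[c("read1", "read2")], sm$panel)
  expect_identical(got$amplicon, reads$amplicon)

  # three substitutions in the forward primer exceed max_mismatch = 2
  r <- reads[1, ]
  mut <- r$read1
  for (p in c(25L, 30L, 35L)) {
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, p, p))[1]
  }
  one <- assign_amplicon(tibble::tibble(read1 = mut, read2 = r$read2),
                         sm$panel)
  expect_true(is.na(one$amplicon))

  # bulk accuracy at 0.1% error on several thousand pairs
  noisy <- simulate_reads(sm$panel, list(ref = sm$reference), 1,
                          read_profile(error_rate = 0.001, depth_mean = 800,
                                       depth_sdlog = 0), seed = 9)
  ga <- assign_amplicon(noisy[c("read1", "read2")], sm$panel)
  acc <- mean(!is.na(ga$amplicon) & ga$amplicon == noisy$amplicon)
  expect_gte(acc, 0.99)
})

test_that("banded realignment finds matches and indels", {
  ref <- random_seq(300, seed = 31)
  read <- substr(ref, 41, 140)
  a <- realign_local(read, ref)
  expect_equal(a$score, 200L)
  expect_equal(a$cigar, "100M")
  expect_equal(a$ref_start, 41L)

  # a 4 bp deletion is recovered as a single 4D operation
  del <- paste0(substr(read, 1, 50), substr(read, 55, 100))
  ad <- realign_local(del, ref, band = 96L, diag_offset = 40L)
  expect_true(grepl("4D", ad$cigar))
  expect_equal(sum(as.integer(
    stringr::str_extract_all(ad$cigar, "\\d+(?=D)")[[1]])), 4L)
  expect_error(realign_local("", ref), "empty")
})

test_that("banded score equals the unbanded optimum (independent oracle)", {
  skip_if_not_installed("Biostrings")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  set.seed(33)
  for (i in 1:30) {
    ref <- random_seq(280)
    st <- sample(1:30, 1)
    read <- substr(ref, st, st + 99)
    if (i %% 2 == 0) {  # inject an indel up to 40 bp
      L <- sample(1:40, 1)
      p <- sample(20:50, 1)
      if (i %% 4 == 0) {
        read <- paste0(substr(read, 1, p), substr(read, p + L + 1, 100))
      } else {
        read <- paste0(substr(read, 1, p), random_seq(L),
                       substr(read, p + 1, 100))
      }
    }
    mine <- realign_local(read, ref, band = 96L, diag_offset = st - 1L)
    full <- Biostrings::pairwiseAlignment(read, ref, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 6, gapExtension = 1,
                                          scoreOnly = TRUE)
    expect_equal(mine$score, full)
  }
})

test_that("pair merging applies the phred consensus rules", {
  ref_start <- 10L
  # agreement: qualities add, capped at 60
  a1 <- aln_allmatch("ACGT", qchar(30, 4), ref_start)
  a2 <- aln_allmatch("ACGT", qchar(30, 4), ref_start)
  m <- merge_pair(a1, a2)
  expect_equal(m$bases, c("A", "C", "G", "T"))
  expect_equal(m$quals, rep(60L, 4))
  expect_equal(unique(m$origin), "both-agree")

  # conflict: higher-quality base wins with quality |Q1 - Q2|
  c1 <- aln_allmatch("AAAA", qchar(35, 4), ref_start)
  c2 <- aln_allmatch("CAAA", qchar(10, 4), ref_start)
  mc <- merge_pair(c1, c2)
  expect_equal(mc$bases[1], "A")
  expect_equal(mc$quals[1], 25L)
  expect_equal(mc$origin[1], "both-conflict")

  # non-overlapping mates concatenate coverage with unchanged qualities
  n1 <- aln_allmatch("ACGT", qchar(30, 4), 1L)
  n2 <- aln_allmatch("TTTT", qchar(20, 4), 10L)
  mn <- merge_pair(n1, n2)
  expect_equal(mn$ref_start, 1L)
  expect_equal(length(mn$bases), 13L)
  expect_equal(mn$quals[1:4], rep(30L, 4))
  expect_equal(mn$quals[10:13], rep(20L, 4))

  # different amplicons refuse to merge
  x <- aln_allmatch("ACGT", qchar(30, 4), 1L, amplicon = "ampA")
  y <- aln_allmatch("ACGT", qchar(30, 4), 1L, amplicon = "ampB")
  expect_error(merge_pair(x, y), "different amplicons")

  # incompatible indel structure in the overlap drops the pair
  d1 <- aln_allmatch("ACGTACGT", qchar(30, 8), 1L)
  d2 <- list(amplicon = "ampX", read = "ACGTGT", qual = qchar(30, 6),
             score = 0L, ref_start = 1L, ref_end = 8L,
             read_start = 1L, read_end = 6L, cigar = "4M2D2M")
  expect_null(merge_pair(d1, d2))
})

test_that("primer clipping restricts contributions to the insert interior", {
  sm <- small_panel()
  a <- sm$panel$amplicons[1, ]
  amplen <- nchar(amplicon_seqs(sm$panel, sm$reference)[[a$id]])
  full <- aln_allmatch(strrep("A", amplen), qchar(30, amplen), 1L,
                       amplicon = a$id)
  m <- merge_pair(full, full)
  cl <- clip_primers(m, sm$panel)
  expect_equal(cl$ref_start, nchar(a$fwd_oligo) + 1L)
  expect_equal(length(cl$bases),
               amplen - nchar(a$fwd_oligo) - nchar(a$rev_oligo))
  expect_equal(cl$gpos0, a$start + nchar(a$fwd_gene))

  # a read lying entirely within the primer region contributes nothing
  inprimer <- aln_allmatch(strrep("A", 10), qchar(30, 10), 3L, amplicon = a$id)
  expect_null(clip_primers(merge_pair(inprimer, inprimer), sm$panel))
})

test_that("noise estimation matches the analytic error expectation", {
  # clean pileup: mu = sd = 0
  sm <- small_panel()
  clean <- simulate_reads(sm$panel, list(ref = sm$reference), 1,
                          read_profile(error_rate = 0, depth_mean = 40,
                                       depth_sdlog = 0), seed = 2)
  res <- call_pairs(clean, sm$panel, sm$reference)
  expect_true(all(res$noise$mu_noise == 0))
  expect_true(all(res$noise$sd_noise == 0))

  # synthetic pileup with uniform 1% substitution error at depth 1000:
  # per-alt-allele mean close to 0.01/3
  set.seed(44)
  npos <- 300L
  refbases <- sample(c("A", "C", "G", "T"), npos, replace = TRUE)
  w_base <- 1 - 10^(-20 / 10)
  alleles <- c("A", "C", "G", "T")
  rows <- list()
  for (i in seq_len(npos)) {
    nerr <- stats::rbinom(1, 1000, 0.01)
    split3 <- as.vector(stats::rmultinom(1, nerr, rep(1 / 3, 3)))
    alts <- setdiff(alleles, refbases[i])
    cnt <- c(1000 - nerr, split3)
    rows[[i]] <- tibble::tibble(
      gpos0 = i - 1L, allele = c(refbases[i], alts),
      weight = cnt * w_base, count = cnt
    )
  }
  pl <- empty_pileup_for_test()
  pl$alleles <- dplyr::bind_rows(rows)
  pl$depth <- tibble::tibble(gpos0 = 0:(npos - 1L), reads = 1000L)
  ref <- c(chrS = paste(refbases, collapse = ""))
  ns <- estimate_noise(pl, ref, "chrS")
  expect_lt(abs(ns$mu_noise - 0.01 / 3) / (0.01 / 3), 0.20)

  # one true 50% het among clean positions is excluded from the noise set
  het_row <- tibble::tibble(gpos0 = 5L,
                            allele = setdiff(alleles, refbases[6])[1],
                            weight = 500 * w_base, count = 500L)
  pl2 <- pl
  pl2$alleles <- dplyr::bind_rows(pl$alleles, het_row)
  ns2 <- estimate_noise(pl2, ref, "chrS")
  expect_lt(abs(ns2$mu_noise - ns$mu_noise), 1e-4)
})

test_that("variant filters implement the 20-read / 20% rules", {
  mk_pileup <- function(alt_count, depth, pos0 = 50L) {
    w <- 1 - 10^(-30 / 10)
    pl <- empty_pileup_for_test()
    pl$alleles <- tibble::tibble(
      gpos0 = pos0, allele = c("A", "C"),
      weight = c(depth - alt_count, alt_count) * w,
      count = c(depth - alt_count, alt_count)
    )
    pl$depth <- tibble::tibble(gpos0 = pos0, reads = as.integer(depth))
    pl
  }
  ref <- c(chrS = paste(rep("A", 200), collapse = ""))
  ns <- tibble::tibble(amplicon = "ampT", mu_noise = 0.0005,
                       sd_noise = 0.0002, n_obs = 100L, flagged = FALSE)

  pass <- call_variants(mk_pileup(500, 1000), ns, ref, "chrS")
  expect_equal(pass$filter, "PASS")
  expect_equal(pass$alt, "C")

  lowf <- call_variants(mk_pileup(190, 1000), ns, ref, "chrS")
  expect_equal(lowf$filter, "low_frequency")

  lows <- call_variants(mk_pileup(19, 38), ns, ref, "chrS")
  expect_equal(lows$filter, "low_support")

  # raising the SD multiplier never adds calls; lowering never removes
  base <- call_variants(mk_pileup(500, 1000), ns, ref, "chrS",
                        slim_call_params(sd_mult = 6))
  up <- call_variants(mk_pileup(500, 1000), ns, ref, "chrS",
                      slim_call_params(sd_mult = 12))
  dn <- call_variants(mk_pileup(500, 1000), ns, ref, "chrS",
                      slim_call_params(sd_mult = 3))
  expect_true(all(paste(up$pos, up$alt) %in% paste(base$pos, base$alt)))
  expect_true(all(paste(base$pos, base$alt) %in% paste(dn$pos, dn$alt)))
})

test_that("a variant under a primer site surfaces only via the neighbour", {
  sm <- small_panel()
  amps <- sm$panel$amplicons
  jn <- sm$panel$junctions[1, ]
  left <- amps[match(jn$left_id, amps$id), ]
  # place the variant inside the left amplicon's reverse primer site, which
  # lies inside the junction overlap and hence inside the neighbour's insert
  pos0 <- left$end - 5L
  b <- toupper(substr(sm$reference[["chrS"]], pos0 + 1, pos0 + 1))
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  h <- build_haplotypes(sm$reference,
                        variant_spec("chrS", pos0 + 1L, b, alt, "hom"))
  reads <- simulate_reads(sm$panel, h$haplotypes, h$fractions,
                          read_profile(error_rate = 0, depth_mean = 120,
                                       depth_sdlog = 0), seed = 12)
  res <- call_pairs(reads, sm$panel, sm$reference)
  hit <- res$segment_calls[res$segment_calls$pos == pos0 + 1L, ]
  expect_true(nrow(hit) >= 1L)
  # called only from the neighbouring amplicon, never from the amplicon
  # whose primer covers (and overwrites) the site
  expect_false(jn$left_id %in% hit$amplicon)
  expect_true(all(hit$filter == "PASS"))
})

test_that("bulk pileup agrees with per-pair merge_pair consensus", {
  sm <- small_panel()
  a <- sm$panel$amplicons[1, ]
  ampref <- toupper(amplicon_seqs(sm$panel, sm$reference)[[a$id]])
  amplen <- nchar(ampref)
  set.seed(55)
  n <- 40L
  rl <- 200L
  r1 <- character(n); r2 <- character(n)
  for (i in seq_len(n)) {
    frag <- ampref
    # sprinkle substitutions
    for (p in sample(seq_len(amplen), 3)) {
      substr(frag, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    r1[i] <- substr(frag, 1, rl)
    r2[i] <- reverse_complement(substr(frag, amplen - rl + 1L, amplen))
  }
  q <- qchar(30, rl)
  pl <- slimamp:::amplicon_pileup(r1, r2, rep(q, n), rep(q, n), a, ampref,
                                  sm$reference, slim_call_params())
  # oracle: per-pair merge_pair + clip, accumulated by hand
  clip_lo <- nchar(a$fwd_oligo) + 1L
  acc <- list()
  for (i in seq_len(n)) {
    a1 <- aln_allmatch(r1[i], q, 1L, amplicon = a$id)
    a2 <- aln_allmatch(reverse_complement(r2[i]), q, amplen - rl + 1L,
                       amplicon = a$id)
    m <- clip_primers(merge_pair(a1, a2), sm$panel)
    pos <- m$gpos0 + seq_along(m$bases) - 1L
    acc[[i]] <- tibble::tibble(gpos0 = pos, allele = m$bases,
                               weight = 1 - 10^(-m$quals / 10))
  }
  oracle <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(acc), gpos0, allele),
    weight = sum(weight), count = dplyr::n(), .groups = "drop"
  )
  mine <- pl$alleles[pl$alleles$count > 0, ]
  joined <- dplyr::inner_join(oracle, mine, by = c("gpos0", "allele"))
  expect_equal(nrow(joined), nrow(oracle))
  expect_equal(joined$count.x, joined$count.y)
  expect_equal(joined$weight.x, joined$weight.y, tolerance = 1e-9)
})

test_that("VCF writing round-trips through an independent parser", {
  calls <- tibble::tibble(
    contig = "chrS", pos = c(100L, 250L),
    ref = c("A", paste(rep("C", 41), collapse = "")),
    alt = c("G", "C"),
    qwf = c(0.5012, 0.47), support = c(480L, 300L), depth = c(1000L, 700L),
    freq = c(0.48, 0.43), filter = c("PASS", "PASS"),
    amplicon = c("amp001", "amp002")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path, contig_lengths = c(chrS = 5000L))
  back <- read_vcf(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(nchar(back$ref[2]), 41L)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$qwf, calls$qwf, tolerance = 1e-6)
  expect_equal(back$support, calls$support)

  # header-only VCF for zero calls is still valid and readable
  empty_path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls[0, ], empty_path, contig_lengths = c(chrS = 5000L))
  expect_equal(nrow(read_vcf(empty_path)), 0L)
})

test_that("coverage report computes the threshold ladder and dropouts", {
  sm <- small_panel()
  reads <- simulate_reads(sm$panel, list(ref = sm$reference), 1,
                          read_profile(error_rate = 0, depth_mean = 50,
                                       depth_sdlog = 0), seed = 3)
  res <- call_pairs(reads, sm$panel, sm$reference)
  cov <- res$coverage
  # threshold fractions are monotone non-increasing in k
  expect_true(all(diff(cov$thresholds$fraction) <= 0))
  expect_equal(cov$uniformity,
               cov$thresholds$fraction[cov$thresholds$k == 0.2])
  expect_equal(cov$mapping_rate, 1)

  # dropping one amplicon's reads pushes the 0.1x row below 100%
  drop_id <- sm$panel$amplicons$id[2]
  res2 <- call_pairs(reads[reads$amplicon != drop_id, ], sm$panel,
                     sm$reference)
  expect_lt(res2$coverage$thresholds$fraction[1], 1)
})
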