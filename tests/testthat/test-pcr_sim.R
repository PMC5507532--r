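test_that("closed-form folds match the four-species formulas", {
  expect_equal(unlist(fold_closed_form(1)[-1]),
               c(amplicon1 = 2, amplicon2 = 2, spanning = 2, overlap = 2))
  expect_equal(unlist(fold_closed_form(0)[-1]),
               c(amplicon1 = 0, amplicon2 = 0, spanning = 1, overlap = 0))
  expect_equal(unlist(fold_closed_form(5)[-1]),
               c(amplicon1 = 160, amplicon2 = 160, spanning = 32, overlap = 800))
  f <- fold_closed_form(0:40)
  expect_equal(f$spanning, 2^(0:40))
  expect_equal(f$overlap, (0:40)^2 * 2^(0:40))
  expect_error(fold_closed_form(-1), "non-negative")
})

test_that("branching recurrence matches an independent evaluation at e = 1", {
  # independent oracle: plain loop, written separately from the package code
  oracle <- function(n) {
    a1 <- a2 <- a3 <- 0; a4 <- 1
    out <- matrix(0, n + 1, 4)
    out[1, ] <- c(a1, a2, a3, a4)
    for (i in seq_len(n)) {
      a4n <- 2 * a4
      a1n <- 2 * a1 + a4
      a2n <- 2 * a2 + a4
      a3n <- 2 * a3 + a1 + a2 + a4
      a1 <- a1n; a2 <- a2n; a3 <- a3n; a4 <- a4n
      out[i + 1, ] <- c(a1, a2, a3, a4)
    }
    out
  }
  tr <- simulate_branching(20)
  orc <- oracle(20)
  expect_equal(tr$amplicon1, orc[, 1])
  expect_equal(tr$overlap, orc[, 3])
  expect_equal(tr$spanning, orc[, 4])
  # closed-form growth orders: A4 = 2^n, A1 = n 2^(n-1), A3 = n(n+1) 2^(n-2)
  n <- 0:20
  expect_equal(tr$spanning, 2^n)
  expect_equal(tr$amplicon1, n * 2^(n - 1) * ifelse(n == 0, 0, 1))
  expect_equal(tr$overlap[-1], (n * (n + 1) * 2^(n - 2))[-1])
})

test_that("overlap/target ratio grows linearly within the stated envelope", {
  tr <- simulate_branching(40)
  ratio <- tr$overlap[-1] / tr$amplicon1[-1]
  n <- 1:40
  expect_true(all(ratio >= n / 4 & ratio <= n))
  expect_true(all(diff(ratio) > 0))
})

test_that("branching limits behave: suppression and single-cycle bounds", {
  offtr <- simulate_branching(10, e = c(amplicon1 = 1, amplicon2 = 1,
                                        overlap = 0, spanning = 1))
  expect_true(all(offtr$overlap == 0))
  expect_gt(offtr$amplicon1[11], 0)
  one <- simulate_branching(1)
  # no species more than doubles its template pool in one cycle
  expect_lte(one$spanning[2], 2)
  expect_lte(one$amplicon1[2], 1)  # template pool was A4(0) = 1
  # copies finite, non-negative, non-decreasing
  tr <- simulate_branching(40)
  for (col in c("amplicon1", "amplicon2", "overlap", "spanning")) {
    expect_true(all(is.finite(tr[[col]])))
    expect_true(all(diff(tr[[col]]) >= 0))
  }
})

test_that("priming efficiency reflects accessible-site melting temperature", {
  p <- slim_sim_params()
  oligo <- paste0(slim_tags()[["t1"]], "AGGGAAGCTTCATAAGTCAGTC")
  # open template at the raised annealing temperature
  expect_gt(priming_efficiency(oligo, nchar(oligo), 72, p), 0.9)
  # stem-occluded template: 16 nt insert leaves 6 accessible bases
  expect_lt(priming_efficiency(oligo, 6L, 72, p), 0.01)
  # tag-only stems leave the gene-specific site accessible: efficiency is
  # exactly that of the insert-0 construction, whatever the extension
  e0 <- priming_efficiency(oligo, 22L, 72, p)
  ext_oligo <- paste0("aggg", oligo)
  expect_equal(priming_efficiency(ext_oligo, 22L, 72, p), e0)
  expect_error(priming_efficiency(oligo, 99L, 72, p))
})

test_that("virtual gel reproduces the lane ordering of the 2-plex study", {
  ref <- twoplex_reference()
  frac <- function(gel, what) {
    if (what %in% gel$species) return(gel$fraction[gel$species == what])
    gel$fraction[gel$type == what]
  }
  a3 <- a1 <- numeric(0)
  for (k in c(4L, 8L, 12L, 16L)) {
    gel <- simulate_slimamp(twoplex_panel("slimamp", insert_len = k), ref)
    expect_true(all(is.finite(gel$copies)) && all(gel$copies >= 0))
    a3 <- c(a3, frac(gel, "overlap"))
    a1 <- c(a1, frac(gel, "amp001"))
    # the long spanning product is the smallest species in every lane
    expect_equal(which.min(gel$fraction), which(gel$type == "spanning"))
  }
  # overlap product decreases monotonically with insert length
  expect_true(all(diff(a3) < 0))
  # >= 12 nt insert: overlap below 1% of the target
  expect_lt(a3[3] / a1[3], 0.01)
  expect_lt(a3[4] / a1[4], 0.01)

  # tag-only stems: overlap stays abundant (>= target) and near-invariant
  t3 <- vapply(c(0L, 4L, 8L, 12L, 16L), function(k) {
    gel <- simulate_slimamp(twoplex_panel("tstem", ext_len = k), ref)
    expect_equal(which.min(gel$fraction), which(gel$type == "spanning"))
    frac(gel, "overlap") / frac(gel, "amp001")
  }, numeric(1))
  expect_true(all(t3 >= 1))
  expect_lt(diff(range(t3)) / mean(t3), 0.25)
})
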