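# Synthetic data generation: references, haplotypes with injected variants,
# and paired-end amplicon reads. Everything is seeded and byte-reproducible,
# so the analysis pipeline is testable without any external data.

#' Generate a random reference sequence
#'
#' @param length Sequence length in bp.
#' @param gc Expected GC fraction. Default 0.5.
#' @param seed Integer seed; the same seed gives identical sequence.
#' @param name Contig name. Default `"chrS"`.
#' @return Named character vector of length 1 (a one-contig reference).
#' @export
#' @examples
#' ref <- make_reference(1000, gc = 0.4, seed = 7)
make_reference <- function(length, gc = 0.5, seed = 1L, name = "chrS") {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  withr::with_seed(seed, {
    bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  })
  stats::setNames(paste(bases, collapse = ""), name)
}

#' Variant specification table
#'
#' A convenience constructor validating the columns used by
#' [apply_variants()] and [simulate_reads()]: `contig`, `pos` (1-based
#' position of the first reference base), `ref`, `alt` (SNV, insertion, or
#' deletion in VCF-like anchored notation), `vaf` (target allele fraction in
#' (0, 1]) and `zygosity` (`"het"` maps to 0.5, `"hom"` to 1 when `vaf` is
#' missing).
#'
#' @param contig,pos,ref,alt,zygosity,vaf Vectors, recycled to a common
#'   length.
#' @return A tibble of variant specs.
#' @export
variant_spec <- function(contig, pos, ref, alt, zygosity = "het", vaf = NULL) {
  out <- tibble::tibble(contig = contig, pos = as.integer(pos),
                        ref = toupper(ref), alt = toupper(alt),
                        zygosity = zygosity)
  out$vaf <- if (is.null(vaf)) ifelse(out$zygosity == "hom", 1, 0.5) else vaf
  check_alphabet(out$ref, arg = "ref"); check_alphabet(out$alt, arg = "alt")
  stopifnot(all(out$vaf > 0), all(out$vaf <= 1))
  out
}

# Shift an anchored indel to its left-most equivalent position.
left_align_variant <- function(refseq, pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) != nchar(alt) && pos > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    prev <- substr(refseq, pos - 1L, pos - 1L)
    ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
    alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Apply variants to a reference, producing an alternate haplotype
#'
#' Edits are applied right-to-left so that earlier (left) coordinates are
#' unaffected by length changes, and the truth table reports each variant in
#' left-aligned, anchored (VCF-style) representation at its original
#' reference coordinate.
#'
#' @param reference Named character vector (one or more contigs).
#' @param specs A [variant_spec()] table; specs must not overlap.
#' @return List with `haplotype` (edited reference) and `truth` (tibble
#'   `contig`, `pos`, `ref`, `alt`, `zygosity`, `vaf`).
#' @export
apply_variants <- function(reference, specs) {
  specs <- tibble::as_tibble(specs)
  if (!nrow(specs)) {
    return(list(haplotype = reference,
                truth = variant_spec(character(), integer(), character(),
                                     character())[0, ]))
  }
  stopifnot(all(specs$contig %in% names(reference)))
  specs <- dplyr::arrange(specs, .data$contig, .data$pos)
  ends <- specs$pos + nchar(specs$ref) - 1L
  same <- specs$contig[-1] == specs$contig[-nrow(specs)]
  if (any(same & specs$pos[-1] <= ends[-nrow(specs)])) {
    stop("variant specs overlap", call. = FALSE)
  }
  hap <- reference
  truth <- vector("list", nrow(specs))
  for (i in rev(seq_len(nrow(specs)))) {
    s <- specs[i, ]
    refseq <- reference[[s$contig]]
    found <- substr(refseq, s$pos, s$pos + nchar(s$ref) - 1L)
    if (toupper(found) != s$ref) {
      stop(sprintf("spec %d: reference has %s at %s:%d, not %s",
                   i, found, s$contig, s$pos, s$ref), call. = FALSE)
    }
    hseq <- hap[[s$contig]]
    hap[[s$contig]] <- paste0(substr(hseq, 1L, s$pos - 1L), s$alt,
                              substr(hseq, s$pos + nchar(s$ref), nchar(hseq)))
    la <- left_align_variant(refseq, s$pos, s$ref, s$alt)
    truth[[i]] <- tibble::tibble(contig = s$contig, pos = la$pos,
                                 ref = la$ref, alt = la$alt,
                                 zygosity = s$zygosity, vaf = s$vaf)
  }
  list(haplotype = hap,
       truth = dplyr::arrange(dplyr::bind_rows(truth), .data$contig, .data$pos))
}

#' Read-simulation profile
#'
#' @param read_len Read length in bp (paired-end, both mates). Default 250.
#' @param error_rate Per-base substitution error rate; base qualities are
#'   set consistently (`Q = -10 log10(error_rate)`). Default 0.001.
#' @param depth_mean Mean read pairs per amplicon. Default 1000.
#' @param depth_sdlog Log-normal sigma of per-amplicon depth (amplification
#'   bias); 0 gives constant depth. Default 0.35.
#' @return A list of class `slim_read_profile`.
#' @export
read_profile <- function(read_len = 250L, error_rate = 0.001,
                         depth_mean = 1000, depth_sdlog = 0.35) {
  stopifnot(read_len > 0, error_rate >= 0, error_rate < 1, depth_mean > 0,
            depth_sdlog >= 0)
  structure(list(read_len = as.integer(read_len), error_rate = error_rate,
                 depth_mean = depth_mean, depth_sdlog = depth_sdlog),
            class = "slim_read_profile")
}

inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, error_rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      new <- sample(setdiff(bases, toupper(old)), 1L)
      substr(reads[i], p, p) <- new
    }
  }
  reads
}

#' Simulate paired-end reads from a panel
#'
#' Each amplicon's expected tagged product is drawn from one of the supplied
#' haplotypes (chosen per fragment according to `fractions`), sequencing
#' errors are injected as substitutions, and the two mates are the first
#' `read_len` bases and the reverse complement of the last `read_len` bases
#' of the fragment. Tags are part of the reads, as in the real library; the
#' analysis clips them together with the primers. Read names carry the truth
#' amplicon id and haplotype for debugging. Byte-reproducible for a fixed
#' seed.
#'
#' @param panel A complete `slim_panel`.
#' @param haplotypes Named list of references (each a named character vector
#'   of contigs); typically `list(ref = reference, alt = hap$haplotype)`.
#' @param fractions Numeric vector, one sampling weight per haplotype
#'   (summing to 1).
#' @param profile A [read_profile()].
#' @param seed Integer seed.
#' @param fastq1,fastq2 Optional output FASTQ paths; written when non-`NULL`.
#' @return Tibble with `name`, `read1`, `read2`, `qual1`, `qual2`,
#'   `amplicon`, `haplotype` (invisibly when writing FASTQ).
#' @export
simulate_reads <- function(panel, haplotypes, fractions = 1,
                           profile = read_profile(), seed = 1L,
                           fastq1 = NULL, fastq2 = NULL) {
  stopifnot(inherits(panel, "slim_panel"), length(haplotypes) == length(fractions),
            abs(sum(fractions) - 1) < 1e-8)
  if (is.null(names(haplotypes))) {
    names(haplotypes) <- paste0("hap", seq_along(haplotypes))
  }
  amps <- panel$amplicons
  # expected fragment per amplicon per haplotype; variants under a primer
  # site are overwritten by the primer itself, as in a real PCR
  frag_tbl <- purrr::map(haplotypes, function(h) amplicon_seqs_hap(panel, h))
  out <- withr::with_seed(seed, {
    rows <- list()
    for (a in seq_len(nrow(amps))) {
      depth <- if (profile$depth_sdlog > 0) {
        as.integer(round(stats::rlnorm(1L, log(profile$depth_mean) -
                                         profile$depth_sdlog^2 / 2,
                                       profile$depth_sdlog)))
      } else {
        as.integer(round(profile$depth_mean))
      }
      if (depth == 0L) next
      hap_idx <- sample.int(length(haplotypes), depth, replace = TRUE,
                            prob = fractions)
      frags <- vapply(hap_idx, function(h) frag_tbl[[h]][[amps$id[a]]],
                      character(1))
      frags <- inject_errors(toupper(frags), profile$error_rate)
      lens <- nchar(frags)
      r1 <- substr(frags, 1L, pmin(profile$read_len, lens))
      r2 <- reverse_complement(
        substr(frags, pmax(1L, lens - profile$read_len + 1L), lens))
      rows[[a]] <- tibble::tibble(
        amplicon = amps$id[a], haplotype = names(haplotypes)[hap_idx],
        read1 = r1, read2 = r2
      )
    }
    dplyr::bind_rows(rows)
  })
  if (!nrow(out)) stop("no reads simulated", call. = FALSE)
  q <- as.integer(round(-10 * log10(max(profile$error_rate, 1e-6))))
  q <- min(max(q, 2L), 41L)
  qc <- intToUtf8(q + 33L)
  out$qual1 <- strrep(qc, nchar(out$read1))
  out$qual2 <- strrep(qc, nchar(out$read2))
  out$name <- sprintf("read%06d AMP=%s HAP=%s", seq_len(nrow(out)),
                      out$amplicon, out$haplotype)
  out <- out[c("name", "read1", "read2", "qual1", "qual2", "amplicon", "haplotype")]
  if (!is.null(fastq1)) {
    write_fastq(out$name, out$read1, out$qual1, fastq1)
    write_fastq(out$name, out$read2, out$qual2, fastq2)
    return(invisible(out))
  }
  out
}

# Expected tagged amplicon sequences against an arbitrary haplotype: primer
# (oligo) sequence at the ends, haplotype sequence in the interior. Interior
# coordinates are mapped through the haplotype's indels by re-locating the
# primer binding sites.
amplicon_seqs_hap <- function(panel, haplotype) {
  amps <- panel$amplicons
  out <- character(nrow(amps))
  for (i in seq_len(nrow(amps))) {
    ctg <- amps$contig[i]
    hseq <- haplotype[[ctg]]
    fg <- toupper(amps$fwd_gene[i])
    rg_rc <- reverse_complement(toupper(amps$rev_gene[i]))
    # search near the reference coordinates first, fall back to full scan
    fs <- locate_site(hseq, fg, amps$start[i])
    rs <- locate_site(hseq, rg_rc, amps$end[i] - nchar(rg_rc))
    if (is.na(fs) || is.na(rs) || rs <= fs) {
      stop(sprintf("amplicon %s: primer site not found on haplotype", amps$id[i]),
           call. = FALSE)
    }
    interior <- substr(hseq, fs + nchar(fg), rs - 1L)
    out[i] <- paste0(amps$fwd_oligo[i], toupper(interior),
                     reverse_complement(amps$rev_oligo[i]))
  }
  stats::setNames(out, amps$id)
}

# Find a primer binding site near its expected coordinate, tolerating a few
# substitutions (a primer anneals over a haplotype SNV and overwrites it).
locate_site <- function(hseq, site, ref_start0, window = 60L, max_mm = 5L) {
  L <- nchar(site)
  lo <- max(1L, ref_start0 + 1L - window)
  hi <- min(nchar(hseq), ref_start0 + nchar(site) + window)
  hit <- stringi::stri_locate_first_fixed(substr(hseq, lo, hi), site)[1, 1]
  if (!is.na(hit)) return(lo + hit - 1L)
  cand <- lo:max(lo, hi - L + 1L)
  sitechars <- strsplit(site, "", fixed = TRUE)[[1]]
  mm <- vapply(cand, function(s) {
    sum(strsplit(substr(hseq, s, s + L - 1L), "", fixed = TRUE)[[1]] !=
          sitechars)
  }, integer(1))
  best <- which.min(mm)
  if (mm[best] <= max_mm) return(cand[best])
  stringi::stri_locate_first_fixed(hseq, site)[1, 1]
}

write_fastq <- function(names, reads, quals, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads),
    Biostrings::PhredQuality(quals)
  )
  names(x) <- names
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on re-read
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble::tibble(
    name = names(x),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x))
  )
}

#' Write a truth table as a minimal VCF
#'
#' @param truth Truth tibble from [apply_variants()].
#' @param path Output path.
#' @param contig_lengths Optional named lengths for the header.
#' @return The path, invisibly.
#' @export
write_truth_vcf <- function(truth, path, contig_lengths = NULL) {
  lines <- c("##fileformat=VCFv4.2",
             "##source=slimamp-readsim")
  if (!is.null(contig_lengths)) {
    lines <- c(lines, sprintf("##contig=<ID=%s,length=%d>",
                              names(contig_lengths), contig_lengths))
  }
  lines <- c(lines, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(truth)) {
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tZYG=%s;VAF=%g",
                              truth$contig, truth$pos, truth$ref, truth$alt,
                              truth$zygosity, truth$vaf))
  }
  writeLines(lines, path)
  invisible(path)
}
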