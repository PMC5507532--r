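# Nucleotide sequence primitives.
#
# Case carries meaning throughout the package: lower case marks universal tag
# sequence, upper case marks gene-specific (or inserted partner-primer)
# sequence. All primitives therefore preserve case.

#' Default universal tag sequences
#'
#' The two TruSeq Custom Amplicon universal tags used as 5' tails on all
#' gene-specific primers. They serve as the binding sites of the indexing
#' primers in the second (universal) PCR, and as the stem material of the
#' inhibitory hairpin in overlap-amplicon products.
#'
#' @return Named character vector with elements `t1` (20 nt) and `t2` (21 nt),
#'   in lower case by the tag convention.
#' @export
#' @examples
#' nchar(slim_tags())  # 20 and 21
slim_tags <- function() {
  c(
    t1 = "caacgatcgtcgaaattcgc",
    t2 = "tacacgacgctcttccgatct"
  )
}

check_alphabet <- function(x, allow_empty = TRUE, arg = "seq") {
  if (!is.character(x)) {
    stop(sprintf("`%s` must be a character vector", arg), call. = FALSE)
  }
  bad <- stringr::str_detect(x, "[^ACGTacgt]")
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf(
      "`%s` contains non-ACGT characters (ambiguity codes are not supported): %s",
      arg, paste(utils::head(x[which(bad)], 3), collapse = ", ")
    ), call. = FALSE)
  }
  if (!allow_empty && any(!nzchar(x))) {
    stop(sprintf("`%s` must be non-empty", arg), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement, preserving case
#'
#' Watson-Crick reverse complement of one or more sequences. Case is preserved
#' per position (a lower-case tag stays lower case in the complement), so the
#' tag/gene-specific annotation of an oligo survives strand flips.
#'
#' @param seq Character vector of sequences over `A`,`C`,`G`,`T` (either case).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AGGG")
#' reverse_complement(slim_tags()[["t1"]])
reverse_complement <- function(seq) {
  check_alphabet(seq)
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", seq))
}

#' Melting temperature of an oligonucleotide
#'
#' Either the Wallace 2+4 rule or a nearest-neighbor calculation with the
#' unified SantaLucia parameter set. The nearest-neighbor default conditions
#' (150 mM effective monovalent cation, 250 nM oligo) approximate a PCR
#' buffer and place typical 18-30 nt primers designed for a 60 degree
#' annealing step inside the 57-63 degree window.
#'
#' @param seq Character vector of sequences (case-insensitive).
#' @param method `"nearest_neighbor"` (default) or `"wallace"`.
#' @param na_m Effective monovalent cation concentration, mol/L. Default 0.15.
#' @param oligo_m Oligo concentration, mol/L. Default 250e-9.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
#' @examples
#' melting_temp("ACGT", method = "wallace")  # 12
#' melting_temp("AGGGAAGCTTCATAAGTCAGTC")    # close to 60
melting_temp <- function(seq, method = c("nearest_neighbor", "wallace"),
                         na_m = 0.15, oligo_m = 250e-9) {
  method <- match.arg(method)
  check_alphabet(seq)
  up <- toupper(seq)
  if (method == "wallace") {
    at <- stringr::str_count(up, "[AT]")
    gc <- stringr::str_count(up, "[GC]")
    return(2 * at + 4 * gc)
  }
  if (any(nchar(up) < 2)) {
    stop("nearest-neighbor Tm requires sequences of length >= 2", call. = FALSE)
  }
  vapply(up, tm_nn_one, numeric(1), na_m = na_m, oligo_m = oligo_m,
         USE.NAMES = FALSE)
}

# Unified nearest-neighbor stack parameters (kcal/mol; cal/mol/K), keyed by
# the 5'->3' dinucleotide step.
.nn_dh <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
  GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.nn_ds <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
  GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)

tm_nn_one <- function(s, na_m, oligo_m) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  steps <- paste0(b[-length(b)], b[-1])
  dh <- sum(.nn_dh[steps])
  ds <- sum(.nn_ds[steps])
  for (term in c(b[1], b[length(b)])) {
    if (term %in% c("A", "T")) {
      dh <- dh + 2.3
      ds <- ds + 4.1
    } else {
      dh <- dh + 0.1
      ds <- ds - 2.8
    }
  }
  ds <- ds + 0.368 * (length(b) - 1) * log(na_m)
  1000 * dh / (ds + 1.987 * log(oligo_m / 4)) - 273.15
}

#' Find the terminal stem (hairpin duplex) of a single strand
#'
#' Returns the largest `L` such that the 5' prefix of length `L` is the exact
#' reverse complement of the 3' suffix of length `L`: a perfect terminal
#' duplex, the structure an overlap-amplicon strand adopts when both of its
#' ends carry the same tag (plus, in a SLIMamp design, the inserted partner
#' primer prefix). Detection is deliberately exact -- no wobble pairs, no
#' bulges -- because the constructed stems are exact by design.
#'
#' @param seq A single non-empty sequence (case-insensitive for pairing).
#' @return A one-row tibble with `stem_length`, `loop_length` and
#'   `stem_sequence` (the 5' prefix, case as given). `stem_length` 0 means no
#'   terminal duplex.
#' @export
#' @examples
#' find_terminal_stem("ACGTaaaaaACGT")  # stem ACGT, loop aaaaa
#' find_terminal_stem("AAAA")           # no stem
find_terminal_stem <- function(seq) {
  check_alphabet(seq, allow_empty = FALSE)
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  a <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(reverse_complement(seq)), "", fixed = TRUE)[[1]]
  lmax <- n %/% 2L
  stem <- 0L
  while (stem < lmax && a[stem + 1L] == b[stem + 1L]) {
    stem <- stem + 1L
  }
  tibble::tibble(
    stem_length = stem,
    loop_length = n - 2L * stem,
    stem_sequence = substr(seq, 1L, stem)
  )
}

#' Read and write FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] returning/accepting plain named character
#' vectors, the currency of this package. Writing wraps at 60 columns.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(toupper(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
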