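# Multiplex PCR kinetics of overlapping amplicons.
#
# Two layers: an idealized branching model (closed-form folds and the
# per-cycle recurrence they summarise) and a calibrated two-stage simulator
# in which per-species efficiencies come from a priming sigmoid on the Tm of
# the accessible portion of each primer-binding site, so that stem-loop
# inhibition of the overlap species emerges from sequence alone.

#' Closed-form amplification folds of the four-species model
#'
#' For two overlapping target amplicons amplified together, the four products
#' are the two targets (amplicon 1 and 2), the short overlap product
#' (amplicon 3, primed by the two inner primers) and the long spanning
#' product (amplicon 4, primed by the two outer primers). At cycle `n` with
#' all efficiencies 1 the amplification folds are `n 2^n`, `n 2^n`, `2^n`
#' and `n^2 2^n` respectively: the overlap product outgrows the targets by a
#' factor of `n` because every other species templates it.
#'
#' @param n Integer vector of cycle numbers, each >= 0.
#' @return Tibble with columns `cycle`, `amplicon1`, `amplicon2`,
#'   `spanning`, `overlap`.
#' @export
#' @examples
#' fold_closed_form(5)
fold_closed_form <- function(n) {
  if (any(n < 0) || any(n != floor(n))) {
    stop("cycle numbers must be non-negative integers", call. = FALSE)
  }
  tibble::tibble(
    cycle = as.integer(n),
    amplicon1 = n * 2^n,
    amplicon2 = n * 2^n,
    spanning = 2^n,
    overlap = n^2 * 2^n
  )
}

#' Per-cycle branching recurrence for two overlapping amplicons
#'
#' The spanning product doubles from itself; each target gains from itself
#' and from the spanning product; the overlap product gains from itself and
#' from every longer species. With all efficiencies 1 this reproduces the
#' closed-form `2^n` spanning fold exactly, and yields targets
#' `n 2^(n-1)` and overlap `n(n+1) 2^(n-2)` -- the same growth orders as the
#' closed-form folds up to constant factors, with overlap/target ratio
#' `(n+1)/2` growing linearly in `n`.
#'
#' @param cycles Number of cycles.
#' @param e Named numeric vector of per-species efficiencies in `[0, 1]`:
#'   `amplicon1`, `amplicon2`, `overlap`, `spanning`.
#' @param n0 Initial template copies (seeds the spanning species, the proxy
#'   for genomic template). Default 1.
#' @return A `slim_trajectory` tibble: `cycle` 0..`cycles` and per-species
#'   expected copy numbers.
#' @export
#' @examples
#' simulate_branching(10)
simulate_branching <- function(cycles,
                               e = c(amplicon1 = 1, amplicon2 = 1,
                                     overlap = 1, spanning = 1),
                               n0 = 1) {
  stopifnot(cycles >= 0, all(e >= 0), all(e <= 1),
            all(c("amplicon1", "amplicon2", "overlap", "spanning") %in% names(e)))
  a1 <- a2 <- a3 <- numeric(cycles + 1L)
  a4 <- numeric(cycles + 1L)
  a4[1] <- n0
  for (i in seq_len(cycles)) {
    a4[i + 1] <- a4[i] + e[["spanning"]] * a4[i]
    a1[i + 1] <- a1[i] + e[["amplicon1"]] * (a1[i] + a4[i])
    a2[i + 1] <- a2[i] + e[["amplicon2"]] * (a2[i] + a4[i])
    a3[i + 1] <- a3[i] + e[["overlap"]] * (a3[i] + a1[i] + a2[i] + a4[i])
  }
  structure(
    tibble::tibble(cycle = 0:cycles, amplicon1 = a1, amplicon2 = a2,
                   overlap = a3, spanning = a4),
    class = c("slim_trajectory", "tbl_df", "tbl", "data.frame")
  )
}

#' Simulation parameters for the two-stage multiplex PCR model
#'
#' The cycling emulates a two-stage protocol: a few initial cycles at a
#' lower annealing temperature where gene-specific primer portions bind the
#' genomic template (all species, including the overlap product, form in
#' full length with tags), then the remaining cycles at a raised annealing
#' temperature where only fully accessible tagged primer sites prime
#' efficiently.
#'
#' @param total_cycles Total PCR cycles. Default 35.
#' @param stage1_cycles Initial gene-specific cycles. Default 5.
#' @param stage1_anneal,stage2_anneal Annealing temperatures in degrees
#'   Celsius. Defaults 60 and 72.
#' @param delta_t Priming sigmoid midpoint offset: priming is 50\% efficient
#'   when the accessible-site Tm sits `delta_t` degrees below the annealing
#'   temperature. Default 12.
#' @param slope Sigmoid width in degrees. Default 3.
#' @param len_half,len_width Logistic length gate on extension efficiency:
#'   products of length `len_half` bp extend at 50\% efficiency, with
#'   transition width `len_width`. Defaults 650 and 25; the ~700 bp spanning
#'   product is strongly penalised while =<550 bp species are not.
#' @param n0 Initial genomic template copies. Default 1.
#' @return A list of class `slim_sim_params`.
#' @export
slim_sim_params <- function(total_cycles = 35L, stage1_cycles = 5L,
                            stage1_anneal = 60, stage2_anneal = 72,
                            delta_t = 12, slope = 3,
                            len_half = 650, len_width = 25, n0 = 1) {
  stopifnot(stage1_cycles <= total_cycles, slope > 0, len_width > 0)
  structure(
    list(total_cycles = as.integer(total_cycles),
         stage1_cycles = as.integer(stage1_cycles),
         stage1_anneal = stage1_anneal, stage2_anneal = stage2_anneal,
         delta_t = delta_t, slope = slope,
         len_half = len_half, len_width = len_width, n0 = n0),
    class = "slim_sim_params"
  )
}

logistic <- function(x) 1 / (1 + exp(-x))

length_gate <- function(len, params) {
  1 / (1 + exp((len - params$len_half) / params$len_width))
}

#' Priming efficiency of a primer on a (possibly stem-occluded) template
#'
#' The probability that a primer productively primes in one annealing step,
#' modelled as a logistic function of the melting temperature of the
#' *accessible* 3' portion of its binding site. On an open, fully
#' single-stranded template the whole oligo (tag included, once tags are
#' incorporated) is accessible. On an overlap-product template whose ends
#' carry the same tag, the terminal stem sequesters the tag; if the stem
#' additionally contains inserted partner-primer sequence (the inhibitory
#' design), the matching 5' part of the gene-specific site is sequestered
#' too, leaving only `gene length - insert length` bases free -- too few to
#' anneal at the raised second-stage temperature. A tag-only stem leaves the
#' whole gene-specific site in the loop, so priming is unaffected by how
#' long that stem is.
#'
#' @param oligo Full primer sequence (tag + insert + gene-specific).
#' @param accessible_len Number of 3'-terminal bases of the binding site that
#'   are accessible on the template.
#' @param anneal_t Annealing temperature, degrees Celsius.
#' @param params A [slim_sim_params()] object (uses `delta_t`, `slope`).
#' @return Priming probability in `[0, 1]`.
#' @export
#' @examples
#' p <- slim_sim_params()
#' oligo <- paste0(slim_tags()[["t1"]], "AGGGAAGCTTCATAAGTCAGTC")
#' priming_efficiency(oligo, nchar(oligo), 72, p)  # open template: > 0.9
#' priming_efficiency(oligo, 6, 72, p)             # stem-occluded: ~ 0
priming_efficiency <- function(oligo, accessible_len, anneal_t,
                               params = slim_sim_params()) {
  stopifnot(accessible_len <= nchar(oligo), accessible_len >= 0)
  if (accessible_len < 2L) return(0)
  site <- substr(oligo, nchar(oligo) - accessible_len + 1L, nchar(oligo))
  tm <- melting_temp(site)
  logistic((tm - anneal_t + params$delta_t) / params$slope)
}

# Species table for a panel: targets, per-junction overlap and spanning
# products, with lengths and the stage-wise efficiencies.
panel_species <- function(panel, params) {
  amps <- panel$amplicons
  jn <- panel$junctions
  e_stage <- function(oligo_fwd, gene_fwd, oligo_rev, gene_rev, len, stage,
                      acc_fwd = NULL, acc_rev = NULL) {
    t_ann <- if (stage == 1L) params$stage1_anneal else params$stage2_anneal
    if (stage == 1L) {
      acc_fwd <- nchar(gene_fwd); acc_rev <- nchar(gene_rev)
      # stage 1: only the gene-specific portion can bind the genomic template
      ef <- priming_efficiency(gene_fwd, acc_fwd, t_ann, params)
      er <- priming_efficiency(gene_rev, acc_rev, t_ann, params)
    } else {
      if (is.null(acc_fwd)) acc_fwd <- nchar(oligo_fwd)
      if (is.null(acc_rev)) acc_rev <- nchar(oligo_rev)
      ef <- priming_efficiency(oligo_fwd, acc_fwd, t_ann, params)
      er <- priming_efficiency(oligo_rev, acc_rev, t_ann, params)
    }
    min(ef, er) * length_gate(len, params)
  }
  nontag <- function(oligo, gene) nchar(oligo) - nchar(gene)
  targets <- purrr::pmap_dfr(
    amps[c("id", "start", "end", "fwd_oligo", "fwd_gene", "rev_oligo", "rev_gene")],
    function(id, start, end, fwd_oligo, fwd_gene, rev_oligo, rev_gene) {
      len <- (end - start) + nontag(fwd_oligo, fwd_gene) + nontag(rev_oligo, rev_gene)
      tibble::tibble(
        species = id, type = "target", length_bp = len,
        e1 = e_stage(fwd_oligo, fwd_gene, rev_oligo, rev_gene, len, 1L),
        e2 = e_stage(fwd_oligo, fwd_gene, rev_oligo, rev_gene, len, 2L)
      )
    }
  )
  overlaps <- spans <- NULL
  if (nrow(jn)) {
    overlaps <- purrr::pmap_dfr(jn, function(junction, contig, left_id, right_id,
                                             ov_start, ov_end, shared_tag_id,
                                             insert_len, insert_side, ...) {
      L <- amps[match(left_id, amps$id), ]
      R <- amps[match(right_id, amps$id), ]
      if (is.na(insert_len)) insert_len <- 0L
      side <- if (is.na(insert_side)) "left_rev" else insert_side
      # overlap product: forward primer = right amplicon's fwd, reverse = left's rev
      fo <- R$fwd_oligo; fg <- R$fwd_gene
      ro <- L$rev_oligo; rg <- L$rev_gene
      len <- (ov_end - ov_start) + nontag(fo, fg) + nontag(ro, rg)
      stem <- !is.na(L$rev_tag_id) && !is.na(R$fwd_tag_id) &&
        L$rev_tag_id == R$fwd_tag_id
      if (!stem) {
        acc_f <- nchar(fo); acc_r <- nchar(ro)
      } else if (side == "left_rev") {
        # stem sequesters tag + inserted fwd-primer prefix on the fwd side
        acc_f <- nchar(fg) - insert_len
        acc_r <- nchar(rg)
      } else {
        acc_f <- nchar(fg)
        acc_r <- nchar(rg) - insert_len
      }
      tibble::tibble(
        species = sprintf("overlap_%s_%s", left_id, right_id),
        type = "overlap", length_bp = len,
        e1 = e_stage(fo, fg, ro, rg, len, 1L),
        e2 = e_stage(fo, fg, ro, rg, len, 2L, acc_f, acc_r),
        left_id = left_id, right_id = right_id
      )
    })
    spans <- purrr::pmap_dfr(jn, function(junction, contig, left_id, right_id, ...) {
      L <- amps[match(left_id, amps$id), ]
      R <- amps[match(right_id, amps$id), ]
      len <- (R$end - L$start) + nontag(L$fwd_oligo, L$fwd_gene) +
        nontag(R$rev_oligo, R$rev_gene)
      tibble::tibble(
        species = sprintf("spanning_%s_%s", left_id, right_id),
        type = "spanning", length_bp = len,
        e1 = e_stage(L$fwd_oligo, L$fwd_gene, R$rev_oligo, R$rev_gene, len, 1L),
        e2 = e_stage(L$fwd_oligo, L$fwd_gene, R$rev_oligo, R$rev_gene, len, 2L),
        left_id = left_id, right_id = right_id
      )
    })
  }
  list(targets = targets, overlaps = overlaps, spans = spans)
}

#' Simulate two-stage multiplex PCR of a panel ("virtual gel")
#'
#' Runs the branching recurrence over all panel species with per-stage,
#' per-species efficiencies derived from [priming_efficiency()]: stage 1 at
#' the gene-specific annealing temperature (everything forms, the overlap
#' products pick up their tagged ends), stage 2 at the raised temperature
#' where targets and spanning products prime on fully accessible tagged
#' ends while overlap products are gated by their terminal stem. Expected
#' copy numbers are deterministic; the output is the abundance table a gel
#' lane would show.
#'
#' @param panel A complete `slim_panel`.
#' @param reference Named character vector of reference sequences (kept for
#'   interface symmetry; lengths come from the panel).
#' @param params A [slim_sim_params()] object.
#' @return A `slim_gel` tibble: `species`, `type`, `length_bp`, `copies`,
#'   `fraction`.
#' @export
simulate_slimamp <- function(panel, reference = NULL,
                             params = slim_sim_params()) {
  sp <- panel_species(panel, params)
  tg <- sp$targets; ov <- sp$overlaps; sn <- sp$spans
  n_t <- nrow(tg)
  n_j <- if (is.null(ov)) 0L else nrow(ov)
  A <- stats::setNames(numeric(n_t), tg$species)
  O <- if (n_j) stats::setNames(numeric(n_j), ov$species) else numeric(0)
  S <- if (n_j) stats::setNames(rep(params$n0, n_j), sn$species) else numeric(0)
  G <- params$n0  # unamplified genomic template, a constant feed
  for (cyc in seq_len(params$total_cycles)) {
    stage <- if (cyc <= params$stage1_cycles) "e1" else "e2"
    eT <- tg[[stage]]
    eO <- if (n_j) ov[[stage]] else numeric(0)
    eS <- if (n_j) sn[[stage]] else numeric(0)
    feedT <- numeric(n_t)
    if (n_j) {
      for (j in seq_len(n_j)) {
        li <- match(ov$left_id[j], tg$species)
        ri <- match(ov$right_id[j], tg$species)
        feedT[li] <- feedT[li] + S[j]
        feedT[ri] <- feedT[ri] + S[j]
      }
    }
    newA <- A + eT * (A + feedT + G)
    if (n_j) {
      li <- match(ov$left_id, tg$species)
      ri <- match(ov$right_id, tg$species)
      newO <- O + eO * (O + A[li] + A[ri] + S + G)
      newS <- S + eS * S
    } else {
      newO <- O; newS <- S
    }
    A <- newA; O <- newO; S <- newS
  }
  out <- dplyr::bind_rows(
    tibble::tibble(species = tg$species, type = "target",
                   length_bp = tg$length_bp, copies = unname(A)),
    if (n_j) tibble::tibble(species = ov$species, type = "overlap",
                            length_bp = ov$length_bp, copies = unname(O)),
    if (n_j) tibble::tibble(species = sn$species, type = "spanning",
                            length_bp = sn$length_bp, copies = unname(S))
  )
  out$fraction <- out$copies / sum(out$copies)
  structure(out, class = c("slim_gel", class(tibble::tibble())),
            params = params)
}

#' @export
autoplot.slim_gel <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$species, y = .data$fraction,
                                       fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "fraction of final copies",
                  title = "Virtual gel: expected species abundances") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.slim_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"cycle",
                              names_to = "species", values_to = "copies")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$copies,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "expected copies", title = "Branching PCR trajectory") +
    ggplot2::theme_minimal()
}
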