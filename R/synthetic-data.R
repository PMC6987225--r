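#' Random DNA with controlled A/T content
#'
#' I.i.d. bases with `P(A) = P(T) = at_content/2` and
#' `P(G) = P(C) = (1 - at_content)/2`; the null model behind the
#' expected motif counts. The default A/T content in downstream
#' analyses is 0.57 (Drosophila-like).
#'
#' @param length Sequence length, bp.
#' @param at_content A/T fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return Uppercase sequence string.
#' @export
random_sequence <- function(length, at_content = 0.57, seed = 1L) {
  stopifnot(length >= 1, at_content >= 0, at_content <= 1)
  p <- c(A = at_content / 2, T = at_content / 2,
         G = (1 - at_content) / 2, C = (1 - at_content) / 2)
  with_seed(seed, paste(sample(names(p), length, replace = TRUE, prob = p),
                        collapse = ""))
}

#' G/C-rich sequence by the designed Markov rule
#'
#' Generates a sequence where, after a G or C, the next base is G/C
#' with probability 0.82 (A/T with 0.18), and after an A or T the next
#' base is G/C with probability 1 — so no two consecutive A/T bases
#' ever occur. Within each class the two bases are equiprobable. The
#' stationary A/T fraction of this chain is `0.18/1.18` (about 0.153).
#'
#' @param length Sequence length, bp.
#' @param seed RNG seed.
#' @param p_gc_after_gc Probability of G/C following a G/C.
#' @return Uppercase sequence string.
#' @export
gc_rich_sequence <- function(length, seed = 1L, p_gc_after_gc = 0.82) {
  stopifnot(length >= 1)
  with_seed(seed, {
    out <- character(length)
    # start from the stationary class distribution
    gc_frac <- 1 / (1 + (1 - p_gc_after_gc))
    is_gc <- stats::runif(1) < gc_frac
    pick <- function(gc) if (gc) sample(c("G", "C"), 1L)
    else sample(c("A", "T"), 1L)
    out[1] <- pick(is_gc)
    if (length > 1L) for (i in 2:length) {
      is_gc <- if (is_gc) stats::runif(1) < p_gc_after_gc else TRUE
      out[i] <- pick(is_gc)
    }
    paste(out, collapse = "")
  })
}

#' Declustered sequence with a fixed base composition
#'
#' Random permutation of an exact base multiset, rejecting any
#' arrangement with a homo-nucleotide run longer than `max_run` —
#' the "minimize clustering" design rule. Composition is preserved
#' exactly.
#'
#' @param composition Named counts, e.g. `c(A = 20, C = 15, G = 15,
#'   T = 25)`.
#' @param seed RNG seed.
#' @param max_run Longest allowed homo-nucleotide run (default 2).
#' @param max_tries Rejection-sampling budget.
#' @return Uppercase sequence string.
#' @export
decluster_sequence <- function(composition, seed = 1L, max_run = 2L,
                               max_tries = 10000L) {
  stopifnot(all(composition >= 0), sum(composition) >= 1)
  bases <- rep(names(composition), composition)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      s <- sample(bases)
      r <- rle(s)
      if (max(r$lengths) <= max_run)
        return(paste(s, collapse = ""))
    }
    stop("no arrangement without runs > ", max_run, " found in ",
         max_tries, " tries (composition too skewed?)")
  })
}

#' Implant hexamer sites into a sequence
#'
#' In-place substitution of 6-bp sites at given positions; length is
#' preserved, sites must be in bounds and non-overlapping. Emulates
#' the designed constructs where the natural high-affinity site is
#' replaced by consensus or degenerate variants.
#'
#' @param seq Template sequence.
#' @param positions 1-based start positions of the sites.
#' @param hexamers Character vector of 6-bp replacements (recycled).
#' @return Modified sequence string.
#' @export
implant_sites <- function(seq, positions, hexamers) {
  seq <- toupper(seq)
  n <- nchar(seq)
  hexamers <- toupper(rep_len(hexamers, length(positions)))
  if (any(nchar(hexamers) != 6L)) stop("implants must be 6 bp")
  if (any(positions < 1L | positions + 5L > n))
    stop("implant position out of bounds")
  ord <- order(positions)
  if (any(diff(positions[ord]) < 6L)) stop("implanted sites overlap")
  for (i in seq_along(positions)) {
    substr(seq, positions[i], positions[i] + 5L) <- hexamers[i]
  }
  seq
}

#' Synthetic antenna-like gene
#'
#' Builds a sequence plus matching [gene_model()] that emulates the
#' architecture of an extended gene under antenna-style regulation:
#' coding exons drawn at a lower A/T content with no implanted sites,
#' and regulatory regions (flanks, UTR-like margins and introns) drawn
#' at genomic A/T content with clusters of degenerate consensus sites
#' implanted. By construction, segment-level dissociation constants
#' are lower (tighter binding) in the regulatory regions than in the
#' coding ones.
#'
#' @param total_length Extended-span length, bp.
#' @param cds_intervals 2-column matrix or list of `c(start, end)`
#'   pairs (1-based, within the span) marking coding intervals.
#' @param rr_at,cds_at A/T content of regulatory / coding portions
#'   (defaults 0.57 and 0.40).
#' @param n_sites Number of degenerate sites implanted into the
#'   regulatory regions (default 20).
#' @param site_pool Hexamers sampled (with replacement) for the
#'   implants: degenerate consensus variants by default.
#' @param gene_id,seq_ref Identifiers stamped on the model.
#' @param seed RNG seed.
#' @return List with `seq` (string) and `gene` (a [gene_model()]).
#' @export
synthetic_gene <- function(total_length = 7000L,
                           cds_intervals = list(c(2500L, 4499L)),
                           rr_at = 0.57, cds_at = 0.40, n_sites = 20L,
                           site_pool = c("TAATTG", "TAATTT", "TAATGA",
                                         "CAATTA", "TAATCA"),
                           gene_id = "synth_gene", seq_ref = "synth_seq",
                           seed = 1L) {
  if (is.list(cds_intervals))
    cds_intervals <- do.call(rbind, cds_intervals)
  cds <- IRanges::reduce(IRanges::IRanges(cds_intervals[, 1],
                                          cds_intervals[, 2]))
  if (length(cds) && (min(IRanges::start(cds)) < 1L ||
                      max(IRanges::end(cds)) > total_length))
    stop("CDS intervals outside the span")
  span <- IRanges::IRanges(1L, total_length)
  rr <- IRanges::setdiff(span, cds)
  with_seed(seed, {
    chars <- strsplit(random_sequence(total_length, rr_at,
                                      seed = sample.int(2^31 - 1, 1)),
                      "")[[1]]
    for (i in seq_along(cds)) {
      idx <- IRanges::start(cds)[i]:IRanges::end(cds)[i]
      chars[idx] <- strsplit(random_sequence(length(idx), cds_at,
                                             seed = sample.int(2^31 - 1, 1)),
                             "")[[1]]
    }
    seq <- paste(chars, collapse = "")
    # implant degenerate clusters into RR bases only, non-overlapping
    rr_starts <- unlist(lapply(seq_along(rr), function(i) {
      s <- IRanges::start(rr)[i]; e <- IRanges::end(rr)[i]
      if (e - s + 1L < 6L) integer() else s:(e - 5L)
    }))
    placed <- integer()
    for (k in seq_len(n_sites)) {
      ok <- rr_starts[vapply(rr_starts, function(s)
        all(abs(s - placed) >= 6L), TRUE)]
      if (length(ok) == 0L) break
      placed <- c(placed, sample(ok, 1L))
    }
    if (length(placed))
      seq <- implant_sites(seq, sort(placed),
                           sample(site_pool, length(placed), replace = TRUE))
  })
  # exons: the CDS intervals (UTRs are left to the flanks here)
  gene <- gene_model(gene_id, seq_ref, span, exons = cds, cds = cds,
                     strand = "+")
  list(seq = seq, gene = gene)
}

#' Synthetic K_D titration table from the forward binding model
#'
#' Computes the global K_D of each construct with the energy model
#' and multiplies it by lognormal noise `10^eps`,
#' `eps ~ N(0, noise_sd)` in log10 units. The table follows the
#' titration TSV schema consumed by [fit_binding_params()].
#'
#' @param sequences Named character vector of construct sequences.
#' @param params [energy_params()] generating the data.
#' @param ionic_strength_M Ionic strength per construct (recycled).
#' @param noise_sd Lognormal noise sd, log10 units (>= 0).
#' @param seed RNG seed.
#' @return `data.frame` with columns `construct_id`, `fasta_id`,
#'   `ionic_strength_M`, `kd_M`, `sigma_log10`.
#' @export
synthetic_titration <- function(sequences, params = energy_params(),
                                ionic_strength_M = 0.06, noise_sd = 0.05,
                                seed = 1L) {
  stopifnot(noise_sd >= 0)
  ids <- names(sequences) %||% paste0("construct", seq_along(sequences))
  I <- rep_len(ionic_strength_M, length(sequences))
  kd_true <- vapply(seq_along(sequences), function(i) {
    p <- params
    p$ionic_strength <- I[i]
    binding_landscape(sequences[[i]], p)$kd
  }, 0)
  eps <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(length(sequences), 0, noise_sd))
  else rep(0, length(sequences))
  data.frame(construct_id = ids, fasta_id = ids, ionic_strength_M = I,
             kd_M = kd_true * 10^eps,
             sigma_log10 = rep(max(noise_sd, 1e-6), length(sequences)))
}

#' Synthetic FCS titration series
#'
#' Simulates one noisy decay per DNA concentration, with the free
#' fraction at each point set by the two-state isotherm at the given
#' K_D.
#'
#' @param kd True dissociation constant, mol/L.
#' @param conc_grid DNA concentrations, mol/L.
#' @param params Template [fcs_params()] (its `p_prot` is overridden
#'   per point; its `n_mean` is used for every decay).
#' @param t Lag grid.
#' @param noise_sd Relative noise sd.
#' @param seed RNG seed (one sub-seed per decay).
#' @return List of [fcs_decay()] objects.
#' @export
synthetic_fcs_titration <- function(kd, conc_grid, params = fcs_params(),
                                    t = lag_grid(), noise_sd = 0.02,
                                    seed = 1L) {
  stopifnot(kd > 0, length(conc_grid) >= 1)
  seeds <- with_seed(seed, sample.int(2^31 - 1, length(conc_grid)))
  lapply(seq_along(conc_grid), function(i) {
    p <- params
    p$p_prot <- bound_fraction(conc_grid[i], kd)
    simulate_decay(p, t = t, noise_sd = noise_sd, seed = seeds[i],
                   dna_conc = conc_grid[i],
                   replicate = paste0("sim", i))
  })
}

#' Designed calibration constructs
#'
#' Builds a panel of 75-bp constructs in the style of the designed
#' calibration molecules: declustered random backbones at genomic A/T
#' content with a central implanted site drawn from consensus,
#' degenerate and scrambled variants, plus a few G/C-rich backbones.
#' Used to generate identifiable synthetic titrations for parameter
#' recovery.
#'
#' @param n Number of constructs.
#' @param length Construct length, bp.
#' @param at_content Backbone A/T content.
#' @param seed RNG seed.
#' @return Named character vector of sequences.
#' @export
design_constructs <- function(n = 30L, length = 75L, at_content = 0.57,
                              seed = 1L) {
  pool <- c("TAATTA", "TAATTG", "TAATTT", "GAATTG", "TATATA", "CGTGTT",
            "GCGCGC", "AATTAA")
  seeds <- with_seed(seed, sample.int(2^31 - 1, 2L * n))
  seqs <- vapply(seq_len(n), function(i) {
    backbone <- if (i %% 10 == 0)
      gc_rich_sequence(length, seed = seeds[i])
    else random_sequence(length, at_content, seed = seeds[i])
    implant_sites(backbone, positions = (length %/% 2) - 2L,
                  hexamers = pool[(i - 1L) %% base::length(pool) + 1L])
  }, "", USE.NAMES = FALSE)
  names(seqs) <- sprintf("construct%02d", seq_len(n))
  seqs
}
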