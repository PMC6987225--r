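#' Motif classes: consensus, quintets and quartets
#'
#' Describes the motif families counted in the enrichment analysis of
#' a consensus hexamer (default `TAATTA`): the full consensus, the two
#' quintets (five consecutive consensus bases at in-frame positions
#' 1-5 or 2-6) and the three quartets (four consecutive consensus
#' bases at positions 1-4, 2-5 or 3-6). Each variant is defined within
#' a 6-bp frame; the in-frame positions *not* in the pattern are
#' required to mismatch the consensus, so a window is counted for at
#' most one class (no over-counting across classes).
#'
#' @param class `"consensus"`, `"quintet"` or `"quartet"`.
#' @param consensus Consensus hexamer.
#' @return Object of class `motif_class`: list with `class`,
#'   `consensus`, and `variants`, a list of integer vectors of matched
#'   in-frame positions.
#' @export
motif_class <- function(class = c("consensus", "quintet", "quartet"),
                        consensus = "TAATTA") {
  class <- match.arg(class)
  stopifnot(nchar(consensus) == 6L)
  variants <- switch(class,
    consensus = list(1:6),
    quintet = list(1:5, 2:6),
    quartet = list(1:4, 2:5, 3:6))
  structure(list(class = class, consensus = toupper(consensus),
                 variants = variants), class = "motif_class")
}

#' Expected motif counts under an i.i.d. base model
#'
#' Expected number of 6-bp windows matching each variant of a motif
#' class in a sequence of given length and A/T content, assuming
#' independent bases with `P(A) = P(T) = at_content / 2`. All
#' consensus bases are A or T, so each matched position contributes a
#' factor `p = at_content/2` and each required mismatch a factor
#' `(1 - p)`; the window count is `L - 5`. Fragments shorter than 6 bp
#' contribute zero windows.
#'
#' @param motif A [motif_class()].
#' @param length Fragment length(s) in bp; multiple lengths are summed
#'   (each fragment contributes `max(L - 5, 0)` windows).
#' @param at_content Genomic A/T fraction (default 0.57, the
#'   Drosophila genome).
#' @return Named numeric vector of per-variant expected counts.
#' @export
expected_motif_count <- function(motif, length, at_content = 0.57) {
  stopifnot(inherits(motif, "motif_class"),
            at_content >= 0, at_content <= 1)
  p <- at_content / 2
  windows <- sum(pmax(length - 5, 0))
  if (windows == 0) warning("no 6-bp windows in fragments of length ",
                            paste(length, collapse = ","))
  n_match <- lengths(motif$variants)
  out <- p^n_match * (1 - p)^(6L - n_match) * windows
  names(out) <- vapply(motif$variants, function(v)
    paste0("pos", min(v), "-", max(v)), "")
  out
}

#' Observed motif counts in a sequence
#'
#' Slides a 6-bp window along the given strand and counts, for each
#' variant of the class, windows whose pattern positions all match the
#' consensus *and* whose remaining in-frame positions all mismatch it
#' (the over-counting exclusion mirroring the `(1-p)` factors of the
#' expected-count formula). Counting is on the supplied strand only:
#' the consensus and the quartet set are closed under reverse
#' complement and the two quintet variants are mutual reverse
#' complements, so single-strand counting of all variants equals
#' one-variant counting over both strands.
#'
#' @param seq Sequence (N >= 6).
#' @param motif A [motif_class()].
#' @return List with `per_variant` (named counts) and `total`.
#' @export
observed_motif_count <- function(seq, motif) {
  stopifnot(inherits(motif, "motif_class"))
  w <- seq_windows(toupper(seq), 6L)
  counts <- count_windows(w$kmer, motif)
  list(per_variant = counts, total = sum(counts))
}

count_windows <- function(kmers, motif) {
  if (length(kmers) == 0L)
    return(stats::setNames(numeric(length(motif$variants)),
                           vapply(motif$variants, function(v)
                             paste0("pos", min(v), "-", max(v)), "")))
  cons <- strsplit(motif$consensus, "")[[1]]
  m <- matrix(unlist(strsplit(kmers, ""), use.names = FALSE),
              ncol = 6L, byrow = TRUE)
  eq <- sweep(m, 2L, cons, "==")
  counts <- vapply(motif$variants, function(v) {
    keep <- rowSums(eq[, v, drop = FALSE]) == length(v)
    if (length(v) < 6L)
      keep <- keep & rowSums(eq[, -v, drop = FALSE]) == 0L
    sum(keep)
  }, 0)
  names(counts) <- vapply(motif$variants, function(v)
    paste0("pos", min(v), "-", max(v)), "")
  counts
}

#' Partition a gene's extended span into regulatory and coding regions
#'
#' The coding region (CDS) is the union of the model's CDS intervals;
#' the regulatory region (RR) is everything else in the extended span:
#' flanks, UTRs and introns. Intervals are clipped to the sequence.
#'
#' @param gene A [gene_model()].
#' @param seq The sequence the gene's coordinates refer to.
#' @return List with `rr` and `cds` (`IRanges`), the extracted
#'   subsequences `rr_seqs`, `cds_seqs`, and bp totals `rr_bp`,
#'   `cds_bp`.
#' @export
region_partition <- function(gene, seq) {
  stopifnot(inherits(gene, "gene_model"))
  n <- nchar(seq)
  if (IRanges::end(gene$span) > n)
    stop("gene span [", IRanges::start(gene$span), ",",
         IRanges::end(gene$span), "] extends past the ", n, "-bp sequence")
  span <- gene$span
  cds <- IRanges::restrict(gene$cds, IRanges::start(span), IRanges::end(span))
  rr <- IRanges::setdiff(span, cds)
  extract <- function(ir) {
    if (length(ir) == 0L) return(character())
    substring(seq, IRanges::start(ir), IRanges::end(ir))
  }
  list(rr = rr, cds = cds, rr_seqs = extract(rr), cds_seqs = extract(cds),
       rr_bp = sum(IRanges::width(rr)), cds_bp = sum(IRanges::width(cds)))
}

#' Motif enrichment table for a gene
#'
#' Observed, expected and observed/expected counts of the three motif
#' classes over the gene's regulatory region (RR), coding region (CDS)
#' and the whole extended span. Observed counts scan the whole
#' extended span once; a window is attributed to the region containing
#' its first base, so RR + CDS observed counts add up to the
#' whole-span counts exactly. Expected counts treat each region
#' fragment independently (`L - 5` windows per fragment).
#'
#' @param seq Gene sequence (the full record the gene model indexes).
#' @param gene A [gene_model()].
#' @param at_content Background A/T fraction for the expected counts.
#' @param consensus Consensus hexamer.
#' @return `data.frame` with columns `gene`, `region`, `motif_class`,
#'   `observed`, `expected`, `ratio` (NA when a region is empty).
#' @export
motif_enrichment <- function(seq, gene, at_content = 0.57,
                             consensus = "TAATTA") {
  seq <- toupper(seq)
  part <- region_partition(gene, seq)
  span <- gene$span
  w <- seq_windows(substring(seq, IRanges::start(span), IRanges::end(span)), 6L)
  # absolute first-base coordinate of each window
  abs_start <- w$start + IRanges::start(span) - 1L
  in_cds <- IRanges::overlapsAny(
    IRanges::IRanges(abs_start, width = 1L), part$cds)
  rows <- list()
  for (cls in c("consensus", "quintet", "quartet")) {
    mc <- motif_class(cls, consensus)
    obs_whole <- sum(count_windows(w$kmer, mc))
    obs_cds <- sum(count_windows(w$kmer[in_cds], mc))
    obs_rr <- obs_whole - obs_cds
    exp_whole <- sum(expected_motif_count(mc, IRanges::width(span),
                                          at_content))
    exp_cds <- if (part$cds_bp > 0)
      sum(expected_motif_count(mc, IRanges::width(part$cds), at_content))
    else 0
    exp_rr <- if (part$rr_bp > 0)
      sum(expected_motif_count(mc, IRanges::width(part$rr), at_content))
    else 0
    add <- function(region, obs, expd) {
      empty <- (region == "RR" && part$rr_bp == 0) ||
        (region == "CDS" && part$cds_bp == 0)
      data.frame(gene = gene$gene_id, region = region, motif_class = cls,
                 observed = if (empty) NA_real_ else obs,
                 expected = if (empty) NA_real_ else expd,
                 ratio = if (empty || expd == 0) NA_real_ else obs / expd)
    }
    rows <- c(rows, list(add("RR", obs_rr, exp_rr),
                         add("CDS", obs_cds, exp_cds),
                         add("whole", obs_whole, exp_whole)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
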