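#' Read DNA sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a named character vector of
#' uppercase sequences. Softmasked (lowercase) bases are uppercased;
#' any character outside the `A/C/G/T` alphabet — including IUPAC
#' ambiguity codes and hard-masked `N` — is rejected with an error that
#' names the offending record and position, because every window of
#' every sequence enters the binding partition function and there is no
#' meaningful energy for an ambiguous base.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are the FASTA record ids
#'   (first whitespace-delimited token), values are uppercase sequences.
#' @seealso [reverse_complement()], [seq_windows()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  for (i in seq_along(seqs)) check_alphabet(seqs[[i]], names(seqs)[i])
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

check_alphabet <- function(seq, id = "sequence") {
  if (nchar(seq) < 1L) stop("empty sequence in record '", id, "'")
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    stop("invalid base '", substr(seq, bad, bad), "' at position ", bad,
         " of record '", id, "' (only A/C/G/T allowed)")
  }
  invisible(TRUE)
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick reverse complement. The recognition hexamer
#' `TAATTA` and its core quartet `AATT` are palindromic: they are their
#' own reverse complements, which is why single-strand motif counts of
#' palindromic classes equal double-strand counts.
#'
#' @param seq Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    check_alphabet(toupper(s))
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
  }, "", USE.NAMES = FALSE)
}

#' Enumerate k-mer windows of a sequence
#'
#' Slides a k-bp window along one strand, 5' to 3'. A sequence of N bp
#' has exactly `N - k + 1` windows.
#'
#' @param seq A single sequence (character scalar).
#' @param k Window width in bp (default 6, the binding-site width).
#' @return `data.frame` with columns `start` (1-based first-base
#'   position) and `kmer`.
#' @export
seq_windows <- function(seq, k = 6L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (k > n) stop("window width k=", k, " exceeds sequence length N=", n)
  starts <- seq_len(n - k + 1L)
  data.frame(start = starts, kmer = substring(seq, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Gene model: the interval structure of an extended gene
#'
#' Holds a transcript padded by regulatory flanks, its exon and CDS
#' intervals, and the derived regulatory region (RR). Following the
#' region definition used throughout the package, the RR is everything
#' in the extended span that is not coding: the two flanks, the UTRs and
#' all introns.
#'
#' @param gene_id Gene identifier.
#' @param seq_ref Id of the sequence record the intervals refer to.
#' @param span `IRanges` of length 1: the extended region
#'   (transcript plus flanks).
#' @param exons,cds `IRanges` of exon / coding intervals (1-based,
#'   closed, as is conventional in R genomics containers).
#' @param strand `"+"` or `"-"`.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_ref, span, exons, cds,
                       strand = c("+", "-")) {
  strand <- match.arg(strand)
  stopifnot(length(span) == 1L)
  exons <- IRanges::reduce(exons)
  cds <- IRanges::reduce(cds)
  if (length(cds) && !all(IRanges::overlapsAny(cds, exons, type = "within")))
    stop("CDS intervals must lie within exons")
  if (length(exons) && (min(IRanges::start(exons)) < IRanges::start(span) ||
                        max(IRanges::end(exons)) > IRanges::end(span)))
    stop("exon intervals outside the extended span")
  structure(list(gene_id = gene_id, seq_ref = seq_ref, span = span,
                 exons = exons, cds = cds, strand = strand),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model:", x$gene_id, " (sequence ", x$seq_ref, ", strand ",
      x$strand, ")\n", sep = "")
  cat("  extended span: [", IRanges::start(x$span), ", ",
      IRanges::end(x$span), "]  (", IRanges::width(x$span), " bp)\n", sep = "")
  cat("  exons:", length(x$exons), " CDS intervals:", length(x$cds),
      " CDS bp:", sum(IRanges::width(x$cds)), "\n")
  invisible(x)
}

#' Read a gene annotation into a gene model
#'
#' Parses a GFF3 or 6-column BED annotation of a single gene and builds
#' a [gene_model()]. The extended span is the transcript span padded by
#' `flank` bp on both ends (clipped at position 1). In GFF3, only
#' `gene`, `mRNA`, `exon` and `CDS` features are consumed (others are
#' ignored with a notice); when several transcripts exist, the CDS of
#' the transcript with the longest total CDS is used. In BED there is
#' no CDS channel: each row is taken as an exon and the CDS is set
#' equal to the exons.
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"bed"` (guessed from the extension when
#'   missing).
#' @param flank Regulatory flank in bp added on each side of the
#'   transcript (default 2000).
#' @param seq_ref Optional sequence-record id to stamp on the model
#'   (defaults to the annotation's seqname).
#' @return A [gene_model()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed"),
                            flank = 2000L, seq_ref = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0L) stop("no intervals in ", path)
    exons <- IRanges::reduce(IRanges::ranges(gr))
    cds <- exons
    tx_span <- range(exons)
    gid <- if (!is.null(gr$name) && !all(is.na(gr$name))) gr$name[1] else "gene"
    strand <- as.character(GenomicRanges::strand(gr))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    sref <- seq_ref %||% as.character(GenomicRanges::seqnames(gr))[1]
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    keep <- as.character(gr$type) %in% c("gene", "mRNA", "exon", "CDS")
    if (any(!keep)) {
      message("read_annotation: ignoring ", sum(!keep),
              " feature(s) of unhandled type")
      gr <- gr[keep]
    }
    type <- as.character(gr$type)
    if (!any(type == "mRNA")) stop("GFF3 must contain an mRNA feature")
    mrna <- gr[type == "mRNA"]
    mrna_ids <- if (!is.null(mrna$ID)) mrna$ID else as.character(seq_along(mrna))
    parent_of <- function(g) vapply(g$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, "")
    cds_all <- gr[type == "CDS"]
    # longest total CDS picks the transcript
    cds_by_tx <- split(cds_all, parent_of(cds_all))
    if (length(cds_by_tx) == 0L) stop("GFF3 contains no CDS features")
    cds_len <- vapply(cds_by_tx, function(g)
      sum(IRanges::width(IRanges::reduce(IRanges::ranges(g)))), 0)
    best_tx <- names(cds_by_tx)[which.max(cds_len)]
    cds <- IRanges::reduce(IRanges::ranges(cds_by_tx[[best_tx]]))
    sel_mrna <- mrna[mrna_ids == best_tx]
    if (length(sel_mrna) == 0L) sel_mrna <- mrna[1]
    ex <- gr[type == "exon"]
    ex_par <- parent_of(ex)
    exons <- IRanges::reduce(IRanges::ranges(ex[ex_par == best_tx]))
    if (length(exons) == 0L) exons <- IRanges::reduce(IRanges::ranges(ex))
    tx_span <- IRanges::ranges(sel_mrna)[1]
    if (IRanges::start(cds)[1] < IRanges::start(tx_span) ||
        max(IRanges::end(cds)) > IRanges::end(tx_span))
      stop("CDS extends outside its transcript")
    gtype <- gr[type == "gene"]
    gid <- if (length(gtype) && !is.null(gtype$ID)) gtype$ID[1] else best_tx
    strand <- as.character(GenomicRanges::strand(sel_mrna))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    sref <- seq_ref %||% as.character(GenomicRanges::seqnames(sel_mrna))[1]
  }
  span <- IRanges::IRanges(
    start = max(1L, IRanges::start(tx_span) - flank),
    end = IRanges::end(tx_span) + flank)
  gene_model(gid, sref, span, exons, cds, strand)
}

#' Write a gene model as GFF3
#'
#' Emits gene/mRNA/exon/CDS features so that a model can round-trip
#' through [read_annotation()].
#'
#' @param gene A [gene_model()].
#' @param path Output path.
#' @param flank Flank width recorded implicitly: the emitted transcript
#'   is the extended span shrunk by `flank` on each side.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(gene, path, flank = 2000L) {
  tx_start <- IRanges::start(gene$span) + flank
  tx_end <- IRanges::end(gene$span) - flank
  lines <- c("##gff-version 3",
    paste(gene$seq_ref, "tfantenna", "gene", tx_start, tx_end, ".",
          gene$strand, ".", paste0("ID=", gene$gene_id), sep = "\t"),
    paste(gene$seq_ref, "tfantenna", "mRNA", tx_start, tx_end, ".",
          gene$strand, ".",
          paste0("ID=", gene$gene_id, ".t1;Parent=", gene$gene_id), sep = "\t"))
  feat <- function(type, ir) {
    if (length(ir) == 0L) return(character())
    paste(gene$seq_ref, "tfantenna", type, IRanges::start(ir),
          IRanges::end(ir), ".", gene$strand, if (type == "CDS") "0" else ".",
          paste0("Parent=", gene$gene_id, ".t1"), sep = "\t")
  }
  writeLines(c(lines, feat("exon", gene$exons), feat("CDS", gene$cds)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
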