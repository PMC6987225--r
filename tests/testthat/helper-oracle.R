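# Independent brute-force re-computation of the binding landscape:
# per-window loops, per-character comparisons, no shared code with the
# package internals beyond the parameter list.
naive_landscape <- function(seq, params) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nchar(seq)
  rt <- 8.314e-3 * params$temperature
  cons <- strsplit(params$consensus, "")[[1]]
  dGs <- numeric(0)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq
    else paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
    for (x in 1:(n - 5)) {
      hex <- strsplit(substr(s, x, x + 5), "")[[1]]
      n_core <- 0; n_deg <- 0
      for (k in 1:6) {
        if (k >= 2 && k <= 5 && hex[k] == cons[k]) {
          n_core <- n_core + 1
        } else if (hex[k] == "A" || hex[k] == "T") {
          n_deg <- n_deg + 1
        }
      }
      d15 <- all(hex[1:5] == cons[1:5])
      d26 <- all(hex[2:6] == cons[2:6])
      d16 <- all(hex == cons)
      coop <- d16 + (d15 + d26) / 2
      start_fwd <- if (strand == "+") x else n - x - 4
      central <- start_fwd > params$end_margin &&
        (start_fwd + 5) <= n - params$end_margin
      ncont <- if (central) params$n_elec_central
      else params$n_elec_central - 1
      dG <- ncont * params$dG_elec0 * exp(-sqrt(params$ionic_strength)) +
        n_core * params$dG_consensus_core +
        n_deg * params$dG_degenerate_AT + coop * params$dG_cp
      dGs <- c(dGs, dG)
    }
  }
  S <- sum(exp(-dGs / rt))
  list(S = S, kd = 1 / (params$w0 * S), dGs = dGs)
}

write_tmp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(seq_along(seqs), function(i)
    c(paste0(">", ids[i]), seqs[[i]]))), path)
  path
}

# minimal two-transcript GFF3 gene: transcript t1 CDS 900 bp,
# t2 CDS 1200 bp; spans in 1-based inclusive coordinates
write_tmp_gff <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t2001\t5000\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t2001\t5000\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t2001\t5000\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\ttest\tCDS\t2501\t3400\t.\t+\t0\tID=c1;Parent=t1",
    "chr1\ttest\tmRNA\t2001\t5000\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\ttest\texon\t2001\t5000\t.\t+\t.\tID=e2;Parent=t2",
    "chr1\ttest\tCDS\t2501\t3700\t.\t+\t0\tID=c2;Parent=t2")
  writeLines(lines, path)
  path
}
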