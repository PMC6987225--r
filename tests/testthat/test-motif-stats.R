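test_that("observed counts apply the over-counting exclusion", {
  expect_equal(observed_motif_count("GGTAATTAGG",
                                    motif_class("consensus"))$total, 1)
  expect_equal(observed_motif_count("GGTAATTAGG",
                                    motif_class("quintet"))$total, 0)
  expect_equal(observed_motif_count("GGTAATTAGG",
                                    motif_class("quartet"))$total, 0)
  # TAATT followed by a non-A: one quintet, no consensus
  q <- observed_motif_count("GTAATTTG", motif_class("quintet"))
  expect_equal(q$total, 1)
  expect_equal(unname(q$per_variant["pos1-5"]), 1)
  expect_equal(observed_motif_count("GTAATTTG",
                                    motif_class("consensus"))$total, 0)
  # a full consensus window is counted only as consensus
  expect_equal(observed_motif_count("TAATTA",
                                    motif_class("consensus"))$total, 1)
  expect_equal(observed_motif_count("TAATTA",
                                    motif_class("quintet"))$total, 0)
})

test_that("expected counts follow the i.i.d. window formulas", {
  cons <- expected_motif_count(motif_class("consensus"), 1005, 0.57)
  expect_equal(unname(cons), 0.285^6 * 1000, tolerance = 1e-12)
  quin <- expected_motif_count(motif_class("quintet"), 1005, 0.57)
  expect_length(quin, 2L)
  expect_equal(unname(quin[1]), (1 - 0.285) * 0.285^5 * 1000,
               tolerance = 1e-12)
  quar <- expected_motif_count(motif_class("quartet"), 1005, 0.57)
  expect_length(quar, 3L)
  expect_equal(unname(quar[1]), (1 - 0.285)^2 * 0.285^4 * 1000,
               tolerance = 1e-12)
  expect_equal(sum(expected_motif_count(motif_class("consensus"), 1005, 0)),
               0)
  # fragments shorter than a window contribute nothing
  expect_warning(z <- expected_motif_count(motif_class("consensus"), 5),
                 "no 6-bp windows")
  expect_equal(unname(z), 0)
  expect_equal(unname(expected_motif_count(motif_class("consensus"),
                                           c(1005, 4), 0.57)),
               0.285^6 * 1000, tolerance = 1e-12)
})

test_that("palindromic classes are strand-symmetric, quintet variants swap", {
  for (seed in 1:5) {
    s <- random_sequence(500, 0.6, seed = seed)
    rc <- reverse_complement(s)
    expect_equal(observed_motif_count(s, motif_class("consensus"))$total,
                 observed_motif_count(rc, motif_class("consensus"))$total)
    expect_equal(observed_motif_count(s, motif_class("quartet"))$total,
                 observed_motif_count(rc, motif_class("quartet"))$total)
    q1 <- observed_motif_count(s, motif_class("quintet"))$per_variant
    q2 <- observed_motif_count(rc, motif_class("quintet"))$per_variant
    expect_equal(unname(q1[c("pos1-5", "pos2-6")]),
                 unname(q2[c("pos2-6", "pos1-5")]))
  }
})

test_that("region partition slices the span by coding status", {
  span <- IRanges::IRanges(1, 7000)
  cds <- IRanges::IRanges(2501, 4500)
  g <- gene_model("g", "s", span, exons = cds, cds = cds)
  seq <- random_sequence(7000, 0.57, seed = 1)
  part <- region_partition(g, seq)
  expect_equal(part$cds_bp, 2000L)
  expect_equal(part$rr_bp, 5000L)
  expect_equal(sum(nchar(part$rr_seqs)), 5000L)

  g_nocds <- gene_model("g2", "s", span, exons = IRanges::IRanges(),
                        cds = IRanges::IRanges())
  p2 <- region_partition(g_nocds, seq)
  expect_equal(p2$rr_bp, 7000L)
  expect_equal(p2$cds_bp, 0L)

  g_all <- gene_model("g3", "s", span, exons = span, cds = span)
  p3 <- region_partition(g_all, seq)
  expect_equal(p3$rr_bp, 0L)

  g_out <- gene_model("g4", "s", IRanges::IRanges(1, 9000),
                      exons = cds, cds = cds)
  expect_error(region_partition(g_out, seq), "extends past")
})

test_that("enrichment observed counts are additive over regions", {
  sg <- synthetic_gene(seed = 21)
  tab <- motif_enrichment(sg$seq, sg$gene)
  for (cls in unique(tab$motif_class)) {
    sub <- tab[tab$motif_class == cls, ]
    expect_equal(sub$observed[sub$region == "whole"],
                 sub$observed[sub$region == "RR"] +
                   sub$observed[sub$region == "CDS"])
  }
})

test_that("empty regions are reported as NA rows", {
  span <- IRanges::IRanges(1, 500)
  g_all <- gene_model("g", "s", span, exons = span, cds = span)
  seq <- random_sequence(500, 0.57, seed = 2)
  tab <- motif_enrichment(seq, g_all)
  expect_true(all(is.na(tab$ratio[tab$region == "RR"])))
  expect_false(all(is.na(tab$observed[tab$region == "whole"])))
})

test_that("an antenna-architecture gene enriches quartets in the RR", {
  sg <- synthetic_gene(rr_at = 0.57, cds_at = 0.35, n_sites = 30, seed = 31)
  tab <- motif_enrichment(sg$seq, sg$gene)
  quart <- tab[tab$motif_class == "quartet", ]
  expect_gt(quart$ratio[quart$region == "RR"],
            quart$ratio[quart$region == "CDS"])
})
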