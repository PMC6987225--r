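p_default <- energy_params(ionic_strength = 0.06)

test_that("electrostatic term follows the screened contact model", {
  p0 <- energy_params(ionic_strength = 0)
  expect_equal(electrostatic_energy(p0, central = TRUE), 6 * -8.18)
  expect_equal(electrostatic_energy(p0, central = FALSE), 5 * -8.18)
  expect_equal(electrostatic_energy(p0, TRUE, ionic_strength_M = 1e6), 0,
               tolerance = 1e-12)
  expect_error(electrostatic_energy(p0, TRUE, ionic_strength_M = -0.1),
               ">= 0")
  # extended-footprint switch uses 8/7 contacts
  p8 <- suppressMessages(energy_params(elec_contacts = "extended",
                                       ionic_strength = 0))
  expect_equal(electrostatic_energy(p8, TRUE), 8 * -8.18)
  expect_equal(electrostatic_energy(p8, FALSE), 7 * -8.18)
})

test_that("specific energy decomposes hexamers into interaction counts", {
  e <- specific_energy(c("TAATTA", "TGACAT", "GCGCGC"))
  expect_equal(e$n_core, c(4, 1, 0))
  expect_equal(e$n_degAT, c(2, 3, 0))
  expect_equal(e$coop, c(2, 0, 0))
  expect_equal(e$dG_specific[1], 4 * -3.53 + 2 * -1.75 + 2 * -3.91)
  expect_equal(e$dG_specific[3], 0)
  # quintet matches take half the cooperative term
  expect_equal(specific_energy("TAATTT")$coop, 0.5)
  expect_equal(specific_energy("AAATTA")$coop, 0.5)
  expect_error(specific_energy("TAAT"), "length 6")
})

test_that("PWM energies are log-odds against uniform background", {
  unif <- pwm_matrix(matrix(0.25, 6, 4), pseudo = 0)
  expect_equal(pwm_energy("TAATTA", unif), 0, tolerance = 1e-12)
  probs <- matrix(0.25, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  probs[1, ] <- c(0.5, 1 / 6, 1 / 6, 1 / 6)
  pwm <- pwm_matrix(probs, pseudo = 0)
  rt <- 8.314e-3 * 297
  expect_equal(pwm_energy("AAAAAA", pwm), -rt * log(2), tolerance = 1e-12)
  # columns renormalized to 1 after pseudo-count
  pwm2 <- pwm_matrix(probs, pseudo = 1e-3)
  expect_equal(unname(rowSums(pwm2$probs)), rep(1, 6), tolerance = 1e-9)
})

test_that("JASPAR-style PWM files are parsed and regularized", {
  path <- tempfile(fileext = ".pwm")
  writeLines(c("A 10 0 0 0 0 10", "C 0 0 0 0 0 0",
               "G 0 10 0 0 0 0", "T 0 0 10 10 10 0"), path)
  pwm <- read_pwm(path)
  expect_true(all(pwm$probs > 0))
  expect_equal(unname(rowSums(pwm$probs)), rep(1, 6), tolerance = 1e-9)
  expect_equal(unname(which.max(pwm$probs[2, ])), 3L)  # G dominates position 2
})

test_that("landscape enumerates both strands and matches closed forms", {
  s75 <- random_sequence(75, 0.57, seed = 11)
  L <- binding_landscape(s75, p_default)
  expect_identical(nrow(L$sites), 140L)   # 2 * (75 - 5)
  expect_error(binding_landscape("ACGTA", p_default), "at least 6")

  # all interactions zeroed: every site has weight 1, K_D = 1/(n w0)
  pz <- energy_params(dG_consensus_core = 0, dG_degenerate_AT = 0,
                      dG_cp = 0, dG_elec0 = 0, ionic_strength = 0)
  expect_equal(binding_landscape("ACGTAC", pz)$kd, 1000)
})

test_that("landscape is invariant under reverse complement", {
  for (seed in 1:5) {
    s <- random_sequence(40 + 20 * seed, 0.57, seed = seed)
    L1 <- binding_landscape(s, p_default)
    L2 <- binding_landscape(reverse_complement(s), p_default)
    expect_equal(L1$kd, L2$kd, tolerance = 1e-12)
    expect_equal(sort(L1$sites$dG), sort(L2$sites$dG), tolerance = 1e-12)
  }
})

test_that("K_D scales inversely with w0 and never grows with appended bases", {
  s <- random_sequence(80, 0.57, seed = 3)
  kd1 <- binding_landscape(s, p_default)$kd
  p2 <- p_default; p2$w0 <- p_default$w0 * 7
  expect_equal(binding_landscape(s, p2)$kd, kd1 / 7, tolerance = 1e-12)
  grown <- s
  for (i in 1:5) {
    grown <- paste0(grown, random_sequence(10, 0.57, seed = 100 + i))
    kd2 <- binding_landscape(grown, p_default)$kd
    expect_lte(kd2, kd1)
    kd1 <- kd2
  }
})

test_that("mutating a site toward consensus lowers its energy", {
  s <- implant_sites(random_sequence(75, 0.57, seed = 5), 35, "TGACAT")
  before <- binding_landscape(s, p_default)
  s2 <- implant_sites(s, 35, "TAACAT")   # position 2 moves to consensus
  after <- binding_landscape(s2, p_default)
  i <- which(before$sites$strand == "+" & before$sites$start == 35)
  expect_lt(after$sites$dG[i], before$sites$dG[i])
})

test_that("full-consensus windows have equal energies on both strands", {
  s <- implant_sites(random_sequence(75, 0.57, seed = 6), 30, "TAATTA")
  L <- binding_landscape(s, p_default)
  fw <- L$sites[L$sites$strand == "+" & L$sites$start == 30, ]
  rv <- L$sites[L$sites$strand == "-" & L$sites$start_fwd == 30, ]
  expect_identical(rv$hexamer, "TAATTA")
  expect_equal(fw$dG, rv$dG, tolerance = 1e-12)
})

test_that("occupancy normalizes and crosses half-saturation at K_D", {
  s <- random_sequence(75, 0.57, seed = 7)
  L <- binding_landscape(s, p_default)
  occ <- occupancy(L, L$kd)
  expect_equal(occ$p_bound, 0.5, tolerance = 1e-12)
  expect_equal(occ$p_free + sum(occ$sites$p_site), 1, tolerance = 1e-9)
  occ_lo <- occupancy(L, L$kd * 1e-9)
  expect_equal(occ_lo$p_free, 1, tolerance = 1e-6)
  for (conc in c(1e-9, 1e-6, 1e-3)) {
    o <- occupancy(L, conc)
    expect_equal(o$p_free + sum(o$sites$p_site), 1, tolerance = 1e-9)
  }
  expect_error(occupancy(L, 0), "> 0")
})

test_that("segment profiles tile the sequence and flag remainders", {
  s150 <- random_sequence(150, 0.57, seed = 8)
  seg <- segment_kd(s150, p_default, window = 75)
  expect_identical(nrow(seg), 2L)
  expect_false(any(seg$partial))

  s75 <- random_sequence(75, 0.57, seed = 9)
  seg1 <- segment_kd(s75, p_default, window = 75)
  expect_identical(nrow(seg1), 1L)
  expect_equal(seg1$kd, binding_landscape(s75, p_default)$kd)

  s190 <- random_sequence(190, 0.57, seed = 10)
  seg3 <- segment_kd(s190, p_default, window = 75)
  expect_identical(nrow(seg3), 3L)
  expect_true(seg3$partial[3])
  expect_identical(seg3$length[3], 40L)
  expect_error(segment_kd(s150, p_default, window = 5), ">= 6")

  # implanted consensus lowers the segment K_D against a matched control
  base <- random_sequence(75, 0.57, seed = 12)
  with_site <- implant_sites(base, 35, "TAATTA")
  expect_lt(binding_landscape(with_site, p_default)$kd,
            binding_landscape(base, p_default)$kd)
})

test_that("batch_kd profiles batches and isolates per-record failures", {
  seqs <- c(a = random_sequence(75, 0.57, seed = 1))
  tab <- batch_kd(seqs, p_default)
  expect_equal(tab$kd, binding_landscape(seqs[[1]], p_default)$kd)

  mixed <- c(good = random_sequence(75, 0.57, seed = 2), short = "ACGT")
  tab2 <- suppressMessages(batch_kd(mixed, p_default))
  expect_identical(nrow(tab2), 2L)
  expect_false(is.na(tab2$kd[1]))
  expect_true(is.na(tab2$kd[2]))
  expect_match(tab2$error[2], "6 bp")

  empty <- batch_kd(character(0), p_default)
  expect_identical(nrow(empty), 0L)
  expect_null(attr(empty, "histogram"))
})

test_that("optimized landscape matches the brute-force oracle", {
  for (seed in 1:10) {
    n <- sample(20:200, 1)
    s <- random_sequence(n, stats::runif(1, 0.3, 0.8), seed = seed)
    L <- binding_landscape(s, p_default)
    oracle <- naive_landscape(s, p_default)
    expect_equal(sort(L$sites$dG), sort(oracle$dGs), tolerance = 1e-12)
    expect_equal(L$kd, oracle$kd, tolerance = 1e-12)
  }
})

test_that("landscape TSV output carries sites and occupancies", {
  s <- random_sequence(40, 0.57, seed = 13)
  L <- binding_landscape(s, p_default)
  path <- tempfile(fileext = ".tsv")
  write_landscape(L, path, dna_conc = 1e-8)
  lines <- readLines(path)
  expect_match(lines[1], "^# strand")
  expect_identical(length(lines) - 1L, nrow(L$sites))
})
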