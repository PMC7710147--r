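# digestion_core: FASTA I/O, cleavage rules, digestion, masses.

test_that("read_fasta parses headers, range offsets and flags bad input", {
  recs <- read_fasta(toy_fasta())
  expect_length(recs, 3L)
  expect_equal(recs[[1]]$start_offset, 1L)
  expect_equal(recs[[2]]$start_offset, 201L)  # range 201-230, 30 residues
  expect_equal(nchar(recs[[2]]$sequence), 30L)

  # range header consistent with a matching sequence length: no warning
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|SYNQ|1663-2318 range-annotated fragment",
               paste(rep("A", 656), collapse = "")), f)
  expect_silent(r <- read_fasta(f))
  expect_equal(r[[1]]$start_offset, 1663L)
  expect_equal(nchar(r[[1]]$sequence), 656L)

  # declared length mismatch: warning, not error
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|X|10-12", "AAAA"), f2)
  expect_warning(r2 <- read_fasta(f2), "declares 3")
  expect_equal(r2[[1]]$start_offset, 10L)

  # no range annotation -> default offset
  f3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|TEST|1", "AAAA"), f3)
  expect_equal(read_fasta(f3)[[1]]$start_offset, 1L)

  # illegal residues are named with record and position
  f4 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "AABAA"), f4)
  expect_error(read_fasta(f4), "illegal residue character 'B' at position 3")

  f5 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f5)
  expect_error(read_fasta(f5))
})

test_that("protein_record validates invariants", {
  expect_error(protein_record("x", ""), "non-empty")
  expect_error(protein_record("x", "AUA"), "illegal residue")
  expect_error(protein_record("x", "AAA", mod_positions = c("5" = "Hyp")),
               "out of")
  expect_error(protein_record("x", "AAA", mod_positions = c("2" = "Nope")),
               "unknown modification")
  r <- protein_record("x", "GPGK", mod_positions = c("2" = "Hyp"))
  expect_equal(unname(r$mod_positions["2"]), "Hyp")
  # X allowed in sequence
  expect_silent(protein_record("x", "AXA"))
})

test_that("cleavage_sites applies rules, sides, and modifiers", {
  pa <- enzyme_preset("proalanase")
  expect_equal(cleavage_sites("AAPKGPR", pa), c(1L, 2L, 3L, 6L))
  expect_equal(cleavage_sites("AAPKGPR", enzyme_preset("trypsin_p")), 4L)
  # classic trypsin suppresses K/R before proline
  expect_equal(cleavage_sites("AKPGRG", enzyme_preset("trypsin")), 5L)
  expect_equal(cleavage_sites("AKPGRG", enzyme_preset("trypsin_p")), c(2L, 5L))
  # N-side (Asp-N): bond before D, so P1 position is the residue before D
  expect_equal(cleavage_sites("GKDAG", enzyme_preset("aspn")), 2L)
  expect_equal(cleavage_sites("DKG", enzyme_preset("aspn")), integer(0))
  # last residue has no following bond
  expect_equal(cleavage_sites("KGP", pa), integer(0))
  # Hyp on P: a site either way (P already in the residue set)
  r <- protein_record("h", "GPGK", mod_positions = c("2" = "Hyp"))
  expect_equal(cleavage_sites(r, pa), 2L)
  pa_nohyp <- enzyme_preset("proalanase", treat_hyp_as_site = FALSE)
  expect_equal(cleavage_sites(r, pa_nohyp), 2L)
  # Hyp-as-site extends an enzyme that does not recognize the letter
  gl <- enzyme_spec("gluc_hyp", c("D", "E"), treat_hyp_as_site = TRUE)
  expect_equal(cleavage_sites(r, gl), 2L)
})

test_that("digest enumerates specific peptides with exact bookkeeping", {
  pa <- enzyme_preset("proalanase")
  d0 <- digest("AAPKGPR", pa, max_missed = 0, min_len = 1, max_len = 50)
  expect_setequal(d0$sequence, c("A", "A", "P", "KGP", "R"))
  expect_true(all(d0$missed_cleavages == 0L))
  # zero-missed digest partitions the sequence
  expect_equal(paste(d0$sequence[order(d0$start)], collapse = ""), "AAPKGPR")

  d1 <- digest("APK", pa, max_missed = 1, min_len = 1, max_len = 50)
  expect_setequal(d1$sequence, c("A", "P", "K", "AP", "PK"))
  # deterministic order: by start then end
  expect_equal(d1$sequence, c("A", "AP", "P", "PK", "K"))
})

test_that("digest agrees with the exhaustive oracle on random proteins", {
  set.seed(101)
  pa <- enzyme_preset("proalanase")
  tp <- enzyme_preset("trypsin_p")
  for (i in 1:25) {
    seqn <- random_protein(sample(5:50, 1))
    enz <- if (i %% 2) pa else tp
    mm <- sample(0:4, 1)
    sites <- cleavage_sites(seqn, enz)
    got <- digest_matrix(digest(seqn, enz, max_missed = mm,
                                min_len = 1, max_len = 60))
    want <- oracle_digest(seqn, sites, mm, 1L, 60L)
    expect_equal(got, want, info = seqn)
  }
})

test_that("digest is monotone in max_missed and conserves residues", {
  set.seed(202)
  pa <- enzyme_preset("proalanase")
  for (i in 1:10) {
    seqn <- random_protein(40)
    prev <- NULL
    for (k in 0:3) {
      d <- digest(seqn, pa, max_missed = k, min_len = 1, max_len = 60)
      key <- paste(d$start, d$end)
      if (!is.null(prev)) expect_true(all(prev %in% key))
      prev <- key
    }
    d0 <- digest(seqn, pa, max_missed = 0, min_len = 1, max_len = 60)
    expect_equal(sum(nchar(d0$sequence)), nchar(seqn))
  }
})

test_that("semi_specific_peptides have exactly one enzymatic terminus", {
  pa <- enzyme_preset("proalanase")
  # extension bound 0 forces the free terminus onto a boundary -> empty
  expect_equal(nrow(semi_specific_peptides("AAPK", pa, 0)), 0L)

  # in "AAPK" every position is an enzymatic boundary (sites after 1,2,3 and
  # the protein termini), so no substring has exactly one specific terminus:
  # the fully specific candidates like "K" (after the site at 3) are excluded
  s <- semi_specific_peptides("AAPK", pa, 3, max_missed = 4,
                              min_len = 1, max_len = 10)
  want <- oracle_semi("AAPK", cleavage_sites("AAPK", pa), 3L, 4L, 1L, 10L)
  expect_equal(nrow(s), nrow(want))
  expect_equal(nrow(s), 0L)

  set.seed(303)
  for (i in 1:10) {
    seqn <- random_protein(sample(8:30, 1))
    ext <- sample(1:4, 1)
    s <- semi_specific_peptides(seqn, pa, ext, max_missed = 10,
                                min_len = 1, max_len = 40)
    expect_true(all(xor(s$nterm_specific, s$cterm_specific)))
    want <- oracle_semi(seqn, cleavage_sites(seqn, pa), ext, 10L, 1L, 40L)
    got <- matrix(as.integer(as.matrix(s[, c("start", "end")])),
                  nrow = nrow(s))
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE], want,
                 info = seqn)
  }
})

test_that("peptide_mass matches reference values and the sum oracle", {
  expect_equal(peptide_mass("PEPTIDE"), 799.3600, tolerance = 1e-4)
  expect_equal(peptide_mass("GP", "Hyp"), 188.0797, tolerance = 1e-4)
  expect_equal(peptide_mass("CA"), 192.056860, tolerance = 1e-4)
  expect_error(peptide_mass(""), "non-empty")
  expect_error(peptide_mass("AXA"), "no defined mass")
  expect_error(peptide_mass("AA", "NotAMod"), "unknown modification")

  set.seed(404)
  for (i in 1:20) {
    s <- random_protein(sample(3:25, 1))
    expect_equal(peptide_mass(s), oracle_mass(s), tolerance = 1e-4)
  }
})

test_that("mass additivity holds to 1e-6", {
  set.seed(505)
  for (i in 1:20) {
    a <- random_protein(sample(2:15, 1))
    b <- random_protein(sample(2:15, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - WATER_MONO,
                 tolerance = 1e-6)
  }
})

test_that("length_distribution counts and thresholds", {
  ld <- length_distribution(c("A", "AP", "KGP"), threshold = 3)
  expect_equal(as.numeric(ld$fractions), rep(1 / 3, 3))
  expect_equal(ld$frac_below_threshold, 2 / 3)
  expect_equal(sum(ld$counts), 3)
  expect_error(length_distribution(character(0)), "empty")

  # digest of a random synthetic protein: fraction below threshold equals
  # the exhaustive-oracle recomputation
  set.seed(606)
  seqn <- random_protein(2000, residues = names(proalanase::AA_MONO))
  tp <- enzyme_preset("trypsin_p")
  d <- digest(seqn, tp, max_missed = 2, min_len = 1, max_len = 10000)
  want <- oracle_digest(seqn, cleavage_sites(seqn, tp), 2L, 1L, 10000L)
  expect_equal(length_distribution(d)$frac_below_threshold,
               mean((want[, 2] - want[, 1] + 1) < 7))
})

test_that("peptide tables round-trip through TSV with sidecars", {
  d <- digest("AAPKGPR", "proalanase", max_missed = 1)
  attr(d, "params") <- list(demo = TRUE, seed = 5)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(d, p)
  expect_true(file.exists(paste0(p, ".params.json")))
  back <- read_peptide_table(p)
  expect_equal(back$sequence, d$sequence)
  expect_equal(back$start, d$start)
})
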