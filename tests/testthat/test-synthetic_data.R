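# synthetic_data: seeded generators for every pipeline input.

test_that("generate_proteome is reproducible and honours composition", {
  a <- generate_proteome(10, 300, seed = 7)
  b <- generate_proteome(10, 300, seed = 7)
  expect_identical(lapply(a, `[[`, "sequence"), lapply(b, `[[`, "sequence"))
  expect_equal(a[[1]]$id, "SYN0001")

  polyA <- generate_proteome(3, 100, composition = c(A = 1.0), seed = 1)
  expect_true(all(grepl("^A+$", vapply(polyA, `[[`, "", "sequence"))))

  expect_error(generate_proteome(5, 100, composition = c(A = 0.5, G = 0.4)),
               "sum to 1")

  # fixed-length single protein usable as a 656-residue target stand-in
  p656 <- generate_proteome(1, 656, seed = 1, length_sdlog = 0)
  expect_equal(nchar(p656[[1]]$sequence), 656L)
})

test_that("mechanistic mode with unit probabilities reproduces the digest", {
  prot <- generate_proteome(5, 200, seed = 11)
  model <- cleavage_model(base_prob = c(P = 1.0, A = 1.0),
                          context_multipliers = NULL,
                          detectable_len = c(1L, 100L), seed = 3)
  sim <- simulate_mechanistic(prot, model)
  ref <- do.call(rbind, lapply(prot, digest, enzyme = "proalanase",
                               max_missed = 0, min_len = 1, max_len = 100))
  expect_equal(sim$sequence[order(sim$protein_id, sim$start)],
               ref$sequence[order(ref$protein_id, ref$start)])
  expect_true(all(sim$missed_cleavages == 0L))
})

test_that("mechanistic site firing matches the binomial expectation", {
  prot <- generate_proteome(60, 450, seed = 13)
  model <- cleavage_model(base_prob = c(P = 2 / 3), context_multipliers = NULL,
                          seed = 13)
  sim <- simulate_mechanistic(prot, model)
  lab <- attr(sim, "site_labels")
  expect_gt(nrow(lab), 300)
  ratio <- sum(lab$cleaved) / sum(!lab$cleaved)
  expect_lt(abs(ratio - 2.0), 0.3)  # within 15% of 2.0

  model_a <- cleavage_model(base_prob = c(A = 1 / 3),
                            context_multipliers = NULL, seed = 14)
  sim_a <- simulate_mechanistic(prot, model_a)
  lab_a <- attr(sim_a, "site_labels")
  ratio_a <- sum(!lab_a$cleaved) / sum(lab_a$cleaved)
  expect_lt(abs(ratio_a - 2.0), 0.3)
})

test_that("context multipliers shift per-site probabilities as configured", {
  # one protein where the K at P2' must halve the P-site probability
  rec <- protein_record("ctx", "GGGPGKGGGGGGA")
  model <- cleavage_model(seed = 1)
  sim <- simulate_mechanistic(rec, model)
  lab <- attr(sim, "site_labels")
  expect_equal(lab$prob[lab$position == 4], 2 / 3 * 0.5)  # P with K at P2'
  expect_equal(lab$prob[lab$position == 13], numeric(0))  # last residue: no bond
  rec2 <- protein_record("ctx2", "GGGGGKACGGGG")  # A at 7 with K at P2 (pos 6)
  lab2 <- attr(simulate_mechanistic(rec2, model), "site_labels")
  expect_equal(lab2$prob[lab2$position == 7], 1 / 3 * 2.0)
})

test_that("terminal-composition mode hits the preset distribution", {
  prot <- generate_proteome(100, 450, seed = 42)
  peps <- simulate_terminal_composition(prot, terminal_preset("pH1_5"), 5000,
                                        seed = 42)
  expect_equal(nrow(peps), 5000L)
  expect_false(any(duplicated(peps$sequence)))
  tf <- terminal_frequency(peps)
  # binomial 3-sigma around the preset probabilities
  expect_lt(abs(tf[["P"]] - 0.49), 3 * sqrt(0.49 * 0.51 / 5000))
  expect_lt(abs(tf[["A"]] - 0.34), 3 * sqrt(0.34 * 0.66 / 5000))

  # all-P preset: every peptide ends in proline
  pp <- simulate_terminal_composition(
    prot, list(name = "allP", cterm_dist = c(P = 1.0)), 200, seed = 1)
  expect_true(all(substring(pp$sequence, nchar(pp$sequence)) == "P"))

  # determinism
  again <- simulate_terminal_composition(prot, terminal_preset("pH1_5"), 5000,
                                         seed = 42)
  expect_identical(peps, again)

  # preset residue absent from the proteome
  polyG <- generate_proteome(2, 200, composition = c(G = 1.0), seed = 2)
  expect_error(simulate_terminal_composition(polyG, terminal_preset("pH1_5"),
                                             100, seed = 1), "absent")
})

test_that("terminal-composition KL divergence shrinks with n", {
  prot <- generate_proteome(150, 450, seed = 8)
  preset <- terminal_preset("pH1_5")
  peps <- simulate_terminal_composition(prot, preset, 50000, seed = 8)
  tf <- terminal_frequency(peps)
  q <- preset$cterm_dist[names(tf)]
  kl <- sum(tf * log(tf / q))
  expect_lt(kl, 0.01)
})

test_that("phosphosite simulation honours observability and distributions", {
  prot <- generate_proteome(1, 3000, seed = 21, length_sdlog = 0)
  full <- simulate_phosphosites(prot[[1]], n_true_sites = 100,
                                per_enzyme_observability = c(1, 1), seed = 5)
  expect_equal(full[[1]]$position, full[[2]]$position)
  expect_true(all(full[[1]]$residue %in% c("S", "T", "Y")))

  point <- simulate_phosphosites(
    prot[[1]], n_true_sites = 50,
    loc_prob_dists = list(a = function(n) rep(1, n),
                          b = function(n) rep(1, n)),
    per_enzyme_observability = c(1, 1), seed = 5)
  expect_equal(nrow(filter_class1(point$a)), 50L)

  # defaults separate the two enzymes' localization quality
  def <- simulate_phosphosites(prot[[1]], n_true_sites = 200, seed = 6)
  cmp <- compare_localization(def[[1]], def[[2]])
  expect_lt(cmp$p, 0.05)
  expect_gt(cmp$mean_a, cmp$mean_b)
})

test_that("disulfide digest simulation constructs exact masses and triads", {
  fx <- mab_fixture()
  obs <- simulate_disulfide_digest(fx$chains, fx$connectivity, "proalanase",
                                   ppm_noise = 0, seed = 9)
  truth <- attr(obs, "truth")
  expect_equal(nrow(truth), 3L)
  expect_setequal(truth$type, c("inter", "inter", "intra"))
  # exact -2H-per-bond bookkeeping at zero noise
  for (k in seq_len(nrow(truth))) {
    masses <- peptide_mass(truth$peptide_a[k])
    if (!is.na(truth$peptide_b[k])) {
      masses <- masses + peptide_mass(truth$peptide_b[k])
    }
    expect_equal(truth$mass[k], masses - truth$n_bonds[k] * DISULFIDE_DELTA,
                 tolerance = 1e-9)
  }
  # ISR triads: linked + both reduced forms for inter species
  for (sid in truth$species_id[truth$type == "inter"]) {
    expect_setequal(obs$form[obs$species_id == sid],
                    c("linked", "reduced_a", "reduced_b"))
  }
  # intra species has no reduced pair
  expect_equal(obs$form[obs$species_id == truth$species_id[truth$type == "intra"]],
               "linked")
  # reproducibility
  again <- simulate_disulfide_digest(fx$chains, fx$connectivity, "proalanase",
                                     ppm_noise = 0, seed = 9)
  expect_identical(obs, again)
  # noise actually perturbs
  noisy <- simulate_disulfide_digest(fx$chains, fx$connectivity, "proalanase",
                                     ppm_noise = 2, seed = 9)
  expect_false(all(noisy$neutral_mass == noisy$true_mass))
  expect_true(all(abs(noisy$neutral_mass / noisy$true_mass - 1) < 1e-5))
})

test_that("de novo read simulation covers and is reproducible", {
  prot <- generate_proteome(1, 400, seed = 31, length_sdlog = 0)
  enz <- list(proalanase = enzyme_preset("proalanase"),
              trypsin = enzyme_preset("trypsin_p"))
  reads <- simulate_denovo_reads(prot[[1]], enz, coverage_target = 0.95,
                                 error_rate = 0, seed = 31)
  # error-free reads are true substrings
  for (lab in names(reads)) {
    if (!nrow(reads[[lab]])) next
    expect_true(all(vapply(reads[[lab]]$sequence, grepl,
                           TRUE, x = prot[[1]]$sequence, fixed = TRUE)))
  }
  again <- simulate_denovo_reads(prot[[1]], enz, coverage_target = 0.95,
                                 error_rate = 0, seed = 31)
  expect_identical(reads, again)
  expect_true(all(unlist(lapply(reads, function(d) d$score)) <= 100))
})
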