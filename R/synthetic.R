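# Synthetic-data generators. Everything here is seeded and attaches a
# `params` attribute which write_peptide_table() serializes as a JSON sidecar.

#' Mechanistic per-site cleavage model
#'
#' Each candidate site (a residue with a nonzero base probability) fires
#' independently with probability `base_prob[residue]` times any applicable
#' context multipliers, clipped to `[0, 1]`. The defaults encode the
#' Pro/Ala-directed acid protease: cleavage probability 2/3 after proline
#' and 1/3 after alanine, so that in expectation twice as many prolines are
#' cleaved as missed and twice as many alanines are missed as cleaved.
#' The default context multipliers encode the observed basophilic (K/R/H)
#' context effects — suppression of proline cleavage with a basophile in
#' P2' and promotion of alanine cleavage with a basophile in P2; their
#' magnitudes (0.5 / 2.0) are model assumptions, only the direction is an
#' empirical observation.
#'
#' @param base_prob named per-residue cleavage probabilities.
#' @param context_multipliers list of rules; each rule is a list with
#'   `offset` (position relative to the scissile bond: `+k` means Pk',
#'   `-k` means Pk), `residues`, `multiplier` and `applies_to` (the site
#'   residue the rule modifies). `NULL` disables context effects.
#' @param detectable_len length window of peptides that survive
#'   LC-MS detection (default 7..35).
#' @param nonspecific_rate fraction of peptides allowed a nonenzymatic
#'   terminus (used by the terminal-composition simulator).
#' @param seed integer seed stored with the model.
#' @return object of class `CleavageModel`.
#' @export
cleavage_model <- function(base_prob = c(P = 2 / 3, A = 1 / 3),
                           context_multipliers = default_context_rules(),
                           detectable_len = c(7L, 35L),
                           nonspecific_rate = 0.2,
                           seed = NULL) {
  stopifnot(all(base_prob >= 0), all(base_prob <= 1), !is.null(names(base_prob)))
  stopifnot(length(detectable_len) == 2L, detectable_len[1] >= 1L,
            detectable_len[2] >= detectable_len[1], detectable_len[2] <= 100L)
  stopifnot(nonspecific_rate >= 0, nonspecific_rate <= 1)
  if (!is.null(context_multipliers)) {
    for (r in context_multipliers) {
      stopifnot(is.numeric(r$offset), r$offset != 0,
                is.character(r$residues), r$multiplier >= 0,
                r$applies_to %in% names(base_prob))
    }
  }
  structure(
    list(base_prob = base_prob, context_multipliers = context_multipliers,
         detectable_len = as.integer(detectable_len),
         nonspecific_rate = nonspecific_rate, seed = seed),
    class = "CleavageModel"
  )
}

#' @rdname cleavage_model
#' @export
default_context_rules <- function() {
  list(
    list(offset = +2L, residues = BASOPHILIC, multiplier = 0.5, applies_to = "P"),
    list(offset = -2L, residues = BASOPHILIC, multiplier = 2.0, applies_to = "A")
  )
}

# P-position offset -> sequence index relative to site residue i.
# offset +k is Pk' (index i + k); offset -k is Pk (index i - k + 1).
ctx_index <- function(i, offset) {
  if (offset > 0) i + offset else i + offset + 1L
}

#' Terminal-composition presets
#'
#' C-terminal residue distributions of identified peptides under the two
#' characterized digestion pH regimes. At pH 1.5 the enzyme's specificity is
#' highest (49% of peptide C-termini are proline and 34% alanine); at pH 2.5
#' it degrades to 35% / 30%. The remaining probability is spread over the
#' other residues proportionally to a background composition.
#'
#' @param name `"pH1_5"` or `"pH2_5"`.
#' @param background residue frequencies used to apportion the non-P/A mass.
#' @return list with `name` and `cterm_dist` (probabilities summing to 1).
#' @export
terminal_preset <- function(name = c("pH1_5", "pH2_5"),
                            background = AA_BACKGROUND) {
  name <- match.arg(name)
  pa <- switch(name, pH1_5 = c(P = 0.49, A = 0.34), pH2_5 = c(P = 0.35, A = 0.30))
  rest <- background[setdiff(names(background), c("P", "A"))]
  rest <- rest / sum(rest) * (1 - sum(pa))
  dist <- c(pa, rest)
  stopifnot(abs(sum(dist) - 1) < 1e-9)
  list(name = name, cterm_dist = dist)
}

#' Generate a synthetic proteome
#'
#' Reproducible random proteome with i.i.d. residues drawn from a
#' composition. Protein lengths are log-normal around `mean_length`
#' (CV about 0.37, roughly the spread of real proteome length
#' distributions), with a floor of 30 residues. IDs are `SYN0001`, ...
#'
#' @param n_proteins number of proteins (>= 1).
#' @param mean_length mean protein length in residues.
#' @param composition residue frequency map summing to 1.
#' @param seed integer seed.
#' @param length_sdlog sdlog of the log-normal length distribution; 0 gives
#'   fixed-length proteins.
#' @return proteome (list of `ProteinRecord`).
#' @export
generate_proteome <- function(n_proteins, mean_length = 450,
                              composition = AA_BACKGROUND, seed = NULL,
                              length_sdlog = 0.35) {
  stopifnot(n_proteins >= 1, mean_length >= 1)
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("generate_proteome: composition must sum to 1")
  }
  bad <- setdiff(names(composition), names(AA_MONO))
  if (length(bad)) stop("generate_proteome: unknown residues: ",
                        paste(bad, collapse = ","))
  if (!is.null(seed)) set.seed(seed)
  if (length_sdlog > 0) {
    meanlog <- log(mean_length) - length_sdlog^2 / 2
    lens <- pmax(30L, as.integer(round(stats::rlnorm(n_proteins, meanlog,
                                                     length_sdlog))))
  } else {
    lens <- rep.int(as.integer(mean_length), n_proteins)
  }
  res <- names(composition)
  recs <- lapply(seq_len(n_proteins), function(i) {
    s <- paste(sample(res, lens[i], replace = TRUE, prob = composition),
               collapse = "")
    protein_record(sprintf("SYN%04d", i), s)
  })
  out <- structure(recs, class = "proteome")
  attr(out, "params") <- list(generator = "generate_proteome",
                              n_proteins = n_proteins,
                              mean_length = mean_length, seed = seed)
  out
}

#' Mechanistic digestion simulation
#'
#' Fires every candidate site independently according to a
#' [cleavage_model()], keeps the fragments inside the detectable length
#' window as the "identified" peptides, and retains the full ground-truth
#' per-site labels (cleaved / missed) as the `site_labels` attribute. With
#' all base probabilities at 1 and no context rules this reduces exactly to
#' the deterministic zero-missed-cleavage digest.
#'
#' @param proteins proteome.
#' @param model `CleavageModel`.
#' @param seed seed; defaults to the model's stored seed.
#' @return data.frame of identified peptides (`protein_id`, `start`, `end`,
#'   `sequence`, `missed_cleavages`) with attributes `site_labels`
#'   (data.frame: `protein_id`, `position`, `residue`, `prob`, `cleaved`)
#'   and `params`.
#' @export
simulate_mechanistic <- function(proteins, model, seed = model$seed) {
  proteins <- as_proteome(proteins)
  stopifnot(inherits(model, "CleavageModel"))
  if (!is.null(seed)) set.seed(seed)
  site_res <- names(model$base_prob)[model$base_prob > 0]
  pep_list <- list(); lab_list <- list()
  dl <- model$detectable_len
  for (rec in proteins) {
    chars <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
    n <- length(chars)
    cand <- which(chars %in% site_res)
    cand <- cand[cand < n]  # no bond after the last residue
    if (!length(cand)) {
      if (n >= dl[1] && n <= dl[2]) {
        pep_list[[length(pep_list) + 1L]] <- data.frame(
          protein_id = rec$id, start = 1L, end = n, sequence = rec$sequence,
          missed_cleavages = 0L, stringsAsFactors = FALSE)
      }
      next
    }
    p <- unname(model$base_prob[chars[cand]])
    if (!is.null(model$context_multipliers)) {
      for (rule in model$context_multipliers) {
        sel <- chars[cand] == rule$applies_to
        if (!any(sel)) next
        ci <- ctx_index(cand[sel], rule$offset)
        ok <- ci >= 1L & ci <= n
        hit <- logical(sum(sel))
        hit[ok] <- chars[ci[ok]] %in% rule$residues
        p[sel][hit] <- p[sel][hit] * rule$multiplier
      }
    }
    p <- pmin(p, 1)
    fired <- stats::runif(length(cand)) < p
    lab_list[[length(lab_list) + 1L]] <- data.frame(
      protein_id = rec$id, position = cand, residue = chars[cand],
      prob = p, cleaved = fired, stringsAsFactors = FALSE)
    cuts <- cand[fired]
    b <- c(0L, cuts, n)
    starts <- b[-length(b)] + 1L
    ends <- b[-1]
    len <- ends - starts + 1L
    keep <- len >= dl[1] & len <= dl[2]
    if (any(keep)) {
      # internal candidate sites that did not fire
      mc <- vapply(which(keep), function(k) {
        idx <- cand >= starts[k] & cand <= ends[k] - 1L
        sum(idx & !fired)
      }, 1L)
      pep_list[[length(pep_list) + 1L]] <- data.frame(
        protein_id = rec$id, start = starts[keep], end = ends[keep],
        sequence = substring(rec$sequence, starts[keep], ends[keep]),
        missed_cleavages = mc, stringsAsFactors = FALSE)
    }
  }
  peptides <- if (length(pep_list)) do.call(rbind, pep_list) else
    data.frame(protein_id = character(0), start = integer(0), end = integer(0),
               sequence = character(0), missed_cleavages = integer(0))
  rownames(peptides) <- NULL
  attr(peptides, "site_labels") <- if (length(lab_list))
    do.call(rbind, lab_list) else NULL
  attr(peptides, "params") <- list(
    generator = "simulate_mechanistic", base_prob = as.list(model$base_prob),
    context = !is.null(model$context_multipliers),
    detectable_len = model$detectable_len, seed = seed)
  peptides
}

#' Terminal-composition simulation
#'
#' Samples identified peptides as proteome substrings whose C-terminal
#' residue is drawn from a [terminal_preset()] distribution, so the expected
#' C-terminal residue composition of the output equals the preset exactly.
#' This makes the printed specificity percentages directly controllable —
#' they are emergent observables in the mechanistic mode. Peptides are
#' unique sequences (the statistic is computed on unique peptides); lengths
#' are uniform within the detectable window, truncated at protein starts.
#' A fraction `1 - nonspecific_rate` of peptides get their N-terminus
#' snapped to the nearest enzymatic position (after P/A) when one exists in
#' range, mimicking fully specific peptides.
#'
#' @param proteins proteome.
#' @param preset a [terminal_preset()] result or preset name.
#' @param n_peptides number of unique peptides to emit (>= 100).
#' @param nonspecific_rate fraction with a free (nonenzymatic) N-terminus.
#' @param detectable_len length window, default 7..35.
#' @param seed integer seed.
#' @return data.frame (`sequence`, `protein_id`, `start`, `end`, `label`)
#'   with a `params` attribute.
#' @export
simulate_terminal_composition <- function(proteins, preset, n_peptides,
                                          nonspecific_rate = 0.2,
                                          detectable_len = c(7L, 35L),
                                          seed = NULL) {
  proteins <- as_proteome(proteins)
  if (is.character(preset)) preset <- terminal_preset(preset)
  stopifnot(n_peptides >= 100)
  if (!is.null(seed)) set.seed(seed)
  dist <- preset$cterm_dist[preset$cterm_dist > 0]
  seqs <- vapply(proteins, function(r) r$sequence, "")
  ids <- vapply(proteins, function(r) r$id, "")
  lens <- nchar(seqs)
  # per-residue occurrence index: (protein index, position)
  occ <- lapply(stats::setNames(names(dist), names(dist)), function(r) {
    hits <- lapply(seq_along(seqs), function(i) {
      pos <- gregexpr(r, seqs[i], fixed = TRUE)[[1]]
      if (pos[1] == -1L) return(NULL)
      cbind(i, pos)
    })
    do.call(rbind, hits)
  })
  missing <- names(dist)[vapply(occ, is.null, TRUE)]
  if (length(missing)) {
    stop("simulate_terminal_composition: preset residue(s) absent from the ",
         "proteome: ", paste(missing, collapse = ","))
  }
  minl <- detectable_len[1]; maxl <- detectable_len[2]
  # Stratified sampling: fix the C-terminal residue counts by a single
  # multinomial draw from the preset, then collect that many *unique*
  # peptides per residue class. Deduplicating after pooled sampling would
  # bias the composition away from high-probability residues (their
  # endpoints collide more often); stratification keeps the empirical
  # distribution an unbiased multinomial around the preset.
  n_per_res <- stats::rmultinom(1L, n_peptides, dist)[, 1]
  acc <- list()
  for (r in names(dist)) {
    need <- n_per_res[r]
    if (need == 0L) next
    seen <- character(0)
    part <- list()
    rounds <- 0L
    while (length(seen) < need && rounds < 200L) {
      rounds <- rounds + 1L
      m <- ceiling((need - length(seen)) * 1.5) + 20L
      pick <- occ[[r]][sample.int(nrow(occ[[r]]), m, replace = TRUE), ,
                       drop = FALSE]
      prot <- pick[, 1]; endpos <- pick[, 2]
      len <- sample(minl:maxl, m, replace = TRUE)
      start <- pmax(1L, endpos - len + 1L)
      specific <- stats::runif(m) >= nonspecific_rate
      for (k in which(specific)) {
        s <- snap_specific_start(seqs[prot[k]], endpos[k], minl, maxl)
        if (!is.na(s)) start[k] <- s
      }
      keep <- (endpos - start + 1L) >= minl
      if (!any(keep)) next
      sq <- substring(seqs[prot[keep]], start[keep], endpos[keep])
      new <- !sq %in% seen & !duplicated(sq)
      if (any(new)) {
        part[[length(part) + 1L]] <- data.frame(
          sequence = sq[new],
          protein_id = ids[prot[keep]][new],
          start = start[keep][new], end = endpos[keep][new],
          stringsAsFactors = FALSE)
        seen <- c(seen, sq[new])
      }
    }
    if (length(seen) < need) {
      stop("simulate_terminal_composition: could not assemble ", need,
           " unique peptides ending in ", r, "; enlarge the proteome")
    }
    part <- do.call(rbind, part)
    acc[[r]] <- part[seq_len(need), , drop = FALSE]
  }
  out <- do.call(rbind, acc)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out$label <- preset$name
  attr(out, "params") <- list(generator = "simulate_terminal_composition",
                              preset = preset$name, n_peptides = n_peptides,
                              nonspecific_rate = nonspecific_rate,
                              detectable_len = detectable_len, seed = seed)
  out
}

# Find a start position in [end-maxl+1, end-minl+1] whose preceding residue
# is P or A (or the protein start); NA when none exists.
snap_specific_start <- function(seq, end, minl, maxl) {
  lo <- max(1L, end - maxl + 1L)
  hi <- end - minl + 1L
  if (hi < lo) return(NA_integer_)
  cand <- lo:hi
  prev <- substring(seq, cand - 1L, cand - 1L)
  ok <- cand == 1L | prev %in% c("P", "A")
  if (!any(ok)) return(NA_integer_)
  cand <- cand[ok]
  cand[sample.int(length(cand), 1L)]
}

#' Phosphosite table simulation
#'
#' Plants `n_true_sites` phosphosites on S/T/Y positions of a record, then
#' lets each of two enzymes observe every site with its observability
#' probability and draw a localization probability from its distribution.
#' The defaults — Beta(8, 2) (mean 0.8) for the acid protease and Beta(4, 2)
#' (mean 2/3) for trypsin, observabilities 0.8 and 0.5 — encode the observed
#' pattern of about twice as many well-localized (class I) sites and a
#' significantly higher mean localization probability for the acid protease.
#'
#' @param record `ProteinRecord` with enough S/T/Y positions.
#' @param n_true_sites number of true phosphosites.
#' @param loc_prob_dists named list of two functions `n -> [0,1]` draws.
#' @param per_enzyme_observability numeric length 2 in the same order.
#' @param seed integer seed.
#' @return named list of two site tables (`protein_id`, `position`,
#'   `residue`, `localization_probability`, `enzyme`), with the planted
#'   truth in `attr(, "truth")`.
#' @export
simulate_phosphosites <- function(record, n_true_sites = 50,
                                  loc_prob_dists = list(
                                    proalanase = function(n) stats::rbeta(n, 8, 2),
                                    trypsin = function(n) stats::rbeta(n, 4, 2)),
                                  per_enzyme_observability = c(0.8, 0.5),
                                  seed = NULL) {
  record <- as_record(record)
  stopifnot(length(loc_prob_dists) == 2L,
            length(per_enzyme_observability) == 2L,
            all(per_enzyme_observability >= 0),
            all(per_enzyme_observability <= 1))
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  sty <- which(chars %in% c("S", "T", "Y"))
  if (length(sty) < n_true_sites) {
    stop("simulate_phosphosites: record has only ", length(sty),
         " S/T/Y positions (need ", n_true_sites, ")")
  }
  truth <- sort(sample(sty, n_true_sites))
  labels <- names(loc_prob_dists)
  out <- stats::setNames(vector("list", 2L), labels)
  for (j in 1:2) {
    obs <- truth[stats::runif(n_true_sites) < per_enzyme_observability[j]]
    out[[j]] <- data.frame(
      protein_id = record$id, position = obs, residue = chars[obs],
      localization_probability = loc_prob_dists[[j]](length(obs)),
      enzyme = labels[j], stringsAsFactors = FALSE)
  }
  attr(out, "truth") <- data.frame(protein_id = record$id, position = truth,
                                   residue = chars[truth])
  attr(out, "params") <- list(generator = "simulate_phosphosites",
                              n_true_sites = n_true_sites,
                              observability = per_enzyme_observability,
                              seed = seed)
  out
}

#' Nonreduced disulfide digest simulation
#'
#' Digests disulfide-linked chains (deterministic, fully cleaved), joins the
#' cysteine-containing peptides according to the supplied connectivity, and
#' emits the observed precursor list: one linked species per connected
#' peptide pair (or loop), mass `sum(peptides) - 2.015650 x n_bonds`, plus —
#' when `include_reduced_forms` — the two constituent reduced peptide masses,
#' the in-source-reduction (ISR) triad. Masses are perturbed with Gaussian
#' ppm noise and reported as m/z at a plausible charge.
#'
#' @param chains proteome (e.g. the two chains of an antibody).
#' @param connectivity data.frame with columns `chain_a`, `pos_a`,
#'   `chain_b`, `pos_b` (1-based cysteine positions; `chain_a == chain_b`
#'   gives an intra-chain bond).
#' @param enzyme `EnzymeSpec` or preset name.
#' @param ppm_noise standard deviation of the mass noise in ppm.
#' @param include_reduced_forms emit ISR triads.
#' @param seed integer seed.
#' @return data.frame of observations (`species_id`, `form`, `mz`, `z`,
#'   `neutral_mass`) with ground truth in `attr(, "truth")`.
#' @export
simulate_disulfide_digest <- function(chains, connectivity, enzyme,
                                      ppm_noise = 0,
                                      include_reduced_forms = TRUE,
                                      seed = NULL) {
  chains <- as_proteome(chains)
  enzyme <- as_enzyme(enzyme)
  stopifnot(is.data.frame(connectivity),
            all(c("chain_a", "pos_a", "chain_b", "pos_b") %in%
                  names(connectivity)))
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(chains, function(r) r$id, "")
  names(chains) <- ids
  # validate cysteines
  for (k in seq_len(nrow(connectivity))) {
    for (side in c("a", "b")) {
      ch <- connectivity[[paste0("chain_", side)]][k]
      po <- connectivity[[paste0("pos_", side)]][k]
      if (!ch %in% ids) stop("connectivity names unknown chain '", ch, "'")
      if (substring(chains[[ch]]$sequence, po, po) != "C") {
        stop("connectivity: position ", po, " of chain '", ch, "' is not Cys")
      }
    }
  }
  digests <- lapply(chains, digest, enzyme = enzyme, max_missed = 0L,
                    min_len = 1L, max_len = 100000L)
  locate <- function(ch, pos) {
    d <- digests[[ch]]
    w <- which(d$start <= pos & d$end >= pos)
    stopifnot(length(w) == 1L)
    w
  }
  pep_key <- function(ch, idx) paste0(ch, "#", idx)
  bonds <- data.frame(
    key_a = character(nrow(connectivity)), key_b = character(nrow(connectivity)),
    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(connectivity))) {
    bonds$key_a[k] <- pep_key(connectivity$chain_a[k],
                              locate(connectivity$chain_a[k], connectivity$pos_a[k]))
    bonds$key_b[k] <- pep_key(connectivity$chain_b[k],
                              locate(connectivity$chain_b[k], connectivity$pos_b[k]))
  }
  # connected components over peptides
  keys <- unique(c(bonds$key_a, bonds$key_b))
  comp <- stats::setNames(seq_along(keys), keys)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(bonds))) {
      a <- comp[bonds$key_a[k]]; b <- comp[bonds$key_b[k]]
      if (a != b) { comp[comp == b] <- a; changed <- TRUE }
    }
    if (!changed) break
  }
  pep_info <- function(key) {
    parts <- strsplit(key, "#", fixed = TRUE)[[1]]
    d <- digests[[parts[1]]][as.integer(parts[2]), ]
    list(chain = parts[1], start = d$start, end = d$end,
         sequence = d$sequence, mass = peptide_mass(d$sequence))
  }
  obs <- list(); truth <- list()
  for (cid in unique(comp)) {
    members <- names(comp)[comp == cid]
    if (length(members) > 2L) {
      stop("simulate_disulfide_digest: a species would join ", length(members),
           " peptides; restrict the connectivity or enzyme settings")
    }
    in_species <- bonds$key_a %in% members & bonds$key_b %in% members
    n_bonds <- sum(in_species)
    infos <- lapply(members, pep_info)
    mass <- sum(vapply(infos, function(x) x$mass, 0)) -
      n_bonds * DISULFIDE_DELTA
    sid <- sprintf("SP%02d", length(truth) + 1L)
    truth[[length(truth) + 1L]] <- data.frame(
      species_id = sid,
      type = if (length(members) == 2L) "inter" else "intra",
      n_bonds = n_bonds,
      peptide_a = infos[[1]]$sequence,
      chain_a = infos[[1]]$chain, start_a = infos[[1]]$start,
      peptide_b = if (length(members) == 2L) infos[[2]]$sequence else NA,
      chain_b = if (length(members) == 2L) infos[[2]]$chain else NA,
      start_b = if (length(members) == 2L) infos[[2]]$start else NA,
      mass = mass, stringsAsFactors = FALSE)
    forms <- data.frame(species_id = sid, form = "linked", true_mass = mass,
                        stringsAsFactors = FALSE)
    if (include_reduced_forms && length(members) == 2L) {
      forms <- rbind(forms,
        data.frame(species_id = sid, form = c("reduced_a", "reduced_b"),
                   true_mass = c(infos[[1]]$mass, infos[[2]]$mass)))
    }
    obs[[length(obs) + 1L]] <- forms
  }
  obs <- do.call(rbind, obs)
  noise <- stats::rnorm(nrow(obs), 0, ppm_noise) * 1e-6
  obs$neutral_mass <- obs$true_mass * (1 + noise)
  obs$z <- pmax(1L, as.integer(ceiling(obs$neutral_mass / 1200)))
  obs$mz <- (obs$neutral_mass + obs$z * PROTON_MASS) / obs$z
  truth <- do.call(rbind, truth)
  rownames(obs) <- rownames(truth) <- NULL
  attr(obs, "truth") <- truth
  attr(obs, "params") <- list(generator = "simulate_disulfide_digest",
                              enzyme = enzyme$name, ppm_noise = ppm_noise,
                              include_reduced_forms = include_reduced_forms,
                              seed = seed)
  obs
}

#' De novo read simulation
#'
#' Draws peptides from the in-silico digest of a record with each enzyme
#' until the sampled spans reach `coverage_target` of the record (or a draw
#' cap), introduces residue substitution errors at `error_rate`, and scores
#' each read. The ground-truth spans survive in `attr(, "truth")`, so a
#' perfect aligner on error-free reads must reproduce the generator's
#' coverage exactly.
#'
#' @param record `ProteinRecord`.
#' @param enzymes named list of `EnzymeSpec` (or preset names).
#' @param coverage_target fraction of the record to cover per enzyme.
#' @param score_dist function `n -> scores in [0,100]`.
#' @param error_rate per-residue substitution probability.
#' @param seed integer seed.
#' @return named list of per-enzyme data.frames (`sequence`, `score`,
#'   `enzyme`), each with a `truth` attribute of the true spans.
#' @export
simulate_denovo_reads <- function(record, enzymes, coverage_target = 0.9,
                                  score_dist = function(n) stats::runif(n, 50, 100),
                                  error_rate = 0.02, seed = NULL) {
  record <- as_record(record)
  stopifnot(coverage_target > 0, coverage_target <= 1,
            error_rate >= 0, error_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(record$sequence)
  out <- list()
  for (lab in names(enzymes)) {
    enz <- as_enzyme(enzymes[[lab]])
    cand <- digest(record, enz, min_len = max(6L, enz$min_len),
                   max_len = min(40L, enz$max_len))
    if (!nrow(cand)) {
      out[[lab]] <- data.frame(sequence = character(0), score = numeric(0),
                               enzyme = character(0))
      next
    }
    covered <- logical(n)
    picked <- integer(0)
    draws <- 0L; cap <- 50L * nrow(cand) + 200L
    # which positions are coverable at all with this enzyme's candidates
    coverable <- logical(n)
    for (i in seq_len(nrow(cand))) coverable[cand$start[i]:cand$end[i]] <- TRUE
    target_abs <- coverage_target * sum(coverable)
    while (sum(covered) < target_abs && draws < cap) {
      draws <- draws + 1L
      i <- sample.int(nrow(cand), 1L)
      picked <- c(picked, i)
      covered[cand$start[i]:cand$end[i]] <- TRUE
    }
    picked <- sort(unique(picked))
    reads <- cand[picked, , drop = FALSE]
    seqs <- reads$sequence
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- stats::runif(length(ch)) < error_rate
        if (any(hit)) {
          ch[hit] <- vapply(ch[hit], function(orig) {
            sample(setdiff(names(AA_MONO), orig), 1L)
          }, "")
        }
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    df <- data.frame(sequence = seqs, score = score_dist(length(seqs)),
                     enzyme = lab, stringsAsFactors = FALSE)
    attr(df, "truth") <- data.frame(start = reads$start, end = reads$end,
                                    true_sequence = reads$sequence)
    out[[lab]] <- df
  }
  attr(out, "params") <- list(generator = "simulate_denovo_reads",
                              coverage_target = coverage_target,
                              error_rate = error_rate, seed = seed)
  out
}
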