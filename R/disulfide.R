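# Low-pH disulfide mapping: cysteine-peptide inventories from nonreduced
# digests, linked-species mass enumeration (-2H per bond), ppm matching of
# observed precursors, in-source-reduction (ISR) triad validation, and
# scrambling detection against an expected connectivity.

#' Neutral mass from m/z and charge
#'
#' `neutral = m/z * z - z * proton`, the standard positive-mode conversion.
#'
#' @param mz observed m/z.
#' @param z charge (>= 1).
#' @export
neutral_mass <- function(mz, z) {
  stopifnot(all(mz > 0), all(z >= 1))
  mz * z - z * PROTON_MASS
}

#' Enumerate cysteine-containing peptides
#'
#' Digests records (fully specific; optionally adding semi-specific
#' peptides, as in permissive second-pass searches of acid digests) and
#' keeps peptides containing at least one cysteine. Masses are unalkylated:
#' nonreduced digestion means no carbamidomethyl fixed modification.
#'
#' @param records proteome.
#' @param enzyme `EnzymeSpec` or preset name.
#' @param semi_specific also include semi-specific peptides.
#' @param max_nonspecific_extension extension bound for the semi-specific
#'   enumeration (default 3).
#' @return data.frame: `protein_id`, `start`, `end`, `sequence`, `n_cys`,
#'   `mass`.
#' @export
enumerate_cys_peptides <- function(records, enzyme, semi_specific = FALSE,
                                   max_nonspecific_extension = 3L) {
  records <- as_proteome(records)
  enzyme <- as_enzyme(enzyme)
  parts <- lapply(records, function(rec) {
    d <- digest(rec, enzyme)
    if (semi_specific) {
      d <- rbind(d, semi_specific_peptides(rec, enzyme,
                                           max_nonspecific_extension))
    }
    d
  })
  d <- do.call(rbind, parts)
  n_cys <- vapply(gregexpr("C", d$sequence, fixed = TRUE),
                  function(m) if (m[1] == -1L) 0L else length(m), 1L)
  d <- d[n_cys > 0L, c("protein_id", "start", "end", "sequence")]
  if (!nrow(d)) {
    d$n_cys <- integer(0); d$mass <- numeric(0)
    rownames(d) <- NULL
    return(d)
  }
  d <- d[!duplicated(d[c("protein_id", "start", "end")]), , drop = FALSE]
  d$n_cys <- vapply(gregexpr("C", d$sequence, fixed = TRUE), length, 1L)
  d$mass <- vapply(d$sequence, peptide_mass, 0, USE.NAMES = FALSE)
  rownames(d) <- NULL
  d
}

#' Enumerate disulfide-linked species
#'
#' All candidate species over a cysteine-peptide inventory: single peptides
#' with 1..`max_bonds` intra-peptide bonds (needs 2 cysteines per bond) and
#' all unordered peptide pairs — including a peptide paired with a second
#' copy of itself — with 1..`max_bonds` inter-peptide bonds (bounded by the
#' smaller cysteine count). Species mass is the constituent sum minus
#' 2.015650 Da per bond. The pair count `n(n+1)/2` is capped to guard
#' against combinatorial blow-up.
#'
#' @param cys_peptides data.frame from [enumerate_cys_peptides()].
#' @param max_bonds maximum bonds per species (default 2).
#' @param allow_intra enumerate intra-peptide species (default TRUE).
#' @param pair_cap maximum candidate pair count (default 1e6).
#' @return data.frame: `species_id`, `type`, `idx_a`, `idx_b`, `peptide_a`,
#'   `peptide_b`, `n_bonds`, `mass`.
#' @export
enumerate_linked_species <- function(cys_peptides, max_bonds = 2L,
                                     allow_intra = TRUE, pair_cap = 1e6) {
  stopifnot(all(c("sequence", "n_cys", "mass") %in% names(cys_peptides)))
  np <- nrow(cys_peptides)
  if (np * (np + 1) / 2 > pair_cap) {
    stop("enumerate_linked_species: ", np * (np + 1) / 2, " candidate pairs ",
         "exceed the cap (", format(pair_cap, scientific = FALSE), "); ",
         "tighten the enzyme settings or raise pair_cap")
  }
  out <- list()
  add <- function(type, ia, ib, nb, mass) {
    out[[length(out) + 1L]] <<- data.frame(
      type = type, idx_a = ia, idx_b = ib,
      peptide_a = cys_peptides$sequence[ia],
      peptide_b = if (is.na(ib)) NA_character_ else cys_peptides$sequence[ib],
      n_bonds = nb, mass = mass, stringsAsFactors = FALSE)
  }
  if (allow_intra) {
    for (i in seq_len(np)) {
      top <- min(max_bonds, cys_peptides$n_cys[i] %/% 2L)
      for (nb in seq_len(max(top, 0L))) {
        add("intra", i, NA_integer_, nb,
            cys_peptides$mass[i] - nb * DISULFIDE_DELTA)
      }
    }
  }
  for (i in seq_len(np)) {
    for (j in i:np) {
      top <- min(max_bonds, cys_peptides$n_cys[i], cys_peptides$n_cys[j])
      for (nb in seq_len(max(top, 0L))) {
        add("inter", i, j, nb,
            cys_peptides$mass[i] + cys_peptides$mass[j] - nb * DISULFIDE_DELTA)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(species_id = character(0), type = character(0),
                      idx_a = integer(0), idx_b = integer(0),
                      peptide_a = character(0), peptide_b = character(0),
                      n_bonds = integer(0), mass = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- cbind(species_id = sprintf("LS%05d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Match observed precursors to candidate species
#'
#' Converts observations to neutral mass and reports every species within
#' the ppm tolerance, sorted by absolute ppm error within each observation
#' (rank 1 is the closest). Observations with no candidate inside the
#' tolerance are listed in `attr(, "unmatched")`.
#'
#' @param observations data.frame with either `mz` + `z` columns or a
#'   `neutral_mass` column.
#' @param species data.frame from [enumerate_linked_species()] (needs
#'   `species_id`, `mass`).
#' @param ppm_tol tolerance in ppm (default 5; precursor-level matching is
#'   much tighter than fragment tolerances).
#' @return data.frame: `obs_id`, `neutral_mass`, `species_id`, `ppm`,
#'   `rank`.
#' @export
match_precursors <- function(observations, species, ppm_tol = 5) {
  stopifnot(all(c("species_id", "mass") %in% names(species)))
  nm <- if ("neutral_mass" %in% names(observations)) {
    observations$neutral_mass
  } else {
    stopifnot(all(c("mz", "z") %in% names(observations)))
    neutral_mass(observations$mz, observations$z)
  }
  obs_id <- if ("obs_id" %in% names(observations)) observations$obs_id else
    sprintf("OBS%04d", seq_along(nm))
  out <- list(); unmatched <- character(0)
  for (i in seq_along(nm)) {
    ppm <- (nm[i] - species$mass) / species$mass * 1e6
    hit <- which(abs(ppm) <= ppm_tol)
    if (!length(hit)) { unmatched <- c(unmatched, obs_id[i]); next }
    hit <- hit[order(abs(ppm[hit]))]
    out[[length(out) + 1L]] <- data.frame(
      obs_id = obs_id[i], neutral_mass = nm[i],
      species_id = species$species_id[hit], ppm = ppm[hit],
      rank = seq_along(hit), stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(obs_id = character(0), neutral_mass = numeric(0),
               species_id = character(0), ppm = numeric(0), rank = integer(0))
  rownames(res) <- NULL
  attr(res, "unmatched") <- unmatched
  res
}

#' Validate an in-source-reduction triad
#'
#' ISR partially reduces disulfide bonds in the source, so a linked species
#' co-occurs with its two constituent reduced peptides in the same MS1 scan.
#' The triad is consistent iff
#' `linked = reduced_a + reduced_b - n_bonds x 2.015650` within a ppm
#' tolerance of the linked mass.
#'
#' @param linked_mass,reduced_a,reduced_b neutral masses (Da).
#' @param n_bonds number of disulfide bonds joining the constituents.
#' @param tol_ppm tolerance in ppm (default 5).
#' @return logical.
#' @export
isr_triad_check <- function(linked_mass, reduced_a, reduced_b, n_bonds = 1L,
                            tol_ppm = 5) {
  expected <- reduced_a + reduced_b - n_bonds * DISULFIDE_DELTA
  abs(linked_mass - expected) <= abs(tol_ppm) * 1e-6 * linked_mass
}

#' Flag disulfide scrambling
#'
#' Compares matched species against an expected cysteine connectivity map
#' and flags species whose implied pairing cannot be realized natively: a
#' species needs at least `n_bonds` expected bonds with both cysteines
#' inside its own cysteine inventory, otherwise it can only arise from
#' scrambled (non-native) pairings.
#'
#' @param matches data.frame from [match_precursors()].
#' @param species species table carrying cysteine annotations — either from
#'   a digest-aware pipeline (columns `chain_a`, `start_a`, `peptide_a`,
#'   optionally `_b`) or built with [annotate_species_cys()].
#' @param expected_connectivity data.frame (`chain_a`, `pos_a`, `chain_b`,
#'   `pos_b`) of native bonds.
#' @return data.frame of matched species with a logical `scrambled` column.
#' @export
scrambling_flags <- function(matches, species, expected_connectivity) {
  stopifnot(all(c("species_id", "n_bonds") %in% names(species)))
  need <- c("chain_a", "start_a", "peptide_a")
  if (!all(need %in% names(species))) {
    stop("scrambling_flags: species table lacks cysteine annotations (",
         paste(setdiff(need, names(species)), collapse = ","), ")")
  }
  exp_keys <- bond_keys(expected_connectivity)
  ids <- unique(matches$species_id)
  rows <- species[match(ids, species$species_id), , drop = FALSE]
  rows$scrambled <- vapply(seq_len(nrow(rows)), function(i) {
    cys <- species_cys_set(rows[i, ])
    native <- sum(vapply(seq_len(nrow(expected_connectivity)), function(k) {
      a <- paste0(expected_connectivity$chain_a[k], ":",
                  expected_connectivity$pos_a[k])
      b <- paste0(expected_connectivity$chain_b[k], ":",
                  expected_connectivity$pos_b[k])
      a %in% cys && b %in% cys
    }, TRUE))
    native < rows$n_bonds[i]
  }, TRUE)
  rownames(rows) <- NULL
  rows
}

# Absolute cysteine coordinates ("chain:pos") of a species row.
species_cys_set <- function(row) {
  cys_of <- function(chain, start, pep) {
    if (is.na(pep)) return(character(0))
    rel <- gregexpr("C", pep, fixed = TRUE)[[1]]
    if (rel[1] == -1L) return(character(0))
    paste0(chain, ":", start + rel - 1L)
  }
  c(cys_of(row$chain_a, row$start_a, row$peptide_a),
    if ("peptide_b" %in% names(row)) {
      cys_of(row$chain_b, row$start_b, row$peptide_b)
    } else character(0))
}

# Canonical unordered keys for a connectivity table.
bond_keys <- function(connectivity) {
  vapply(seq_len(nrow(connectivity)), function(k) {
    a <- paste0(connectivity$chain_a[k], ":", connectivity$pos_a[k])
    b <- paste0(connectivity$chain_b[k], ":", connectivity$pos_b[k])
    paste(sort(c(a, b)), collapse = "--")
  }, "")
}

#' Annotate enumerated species with chain coordinates
#'
#' Joins an [enumerate_linked_species()] table back to its cysteine-peptide
#' inventory so the species rows carry the chain ids and start coordinates
#' that [scrambling_flags()] needs.
#'
#' @param species species table with `idx_a`, `idx_b`.
#' @param cys_peptides the inventory the species were enumerated from.
#' @return species table with `chain_a`, `start_a`, `chain_b`, `start_b`.
#' @export
annotate_species_cys <- function(species, cys_peptides) {
  species$chain_a <- cys_peptides$protein_id[species$idx_a]
  species$start_a <- cys_peptides$start[species$idx_a]
  species$chain_b <- cys_peptides$protein_id[species$idx_b]
  species$start_b <- cys_peptides$start[species$idx_b]
  species
}
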