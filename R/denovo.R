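# Database-independent assembly: score filtering, combinatorial merging of
# per-enzyme de novo peptide sets, and alignment to a reference sequence.

#' Filter and deduplicate de novo peptides
#'
#' Keeps peptides with `score >= min_score` (inclusive) and removes
#' duplicate sequences, retaining the highest-scoring entry.
#'
#' @param peptides data.frame with `sequence` and `score` (0..100) columns.
#' @param min_score score threshold, default 90.
#' @return filtered data.frame.
#' @export
filter_denovo <- function(peptides, min_score = 90) {
  stopifnot(all(c("sequence", "score") %in% names(peptides)))
  kept <- peptides[peptides$score >= min_score, , drop = FALSE]
  if (!nrow(kept)) return(kept)
  kept <- kept[order(kept$sequence, -kept$score), , drop = FALSE]
  kept <- kept[!duplicated(kept$sequence), , drop = FALSE]
  kept[order(-kept$score, kept$sequence), , drop = FALSE]
}

#' Merge per-enzyme de novo sets
#'
#' Union (with sequence-level deduplication keeping the best score) of the
#' peptide sets of a chosen label combination; with `combination = NULL`,
#' returns all `2^k - 1` non-empty combinations, the full combinatorial
#' merge.
#'
#' @param sets named list of de novo peptide data.frames.
#' @param combination character vector of labels to merge, or `NULL` for all
#'   non-empty subsets.
#' @return a merged data.frame, or (for `NULL`) a named list of them with
#'   `+`-joined combination names.
#' @export
merge_enzyme_sets <- function(sets, combination = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (!is.null(combination)) {
    bad <- setdiff(combination, names(sets))
    if (length(bad)) stop("merge_enzyme_sets: unknown label(s): ",
                          paste(bad, collapse = ","))
    merged <- do.call(rbind, unname(sets[combination]))
    if (is.null(merged) || !nrow(merged)) return(merged)
    merged <- merged[order(merged$sequence, -merged$score), , drop = FALSE]
    merged <- merged[!duplicated(merged$sequence), , drop = FALSE]
    rownames(merged) <- NULL
    return(merged)
  }
  labels <- names(sets)
  out <- list()
  for (k in seq_along(labels)) {
    for (combo in utils::combn(labels, k, simplify = FALSE)) {
      out[[paste(combo, collapse = "+")]] <- merge_enzyme_sets(sets, combo)
    }
  }
  out
}

#' Align de novo peptides to a reference
#'
#' Places each peptide at the reference position minimizing the number of
#' mismatches, with isoleucine and leucine treated as interchangeable when
#' `il_equivalent` (they are isobaric and indistinguishable by standard
#' fragmentation). Ties break to the smallest start. Peptides whose best
#' placement exceeds `max_mismatch` are left unplaced. The coverage mask is
#' the union of placed spans.
#'
#' @param peptides de novo data.frame (`sequence`, optionally `score`,
#'   `enzyme`) or character vector.
#' @param reference `ProteinRecord` or sequence string.
#' @param max_mismatch maximum tolerated mismatches (default 1).
#' @param il_equivalent treat I and L as equal (default TRUE).
#' @return list with `placements` (data.frame: `sequence`, `start`,
#'   `mismatches`, `placed`), `mask` (`CoverageMask`) and `unplaced`
#'   (character vector).
#' @export
align_to_reference <- function(peptides, reference, max_mismatch = 1L,
                               il_equivalent = TRUE) {
  reference <- as_record(reference)
  seqs <- peptide_sequences(peptides)
  ref <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  n <- length(ref)
  if (!n) stop("align_to_reference: empty reference")
  refc <- if (il_equivalent) replace(ref, ref == "I", "L") else ref
  place <- data.frame(sequence = seqs, start = NA_integer_,
                      mismatches = NA_integer_, placed = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_along(seqs)) {
    pep <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    if (il_equivalent) pep <- replace(pep, pep == "I", "L")
    lp <- length(pep)
    if (lp > n || lp == 0L) next
    nstarts <- n - lp + 1L
    mm <- integer(nstarts)
    for (s in seq_len(nstarts)) {
      mm[s] <- sum(pep != refc[s:(s + lp - 1L)])
    }
    best <- which.min(mm)  # ties -> smallest start
    if (mm[best] <= max_mismatch) {
      place$start[i] <- best
      place$mismatches[i] <- mm[best]
      place$placed[i] <- TRUE
    }
  }
  covered <- logical(n)
  for (i in which(place$placed)) {
    covered[place$start[i]:(place$start[i] + nchar(seqs[i]) - 1L)] <- TRUE
  }
  list(
    placements = place,
    mask = structure(list(protein_id = reference$id, length = n,
                          covered = covered), class = "CoverageMask"),
    unplaced = seqs[!place$placed]
  )
}

#' Coverage per enzyme combination
#'
#' Score-filters each enzyme's de novo set, merges every non-empty label
#' combination, aligns each merged set to the reference and tabulates
#' percent coverage. Coverage is monotone over the subset lattice: adding an
#' enzyme can never lose coverage.
#'
#' @param sets named list of de novo peptide data.frames.
#' @param reference `ProteinRecord` or sequence string.
#' @param min_score score threshold applied before merging (default 90).
#' @param max_mismatch,il_equivalent alignment settings.
#' @return data.frame: `combination`, `n_enzymes`, `n_peptides`,
#'   `coverage_pct`.
#' @export
combination_coverage_table <- function(sets, reference, min_score = 90,
                                       max_mismatch = 1L,
                                       il_equivalent = TRUE) {
  filtered <- lapply(sets, filter_denovo, min_score = min_score)
  merged <- merge_enzyme_sets(filtered, NULL)
  rows <- lapply(names(merged), function(nm) {
    m <- merged[[nm]]
    npep <- if (is.null(m)) 0L else nrow(m)
    cov <- if (npep == 0L) 0 else {
      percent_coverage(align_to_reference(m, reference, max_mismatch,
                                          il_equivalent)$mask, 1L)
    }
    data.frame(combination = nm,
               n_enzymes = length(strsplit(nm, "+", fixed = TRUE)[[1]]),
               n_peptides = npep, coverage_pct = cov,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$n_enzymes, out$combination), ]
}
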