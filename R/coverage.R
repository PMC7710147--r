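# Per-protein coverage masks, multi-enzyme merging, and phosphosite
# filtering / comparison.

#' Coverage mask of a protein
#'
#' Boolean per-residue vector: a position is covered iff it lies within at
#' least one peptide span. Peptides are located by coordinates when present,
#' otherwise by exact sequence match (all match positions are marked).
#'
#' @param record `ProteinRecord` or sequence string.
#' @param peptides peptide table or character vector (may be empty).
#' @return object of class `CoverageMask` (`protein_id`, `length`,
#'   `covered`).
#' @export
coverage_mask <- function(record, peptides) {
  record <- as_record(record)
  n <- nchar(record$sequence)
  covered <- logical(n)
  if (is.data.frame(peptides) && nrow(peptides) &&
      all(c("start", "end") %in% names(peptides))) {
    keep <- if ("protein_id" %in% names(peptides)) {
      peptides$protein_id == record$id
    } else rep(TRUE, nrow(peptides))
    for (i in which(keep)) {
      s <- max(1L, peptides$start[i]); e <- min(n, peptides$end[i])
      if (s <= e) covered[s:e] <- TRUE
    }
  } else {
    seqs <- peptide_sequences(peptides)
    for (sq in seqs) {
      m <- gregexpr(sq, record$sequence, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (s in m) covered[s:(s + nchar(sq) - 1L)] <- TRUE
    }
  }
  structure(list(protein_id = record$id, length = n, covered = covered),
            class = "CoverageMask")
}

#' @export
print.CoverageMask <- function(x, ...) {
  cat(sprintf("CoverageMask %s: %d/%d residues (%.1f%%)\n", x$protein_id,
              sum(x$covered), x$length, 100 * mean(x$covered)))
  invisible(x)
}

#' Empty coverage mask (merge identity)
#' @param record `ProteinRecord` or sequence string.
#' @export
empty_mask <- function(record) coverage_mask(record, character(0))

#' Merge coverage masks
#'
#' Element-wise OR over masks of the same protein. Commutative, associative
#' and idempotent, with the empty mask as identity — merging search results
#' from several enzymes can only increase coverage.
#'
#' @param ... `CoverageMask` objects, or a single list of them.
#' @return merged `CoverageMask`.
#' @export
merge_masks <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && !inherits(masks[[1]], "CoverageMask")) {
    masks <- masks[[1]]
  }
  stopifnot(length(masks) >= 1L,
            all(vapply(masks, inherits, TRUE, what = "CoverageMask")))
  lens <- vapply(masks, function(m) m$length, 1L)
  if (length(unique(lens)) != 1L) {
    stop("merge_masks: masks have different lengths")
  }
  covered <- Reduce(`|`, lapply(masks, function(m) m$covered))
  structure(list(protein_id = masks[[1]]$protein_id, length = lens[1],
                 covered = covered), class = "CoverageMask")
}

#' Percent sequence coverage
#'
#' `100 * covered / length`, rounded half-up (the convention behind headline
#' integer coverage figures: 584 of 656 residues gives 89%).
#'
#' @param mask `CoverageMask`.
#' @param ndigits digits after the decimal point (default 0).
#' @export
percent_coverage <- function(mask, ndigits = 0L) {
  stopifnot(inherits(mask, "CoverageMask"))
  round_half_up(100 * sum(mask$covered) / mask$length, ndigits)
}

round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Set complementarity between labelled collections
#'
#' For named collections of items (protein ids, residue positions, site
#' keys), counts the items falling in every non-empty label combination —
#' the numbers behind 2- and 3-way Venn diagrams.
#'
#' @param per_label_items named list of vectors.
#' @return named numeric vector; names are `+`-joined label combinations.
#' @export
complementarity <- function(per_label_items) {
  stopifnot(is.list(per_label_items), length(per_label_items) >= 2L,
            !is.null(names(per_label_items)))
  labels <- names(per_label_items)
  sets <- lapply(per_label_items, unique)
  items <- unique(unlist(sets))
  sig <- vapply(items, function(it) {
    paste(labels[vapply(sets, function(s) it %in% s, TRUE)], collapse = "+")
  }, "")
  combos <- unlist(lapply(seq_along(labels), function(k) {
    utils::combn(labels, k, paste, collapse = "+")
  }))
  counts <- stats::setNames(numeric(length(combos)), combos)
  tab <- table(sig)
  counts[names(tab)] <- as.numeric(tab)
  counts
}

#' Coverage of diagnostic positions
#'
#' Fraction of a set of positions of interest (e.g. species-diagnostic
#' substitution sites) covered by a mask.
#'
#' @param mask `CoverageMask`.
#' @param positions integer positions (non-empty, within the protein).
#' @export
diagnostic_position_coverage <- function(mask, positions) {
  stopifnot(inherits(mask, "CoverageMask"))
  if (!length(positions)) {
    stop("diagnostic_position_coverage: empty position list")
  }
  positions <- as.integer(positions)
  if (any(positions < 1L) || any(positions > mask$length)) {
    stop("diagnostic_position_coverage: positions out of range")
  }
  mean(mask$covered[positions])
}

#' Filter class I phosphosites
#'
#' Keeps sites with localization probability at or above the threshold
#' (inclusive, per the standard class-I definition of >= 0.75).
#'
#' @param sites site table with a `localization_probability` column.
#' @param threshold default 0.75.
#' @export
filter_class1 <- function(sites, threshold = 0.75) {
  stopifnot("localization_probability" %in% names(sites))
  sites[sites$localization_probability >= threshold, , drop = FALSE]
}

#' Compare localization-probability distributions
#'
#' One-tailed two-sample pooled-variance t test of `mean(a) > mean(b)` with
#' `df = n_a + n_b - 2` — the test used to compare site-localization quality
#' between two enzymes. The pooled variance is floored at 1e-12 so that
#' zero-variance degenerate inputs stay finite; identical groups give
#' `t = 0`, `p = 0.5`.
#'
#' @param sites_a,sites_b numeric vectors of localization probabilities, or
#'   site tables with a `localization_probability` column.
#' @return list: `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
compare_localization <- function(sites_a, sites_b) {
  a <- loc_probs(sites_a); b <- loc_probs(sites_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("compare_localization: each group needs n >= 2")
  }
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  sp2 <- max(sp2, 1e-12)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = stats::pt(t, df, lower.tail = FALSE),
       mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb)
}

loc_probs <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("localization_probability" %in% names(x))
    return(x$localization_probability)
  }
  as.numeric(x)
}
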