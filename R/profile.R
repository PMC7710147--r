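# Specificity profiling of identified-peptide lists.

#' Terminal residue frequencies
#'
#' Fraction of identified peptides whose terminal residue is each amino
#' acid: `fraction(X) = #peptides ending in X / #peptides`. This is the
#' statistic plotted in enzyme-specificity panels from unspecific searches.
#' Peptides are deduplicated to unique sequences by default (the statistic
#' is defined on unique peptide sequences); set `unique_sequences = FALSE`
#' for PSM-level counting.
#'
#' @param peptides peptide table (data.frame with `sequence`) or character
#'   vector.
#' @param terminus `"C"` or `"N"`.
#' @param unique_sequences deduplicate sequences before counting.
#' @param exclude_protein_terminal drop peptides flagged as protein-terminal
#'   (requires a logical `protein_terminal` column); off by default since
#'   the statistic's plain definition includes them.
#' @return named numeric vector of fractions summing to 1, sorted
#'   decreasingly.
#' @export
terminal_frequency <- function(peptides, terminus = c("C", "N"),
                               unique_sequences = TRUE,
                               exclude_protein_terminal = FALSE) {
  terminus <- match.arg(terminus)
  if (exclude_protein_terminal && is.data.frame(peptides) &&
      "protein_terminal" %in% names(peptides)) {
    peptides <- peptides[!peptides$protein_terminal, , drop = FALSE]
  }
  seqs <- peptide_sequences(peptides)
  if (unique_sequences) seqs <- unique(seqs)
  if (!length(seqs)) stop("terminal_frequency: empty peptide list")
  term <- if (terminus == "C") {
    substring(seqs, nchar(seqs), nchar(seqs))
  } else {
    substring(seqs, 1L, 1L)
  }
  tab <- table(term)
  sort(tab / length(seqs), decreasing = TRUE)
}

#' Enzyme specificity fraction
#'
#' Fraction of peptides whose enzymatic terminus carries a residue in the
#' enzyme's recognition set: the C-terminal residue for C-side enzymes, the
#' N-terminal residue for N-side enzymes.
#'
#' @inheritParams terminal_frequency
#' @param enzyme `EnzymeSpec` or preset name.
#' @return fraction in `[0, 1]`.
#' @export
specificity_fraction <- function(peptides, enzyme, unique_sequences = TRUE) {
  enzyme <- as_enzyme(enzyme)
  seqs <- peptide_sequences(peptides)
  if (unique_sequences) seqs <- unique(seqs)
  if (!length(seqs)) stop("specificity_fraction: empty peptide list")
  term <- if (enzyme$side == "C") {
    substring(seqs, nchar(seqs), nchar(seqs))
  } else {
    substring(seqs, 1L, 1L)
  }
  mean(term %in% enzyme$cleave_after)
}

#' Missed-cleavage distribution
#'
#' Counts missed cleavages per peptide from the sequence alone: enzyme
#' residues whose following bond is internal to the peptide (for C-side
#' enzymes, recognized residues at positions `1..len-1`; the C-terminal
#' residue is the cleaved site, not a missed one). Counts at or above `cap`
#' are pooled into a `"cap+"` bin.
#'
#' @inheritParams specificity_fraction
#' @param cap pool counts `>= cap` (default 5, i.e. bins 0..4 and `5+`).
#' @return named numeric vector of fractions summing to 1.
#' @export
missed_cleavage_distribution <- function(peptides, enzyme, cap = 5L,
                                         unique_sequences = TRUE) {
  enzyme <- as_enzyme(enzyme)
  seqs <- peptide_sequences(peptides)
  if (unique_sequences) seqs <- unique(seqs)
  if (!length(seqs)) stop("missed_cleavage_distribution: empty peptide list")
  counts <- vapply(seqs, count_missed_in_sequence, 1L, enzyme = enzyme,
                   USE.NAMES = FALSE)
  lab <- ifelse(counts >= cap, paste0(cap, "+"), as.character(counts))
  tab <- table(lab)
  ord <- order(suppressWarnings(as.numeric(sub("\\+$", "", names(tab)))))
  tab[ord] / length(seqs)
}

count_missed_in_sequence <- function(seq, enzyme) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(0L)
  if (enzyme$side == "C") {
    idx <- which(chars[-n] %in% enzyme$cleave_after)
    if (enzyme$restrict_before_proline && length(idx)) {
      idx <- idx[chars[idx + 1L] != "P"]
    }
    length(idx)
  } else {
    # N-side: a recognized residue at position >= 2 means the bond before it
    # (internal to the peptide) was not cut.
    sum(chars[-1L] %in% enzyme$cleave_after)
  }
}

#' Full specificity profile
#'
#' Bundles [terminal_frequency()], [specificity_fraction()] and
#' [missed_cleavage_distribution()] for one labelled peptide list.
#'
#' @inheritParams specificity_fraction
#' @param label condition label stored with the profile.
#' @return object of class `SpecificityProfile`.
#' @export
specificity_profile <- function(peptides, enzyme, label = NULL,
                                unique_sequences = TRUE) {
  enzyme <- as_enzyme(enzyme)
  seqs <- peptide_sequences(peptides)
  if (unique_sequences) seqs <- unique(seqs)
  structure(
    list(label = label, n_peptides = length(seqs),
         terminal = terminal_frequency(seqs, "C", unique_sequences = FALSE),
         specific_fraction = specificity_fraction(seqs, enzyme,
                                                  unique_sequences = FALSE),
         mc_distribution = missed_cleavage_distribution(seqs, enzyme,
                                                        unique_sequences = FALSE),
         enzyme = enzyme$name),
    class = "SpecificityProfile"
  )
}

#' @export
print.SpecificityProfile <- function(x, ...) {
  cat("SpecificityProfile", if (!is.null(x$label)) paste0("[", x$label, "]"),
      "-", x$n_peptides, "unique peptides,", x$enzyme, "\n")
  top <- utils::head(x$terminal, 5)
  cat("  C-terminal:",
      paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", "), "\n")
  cat(sprintf("  specific fraction: %.1f%%\n", 100 * x$specific_fraction))
  cat("  missed cleavages:",
      paste(sprintf("%s: %.1f%%", names(x$mc_distribution),
                    100 * x$mc_distribution), collapse = ", "), "\n")
  invisible(x)
}

#' Average profiles across replicates
#'
#' Element-wise mean of the terminal-frequency vectors of several profiles
#' (replicates are averaged after per-replicate normalization).
#'
#' @param profiles list of `SpecificityProfile`.
#' @return named numeric vector of averaged C-terminal fractions.
#' @export
average_terminal_frequency <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  res <- sort(unique(unlist(lapply(profiles, function(p) names(p$terminal)))))
  m <- vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(res)), res)
    v[names(p$terminal)] <- p$terminal
    v
  }, numeric(length(res)))
  sort(rowMeans(m), decreasing = TRUE)
}
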