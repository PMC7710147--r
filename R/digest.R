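#' Cleavage sites of an enzyme in a protein
#'
#' Returns the ordered 1-based P1 positions, i.e. residues immediately
#' N-terminal of each scissile bond. The bond after the last residue does not
#' exist, so `position == length` is never reported. For N-side enzymes
#' (Asp-N style) the reported position is the residue *before* the recognized
#' residue. Hydroxyproline-modified positions count as sites when the enzyme
#' has `treat_hyp_as_site`.
#'
#' @param record `ProteinRecord` (or plain sequence string).
#' @param enzyme `EnzymeSpec` or preset name.
#' @return integer vector of P1 positions (possibly empty).
#' @examples
#' cleavage_sites("AAPKGPR", enzyme_preset("proalanase"))  # 1 2 3 6
#' @export
cleavage_sites <- function(record, enzyme) {
  record <- as_record(record)
  enzyme <- as_enzyme(enzyme)
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (enzyme$side == "C") {
    sites <- which(chars %in% enzyme$cleave_after)
  } else {
    sites <- which(chars %in% enzyme$cleave_after) - 1L
    sites <- sites[sites >= 1L]
  }
  if (enzyme$treat_hyp_as_site && length(record$mod_positions)) {
    hyp <- as.integer(names(record$mod_positions)[record$mod_positions == "Hyp"])
    if (enzyme$side == "C") sites <- union(sites, hyp)
  }
  sites <- sort(unique(sites[sites >= 1L & sites < n]))
  if (enzyme$restrict_before_proline && length(sites)) {
    sites <- sites[chars[sites + 1L] != "P"]
  }
  sites
}

as_record <- function(record) {
  if (inherits(record, "ProteinRecord")) return(record)
  if (is.character(record) && length(record) == 1L) {
    return(protein_record("unnamed", record))
  }
  stop("expected a ProteinRecord or a sequence string")
}

#' In-silico digestion
#'
#' Enumerates all fully specific peptides with `0..max_missed` missed
#' cleavages and length within bounds. Coordinates are 1-based inclusive in
#' the supplied record (the record's `start_offset` is a reporting concern
#' and is not applied here). The protein N- and C-termini always count as
#' specific termini. Order is deterministic: by start, then end.
#'
#' @param record `ProteinRecord` or sequence string.
#' @param enzyme `EnzymeSpec` or preset name.
#' @param max_missed,min_len,max_len overrides of the enzyme's policy.
#' @return data.frame with columns `protein_id`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, `nterm_specific`, `cterm_specific`.
#' @examples
#' digest("AAPKGPR", enzyme_preset("proalanase"), max_missed = 0)$sequence
#' @export
digest <- function(record, enzyme, max_missed = NULL,
                   min_len = NULL, max_len = NULL) {
  record <- as_record(record)
  enzyme <- as_enzyme(enzyme)
  if (is.null(max_missed)) max_missed <- enzyme$max_missed
  if (is.null(min_len)) min_len <- enzyme$min_len
  if (is.null(max_len)) max_len <- enzyme$max_len
  n <- nchar(record$sequence)
  b <- c(0L, cleavage_sites(record, enzyme), n)  # boundary positions
  nb <- length(b)
  starts <- ends <- mc <- integer(0)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    js <- (i + 1L):jmax
    s <- b[i] + 1L
    e <- b[js]
    len <- e - s + 1L
    keep <- len >= min_len & len <= max_len
    if (any(keep)) {
      starts <- c(starts, rep.int(s, sum(keep)))
      ends <- c(ends, e[keep])
      mc <- c(mc, (js - i - 1L)[keep])
    }
  }
  data.frame(
    protein_id = rep.int(record$id, length(starts)),
    start = starts, end = ends,
    sequence = substring(record$sequence, starts, ends),
    missed_cleavages = mc,
    nterm_specific = TRUE, cterm_specific = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Semi-specific peptides
#'
#' Peptides with exactly one enzymatic terminus; the free terminus may sit at
#' most `max_nonspecific_extension` residues away from the nearest enzymatic
#' boundary. With an extension bound of 0 the free terminus would have to sit
#' on a boundary, making the peptide fully specific, so the result is empty.
#'
#' @inheritParams digest
#' @param max_nonspecific_extension maximum distance (residues) of the
#'   nonspecific terminus from an enzymatic boundary.
#' @return data.frame in the same schema as [digest()], with the specificity
#'   booleans identifying the enzymatic terminus.
#' @export
semi_specific_peptides <- function(record, enzyme, max_nonspecific_extension,
                                   max_missed = NULL, min_len = NULL,
                                   max_len = NULL) {
  record <- as_record(record)
  enzyme <- as_enzyme(enzyme)
  if (is.null(max_missed)) max_missed <- enzyme$max_missed
  if (is.null(min_len)) min_len <- enzyme$min_len
  if (is.null(max_len)) max_len <- enzyme$max_len
  n <- nchar(record$sequence)
  sites <- cleavage_sites(record, enzyme)
  spec_starts <- unique(c(1L, sites + 1L))
  spec_starts <- spec_starts[spec_starts <= n]
  spec_ends <- unique(c(sites, n))
  boundaries <- sort(unique(c(0L, sites, n)))
  out <- list()
  if (max_nonspecific_extension >= 1L) {
    # anchored specific N-terminus, free C-terminus
    for (s in spec_starts) {
      for (e in s:n) {
        if (e %in% spec_ends) next
        ext <- min(abs(e - boundaries))
        if (ext > max_nonspecific_extension) next
        len <- e - s + 1L
        if (len < min_len || len > max_len) next
        if (count_internal_sites(sites, s, e) > max_missed) next
        out[[length(out) + 1L]] <- c(s, e, 1L)
      }
    }
    # anchored specific C-terminus, free N-terminus
    for (e in spec_ends) {
      for (s in 1:e) {
        if (s %in% spec_starts) next
        ext <- min(abs((s - 1L) - boundaries))
        if (ext > max_nonspecific_extension) next
        len <- e - s + 1L
        if (len < min_len || len > max_len) next
        if (count_internal_sites(sites, s, e) > max_missed) next
        out[[length(out) + 1L]] <- c(s, e, 2L)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      missed_cleavages = integer(0),
                      nterm_specific = logical(0), cterm_specific = logical(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  ord <- order(m[, 1], m[, 2])
  m <- m[ord, , drop = FALSE]
  data.frame(
    protein_id = rep.int(record$id, nrow(m)),
    start = m[, 1], end = m[, 2],
    sequence = substring(record$sequence, m[, 1], m[, 2]),
    missed_cleavages = vapply(seq_len(nrow(m)), function(i) {
      count_internal_sites(sites, m[i, 1], m[i, 2])
    }, 1L),
    nterm_specific = m[, 3] == 1L,
    cterm_specific = m[, 3] == 2L,
    stringsAsFactors = FALSE
  )
}

# Enzyme sites whose following bond is internal to [s, e].
count_internal_sites <- function(sites, s, e) {
  sum(sites >= s & sites <= e - 1L)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus modification
#' deltas, reported at 6-decimal precision. Peptides containing `X` (or any
#' unknown residue) have no defined mass and raise an error, as do unknown
#' modification names.
#'
#' @param sequence peptide sequence.
#' @param mods character vector (multiset) of modification names, e.g.
#'   `c("Hyp", "Phospho")`; see [MOD_DELTAS].
#' @return neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")  # 799.35997
#' @export
peptide_mass <- function(sequence, mods = character(0)) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("peptide_mass: sequence must be a non-empty string")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  m <- AA_MONO[chars]
  if (anyNA(m)) {
    bad <- chars[which(is.na(m))[1]]
    stop("peptide_mass: residue '", bad, "' has no defined mass")
  }
  extra <- 0
  if (length(mods)) {
    d <- MOD_DELTAS[mods]
    if (anyNA(d)) {
      stop("peptide_mass: unknown modification name(s): ",
           paste(mods[is.na(d)], collapse = ", "))
    }
    extra <- sum(d)
  }
  round(sum(m) + WATER_MONO + extra, 6)
}

#' Peptide length distribution
#'
#' Histogram of peptide lengths together with the fraction of peptides
#' shorter than a threshold — the statistic behind the observation that most
#' theoretical tryptic peptides of a K/R-rich proteome are too short to be
#' informative.
#'
#' @param peptides digest data.frame (uses `sequence`) or character vector.
#' @param threshold count the fraction of peptides with length `< threshold`
#'   (default 7, the usual identification minimum).
#' @return list with `counts` (named integer), `fractions` and
#'   `frac_below_threshold`.
#' @export
length_distribution <- function(peptides, threshold = 7L) {
  seqs <- peptide_sequences(peptides)
  if (!length(seqs)) stop("length_distribution: empty peptide list")
  len <- nchar(seqs)
  counts <- table(len)
  list(
    counts = counts,
    fractions = counts / length(len),
    frac_below_threshold = mean(len < threshold),
    threshold = threshold
  )
}

# Extract sequences from a peptide table or character vector.
peptide_sequences <- function(peptides) {
  if (is.data.frame(peptides)) {
    if (!"sequence" %in% names(peptides)) {
      stop("peptide table must have a 'sequence' column")
    }
    return(peptides$sequence)
  }
  as.character(peptides)
}

#' Write / read the TSV peptide-table interchange format
#'
#' Plain tab-separated tables; when the object carries a `params` attribute
#' (all synthetic generators attach one) a JSON sidecar
#' `<path>.params.json` is written alongside.
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_peptide_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  params <- attr(x, "params")
  if (!is.null(params)) {
    jsonlite::write_json(params, paste0(path, ".params.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_peptide_table
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop("read_peptide_table: file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}
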