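#' Construct a protein record
#'
#' A `ProteinRecord` holds one protein (or protein fragment) sequence together
#' with its identifier, an optional 1-based start offset in the parent protein
#' (parsed from UniProt-style header range annotations such as
#' `sp|ACC|1663-2318`), and optional per-residue modifications such as
#' hydroxyproline positions.
#'
#' @param id accession string.
#' @param sequence uppercase amino-acid string (20 canonical letters plus `X`).
#' @param description free-text description (default empty).
#' @param start_offset 1-based coordinate of the first residue in the parent
#'   protein; used for reporting only, never for internal indexing.
#' @param mod_positions named character vector mapping 1-based positions
#'   (names) to modification names (values), e.g. `c("12" = "Hyp")`.
#' @return object of class `ProteinRecord`.
#' @examples
#' protein_record("SYN0001", "MKAPLLG")
#' @export
protein_record <- function(id, sequence, description = "",
                           start_offset = 1L, mod_positions = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) {
    stop("protein_record: sequence must be non-empty for record '", id, "'")
  }
  sequence <- toupper(sequence)
  check_alphabet(sequence, id)
  n <- nchar(sequence)
  start_offset <- as.integer(start_offset)
  stopifnot(length(start_offset) == 1L, !is.na(start_offset), start_offset >= 1L)
  mods <- character(0)
  if (!is.null(mod_positions) && length(mod_positions)) {
    mods <- mod_positions
    pos <- as.integer(names(mods))
    if (anyNA(pos) || any(pos < 1L) || any(pos > n)) {
      stop("protein_record: modification positions out of [1, ", n,
           "] for record '", id, "'")
    }
    unknown <- setdiff(unique(unname(mods)), names(MOD_DELTAS))
    if (length(unknown)) {
      stop("protein_record: unknown modification name(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(id = id, description = description, sequence = sequence,
         start_offset = start_offset, mod_positions = mods),
    class = "ProteinRecord"
  )
}

# Validate the allowed alphabet, reporting the offending record and position.
check_alphabet <- function(sequence, id) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    stop("illegal residue character '", chars[bad[1]], "' at position ",
         bad[1], " in record '", id, "'")
  }
  invisible(TRUE)
}

#' @export
print.ProteinRecord <- function(x, ...) {
  cat("ProteinRecord", x$id, sprintf("(%d aa", nchar(x$sequence)))
  if (x$start_offset != 1L) {
    cat(sprintf(", parent coordinates %d-%d",
                x$start_offset, x$start_offset + nchar(x$sequence) - 1L))
  }
  cat(")\n")
  if (length(x$mod_positions)) {
    cat("  modifications:",
        paste0(unname(x$mod_positions), "@", names(x$mod_positions),
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Parses a FASTA file into a list of [protein_record()] objects. Headers
#' follow the UniProt convention: the identifier is the first
#' whitespace-delimited token; if its last pipe-delimited field matches
#' `a-b` with integers `a <= b`, it is taken as a residue-range annotation
#' and `a` becomes the record's `start_offset`. A mismatch between the
#' declared range length and the actual sequence length is reported as a
#' warning, not an error.
#'
#' @param path path to a FASTA file.
#' @return list of `ProteinRecord`, classed as `proteome`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("read_fasta: no FASTA records in ", path)
  headers <- names(aa)
  seqs <- unname(as.character(aa))
  recs <- vector("list", length(aa))
  for (i in seq_along(aa)) {
    header <- headers[i]
    toks <- strsplit(header, "[ \t]+")[[1]]
    id <- toks[1]
    desc <- if (length(toks) > 1L) paste(toks[-1], collapse = " ") else ""
    start_offset <- 1L
    pipe_toks <- strsplit(id, "|", fixed = TRUE)[[1]]
    last <- pipe_toks[length(pipe_toks)]
    m <- regmatches(last, regexec("^([0-9]+)-([0-9]+)$", last))[[1]]
    if (length(m) == 3L) {
      a <- as.integer(m[2]); b <- as.integer(m[3])
      if (!is.na(a) && !is.na(b) && a <= b) {
        start_offset <- a
        declared <- b - a + 1L
        if (declared != nchar(seqs[i])) {
          warning("read_fasta: record '", id, "' declares ", declared,
                  " residues (range ", a, "-", b, ") but sequence has ",
                  nchar(seqs[i]))
        }
      }
    }
    recs[[i]] <- protein_record(id, seqs[i], description = desc,
                                start_offset = start_offset)
  }
  structure(recs, class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("proteome of", length(x), "records,",
      sum(vapply(x, function(r) nchar(r$sequence), 1L)), "residues\n")
  invisible(x)
}

#' Write protein records to FASTA
#'
#' @param proteins list of `ProteinRecord`.
#' @param path output path.
#' @export
write_fasta <- function(proteins, path) {
  proteins <- as_proteome(proteins)
  lines <- unlist(lapply(proteins, function(r) {
    hdr <- paste0(">", r$id,
                  if (nzchar(r$description)) paste0(" ", r$description) else "")
    c(hdr, r$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

# Accept a single record, a bare list of records, or a proteome.
as_proteome <- function(x) {
  if (inherits(x, "ProteinRecord")) x <- list(x)
  if (!length(x)) stop("empty protein list")
  ok <- vapply(x, inherits, TRUE, what = "ProteinRecord")
  if (!all(ok)) stop("expected ProteinRecord objects")
  structure(unclass(x), class = "proteome")
}

#' Residue composition of a protein set
#'
#' Fraction of each canonical residue across all sequences; `X` residues are
#' excluded from the denominator so that the result is a proper distribution
#' over the 20 residues (usable as a motif-enrichment background).
#'
#' @param proteins `ProteinRecord` list / proteome.
#' @return named numeric vector summing to 1.
#' @export
residue_composition <- function(proteins) {
  proteins <- as_proteome(proteins)
  chars <- unlist(strsplit(vapply(proteins, function(r) r$sequence, ""), "",
                           fixed = TRUE))
  chars <- chars[chars != "X"]
  if (!length(chars)) stop("residue_composition: no canonical residues")
  tab <- table(factor(chars, levels = names(AA_MONO)))
  as.numeric(tab / sum(tab)) |> stats::setNames(names(AA_MONO))
}
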