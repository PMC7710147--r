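#' Define a cleavage rule
#'
#' An `EnzymeSpec` captures a protease's cleavage rule: the recognized residue
#' set, which side of the recognized residue the scissile bond lies on
#' (C-terminal for trypsin-like enzymes and for the Pro/Ala-directed acid
#' protease; N-terminal for Asp-N), and search-style policies (missed-cleavage
#' maximum, peptide length bounds, the classic-trypsin proline restriction,
#' and whether hydroxyproline-modified positions count as sites).
#'
#' @param name enzyme name.
#' @param cleave_after character vector of recognized residues (e.g. `c("P","A")`).
#' @param side `"C"` (bond after the residue) or `"N"` (bond before it).
#' @param treat_hyp_as_site should positions carrying a `Hyp` modification be
#'   treated as cleavage sites even if their letter is outside `cleave_after`?
#' @param restrict_before_proline classic trypsin behaviour: suppress cleavage
#'   when the next residue is proline.
#' @param max_missed maximum missed cleavages (0..20).
#' @param min_len,max_len peptide length bounds.
#' @return object of class `EnzymeSpec`.
#' @examples
#' enzyme_spec("proalanase", c("P", "A"), max_missed = 4)
#' @export
enzyme_spec <- function(name, cleave_after, side = c("C", "N"),
                        treat_hyp_as_site = FALSE,
                        restrict_before_proline = FALSE,
                        max_missed = 2L, min_len = 1L, max_len = 1000L) {
  side <- match.arg(side)
  cleave_after <- toupper(unique(cleave_after))
  if (!length(cleave_after)) stop("enzyme_spec: cleave_after must be non-empty")
  bad <- setdiff(cleave_after, names(AA_MONO))
  if (length(bad)) stop("enzyme_spec: unknown residue(s): ", paste(bad, collapse = ","))
  max_missed <- as.integer(max_missed)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  stopifnot(max_missed >= 0L, max_missed <= 20L,
            min_len >= 1L, max_len >= min_len)
  structure(
    list(name = name, cleave_after = cleave_after, side = side,
         treat_hyp_as_site = treat_hyp_as_site,
         restrict_before_proline = restrict_before_proline,
         max_missed = max_missed, min_len = min_len, max_len = max_len),
    class = "EnzymeSpec"
  )
}

#' @export
print.EnzymeSpec <- function(x, ...) {
  cat(sprintf("EnzymeSpec '%s': %s-side of {%s}, max_missed %d, len %d-%d\n",
              x$name, x$side, paste(x$cleave_after, collapse = ","),
              x$max_missed, x$min_len, x$max_len))
  invisible(x)
}

#' Bundled enzyme presets
#'
#' * `proalanase`: C-terminal of Pro and Ala, hydroxyproline counted as a
#'   site, up to 4 missed cleavages (the standard search setting for this
#'   enzyme on human samples; raise `max_missed` to 10 for very
#'   missed-cleavage-rich digests).
#' * `trypsin_p`: C-terminal of Lys/Arg without the proline restriction
#'   (the common search-engine default), 2 missed cleavages.
#' * `trypsin`: classic trypsin, no cleavage before proline.
#' * `gluc`: C-terminal of Asp/Glu. `aspn`: N-terminal of Asp.
#' * `pasg`: C-terminal of Pro/Ala/Ser/Gly, the permissive residue set used
#'   for semi-specific second-pass searches of acid digests.
#'
#' @param name preset name.
#' @param ... overrides forwarded to [enzyme_spec()] fields.
#' @return `EnzymeSpec`.
#' @export
enzyme_preset <- function(name, ...) {
  presets <- list(
    proalanase = list(cleave_after = c("P", "A"), side = "C",
                      treat_hyp_as_site = TRUE, max_missed = 4L),
    trypsin_p  = list(cleave_after = c("K", "R"), side = "C", max_missed = 2L),
    trypsin    = list(cleave_after = c("K", "R"), side = "C",
                      restrict_before_proline = TRUE, max_missed = 2L),
    gluc       = list(cleave_after = c("D", "E"), side = "C", max_missed = 4L),
    aspn       = list(cleave_after = c("D"), side = "N", max_missed = 4L),
    pasg       = list(cleave_after = c("P", "A", "S", "G"), side = "C",
                      max_missed = 10L)
  )
  if (!name %in% names(presets)) {
    stop("unknown enzyme preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  args <- utils::modifyList(c(list(name = name), presets[[name]]), list(...))
  do.call(enzyme_spec, args)
}

# Coerce a preset name or EnzymeSpec to an EnzymeSpec.
as_enzyme <- function(enzyme) {
  if (inherits(enzyme, "EnzymeSpec")) return(enzyme)
  if (is.character(enzyme) && length(enzyme) == 1L) return(enzyme_preset(enzyme))
  stop("expected an EnzymeSpec or a preset name")
}
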