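# Cleavage-site sequence context: windows aligned at the scissile bond
# (P1/P1' convention), motif enrichment against a background composition,
# and cleaved/missed ratios per site residue.

#' Extract cleavage-context windows
#'
#' Aligns sequence windows at the scissile bond for every observable site of
#' an identified-peptide list. *Cleaved* windows come from peptide C-termini
#' carrying an enzyme residue (a cut was observed there); *missed* windows
#' come from enzyme residues whose following bond is internal to a peptide
#' (the protease failed to cut). Positions are labelled `P6..P1` (N-terminal
#' of the bond, `P1` = site residue) and `P1'..P6'`; positions outside the
#' protein hold the gap symbol `-`.
#'
#' Peptides are located by their `start`/`end` coordinates when present,
#' otherwise by unique exact sequence match (ambiguous matches resolve to
#' the first protein by sorted id and are counted; unmatched peptides are
#' recorded and skipped — see `attr(, "skipped")`).
#'
#' @param proteins proteome.
#' @param peptides peptide table or character vector.
#' @param enzyme `EnzymeSpec` or preset name (C-side).
#' @param half_width window half-width (default 6, the logo convention).
#' @return data.frame of windows: `protein_id`, `position`, `site_residue`,
#'   `class` (`"cleaved"`/`"missed"`), and one column per window position.
#' @export
extract_windows <- function(proteins, peptides, enzyme, half_width = 6L) {
  proteins <- as_proteome(proteins)
  enzyme <- as_enzyme(enzyme)
  if (enzyme$side != "C") {
    stop("extract_windows: only C-side enzymes are supported")
  }
  seqs <- vapply(proteins, function(r) r$sequence, "")
  ids <- vapply(proteins, function(r) r$id, "")
  ord <- order(ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  if (!is.data.frame(peptides)) {
    peptides <- data.frame(sequence = as.character(peptides),
                           stringsAsFactors = FALSE)
  }
  have_coords <- all(c("protein_id", "start", "end") %in% names(peptides)) &&
    !anyNA(peptides$start)
  skipped <- character(0); ambiguous <- 0L
  rows <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    if (have_coords) {
      pid <- peptides$protein_id[i]
      w <- match(pid, ids)
      if (is.na(w)) { skipped <- c(skipped, peptides$sequence[i]); next }
      s <- peptides$start[i]; e <- peptides$end[i]
    } else {
      hits <- which(vapply(seqs, function(ps)
        grepl(peptides$sequence[i], ps, fixed = TRUE), TRUE))
      if (!length(hits)) { skipped <- c(skipped, peptides$sequence[i]); next }
      if (length(hits) > 1L) ambiguous <- ambiguous + 1L
      w <- hits[1]
      s <- regexpr(peptides$sequence[i], seqs[w], fixed = TRUE)[1]
      e <- s + nchar(peptides$sequence[i]) - 1L
    }
    rows[[i]] <- c(w, s, e)
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  win <- list()
  if (!is.null(rows)) {
    for (k in seq_len(nrow(rows))) {
      w <- rows[k, 1]; s <- rows[k, 2]; e <- rows[k, 3]
      chars <- strsplit(seqs[w], "", fixed = TRUE)[[1]]
      n <- length(chars)
      # cleaved: peptide C-terminus at an enzyme residue with a real bond after
      if (e < n && chars[e] %in% enzyme$cleave_after) {
        win[[length(win) + 1L]] <-
          window_row(ids[w], e, chars, "cleaved", half_width)
      }
      # missed: enzyme residues whose following bond is internal to [s, e]
      internal <- s:(e - 1L)
      internal <- internal[internal >= 1L]
      for (p in internal[chars[internal] %in% enzyme$cleave_after]) {
        win[[length(win) + 1L]] <-
          window_row(ids[w], p, chars, "missed", half_width)
      }
    }
  }
  cols <- window_colnames(half_width)
  if (!length(win)) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0), integer(0), character(0), character(0)),
        rep(list(character(0)), length(cols))),
      c("protein_id", "position", "site_residue", "class", cols)))
  } else {
    out <- do.call(rbind, win)
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  attr(out, "n_ambiguous") <- ambiguous
  out
}

window_colnames <- function(hw) {
  c(paste0("P", hw:1), paste0("P", 1:hw, "p"))
}

window_row <- function(id, p, chars, class, hw) {
  n <- length(chars)
  idx <- c((p - hw + 1L):p, (p + 1L):(p + hw))
  res <- ifelse(idx >= 1L & idx <= n, chars[pmax(pmin(idx, n), 1L)], GAP_CHAR)
  df <- data.frame(protein_id = id, position = p, site_residue = chars[p],
                   class = class, stringsAsFactors = FALSE)
  df[window_colnames(hw)] <- as.list(res)
  df
}

#' Positional motif enrichment
#'
#' Compares per-position residue frequencies of aligned windows to a
#' background composition with a two-sided one-sample proportion test per
#' (position, residue) cell: normal approximation without continuity
#' correction, switching to the exact binomial test when the observed count
#' is below 5. Gap positions are excluded from the per-position totals.
#'
#' @param windows windows data.frame from [extract_windows()] (typically a
#'   class/site subset).
#' @param background_freq named residue frequencies summing to 1.
#' @param alpha significance level (default 0.05, uncorrected, as in
#'   logo-style analyses).
#' @param correction `"none"` or `"bonferroni"` across cells.
#' @return data.frame: `position`, `residue`, `count`, `n`, `fg`, `bg`,
#'   `diff`, `p`, `significant`.
#' @export
motif_enrichment <- function(windows, background_freq = AA_BACKGROUND,
                             alpha = 0.05, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  cols <- grep("^P[0-9]+p?$", names(windows), value = TRUE)
  if (nrow(windows) < 20L) {
    stop("motif_enrichment: need at least 20 windows")
  }
  if (abs(sum(background_freq) - 1) > 1e-6) {
    stop("motif_enrichment: background frequencies must sum to 1")
  }
  out <- list()
  for (col in cols) {
    v <- windows[[col]]
    v <- v[v != GAP_CHAR]
    n <- length(v)
    if (!n) next
    fg_res <- unique(v)
    miss <- setdiff(fg_res, names(background_freq))
    if (length(miss)) {
      stop("motif_enrichment: background is missing residue(s) present in ",
           "the foreground: ", paste(miss, collapse = ","))
    }
    counts <- table(factor(v, levels = names(background_freq)))
    for (r in names(background_freq)) {
      cnt <- as.integer(counts[r])
      p0 <- unname(background_freq[r])
      fg <- cnt / n
      p <- if (cnt < 5L) {
        stats::binom.test(cnt, n, p0)$p.value
      } else {
        z <- (fg - p0) / sqrt(p0 * (1 - p0) / n)
        2 * stats::pnorm(-abs(z))
      }
      out[[length(out) + 1L]] <- data.frame(
        position = col, residue = r, count = cnt, n = n, fg = fg, bg = p0,
        diff = fg - p0, p = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  thr <- if (correction == "bonferroni") alpha / nrow(res) else alpha
  res$significant <- res$p < thr
  attr(res, "alpha") <- alpha
  attr(res, "correction") <- correction
  res
}

#' Cleaved/missed ratio per site residue
#'
#' For each site residue, the number of cleaved windows over the number of
#' missed windows, with the reciprocal reported alongside. A residue with
#' zero missed (or cleaved) windows yields an infinite ratio and a warning.
#'
#' @param windows data.frame from [extract_windows()].
#' @return data.frame: `residue`, `n_cleaved`, `n_missed`,
#'   `cleaved_to_missed`, `missed_to_cleaved`.
#' @export
cleaved_missed_ratio <- function(windows) {
  stopifnot(all(c("site_residue", "class") %in% names(windows)))
  res <- sort(unique(windows$site_residue))
  out <- data.frame(residue = res,
                    n_cleaved = NA_integer_, n_missed = NA_integer_,
                    cleaved_to_missed = NA_real_, missed_to_cleaved = NA_real_)
  for (i in seq_along(res)) {
    nc <- sum(windows$site_residue == res[i] & windows$class == "cleaved")
    nm <- sum(windows$site_residue == res[i] & windows$class == "missed")
    out$n_cleaved[i] <- nc; out$n_missed[i] <- nm
    if (nm == 0L || nc == 0L) {
      warning("cleaved_missed_ratio: degenerate counts for residue ", res[i])
    }
    out$cleaved_to_missed[i] <- if (nm == 0L) Inf else nc / nm
    out$missed_to_cleaved[i] <- if (nc == 0L) Inf else nm / nc
  }
  out
}
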