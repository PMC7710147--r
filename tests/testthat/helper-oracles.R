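# Independent oracles: deliberately naive re-implementations used to verify
# the package's algorithms on small inputs. They share no code with R/.

# Exhaustive digestion oracle: every substring passing the
# (specific termini, missed-cleavage, length-bounds) predicate.
oracle_digest <- function(sequence, sites, max_missed, min_len, max_len) {
  n <- nchar(sequence)
  starts_ok <- c(1L, sites + 1L)
  ends_ok <- c(sites, n)
  out <- list()
  for (s in 1:n) {
    for (e in s:n) {
      if (!(s %in% starts_ok) || !(e %in% ends_ok)) next
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      mc <- sum(sites >= s & sites <= e - 1L)
      if (mc > max_missed) next
      out[[length(out) + 1L]] <- c(s, e, mc)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Semi-specific oracle: substrings with exactly one enzymatic terminus and
# the free terminus within `ext` of an enzymatic boundary.
oracle_semi <- function(sequence, sites, ext, max_missed, min_len, max_len) {
  n <- nchar(sequence)
  starts_ok <- c(1L, sites + 1L)
  ends_ok <- c(sites, n)
  boundaries <- sort(unique(c(0L, sites, n)))
  out <- list()
  for (s in 1:n) {
    for (e in s:n) {
      nt <- s %in% starts_ok
      ct <- e %in% ends_ok
      if (nt == ct) next  # need exactly one specific terminus
      free_pos <- if (nt) e else s - 1L
      if (min(abs(free_pos - boundaries)) > ext) next
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      if (sum(sites >= s & sites <= e - 1L) > max_missed) next
      out[[length(out) + 1L]] <- c(s, e)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Residue-by-residue mass oracle with its own constant table (CODATA-style
# element masses composed per residue formula would be overkill; this table
# was transcribed independently from a standard reference).
oracle_mass <- function(sequence) {
  tab <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
           V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
           I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
           K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
           F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  sum(tab[strsplit(sequence, "")[[1]]]) + 18.01056
}

# Sliding-window alignment oracle.
oracle_align <- function(pep, ref, il = TRUE) {
  if (il) {
    pep <- gsub("I", "L", pep)
    ref <- gsub("I", "L", ref)
  }
  lp <- nchar(pep); n <- nchar(ref)
  if (lp > n) return(NULL)
  best_mm <- Inf; best_s <- NA_integer_
  for (s in 1:(n - lp + 1)) {
    mm <- sum(strsplit(pep, "")[[1]] != strsplit(substring(ref, s, s + lp - 1),
                                                 "")[[1]])
    if (mm < best_mm) { best_mm <- mm; best_s <- s }
  }
  list(start = best_s, mismatches = best_mm)
}

random_protein <- function(n, residues = c("A", "P", "K", "R", "G", "S", "L",
                                           "D", "E", "C")) {
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

# Small helper: digest rows as a comparable matrix.
digest_matrix <- function(d) {
  m <- as.matrix(d[, c("start", "end", "missed_cleavages")])
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

toy_fasta <- function() {
  system.file("extdata", "toy.fasta", package = "proalanase")
}

mab_fixture <- function() {
  list(
    chains = read_fasta(system.file("extdata", "synthetic_mab.fasta",
                                    package = "proalanase")),
    connectivity = jsonlite::fromJSON(
      system.file("extdata", "synthetic_mab_connectivity.json",
                  package = "proalanase"))
  )
}
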