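## Secondary-structure engine and structure arithmetic.
##
## Minimum-free-energy folding is delegated to the ViennaRNA command-line
## programs (RNAfold for single sequences, RNAduplex for hybridization
## energies), batched over stdin. Everything built on top of the returned
## dot-bracket strings -- pairing maps, stem-loop decomposition, MFEI,
## star-arm geometry -- is computed here.

vienna_available <- function() {
  nzchar(Sys.which("RNAfold")) && nzchar(Sys.which("RNAduplex"))
}

require_vienna <- function() {
  if (!vienna_available())
    stop("ViennaRNA programs RNAfold/RNAduplex not found on PATH")
}

#' Fold sequences at minimum free energy
#'
#' Runs RNAfold (nearest-neighbor thermodynamic model) on a batch of
#' sequences and returns the MFE dot-bracket structure and energy for each.
#'
#' @param seqs character vector of nucleotide sequences (U or T form).
#' @return data.frame with columns `sequence`, `structure` (dot-bracket, same
#'   length as the sequence) and `mfe` (kcal/mol, <= 0).
#' @export
fold <- function(seqs) {
  if (length(seqs) == 0L)
    return(data.frame(sequence = character(), structure = character(),
                      mfe = numeric(), stringsAsFactors = FALSE))
  require_vienna()
  seqs <- normalize_rna(seqs)
  out <- system2("RNAfold", args = c("--noPS"), input = seqs, stdout = TRUE)
  if (length(out) != 2L * length(seqs))
    stop("RNAfold produced unexpected output")
  struct_lines <- out[seq(2L, length(out), by = 2L)]
  m <- regmatches(struct_lines,
                  regexpr("\\(\\s*(-?[0-9]+\\.[0-9]+)\\)\\s*$", struct_lines))
  mfe <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
  structure_str <- sub("\\s*\\(\\s*-?[0-9]+\\.[0-9]+\\)\\s*$", "", struct_lines)
  if (any(nchar(structure_str) != nchar(seqs)))
    stop("RNAfold structure length mismatch")
  data.frame(sequence = seqs, structure = structure_str, mfe = mfe,
             stringsAsFactors = FALSE)
}

#' Hybridization energy of sequence pairs
#'
#' Runs RNAduplex on pairs (a[i], b[i]) and returns the duplex MFE of each.
#'
#' @param a,b character vectors of equal length, both 5'->3'.
#' @return numeric vector of duplex energies (kcal/mol).
#' @export
duplex_energy <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(numeric())
  require_vienna()
  input <- as.vector(rbind(normalize_rna(a), normalize_rna(b)))
  out <- system2("RNAduplex", input = input, stdout = TRUE, stderr = FALSE)
  out <- out[grepl("\\(\\s*-?[0-9.]+\\)\\s*$", out)]
  if (length(out) != length(a)) stop("RNAduplex produced unexpected output")
  m <- regmatches(out, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
  as.numeric(gsub("[() ]", "", m))
}

#' Minimal folding free energy index
#'
#' MFEI = AMFE / GC%, with AMFE = |MFE| / length x 100 and GC% the G+C
#' percentage of the sequence. Pre-miRNA hairpins typically exceed 0.85,
#' a level essentially never reached by other non-coding RNAs or mRNA
#' fragments, which makes the index a strong precursor filter.
#'
#' @param mfe minimum free energy in kcal/mol (<= 0).
#' @param length sequence length in nt (> 0).
#' @param gc_fraction G+C fraction in (0, 1].
#' @return non-negative MFEI value.
#' @export
mfei <- function(mfe, length, gc_fraction) {
  stopifnot(length > 0)
  if (any(gc_fraction <= 0)) stop("mfei: undefined for gc_fraction == 0")
  stopifnot(all(gc_fraction <= 1))
  (abs(mfe) / length * 100) / (gc_fraction * 100)
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  gc <- nchar(gsub("[^GCgc]", "", seq))
  gc / n
}

#' Pairing map of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector p with p[i] = partner of position i, or NA if
#'   unpaired.
#' @export
pairing_map <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  n <- length(chars)
  p <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket structure")
  p
}

## Decompose a structure into stem-loop units. A unit is the maximal
## enclosing helix chain around one hairpin loop that contains no multiloop
## branching and no interior loop/bulge wider than max_gap unpaired bases
## on either side (helices separated by larger interior loops are distinct
## structural elements, not one precursor stem). Returns a data.frame with
## one row per hairpin loop: outer5/outer3 (outermost pair of the unit) and
## inner5/inner3 (the hairpin-closing pair).
stem_loop_units <- function(structure, max_gap = 8L) {
  p <- pairing_map(structure)
  n <- length(p)
  opens <- which(!is.na(p) & p > seq_len(n))   # i with partner j > i
  if (length(opens) == 0L)
    return(data.frame(outer5 = integer(), outer3 = integer(),
                      inner5 = integer(), inner3 = integer()))

  # hairpin-closing pairs: no paired position strictly inside (i, j)
  closing <- opens[vapply(opens, function(i) {
    j <- p[i]
    i + 1L > j - 1L || all(is.na(p[(i + 1L):(j - 1L)]))
  }, logical(1))]

  # count, for each pair, the number of direct child helices
  out <- lapply(closing, function(ci) {
    i <- ci; j <- p[ci]
    repeat {
      # candidate enclosing pair: nearest (i2, j2) with i2 < i, j2 > j paired
      # together and with no other helix branching between
      i2 <- i - 1L
      while (i2 >= 1L && is.na(p[i2])) i2 <- i2 - 1L
      if (i2 < 1L || p[i2] < i2) break          # nothing enclosing on left
      j2 <- p[i2]
      if (j2 <= j) break                        # sibling helix, not enclosing
      # positions between j and j2 must be unpaired, else (i2,j2) encloses
      # a multiloop and the unit stops at (i,j)
      between_right <- if (j + 1L <= j2 - 1L) p[(j + 1L):(j2 - 1L)] else integer(0)
      if (any(!is.na(between_right))) break
      if ((i - i2 - 1L) > max_gap || (j2 - j - 1L) > max_gap) break
      i <- i2; j <- j2
    }
    c(outer5 = i, outer3 = j, inner5 = ci, inner3 = p[ci])
  })
  as.data.frame(do.call(rbind, out))
}

#' Build a hairpin candidate from a folded precursor sequence
#'
#' Folds the sequence, verifies that the structure is a single stem-loop
#' (exactly one hairpin loop, no multiloop branching), and records the
#' arm/loop geometry plus MFE, AMFE and MFEI. Returns NULL when the
#' structure is not a single hairpin.
#'
#' @param seq precursor sequence.
#' @param chrom,start,strand optional genomic placement (1-based closed;
#'   `start` is the genomic coordinate of position 1 of `seq` on the plus
#'   strand, or of its last position's complement when `strand == "-"`).
#' @return a `HairpinCandidate` (list) or NULL.
#' @export
hairpin_candidate <- function(seq, chrom = NA_character_, start = NA_integer_,
                              strand = "+") {
  f <- fold(seq)
  units <- stem_loop_units(f$structure)
  if (nrow(units) != 1L) return(NULL)
  n <- nchar(seq)
  gc <- gc_fraction(seq)
  cand <- list(
    sequence = f$sequence,
    structure = f$structure,
    mfe = f$mfe,
    length = n,
    gc_fraction = gc,
    amfe = abs(f$mfe) / n * 100,
    mfei = mfei(f$mfe, n, gc),
    arm5 = c(1L, units$inner5),
    arm3 = c(units$inner3, n),
    loop = c(units$inner5 + 1L, units$inner3 - 1L),
    pairs = pairing_map(f$structure),
    chrom = chrom, start = start, strand = strand
  )
  class(cand) <- "HairpinCandidate"
  cand
}

#' @export
print.HairpinCandidate <- function(x, ...) {
  cat(sprintf("HairpinCandidate: %d nt, MFE %.2f kcal/mol, MFEI %.3f\n",
              x$length, x$mfe, x$mfei))
  cat(sprintf("  loop %d-%d; arms 1-%d / %d-%d\n",
              x$loop[1], x$loop[2], x$arm5[2], x$arm3[1], x$length))
  invisible(x)
}

## Excise the precursor region of a folded window around the given focus
## positions (window coordinates). Picks the stem-loop unit with the
## largest focus overlap, then trims it to the innermost base pair of its
## helix chain that still covers the focus interval: weakly paired flanking
## helices that the fold happens to stack onto the precursor stem would
## otherwise dilute the candidate (and its MFEI) with non-precursor
## sequence. Returns c(start, end) or NULL if no unit overlaps the focus.
excise_unit <- function(structure, focus_start, focus_end) {
  units <- stem_loop_units(structure)
  if (nrow(units) == 0L) return(NULL)
  ov <- units$outer5 <= focus_end & units$outer3 >= focus_start
  if (!any(ov)) return(NULL)
  u <- units[ov, , drop = FALSE]
  ovlen <- pmin(u$outer3, focus_end) - pmax(u$outer5, focus_start) + 1L
  u <- u[which.max(ovlen), ]
  p <- pairing_map(structure)
  i <- u$inner5; j <- u$inner3
  repeat {
    if (i <= focus_start && j >= focus_end) return(c(i, j))
    if (i <= u$outer5) break
    i2 <- i - 1L
    while (i2 >= u$outer5 && is.na(p[i2])) i2 <- i2 - 1L
    if (i2 < u$outer5 || is.na(p[i2]) || p[i2] <= j) break
    i <- i2; j <- p[i2]
  }
  c(u$outer5, u$outer3)
}
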