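# Genome container and gene-local coordinate arithmetic.
#
# All genome coordinates in the package are 0-based half-open on the
# forward strand.  A feature crossing the origin of a circular genome keeps
# start < end by letting end exceed the genome length; sequence extraction
# wraps modulo the length.

#' Construct a genome object
#'
#' @param id Sequence identifier.
#' @param sequence DNA string over \{A,C,G,T,N\} (case normalized).
#' @param circular Is the molecule circular?  Metazoan mitogenomes
#'   typically are.
#' @param code_table NCBI translation table number in effect for this
#'   genome; must be registered (see \code{\link{available_code_tables}}).
#' @return An object of class \code{mito_genome}.
#' @export
genome <- function(id, sequence, circular = TRUE, code_table = 2L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty genome sequence for '", id, "'")
  if (grepl("[^ACGTN]", sequence)) {
    stop("genome '", id, "' contains characters outside {A,C,G,T,N}")
  }
  get_genetic_code(code_table)  # errors on unregistered tables
  structure(list(id = id, sequence = sequence,
                 length = nchar(sequence),
                 circular = isTRUE(circular),
                 code_table = as.integer(code_table)),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome %s: %d nt, %s, code table %d>\n",
              x$id, x$length, if (x$circular) "circular" else "linear",
              x$code_table))
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Extract a forward-strand slice, wrapping on circular genomes
#'
#' @param g A \code{mito_genome}.
#' @param start,end 0-based half-open span; \code{end} may exceed the
#'   genome length on circular genomes and \code{start} may be negative.
#' @param strand \code{"+"} returns the forward slice, \code{"-"} its
#'   reverse complement.
#' @return The extracted sequence, or \code{NA} if the span falls outside a
#'   linear genome.
#' @export
genome_slice <- function(g, start, end, strand = "+") {
  stopifnot(end >= start)
  L <- g$length
  if (g$circular) {
    # normalize start into [0, L)
    shift <- floor(start / L) * L
    start <- start - shift
    end <- end - shift
    if (end - start > L) stop("slice longer than the circular genome")
    s <- if (end <= L) {
      substr(g$sequence, start + 1L, end)
    } else {
      paste0(substr(g$sequence, start + 1L, L),
             substr(g$sequence, 1L, end - L))
    }
  } else {
    if (start < 0L || end > L) return(NA_character_)
    s <- substr(g$sequence, start + 1L, end)
  }
  if (strand == "-") revcomp(s) else s
}

# Forward-axis span of codon index p in a gene-local reading frame.
# `anchor` is the genome coordinate of codon index 0: for "+" the first
# base of codon 0; for "-" the exclusive end of codon 0 on the forward
# axis (codon p occupies [anchor - 3p - width, anchor - 3p)).  `width`
# trims incomplete stop codons (3, 2 or 1 nt, always the 5'-most bases of
# the codon on the coding strand).
codon_span <- function(strand, anchor, p, width = 3L) {
  if (strand == "+") {
    cbind(start = anchor + 3L * p, end = anchor + 3L * p + width)
  } else {
    cbind(start = anchor - 3L * p - width, end = anchor - 3L * p)
  }
}

# Codon strings at gene-local codon indices `p` (vectorized).  Returns NA
# where a full 3-mer is not available (linear genome edge).
codons_at <- function(g, strand, anchor, p) {
  sp <- codon_span(strand, anchor, p, 3L)
  vapply(seq_along(p), function(i) {
    s <- genome_slice(g, sp[i, "start"], sp[i, "end"], strand)
    if (is.na(s)) NA_character_ else s
  }, character(1))
}

# Leading `k` coding-strand nucleotides of the codon at index p (used for
# incomplete stop candidates at linear genome edges).
codon_prefix <- function(g, strand, anchor, p, k) {
  if (strand == "+") {
    genome_slice(g, anchor + 3L * p, anchor + 3L * p + k, "+")
  } else {
    genome_slice(g, anchor - 3L * p - k, anchor - 3L * p, "-")
  }
}

# Normalize an unwrapped span so that start lies in [0, L).
normalize_span <- function(start, end, L, circular) {
  if (!circular) return(cbind(start = start, end = end))
  shift <- floor(start / L) * L
  cbind(start = start - shift, end = end - shift)
}

# Does span [s1, e1) fully contain locus [s2, e2) on a (possibly circular)
# genome?  Both spans unwrapped; on circular genomes the locus is also
# tested shifted by one genome length in either direction.
span_contains <- function(s1, e1, s2, e2, L, circular) {
  hit <- s2 >= s1 & e2 <= e1
  if (circular) {
    hit <- hit | (s2 + L >= s1 & e2 + L <= e1) | (s2 - L >= s1 & e2 - L <= e1)
  }
  hit
}
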