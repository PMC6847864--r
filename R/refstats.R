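# Empirical parameter tables: per-gene, per-code-table start/stop/internal
# codon frequencies (the phi source) and reference CDS length multisets
# (the lambda source), built from reference annotations.

# Split a coding-strand CDS sequence into its parts.  The trailing 1 or 2
# nucleotides of a CDS whose length is not a multiple of 3 are an
# incomplete stop codon, stored under the pseudo-codons "T--" / "TA-"
# (padded with '-' so full and incomplete keys cannot collide).
.split_cds <- function(seq) {
  n <- nchar(seq)
  r <- n %% 3L
  k <- (n - r) %/% 3L  # number of complete codons
  codons <- substring(seq, seq(1L, by = 3L, length.out = k),
                      seq(3L, by = 3L, length.out = k))
  if (r == 0L) {
    list(start = codons[1L], stop = codons[k],
         internal = codons[seq_len(k - 2L) + 1L])
  } else {
    pad <- strrep("-", 3L - r)
    list(start = codons[1L],
         stop = paste0(substr(seq, n - r + 1L, n), pad),
         internal = codons[seq_len(k - 1L) + 1L])
  }
}

#' Count start, stop and internal codons in reference CDS features
#'
#' For every CDS the first codon is counted as a start codon; the final 3
#' nucleotides as a full stop when the length is a multiple of 3, otherwise
#' the trailing 1 or 2 nucleotides as an incomplete stop (pseudo-codons
#' \code{"T--"}, \code{"TA-"}); every complete codon strictly between them
#' as internal.  Counts are stratified by (code table, gene).
#'
#' @param features Features data.frame; only rows with kind "CDS" and a
#'   gene symbol are used.
#' @param genomes Named list of \code{\link{genome}} objects (names =
#'   seqid); each genome carries its code table.
#' @return Nested list: \code{counts[[code_table]][[gene]]} with named
#'   integer tables \code{start}, \code{stop}, \code{internal}.
#' @export
count_codons <- function(features, genomes) {
  cds <- features[features$kind == "CDS" & !is.na(features$gene) &
                    features$gene != "", , drop = FALSE]
  counts <- list()
  for (i in seq_len(nrow(cds))) {
    f <- cds[i, ]
    g <- genomes[[f$seqid]]
    if (is.null(g)) stop("no genome for seqid '", f$seqid, "'")
    if (f$end - f$start < 6L) {
      warning("skipping CDS of ", f$gene, " on ", f$seqid,
              ": shorter than 6 nt")
      next
    }
    seq <- genome_slice(g, f$start, f$end, f$strand)
    parts <- .split_cds(seq)
    tk <- as.character(g$code_table)
    gk <- f$gene
    if (is.null(counts[[tk]])) counts[[tk]] <- list()
    if (is.null(counts[[tk]][[gk]])) {
      counts[[tk]][[gk]] <- list(start = integer(), stop = integer(),
                                 internal = integer())
    }
    cur <- counts[[tk]][[gk]]
    bump <- function(tab, keys) {
      tt <- table(keys)
      for (k in names(tt)) tab[k] <- (if (k %in% names(tab)) tab[k] else 0L) + tt[[k]]
      tab
    }
    cur$start <- bump(cur$start, parts$start)
    cur$stop <- bump(cur$stop, parts$stop)
    cur$internal <- bump(cur$internal, parts$internal)
    counts[[tk]][[gk]] <- cur
  }
  counts
}

#' Build the codon usage table from raw counts
#'
#' Frequencies are counts divided by the category total within each
#' (code table, gene) key.  Start codons observed with a frequency below
#' \code{start_min_freq} are removed, guarding against annotation errors;
#' frequencies are not renormalized afterwards, so retained start
#' frequencies sum to at most 1.  A codon is accepted as a stop codon only
#' if it is essentially absent as an internal codon: any codon whose
#' internal frequency reaches \code{internal_stop_max_freq} is removed
#' from the stop table.  Incomplete stop codons keep their raw frequency
#' here; the chance-hit corrections (/3 for TA, /12 for T) are applied at
#' scoring time.
#'
#' @param counts Output of \code{\link{count_codons}}.
#' @param start_min_freq Minimum retained start codon frequency
#'   (default 0.01).
#' @param internal_stop_max_freq Internal-codon frequency at or above
#'   which a codon is rejected as a stop codon (default 0.001).
#' @param stop_min_freq Optional floor on stop codon frequencies
#'   (default 0: keep all surviving stop codons).
#' @return An object of class \code{codon_usage}.
#' @export
build_usage_table <- function(counts, start_min_freq = 0.01,
                              internal_stop_max_freq = 0.001,
                              stop_min_freq = 0) {
  tables <- list()
  for (tk in names(counts)) {
    for (gk in names(counts[[tk]])) {
      cc <- counts[[tk]][[gk]]
      n_start <- sum(cc$start); n_stop <- sum(cc$stop)
      n_internal <- sum(cc$internal)
      if (n_start == 0L || n_stop == 0L) {
        message("usage table: omitting (", tk, ", ", gk,
                "): no supporting counts")
        next
      }
      start_freq <- cc$start / n_start
      start_freq <- start_freq[start_freq >= start_min_freq]
      internal_freq <- if (n_internal > 0L) cc$internal / n_internal
                       else numeric()
      stop_freq <- cc$stop / n_stop
      banned <- names(internal_freq)[internal_freq >= internal_stop_max_freq]
      stop_freq <- stop_freq[!names(stop_freq) %in% banned]
      stop_freq <- stop_freq[stop_freq >= stop_min_freq & stop_freq > 0]
      if (is.null(tables[[tk]])) tables[[tk]] <- list()
      tables[[tk]][[gk]] <- list(
        start_freq = start_freq, stop_freq = stop_freq,
        internal_freq = internal_freq,
        n_start = n_start, n_stop = n_stop, n_internal = n_internal)
    }
  }
  structure(list(tables = tables,
                 start_min_freq = start_min_freq,
                 internal_stop_max_freq = internal_stop_max_freq,
                 stop_min_freq = stop_min_freq),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  nk <- sum(vapply(x$tables, length, integer(1)))
  cat("<codon_usage: ", nk, " (code table, gene) keys over tables ",
      paste(names(x$tables), collapse = ", "), ">\n", sep = "")
  invisible(x)
}

# Frequency lookups; 0 when the codon was dropped or never seen.
.usage_entry <- function(usage, code_table, gene) {
  e <- usage$tables[[as.character(code_table)]][[gene]]
  if (is.null(e)) stop("no codon usage statistics for (code table ",
                       code_table, ", gene ", gene, ")")
  e
}

phi_start <- function(usage, code_table, gene, codon) {
  f <- .usage_entry(usage, code_table, gene)$start_freq[codon]
  unname(ifelse(is.na(f), 0, f))
}

phi_stop_raw <- function(usage, code_table, gene, key) {
  f <- .usage_entry(usage, code_table, gene)$stop_freq[key]
  unname(ifelse(is.na(f), 0, f))
}

#' Build the reference gene-length distribution
#'
#' Collects, per (code table, gene), the reference CDS lengths in
#' nucleotides (including the possibly incomplete stop codon), one value
#' per species; when a species carries multiple copies of a gene the
#' longest is kept.
#'
#' @inheritParams count_codons
#' @return An object of class \code{length_dist}.
#' @export
build_length_distribution <- function(features, genomes) {
  cds <- features[features$kind == "CDS" & !is.na(features$gene) &
                    features$gene != "", , drop = FALSE]
  tables <- list()
  if (nrow(cds)) {
    cds$len <- cds$end - cds$start
    cds$tk <- vapply(cds$seqid, function(s) {
      g <- genomes[[s]]
      if (is.null(g)) stop("no genome for seqid '", s, "'")
      as.character(g$code_table)
    }, character(1))
    agg <- stats::aggregate(len ~ tk + gene + seqid, data = cds, FUN = max)
    for (tk in unique(agg$tk)) {
      sub <- agg[agg$tk == tk, ]
      tables[[tk]] <- lapply(split(sub$len, sub$gene), sort)
    }
  }
  structure(list(tables = tables), class = "length_dist")
}

#' @export
print.length_dist <- function(x, ...) {
  nk <- sum(vapply(x$tables, length, integer(1)))
  cat("<length_dist: ", nk, " (code table, gene) keys>\n", sep = "")
  invisible(x)
}

#' Empirical two-sided length p-value
#'
#' \deqn{\lambda(l) = 2 \min(L_{\le,l}, L_{\ge,l}) / (L_{\le,l} + L_{\ge,l})}
#' where \eqn{L_{\le,l}} (\eqn{L_{\ge,l}}) is the number of reference
#' species whose gene is at most (at least) \eqn{l} nucleotides long.
#' Species of length exactly \eqn{l} count on both sides, so the
#' denominator can exceed the number of species.  Typical lengths score
#' near 1, lengths outside the observed range score 0.
#'
#' @param dist A \code{length_dist}.
#' @param code_table NCBI table number.
#' @param gene Canonical PCG symbol.
#' @param l Candidate gene length(s) in nucleotides (vectorized).
#' @return Numeric vector of p-values in [0, 1].
#' @export
lambda_pvalue <- function(dist, code_table, gene, l) {
  lens <- dist$tables[[as.character(code_table)]][[gene]]
  if (is.null(lens)) stop("no length distribution for (code table ",
                          code_table, ", gene ", gene, ")")
  # lens is sorted; findInterval counts reference lengths <= l (and < l
  # via the half-integer shift, valid because lengths are integer nt)
  n <- length(lens)
  le <- findInterval(l, lens)
  ge <- n - findInterval(l - 0.5, lens)
  2 * pmin(le, ge) / (le + ge)
}
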