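# NCBI mitochondrial translation tables, vendored as static data so that
# codon queries never require network access.

.codes_env <- new.env(parent = emptyenv())

.load_code_registry <- function() {
  if (!is.null(.codes_env$registry)) {
    return(.codes_env$registry)
  }
  path <- system.file("extdata", "genetic_codes.json",
                      package = "mitoboundaries", mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  registry <- lapply(names(raw), function(id) {
    entry <- raw[[id]]
    codon_to_aa <- unlist(entry$codon_to_aa)
    starts <- unlist(entry$starts)
    stops <- sort(names(codon_to_aa)[codon_to_aa == "*"])
    structure(
      list(table_id = as.integer(id),
           name = entry$name,
           codon_to_aa = codon_to_aa,
           starts = starts,
           stops = stops),
      class = "genetic_code")
  })
  names(registry) <- names(raw)
  .codes_env$registry <- registry
  registry
}

#' Retrieve an NCBI genetic code table
#'
#' Returns one of the mitochondrial translation tables of the NCBI Taxonomy
#' registry.  The seven tables described for metazoan mitochondrial genomes
#' (2, 4, 5, 9, 13, 14 and 24) are available.  Each table maps all 64 DNA
#' codons to an amino acid or to the stop symbol \code{"*"} and lists the
#' codons defined as initiation codons.
#'
#' @param table_id Integer NCBI translation table number.
#' @return An object of class \code{genetic_code}: a list with elements
#'   \code{table_id}, \code{name}, \code{codon_to_aa} (named character
#'   vector over all 64 codons), \code{starts} and \code{stops}.
#' @examples
#' code <- get_genetic_code(5)
#' code$starts
#' @export
get_genetic_code <- function(table_id) {
  registry <- .load_code_registry()
  key <- as.character(as.integer(table_id))
  if (!key %in% names(registry)) {
    stop("unknown NCBI genetic code table id: ", table_id,
         " (available: ", paste(names(registry), collapse = ", "), ")")
  }
  registry[[key]]
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("NCBI genetic code table ", x$table_id, " (", x$name, ")\n", sep = "")
  cat("  start codons:", paste(x$starts, collapse = " "), "\n")
  cat("  stop codons: ", paste(x$stops, collapse = " "), "\n")
  invisible(x)
}

#' List the registered genetic code table ids
#' @return Integer vector of available NCBI table numbers.
#' @export
available_code_tables <- function() {
  as.integer(names(.load_code_registry()))
}

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

.check_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- nchar(codon) != 3L |
    vapply(strsplit(codon, ""), function(ch) any(!ch %in% .IUPAC), logical(1))
  if (any(bad)) {
    stop("not a codon over the IUPAC DNA alphabet: ",
         paste(unique(codon[bad]), collapse = ", "))
  }
  codon
}

#' Translate a single codon
#'
#' Maps a codon to its amino acid under the given code table.  Codons that
#' contain ambiguity characters (N and the other IUPAC wildcards) translate
#' to \code{NA}: the outcome is unknown and such positions are excluded from
#' boundary candidate sets rather than risking a spurious stop.
#'
#' @param codon Character vector of 3-mers (DNA alphabet, T not U; case is
#'   normalized).
#' @param code A \code{genetic_code} object.
#' @return Character vector of one-letter amino acids, \code{"*"} for stop,
#'   \code{NA} for ambiguous codons.
#' @export
translate_codon <- function(codon, code) {
  codon <- .check_codon(codon)
  out <- unname(code$codon_to_aa[codon])
  out  # unmatched (ambiguous) codons are NA already
}

#' Is a codon a full stop codon?
#'
#' @inheritParams translate_codon
#' @return Logical vector; \code{NA} for codons containing ambiguity codes.
#' @export
is_full_stop <- function(codon, code) {
  aa <- translate_codon(codon, code)
  ifelse(is.na(aa), NA, aa == "*")
}

#' Is a codon a canonical start codon?
#'
#' Canonical means listed as an initiation codon in the NCBI table; the
#' empirically annotated (possibly non-canonical) start codon spectrum lives
#' in the codon usage tables instead.
#'
#' @inheritParams translate_codon
#' @return Logical vector; \code{NA} for ambiguous codons.
#' @export
is_canonical_start <- function(codon, code) {
  codon <- .check_codon(codon)
  amb <- is.na(code$codon_to_aa[codon])
  ifelse(amb, NA, codon %in% code$starts)
}
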