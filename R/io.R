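# Readers and writers for the standard annotation formats.  GFF3 and BED go
# through rtracklayer, FASTA through Biostrings; NCBI 5-column feature
# tables have a dedicated parser.  Everything is normalized on read to
# 0-based half-open coordinates on the forward strand.

.PCG_NAMES <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
                "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")

# alias -> canonical symbol; applied case-insensitively after stripping
# separators.  Reference annotations are wildly inconsistent here.
.GENE_ALIASES <- c(
  co1 = "cox1", coi = "cox1", cox1 = "cox1", mtco1 = "cox1",
  co2 = "cox2", coii = "cox2", cox2 = "cox2", mtco2 = "cox2",
  co3 = "cox3", coiii = "cox3", cox3 = "cox3", mtco3 = "cox3",
  cytb = "cob", cob = "cob", mtcyb = "cob",
  nd1 = "nad1", nad1 = "nad1", nd2 = "nad2", nad2 = "nad2",
  nd3 = "nad3", nad3 = "nad3", nd4 = "nad4", nad4 = "nad4",
  nd4l = "nad4l", nad4l = "nad4l", nd5 = "nad5", nad5 = "nad5",
  nd6 = "nad6", nad6 = "nad6",
  atp6 = "atp6", atpase6 = "atp6", atp8 = "atp8", atpase8 = "atp8")

#' Canonicalize mitochondrial gene symbols
#'
#' Maps the common aliases found in reference annotations (COX1/COI/CO1,
#' CYTB/COB, ND1/NAD1, ...) to the 13 canonical lowercase PCG symbols;
#' tRNA names are lowercased and otherwise left alone.
#'
#' @param x Character vector of gene names.
#' @return Character vector of canonical symbols.
#' @export
normalize_gene_names <- function(x) {
  key <- gsub("[ _-]", "", tolower(x))
  hit <- .GENE_ALIASES[key]
  unname(ifelse(is.na(hit), tolower(x), hit))
}

#' The 13 metazoan mitochondrial protein-coding gene symbols
#' @return Character vector of canonical PCG names.
#' @export
pcg_names <- function() .PCG_NAMES

.feature_df <- function(seqid = character(), gene = character(),
                        kind = character(), start = integer(),
                        end = integer(), strand = character(),
                        stop_completeness = character()) {
  data.frame(seqid = as.character(seqid), gene = as.character(gene),
             kind = as.character(kind), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             stop_completeness = as.character(stop_completeness),
             stringsAsFactors = FALSE)
}

.completeness_from_length <- function(len) {
  c("full", "T", "TA")[(len %% 3L) + 1L]
}

#' Read genomes from a FASTA file
#'
#' Circularity and the genetic code table are properties of the organism,
#' not of the FASTA record, so they are supplied by the caller.
#'
#' @param path FASTA file.
#' @param circular Logical, recycled over records.
#' @param code_table NCBI table number, recycled over records.
#' @return List of \code{\link{genome}} objects, in file order.
#' @export
read_genome_fasta <- function(path, circular = TRUE, code_table = 2L) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  circular <- rep_len(circular, length(seqs))
  code_table <- rep_len(code_table, length(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    genome(ids[i], as.character(seqs[[i]]), circular[i], code_table[i])
  })
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#' @param genomes List of \code{\link{genome}} objects.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genomes, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(genomes, function(g) g$sequence, character(1)))
  names(seqs) <- vapply(genomes, function(g) g$id, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

.granges_to_features <- function(gr, kind = NULL) {
  mc <- S4Vectors::mcols(gr)
  gene <- if ("gene" %in% names(mc) && !all(is.na(mc$gene))) mc$gene
          else if ("Name" %in% names(mc)) mc$Name
          else if ("name" %in% names(mc)) mc$name
          else if ("ID" %in% names(mc)) mc$ID
          else rep(NA_character_, length(gr))
  gene <- normalize_gene_names(as.character(gene))
  if (is.null(kind)) {
    kind <- if ("type" %in% names(mc)) as.character(mc$type)
            else ifelse(grepl("^trn", gene), "tRNA", "CDS")
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  comp <- rep("unknown", length(gr))
  is_cds <- kind == "CDS"
  comp[is_cds] <- .completeness_from_length(end0[is_cds] - start0[is_cds])
  if ("Note" %in% names(mc)) {
    note <- vapply(mc$Note, function(n) paste(n, collapse = ";"), character(1))
    m <- regmatches(note, regexpr("incomplete_stop:(TA?|full)", note))
    has <- grepl("incomplete_stop:", note)
    comp[has] <- sub("incomplete_stop:", "", m[match(note[has], note[has])])
  }
  .feature_df(as.character(GenomicRanges::seqnames(gr)), gene, kind,
              start0, end0,
              as.character(GenomicRanges::strand(gr)), comp)
}

.read_tbl <- function(path) {
  lines <- readLines(path)
  seqid <- NA_character_
  rows <- list()
  cur <- NULL
  flush <- function(cur, rows) {
    if (!is.null(cur)) rows[[length(rows) + 1L]] <- cur
    rows
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "") next
    if (startsWith(ln, ">Feature")) {
      rows <- flush(cur, rows); cur <- NULL
      seqid <- sub("^>Feature\\s+", "", ln)
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) >= 3 && f[1] != "" && f[3] != "") {
      rows <- flush(cur, rows)
      a <- suppressWarnings(as.integer(gsub("[<>]", "", f[1])))
      b <- suppressWarnings(as.integer(gsub("[<>]", "", f[2])))
      if (is.na(a) || is.na(b)) {
        stop("malformed feature-table line ", i, " in ", path)
      }
      cur <- list(seqid = seqid, kind = f[3],
                  start = min(a, b) - 1L, end = max(a, b),
                  strand = if (a <= b) "+" else "-", gene = NA_character_)
    } else if (length(f) >= 5 && !is.null(cur)) {
      if (f[4] == "gene") cur$gene <- f[5]
      if (f[4] == "transl_table") cur$transl_table <- as.integer(f[5])
    } else if (is.null(cur)) {
      stop("malformed feature-table line ", i, " in ", path)
    }
  }
  rows <- flush(cur, rows)
  if (length(rows) == 0L) return(.feature_df())
  df <- .feature_df(
    vapply(rows, `[[`, character(1), "seqid"),
    normalize_gene_names(vapply(rows, function(r)
      if (is.na(r$gene)) "" else r$gene, character(1))),
    vapply(rows, `[[`, character(1), "kind"),
    vapply(rows, `[[`, integer(1), "start"),
    vapply(rows, `[[`, integer(1), "end"),
    vapply(rows, `[[`, character(1), "strand"),
    "unknown")
  is_cds <- df$kind == "CDS"
  df$stop_completeness[is_cds] <-
    .completeness_from_length(df$end[is_cds] - df$start[is_cds])
  df
}

#' Read annotation features
#'
#' Reads CDS/gene/tRNA features from GFF3, BED or an NCBI 5-column feature
#' table and normalizes them to 0-based half-open coordinates.  Gene names
#' are canonicalized (see \code{\link{normalize_gene_names}}).  For CDS
#' features the stop completeness is inferred from the span length modulo 3
#' (0: full; 1: trailing T; 2: trailing TA), unless a GFF3
#' \code{Note=incomplete_stop:...} attribute states it explicitly.
#'
#' @param path Input file.
#' @param dialect One of \code{"gff3"}, \code{"bed"}, \code{"tbl"}.
#' @return A features data.frame with columns seqid, gene, kind, start,
#'   end, strand, stop_completeness.
#' @export
read_features <- function(path, dialect = c("gff3", "bed", "tbl")) {
  dialect <- match.arg(dialect)
  if (dialect == "tbl") return(.read_tbl(path))
  gr <- rtracklayer::import(path, format = dialect)
  if (length(gr) == 0L) return(.feature_df())
  .granges_to_features(gr)
}

#' Read approximate gene hits
#'
#' Parses the tab-separated hit table produced by the homology search:
#' columns \code{gene, strand, target_start, target_end, query_start,
#' query_end, query_length}, plus optional \code{seqid} and
#' \code{frame_anchor}.  \code{target_start}/\code{target_end} are 0-based
#' codon indices in the gene-local reading frame whose codon 0 sits at
#' genome coordinate \code{frame_anchor}; \code{query_*} are 1-based
#' amino-acid columns of the query model.
#'
#' @param path TSV file with header.
#' @return A hits data.frame with columns seqid, gene, strand, s_s, s_e,
#'   q_s, q_e, l_q, frame_anchor.
#' @export
read_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "strand", "target_start", "target_end",
            "query_start", "query_end", "query_length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("hit table lacks columns: ",
                         paste(miss, collapse = ", "))
  out <- data.frame(
    seqid = if ("seqid" %in% names(df)) as.character(df$seqid)
            else rep(NA_character_, nrow(df)),
    gene = normalize_gene_names(df$gene),
    strand = as.character(df$strand),
    s_s = as.integer(df$target_start), s_e = as.integer(df$target_end),
    q_s = as.integer(df$query_start), q_e = as.integer(df$query_end),
    l_q = as.integer(df$query_length),
    frame_anchor = if ("frame_anchor" %in% names(df))
      as.integer(df$frame_anchor) else rep(0L, nrow(df)),
    stringsAsFactors = FALSE)
  validate_hits(out)
  out
}

#' Validate hit invariants
#' @param hits A hits data.frame.
#' @return Invisibly, the hits; stops with the offending row otherwise.
#' @export
validate_hits <- function(hits) {
  if (nrow(hits) == 0L) return(invisible(hits))
  bad <- which(hits$s_s >= hits$s_e | hits$q_s < 1L |
                 hits$q_s >= hits$q_e | hits$q_e > hits$l_q |
                 !hits$strand %in% c("+", "-"))
  if (length(bad)) {
    stop("invalid hit row(s): ", paste(bad, collapse = ", "),
         " (need target_start < target_end, 1 <= query_start < query_end",
         " <= query_length, strand +/-)")
  }
  invisible(hits)
}

#' Write a hit table
#' @param hits A hits data.frame (see \code{\link{read_hits}}).
#' @param path Output TSV.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(seqid = hits$seqid, gene = hits$gene,
                    strand = hits$strand,
                    target_start = hits$s_s, target_end = hits$s_e,
                    query_start = hits$q_s, query_end = hits$q_e,
                    query_length = hits$l_q,
                    frame_anchor = hits$frame_anchor)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write predictions or features to GFF3 or BED
#'
#' Incomplete stop codons are annotated at their last covered position and
#' flagged in GFF3 with \code{Note=incomplete_stop:T} (or \code{TA}).
#' Reading the file back with \code{\link{read_features}} reproduces spans
#' and strands exactly.
#'
#' @param features A features (or prediction) data.frame with at least
#'   seqid, gene, start, end, strand; kind and stop_completeness are used
#'   when present, and a numeric \code{score} column is carried through.
#' @param path Output file.
#' @param dialect \code{"gff3"} or \code{"bed"}.
#' @export
write_predictions <- function(features, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (nrow(features) == 0L) {
    if (dialect == "gff3") writeLines("##gff-version 3", path)
    else writeLines(character(), path)
    return(invisible(path))
  }
  kind <- if ("kind" %in% names(features)) features$kind else "CDS"
  comp <- if ("stop_completeness" %in% names(features))
    features$stop_completeness else "unknown"
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- kind
  S4Vectors::mcols(gr)$phase <- ifelse(kind == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$source <- "mitoboundaries"
  S4Vectors::mcols(gr)$Name <- features$gene
  S4Vectors::mcols(gr)$ID <- paste0(features$gene, ".", seq_len(nrow(features)))
  if ("score" %in% names(features)) {
    S4Vectors::mcols(gr)$score <- features$score
  }
  note <- rep(NA_character_, nrow(features))
  inc <- comp %in% c("T", "TA")
  note[inc] <- paste0("incomplete_stop:", comp[inc])
  if (any(inc)) S4Vectors::mcols(gr)$Note <- note
  if (dialect == "bed") {
    S4Vectors::mcols(gr)$name <- features$gene
  }
  rtracklayer::export(gr, path, format = dialect)
  invisible(path)
}
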