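# The fitted boundary model: empirical codon usage (phi) plus gene length
# distributions (lambda), estimated from reference annotations, with the
# usual modelling-object methods and a versioned JSON persistence format.

STATS_SCHEMA_VERSION <- "1.0"

#' Fit the empirical boundary model from reference annotations
#'
#' Estimates, per (genetic code table, gene), the start/stop/internal
#' codon frequencies and the reference gene-length multiset that
#' parameterize \code{\link{predict_boundaries}}.  Start codons observed
#' with frequency below \code{start_min_freq} are discarded as probable
#' annotation errors, and codons whose internal frequency reaches
#' \code{internal_stop_max_freq} are rejected as stop codons.
#'
#' @param features Features data.frame of reference annotations (CDS rows
#'   are used; see \code{\link{read_features}}).
#' @param genomes Named list of \code{\link{genome}} objects, names
#'   matching the features' seqid.
#' @param start_min_freq Minimum retained start codon frequency.
#' @param internal_stop_max_freq Internal-frequency bound above which a
#'   codon cannot be a stop codon.
#' @return An object of class \code{mito_model} with components
#'   \code{usage} (\code{codon_usage}), \code{lengths}
#'   (\code{length_dist}) and \code{thresholds}.
#' @seealso \code{\link{predict.mito_model}}, \code{\link{write_stats}}
#' @examples
#' cfg <- sim_config(n_species = 3, seed = 1)
#' ref <- simulate_reference_set(cfg)
#' fit <- fit_boundary_model(ref$features, ref$genomes)
#' fit
#' @export
fit_boundary_model <- function(features, genomes, start_min_freq = 0.01,
                               internal_stop_max_freq = 0.001) {
  counts <- count_codons(features, genomes)
  usage <- build_usage_table(counts, start_min_freq = start_min_freq,
                             internal_stop_max_freq = internal_stop_max_freq)
  lengths <- build_length_distribution(features, genomes)
  structure(list(usage = usage, lengths = lengths,
                 thresholds = list(
                   start_min_freq = start_min_freq,
                   internal_stop_max_freq = internal_stop_max_freq),
                 n_species = length(unique(features$seqid)),
                 call = match.call()),
            class = "mito_model")
}

#' @export
print.mito_model <- function(x, ...) {
  cat("Empirical mitochondrial gene-boundary model\n")
  cat("  code tables:", paste(names(x$usage$tables), collapse = ", "), "\n")
  cat("  genes:",
      paste(sort(unique(unlist(lapply(x$usage$tables, names)))),
            collapse = " "), "\n")
  cat("  reference species:", x$n_species, "\n")
  cat(sprintf("  thresholds: start_min_freq=%g, internal_stop_max_freq=%g\n",
              x$thresholds$start_min_freq,
              x$thresholds$internal_stop_max_freq))
  invisible(x)
}

#' @export
summary.mito_model <- function(object, ...) {
  rows <- list()
  for (tk in names(object$usage$tables)) {
    for (gk in names(object$usage$tables[[tk]])) {
      e <- object$usage$tables[[tk]][[gk]]
      lens <- object$lengths$tables[[tk]][[gk]]
      rows[[length(rows) + 1L]] <- data.frame(
        code_table = as.integer(tk), gene = gk,
        n_start = e$n_start, n_stop = e$n_stop,
        n_starts_kept = length(e$start_freq),
        n_stops_kept = length(e$stop_freq),
        top_start = names(e$start_freq)[which.max(e$start_freq)],
        incomplete_stop_freq =
          sum(e$stop_freq[names(e$stop_freq) %in% c("TA-", "T--")]),
        median_length = if (is.null(lens)) NA_real_
                        else stats::median(lens),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("summary.mito_model", "data.frame")
  out
}

#' Extract the fitted codon frequencies
#'
#' @param object A \code{mito_model}.
#' @param ... Unused.
#' @return Long data.frame with columns code_table, gene, category
#'   (start/stop/internal), codon, freq.  Incomplete stop codons appear
#'   under the pseudo-codons \code{"TA-"} and \code{"T--"}.
#' @export
coef.mito_model <- function(object, ...) {
  rows <- list()
  for (tk in names(object$usage$tables)) {
    for (gk in names(object$usage$tables[[tk]])) {
      e <- object$usage$tables[[tk]][[gk]]
      for (cat_ in c("start_freq", "stop_freq", "internal_freq")) {
        f <- e[[cat_]]
        if (!length(f)) next
        rows[[length(rows) + 1L]] <- data.frame(
          code_table = as.integer(tk), gene = gk,
          category = sub("_freq$", "", cat_),
          codon = names(f), freq = unname(f), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Plot fitted start/stop codon frequency spectra
#'
#' Barplots of the retained start and stop codon frequencies per gene for
#' one code table, in the spirit of the usual codon-usage overview
#' figures.
#'
#' @param x A \code{mito_model}.
#' @param code_table Which code table to show (default: first fitted).
#' @param category \code{"start"} or \code{"stop"}.
#' @param ... Passed to \code{barplot}.
#' @export
plot.mito_model <- function(x, code_table = names(x$usage$tables)[1],
                            category = c("start", "stop"), ...) {
  category <- match.arg(category)
  tab <- x$usage$tables[[as.character(code_table)]]
  if (is.null(tab)) stop("model has no code table ", code_table)
  field <- paste0(category, "_freq")
  codons <- sort(unique(unlist(lapply(tab, function(e) names(e[[field]])))))
  mat <- sapply(names(tab), function(gk) {
    f <- tab[[gk]][[field]]
    out <- stats::setNames(numeric(length(codons)), codons)
    out[names(f)] <- f
    out
  })
  graphics::barplot(mat, beside = TRUE, legend.text = codons,
                    main = sprintf("%s codon frequencies (code table %s)",
                                   category, code_table),
                    ylab = "frequency", las = 2, ...)
  invisible(mat)
}

#' Predict gene boundaries for a set of approximate hits
#'
#' Applies \code{\link{predict_boundaries}} (or the legacy fixed-window
#' rule with \code{legacy = TRUE}) to every hit.
#'
#' @param object A fitted \code{mito_model}.
#' @param genomes A single \code{\link{genome}} or named list of genomes.
#' @param hits Hits data.frame (see \code{\link{read_hits}}); rows with a
#'   missing seqid are assigned to the single genome if only one is given.
#' @param trnas Optional tRNA features data.frame.
#' @param legacy Use the legacy fixed-window baseline instead.
#' @param window_aa Legacy search half-width in codons.
#' @param literal_delta_e Use the non-mirrored \eqn{r_e} form.
#' @param ... Unused.
#' @return Prediction data.frame, one row per hit, with genome spans
#'   (0-based half-open), chosen codons, stop completeness, the five
#'   score components and fallback flags.
#' @export
predict.mito_model <- function(object, genomes, hits, trnas = NULL,
                               legacy = FALSE, window_aa = 6L,
                               literal_delta_e = FALSE, ...) {
  if (inherits(genomes, "mito_genome")) {
    genomes <- stats::setNames(list(genomes), genomes$id)
  }
  validate_hits(hits)
  if (length(genomes) == 1L && anyNA(hits$seqid)) {
    hits$seqid[is.na(hits$seqid)] <- names(genomes)[1]
  }
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    hit <- hits[i, ]
    g <- genomes[[hit$seqid]]
    if (is.null(g)) stop("no genome named '", hit$seqid, "' for hit ", i)
    if (legacy) {
      legacy_predict(g, hit, window_aa = window_aa)
    } else {
      predict_boundaries(g, hit, object$usage, object$lengths,
                         trnas = trnas, literal_delta_e = literal_delta_e)
    }
  })
  do.call(rbind, rows)
}

#' Simulate reference-like mitogenomes from a fitted model
#'
#' Draws synthetic species whose start/stop codon spectra and gene
#' lengths follow the model's fitted empirical distributions (one code
#' table at a time).  Mainly useful for posterior-predictive style checks
#' of the statistics builder.
#'
#' @param object A \code{mito_model}.
#' @param nsim Number of species to simulate.
#' @param seed Optional RNG seed.
#' @param code_table Code table to draw from (default: first fitted).
#' @param ... Unused.
#' @return As \code{\link{simulate_reference_set}}.
#' @export
simulate.mito_model <- function(object, nsim = 1, seed = NULL,
                                code_table = names(object$usage$tables)[1],
                                ...) {
  tab <- object$usage$tables[[as.character(code_table)]]
  if (is.null(tab)) stop("model has no code table ", code_table)
  lens <- object$lengths$tables[[as.character(code_table)]]
  genes <- names(tab)
  norm <- function(x) x / sum(x)
  cfg <- sim_config(
    code_table = as.integer(code_table),
    n_species = nsim,
    genes = genes,
    length_mean = vapply(genes, function(gk) mean(lens[[gk]]), numeric(1)),
    length_sd = vapply(genes, function(gk)
      max(3, stats::sd(lens[[gk]])), numeric(1)),
    start_dist = lapply(genes, function(gk) norm(tab[[gk]]$start_freq)),
    stop_dist = lapply(genes, function(gk) norm(tab[[gk]]$stop_freq)),
    seed = if (is.null(seed)) 1L else seed)
  names(cfg$start_dist) <- genes
  names(cfg$stop_dist) <- genes
  simulate_reference_set(cfg)
}

#' Residual boundary errors of a prediction against a reference
#'
#' Convenience wrapper pairing predictions with reference features and
#' returning the signed start/stop differences (see
#' \code{\link{signed_difference}}).
#'
#' @param object A \code{mito_model} (unused beyond dispatch; the
#'   residuals are a property of the compared annotation sets).
#' @param predictions Prediction data.frame.
#' @param reference Reference features data.frame.
#' @param ... Unused.
#' @return data.frame with one row per matched gene pair and columns
#'   gene, seqid, d_start, d_stop.
#' @export
residuals.mito_model <- function(object, predictions, reference, ...) {
  m <- match_genes(predictions, reference)
  if (nrow(m$pairs) == 0L) {
    return(data.frame(gene = character(), seqid = character(),
                      d_start = integer(), d_stop = integer()))
  }
  data.frame(gene = m$pairs$gene, seqid = m$pairs$seqid,
             d_start = signed_difference(m$pairs, "start"),
             d_stop = signed_difference(m$pairs, "stop"),
             stringsAsFactors = FALSE)
}

#' Persist a fitted model to the versioned statistics JSON
#'
#' @param model A \code{mito_model}.
#' @param path Output JSON file.
#' @export
write_stats <- function(model, path) {
  tables <- list()
  for (tk in names(model$usage$tables)) {
    tables[[tk]] <- list()
    for (gk in names(model$usage$tables[[tk]])) {
      e <- model$usage$tables[[tk]][[gk]]
      tables[[tk]][[gk]] <- list(
        start_freq = as.list(e$start_freq),
        stop_freq = as.list(e$stop_freq),
        internal_freq = as.list(e$internal_freq),
        counts = list(n_start = e$n_start, n_stop = e$n_stop,
                      n_internal = e$n_internal),
        lengths = model$lengths$tables[[tk]][[gk]])
    }
  }
  obj <- list(schema_version = STATS_SCHEMA_VERSION,
              thresholds = model$thresholds,
              n_species = model$n_species,
              tables = tables)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a fitted model from a statistics JSON file
#'
#' @param path JSON file written by \code{\link{write_stats}} (or built
#'   elsewhere to the same schema).
#' @return A \code{mito_model}.
#' @export
read_stats <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$schema_version)) {
    stop("not a statistics file (no schema_version): ", path)
  }
  if (obj$schema_version != STATS_SCHEMA_VERSION) {
    stop("unsupported statistics schema version ", obj$schema_version,
         " (expected ", STATS_SCHEMA_VERSION, ")")
  }
  usage_tables <- list()
  length_tables <- list()
  for (tk in names(obj$tables)) {
    usage_tables[[tk]] <- list()
    length_tables[[tk]] <- list()
    for (gk in names(obj$tables[[tk]])) {
      e <- obj$tables[[tk]][[gk]]
      usage_tables[[tk]][[gk]] <- list(
        start_freq = unlist(e$start_freq),
        stop_freq = unlist(e$stop_freq),
        internal_freq = if (length(e$internal_freq))
          unlist(e$internal_freq) else numeric(),
        n_start = e$counts$n_start, n_stop = e$counts$n_stop,
        n_internal = e$counts$n_internal)
      length_tables[[tk]][[gk]] <- sort(as.numeric(unlist(e$lengths)))
    }
  }
  th <- obj$thresholds
  structure(list(
    usage = structure(list(tables = usage_tables,
                           start_min_freq = th$start_min_freq,
                           internal_stop_max_freq = th$internal_stop_max_freq,
                           stop_min_freq = 0),
                      class = "codon_usage"),
    lengths = structure(list(tables = length_tables),
                        class = "length_dist"),
    thresholds = th,
    n_species = obj$n_species,
    call = NULL), class = "mito_model")
}
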