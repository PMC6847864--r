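# Annotation comparison: bidirectional-largest-overlap gene pairing,
# strand-aware signed boundary differences, and the summary statistics
# (mean/sd of |d|, fractions of genes within 0/3/9/30 bp).

.overlap_nt <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Pair predicted and reference genes by bidirectional largest overlap
#'
#' Within each (seqid, gene, strand) group, a predicted and a reference
#' feature form a pair iff each is the other's largest-overlap partner
#' and the overlap is positive.  Unpaired features are returned as false
#' positives / false negatives.
#'
#' @param predicted,reference Features (or prediction) data.frames with
#'   seqid, gene, start, end, strand; rows with kind other than CDS are
#'   ignored when a kind column is present.
#' @return List with elements \code{pairs} (data.frame: seqid, gene,
#'   strand, pred_start, pred_end, ref_start, ref_end, overlap),
#'   \code{unmatched_pred} and \code{unmatched_ref}.
#' @export
match_genes <- function(predicted, reference) {
  keep <- function(df) {
    if ("kind" %in% names(df)) df <- df[df$kind == "CDS", , drop = FALSE]
    df
  }
  p <- keep(predicted); r <- keep(reference)
  pairs <- list()
  used_p <- rep(FALSE, nrow(p)); used_r <- rep(FALSE, nrow(r))
  keys <- unique(rbind(p[, c("seqid", "gene", "strand")],
                       r[, c("seqid", "gene", "strand")]))
  for (k in seq_len(nrow(keys))) {
    pi <- which(p$seqid == keys$seqid[k] & p$gene == keys$gene[k] &
                  p$strand == keys$strand[k])
    ri <- which(r$seqid == keys$seqid[k] & r$gene == keys$gene[k] &
                  r$strand == keys$strand[k])
    if (!length(pi) || !length(ri)) next
    ov <- outer(seq_along(pi), seq_along(ri), function(a, b)
      .overlap_nt(p$start[pi[a]], p$end[pi[a]],
                  r$start[ri[b]], r$end[ri[b]]))
    for (a in seq_along(pi)) {
      b <- which.max(ov[a, ])
      if (ov[a, b] > 0L && which.max(ov[, b]) == a) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          seqid = keys$seqid[k], gene = keys$gene[k],
          strand = keys$strand[k],
          pred_start = p$start[pi[a]], pred_end = p$end[pi[a]],
          ref_start = r$start[ri[b]], ref_end = r$end[ri[b]],
          overlap = ov[a, b], stringsAsFactors = FALSE)
        used_p[pi[a]] <- TRUE; used_r[ri[b]] <- TRUE
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(seqid = character(), gene = character(),
               strand = character(), pred_start = integer(),
               pred_end = integer(), ref_start = integer(),
               ref_end = integer(), overlap = integer())
  list(pairs = pairs,
       unmatched_pred = p[!used_p, , drop = FALSE],
       unmatched_ref = r[!used_r, , drop = FALSE])
}

#' Signed boundary difference of matched gene pairs
#'
#' Strand-aware differences in nucleotides: positive when the predicted
#' boundary lies outside the reference gene (upstream of the reference 5'
#' boundary, or downstream of the reference 3' boundary), negative when
#' inside.  On a circular genome of known length the shorter arc is
#' reported.
#'
#' @param pairs \code{pairs} data.frame from \code{\link{match_genes}}.
#' @param boundary \code{"start"} (5') or \code{"stop"} (3').
#' @param genome_length Optional named vector of genome lengths (by
#'   seqid) for shorter-arc reduction on circular genomes.
#' @return Integer vector of signed differences in bp.
#' @export
signed_difference <- function(pairs, boundary = c("start", "stop"),
                              genome_length = NULL) {
  boundary <- match.arg(boundary)
  plus <- pairs$strand == "+"
  d <- if (boundary == "start") {
    ifelse(plus, pairs$ref_start - pairs$pred_start,
           pairs$pred_end - pairs$ref_end)
  } else {
    ifelse(plus, pairs$pred_end - pairs$ref_end,
           pairs$ref_start - pairs$pred_start)
  }
  if (!is.null(genome_length)) {
    L <- unname(genome_length[pairs$seqid])
    wrap <- !is.na(L) & abs(d) > L / 2
    d[wrap] <- d[wrap] - sign(d[wrap]) * L[wrap]
  }
  as.integer(d)
}

#' Summarize boundary differences
#'
#' Computes, per boundary, the mean and standard deviation (population
#' convention, divide by N) of the absolute differences, and the fraction
#' of genes whose maximum absolute start/stop difference is at most each
#' threshold.
#'
#' @inheritParams signed_difference
#' @param thresholds Integer thresholds for the cumulative fractions.
#' @return Object of class \code{boundary_summary}: list with
#'   \code{start} and \code{stop} (each mu, sigma, d = signed vector),
#'   \code{fractions} (named numeric), \code{n}.
#' @export
summarize_differences <- function(pairs, thresholds = c(0, 3, 9, 30),
                                  genome_length = NULL) {
  if (nrow(pairs) == 0L) stop("no gene pairs to summarize")
  d_s <- signed_difference(pairs, "start", genome_length)
  d_e <- signed_difference(pairs, "stop", genome_length)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  dmax <- pmax(abs(d_s), abs(d_e))
  fr <- vapply(thresholds, function(t) mean(dmax <= t), numeric(1))
  names(fr) <- paste0("d<=", thresholds)
  structure(list(
    start = list(mu = mean(abs(d_s)), sigma = pop_sd(abs(d_s)), d = d_s),
    stop = list(mu = mean(abs(d_e)), sigma = pop_sd(abs(d_e)), d = d_e),
    fractions = fr, thresholds = thresholds, n = nrow(pairs)),
    class = "boundary_summary")
}

#' @export
print.boundary_summary <- function(x, ...) {
  cat("Boundary difference summary over", x$n, "gene pairs\n")
  cat(sprintf("  start: mu = %.2f bp, sigma = %.2f bp\n",
              x$start$mu, x$start$sigma))
  cat(sprintf("  stop:  mu = %.2f bp, sigma = %.2f bp\n",
              x$stop$mu, x$stop$sigma))
  for (i in seq_along(x$fractions)) {
    cat(sprintf("  %s: %.2f%%\n", names(x$fractions)[i],
                100 * x$fractions[i]))
  }
  invisible(x)
}

#' Cumulative difference curve on an arcsinh axis
#'
#' Table of the empirical cumulative distribution of the signed start and
#' stop differences, with the difference axis transformed by the inverse
#' hyperbolic sine (convenient for plotting heavy-tailed bp differences
#' around zero).
#'
#' @param summary A \code{boundary_summary}.
#' @return data.frame with columns d, asinh_d, cum_start, cum_stop.
#' @export
difference_curve <- function(summary) {
  d <- sort(unique(c(summary$start$d, summary$stop$d)))
  data.frame(
    d = d, asinh_d = asinh(d),
    cum_start = vapply(d, function(t) mean(summary$start$d <= t),
                       numeric(1)),
    cum_stop = vapply(d, function(t) mean(summary$stop$d <= t),
                      numeric(1)))
}

#' Write the evaluation summary as TSV
#'
#' Emits the summary block (mu/sigma per boundary plus threshold
#' fractions) followed by the raw signed-difference table.
#'
#' @param summary A \code{boundary_summary}.
#' @param pairs The pairs the summary was computed from.
#' @param path Output TSV path.
#' @export
write_summary_tsv <- function(summary, pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# metric\tstart\tstop", con)
  writeLines(sprintf("mu\t%.4f\t%.4f", summary$start$mu, summary$stop$mu),
             con)
  writeLines(sprintf("sigma\t%.4f\t%.4f", summary$start$sigma,
                     summary$stop$sigma), con)
  for (i in seq_along(summary$fractions)) {
    writeLines(sprintf("%s\t%.4f\t", names(summary$fractions)[i],
                       summary$fractions[i]), con)
  }
  writeLines("", con)
  df <- data.frame(pairs, d_start = summary$start$d,
                   d_stop = summary$stop$d)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
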