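# Core boundary predictor: candidate enumeration, the delta/phi/lambda
# factors, the constrained argmax, and the legacy fixed-window baseline.

#' In-frame center codon of an approximate hit
#'
#' @param hit One-row hits data.frame (or list) with codon indices
#'   \code{s_s}, \code{s_e}.
#' @return Integer codon index, \code{floor((s_s + s_e) / 2)}.
#' @export
center_codon <- function(hit) {
  as.integer(floor((hit$s_s + hit$s_e) / 2))
}

#' Distance factor for start candidates
#'
#' Projects a candidate codon index onto the query model axis,
#' \eqn{r_s(p) = q_s + \frac{q_e - q_s}{s_e - s_s}(p - s_s)}, and scores
#' \eqn{\delta_s(p) = 1 - r_s(p)/l_q}: the closer the candidate to the
#' model-implied 5' boundary, the closer the factor to 1.  The homology
#' hits are typically too short, so positions outside \eqn{[s_s, s_e]}
#' (in particular upstream of the hit) score 1.
#'
#' @param p Codon index (vectorized).
#' @param hit One-row hits data.frame.
#' @return Numeric vector in [0, 1].
#' @export
delta_start <- function(p, hit) {
  inside <- p >= hit$s_s & p <= hit$s_e
  r <- hit$q_s + (hit$q_e - hit$q_s) / (hit$s_e - hit$s_s) * (p - hit$s_s)
  ifelse(inside, 1 - r / hit$l_q, 1)
}

#' Distance factor for stop candidates
#'
#' Mirror image of \code{\link{delta_start}}: by default
#' \eqn{r_e(p) = (l_q - q_e) + \frac{q_e - q_s}{s_e - s_s}(s_e - p)} and
#' \eqn{\delta_e(p) = 1 - r_e(p)/l_q}, which increases towards the hit's
#' 3' end and equals 1 outside \eqn{[s_s, s_e]}.  With
#' \code{literal = TRUE} an alternative, non-mirrored form
#' \eqn{r_e(p) = (l_q - q_s) + \frac{q_e - q_s}{s_e - s_s}(p - s_s)} is
#' used; that form decreases towards the 3' end and can go negative, so
#' it is not the default (see the methods vignette).
#'
#' @inheritParams delta_start
#' @param literal Use the non-mirrored variant of \eqn{r_e}.
#' @return Numeric vector (in [0, 1] for the default form).
#' @export
delta_end <- function(p, hit, literal = FALSE) {
  inside <- p >= hit$s_s & p <= hit$s_e
  slope <- (hit$q_e - hit$q_s) / (hit$s_e - hit$s_s)
  r <- if (literal) (hit$l_q - hit$q_s) + slope * (p - hit$s_s)
       else (hit$l_q - hit$q_e) + slope * (hit$s_e - p)
  ifelse(inside, 1 - r / hit$l_q, 1)
}

# Range of codon indices holding a complete in-frame codon.  For circular
# genomes the range is centred on `at` and capped at one genome length so
# scans terminate even without any in-frame stop codon.
.codon_index_range <- function(g, strand, anchor) {
  L <- g$length
  if (g$circular) return(NULL)  # no static bound; caller caps by length
  if (strand == "+") {
    c(lo = as.integer(ceiling(-anchor / 3)),
      hi = as.integer(floor((L - anchor - 3) / 3)))
  } else {
    c(lo = as.integer(ceiling((anchor - L) / 3)),
      hi = as.integer(floor((anchor - 3) / 3)))
  }
}

# Contiguous codons for indices a..b (a <= b), one slice call.
.codon_block <- function(g, strand, anchor, a, b) {
  n <- b - a + 1L
  s <- if (strand == "+") {
    genome_slice(g, anchor + 3L * a, anchor + 3L * (b + 1L), "+")
  } else {
    genome_slice(g, anchor - 3L * (b + 1L), anchor - 3L * a, "-")
  }
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Scan in-frame codons from `from` in `direction` (+1/-1), in chunks,
# until the first full stop codon of `code` or the scan bound.  Returns
# list(p, codon, hit_stop): codons strictly before the stop, plus the
# stop itself when include_stop.
.scan_until_stop <- function(g, strand, anchor, from, direction, code,
                             include_stop, chunk = 256L) {
  rng <- .codon_index_range(g, strand, anchor)
  cap <- g$length %/% 3L  # at most one full genome length
  ps <- integer(); cods <- character(); scanned <- 0L
  at <- from
  hit_stop <- FALSE
  while (scanned < cap) {
    k <- min(chunk, cap - scanned)
    block_p <- at + direction * (0:(k - 1L))
    if (!is.null(rng)) {
      block_p <- block_p[block_p >= rng["lo"] & block_p <= rng["hi"]]
      if (length(block_p) == 0L) break
    }
    a <- min(block_p); b <- max(block_p)
    bc <- .codon_block(g, strand, anchor, a, b)
    if (direction < 0L) bc <- rev(bc)
    block_c <- bc[seq_along(block_p)]
    stopf <- is_full_stop(block_c, code) %in% TRUE
    if (any(stopf)) {
      j <- which(stopf)[1]
      keep <- seq_len(if (include_stop) j else j - 1L)
      ps <- c(ps, block_p[keep]); cods <- c(cods, block_c[keep])
      hit_stop <- TRUE
      break
    }
    ps <- c(ps, block_p); cods <- c(cods, block_c)
    scanned <- scanned + length(block_p)
    at <- at + direction * k
    if (!is.null(rng) && length(block_p) < k) break  # hit the edge
  }
  list(p = ps, codon = cods, hit_stop = hit_stop)
}

#' Enumerate start codon candidates
#'
#' Scans in-frame codons upstream from the hit's center codon until the
#' first full stop codon of the genome's code table (which delimits the
#' open reading frame and is excluded) or the sequence edge; on circular
#' genomes the scan is capped at one genome length.  Every codon in that
#' window with a positive empirical start frequency becomes a candidate.
#'
#' @param g A \code{\link{genome}}.
#' @param hit One-row hits data.frame.
#' @param code \code{genetic_code} of the genome.
#' @param usage \code{codon_usage} table.
#' @return data.frame with columns p, codon, phi_s, delta_s (possibly
#'   empty; an empty set triggers the fallback in
#'   \code{\link{predict_boundaries}}).
#' @export
enumerate_start_candidates <- function(g, hit, code, usage) {
  ctr <- center_codon(hit)
  w <- .scan_until_stop(g, hit$strand, hit$frame_anchor, ctr, -1L, code,
                        include_stop = FALSE)
  valid <- !grepl("[^ACGT]", w$codon)
  ps <- w$p[valid]; cods <- w$codon[valid]
  phi <- phi_start(usage, g$code_table, hit$gene, cods)
  sel <- phi > 0
  data.frame(p = ps[sel], codon = cods[sel], phi_s = phi[sel],
             delta_s = delta_start(ps[sel], hit),
             stringsAsFactors = FALSE)
}

#' Enumerate stop codon candidates
#'
#' Scans in-frame codons downstream from the hit's center codon up to and
#' including the nearest full stop codon (or the sequence edge / one
#' genome length on circular molecules).  At every window position up to
#' three candidates are emitted: a full-codon candidate when the codon has
#' positive stop frequency; an incomplete-TA candidate when the codon
#' starts with TA and the reference set contains incomplete TA stops; and
#' an incomplete-T candidate likewise.  Incomplete stop codons are found
#' by chance far more easily than a specific full codon, so their stored
#' frequencies are adjusted here: divided by 3 for TA (TAA is already
#' accounted among the full stops) and by 12 for T (TAN already
#' accounted).
#'
#' @inheritParams enumerate_start_candidates
#' @param literal_delta_e Use the non-mirrored \eqn{r_e} form for
#'   \code{delta_e}.
#' @return data.frame with columns p, kind ("full", "TA", "T"), key (the
#'   codon or pseudo-codon scored), phi_e (adjusted), delta_e, end_offset
#'   (3, 2 or 1 nucleotides consumed at position p).
#' @export
enumerate_stop_candidates <- function(g, hit, code, usage,
                                      literal_delta_e = FALSE) {
  ctr <- center_codon(hit)
  w <- .scan_until_stop(g, hit$strand, hit$frame_anchor, ctr, +1L, code,
                        include_stop = TRUE)
  ps <- w$p; cods <- w$codon
  rows <- list()
  if (length(ps)) {
    full_ok <- !grepl("[^ACGT]", cods)
    phi_full <- ifelse(full_ok,
                       phi_stop_raw(usage, g$code_table, hit$gene, cods), 0)
    sel <- phi_full > 0
    if (any(sel)) {
      rows[[length(rows) + 1L]] <- data.frame(
        p = ps[sel], kind = "full", key = cods[sel], phi_e = phi_full[sel],
        end_offset = 3L, stringsAsFactors = FALSE)
    }
  }
  f_ta <- phi_stop_raw(usage, g$code_table, hit$gene, "TA-")
  f_t <- phi_stop_raw(usage, g$code_table, hit$gene, "T--")
  if (f_ta > 0 || f_t > 0) {
    pre_p <- ps
    pre2 <- unname(substr(cods, 1L, 2L))
    if (!w$hit_stop && !g$circular) {
      # a partial codon at the linear 3' edge can still carry T / TA
      nxt <- if (length(ps)) max(ps) + 1L else ctr
      part <- codon_prefix(g, hit$strand, hit$frame_anchor, nxt, 2L)
      if (is.na(part)) part <- codon_prefix(g, hit$strand,
                                            hit$frame_anchor, nxt, 1L)
      if (!is.na(part) && nchar(part) > 0L) {
        pre_p <- c(pre_p, nxt)
        pre2 <- c(pre2, part)
      }
    }
    if (f_ta > 0) {
      sel <- !is.na(pre2) & pre2 == "TA"
      if (any(sel)) rows[[length(rows) + 1L]] <- data.frame(
        p = pre_p[sel], kind = "TA", key = "TA-", phi_e = f_ta / 3,
        end_offset = 2L, stringsAsFactors = FALSE)
    }
    if (f_t > 0) {
      sel <- !is.na(pre2) & substr(pre2, 1L, 1L) == "T"
      if (any(sel)) rows[[length(rows) + 1L]] <- data.frame(
        p = pre_p[sel], kind = "T", key = "T--", phi_e = f_t / 12,
        end_offset = 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(p = integer(), kind = character(), key = character(),
                      phi_e = numeric(), delta_e = numeric(),
                      end_offset = integer()))
  }
  out <- do.call(rbind, rows)
  out$delta_e <- delta_end(out$p, hit, literal = literal_delta_e)
  out <- out[order(out$p, -out$end_offset), ]
  rownames(out) <- NULL
  out[, c("p", "kind", "key", "phi_e", "delta_e", "end_offset")]
}

# Deterministic argmax over the score matrix S x E.  Ties: longer gene
# first, then start closer to s_s, then the most upstream start.
.pick_best <- function(S, E, score, hit) {
  idx <- which(score == max(score), arr.ind = TRUE)
  si <- unname(idx[, 1]); ei <- unname(idx[, 2])
  len <- 3L * (E$p[ei] - S$p[si]) + E$end_offset[ei]
  ord <- order(-len, abs(S$p[si] - hit$s_s), S$p[si], E$p[ei])
  c(s = si[ord[1]], e = ei[ord[1]])
}

.prediction_row <- function(g, hit, s_p, e_p, end_offset, start_codon,
                            stop_kind, score, comps, start_fb, stop_fb,
                            method = "probabilistic") {
  sp <- codon_span(hit$strand, hit$frame_anchor, s_p, 3L)
  ep <- codon_span(hit$strand, hit$frame_anchor, e_p, end_offset)
  raw_start <- min(sp[, "start"], ep[, "start"])
  raw_end <- max(sp[, "end"], ep[, "end"])
  nsp <- normalize_span(raw_start, raw_end, g$length, g$circular)
  data.frame(
    seqid = g$id, gene = hit$gene, kind = "CDS",
    start = as.integer(nsp[, "start"]), end = as.integer(nsp[, "end"]),
    strand = hit$strand,
    stop_completeness = switch(stop_kind, full = "full", TA = "TA",
                               T = "T", "unknown"),
    start_codon = start_codon, stop_kind = stop_kind,
    s = as.integer(s_p), e = as.integer(e_p),
    end_offset = as.integer(end_offset),
    score = score,
    delta_s = comps[1], phi_s = comps[2], delta_e = comps[3],
    phi_e = comps[4], lambda = comps[5],
    start_fallback = start_fb, stop_fallback = stop_fb,
    method = method, stringsAsFactors = FALSE)
}

#' Predict precise gene boundaries for one approximate hit
#'
#' Builds the candidate sets S (starts) and E (stops), scores every pair
#' by the product
#' \eqn{\delta_s(s)\,\phi_s(s)\,\delta_e(e)\,\phi_e(e)\,\lambda(l(s,e))}
#' with candidate gene length \eqn{l(s,e) = 3(e-s) + \mathrm{offset}(e)}
#' nucleotides, forbids pairs whose span would fully contain a tRNA
#' locus, and returns the maximizing pair.  If S (or E) is empty, or
#' every admissible product is zero, the corresponding boundary falls
#' back to the approximate hit position; the two fallbacks are
#' independent.
#'
#' @param g A \code{\link{genome}}.
#' @param hit One-row hits data.frame.
#' @param usage \code{codon_usage} table.
#' @param lengths \code{length_dist} table.
#' @param trnas Optional features data.frame of tRNA loci (at most the
#'   best locus per tRNA type).
#' @param literal_delta_e Use the non-mirrored \eqn{r_e} form.
#' @return One-row prediction data.frame (see
#'   \code{\link{predict.mito_model}} for the column contract).
#' @export
predict_boundaries <- function(g, hit, usage, lengths, trnas = NULL,
                               literal_delta_e = FALSE) {
  code <- get_genetic_code(g$code_table)
  .usage_entry(usage, g$code_table, hit$gene)
  S <- enumerate_start_candidates(g, hit, code, usage)
  E <- enumerate_stop_candidates(g, hit, code, usage,
                                 literal_delta_e = literal_delta_e)
  if (!is.null(trnas)) {
    trnas <- trnas[trnas$seqid == g$id, , drop = FALSE]
    if (nrow(trnas) == 0L) trnas <- NULL
  }

  admissible <- function(s_p, e_p, end_offset) {
    if (is.null(trnas)) return(rep(TRUE, length(s_p)))
    sp <- codon_span(hit$strand, hit$frame_anchor, s_p, 3L)
    ep <- codon_span(hit$strand, hit$frame_anchor, e_p, end_offset)
    lo <- pmin(sp[, "start"], ep[, "start"])
    hi <- pmax(sp[, "end"], ep[, "end"])
    ok <- rep(TRUE, length(s_p))
    for (j in seq_len(nrow(trnas))) {
      ok <- ok & !span_contains(lo, hi, trnas$start[j], trnas$end[j],
                                g$length, g$circular)
    }
    ok
  }

  fb_start <- nrow(S) == 0L
  fb_stop <- nrow(E) == 0L

  if (!fb_start && !fb_stop) {
    len <- outer(-3L * S$p, 3L * E$p + E$end_offset, `+`)
    lam <- matrix(lambda_pvalue(lengths, g$code_table, hit$gene,
                                as.vector(len)),
                  nrow = nrow(S))
    score <- outer(S$delta_s * S$phi_s, E$delta_e * E$phi_e) * lam
    if (!is.null(trnas)) {
      grid <- expand.grid(si = seq_len(nrow(S)), ei = seq_len(nrow(E)))
      adm <- admissible(S$p[grid$si], E$p[grid$ei], E$end_offset[grid$ei])
      score[cbind(grid$si, grid$ei)[!adm, , drop = FALSE]] <- -Inf
    }
    if (any(score > 0)) {
      best <- .pick_best(S, E, score, hit)
      si <- best[["s"]]; ei <- best[["e"]]
      return(.prediction_row(
        g, hit, S$p[si], E$p[ei], E$end_offset[ei], S$codon[si],
        E$kind[ei], score[si, ei],
        c(S$delta_s[si], S$phi_s[si], E$delta_e[ei], E$phi_e[ei],
          lam[si, ei]),
        start_fb = FALSE, stop_fb = FALSE))
    }
    fb_start <- TRUE; fb_stop <- TRUE
  }

  if (fb_start && nrow(E) > 0L) {
    # start anchored at the hit; stop scored with delta_s * phi_s dropped
    len <- 3L * (E$p - hit$s_s) + E$end_offset
    lam <- lambda_pvalue(lengths, g$code_table, hit$gene, len)
    sc <- E$delta_e * E$phi_e * lam
    sc[!admissible(rep(hit$s_s, nrow(E)), E$p, E$end_offset)] <- -Inf
    if (any(sc > 0)) {
      ei <- order(-sc, -(E$p - hit$s_s), E$p)[1]
      cod <- .codon_block(g, hit$strand, hit$frame_anchor, hit$s_s, hit$s_s)
      return(.prediction_row(
        g, hit, hit$s_s, E$p[ei], E$end_offset[ei], cod, E$kind[ei],
        sc[ei], c(NA, NA, E$delta_e[ei], E$phi_e[ei], lam[ei]),
        start_fb = TRUE, stop_fb = FALSE))
    }
  }
  if (fb_stop && !fb_start) {
    len <- 3L * (hit$s_e - S$p) + 3L
    lam <- lambda_pvalue(lengths, g$code_table, hit$gene, len)
    sc <- S$delta_s * S$phi_s * lam
    sc[!admissible(S$p, rep(hit$s_e, nrow(S)), 3L)] <- -Inf
    if (any(sc > 0)) {
      si <- order(-sc, abs(S$p - hit$s_s), S$p)[1]
      return(.prediction_row(
        g, hit, S$p[si], hit$s_e, 3L, S$codon[si], "unknown", sc[si],
        c(S$delta_s[si], S$phi_s[si], NA, NA, lam[si]),
        start_fb = FALSE, stop_fb = TRUE))
    }
  }

  # both boundaries fall back to the approximate hit positions
  cod <- .codon_block(g, hit$strand, hit$frame_anchor, hit$s_s, hit$s_s)
  .prediction_row(g, hit, hit$s_s, hit$s_e, 3L, cod, "unknown",
                  NA_real_, rep(NA_real_, 5),
                  start_fb = TRUE, stop_fb = TRUE)
}

#' Legacy fixed-window boundary prediction
#'
#' The original strategy: look for a canonical start codon within
#' \code{window_aa} codons of the approximate start, and a canonical full
#' stop codon within \code{window_aa} codons of the approximate stop, and
#' take the nearest (at equal distance the upstream codon wins).  If none
#' is found the approximate position itself is used.  Incomplete stop
#' codons and empirical codon frequencies play no role here.
#'
#' @inheritParams enumerate_start_candidates
#' @param window_aa Search half-width in codons (default 6).
#' @return One-row prediction data.frame with \code{method = "legacy"}.
#' @export
legacy_predict <- function(g, hit, code = get_genetic_code(g$code_table),
                           window_aa = 6L) {
  rng <- .codon_index_range(g, hit$strand, hit$frame_anchor)
  nearest <- function(center, want_stop) {
    ps <- center + (-window_aa):window_aa
    if (!is.null(rng)) ps <- ps[ps >= rng["lo"] & ps <= rng["hi"]]
    if (length(ps) == 0L) return(NULL)
    cods <- .codon_block(g, hit$strand, hit$frame_anchor, min(ps), max(ps))
    ok <- !grepl("[^ACGT]", cods)
    match_ <- if (want_stop) {
      ok & is_full_stop(ifelse(ok, cods, "AAA"), code) %in% TRUE
    } else {
      ok & is_canonical_start(ifelse(ok, cods, "AAA"), code) %in% TRUE
    }
    if (!any(match_)) return(NULL)
    cand <- ps[match_]
    d <- abs(cand - center)
    cand[order(d, cand)][1]  # nearest; upstream wins ties
  }
  s_p <- nearest(hit$s_s, FALSE)
  e_p <- nearest(hit$s_e, TRUE)
  start_fb <- is.null(s_p); stop_fb <- is.null(e_p)
  if (start_fb) s_p <- hit$s_s
  if (stop_fb) e_p <- hit$s_e
  cod_s <- .codon_block(g, hit$strand, hit$frame_anchor, s_p, s_p)
  .prediction_row(g, hit, s_p, e_p, 3L, cod_s,
                  if (stop_fb) "unknown" else "full",
                  NA_real_, rep(NA_real_, 5),
                  start_fb = start_fb, stop_fb = stop_fb,
                  method = "legacy")
}
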