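# Independent exhaustive scorer used as the oracle for the boundary
# predictor.  Deliberately written from scratch with plain per-codon
# loops and its own coordinate arithmetic: it shares no helper with the
# package's candidate enumeration or scoring path.

oracle_codon <- function(g, strand, anchor, p, k = 3L) {
  L <- nchar(g$sequence)
  idx <- if (strand == "+") anchor + 3 * p + seq_len(k) - 1
         else anchor - 3 * p - seq_len(k)
  if (g$circular) {
    idx <- idx %% L
  } else if (any(idx < 0 | idx >= L)) {
    return(NA_character_)
  }
  bases <- substring(g$sequence, idx + 1, idx + 1)
  if (strand == "-") {
    bases <- chartr("ACGTN", "TGCAN", bases)
  }
  paste(bases, collapse = "")
}

oracle_lambda <- function(lens, l) {
  le <- 0; ge <- 0
  for (x in lens) {
    if (x <= l) le <- le + 1
    if (x >= l) ge <- ge + 1
  }
  2 * min(le, ge) / (le + ge)
}

oracle_delta_s <- function(p, hit) {
  if (p < hit$s_s || p > hit$s_e) return(1)
  r <- hit$q_s + (hit$q_e - hit$q_s) / (hit$s_e - hit$s_s) * (p - hit$s_s)
  1 - r / hit$l_q
}

oracle_delta_e <- function(p, hit) {
  if (p < hit$s_s || p > hit$s_e) return(1)
  r <- (hit$l_q - hit$q_e) +
    (hit$q_e - hit$q_s) / (hit$s_e - hit$s_s) * (hit$s_e - p)
  1 - r / hit$l_q
}

# forward-axis nucleotide span of the candidate pair, unwrapped
oracle_span <- function(strand, anchor, s, e, off) {
  if (strand == "+") c(anchor + 3 * s, anchor + 3 * e + off)
  else c(anchor - 3 * e - off, anchor - 3 * s)
}

oracle_contains <- function(span, t_start, t_end, L, circular) {
  for (shift in if (circular) c(-L, 0, L) else 0) {
    if (t_start + shift >= span[1] && t_end + shift <= span[2]) return(TRUE)
  }
  FALSE
}

# Exhaustive enumeration of every admissible in-frame (s, e) pair, all
# five factors recomputed from scratch; returns the argmax under the same
# deterministic tie rules (longer gene, start nearer s_s, most upstream).
oracle_predict <- function(g, hit, usage, lengths, trnas = NULL) {
  code <- get_genetic_code(g$code_table)
  stops <- code$stops
  entry <- usage$tables[[as.character(g$code_table)]][[hit$gene]]
  lens <- lengths$tables[[as.character(g$code_table)]][[hit$gene]]
  ctr <- (hit$s_s + hit$s_e) %/% 2
  cap <- nchar(g$sequence) %/% 3

  S <- list()
  p <- ctr
  while (ctr - p < cap) {
    cod <- oracle_codon(g, hit$strand, hit$frame_anchor, p)
    if (is.na(cod)) break
    if (cod %in% stops) break
    f <- entry$start_freq[cod]
    if (!is.na(f) && f > 0) S[[length(S) + 1]] <- list(p = p, codon = cod,
                                                       phi = unname(f))
    p <- p - 1
  }

  E <- list()
  p <- ctr
  while (p - ctr < cap) {
    cod <- oracle_codon(g, hit$strand, hit$frame_anchor, p)
    if (is.na(cod)) {
      pre <- oracle_codon(g, hit$strand, hit$frame_anchor, p, 2L)
      if (is.na(pre)) pre <- oracle_codon(g, hit$strand, hit$frame_anchor,
                                          p, 1L)
      if (!is.na(pre)) {
        f <- entry$stop_freq["TA-"]
        if (pre == "TA" && !is.na(f) && f > 0) {
          E[[length(E) + 1]] <- list(p = p, kind = "TA", phi = unname(f) / 3,
                                     off = 2)
        }
        f <- entry$stop_freq["T--"]
        if (substr(pre, 1, 1) == "T" && !is.na(f) && f > 0) {
          E[[length(E) + 1]] <- list(p = p, kind = "T", phi = unname(f) / 12,
                                     off = 1)
        }
      }
      break
    }
    f <- entry$stop_freq[cod]
    if (!is.na(f) && f > 0) {
      E[[length(E) + 1]] <- list(p = p, kind = "full", phi = unname(f),
                                 off = 3)
    }
    f <- entry$stop_freq["TA-"]
    if (substr(cod, 1, 2) == "TA" && !is.na(f) && f > 0) {
      E[[length(E) + 1]] <- list(p = p, kind = "TA", phi = unname(f) / 3,
                                 off = 2)
    }
    f <- entry$stop_freq["T--"]
    if (substr(cod, 1, 1) == "T" && !is.na(f) && f > 0) {
      E[[length(E) + 1]] <- list(p = p, kind = "T", phi = unname(f) / 12,
                                 off = 1)
    }
    if (cod %in% stops) break
    p <- p + 1
  }

  L <- nchar(g$sequence)
  trnas <- if (is.null(trnas)) NULL else
    trnas[trnas$seqid == g$id, , drop = FALSE]
  best <- NULL
  for (sc in S) {
    for (ec in E) {
      len <- 3 * (ec$p - sc$p) + ec$off
      span <- oracle_span(hit$strand, hit$frame_anchor, sc$p, ec$p, ec$off)
      blocked <- FALSE
      if (!is.null(trnas) && nrow(trnas)) {
        for (j in seq_len(nrow(trnas))) {
          if (oracle_contains(span, trnas$start[j], trnas$end[j], L,
                              g$circular)) {
            blocked <- TRUE
            break
          }
        }
      }
      if (blocked) next
      score <- oracle_delta_s(sc$p, hit) * sc$phi *
        oracle_delta_e(ec$p, hit) * ec$phi * oracle_lambda(lens, len)
      if (score <= 0) next
      cand <- list(s = sc$p, e = ec$p, off = ec$off, kind = ec$kind,
                   score = score, len = len)
      if (is.null(best)) {
        best <- cand
      } else {
        d <- score - best$score
        take <- FALSE
        if (d > 1e-15 * max(score, best$score)) take <- TRUE
        else if (abs(d) <= 1e-15 * max(score, best$score)) {
          if (cand$len > best$len) take <- TRUE
          else if (cand$len == best$len) {
            if (abs(cand$s - hit$s_s) < abs(best$s - hit$s_s)) take <- TRUE
            else if (abs(cand$s - hit$s_s) == abs(best$s - hit$s_s) &&
                       cand$s < best$s) take <- TRUE
            else if (cand$s == best$s && cand$e < best$e) take <- TRUE
          }
        }
        if (take) best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)  # fallback territory
  best
}
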