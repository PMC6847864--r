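# Small deterministic fixtures, built in code.

# A hand-made usage table for one (code_table, gene) key.
make_usage <- function(code_table = 2, gene = "nad3",
                       start_freq = c(ATG = 0.8, ATA = 0.2),
                       stop_freq = c(TAA = 0.6, TAG = 0.2,
                                     "TA-" = 0.06, "T--" = 0.14),
                       internal_freq = numeric()) {
  tables <- list()
  tables[[as.character(code_table)]] <- stats::setNames(
    list(list(start_freq = start_freq, stop_freq = stop_freq,
              internal_freq = internal_freq,
              n_start = 100L, n_stop = 100L, n_internal = 1000L)),
    gene)
  structure(list(tables = tables, start_min_freq = 0.01,
                 internal_stop_max_freq = 0.001, stop_min_freq = 0),
            class = "codon_usage")
}

make_lengths <- function(code_table = 2, gene = "nad3", lens) {
  tables <- list()
  tables[[as.character(code_table)]] <- stats::setNames(
    list(sort(lens)), gene)
  structure(list(tables = tables), class = "length_dist")
}

make_hit <- function(gene = "nad3", strand = "+", s_s, s_e, q_s, q_e,
                     l_q, frame_anchor = 0L, seqid = "g") {
  data.frame(seqid = seqid, gene = gene, strand = strand,
             s_s = s_s, s_e = s_e, q_s = q_s, q_e = q_e, l_q = l_q,
             frame_anchor = frame_anchor, stringsAsFactors = FALSE)
}

# Assemble a plus-strand single-gene genome: upstream, cds, downstream.
make_gene_genome <- function(upstream, cds, downstream, circular = FALSE,
                             code_table = 2, id = "g") {
  g <- genome(id, paste0(upstream, cds, downstream), circular = circular,
              code_table = code_table)
  attr(g, "cds_start") <- nchar(upstream)
  attr(g, "cds_end") <- nchar(upstream) + nchar(cds)
  g
}

rand_dna <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}
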