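# Synthetic mitogenome generator: genomes with known-truth PCG
# annotations, interleaved tRNA loci in the manner of the tRNA
# punctuation arrangement, and shortened approximate hits emulating the
# homology search's bias towards too-short predictions.

# Typical metazoan mitochondrial PCG lengths (nt), used as generator
# defaults.
.DEFAULT_LENGTH_MEAN <- c(
  atp6 = 681, atp8 = 165, cob = 1140, cox1 = 1545, cox2 = 684,
  cox3 = 784, nad1 = 957, nad2 = 1042, nad3 = 348, nad4 = 1378,
  nad4l = 297, nad5 = 1812, nad6 = 525)

.default_start_dist <- function(code) {
  w <- c(ATG = 0.70, ATA = 0.12, ATT = 0.06, ATC = 0.03, GTG = 0.05,
         TTG = 0.04)
  w <- w[names(w) %in% code$starts]
  w / sum(w)
}

.default_stop_dist <- function(code) {
  w <- c(TAA = 0.40, TAG = 0.15, AGA = 0.10, AGG = 0.03)
  w <- w[names(w) %in% code$stops]
  # incomplete stops: T is observed more often than TA
  w <- c(w, "TA-" = 0.10, "T--" = 0.22)
  w / sum(w)
}

#' Configuration for the synthetic mitogenome generator
#'
#' Defaults emulate a vertebrate-like (code table 2) reference set:
#' ATG-dominated start codons with the rest of the ATN box and GTG at
#' lower frequency, TAR/AGR full stops plus incomplete stops (T more
#' frequent than TA), typical PCG lengths with a few percent spread
#' between species, AT-rich internal composition free of in-frame stop
#' codons, tRNA loci interleaved between genes, and hits shrunk by up to
#' \code{shrink_max} codons at either end.
#'
#' @param code_table NCBI table number.
#' @param n_species Number of species to simulate.
#' @param genes Gene symbols to place, in genome order.
#' @param length_mean,length_sd Named (or recycled) per-gene mean and sd
#'   of gene length in nucleotides.
#' @param start_dist Named probability vector over start codons, or a
#'   per-gene list of such vectors.
#' @param stop_dist Named probability vector over stop codons, with
#'   incomplete stops as \code{"TA-"} and \code{"T--"}; or a per-gene
#'   list.
#' @param base_probs Background base composition for internal codons and
#'   intergenic sequence (AT-rich by default).
#' @param prob_minus Probability that a gene lies on the minus strand.
#' @param trna_len tRNA locus length (nt).
#' @param trna_between_prob Probability of a tRNA locus between
#'   consecutive genes.
#' @param spacer_max Maximum random spacer length (nt) between loci.
#' @param shrink_min,shrink_max Bounds (codons) of the uniform hit
#'   truncation at each gene end.
#' @param circular Simulate circular genomes?
#' @param species_offset Index offset for the deterministic per-species
#'   RNG substreams (lets a test set extend a training set without
#'   duplicating species).
#' @param seed Global RNG seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(code_table = 2L, n_species = 10L,
                       genes = pcg_names(),
                       length_mean = .DEFAULT_LENGTH_MEAN[genes],
                       length_sd = pmax(3, 0.04 * length_mean),
                       start_dist = NULL, stop_dist = NULL,
                       base_probs = c(A = 0.32, C = 0.22, G = 0.13,
                                      T = 0.33),
                       prob_minus = 0.15, trna_len = 70L,
                       trna_between_prob = 0.8, spacer_max = 5L,
                       shrink_min = 0L, shrink_max = 10L,
                       circular = TRUE, species_offset = 0L, seed = 1L) {
  code <- get_genetic_code(code_table)
  if (is.null(start_dist)) start_dist <- .default_start_dist(code)
  if (is.null(stop_dist)) stop_dist <- .default_stop_dist(code)
  if (is.null(names(length_mean))) names(length_mean) <- genes
  length_sd <- rep_len(length_sd, length(genes))
  names(length_sd) <- genes
  check_dist <- function(d, what) {
    dd <- if (is.list(d)) d else list(d)
    for (x in dd) {
      if (abs(sum(x) - 1) > 1e-8) {
        stop(what, " probabilities must sum to 1")
      }
    }
  }
  check_dist(start_dist, "start codon")
  check_dist(stop_dist, "stop codon")
  if (any(length_mean < 9)) stop("gene lengths below 9 nt not representable")
  structure(list(
    code_table = as.integer(code_table), n_species = as.integer(n_species),
    genes = genes, length_mean = length_mean, length_sd = length_sd,
    start_dist = start_dist, stop_dist = stop_dist,
    base_probs = base_probs / sum(base_probs),
    prob_minus = prob_minus, trna_len = as.integer(trna_len),
    trna_between_prob = trna_between_prob,
    spacer_max = as.integer(spacer_max),
    shrink_min = as.integer(shrink_min),
    shrink_max = as.integer(shrink_max),
    circular = isTRUE(circular),
    species_offset = as.integer(species_offset),
    seed = as.integer(seed)), class = "sim_config")
}

.gene_dist <- function(dist, gene) {
  if (is.list(dist)) dist[[gene]] else dist
}

# deterministic per-species RNG substream
.species_seed <- function(cfg, i) {
  as.integer((as.numeric(cfg$seed) * 1000003 +
                (cfg$species_offset + i) * 2654435) %% 2147483647)
}

.random_seq <- function(n, base_probs) {
  if (n <= 0L) return("")
  paste(sample(names(base_probs), n, replace = TRUE, prob = base_probs),
        collapse = "")
}

# Internal codons drawn from the background composition conditioned on
# not being a full stop codon of the table (rejection sampling,
# vectorized).
.internal_codons <- function(n, code, base_probs) {
  if (n <= 0L) return(character())
  draw <- function(k) {
    m <- matrix(sample(names(base_probs), 3L * k, replace = TRUE,
                       prob = base_probs), nrow = 3L)
    paste0(m[1, ], m[2, ], m[3, ])
  }
  out <- draw(n)
  bad <- out %in% code$stops
  while (any(bad)) {
    out[bad] <- draw(sum(bad))
    bad <- out %in% code$stops
  }
  out
}

.TRNA_NAMES <- paste0("trn", c("F", "V", "L1", "I", "Q", "M", "W", "A",
                               "N", "C", "Y", "S1", "D", "K", "G", "R",
                               "H", "S2", "L2", "E", "T", "P"))

#' Simulate a reference set of mitogenome-like species
#'
#' Each species genome carries the configured genes in order, every CDS
#' assembled as a sampled start codon, stop-free internal codons, and a
#' sampled (possibly incomplete) stop codon, with tRNA loci and short
#' random spacers interleaved.  Truth annotations are returned alongside.
#' The same seed always yields the same output; species draw from
#' deterministic per-species substreams.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{genomes} (named list of \code{\link{genome}})
#'   and \code{features} (truth CDS + tRNA features data.frame).
#' @export
simulate_reference_set <- function(cfg) {
  code <- get_genetic_code(cfg$code_table)
  genomes <- list()
  feats <- list()
  for (i in seq_len(cfg$n_species)) {
    set.seed(.species_seed(cfg, i))
    sid <- sprintf("sim%04d", cfg$species_offset + i)
    chunks <- character(); pos <- 0L
    trna_pool <- .TRNA_NAMES
    add <- function(s) {
      chunks[[length(chunks) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    for (gi in seq_along(cfg$genes)) {
      gene <- cfg$genes[gi]
      add(.random_seq(sample(0:cfg$spacer_max, 1L), cfg$base_probs))
      if (length(trna_pool) &&
            stats::runif(1) < cfg$trna_between_prob) {
        tn <- trna_pool[1L]; trna_pool <- trna_pool[-1L]
        t_start <- pos
        add(.random_seq(cfg$trna_len, cfg$base_probs))
        feats[[length(feats) + 1L]] <- data.frame(
          seqid = sid, gene = tolower(tn), kind = "tRNA",
          start = t_start, end = pos,
          strand = if (stats::runif(1) < 0.5) "+" else "-",
          stop_completeness = "unknown", stringsAsFactors = FALSE)
        add(.random_seq(sample(0:cfg$spacer_max, 1L), cfg$base_probs))
      }
      sd_ <- .gene_dist(cfg$start_dist, gene)
      ed_ <- .gene_dist(cfg$stop_dist, gene)
      start_codon <- sample(names(sd_), 1L, prob = sd_)
      stop_key <- sample(names(ed_), 1L, prob = ed_)
      stop_nt <- sub("-+$", "", stop_key)
      target <- stats::rnorm(1, cfg$length_mean[gene],
                             cfg$length_sd[gene])
      n_aa <- max(3L, round((target - nchar(stop_nt)) / 3))
      cds <- paste0(start_codon,
                    paste(.internal_codons(n_aa - 1L, code,
                                           cfg$base_probs),
                          collapse = ""),
                    stop_nt)
      strand <- if (stats::runif(1) < cfg$prob_minus) "-" else "+"
      g_start <- pos
      add(if (strand == "+") cds else revcomp(cds))
      feats[[length(feats) + 1L]] <- data.frame(
        seqid = sid, gene = gene, kind = "CDS",
        start = g_start, end = pos, strand = strand,
        stop_completeness = c("full", "T", "TA")[nchar(cds) %% 3L + 1L],
        stringsAsFactors = FALSE)
    }
    add(.random_seq(20L + sample(0:cfg$spacer_max, 1L), cfg$base_probs))
    genomes[[sid]] <- genome(sid, paste(chunks, collapse = ""),
                             circular = cfg$circular,
                             code_table = cfg$code_table)
  }
  list(genomes = genomes, features = do.call(rbind, feats))
}

#' Simulate shortened approximate hits from truth annotations
#'
#' Emulates the homology search's systematic bias: each hit lies inside
#' its true gene, truncated at both ends by amounts drawn uniformly from
#' \code{[shrink_min, shrink_max]} codons, with the query-model
#' coordinates set consistently (\code{q_s = 1 + } 5' shrink,
#' \code{q_e = l_q - } 3' shrink, \code{l_q} = the gene's amino-acid
#' count).
#'
#' @param truth Features data.frame (CDS rows used).
#' @param cfg A \code{\link{sim_config}}.
#' @return Hits data.frame (see \code{\link{read_hits}}).
#' @export
simulate_hits <- function(truth, cfg) {
  cds <- truth[truth$kind == "CDS", , drop = FALSE]
  set.seed(as.integer((.species_seed(cfg, 0) + 999983) %% 2147483647))
  rows <- lapply(seq_len(nrow(cds)), function(i) {
    f <- cds[i, ]
    len <- f$end - f$start
    stop_len <- c(3L, 1L, 2L)[len %% 3L + 1L]
    n_aa <- (len - stop_len) %/% 3L
    sh5 <- sample(cfg$shrink_min:cfg$shrink_max, 1L)
    sh3 <- sample(cfg$shrink_min:cfg$shrink_max, 1L)
    # keep at least two codons of hit
    while (sh5 + sh3 > n_aa - 2L) {
      if (sh3 >= sh5) sh3 <- sh3 - 1L else sh5 <- sh5 - 1L
    }
    data.frame(
      seqid = f$seqid, gene = f$gene, strand = f$strand,
      s_s = sh5, s_e = n_aa - 1L - sh3,
      q_s = 1L + sh5, q_e = n_aa - sh3, l_q = n_aa,
      frame_anchor = if (f$strand == "+") f$start else f$end,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train/test recovery experiment on synthetic data
#'
#' Fits the boundary model on one simulated reference set, simulates
#' fresh test species and shrunken hits, predicts boundaries with both
#' the probabilistic method and the legacy fixed-window baseline, and
#' evaluates against the known truth.
#'
#' @param cfg Training \code{\link{sim_config}}.
#' @param n_test Number of fresh test species.
#' @param window_aa Legacy search half-width.
#' @return List with the fitted \code{model}, the test \code{summary}
#'   (class \code{boundary_summary}), exact recovery fractions
#'   \code{start_recovery} / \code{stop_recovery} (and
#'   \code{legacy_*} counterparts), and the matched pair count \code{n}.
#' @export
recovery_experiment <- function(cfg, n_test = 20L, window_aa = 6L) {
  train <- simulate_reference_set(cfg)
  model <- fit_boundary_model(train$features, train$genomes)
  test_cfg <- cfg
  test_cfg$n_species <- as.integer(n_test)
  test_cfg$species_offset <- cfg$species_offset + cfg$n_species
  test <- simulate_reference_set(test_cfg)
  hits <- simulate_hits(test$features, test_cfg)
  trnas <- test$features[test$features$kind == "tRNA", , drop = FALSE]
  truth <- test$features[test$features$kind == "CDS", , drop = FALSE]
  run <- function(legacy) {
    pred <- predict(model, test$genomes, hits, trnas = trnas,
                    legacy = legacy, window_aa = window_aa)
    m <- match_genes(pred, truth)
    s <- summarize_differences(m$pairs)
    list(pred = pred, pairs = m$pairs, summary = s,
         start_recovery = mean(s$start$d == 0),
         stop_recovery = mean(s$stop$d == 0))
  }
  new <- run(FALSE)
  old <- run(TRUE)
  list(model = model, summary = new$summary,
       start_recovery = new$start_recovery,
       stop_recovery = new$stop_recovery,
       legacy_summary = old$summary,
       legacy_start_recovery = old$start_recovery,
       legacy_stop_recovery = old$stop_recovery,
       n = nrow(new$pairs),
       predictions = new$pred, legacy_predictions = old$pred,
       truth = truth)
}
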