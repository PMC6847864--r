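test_that("the center codon is the floor of the hit midpoint", {
  expect_equal(center_codon(list(s_s = 0, s_e = 100)), 50L)
  expect_equal(center_codon(list(s_s = 3, s_e = 4)), 3L)
  expect_equal(center_codon(list(s_s = 10, s_e = 11)), 10L)
})

test_that("delta factors match direct substitution and the outside rule", {
  hit <- make_hit(s_s = 0, s_e = 80, q_s = 10, q_e = 90, l_q = 100)
  expect_equal(delta_start(0, hit), 0.9)    # r_s = 10
  expect_equal(delta_start(80, hit), 0.1)   # r_s = 90
  expect_equal(delta_start(-5, hit), 1.0)   # upstream of the hit
  expect_equal(delta_end(80, hit), 0.9)     # r_e = 10
  expect_equal(delta_end(0, hit), 0.1)      # r_e = 90
  expect_equal(delta_end(95, hit), 1.0)     # downstream of the hit
  # the non-mirrored variant decreases towards the 3' end instead
  expect_equal(delta_end(0, hit, literal = TRUE), 0.1)
  expect_equal(delta_end(80, hit, literal = TRUE), 1 - 170 / 100)
})

test_that("delta is bounded and monotone over random hits", {
  set.seed(42)
  for (i in 1:200) {
    l_q <- sample(40:400, 1)
    q_s <- sample(1:(l_q - 2), 1)
    q_e <- sample((q_s + 1):l_q, 1)
    span <- sample(2:150, 1)
    s_s <- sample(0:50, 1)
    hit <- make_hit(s_s = s_s, s_e = s_s + span, q_s = q_s, q_e = q_e,
                    l_q = l_q)
    p <- (s_s - 5):(s_s + span + 5)
    ds <- delta_start(p, hit)
    de <- delta_end(p, hit)
    expect_true(all(ds >= 0 & ds <= 1))
    expect_true(all(de >= 0 & de <= 1))
    inside <- p >= hit$s_s & p <= hit$s_e
    expect_true(all(diff(ds[inside]) <= 1e-12))
    expect_true(all(diff(de[inside]) >= -1e-12))
    expect_true(all(ds[!inside] == 1) && all(de[!inside] == 1))
  }
})

test_that("start candidates stop at the delimiting upstream stop codon", {
  # codon layout (plus strand, anchor 0): indices 0..24
  cods <- rep("GGG", 25)
  cods[8 + 1] <- "TAA"   # codon index 8: upstream in-frame stop
  cods[10 + 1] <- "ATG"  # index 10: a start inside the window
  cods[5 + 1] <- "ATG"   # index 5, behind the stop: must be excluded
  cods[12 + 1] <- "ATT"  # index 12: phi_s = 0 under this usage table
  g <- genome("g", paste(cods, collapse = ""), circular = FALSE)
  hit <- make_hit(s_s = 12, s_e = 20, q_s = 3, q_e = 60, l_q = 70)
  usage <- make_usage(start_freq = c(ATG = 0.9, ATA = 0.1))
  S <- enumerate_start_candidates(g, hit, get_genetic_code(2), usage)
  expect_true(10 %in% S$p)
  expect_false(5 %in% S$p)
  expect_false(8 %in% S$p)
  expect_false(12 %in% S$p)  # ATT has no start frequency here
  expect_true(all(S$phi_s > 0))
})

test_that("stop candidates include the delimiting stop and apply /3 and /12", {
  cods <- rep("GGG", 30)
  cods[20 + 1] <- "TAC"  # index 20: TA prefix
  cods[22 + 1] <- "TGG"  # index 22: T prefix
  cods[25 + 1] <- "TAA"  # index 25: nearest full stop (TA/T prefixed too)
  g <- genome("g", paste(cods, collapse = ""), circular = FALSE)
  hit <- make_hit(s_s = 5, s_e = 27, q_s = 1, q_e = 60, l_q = 60)
  usage <- make_usage(stop_freq = c(TAA = 0.6, "TA-" = 0.6, "T--" = 0.6))
  E <- enumerate_stop_candidates(g, hit, get_genetic_code(2), usage)
  full <- E[E$kind == "full", ]
  expect_equal(full$p, 25L)
  expect_equal(full$phi_e, 0.6)
  expect_equal(max(E$p), 25L)  # scan ends at the nearest stop, inclusive
  ta <- E[E$kind == "TA", ]
  expect_true(all(c(20, 25) %in% ta$p))
  expect_equal(unique(ta$phi_e), 0.6 / 3)
  tt <- E[E$kind == "T", ]
  expect_true(all(c(20, 22, 25) %in% tt$p))
  expect_equal(unique(tt$phi_e), 0.6 / 12)
  expect_equal(unname(c(table(E$end_offset)[c("1", "2", "3")])),
               c(nrow(tt), nrow(ta), nrow(full)))
})

test_that("candidate scans terminate on circular genomes without stops", {
  g <- genome("g", strrep("GGGATG", 20), circular = TRUE)
  hit <- make_hit(s_s = 2, s_e = 30, q_s = 1, q_e = 35, l_q = 40)
  usage <- make_usage(start_freq = c(ATG = 1))
  S <- enumerate_start_candidates(g, hit, get_genetic_code(2), usage)
  expect_lte(nrow(S), g$length %/% 3)
  expect_gt(nrow(S), 0)
  E <- enumerate_stop_candidates(g, hit, get_genetic_code(2), usage)
  expect_true(nrow(E) >= 0)  # no stop frequencies here: empty is fine
})

test_that("predict_boundaries returns the single admissible pair and its score", {
  # one ATG upstream of the hit, one TAA downstream, nothing else scores
  cods <- rep("GGG", 40)
  cods[4 + 1] <- "ATG"
  cods[30 + 1] <- "TAA"
  g <- genome("g", paste(cods, collapse = ""), circular = FALSE)
  hit <- make_hit(s_s = 10, s_e = 25, q_s = 8, q_e = 24, l_q = 30)
  usage <- make_usage(start_freq = c(ATG = 0.8),
                      stop_freq = c(TAA = 0.7))
  lens <- make_lengths(lens = c(70, 78, 81, 90))
  pred <- predict_boundaries(g, hit, usage, lens)
  expect_equal(pred$s, 4L)
  expect_equal(pred$e, 30L)
  expect_equal(pred$start, 12L)
  expect_equal(pred$end, 93L)
  expect_equal(pred$stop_kind, "full")
  lam <- lambda_pvalue(lens, 2, "nad3", 3 * (30 - 4) + 3)
  expect_equal(pred$score, 1 * 0.8 * 1 * 0.7 * lam)
  expect_false(pred$start_fallback || pred$stop_fallback)
})

test_that("pairs spanning a tRNA locus are forbidden", {
  cods <- rep("GGG", 40)
  cods[2 + 1] <- "ATG"; cods[12 + 1] <- "ATG"; cods[30 + 1] <- "TAA"
  g <- genome("g", paste(cods, collapse = ""), circular = FALSE)
  hit <- make_hit(s_s = 14, s_e = 26, q_s = 4, q_e = 28, l_q = 32)
  usage <- make_usage(start_freq = c(ATG = 0.8), stop_freq = c(TAA = 0.7))
  lens <- make_lengths(lens = c(57, 60, 87, 90))
  free <- predict_boundaries(g, hit, usage, lens)
  expect_equal(free$s, 2L)  # longer pair wins without the constraint
  trna <- data.frame(seqid = "g", gene = "trnf", kind = "tRNA",
                     start = 18L, end = 30L, strand = "+",
                     stop_completeness = "unknown")
  constrained <- predict_boundaries(g, hit, usage, lens, trnas = trna)
  expect_equal(constrained$s, 12L)
  # partial overlap is still allowed
  trna2 <- within(trna, start <- 0L)
  partial <- predict_boundaries(g, hit, usage, lens, trnas = trna2)
  expect_equal(partial$s, 2L)
})

test_that("empty candidate sets fall back to the hit boundaries independently", {
  cods <- rep("GGG", 40); cods[30 + 1] <- "TAA"
  g <- genome("g", paste(cods, collapse = ""), circular = FALSE)
  hit <- make_hit(s_s = 10, s_e = 25, q_s = 8, q_e = 24, l_q = 30)
  usage <- make_usage(start_freq = c(ATG = 1), stop_freq = c(TAA = 0.7))
  lens <- make_lengths(lens = c(48, 63, 78))
  pred <- predict_boundaries(g, hit, usage, lens)
  expect_true(pred$start_fallback)
  expect_false(pred$stop_fallback)
  expect_equal(pred$s, hit$s_s)
  expect_equal(pred$e, 30L)

  # no stop frequencies at all: stop falls back too
  usage2 <- make_usage(start_freq = c(ATG = 1), stop_freq = c(TAG = 1))
  cods2 <- cods; cods2[5 + 1] <- "ATG"
  g2 <- genome("g", paste(cods2, collapse = ""), circular = FALSE)
  pred2 <- predict_boundaries(g2, hit, usage2, lens)
  expect_true(pred2$stop_fallback)
  expect_false(pred2$start_fallback)
  expect_equal(pred2$e, hit$s_e)
  expect_equal(pred2$s, 5L)
})

test_that("predictions mirror exactly across strands", {
  set.seed(31)
  cfg <- sim_config(n_species = 12, seed = 31, genes = c("nad3", "atp8"),
                    prob_minus = 0)
  ref <- simulate_reference_set(cfg)
  model <- fit_boundary_model(ref$features, ref$genomes)
  cfg2 <- cfg; cfg2$n_species <- 2L; cfg2$species_offset <- 50L
  test <- simulate_reference_set(cfg2)
  hits <- simulate_hits(test$features, cfg2)
  for (i in seq_len(nrow(hits))) {
    g <- test$genomes[[hits$seqid[i]]]
    fwd <- predict_boundaries(g, hits[i, ], model$usage, model$lengths)
    # mirror the genome: reverse complement, flip strand and anchor
    gm <- genome(g$id, revcomp(g$sequence), circular = g$circular,
                 code_table = g$code_table)
    hm <- hits[i, ]
    hm$strand <- "-"
    hm$frame_anchor <- g$length - hm$frame_anchor
    rev_ <- predict_boundaries(gm, hm, model$usage, model$lengths)
    expect_equal(rev_$score, fwd$score)
    expect_equal(rev_$start, g$length - fwd$end)
    expect_equal(rev_$end, g$length - fwd$start)
    expect_equal(rev_$stop_kind, fwd$stop_kind)
  }
})

test_that("predict_boundaries agrees with the exhaustive oracle on random genomes", {
  cfg <- sim_config(n_species = 40, seed = 77, genes = c("nad3", "atp8"))
  ref <- simulate_reference_set(cfg)
  model <- fit_boundary_model(ref$features, ref$genomes)
  cfg2 <- cfg; cfg2$n_species <- 15L; cfg2$species_offset <- 100L
  test <- simulate_reference_set(cfg2)
  hits <- simulate_hits(test$features, cfg2)
  trnas <- test$features[test$features$kind == "tRNA", ]
  checked <- 0L
  for (i in seq_len(nrow(hits))) {
    g <- test$genomes[[hits$seqid[i]]]
    got <- predict_boundaries(g, hits[i, ], model$usage, model$lengths,
                              trnas = trnas)
    want <- oracle_predict(g, hits[i, ], model$usage, model$lengths,
                           trnas = trnas)
    if (is.null(want)) {
      expect_true(got$start_fallback || got$stop_fallback)
    } else {
      expect_equal(got$s, want$s, info = paste("hit", i))
      expect_equal(got$e, want$e, info = paste("hit", i))
      expect_equal(got$end_offset, want$off, info = paste("hit", i))
      expect_equal(got$score, want$score, tolerance = 1e-12)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20L)
})

test_that("shrinking the hit does not change candidates scored outside it", {
  cods <- rep("GGG", 60)
  cods[4 + 1] <- "ATG"; cods[50 + 1] <- "TAA"
  g <- genome("g", paste(cods, collapse = ""), circular = FALSE)
  usage <- make_usage(start_freq = c(ATG = 0.8), stop_freq = c(TAA = 0.7))
  lens <- make_lengths(lens = c(135, 141, 144))
  hit1 <- make_hit(s_s = 10, s_e = 45, q_s = 7, q_e = 43, l_q = 47)
  hit2 <- make_hit(s_s = 14, s_e = 41, q_s = 11, q_e = 39, l_q = 47)
  p1 <- predict_boundaries(g, hit1, usage, lens)
  p2 <- predict_boundaries(g, hit2, usage, lens)
  expect_equal(p1[, c("s", "e", "start", "end")],
               p2[, c("s", "e", "start", "end")])
})

test_that("the legacy window picks the nearest canonical codon or falls back", {
  cods <- rep("GGG", 40)
  cods[10 + 1] <- "ATG"; cods[30 + 1] <- "TAA"
  g <- genome("g", paste(cods, collapse = ""), circular = FALSE)
  hit <- make_hit(s_s = 10, s_e = 30, q_s = 1, q_e = 20, l_q = 21)
  p <- legacy_predict(g, hit)
  expect_equal(p$s, 10L)  # ATG exactly at s_s
  expect_equal(p$e, 30L)
  expect_equal(p$method, "legacy")

  # nothing within the window: fall back to the approximate position
  hit2 <- make_hit(s_s = 20, s_e = 37, q_s = 1, q_e = 17, l_q = 18)
  p2 <- legacy_predict(g, hit2)
  expect_true(p2$start_fallback)
  expect_equal(p2$s, 20L)

  # GTG one codon downstream beats ATG two codons upstream
  cods3 <- rep("GGG", 40)
  cods3[8 + 1] <- "ATG"; cods3[11 + 1] <- "GTG"; cods3[30 + 1] <- "TAA"
  g3 <- genome("g", paste(cods3, collapse = ""), circular = FALSE)
  p3 <- legacy_predict(g3, hit)
  expect_equal(p3$s, 11L)

  # equidistant codons: upstream wins
  cods4 <- rep("GGG", 40)
  cods4[8 + 1] <- "ATG"; cods4[12 + 1] <- "GTG"; cods4[30 + 1] <- "TAA"
  g4 <- genome("g", paste(cods4, collapse = ""), circular = FALSE)
  p4 <- legacy_predict(g4, hit)
  expect_equal(p4$s, 8L)
})
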