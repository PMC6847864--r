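feat <- function(seqid = "g", gene, start, end, strand = "+") {
  data.frame(seqid = seqid, gene = gene, kind = "CDS",
             start = as.integer(start), end = as.integer(end),
             strand = strand, stop_completeness = "unknown",
             stringsAsFactors = FALSE)
}

test_that("gene pairing requires mutual largest overlap", {
  p <- feat(gene = "nad3", start = 10, end = 100)
  r <- feat(gene = "nad3", start = 20, end = 110)
  m <- match_genes(p, r)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$overlap, 80L)

  # duplicated reference gene: paired with the larger overlap only
  r2 <- rbind(feat(gene = "nad3", start = 0, end = 30),
              feat(gene = "nad3", start = 20, end = 110))
  m2 <- match_genes(p, r2)
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$pairs$ref_start, 20L)
  expect_equal(nrow(m2$unmatched_ref), 1)

  # zero overlap: no pair, both reported unmatched
  m3 <- match_genes(feat(gene = "nad3", start = 0, end = 10),
                    feat(gene = "nad3", start = 50, end = 60))
  expect_equal(nrow(m3$pairs), 0)
  expect_equal(nrow(m3$unmatched_pred), 1)
  expect_equal(nrow(m3$unmatched_ref), 1)

  # different strands never pair
  m4 <- match_genes(feat(gene = "nad3", start = 10, end = 100),
                    feat(gene = "nad3", start = 10, end = 100,
                         strand = "-"))
  expect_equal(nrow(m4$pairs), 0)
})

test_that("signed differences follow the outside-positive convention on both strands", {
  # identical spans
  m <- match_genes(feat(gene = "nad3", start = 10, end = 100),
                   feat(gene = "nad3", start = 10, end = 100))
  expect_equal(signed_difference(m$pairs, "start"), 0L)
  expect_equal(signed_difference(m$pairs, "stop"), 0L)

  # plus strand: prediction starts 3 nt before (outside) the reference
  m2 <- match_genes(feat(gene = "nad3", start = 7, end = 100),
                    feat(gene = "nad3", start = 10, end = 100))
  expect_equal(signed_difference(m2$pairs, "start"), 3L)

  # minus strand: the 5' boundary sits at the forward-axis end; a
  # prediction extending 2 nt beyond it is 2 nt outside
  m3 <- match_genes(feat(gene = "nad3", start = 10, end = 102,
                         strand = "-"),
                    feat(gene = "nad3", start = 10, end = 100,
                         strand = "-"))
  expect_equal(signed_difference(m3$pairs, "start"), 2L)
  expect_equal(signed_difference(m3$pairs, "stop"), 0L)

  # prediction inside the reference is negative
  m4 <- match_genes(feat(gene = "nad3", start = 16, end = 94),
                    feat(gene = "nad3", start = 10, end = 100))
  expect_equal(signed_difference(m4$pairs, "start"), -6L)
  expect_equal(signed_difference(m4$pairs, "stop"), -6L)
})

test_that("circular differences use the shorter arc when a length is given", {
  m <- match_genes(feat(gene = "nad3", start = 0, end = 100),
                   feat(gene = "nad3", start = 2, end = 100))
  d <- signed_difference(m$pairs, "start", genome_length = c(g = 1000L))
  expect_equal(d, 2L)
  # a difference of 990 on a 1000 nt circle is really -10
  m2 <- match_genes(feat(gene = "nad3", start = 5, end = 1000),
                    feat(gene = "nad3", start = 995, end = 1990))
  d2 <- signed_difference(m2$pairs, "start", genome_length = c(g = 1000L))
  expect_equal(abs(d2), 10L)
})

test_that("summaries aggregate absolute differences and max-based fractions", {
  p <- rbind(feat(gene = "nad3", start = 10, end = 103),
             feat(gene = "cox1", start = 200, end = 309))
  r <- rbind(feat(gene = "nad3", start = 10, end = 100),
             feat(gene = "cox1", start = 200, end = 300))
  m <- match_genes(p, r)
  s <- summarize_differences(m$pairs)
  # per-gene d values are max(|0|, |3|) = 3 and max(|0|, |9|) = 9
  expect_equal(unname(s$fractions["d<=0"]), 0)
  expect_equal(unname(s$fractions["d<=3"]), 0.5)
  expect_equal(unname(s$fractions["d<=9"]), 1)
  expect_equal(s$stop$mu, 6)
  expect_equal(s$stop$sigma, 3)  # population convention
  expect_true(all(diff(s$fractions) >= 0))

  # identity input gives the all-zero summary
  si <- summarize_differences(match_genes(r, r)$pairs)
  expect_equal(si$start$mu, 0)
  expect_equal(si$stop$sigma, 0)
  expect_true(all(si$fractions == 1))

  # single pair: sigma = 0
  s1 <- summarize_differences(match_genes(p[1, ], r[1, ])$pairs)
  expect_equal(s1$stop$sigma, 0)

  expect_error(summarize_differences(m$pairs[0, ]), "no gene pairs")
})

test_that("summaries are invariant under input order", {
  set.seed(8)
  genes <- sample(pcg_names(), 8)
  p <- do.call(rbind, lapply(seq_along(genes), function(i)
    feat(gene = genes[i], start = 100 * i + sample(-5:5, 1),
         end = 100 * i + 60 + sample(-5:5, 1))))
  r <- do.call(rbind, lapply(seq_along(genes), function(i)
    feat(gene = genes[i], start = 100 * i, end = 100 * i + 60)))
  s1 <- summarize_differences(match_genes(p, r)$pairs)
  perm <- sample(nrow(p))
  s2 <- summarize_differences(match_genes(p[perm, ], r[rev(perm), ])$pairs)
  expect_equal(s1$start$mu, s2$start$mu)
  expect_equal(s1$fractions, s2$fractions)
  expect_equal(sort(s1$start$d), sort(s2$start$d))
})

test_that("the cumulative curve uses the arcsinh transform and is monotone", {
  p <- rbind(feat(gene = "nad3", start = 10, end = 103),
             feat(gene = "cox1", start = 195, end = 309))
  r <- rbind(feat(gene = "nad3", start = 10, end = 100),
             feat(gene = "cox1", start = 200, end = 300))
  s <- summarize_differences(match_genes(p, r)$pairs)
  cv <- difference_curve(s)
  expect_equal(cv$asinh_d, asinh(cv$d))
  expect_true(all(diff(cv$cum_start) >= 0))
  expect_true(all(diff(cv$cum_stop) >= 0))
})

test_that("summary TSV export is parseable and carries the raw differences", {
  p <- feat(gene = "nad3", start = 7, end = 100)
  r <- feat(gene = "nad3", start = 10, end = 100)
  m <- match_genes(p, r)
  s <- summarize_differences(m$pairs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(s, m$pairs, f)
  lines <- readLines(f)
  expect_true(any(grepl("^mu\t", lines)))
  expect_true(any(grepl("d_start", lines)))
})
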