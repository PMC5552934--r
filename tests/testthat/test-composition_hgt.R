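test_that("gc_content handles plain, ambiguous and degenerate input", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATNNGC"), 50)  # N excluded from both sides
  expect_error(gc_content("NNN"), "no countable")
})

test_that("gc_deviation_test matches a hand-computed 3-pair toy", {
  gene <- c(62, 64, 63)
  genome <- c(60, 60, 60)
  d <- gene - genome                    # 2, 4, 3
  t_hand <- mean(d) / (stats::sd(d) / sqrt(3))
  res <- gc_deviation_test(gene, genome)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$mean_delta, 3)
  # identical vectors -> degenerate, no p-value
  same <- gc_deviation_test(c(60, 61, 62), c(60, 61, 62))
  expect_true(same$degenerate)
  expect_true(is.na(same$p_value))
  expect_equal(same$mean_delta, 0)
})

test_that("codon usage table satisfies the relative-adaptiveness contract", {
  u <- codon_usage_table(c("ATGAAAAAGCTGTAA", "ATGAAGCTGCTGTAA"))
  expect_true(all(is.na(u$w[u$aa == "*"])))
  w <- u$w[!is.na(u$w)]
  expect_true(all(w > 0 & w <= 1))
  # the most frequent synonymous codon of every amino acid has w = 1
  for (a in unique(u$aa[u$aa != "*"])) {
    expect_equal(max(u$w[names(u$aa)[u$aa == a]]), 1)
  }
  # gene1 contributes AAA+AAG, gene2 a second AAG
  expect_equal(unname(u$counts[["AAA"]]), 1)
  expect_equal(unname(u$counts[["AAG"]]), 2)
  expect_equal(unname(u$w[["AAA"]]), 0.5)
  expect_equal(unname(u$w[["AAG"]]), 1)
})

test_that("CAI equals hand-computed geometric means and is order-invariant", {
  u <- codon_usage_table(c("AAAAAGAAACTGCTGTTATAA"))
  # counts: AAA=2, AAG=1 -> w(AAA)=1, w(AAG)=0.5; CTG=2, TTA=1 -> w(TTA)=0.5
  g <- "AAAAAGTAA"  # Lys Lys stop
  expect_equal(cai(g, u), exp(mean(log(c(1, 0.5)))))
  g2 <- "AAGAAATAA"  # permuted codons
  expect_equal(cai(g2, u), cai(g, u))
  # optimal-codon-only gene -> CAI 1; Met/Trp excluded
  expect_equal(cai("ATGAAACTGTGGTAA", u), 1)
  expect_error(cai("ATGTGGTAA", u), "no countable")
})

test_that("eCAI is deterministic, bounded, and a (1-p) quantile", {
  u <- codon_usage_table(c("AAAAAGAAACTGCTGTTACGTCGCGGATAA"))
  g <- "AAACTGCGTGGAAAGTTATAA"
  e1 <- expected_cai(g, u, n = 200, seed = 5)
  e2 <- expected_cai(g, u, n = 200, seed = 5)
  expect_identical(e1, e2)
  expect_true(e1 > 0 && e1 <= 1)
  expect_error(expected_cai(g, u, n = 50), ">= 100")
  # p = 0.5 quantile is below the p = 0.01 quantile
  expect_lte(expected_cai(g, u, n = 200, p = 0.5, seed = 5), e1)
})

test_that("normalized CAI flags shifted codon usage and clears native genes", {
  prefs <- random_codon_prefs(seed = 2)
  donor <- random_codon_prefs(seed = 2, rotate = TRUE)
  set.seed(3)
  aa <- paste(c("M", sample(setdiff(copascan:::AA20, "C"), 120,
                            replace = TRUE)), collapse = "")
  native_cds <- vapply(1:12, function(i)
    make_cds(aa, prefs = prefs, seed = 10 + i), character(1))
  u <- codon_usage_table(native_cds)
  nc_nat <- normalized_cai(native_cds[1], u, n = 300, seed = 4)
  expect_gte(nc_nat$ratio, 1)
  expect_false(nc_nat$deviant)
  foreign <- make_cds(aa, prefs = donor, seed = 99)
  nc_for <- normalized_cai(foreign, u, n = 300, seed = 4)
  expect_true(nc_for$deviant)
  expect_gt(nc_for$ratio, 0)
})

test_that("closest_homolog matches identity/prefix cases and the SW oracle", {
  q <- data.frame(id = "q", sequence = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                  taxon_class = "Rhizobiales", stringsAsFactors = FALSE)
  db <- data.frame(
    id = c("self", "other"),
    sequence = c(q$sequence, "MWWHHHWWKRKRKRNNDNDNQEQEQE"),
    taxon_class = c("Rhizobiales", "gamma-proteobacteria"),
    stringsAsFactors = FALSE)
  hit <- closest_homolog(q, db)
  expect_equal(hit$subject_id, "self")
  expect_equal(hit$identity, 100)
  expect_equal(hit$similarity, 100)
  expect_equal(hit$coverage, 100)
  expect_false(hit$foreign)  # same taxon class

  # half-length prefix: coverage ~50 blocks the foreign flag
  prefix_db <- data.frame(id = "pre",
                          sequence = substr(q$sequence, 1, 16),
                          taxon_class = "gamma-proteobacteria",
                          stringsAsFactors = FALSE)
  hp <- closest_homolog(q, prefix_db)
  expect_lt(hp$coverage, 60)
  expect_false(hp$foreign)

  # identical sequence under a foreign taxon -> foreign flag
  fdb <- data.frame(id = "f", sequence = q$sequence,
                    taxon_class = "gamma-proteobacteria",
                    stringsAsFactors = FALSE)
  expect_true(closest_homolog(q, fdb)$foreign)

  # scores agree with a quadratic-time affine Smith-Waterman oracle
  mat <- copascan:::blosum62()
  set.seed(6)
  for (i in 1:10) {
    a <- paste(sample(copascan:::AA20, 30, TRUE), collapse = "")
    b <- paste(sample(copascan:::AA20, 35, TRUE), collapse = "")
    got <- copascan:::pairwise_stats(a, b)$score
    expect_equal(got, sw_affine_score(a, b, mat), tolerance = 1e-9)
  }
})

test_that("cluster_scan finds planted metal clusters and honors the window", {
  ann <- data.frame(
    feature_id = c("copA", "n1", "n2", "far", "other_rep"),
    replicon = c("chr", "chr", "chr", "chr", "p1"),
    start = c(10000L, 12500L, 15000L, 200000L, 11000L),
    end = c(12000L, 13400L, 15800L, 201000L, 11900L),
    strand = "+", stringsAsFactors = FALSE)
  ann$keywords <- I(list(c("copper", "atpase"),
                         c("heavy", "metal", "transporter"),
                         c("transposase"), c("czc", "system"),
                         c("cus", "system")))
  prot <- data.frame(id = "copA", sequence = "MK", stringsAsFactors = FALSE)
  cds <- data.frame(id = "copA", sequence = "ATGAAA", stringsAsFactors = FALSE)
  b <- genome_bundle("g", prot, cds, ann)
  res <- cluster_scan(b, "copA", window = 10000)
  expect_true(res$in_cluster)  # n1 (metal) + n2 (transposase)
  expect_equal(sort(res$context$feature_id), c("n1", "n2"))
  # window = 0 -> no neighbors beyond the gene span
  res0 <- cluster_scan(b, "copA", window = 0)
  expect_equal(nrow(res0$context), 0)
  expect_false(res0$in_cluster)
  expect_error(cluster_scan(b, "nope"), "absent")
})

test_that("hgt_verdict composes the evidence correctly", {
  expect_true(hgt_verdict(TRUE, TRUE, TRUE, TRUE)$candidate)
  expect_true(hgt_verdict(TRUE, FALSE, TRUE)$candidate)
  expect_true(hgt_verdict(TRUE, TRUE, FALSE)$candidate)
  expect_false(hgt_verdict(FALSE, TRUE, TRUE, TRUE)$candidate)
  expect_false(hgt_verdict(TRUE, FALSE, FALSE)$candidate)
})
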