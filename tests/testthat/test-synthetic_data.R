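test_that("make_cu_atpase plants the documented motifs and is seed-stable", {
  r <- make_cu_atpase("P1B-3a", seed = 5)
  expect_equal(substr(r$sequence, 200, 202), "CPD")
  r1b <- make_cu_atpase("P1B-1b", seed = 5)
  expect_equal(substr(r1b$sequence, 160, 163), "CPKC")
  expect_gte(copascan:::max_his_window(substr(r1b$sequence, 1, 20)), 6)
  expect_equal(length(copascan:::find_overlapping(
    substr(r1b$sequence, 1, 180), "C.C.C")), 2)
  expect_identical(make_cu_atpase("P1B-1", seed = 9)$sequence,
                   make_cu_atpase("P1B-1", seed = 9)$sequence)
  expect_error(make_cu_atpase("P1B-9", seed = 1))
})

test_that("noise-free generator/classifier loop closes for every subtype", {
  for (s in copascan:::CU_SUBTYPES) {
    r <- make_cu_atpase(s, seed = 21)
    expect_equal(classify_via_profile(r)$label, s)
  }
})

test_that("make_cds translates back to its protein and honors gc targets", {
  prefs <- random_codon_prefs(seed = 7)
  aa <- "MKLAGRPEDVA"
  nt <- make_cds(aa, prefs = prefs, seed = 3)
  tr <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  expect_equal(sub("\\*$", "", tr), aa)
  nt65 <- make_cds(strrep("AGPR", 30), prefs = prefs, gc_target = 65,
                   seed = 4)
  expect_lte(abs(gc_content(nt65) - 65), 0.6)
  # concentrated preferences give CAI near 1 against their own usage
  ct <- copascan:::codon_table()
  sense <- ct[ct$aa != "*", ]
  conc <- prefs
  for (a in unique(sense$aa)) {
    idx <- sense$codon[sense$aa == a]
    w <- conc[idx]
    conc[idx] <- ifelse(seq_along(idx) == which.max(w), 0.97, 0.03 /
                          max(length(idx) - 1, 1))
  }
  aa_long <- strrep("KLAGRPEDV", 12)
  u <- codon_usage_table(vapply(1:10, function(i)
    make_cds(aa_long, prefs = conc, seed = i), character(1)))
  expect_gt(cai(make_cds(aa_long, prefs = conc, seed = 99), u), 0.8)
})

test_that("hgt scenario carries its ground truth", {
  sc <- make_hgt_scenario(n_native = 6, n_foreign = 3, seed = 2,
                          protein_length = 90)
  expect_length(sc$truth, 3)
  expect_equal(nrow(sc$bundle$cds), 9)
  expect_s3_class(sc$bundle, "genome_bundle")
  # foreign genes have homologs under a foreign taxon
  for (id in sc$truth) {
    expect_equal(sc$db$taxon_class[sc$db$id == paste0("hom_", id)],
                 "gamma-proteobacteria")
  }
  # null scenario: no GC shift, shared codon table -> no candidates expected
  # beyond noise (delta_gc jitter ~ N(0, 0.5) stays under the 2-pt margin)
  sc0 <- make_hgt_scenario(n_native = 6, n_foreign = 0, seed = 3,
                           protein_length = 90)
  scr0 <- composition_screen(sc0$bundle, sc0$db, sc0$usage, n_ecai = 100,
                             seed = 1)
  expect_equal(sum(scr0$hgt_candidate), 0)
})

test_that("simulate_alignment: star tree, equilibrium and determinism", {
  m <- make_subst_model("JC", alpha = 1, k = 4)
  star <- ape::read.tree(text = "(a:0,b:0,c:0,d:0);")
  al <- simulate_alignment(star, m, 50, seed = 4)
  expect_true(all(al$seqs == al$seqs[1]))  # zero branch lengths copy the root
  m2 <- make_subst_model("GTR", frequencies = c(A = .4, C = .1, G = .1,
                                                T = .4), alpha = Inf, k = 1)
  tr <- ape::read.tree(text = "(a:0.3,b:0.3,(c:0.3,d:0.3):0.1);")
  big <- simulate_alignment(tr, m2, 10000, seed = 5)
  freq <- table(strsplit(paste(big$seqs, collapse = ""), "")[[1]])
  freq <- freq / sum(freq)
  expect_lt(max(abs(freq[c("A", "C", "G", "T")] - m2$pi)), 0.02)
  expect_identical(simulate_alignment(tr, m2, 30, seed = 9)$seqs,
                   simulate_alignment(tr, m2, 30, seed = 9)$seqs)
  expect_error(simulate_alignment(tr, m2, 0, seed = 1), "zero sites")
})

test_that("bundles carry consistent truth and write/read cleanly", {
  bun <- make_bundle(n_genomes = 3, seed = 6)
  expect_length(bun$genomes, 3)
  for (gid in names(bun$genomes)) {
    b <- bun$genomes[[gid]]
    tr <- bun$truth[[gid]]
    expect_true(all(tr$atpases$id %in% b$proteins$id))
    expect_true(all(tr$chaperones$id %in% b$proteins$id))
    expect_true(all(b$cds$id %in% b$annotation$feature_id))
  }
  d <- withr::local_tempdir()
  bun2 <- make_bundle(n_genomes = 2, seed = 7, out_dir = d)
  gid <- names(bun2$genomes)[1]
  back <- read_fasta(file.path(d, paste0(gid, "_proteins.faa")), "protein")
  expect_setequal(back$id, bun2$genomes[[gid]]$proteins$id)
  expect_setequal(back$sequence, bun2$genomes[[gid]]$proteins$sequence)
  ann <- read_annotation(file.path(d, paste0(gid, ".gff3")))
  expect_setequal(ann$feature_id, bun2$genomes[[gid]]$annotation$feature_id)
  expect_true(file.exists(file.path(d, "truth.json")))
})
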