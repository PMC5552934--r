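# direct construction of motif evidence, bypassing alignment
mp <- function(cxxc = character(), his = FALSE, trash = 0L, tm6 = "CPC",
               tm7 = TRUE, tm8 = "MALSS", nlen = 60L, fix = FALSE) {
  structure(list(n_mbd_cxxc = cxxc, his_rich = his, his_support = 0L,
                 trash_count = trash, tm6_triad = tm6, tm7_motif = tm7,
                 tm8_pentad = tm8, n_mbd_length = nlen, fix_context = fix,
                 absent = c(tm6 = FALSE, tm7 = FALSE, tm8 = FALSE)),
            class = "motif_profile")
}

test_that("the published motif combinations map to their subtypes", {
  cases <- list(
    # group VIII: CASC repeats, CPC, MALSS
    list(mp(c("CASC", "CASC")), "P1B-1"),
    # groups VIa/VIb: H-rich, CPH, MSAST
    list(mp(his = TRUE, tm6 = "CPH", tm8 = "MSAST"), "P1B-3"),
    # group VIc: poor H, CPD, MSGSS
    list(mp(tm6 = "CPD", tm8 = "MSGSS"), "P1B-3a"),
    # group VII: H-rich + CPIC, CPC, MSLSS
    list(mp("CPIC", his = TRUE, tm8 = "MSLSS"), "P1B-1a"),
    # group VII long N-MBD: CPKC + 2 TRASH, CPC, MSLSS
    list(mp("CPKC", his = TRUE, trash = 2L, tm8 = "MSLSS", nlen = 160L),
         "P1B-1b"),
    # group XIV: CAGC, CPC, MSGSS with FixI context
    list(mp("CAGC", tm8 = "MSGSS", fix = TRUE), "P1B-1c"))
  for (cs in cases) {
    lab <- classify_subtype(cs[[1]])
    expect_equal(lab$label, cs[[2]])
    expect_gt(length(lab$evidence), 0)
  }
})

test_that("rule order, fallbacks and degenerate inputs behave", {
  # CAGC/MSGSS without FixI context falls through to plain P1B-1
  expect_equal(classify_subtype(mp("CAGC", tm8 = "MSGSS"))$label, "P1B-1")
  # short N-MBD blocks the P1B-1b rule even with CPKC + TRASH
  expect_equal(classify_subtype(mp("CPKC", trash = 2L, nlen = 80L))$label,
               "P1B-1")
  # non-copper TM6 triad
  expect_equal(classify_subtype(mp(tm6 = "SPC"))$label, "non-copper")
  # no TM6 at all -> unclassified
  expect_equal(classify_subtype(mp(cxxc = "CASC", tm6 = NA_character_))$label,
               "unclassified")
})

test_that("CPC without any CXXC is unclassified and MXXSS fallback warns", {
  expect_equal(classify_subtype(mp(cxxc = character()))$label, "unclassified")
  lab <- classify_subtype(mp("CASC", tm8 = "MKQSS"))
  expect_equal(lab$label, "P1B-1")
  expect_true(any(grepl("MXXSS fallback", lab$evidence)))
})

test_that("extraction reads planted regions off the real alignment", {
  prof <- get_cu_profile()
  r <- make_cu_atpase("P1B-3a", seed = 77)
  h <- viterbi_align(prof, r$sequence)
  m <- extract_regions(h, r$sequence)
  expect_equal(m$tm6_triad, "CPD")
  expect_equal(m$tm8_pentad, "MSGSS")
  expect_true(m$tm7_motif)
  r2 <- make_cu_atpase("P1B-1b", seed = 78)
  m2 <- extract_regions(viterbi_align(prof, r2$sequence), r2$sequence)
  expect_gte(m2$trash_count, 2)
  expect_true("CPKC" %in% m2$n_mbd_cxxc)
  expect_gte(m2$n_mbd_length, 120)
  # engineered deletion across the TM8 anchor -> pentad absent
  chopped <- paste0(substr(r$sequence, 1, 278), substr(r$sequence, 290, 320))
  m3 <- extract_regions(viterbi_align(prof, chopped), chopped)
  expect_true(is.na(m3$tm8_pentad))
  expect_true(m3$absent[["tm8"]])
})

test_that("His-richness rule fires on window count or consecutive run", {
  expect_true(copascan:::is_his_rich("MHHHHHHSGAAAA"))
  expect_true(copascan:::is_his_rich(
    paste0("HAHAHAHAHAH", strrep("A", 30))))  # 6 H in a 20-window
  expect_false(copascan:::is_his_rich(paste0("HAH", strrep("A", 40), "HH")))
})

test_that("classification is deterministic and order-stable", {
  set.seed(9)
  recs <- lapply(1:12, function(i) {
    make_cu_atpase(sample(copascan:::CU_SUBTYPES, 1), seed = 600 + i,
                   noise = 0.05)
  })
  labs1 <- vapply(recs, function(r) classify_via_profile(r)$label,
                  character(1))
  perm <- sample(length(recs))
  labs2 <- vapply(recs[perm], function(r) classify_via_profile(r)$label,
                  character(1))
  expect_identical(labs1[perm], labs2)
})

test_that("census summarizes histogram, prevalence and replicon split", {
  labels <- data.frame(
    id = paste0("p", 1:5),
    genome_id = c("g1", "g1", "g1", "g2", "g2"),
    replicon = c("plasmid", "chromosome", "plasmid", "chromosome",
                 "chromosome"),
    subtype = c("P1B-1", "P1B-1", "P1B-1a", "P1B-1", "non-copper"),
    stringsAsFactors = FALSE)
  cz <- subtype_census(labels, all_genomes = c("g1", "g2", "g3"))
  expect_equal(cz$histogram$n_genomes[cz$histogram$count == 0], 1)  # g3
  expect_equal(cz$histogram$n_genomes[cz$histogram$count == 3], 1)  # g1
  expect_equal(cz$subtype_pct$pct[cz$subtype_pct$subtype == "P1B-1"],
               round(100 * 2 / 3))
  sp <- cz$replicon_split
  expect_equal(sp$n[sp$replicon == "plasmid"], 2)
  expect_equal(sum(sp$fraction), 1)
})
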