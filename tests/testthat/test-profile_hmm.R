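test_that("build_profile applies the occupancy rule and pseudocount mixing", {
  # single ungapped row: every column is a match state
  p1 <- build_profile(seed_alignment("a", "ACD"), 0.5, 1)
  expect_equal(p1$M, 3)
  expect_equal(which.max(p1$match_emis[1, ]), c(A = 1))

  # two rows, column 2 occupancy 0.5 < 0.6 -> insert column
  p2 <- build_profile(seed_alignment(c("a", "b"), c("A-", "AC")), 0.6, 1)
  expect_equal(p2$M, 1)

  # Laplace-style mixing with uniform background:
  # P(A) = (2 + w * bg_A) / (2 + w)
  sa <- seed_alignment(c("a", "b"), c("A", "A"))
  p3 <- build_profile(sa, 0.5, 1)
  bgA <- p3$bg[["A"]]
  expect_equal(unname(p3$match_emis[1, "A"]), (2 + 1 * bgA) / (2 + 1))

  # zero match states is an error; all-gap columns warn
  expect_error(
    suppressWarnings(build_profile(seed_alignment(c("a", "b", "c"),
                                                  c("A--", "-C-", "--D")),
                                   0.9, 1)),
    "zero match states")
  expect_warning(build_profile(seed_alignment(c("a", "b"), c("A-", "C-")),
                               0.5, 1), "all-gap")
})

test_that("emissions and transitions stay normalized after any build", {
  set.seed(11)
  for (i in 1:10) {
    p <- random_tiny_profile(i * 3)
    expect_true(all(abs(rowSums(p$match_emis) - 1) < 1e-9))
    expect_true(all(abs(p$tMM[1:p$M] + p$tMI[1:p$M] + p$tMD[1:p$M] - 1)
                    < 1e-9))
    expect_true(all(abs(p$tIM + p$tII - 1) < 1e-9))
    expect_true(all(abs(p$tDM + p$tDD - 1) < 1e-9))
  }
})

test_that("Viterbi and forward agree with exhaustive enumeration", {
  set.seed(7)
  for (trial in 1:20) {
    p <- random_tiny_profile(trial)
    L <- sample(1:6, 1)
    s <- paste(sample(copascan:::AA20, L, replace = TRUE), collapse = "")
    oracle <- enumerate_profile_paths(p, s)
    v <- viterbi_align(p, s)
    f <- forward_score(p, s)
    expect_lt(abs(v$score_nats - oracle$viterbi), 1e-8)
    expect_lt(abs(f$score_nats - oracle$forward), 1e-8)
    # forward >= viterbi (sum over paths >= best path)
    expect_gte(f$score_nats, v$score_nats - 1e-10)
    # replaying the returned path reproduces its score
    expect_lt(abs(score_path(p, s, v$path) - v$score_nats), 1e-8)
  }
})

test_that("Viterbi path structure reflects planted edits", {
  # sharply peaked profile from identical rows; consensus aligns all-match
  cons <- "MKLVDE"
  sa <- seed_alignment(c("a", "b", "c"), rep(cons, 3))
  p <- build_profile(sa, 0.5, 0.1)
  v <- viterbi_align(p, cons)
  expect_equal(sum(grepl("^M[0-9]+$", v$path)), 6)
  expect_false(any(grepl("^[ID]", v$path)))
  # one residue removed -> exactly one delete state
  v2 <- viterbi_align(p, "MKLDE")
  expect_equal(sum(grepl("^D", v2$path)), 1)
  expect_error(viterbi_align(p, ""), "empty")
})

test_that("search recovers the seed and controls decoys", {
  seedrecs <- get_cu_seed()
  prof <- get_cu_profile()
  db <- data.frame(id = seedrecs$meta$id, sequence = seedrecs$meta$sequence,
                   stringsAsFactors = FALSE)
  hits <- hmm_search(prof, db, evalue_cutoff = 1e-3,
                     calibration = list(n_decoys = 100, seed = 2))
  expect_setequal(hits$id, db$id)  # self-recovery
  expect_true(all(diff(hits$score_bits) <= 0))  # sorted by score

  # shuffled decoys: expected hits bounded by db_size * cutoff * 10
  set.seed(5)
  dec <- data.frame(
    id = paste0("dec", 1:100),
    sequence = vapply(db$sequence[sample(nrow(db), 100, replace = TRUE)],
                      function(s) paste(sample(strsplit(s, "")[[1]]),
                                        collapse = ""), character(1)),
    stringsAsFactors = FALSE)
  dh <- hmm_search(prof, dec, evalue_cutoff = 1e-3,
                   calibration = list(n_decoys = 100, seed = 2))
  expect_lte(nrow(dh), 100 * 1e-3 * 10)

  expect_error(hmm_search(prof, db, calibration = list(n_decoys = 20,
                                                       seed = 1)),
               "fewer than 50")
})

test_that("planted-domain retrieval is sensitive at E <= 1e-3", {
  prof <- calibrate_profile(get_cu_profile(), n_decoys = 100, seed = 9,
                            decoy_length = 420)
  set.seed(31)
  n <- 100
  recs <- data.frame(
    id = paste0("planted", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      dom <- make_cu_atpase(sample(copascan:::CU_SUBTYPES, 1),
                            seed = 4000 + i, noise = 0.1)$sequence
      paste0(paste(sample(copascan:::AA20, 50, replace = TRUE),
                   collapse = ""), dom,
             paste(sample(copascan:::AA20, 50, replace = TRUE),
                   collapse = ""))
    }, character(1)), stringsAsFactors = FALSE)
  hits <- hmm_search(prof, recs, evalue_cutoff = 1e-3)
  expect_gte(nrow(hits) / n, 0.95)
})

test_that("profile JSON serialization round-trips and A2M export is sound", {
  p <- random_tiny_profile(4)
  f <- withr::local_tempfile(fileext = ".json")
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(p2$M, p$M)
  expect_equal(p2$match_emis, p$match_emis, tolerance = 1e-12)
  expect_equal(p2$tMM, p$tMM, tolerance = 1e-12)
  s <- "ACDKL"
  v <- viterbi_align(p, s)
  a2m <- a2m_string(v, s)
  # uppercase (match) + "-" (delete) columns equal M; residues preserved
  expect_equal(sum(strsplit(a2m, "")[[1]] %in% c(LETTERS, "-")), p$M)
  expect_equal(toupper(gsub("-", "", a2m)), s)
})
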