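gtr_model <- function(...) {
  make_subst_model("GTR", frequencies = c(A = .3, C = .2, G = .3, T = .2),
                   gtr_rates = c(1, 2, 1.5, 0.8, 3, 1), alpha = 0.7, k = 4,
                   ...)
}

test_that("substitution models are normalized and P(t) matches expm", {
  skip_if_not_installed("Matrix")
  for (m in list(gtr_model(), make_subst_model("LG", alpha = 0.9))) {
    expect_lt(max(abs(rowSums(m$Q))), 1e-10)
    expect_lt(abs(-sum(m$pi * diag(m$Q)) - 1), 1e-10)  # mean rate 1
    expect_lt(abs(sum(m$pi) - 1), 1e-12)
    expect_lt(abs(mean(m$rates) - 1), 1e-12)
    P <- prob_matrix(m, 0.37, 1.4)
    P2 <- as.matrix(Matrix::expm(m$Q * 0.37 * 1.4))
    expect_lt(max(abs(P - P2)), 1e-9)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  }
  expect_error(make_subst_model("LG", pinv = 0.2), "nucleotide")
})

test_that("ml_distance: identity, symmetry, and the Jukes-Cantor closed form", {
  m <- gtr_model()
  set.seed(1)
  seqs <- replicate(4, paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                             collapse = ""))
  al <- msa(paste0("t", 1:4), seqs, "dna")
  D <- ml_distance(al, m)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  a2 <- msa(c("x", "y"), c(seqs[1], seqs[1]), "dna")
  expect_equal(ml_distance(a2, m)[1, 2], 0)

  mjc <- make_subst_model("JC", alpha = Inf, k = 1)
  s1 <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  ch <- strsplit(s1, "")[[1]]
  mut <- sample(500, 60)
  for (i in mut) ch[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(s1, i, i)), 1)
  Djc <- ml_distance(msa(c("x", "y"), c(s1, paste(ch, collapse = "")),
                         "dna"), mjc)
  p <- 60 / 500
  expect_lt(abs(Djc[1, 2] - (-3 / 4 * log(1 - 4 * p / 3))), 1e-6)
})

test_that("bionj recovers additive and ultrametric matrices exactly", {
  true5 <- ape::read.tree(
    text = "((a:0.1,b:0.2):0.1,(c:0.15,d:0.05):0.2,e:0.3);")
  expect_equal(phangorn::RF.dist(
    bionj_tree(ape::cophenetic.phylo(true5)), true5), 0)
  ultra <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  bt <- bionj_tree(ape::cophenetic.phylo(ultra))
  expect_equal(phangorn::RF.dist(bt, ape::unroot(ultra)), 0)
  # taxon order invariance
  D <- ape::cophenetic.phylo(true5)
  perm <- c(3, 5, 1, 4, 2)
  expect_equal(phangorn::RF.dist(bionj_tree(D[perm, perm]),
                                 bionj_tree(D)), 0)
  expect_error(bionj_tree(matrix(c(0, Inf, Inf, 0), 2)), "non-finite")
})

test_that("pruning equals brute-force state enumeration and expm closed form", {
  skip_if_not_installed("Matrix")
  m <- gtr_model()
  # 2 taxa, 1 site closed form
  aln <- msa(c("t1", "t2"), c("A", "G"), "dna")
  tr <- ape::read.tree(text = "(t1:0.1,t2:0.2);")
  direct <- 0
  for (r in m$rates) {
    P <- as.matrix(Matrix::expm(m$Q * 0.3 * r))
    direct <- direct + 0.25 * m$pi["A"] * P["A", "G"]
  }
  expect_lt(abs(tree_loglik(tr, aln, m) - log(direct)), 1e-8)

  # 5 taxa, 3 sites (with a gap) vs enumeration over internal states
  tr5 <- ape::read.tree(
    text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.1):0.05,e:0.4);")
  aln5 <- msa(c("a", "b", "c", "d", "e"),
              c("ACG", "ACT", "GCG", "AAT", "AC-"), "dna")
  expect_lt(abs(tree_loglik(tr5, aln5, m) -
                  brute_force_loglik(tr5, aln5, m)), 1e-8)

  # invariances
  rooted <- ape::root(tr5, outgroup = "e", resolve.root = TRUE)
  expect_lt(abs(tree_loglik(rooted, aln5, m) - tree_loglik(tr5, aln5, m)),
            1e-8)
  doubled <- msa(aln5$ids, paste0(aln5$seqs, aln5$seqs), "dna")
  expect_lt(abs(tree_loglik(tr5, doubled, m) - 2 * tree_loglik(tr5, aln5, m)),
            1e-8)
  expect_error(tree_loglik(tr5, msa(aln5$ids, rep("", 5), "dna"), m),
               "zero-length")
})

test_that("+I mixture matches a hand-computed invariant-site likelihood", {
  skip_if_not_installed("Matrix")
  m <- make_subst_model("JC", alpha = Inf, k = 1, pinv = 0.3)
  aln <- msa(c("t1", "t2"), c("A", "A"), "dna")
  tr <- ape::read.tree(text = "(t1:0.05,t2:0.05);")
  P <- as.matrix(Matrix::expm(m$Q * 0.1 / 0.7))
  expected <- 0.3 * 0.25 + 0.7 * 0.25 * P["A", "A"]
  expect_lt(abs(tree_loglik(tr, aln, m) - log(expected)), 1e-8)
})

test_that("NNI search is monotone and does not worsen the true tree", {
  set.seed(4)
  tt <- ape::read.tree(
    text = "(((a:0.3,b:0.3):0.2,(c:0.3,d:0.3):0.2):0.1,e:0.5,f:0.5);")
  mjc <- make_subst_model("JC", alpha = 1, k = 4)
  al <- simulate_alignment(tt, mjc, 300, seed = 8)
  out <- nni_search(al, mjc, n_starts = 2, seed = 3)
  for (traj in attr(out, "trajectories")) {
    expect_true(all(diff(traj) >= -1e-6))
  }
  # starting at the truth can only match or improve its likelihood
  truth_opt <- optimize_branch_lengths(tt, al, mjc, rounds = 2)
  out2 <- nni_search(al, mjc, n_starts = 1, seed = 3, start_tree = tt)
  expect_gte(attr(out2, "loglik"), attr(truth_opt, "loglik") - 1e-6)
})

test_that("nni_neighbors yields the 2-per-internal-edge neighborhood", {
  set.seed(3)
  tr <- ape::unroot(ape::rtree(6))
  nb <- nni_neighbors(tr)
  n_internal <- sum(tr$edge[, 2] > 6)
  expect_length(nb, 2 * n_internal)
  expect_true(all(vapply(nb, function(x) phangorn::RF.dist(x, tr),
                         numeric(1)) == 2))
})

test_that("bootstrap supports are deterministic, bounded, and informative", {
  set.seed(10)
  tt <- ape::read.tree(
    text = "(((a:0.2,b:0.2):0.5,(c:0.2,d:0.2):0.5):0.2,e:0.4,f:0.4);")
  mjc <- make_subst_model("JC", alpha = 1, k = 4)
  al <- simulate_alignment(tt, mjc, 500, seed = 21)
  bt1 <- bootstrap_support(NULL, al, mjc, reps = 50, seed = 6)
  bt2 <- bootstrap_support(NULL, al, mjc, reps = 50, seed = 6)
  expect_identical(ape::write.tree(bt1), ape::write.tree(bt2))
  sup <- tree_supports(bt1)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 1))
  # the long internal branch separating ab|cdef is strongly supported
  ab_node <- ape::getMRCA(bt1, c("a", "b"))
  if (!is.null(ab_node) && ab_node > 6) {
    expect_gte(sup[ab_node - 6], 0.9)
  }
  expect_error(bootstrap_support(NULL, al, mjc, reps = 10, seed = 1),
               "fewer than 50")
})

test_that("extract_clades honors support threshold, anchors and monophyly", {
  txt <- "(((a1:1,a2:1)0.95:1,(b1:1,b2:1)0.95:1)0.3:1,(c1:1,c2:1)0.4:1,o:3);"
  tr <- ape::read.tree(text = txt)
  anchors <- c(a1 = "Cu+", b1 = "Cu2+")
  groups <- extract_clades(tr, threshold = 0.9, anchors = anchors)
  expect_length(groups, 2)
  members <- lapply(groups, `[[`, "members")
  expect_true(any(vapply(members, setequal, TRUE, y = c("a1", "a2"))))
  expect_true(any(vapply(members, setequal, TRUE, y = c("b1", "b2"))))
  # c-clade is well-formed but anchor-free and low-support -> unassigned
  expect_true(all(c("c1", "c2", "o") %in% attr(groups, "unassigned")))
  # substrates travel from anchors
  subs <- vapply(groups, `[[`, "", "substrate")
  expect_setequal(subs, c("Cu+", "Cu2+"))
  # monophyly of every returned group
  for (g in groups) {
    nd <- ape::getMRCA(tr, g$members)
    tips <- tr$tip.label[phangorn::Descendants(tr, nd, "tips")[[1]]]
    expect_setequal(tips, g$members)
  }
  expect_warning(res <- extract_clades(tr, anchors = c(zz = "Cu+")),
                 "no anchors")
  expect_length(res, 0)
})

test_that("incongruence report: RF, monophyly and scattered taxa", {
  marker <- ape::read.tree(
    text = "(((al1:1,al2:1):1,al3:1):1,((g1:1,g2:1):1,g3:1):1,out:2);")
  cls <- c(al1 = "alpha", al2 = "alpha", al3 = "alpha",
           g1 = "gamma", g2 = "gamma", g3 = "gamma", out = "out")
  same <- incongruence_report(marker, marker, cls)
  expect_equal(same$rf, 0)
  expect_equal(nrow(same$scattered), 0)
  # graft g1 inside the alpha clade of the gene tree
  gene <- ape::read.tree(
    text = "(((al1:1,g1:1):1,(al2:1,al3:1):1):1,(g2:1,g3:1):1,out:2);")
  rep1 <- incongruence_report(marker, gene, cls, root_leaf = "out")
  expect_gt(rep1$rf, 0)
  expect_true("g1" %in% rep1$scattered$leaf)
  expect_true("alpha" %in% rep1$scattered$host_class)
  mono <- rep1$monophyly
  expect_true(mono$marker[mono$class == "gamma"])
  expect_false(mono$gene[mono$class == "gamma"])
  # RF is symmetric
  rep2 <- incongruence_report(gene, marker, cls, root_leaf = "out")
  expect_equal(rep1$rf, rep2$rf)
  expect_error(incongruence_report(
    ape::read.tree(text = "(al1:1,(al2:1,g1:1):1);"),
    gene, cls), "fewer than 4")
})

test_that("gamma shape recovery on simulated data stays within 20%", {
  set.seed(12)
  tt <- ape::rtree(8)
  tt$edge.length <- pmax(tt$edge.length * 0.4, 0.05)
  for (a_true in c(0.5, 2)) {
    gen <- make_subst_model("JC", alpha = a_true, k = 4)
    al <- simulate_alignment(tt, gen, 1000, seed = 300 + a_true * 10)
    start <- make_subst_model("JC", alpha = 1, k = 4)
    tr0 <- optimize_branch_lengths(ape::unroot(tt), al, start, rounds = 1)
    fit <- fit_gamma_alpha(tr0, al, start, outer_rounds = 2)
    expect_lt(abs(fit$alpha - a_true) / a_true, 0.2)
  }
})
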