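DNA4 <- c("A", "C", "G", "T")

#' Build a substitution model
#'
#' Supported kinds: `"LG"` (amino acids, Le-Gascuel exchangeabilities,
#' `+F` empirical frequencies when supplied), `"GTR"` (nucleotides, six
#' exchangeabilities, optional proportion of invariant sites) and `"JC"`
#' (equal-rate nucleotide model, mostly for closed-form oracles). Rate
#' heterogeneity uses a discrete gamma with `k` categories placed at the
#' category medians and renormalized to mean rate 1; the rate matrix is
#' scaled to one expected substitution per unit branch length.
#'
#' @param kind `"LG"`, `"GTR"` or `"JC"`.
#' @param frequencies Equilibrium frequencies (named by state); defaults to
#'   the LG frequencies or uniform for nucleotides. Supplying alignment
#'   frequencies gives the `+F` variant.
#' @param gtr_rates Six GTR exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @param alpha Gamma shape; `Inf` disables rate heterogeneity.
#' @param k Number of discrete gamma categories.
#' @param pinv Proportion of invariant sites (nucleotide models only).
#' @return Object of class `subst_model`.
#' @export
make_subst_model <- function(kind = c("LG", "GTR", "JC"), frequencies = NULL,
                             gtr_rates = rep(1, 6), alpha = 1, k = 4L,
                             pinv = 0) {
  kind <- match.arg(kind)
  if (kind == "LG") {
    states <- .LG_AA_ORDER
    S <- matrix(0, 20, 20, dimnames = list(states, states))
    S[lower.tri(S)] <- .LG_EXCH_LOWER
    S <- S + t(S)
    pi <- if (is.null(frequencies)) {
      stats::setNames(.LG_FREQS, states)
    } else frequencies[states]
    if (pinv != 0) stop("+I is only supported for nucleotide models")
  } else {
    states <- DNA4
    if (kind == "JC") gtr_rates <- rep(1, 6)
    S <- matrix(0, 4, 4, dimnames = list(states, states))
    S["C", "A"] <- gtr_rates[1]; S["G", "A"] <- gtr_rates[2]
    S["T", "A"] <- gtr_rates[3]; S["G", "C"] <- gtr_rates[4]
    S["T", "C"] <- gtr_rates[5]; S["T", "G"] <- gtr_rates[6]
    S <- S + t(S)
    pi <- if (is.null(frequencies)) {
      stats::setNames(rep(0.25, 4), states)
    } else frequencies[states]
  }
  pi <- pi / sum(pi)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(states, states)
  # reversible: symmetrize with sqrt(pi) for a stable eigendecomposition
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  rates <- discrete_gamma_rates(alpha, k)
  structure(list(kind = kind, states = states, Q = Q, pi = pi,
                 alpha = alpha, k = as.integer(k), rates = rates,
                 pinv = pinv,
                 eig_values = eig$values,
                 U = diag(1 / d) %*% eig$vectors,
                 Uinv = t(eig$vectors) %*% diag(d)),
            class = "subst_model")
}

#' Discrete gamma category rates (median discretization, mean 1)
#'
#' @param alpha Gamma shape parameter.
#' @param k Number of categories.
#' @return Numeric vector of `k` rates with mean exactly 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (!is.finite(alpha) || k == 1L) return(rep(1, k))
  r <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k), shape = alpha,
                     rate = alpha)
  r / mean(r)
}

#' Transition probability matrix P(t) for a model
#'
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions/site).
#' @param rate Rate multiplier (gamma category).
#' @return A stochastic matrix over the model's states.
#' @export
prob_matrix <- function(model, t, rate = 1) {
  P <- model$U %*% (exp(model$eig_values * t * rate) * model$Uinv)
  P[P < 0] <- 0
  dimnames(P) <- list(model$states, model$states)
  P
}

#' Construct a multiple sequence alignment object
#'
#' @param ids Row ids.
#' @param seqs Equal-length aligned sequences (gaps `-`).
#' @param alphabet `"protein"` or `"dna"`.
#' @return Object of class `msa`.
#' @export
msa <- function(ids, seqs, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(ids) == length(seqs), length(unique(nchar(seqs))) == 1)
  structure(list(ids = ids, seqs = toupper(seqs),
                 ncol = nchar(seqs[1]), alphabet = alphabet),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$ids), x$alphabet, "rows x", x$ncol, "columns\n")
  invisible(x)
}

msa_index <- function(aln, states) {
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  idx <- matrix(match(mat, states), nrow = nrow(mat))
  rownames(idx) <- aln$ids
  idx  # NA for gaps/ambiguity = missing data
}

# collapse alignment columns into unique site patterns with weights
msa_patterns <- function(aln, states) {
  idx <- msa_index(aln, states)
  key <- apply(idx, 2, paste, collapse = ",")
  uk <- unique(key)
  pos <- match(key, uk)
  w <- tabulate(pos, nbins = length(uk))
  list(idx = idx[, match(uk, key), drop = FALSE], weights = w)
}

#' Pairwise maximum-likelihood distances under a substitution model
#'
#' For each pair of rows the distance maximizing the two-sequence likelihood
#' (with the model's discrete-gamma mixture) is found by 1-D optimization;
#' pairwise-complete sites only. Saturated pairs whose optimum hits the cap
#' are set to `max_dist` with a warning.
#'
#' @param aln An [msa()].
#' @param model A `subst_model`.
#' @param max_dist Distance cap.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
ml_distance <- function(aln, model, max_dist = 10) {
  n <- length(aln$ids)
  stopifnot(n >= 2)
  idx <- msa_index(aln, model$states)
  ns <- length(model$states)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  lpi <- model$pi
  capped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
      if (!any(ok)) { D[i, j] <- D[j, i] <- max_dist; capped <- TRUE; next }
      tab <- table(factor(idx[i, ok], levels = seq_len(ns)),
                   factor(idx[j, ok], levels = seq_len(ns)))
      cnt <- as.numeric(tab)
      nz <- cnt > 0
      a <- as.integer(row(tab))[nz]; b <- as.integer(col(tab))[nz]
      cnt <- cnt[nz]
      if (all(a == b)) { D[i, j] <- D[j, i] <- 0; next }
      nll <- function(t) {
        mix <- 0
        for (r in model$rates) mix <- mix + prob_matrix(model, t, r)
        mix <- mix / length(model$rates)
        lik <- lpi[a] * mix[cbind(a, b)]
        -sum(cnt * log(pmax(lik, 1e-300)))
      }
      opt <- stats::optimize(nll, c(1e-8, max_dist), tol = 1e-8)
      d <- opt$minimum
      if (d > max_dist * 0.99) { d <- max_dist; capped <- TRUE }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (capped) warning("saturated pair(s) capped at max_dist = ", max_dist)
  D
}

#' BioNJ tree from a distance matrix
#'
#' Variance-weighted neighbor joining via [ape::bionj()], with input checks;
#' returns an unrooted tree.
#'
#' @param distances Symmetric distance matrix (>= 4 taxa).
#' @return An `ape::phylo` tree.
#' @export
bionj_tree <- function(distances) {
  if (any(!is.finite(distances))) stop("non-finite distance")
  stopifnot(nrow(distances) >= 4)
  ape::bionj(stats::as.dist(distances))
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Discrete-gamma mixture over site rates; gaps are missing data; column
#' likelihoods are computed with per-node rescaling so large trees do not
#' underflow. With `pinv > 0` (nucleotide models) the invariant-site mixture
#' component is added and gamma category rates are inflated by
#' `1 / (1 - pinv)`.
#'
#' @param tree `ape::phylo` with branch lengths; leaves must match `aln$ids`.
#' @param aln An [msa()].
#' @param model A `subst_model`.
#' @return Total log-likelihood (numeric scalar).
#' @export
tree_loglik <- function(tree, aln, model) {
  if (aln$ncol == 0) stop("zero-length alignment")
  stopifnot(setequal(tree$tip.label, aln$ids))
  pat <- msa_patterns(aln, model$states)
  tree_loglik_patterns(tree, pat, model)
}

tree_loglik_patterns <- function(tree, pat, model) {
  idx <- pat$idx[tree$tip.label, , drop = FALSE]
  np <- ncol(idx)
  ns <- length(model$states)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tr$Nnode
  rates <- model$rates
  pinv <- model$pinv
  if (pinv > 0) rates <- rates / (1 - pinv)
  K <- length(rates)

  tip_partial <- function(tipidx) {
    L <- matrix(0, ns, np)
    obs <- !is.na(idx[tipidx, ])
    L[cbind(idx[tipidx, obs], which(obs))] <- 1
    L[, !obs] <- 1
    L
  }

  site_lik <- matrix(0, K, np)
  for (ci in seq_len(K)) {
    partial <- vector("list", nnode)
    logscale <- numeric(np)
    Pcache <- list()
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      P <- prob_matrix(model, tr$edge.length[e], rates[ci])
      Lc <- if (child <= ntip) tip_partial(child) else partial[[child]]
      cond <- P %*% Lc  # cond[s] = sum_j P(s -> j) L_child(j)
      if (is.null(partial[[parent]])) {
        partial[[parent]] <- cond
      } else {
        partial[[parent]] <- partial[[parent]] * cond
      }
      if (child > ntip) partial[child] <- list(NULL)
      if (min(partial[[parent]]) < 1e-150) {
        mx <- colmax_fast(partial[[parent]])
        mx[mx == 0] <- 1
        partial[[parent]] <- sweep(partial[[parent]], 2, mx, "/")
        logscale <- logscale + log(mx)
      }
    }
    root <- tr$edge[nrow(tr$edge), 1]
    site_lik[ci, ] <- exp(log(pmax(as.numeric(model$pi %*% partial[[root]]),
                                   1e-300)) + logscale)
  }
  lik <- colMeans(site_lik)
  if (pinv > 0) {
    const <- apply(idx, 2, function(col) {
      s <- unique(col[!is.na(col)])
      if (length(s) == 0) 1 else if (length(s) == 1) model$pi[s] else 0
    })
    lik <- pinv * const + (1 - pinv) * lik
  }
  sum(pat$weights * log(pmax(lik, 1e-300)))
}

colmax_fast <- function(m) {
  mx <- m[1, ]
  for (r in seq_len(nrow(m))[-1]) mx <- pmax(mx, m[r, ])
  mx
}

#' Optimize branch lengths by coordinate ascent
#'
#' Round-robin Brent optimization of each branch length against the full
#' pruning likelihood.
#'
#' @param tree Starting tree with branch lengths.
#' @param aln Alignment.
#' @param model Substitution model.
#' @param rounds Sweeps over all edges.
#' @param max_blen Upper bound per branch.
#' @return The tree with optimized `edge.length` and attribute `loglik`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, rounds = 2,
                                    max_blen = 10) {
  pat <- msa_patterns(aln, model$states)
  tree <- optimize_blen_patterns(tree, pat, model, rounds, max_blen)
  tree
}

optimize_blen_patterns <- function(tree, pat, model, rounds = 2,
                                   max_blen = 10, tol = 1e-4) {
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  for (r in seq_len(rounds)) {
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(b) {
        tree$edge.length[e] <- b
        -tree_loglik_patterns(tree, pat, model)
      }
      cur <- tree$edge.length[e]
      fc <- f(cur)
      # bracket locally around the current value to keep Brent cheap
      opt <- stats::optimize(f, c(max(1e-9, cur / 30), min(max_blen, cur * 30 + 0.2)),
                             tol = tol)
      tree$edge.length[e] <- if (opt$objective <= fc) opt$minimum else cur
    }
  }
  attr(tree, "loglik") <- tree_loglik_patterns(tree, pat, model)
  tree
}

#' Estimate the gamma shape parameter on a fixed topology
#'
#' Alternates golden-section optimization of alpha on \[0.05, 10\] with
#' branch-length re-optimization.
#'
#' @param tree Tree with branch lengths.
#' @param aln Alignment.
#' @param model Substitution model (its `alpha` is the starting value).
#' @param outer_rounds Alternation rounds.
#' @return List with `alpha`, `tree`, `loglik`.
#' @export
fit_gamma_alpha <- function(tree, aln, model, outer_rounds = 2) {
  pat <- msa_patterns(aln, model$states)
  alpha <- model$alpha
  for (r in seq_len(outer_rounds)) {
    f <- function(a) {
      m <- model
      m$alpha <- a
      m$rates <- discrete_gamma_rates(a, model$k)
      -tree_loglik_patterns(tree, pat, m)
    }
    alpha <- stats::optimize(f, c(0.05, 10), tol = 1e-3)$minimum
    model$alpha <- alpha
    model$rates <- discrete_gamma_rates(alpha, model$k)
    tree <- optimize_blen_patterns(tree, pat, model, rounds = 1)
  }
  list(alpha = alpha, tree = tree, loglik = attr(tree, "loglik"),
       model = model)
}

random_topology <- function(ids) {
  ape::unroot(ape::rtree(length(ids), tip.label = sample(ids)))
}

#' All nearest-neighbor-interchange neighbors of an unrooted tree
#'
#' For every internal edge (u, v) the two topologies obtained by swapping one
#' of v's child subtrees with one of u's other subtrees; branch lengths
#' travel with their subtrees.
#'
#' @param tree Unrooted binary `ape::phylo`.
#' @return List of `phylo` neighbors (2 per internal edge).
#' @export
nni_neighbors <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    if (v <= ntip) next
    w_edge <- which(tree$edge[, 1] == u & seq_len(nrow(tree$edge)) != e)[1]
    c_edges <- which(tree$edge[, 1] == v)
    if (is.na(w_edge) || length(c_edges) < 2) next
    for (ce in c_edges[1:2]) {
      nt <- tree
      nt$edge[ce, 1] <- u
      nt$edge[w_edge, 1] <- v
      attr(nt, "order") <- NULL
      nt <- ape::reorder.phylo(nt, "cladewise")
      out[[length(out) + 1]] <- nt
    }
  }
  out
}

#' Maximum-likelihood tree search by NNI hill climbing
#'
#' Multi-start search: a BioNJ tree on ML distances plus `n_starts - 1`
#' random leaf-order stepwise topologies. Each start is hill-climbed over
#' nearest-neighbor-interchange moves with branch-length optimization; the
#' per-start log-likelihood trajectory is monotone non-decreasing, and the
#' best tree over all starts is returned.
#'
#' @param aln Alignment (>= 4 rows).
#' @param model Substitution model.
#' @param n_starts Number of starting trees (first is always BioNJ).
#' @param seed RNG seed for the random starts.
#' @param start_tree Optional explicit extra starting tree.
#' @param max_nni_rounds Cap on NNI acceptance rounds per start.
#' @return Best tree with attributes `loglik` and `trajectories` (list of
#'   per-start log-likelihood vectors).
#' @export
nni_search <- function(aln, model, n_starts = 1, seed = 1, start_tree = NULL,
                       max_nni_rounds = 20) {
  stopifnot(n_starts >= 1, length(aln$ids) >= 4)
  pat <- msa_patterns(aln, model$states)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  starts <- list(bionj_tree(ml_distance(aln, model)))
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) starts <- c(starts, list(random_topology(aln$ids)))
  }
  if (!is.null(start_tree)) starts <- c(starts, list(start_tree))
  best <- NULL; best_ll <- -Inf
  trajectories <- list()
  for (s in seq_along(starts)) {
    tr <- starts[[s]]
    if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
    tr$edge.length[tr$edge.length <= 0] <- 1e-6
    tr <- optimize_blen_patterns(tr, pat, model, rounds = 2)
    ll <- attr(tr, "loglik")
    traj <- ll
    for (round in seq_len(max_nni_rounds)) {
      nb <- nni_neighbors(tr)
      cand_best <- NULL; cand_ll <- ll
      for (cand in nb) {
        if (is.null(cand$edge.length)) cand$edge.length <- rep(0.1, nrow(cand$edge))
        cand <- optimize_blen_patterns(cand, pat, model, rounds = 1)
        cll <- attr(cand, "loglik")
        if (cll > cand_ll + 1e-6) { cand_best <- cand; cand_ll <- cll }
      }
      if (is.null(cand_best)) break
      tr <- optimize_blen_patterns(cand_best, pat, model, rounds = 1)
      ll <- attr(tr, "loglik")
      traj <- c(traj, ll)
    }
    trajectories[[s]] <- traj
    if (ll > best_ll) { best <- tr; best_ll <- ll }
  }
  attr(best, "loglik") <- best_ll
  attr(best, "trajectories") <- trajectories
  best
}

#' Nonparametric bootstrap supports for a tree
#'
#' Site-resampled replicates are rebuilt with `builder` (`"bionj"` rebuilds
#' BioNJ on ML distances, the scaled-down default; `"nni"` runs the full NNI
#' search) and each bipartition of `best_tree` gets the fraction of
#' replicates containing it, stored in `node.label`.
#'
#' @param best_tree Reference tree; inferred with `builder` when `NULL`.
#' @param aln Alignment.
#' @param model Substitution model.
#' @param reps Replicates (>= 50 enforced).
#' @param seed RNG seed.
#' @param builder `"bionj"` or `"nni"`.
#' @return `best_tree` with supports in `node.label` (root label empty).
#' @export
bootstrap_support <- function(best_tree = NULL, aln, model, reps = 100,
                              seed = 1, builder = c("bionj", "nni")) {
  if (reps < 50) stop("refusing to bootstrap with fewer than 50 replicates")
  builder <- match.arg(builder)
  build <- function(a) {
    if (builder == "bionj") bionj_tree(ml_distance(a, model))
    else nni_search(a, model, n_starts = 1, seed = seed)
  }
  if (is.null(best_tree)) best_tree <- build(aln)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  rep_trees <- vector("list", reps)
  for (r in seq_len(reps)) {
    cols <- sample.int(aln$ncol, aln$ncol, replace = TRUE)
    seqs <- vapply(strsplit(aln$seqs, ""), function(ch)
      paste(ch[cols], collapse = ""), character(1))
    rep_trees[[r]] <- build(msa(aln$ids, seqs, aln$alphabet))
  }
  class(rep_trees) <- "multiPhylo"
  counts <- ape::prop.clades(best_tree, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  best_tree$node.label <- formatC(counts / reps, digits = 4, format = "f")
  best_tree$node.label[1] <- ""
  best_tree
}

#' Extract well-supported anchored clades from a tree
#'
#' Returns the maximal clades whose defining-edge support is at least
#' `threshold` and that contain at least one anchor (characterized) leaf;
#' each clade's substrate is taken from its anchors. Leaves in no such clade
#' are reported unassigned.
#'
#' @param tree Tree with supports in `node.label` (see [tree_supports()]).
#' @param threshold Minimum support (default 0.9).
#' @param anchors Named character vector: leaf id -> substrate.
#' @return List of clade groups (`group_id`, `members`, `support`,
#'   `anchors`, `substrate`) plus attribute `unassigned`.
#' @export
extract_clades <- function(tree, threshold = 0.9, anchors) {
  if (length(anchors) == 0 || !any(names(anchors) %in% tree$tip.label)) {
    warning("no anchors present in the tree; no clades extracted")
    out <- list()
    attr(out, "unassigned") <- tree$tip.label
    return(out)
  }
  sup <- tree_supports(tree)
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  clade_tips <- lapply(nodes, function(nd) {
    tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1]]]
  })
  sizes <- lengths(clade_tips)
  ord <- order(sizes, decreasing = TRUE)
  accepted <- list()
  covered <- character()
  for (o in ord) {
    nd <- nodes[o]
    if (nd == ntip + 1) next  # root edge has no defining bipartition support
    s <- sup[nd - ntip]
    if (is.na(s) || s < threshold) next
    tips <- clade_tips[[o]]
    anc <- intersect(tips, names(anchors))
    if (length(anc) == 0) next
    if (all(tips %in% covered)) next
    if (any(tips %in% covered)) next  # maximal, disjoint groups
    substrate <- unique(anchors[anc])
    accepted[[length(accepted) + 1]] <- list(
      group_id = paste0("G", length(accepted) + 1),
      members = tips, support = s, anchors = anc,
      substrate = paste(substrate, collapse = "/"))
    covered <- c(covered, tips)
  }
  attr(accepted, "unassigned") <- setdiff(tree$tip.label, covered)
  accepted
}

# does the leaf set form a bipartition of the unrooted tree?
split_in_tree <- function(tree, tips) {
  n <- length(tree$tip.label)
  s <- length(tips)
  if (s <= 1 || s >= n - 1) return(TRUE)
  parts <- ape::prop.part(tree)
  target <- sort(match(tips, tree$tip.label))
  comp <- sort(setdiff(seq_len(n), target))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, target) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}

#' Topological incongruence report between a marker tree and a gene tree
#'
#' Restricts both trees to their shared leaves, then reports the
#' Robinson-Foulds distance, a per-class monophyly verdict in each tree, and
#' the "scattered" taxa: leaves nested inside a different class's smallest
#' containing clade in the gene tree but not in the marker tree (the classic
#' footprint of horizontally transferred genes).
#'
#' @param tree_marker Species/marker tree (e.g., 16S rRNA).
#' @param tree_gene Gene tree (e.g., CopA).
#' @param class_labels Named character vector: leaf id -> taxon class.
#' @param root_leaf Leaf used to root both trees for nesting queries;
#'   defaults to a member of the smallest class.
#' @return List with `rf`, `n_shared`, `monophyly` (data frame) and
#'   `scattered` (data frame leaf/class/host_class).
#' @export
incongruence_report <- function(tree_marker, tree_gene, class_labels,
                                root_leaf = NULL) {
  shared <- intersect(tree_marker$tip.label, tree_gene$tip.label)
  if (length(shared) < 4) stop("fewer than 4 shared leaves")
  tm <- ape::keep.tip(tree_marker, shared)
  tg <- ape::keep.tip(tree_gene, shared)
  rf <- phangorn::RF.dist(ape::unroot(tm), ape::unroot(tg))
  cls <- class_labels[shared]
  classes <- unique(cls)
  monophyly <- do.call(rbind, lapply(classes, function(cc) {
    tips <- shared[cls == cc]
    data.frame(class = cc,
               marker = split_in_tree(tm, tips),
               gene = split_in_tree(tg, tips))
  }))
  if (is.null(root_leaf)) {
    smallest <- classes[which.min(table(cls)[classes])]
    root_leaf <- shared[cls == smallest][1]
  }
  rtm <- ape::root(tm, outgroup = root_leaf, resolve.root = TRUE)
  rtg <- ape::root(tg, outgroup = root_leaf, resolve.root = TRUE)
  scattered <- list()
  for (host in classes) {
    tips <- setdiff(shared[cls == host], root_leaf)
    if (length(tips) < 2) next
    dg <- clade_members(rtg, tips)
    dm <- clade_members(rtm, tips)
    if (is.null(dg) || is.null(dm)) next
    for (x in setdiff(dg, tips)) {
      if (!x %in% dm && x != root_leaf) {
        scattered[[length(scattered) + 1]] <- data.frame(
          leaf = x, class = unname(cls[x]), host_class = host)
      }
    }
  }
  scattered <- if (length(scattered)) do.call(rbind, scattered) else
    data.frame(leaf = character(), class = character(),
               host_class = character())
  list(rf = rf, n_shared = length(shared), monophyly = monophyly,
       scattered = scattered)
}

# tips descending from the MRCA of `tips` in a rooted tree, or NULL when the
# MRCA is the root (uninformative host clade)
clade_members <- function(rtree, tips) {
  ntip <- length(rtree$tip.label)
  mrca <- ape::getMRCA(rtree, tips)
  if (is.null(mrca) || mrca == ntip + 1) return(NULL)
  rtree$tip.label[phangorn::Descendants(rtree, mrca, "tips")[[1]]]
}
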