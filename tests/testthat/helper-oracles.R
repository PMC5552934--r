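# Independent oracles used across the suite. Each implements the quantity a
# package routine computes, by a different route (enumeration, closed form,
# naive DP), and must stay independent of the package internals it checks.

# --- profile HMM: exhaustive path enumeration (M <= 4, |seq| <= 6) --------

enumerate_profile_paths <- function(profile, seq) {
  x <- copascan:::seq_to_idx(seq)
  L <- length(x); M <- profile$M
  lg <- copascan:::profile_logs(profile)
  best <- -Inf; total <- -Inf
  lse <- function(a, b) {
    if (!is.finite(a)) return(b)
    if (!is.finite(b)) return(a)
    max(a, b) + log1p(exp(-abs(a - b)))
  }
  rec <- function(state, k, pos, sc) {
    nexts <- if (state == "M") {
      n <- list(c("M", k + 1, lg$lMM[k + 1]), c("I", k, lg$lMI[k + 1]))
      if (k + 1 <= M) c(n, list(c("D", k + 1, lg$lMD[k + 1]))) else n
    } else if (state == "I") {
      list(c("M", k + 1, lg$lIM[k + 1]), c("I", k, lg$lII[k + 1]))
    } else {
      if (k < M) list(c("M", k + 1, lg$lDM[k]), c("D", k + 1, lg$lDD[k]))
      else list(c("M", k + 1, lg$lDM[k]))
    }
    for (nx in nexts) {
      ns <- nx[1]; nk <- as.integer(nx[2]); t <- as.numeric(nx[3])
      if (ns == "M" && nk == M + 1) {
        if (pos == L) { s <- sc + t; best <<- max(best, s); total <<- lse(total, s) }
        next
      }
      if (ns == "M") {
        if (pos + 1 > L || nk > M) next
        e <- if (is.na(x[pos + 1])) 0 else profile$log_odds[nk, x[pos + 1]]
        rec("M", nk, pos + 1, sc + t + e)
      } else if (ns == "I") {
        if (pos + 1 > L) next
        rec("I", nk, pos + 1, sc + t)
      } else {
        rec("D", nk, pos, sc + t)
      }
    }
  }
  rec("M", 0L, 0L, 0)
  list(viterbi = best, forward = total)
}

random_tiny_profile <- function(seed) {
  set.seed(seed)
  repeat {
    M <- sample(2:4, 1)
    rows <- replicate(3, paste(
      sample(c(copascan:::AA20, "-"), M + 1, replace = TRUE,
             prob = c(rep(0.04, 20), 0.2)), collapse = ""))
    rows[1] <- gsub("-", "A", rows[1])
    sa <- try(seed_alignment(letters[1:3], rows), silent = TRUE)
    if (inherits(sa, "try-error")) next
    p <- try(suppressWarnings(build_profile(sa, 0.5, 1)), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

# --- phylogenetics: brute-force likelihood over internal states ----------

brute_force_loglik <- function(tree, aln, model) {
  idx <- copascan:::msa_index(aln, model$states)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  idx <- idx[tr$tip.label, , drop = FALSE]
  nnode <- ntip + tr$Nnode
  internal <- (ntip + 1):nnode
  ns <- length(model$states)
  K <- length(model$rates)
  edges <- tr$edge
  site_lik <- function(site_states) {
    tot <- 0
    for (r in model$rates) {
      Ps <- lapply(seq_len(nrow(edges)), function(e) {
        as.matrix(Matrix::expm(model$Q * tr$edge.length[e] * r))
      })
      grid <- do.call(expand.grid, rep(list(seq_len(ns)), length(internal)))
      s <- 0
      root <- edges[nrow(edges), 1]
      for (g in seq_len(nrow(grid))) {
        assign_state <- function(nd) {
          if (nd <= ntip) site_states[nd] else
            grid[g, match(nd, internal)]
        }
        pr <- model$pi[assign_state(root)]
        ok <- TRUE
        for (e in seq_len(nrow(edges))) {
          ps <- assign_state(edges[e, 1]); cs <- assign_state(edges[e, 2])
          if (is.na(cs)) next  # gap tip: marginalized by summing all states
          pr <- pr * Ps[[e]][ps, cs]
        }
        s <- s + pr
      }
      tot <- tot + s / K
    }
    tot
  }
  ll <- 0
  for (j in seq_len(ncol(idx))) {
    col <- idx[, j]
    if (anyNA(col)) {
      # marginalize gap tips by explicit summation
      gaps <- which(is.na(col))
      combos <- do.call(expand.grid, rep(list(seq_len(ns)), length(gaps)))
      s <- 0
      for (g in seq_len(nrow(combos))) {
        col2 <- col
        col2[gaps] <- as.numeric(combos[g, ])
        s <- s + site_lik(col2)
      }
      # each gap tip sums over all its states
      ll <- ll + log(s)
    } else {
      ll <- ll + log(site_lik(col))
    }
  }
  ll
}

# --- pairwise alignment: naive affine-gap Smith-Waterman -----------------

sw_affine_score <- function(q, s, mat, open = 10, ext = 0.5) {
  qa <- strsplit(q, "")[[1]]; sa <- strsplit(s, "")[[1]]
  n <- length(qa); m <- length(sa)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qa[i - 1], sa[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# --- shared expensive fixtures (built once per test run) -----------------

.fixtures <- new.env()

get_cu_seed <- function() {
  if (is.null(.fixtures$cu_seed)) {
    .fixtures$cu_seed <- cu_atpase_seed(n_per_subtype = 2, seed = 100,
                                        noise = 0.05)
  }
  .fixtures$cu_seed
}

get_cu_profile <- function() {
  if (is.null(.fixtures$cu_profile)) {
    .fixtures$cu_profile <- build_profile(get_cu_seed()$seed)
  }
  .fixtures$cu_profile
}

get_chap_profiles <- function() {
  if (is.null(.fixtures$chap_profiles)) {
    .fixtures$chap_profiles <- chaperone_profiles(seed = 3)
  }
  .fixtures$chap_profiles
}

classify_via_profile <- function(rec, profile = get_cu_profile()) {
  h <- viterbi_align(profile, rec$sequence)
  mp <- extract_regions(h, rec$sequence)
  classify_subtype(mp, fix_context = rec$fix_context)
}
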