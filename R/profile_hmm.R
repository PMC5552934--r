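AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a seed alignment object
#'
#' @param ids Character vector of row ids.
#' @param gapped Character vector of equal-length gapped sequences
#'   (`-` or `.` for gaps).
#' @return An object of class `seed_alignment`.
#' @export
seed_alignment <- function(ids, gapped) {
  stopifnot(length(ids) == length(gapped), length(ids) >= 1)
  gapped <- toupper(gsub(".", "-", gapped, fixed = TRUE))
  w <- unique(nchar(gapped))
  if (length(w) != 1) stop("all gapped sequences must have equal length")
  mat <- do.call(rbind, strsplit(gapped, ""))
  occ <- colMeans(mat != "-")
  structure(list(ids = ids, mat = mat, ncol = w,
                 occupancy = occ), class = "seed_alignment")
}

#' Build a profile HMM from a seed alignment
#'
#' Columns whose residue occupancy is at least `occupancy_threshold` become
#' match states; the rest are modeled by insert states. Match emissions mix
#' observed counts with `pseudocount_weight` times the background:
#' `P(a) = (count_a + w * bg_a) / (n + w)`. Transition probabilities are
#' estimated from the implied per-row state paths with an analogous
#' pseudocount spread uniformly over each state's outgoing edges. Background
#' residue frequencies are estimated from the seed itself (uniform 1/20
#' fallback for unseen residues).
#'
#' @param seed A [seed_alignment()].
#' @param occupancy_threshold Occupancy needed for a match state, in (0, 1].
#' @param pseudocount_weight Pseudocount mass added per distribution.
#' @return Object of class `profile_hmm` with `M` match states, emission and
#'   transition probabilities, and the match-state -> seed-column map.
#' @export
build_profile <- function(seed, occupancy_threshold = 0.5,
                          pseudocount_weight = 1) {
  stopifnot(inherits(seed, "seed_alignment"),
            occupancy_threshold > 0, occupancy_threshold <= 1)
  if (any(seed$occupancy == 0)) {
    warning(sum(seed$occupancy == 0), " all-gap column(s) dropped")
  }
  is_match <- seed$occupancy >= occupancy_threshold
  M <- sum(is_match)
  if (M == 0) stop("no columns pass the occupancy threshold; zero match states")
  match_cols <- which(is_match)

  residues <- seed$mat[seed$mat != "-" & seed$mat != "X"]
  bg <- rep(1 / 20, 20)
  names(bg) <- AA20
  if (length(residues) > 0) {
    tab <- table(factor(residues, levels = AA20))
    if (sum(tab) > 0) bg <- (as.numeric(tab) + 1) / (sum(tab) + 20)
    names(bg) <- AA20
  }

  w <- pseudocount_weight
  emis <- matrix(0, M, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(M)) {
    col <- seed$mat[, match_cols[j]]
    col <- col[col != "-" & col != "X"]
    cnt <- as.numeric(table(factor(col, levels = AA20)))
    emis[j, ] <- (cnt + w * bg) / (length(col) + w)
  }

  trans <- count_seed_transitions(seed$mat, is_match, M, w)

  prof <- structure(c(list(M = M, alphabet = AA20, match_emis = emis,
                           bg = bg, match_cols = match_cols,
                           occupancy_threshold = occupancy_threshold),
                      trans),
                    class = "profile_hmm")
  prof$log_odds <- log(sweep(emis, 2, bg, "/"))
  prof
}

# Count M/I/D transitions along each seed row and convert to probabilities.
# State indexing: M_0 is begin, M_{M+1} is end; I_k sits between M_k and
# M_{k+1}; D_k parallels M_k.
count_seed_transitions <- function(mat, is_match, M, w) {
  cMM <- numeric(M + 1); cMI <- numeric(M + 1); cMD <- numeric(M + 1)
  cIM <- numeric(M + 1); cII <- numeric(M + 1)
  cDM <- numeric(M); cDD <- numeric(M)
  match_idx <- cumsum(is_match)
  for (r in seq_len(nrow(mat))) {
    prev <- c("M", 0L)  # begin
    for (j in seq_len(ncol(mat))) {
      ch <- mat[r, j]
      if (is_match[j]) {
        k <- match_idx[j]
        st <- if (ch == "-") c("D", k) else c("M", k)
      } else {
        if (ch == "-") next
        st <- c("I", match_idx[j])
      }
      pk <- as.integer(prev[2])
      if (prev[1] == "M") {
        if (st[1] == "M") cMM[pk + 1] <- cMM[pk + 1] + 1
        else if (st[1] == "I") cMI[pk + 1] <- cMI[pk + 1] + 1
        else cMD[pk + 1] <- cMD[pk + 1] + 1
      } else if (prev[1] == "I") {
        if (st[1] == "M") cIM[pk + 1] <- cIM[pk + 1] + 1
        else cII[pk + 1] <- cII[pk + 1] + 1
      } else {
        if (st[1] == "M") cDM[pk] <- cDM[pk] + 1
        else cDD[pk] <- cDD[pk] + 1
      }
      prev <- st
    }
    # close with end state (M_{M+1})
    pk <- as.integer(prev[2])
    if (prev[1] == "M") cMM[pk + 1] <- cMM[pk + 1] + 1
    else if (prev[1] == "I") cIM[pk + 1] <- cIM[pk + 1] + 1
    else cDM[pk] <- cDM[pk] + 1
  }
  norm3 <- function(a, b, cc) {
    tot <- a + b + cc + w
    list((a + w / 3) / tot, (b + w / 3) / tot, (cc + w / 3) / tot)
  }
  norm2 <- function(a, b) {
    tot <- a + b + w
    list((a + w / 2) / tot, (b + w / 2) / tot)
  }
  tMM <- numeric(M + 1); tMI <- numeric(M + 1); tMD <- numeric(M + 1)
  for (k in seq_len(M + 1)) {
    if (k <= M) {
      p <- norm3(cMM[k], cMI[k], cMD[k])
      tMM[k] <- p[[1]]; tMI[k] <- p[[2]]; tMD[k] <- p[[3]]
    } else {
      p <- norm2(cMM[k], cMI[k])  # from M_M: only E or I_M
      tMM[k] <- p[[1]]; tMI[k] <- p[[2]]
    }
  }
  tIM <- numeric(M + 1); tII <- numeric(M + 1)
  for (k in seq_len(M + 1)) {
    p <- norm2(cIM[k], cII[k])
    tIM[k] <- p[[1]]; tII[k] <- p[[2]]
  }
  tDM <- numeric(M); tDD <- numeric(M)
  if (M >= 1) {
    for (k in seq_len(M)) {
      if (k < M) {
        p <- norm2(cDM[k], cDD[k])
        tDM[k] <- p[[1]]; tDD[k] <- p[[2]]
      } else {
        tDM[k] <- 1; tDD[k] <- 0  # D_M can only exit to E
      }
    }
  }
  list(tMM = tMM, tMI = tMI, tMD = tMD, tIM = tIM, tII = tII,
       tDM = tDM, tDD = tDD)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm with", x$M, "match states",
      if (!is.null(x$calibration)) "(calibrated)" else "(uncalibrated)", "\n")
  invisible(x)
}

seq_to_idx <- function(seq, alphabet = AA20) {
  idx <- match(strsplit(toupper(seq), "")[[1]], alphabet)
  idx  # NA for X / unknown -> emission log-odds 0
}

profile_logs <- function(p) {
  list(lMM = log(p$tMM), lMI = log(p$tMI), lMD = log(c(p$tMD[seq_len(p$M)])),
       lIM = log(p$tIM), lII = log(p$tII),
       lDM = log(p$tDM), lDD = log(c(p$tDD[seq_len(max(p$M - 1, 0))], 0)))
}

#' Align a sequence to a profile HMM (Viterbi)
#'
#' Computes the maximum log-odds state path through the standard
#' seven-transition profile topology, global in the model with flanking
#' insert states (so N/C-terminal overhangs are absorbed by I_0 / I_M).
#' Scores are log-odds against the profile background, reported in bits.
#'
#' @param profile A [build_profile()] result.
#' @param seq Amino-acid sequence (string).
#' @return List of class `hmm_hit` with `score_bits`, `score_nats`, `path`
#'   (character vector of states like `"M3"`, `"I0"`, `"D2"` bracketed by
#'   `"B"`/`"E"`) and `colmap` (per-residue match-state index, `NA` for
#'   insert-emitted residues).
#' @export
viterbi_align <- function(profile, seq) {
  x <- seq_to_idx(seq)
  L <- length(x)
  if (L == 0) stop("empty sequence")
  M <- profile$M
  lg <- profile_logs(profile)
  lo <- profile$log_odds
  # cdd[j] = sum_{l<=j} lDD[l]; D-chain cost M_j -> D_{j+1} -> .. -> D_k is
  # lMD[j+1] + cdd[k-1] - cdd[j]
  cdd <- cumsum(lg$lDD[seq_len(max(M - 1, 0))])

  NEG <- -Inf
  vm <- matrix(NEG, M, L + 1)   # [k, i+1]
  vi <- matrix(NEG, M + 1, L + 1)  # I_0..I_M -> rows 1..M+1
  vd <- matrix(NEG, M, L + 1)
  # i = 0: begin at M_0 with value 0; D chain from begin
  b0 <- 0
  vd[1, 1] <- b0 + lg$lMD[1]
  if (M > 1) {
    for (k in 2:M) vd[k, 1] <- vd[k - 1, 1] + lg$lDD[k - 1]
  }
  for (i in seq_len(L)) {
    e <- if (is.na(x[i])) rep(0, M) else lo[, x[i]]
    mprev <- vm[, i]; iprev <- vi[, i]; dprev <- vd[, i]
    bprev <- if (i == 1) b0 else NEG
    cand1 <- c(bprev, mprev[seq_len(M - 1)]) + lg$lMM[seq_len(M)]
    cand2 <- iprev[seq_len(M)] + lg$lIM[seq_len(M)]
    cand3 <- c(NEG, dprev[seq_len(M - 1)] + lg$lDM[seq_len(M - 1)])
    newm <- e + pmax(cand1, cand2, cand3)
    vm[, i + 1] <- newm
    # insert states I_0..I_M (emit at background: log-odds 0)
    msrc <- c(bprev, mprev)  # M_k feeding I_k, k=0..M
    vi[, i + 1] <- pmax(msrc + lg$lMI, iprev + lg$lII)
    # delete states from current-column matches via cummax scan
    if (M > 1) {
      a <- newm[seq_len(M - 1)] + lg$lMD[2:M] - cdd[seq_len(M - 1)]
      vd[2:M, i + 1] <- cdd[seq_len(M - 1)] + cummax(a)
    }
    vd[1, i + 1] <- NEG  # D_1 only reachable from begin (i = 0)
  }
  iL <- L + 1
  ends <- c(vm[M, iL] + lg$lMM[M + 1],
            vi[M + 1, iL] + lg$lIM[M + 1],
            vd[M, iL] + lg$lDM[M])
  score <- max(ends)
  path <- viterbi_traceback(profile, lg, x, vm, vi, vd, b0, which.max(ends))
  colmap <- rep(NA_integer_, L)
  pos <- 0L
  for (st in path) {
    t <- substr(st, 1, 1)
    if (t == "M" && st != "B" && st != "E") {
      pos <- pos + 1L
      colmap[pos] <- as.integer(substring(st, 2))
    } else if (t == "I") {
      pos <- pos + 1L
    }
  }
  structure(list(id = attr(seq, "id"), score_nats = score,
                 score_bits = score / log(2), path = path, colmap = colmap),
            class = "hmm_hit")
}

viterbi_traceback <- function(profile, lg, x, vm, vi, vd, b0, end_choice) {
  M <- profile$M; L <- length(x)
  eps <- 1e-9
  st <- switch(end_choice, c("M", M), c("I", M), c("D", M))
  i <- L
  path <- c("E")
  repeat {
    k <- as.integer(st[2])
    path <- c(paste0(st[1], k), path)
    if (st[1] == "M") {
      val <- vm[k, i + 1]
      e <- if (is.na(x[i])) 0 else profile$log_odds[k, x[i]]
      mp <- if (k > 1) vm[k - 1, i] else if (i == 1) b0 else -Inf
      ip <- vi[k, i]
      dp <- if (k > 1) vd[k - 1, i] else -Inf
      if (k == 1 && i == 1 && abs(val - (e + b0 + lg$lMM[1])) < eps) {
        path <- c("B", path); break
      }
      if (is.finite(mp) && abs(val - (e + mp + lg$lMM[k])) < eps) {
        if (k == 1) { path <- c("B", path); break }
        st <- c("M", k - 1); i <- i - 1
      } else if (is.finite(ip) && abs(val - (e + ip + lg$lIM[k])) < eps) {
        st <- c("I", k - 1); i <- i - 1
      } else {
        st <- c("D", k - 1); i <- i - 1
      }
    } else if (st[1] == "I") {
      val <- vi[k + 1, i + 1]
      mp <- if (k == 0) (if (i == 1) b0 else -Inf) else vm[k, i]
      ip <- vi[k + 1, i]
      if (is.finite(mp) && abs(val - (mp + lg$lMI[k + 1])) < eps) {
        if (k == 0) { path <- c("B", path); break }
        st <- c("M", k); i <- i - 1
      } else if (is.finite(ip) && abs(val - (ip + lg$lII[k + 1])) < eps) {
        st <- c("I", k); i <- i - 1
      } else {
        if (k == 0 && i == 1) { path <- c("B", path); break }
        stop("traceback failure at I", k)
      }
    } else {  # D_k, same column i
      val <- vd[k, i + 1]
      if (k == 1) {
        path <- c("B", path); break  # D_1 only from begin, i must be 0
      }
      mp <- vm[k - 1, i + 1]
      dp <- vd[k - 1, i + 1]
      if (is.finite(mp) && abs(val - (mp + lg$lMD[k])) < eps) {
        st <- c("M", k - 1)
      } else {
        st <- c("D", k - 1)
      }
    }
    if (i < 0) stop("traceback ran past sequence start")
  }
  # rename boundary match states
  path[path == "M0"] <- "B"
  path
}

#' Recompute the log-odds score of an explicit state path
#'
#' Replays a Viterbi path through the profile, summing transition and emission
#' log-odds terms; used as an internal-consistency oracle for the DP.
#'
#' @param profile A `profile_hmm`.
#' @param seq The aligned sequence.
#' @param path State path as returned by [viterbi_align()].
#' @return Log-odds score in nats.
#' @export
score_path <- function(profile, seq, path) {
  x <- seq_to_idx(seq)
  lg <- profile_logs(profile)
  score <- 0
  pos <- 0L
  states <- path[path != "B" & path != "E"]
  prev <- c("M", 0L)
  for (st in c(states, "END")) {
    if (st == "END") cur <- c("M", profile$M + 1L)
    else cur <- c(substr(st, 1, 1), as.integer(substring(st, 2)))
    pk <- as.integer(prev[2]); ck <- as.integer(cur[2])
    score <- score + switch(prev[1],
      M = switch(cur[1], M = lg$lMM[pk + 1], I = lg$lMI[pk + 1],
                 D = lg$lMD[pk + 1]),
      I = switch(cur[1], M = lg$lIM[pk + 1], I = lg$lII[pk + 1],
                 D = stop("I->D transition is not in the topology")),
      D = switch(cur[1], M = lg$lDM[pk], D = lg$lDD[pk],
                 I = stop("D->I transition is not in the topology")))
    if (st != "END") {
      if (cur[1] == "M") {
        pos <- pos + 1L
        if (!is.na(x[pos])) score <- score + profile$log_odds[ck, x[pos]]
      } else if (cur[1] == "I") {
        pos <- pos + 1L  # background emission, log-odds 0
      }
    }
    prev <- cur
  }
  if (pos != length(x)) stop("path emits ", pos, " residues for a length-",
                             length(x), " sequence")
  score
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- -Inf
  out
}

#' Forward-algorithm log-odds score of a sequence against a profile
#'
#' @param profile A `profile_hmm`.
#' @param seq Amino-acid sequence.
#' @return List with `score_nats` and `score_bits` (log-sum over all paths).
#' @export
forward_score <- function(profile, seq) {
  x <- seq_to_idx(seq)
  L <- length(x)
  if (L == 0) stop("empty sequence")
  M <- profile$M
  lg <- profile_logs(profile)
  lo <- profile$log_odds
  NEG <- -Inf
  fm <- rep(NEG, M); fi <- rep(NEG, M + 1); fd <- rep(NEG, M)
  cdd <- cumsum(lg$lDD[seq_len(max(M - 1, 0))])
  b0 <- 0
  fd[1] <- b0 + lg$lMD[1]
  if (M > 1) for (k in 2:M) fd[k] <- fd[k - 1] + lg$lDD[k - 1]
  for (i in seq_len(L)) {
    e <- if (is.na(x[i])) rep(0, M) else lo[, x[i]]
    bprev <- if (i == 1) b0 else NEG
    cand1 <- c(bprev, fm[seq_len(M - 1)]) + lg$lMM[seq_len(M)]
    cand2 <- fi[seq_len(M)] + lg$lIM[seq_len(M)]
    cand3 <- c(NEG, fd[seq_len(M - 1)] + lg$lDM[seq_len(M - 1)])
    newm <- e + logsumexp2(logsumexp2(cand1, cand2), cand3)
    msrc <- c(bprev, fm)
    newi <- logsumexp2(msrc + lg$lMI, fi + lg$lII)
    newd <- rep(NEG, M)
    if (M > 1) {
      # prefix log-sum-exp over the delete chain:
      # newd[k] = log sum_{j<k} exp(newm[j] + lMD[j+1] + cdd[k-1] - cdd[j])
      a <- newm[seq_len(M - 1)] + lg$lMD[2:M] - cdd[seq_len(M - 1)]
      amax <- max(a)
      if (is.finite(amax)) {
        newd[2:M] <- cdd[seq_len(M - 1)] + amax +
          log(cumsum(exp(a - amax)))
      }
    }
    fm <- newm; fi <- newi; fd <- newd
  }
  score <- logsumexp2(logsumexp2(fm[M] + lg$lMM[M + 1],
                                 fi[M + 1] + lg$lIM[M + 1]),
                      fd[M] + lg$lDM[M])
  list(score_nats = score, score_bits = score / log(2))
}

#' Calibrate a profile's E-value statistics by decoy shuffling
#'
#' Scores `n_decoys` residue-shuffled decoy sequences with the forward
#' algorithm and fits a Gumbel (extreme value) distribution to the bit scores
#' by the method of moments. E-values in [hmm_search()] are then
#' `N * P(S >= s)` under this fit, with `N` the database size.
#'
#' @param profile A `profile_hmm`.
#' @param decoy_source Character vector of sequences to shuffle for decoys;
#'   when `NULL`, decoys are drawn i.i.d. from the profile background.
#' @param n_decoys Number of decoys (>= 50 enforced).
#' @param seed Integer RNG seed.
#' @param decoy_length Length of background-sampled decoys.
#' @return The profile with a `calibration` element (`mu`, `beta`, scores).
#' @export
calibrate_profile <- function(profile, decoy_source = NULL, n_decoys = 200,
                              seed = 1, decoy_length = NULL) {
  if (n_decoys < 50) stop("refusing to calibrate with fewer than 50 decoys")
  if (is.null(decoy_length)) {
    decoy_length <- if (!is.null(decoy_source)) {
      as.integer(stats::median(nchar(decoy_source)))
    } else {
      profile$M
    }
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  decoys <- vapply(seq_len(n_decoys), function(i) {
    if (!is.null(decoy_source)) {
      src <- decoy_source[[((i - 1L) %% length(decoy_source)) + 1L]]
      paste(sample(strsplit(src, "")[[1]]), collapse = "")
    } else {
      paste(sample(AA20, decoy_length, replace = TRUE, prob = profile$bg),
            collapse = "")
    }
  }, character(1))
  scores <- vapply(decoys, function(s) forward_score(profile, s)$score_bits,
                   numeric(1))
  lens <- nchar(decoys)
  # null scores depend strongly on sequence length (each residue short of M
  # costs a deletion); regress it out and fit the Gumbel on the residuals
  if (stats::sd(lens) > 0) {
    fit <- stats::lm(scores ~ lens)
    coefs <- unname(stats::coef(fit))
    resid <- stats::residuals(fit)
  } else {
    coefs <- c(mean(scores), 0)
    resid <- scores - mean(scores)
  }
  beta <- stats::sd(resid) * sqrt(6) / pi
  mu <- 0.5772156649 * -beta  # residuals have mean 0
  profile$calibration <- list(mu = mu, beta = beta,
                              intercept = coefs[1], slope = coefs[2],
                              n_decoys = n_decoys, seed = seed)
  profile
}

# length-corrected decoy-relative score used for the Gumbel tail
calibrated_excess <- function(cal, score_bits, len) {
  score_bits - (cal$intercept + cal$slope * len)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

gumbel_pvalue <- function(s, mu, beta) {
  # upper tail of a Gumbel(mu, beta)
  -expm1(-exp(-(s - mu) / beta))
}

#' Search a protein database with a profile HMM
#'
#' Forward-algorithm bit scores with Gumbel-calibrated E-values, scaled by
#' database size; hits at or below the E-value cutoff are returned sorted by
#' score, each with its Viterbi alignment path.
#'
#' @param profile A `profile_hmm`, calibrated or not.
#' @param records Protein records data frame ([read_fasta()]).
#' @param evalue_cutoff E-value threshold (default `1e-3`).
#' @param calibration List with `n_decoys` and `seed` used when the profile
#'   carries no calibration.
#' @return Data frame of hits (`id`, `score_bits`, `evalue`) with the per-hit
#'   `hmm_hit` objects in the `hits` attribute.
#' @export
hmm_search <- function(profile, records, evalue_cutoff = 1e-3,
                       calibration = list(n_decoys = 200, seed = 1)) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (is.null(profile$calibration)) {
    profile <- calibrate_profile(profile, decoy_source = records$sequence,
                                 n_decoys = calibration$n_decoys,
                                 seed = calibration$seed)
  }
  cal <- profile$calibration
  bits <- vapply(records$sequence,
                 function(s) forward_score(profile, s)$score_bits, numeric(1))
  bits <- unname(bits)
  excess <- calibrated_excess(cal, bits, nchar(records$sequence))
  ev <- nrow(records) * gumbel_pvalue(excess, cal$mu, cal$beta)
  keep <- which(ev <= evalue_cutoff)
  keep <- keep[order(bits[keep], decreasing = TRUE)]
  hits <- lapply(keep, function(i) {
    h <- viterbi_align(profile, records$sequence[i])
    h$id <- records$id[i]
    h$evalue <- ev[i]
    h
  })
  out <- data.frame(id = records$id[keep],
                    score_bits = bits[keep],
                    evalue = ev[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "hits") <- hits
  attr(out, "calibration") <- cal
  out
}

#' A2M-style aligned string for a hit
#'
#' Uppercase letters are match-emitted residues, lowercase insert-emitted
#' residues, `-` deletions, so every A2M string has one column per match
#' state plus local insertions.
#'
#' @param hit An `hmm_hit`.
#' @param seq The sequence that was aligned.
#' @return A single A2M string.
#' @export
a2m_string <- function(hit, seq) {
  chars <- strsplit(seq, "")[[1]]
  out <- character(0)
  pos <- 0L
  for (st in hit$path) {
    t <- substr(st, 1, 1)
    if (st == "B" || st == "E") next
    if (t == "M") {
      pos <- pos + 1L
      out <- c(out, toupper(chars[pos]))
    } else if (t == "I") {
      pos <- pos + 1L
      out <- c(out, tolower(chars[pos]))
    } else {
      out <- c(out, "-")
    }
  }
  paste(out, collapse = "")
}

#' Matrix of match-state residues for a set of hits
#'
#' Projects each hit onto the profile's match states (inserts dropped,
#' deletions as `-`), yielding a fixed-width alignment usable for phylogeny.
#'
#' @param hits_df Result of [hmm_search()].
#' @param records The records that were searched.
#' @param profile The profile used.
#' @return Data frame `id`, `aligned` (strings of width `profile$M`).
#' @export
match_state_msa <- function(hits_df, records, profile) {
  hits <- attr(hits_df, "hits")
  aligned <- vapply(hits, function(h) {
    s <- records$sequence[records$id == h$id][1]
    chars <- strsplit(s, "")[[1]]
    row <- rep("-", profile$M)
    mapped <- which(!is.na(h$colmap))
    row[h$colmap[mapped]] <- chars[mapped]
    paste(row, collapse = "")
  }, character(1))
  data.frame(id = hits_df$id, aligned = aligned, stringsAsFactors = FALSE)
}

#' Serialize a profile HMM to a versioned JSON text file
#'
#' @param profile A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  obj <- unclass(profile)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a profile HMM written by [write_profile()]
#'
#' @param path Path to the JSON profile.
#' @return A `profile_hmm`.
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported profile format version")
  }
  obj$format_version <- NULL
  obj$match_emis <- matrix(unlist(obj$match_emis), nrow = obj$M, byrow = FALSE,
                           dimnames = list(NULL, AA20))
  obj$log_odds <- matrix(unlist(obj$log_odds), nrow = obj$M, byrow = FALSE,
                         dimnames = list(NULL, AA20))
  names(obj$bg) <- AA20
  structure(obj, class = "profile_hmm")
}
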