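CU_SUBTYPES <- c("P1B-1", "P1B-1a", "P1B-1b", "P1B-1c", "P1B-3", "P1B-3a")

# background alphabets: cysteine is excluded everywhere outside planted
# motifs (Cys is rare and spurious CXXC/CXCXC motifs would corrupt ground
# truth); histidine is additionally excluded from the N-MBD background so
# His-richness is only ever a planted feature
BG_NMBD <- setdiff(AA20, c("C", "H"))
BG_REST <- setdiff(AA20, "C")

CU_TEMPLATE_LENGTH <- 320L

# planted motif layout per subtype; positions refer to the fixed 320-residue
# template whose anchors are cu_atpase_anchors()
cu_subtype_template <- function(subtype) {
  common <- list(list(pos = 240L, text = "YNAAAAP"))  # TM7 YN(X)4P
  plants <- switch(subtype,
    "P1B-1" = list(list(pos = 20L, text = "CASC"),
                   list(pos = 60L, text = "CASC"),
                   list(pos = 200L, text = "CPC"),
                   list(pos = 280L, text = "MALSS")),
    "P1B-1a" = list(list(pos = 5L, text = "HHHHHHHH"),
                    list(pos = 40L, text = "CPIC"),
                    list(pos = 200L, text = "CPC"),
                    list(pos = 280L, text = "MSLSS")),
    "P1B-1b" = list(list(pos = 5L, text = "HHHHHHH"),
                    list(pos = 20L, text = "CACAC"),
                    list(pos = 40L, text = "CGCGC"),
                    list(pos = 160L, text = "CPKC"),
                    list(pos = 200L, text = "CPC"),
                    list(pos = 280L, text = "MSLSS")),
    "P1B-1c" = list(list(pos = 20L, text = "CAGC"),
                    list(pos = 200L, text = "CPC"),
                    list(pos = 280L, text = "MSGSS")),
    "P1B-3" = list(list(pos = 5L, text = "HHHHHHHH"),
                   list(pos = 200L, text = "CPH"),
                   list(pos = 280L, text = "MSAST")),
    "P1B-3a" = list(list(pos = 200L, text = "CPD"),
                    list(pos = 280L, text = "MSGSS")),
    stop("unknown subtype: ", subtype))
  c(plants, common)
}

#' Generate a synthetic Cu-ATPase with a known subtype
#'
#' Builds a 320-residue protein from a controlled random background and
#' plants the subtype's signature motif layout (N-MBD CXXC variant / His-rich
#' stretch / TRASH repeats, the TM6 triad, the TM7 YN(X)4P motif and the TM8
#' pentad) at the fixed template coordinates of [cu_atpase_anchors()].
#' Optional substitution noise is applied outside the planted motif spans.
#'
# deterministic family-wide background consensus: homologous Cu-ATPases
# share a conserved core onto which subtype motifs are planted
cu_consensus <- function() {
  if (!is.null(.copascan_cache$cu_consensus)) {
    return(.copascan_cache$cu_consensus)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(90001L)
  anchors <- cu_atpase_anchors()
  ch <- character(CU_TEMPLATE_LENGTH)
  nm <- seq(anchors$n_mbd[1], anchors$n_mbd[2])
  ch[nm] <- sample(BG_NMBD, length(nm), replace = TRUE)
  rest <- setdiff(seq_len(CU_TEMPLATE_LENGTH), nm)
  ch[rest] <- sample(BG_REST, length(rest), replace = TRUE)
  .copascan_cache$cu_consensus <- ch
  ch
}

#' @param subtype One of the six copper subtypes.
#' @param seed RNG seed.
#' @param noise Per-residue substitution probability outside motifs
#'   (divergence from the family consensus).
#' @param noise_alphabet Residues used for noise; callers needing exact motif
#'   ground truth restrict this to a cysteine-free alphabet.
#' @param id Record id.
#' @return One-row protein records data frame with `truth_subtype` and
#'   `fix_context` columns.
#' @export
make_cu_atpase <- function(subtype, seed = 1, noise = 0,
                           noise_alphabet = AA20, id = NULL) {
  subtype <- match.arg(subtype, CU_SUBTYPES)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ch <- cu_consensus()
  protected <- integer()
  for (pl in cu_subtype_template(subtype)) {
    span <- pl$pos:(pl$pos + nchar(pl$text) - 1L)
    ch[span] <- strsplit(pl$text, "")[[1]]
    protected <- c(protected, span)
  }
  if (noise > 0) {
    free <- setdiff(seq_len(CU_TEMPLATE_LENGTH), protected)
    hit <- free[stats::runif(length(free)) < noise]
    if (length(hit)) {
      ch[hit] <- sample(noise_alphabet, length(hit), replace = TRUE)
    }
  }
  if (is.null(id)) id <- paste0("cuatp_", subtype, "_", seed)
  data.frame(id = id, sequence = paste(ch, collapse = ""),
             genome_id = NA_character_, replicon = "unknown",
             truth_subtype = subtype,
             fix_context = subtype == "P1B-1c",
             stringsAsFactors = FALSE)
}

#' Seed alignment of characterized synthetic Cu-ATPases
#'
#' Noise-free template proteins, `n_per_subtype` per subtype, stacked as an
#' ungapped alignment (all templates share the fixed layout). Used to build
#' the ad hoc retrieval profile and to calibrate region anchors.
#'
#' @param n_per_subtype Rows per subtype.
#' @param seed RNG seed.
#' @param noise Optional within-seed divergence.
#' @return List with `seed` ([seed_alignment()]) and `meta` (data frame with
#'   `truth_subtype` and `substrate`).
#' @export
cu_atpase_seed <- function(n_per_subtype = 3, seed = 100, noise = 0.05) {
  recs <- list()
  for (s in CU_SUBTYPES) {
    for (i in seq_len(n_per_subtype)) {
      r <- make_cu_atpase(s, seed = seed + length(recs),
                          noise = noise, noise_alphabet = BG_REST)
      r$id <- paste0("anchor_", s, "_", i)
      recs[[length(recs) + 1]] <- r
    }
  }
  df <- do.call(rbind, recs)
  df$substrate <- ifelse(grepl("^P1B-3", df$truth_subtype), "Cu2+", "Cu+")
  list(seed = seed_alignment(df$id, df$sequence), meta = df)
}

#' Random background protein (non-homologous negative control)
#'
#' @param length Protein length.
#' @param seed RNG seed.
#' @param id Record id.
#' @return One-row protein records data frame.
#' @export
make_background_protein <- function(length = 250, seed = 1, id = "bgprot") {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  data.frame(id = id,
             sequence = paste(sample(AA20, length, replace = TRUE),
                              collapse = ""),
             genome_id = NA_character_, replicon = "unknown",
             stringsAsFactors = FALSE)
}

chaperone_consensus <- function(family) {
  key <- paste0("consensus_", family)
  if (!is.null(.copascan_cache[[key]])) return(.copascan_cache[[key]])
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(match(family, c("CopZ", "CupA", "CusF")) * 7919L)
  cons <- switch(family,
    CopZ = {
      ch <- sample(BG_NMBD, 80, replace = TRUE)
      ch[1:6] <- strsplit("MTCAAC", "")[[1]]
      ch
    },
    CupA = {
      ch <- sample(BG_NMBD, 120, replace = TRUE)
      ch[1:19] <- sample(c("I", "L", "V", "F", "A"), 19, replace = TRUE,
                         prob = c(0.3, 0.3, 0.25, 0.1, 0.05))
      ch[1] <- "M"
      ch
    },
    CusF = {
      ch <- sample(BG_NMBD, 100, replace = TRUE)
      ch[23] <- "K"; ch[30] <- "K"; ch[31] <- "K"; ch[35] <- "H"
      ch[36] <- "H"; ch[47] <- "M"; ch[49] <- "M"; ch[50] <- "R"
      ch
    },
    stop("unknown family: ", family))
  .copascan_cache[[key]] <- cons
  cons
}

chaperone_protected <- function(family) {
  switch(family,
         CopZ = 1:6,
         CupA = 1:19,
         CusF = c(23, 30, 31, 35, 36, 47, 49, 50))
}

#' Generate a synthetic copper chaperone
#'
#' Family members are the fixed family consensus with `divergence`
#' substitutions outside the protected motif positions. The CusF
#' electropositive positions (23/30/31/35/50) can optionally be polymorphized
#' while the invariant H36/M47/M49 stay fixed.
#'
#' @param family `"CopZ"`, `"CupA"` or `"CusF"`.
#' @param seed RNG seed.
#' @param divergence Substitution rate outside protected positions.
#' @param polymorphic For CusF, substitute the electropositive residues with
#'   probability 0.3 each.
#' @param id Record id.
#' @return One-row protein records data frame with `truth_family`.
#' @export
make_chaperone <- function(family, seed = 1, divergence = 0.08,
                           polymorphic = FALSE, id = NULL) {
  family <- match.arg(family, c("CopZ", "CupA", "CusF"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ch <- chaperone_consensus(family)
  prot <- chaperone_protected(family)
  free <- setdiff(seq_along(ch), prot)
  hit <- free[stats::runif(length(free)) < divergence]
  if (length(hit)) ch[hit] <- sample(BG_NMBD, length(hit), replace = TRUE)
  if (family == "CusF" && polymorphic) {
    for (p in c(23, 30, 31, 35, 50)) {
      if (stats::runif(1) < 0.3) ch[p] <- sample(c("K", "R", "Q", "E", "A"), 1)
    }
  }
  if (is.null(id)) id <- paste0(tolower(family), "_", seed)
  data.frame(id = id, sequence = paste(ch, collapse = ""),
             genome_id = NA_character_, replicon = "unknown",
             truth_family = family, stringsAsFactors = FALSE)
}

#' Seed alignment for a chaperone family profile
#'
#' @param family Chaperone family.
#' @param n Number of rows.
#' @param seed RNG seed.
#' @return A [seed_alignment()]; for CusF the first row is the reference
#'   (`CusF_ref`) whose numbering defines the canonical positions.
#' @export
chaperone_seed <- function(family, n = 15, seed = 500) {
  ids <- character(n); seqs <- character(n)
  cons <- paste(chaperone_consensus(family), collapse = "")
  ids[1] <- paste0(family, "_ref"); seqs[1] <- cons
  for (i in seq_len(n - 1)) {
    r <- make_chaperone(family, seed = seed + i, divergence = 0.06)
    ids[i + 1] <- paste0(family, "_seed", i)
    seqs[i + 1] <- r$sequence
  }
  seed_alignment(ids, seqs)
}

#' Build and calibrate the three chaperone detection profiles
#'
#' @param seed RNG seed for decoy calibration.
#' @param n Seed rows per family.
#' @return List with calibrated `copz`, `cupa`, `cusf` profiles (the CusF
#'   profile carries its canonical `position_map`).
#' @export
chaperone_profiles <- function(seed = 1, n = 15) {
  out <- list()
  for (fam in c("CopZ", "CupA", "CusF")) {
    sa <- chaperone_seed(fam, n = n, seed = 500 + 37 * match(fam, c("CopZ", "CupA", "CusF")))
    prof <- build_profile(sa)
    prof <- calibrate_profile(prof, n_decoys = 100, seed = seed,
                              decoy_length = sa$ncol)
    if (fam == "CusF") {
      prof$position_map <- cusf_position_map(sa, prof, "CusF_ref",
                                             c(23, 30, 31, 35, 36, 47, 49, 50))
    }
    out[[tolower(fam)]] <- prof
  }
  out
}

#' Random synonymous-codon preference weights
#'
#' Per-amino-acid preference weights over synonymous codons, optionally
#' tilted toward G+C-rich codons. `rotate = TRUE` reverses every
#' preference ranking, producing a maximally contrasting "donor" table.
#'
#' @param seed RNG seed.
#' @param gc_bias Multiplicative tilt per G/C base in the codon.
#' @param rotate Reverse the preference order within each amino acid.
#' @return Named numeric vector over sense codons (sums to 1 within each
#'   amino acid).
#' @export
random_codon_prefs <- function(seed = 1, gc_bias = 0, rotate = FALSE) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ct <- codon_table()
  sense <- ct[ct$aa != "*", ]
  prefs <- numeric(nrow(sense))
  names(prefs) <- sense$codon
  for (a in unique(sense$aa)) {
    idx <- which(sense$aa == a)
    w <- stats::rexp(length(idx)) + 0.1
    if (gc_bias != 0) {
      ngc <- vapply(sense$codon[idx], function(cc) {
        sum(strsplit(cc, "")[[1]] %in% c("G", "C"))
      }, numeric(1))
      w <- w * (1 + gc_bias)^ngc
    }
    if (rotate) w <- rev(sort(w))[rank(w)]  # best becomes worst
    prefs[idx] <- w / sum(w)
  }
  prefs
}

#' Reverse-complement-free synonymous CDS for a protein
#'
#' Samples one synonymous codon per residue according to `prefs`, then
#' greedily swaps synonymous codons to pull the realized G+C content within
#' +/- `gc_tol` points of `gc_target` (best-achievable with a warning when
#' the amino-acid sequence cannot reach the target). The translation is
#' invariant by construction. A stop codon (TAA) is appended.
#'
#' @param protein_seq Amino-acid sequence (no stop).
#' @param prefs Codon preference weights ([random_codon_prefs()]).
#' @param gc_target Target G+C percentage, or `NULL` to skip adjustment.
#' @param gc_tol Tolerance in points (default 0.5).
#' @param seed RNG seed.
#' @return Nucleotide CDS string (length `3 * (nchar(protein) + 1)`).
#' @export
make_cds <- function(protein_seq, prefs = random_codon_prefs(),
                     gc_target = NULL, gc_tol = 0.5, seed = 1) {
  if (!is.null(gc_target)) stopifnot(gc_target >= 25, gc_target <= 75)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ct <- codon_table()
  sense <- ct[ct$aa != "*", ]
  syn <- split(sense$codon, sense$aa)
  aa <- strsplit(toupper(protein_seq), "")[[1]]
  if (!all(aa %in% names(syn))) stop("protein contains letters with no codon")
  gc_of <- vapply(sense$codon, function(cc) {
    sum(strsplit(cc, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  cods <- vapply(aa, function(a) {
    s <- syn[[a]]
    if (length(s) == 1) s else sample(s, 1, prob = prefs[s])
  }, character(1))
  if (!is.null(gc_target)) {
    n_bases <- 3 * length(cods)
    gc_now <- sum(gc_of[cods])
    target_count <- gc_target / 100 * n_bases
    for (iter in seq_len(10 * length(cods))) {
      if (abs(100 * gc_now / n_bases - gc_target) <= gc_tol) break
      need_up <- gc_now < target_count
      pos <- sample(length(cods))
      moved <- FALSE
      for (i in pos) {
        s <- syn[[aa[i]]]
        if (length(s) == 1) next
        cur <- gc_of[cods[i]]
        cand <- if (need_up) s[gc_of[s] > cur] else s[gc_of[s] < cur]
        if (length(cand) == 0) next
        new <- if (length(cand) == 1) cand else sample(cand, 1)
        gc_now <- gc_now - cur + gc_of[new]
        cods[i] <- new
        moved <- TRUE
        break
      }
      if (!moved) {
        warning("gc_target ", gc_target, " infeasible; realized ",
                round(100 * gc_now / n_bases, 2))
        break
      }
    }
  }
  paste0(paste(cods, collapse = ""), "TAA")
}

#' Planted horizontal-gene-transfer scenario with ground truth
#'
#' Builds a single-genome bundle with `n_native` genes drawn from the native
#' codon preferences at the genome's G+C and `n_foreign` genes from a donor
#' with rotated codon preferences and G+C shifted by `delta_gc` points
#' (default +4.8). Every gene's closest database homolog is a mutated copy:
#' same-order (`Rhizobiales`) for native genes, foreign-order
#' (`gamma-proteobacteria`) for foreign genes. Foreign genes additionally get
#' metal/transposase-annotated neighbors. The truth list names the planted
#' foreign genes.
#'
#' @param n_native,n_foreign Gene counts.
#' @param delta_gc Foreign G+C shift in points.
#' @param seed RNG seed.
#' @param native_gc Genome G+C percentage.
#' @param gc_jitter SD of per-gene G+C around its class mean (default 0.5).
#' @param protein_length Residues per generated protein.
#' @return List with `bundle` ([genome_bundle()]), `db` (homolog records),
#'   `usage` (host [codon_usage_table()]), `truth` (foreign gene ids).
#' @export
make_hgt_scenario <- function(n_native = 20, n_foreign = 10, delta_gc = 4.8,
                              seed = 1, native_gc = 60, gc_jitter = 0.5,
                              protein_length = 150) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  native_prefs <- random_codon_prefs(seed = seed + 1)
  donor_prefs <- random_codon_prefs(seed = seed + 1, rotate = TRUE)
  n <- n_native + n_foreign
  is_foreign <- c(rep(FALSE, n_native), rep(TRUE, n_foreign))
  prot <- list(); cds <- list(); db <- list(); ann <- list()
  pos <- 1000L
  # alanine/glycine/arginine-rich composition typical of GC-rich genomes, so
  # that G+C targets up to ~65% + 4.8 points stay synonymous-reachable
  aa_pool <- BG_REST
  aa_w <- stats::setNames(rep(1, length(aa_pool)), aa_pool)
  aa_w[c("A", "G", "R", "P")] <- 4
  aa_w[c("L", "V")] <- 2
  for (i in seq_len(n)) {
    gid <- sprintf("gene%03d", i)
    aaseq <- paste(c("M", sample(aa_pool, protein_length - 1, replace = TRUE,
                                 prob = aa_w)),
                   collapse = "")
    gc_i <- (if (is_foreign[i]) native_gc + delta_gc else native_gc) +
      stats::rnorm(1, 0, gc_jitter)
    gc_i <- min(max(gc_i, 25), 75)
    nt <- make_cds(aaseq, prefs = if (is_foreign[i]) donor_prefs else
      native_prefs, gc_target = gc_i, seed = seed + 100 + i)
    prot[[i]] <- data.frame(id = gid, sequence = aaseq, genome_id = "synthg",
                            replicon = "chromosome",
                            taxon_class = "Rhizobiales",
                            stringsAsFactors = FALSE)
    cds[[i]] <- data.frame(id = gid, sequence = nt, genome_id = "synthg",
                           product_protein_id = gid, stringsAsFactors = FALSE)
    # homolog: lightly mutated copy under the appropriate taxon label
    hseq <- strsplit(aaseq, "")[[1]]
    nmut <- max(1, round(0.05 * protein_length))
    at <- sample(protein_length, nmut)
    hseq[at] <- sample(BG_REST, nmut, replace = TRUE)
    db[[i]] <- data.frame(
      id = paste0("hom_", gid), sequence = paste(hseq, collapse = ""),
      genome_id = "donor", replicon = "unknown",
      taxon_class = if (is_foreign[i]) "gamma-proteobacteria" else
        "Rhizobiales",
      stringsAsFactors = FALSE)
    ann[[length(ann) + 1]] <- data.frame(
      feature_id = gid, replicon = "chr1", start = pos,
      end = pos + 3L * protein_length + 2L, strand = "+",
      stringsAsFactors = FALSE)
    ann[[length(ann)]]$keywords <- I(list(c("copper-translocating", "atpase")))
    if (is_foreign[i]) {
      for (j in 1:2) {
        nb <- pos + j * 600L
        ann[[length(ann) + 1]] <- data.frame(
          feature_id = paste0(gid, "_nb", j), replicon = "chr1",
          start = nb, end = nb + 450L, strand = "-",
          stringsAsFactors = FALSE)
        ann[[length(ann)]]$keywords <-
          I(list(if (j == 1) c("heavy", "metal", "transporter", "czc")
                 else c("transposase", "is66")))
      }
    }
    pos <- pos + 80000L  # genes isolated relative to the 75 kb cluster window
  }
  proteins <- do.call(rbind, prot)
  cds_df <- do.call(rbind, cds)
  annotation <- do.call(rbind, ann)
  usage <- codon_usage_table(cds_df$sequence[!is_foreign])
  bundle <- genome_bundle("synthg", proteins, cds_df, annotation,
                          genome_gc = native_gc)
  list(bundle = bundle, db = do.call(rbind, db), usage = usage,
       truth = cds_df$id[is_foreign])
}

#' Simulate an alignment along a tree under a substitution model
#'
#' Root states are drawn from the model's equilibrium frequencies and evolved
#' down every branch with the model's transition probabilities; each site
#' carries a gamma rate category sampled once at the root (no indels).
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param model A [make_subst_model()].
#' @param n_sites Alignment columns (> 0).
#' @param seed RNG seed.
#' @return An [msa()] over the tree's tip labels.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1) {
  if (n_sites <= 0) stop("zero sites requested")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  ns <- length(model$states)
  K <- length(model$rates)
  cat_idx <- sample.int(K, n_sites, replace = TRUE)
  states <- matrix(NA_integer_, nnode, n_sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(ns, n_sites, replace = TRUE, prob = model$pi)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    t <- tr$edge.length[e]
    for (ci in seq_len(K)) {
      P <- prob_matrix(model, t, model$rates[ci])
      for (s in seq_len(ns)) {
        sel <- which(cat_idx == ci & states[parent, ] == s)
        if (length(sel)) {
          states[child, sel] <- sample.int(ns, length(sel), replace = TRUE,
                                           prob = P[s, ])
        }
      }
    }
  }
  seqs <- vapply(seq_len(ntip), function(i) {
    paste(model$states[states[i, ]], collapse = "")
  }, character(1))
  msa(tr$tip.label, seqs,
      alphabet = if (ns == 4) "dna" else "protein")
}

#' Generate a multi-genome synthetic survey bundle with ground truth
#'
#' Emulates the statistical shape of a multireplicon Cu-ATPase survey:
#' per-genome Cu-ATPase copy numbers drawn from the reported copy-number
#' histogram, subtypes drawn with the reported prevalence ranking, a 43%
#' plasmid fraction, chaperone complements, decoy proteins, coding sequences
#' and GFF3-style annotation (FixI genes get cbb3-oxidase neighbors). All
#' truths are returned machine-readable; with `out_dir` the bundle is also
#' written as FASTA/GFF3/TSV plus a truth JSON.
#'
#' @param n_genomes Number of genomes (default 10).
#' @param seed RNG seed.
#' @param noise Off-motif substitution rate for ATPases (cysteine-free noise
#'   alphabet so motif ground truth stays exact).
#' @param plasmid_fraction Probability a Cu-ATPase is plasmid-borne.
#' @param out_dir Optional output directory.
#' @return List with `genomes` (list of [genome_bundle()]), `truth` (per
#'   genome: subtype table, chaperone table), `proteins` (all records),
#'   `paths` (when written).
#' @export
make_bundle <- function(n_genomes = 10, seed = 1, noise = 0.02,
                        plasmid_fraction = 0.43, out_dir = NULL) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  # reported copy-number histogram of surveyed multireplicon genomes as weights
  copy_values <- c(0, 1, 2, 3, 4, 5, 6, 8)
  copy_weights <- c(2, 11, 8, 11, 8, 5, 4, 2)
  subtype_weights <- c("P1B-1" = 88, "P1B-1a" = 77, "P1B-1b" = 36,
                       "P1B-1c" = 94, "P1B-3" = 13, "P1B-3a" = 6)
  prefs <- random_codon_prefs(seed = seed + 5)
  genomes <- list(); truth <- list(); all_prot <- list()
  uid <- 0L
  for (g in seq_len(n_genomes)) {
    gid <- sprintf("genome%02d", g)
    gc_g <- stats::runif(1, 57, 63)
    n_atp <- sample(copy_values, 1, prob = copy_weights)
    prot <- list(); cds <- list(); ann <- list()
    t_sub <- character(); t_rep <- character(); t_ids <- character()
    pos <- 1000L
    add_feature <- function(fid, repl, len, kw) {
      ann[[length(ann) + 1]] <<- local({
        d <- data.frame(feature_id = fid, replicon = repl, start = pos,
                        end = pos + len - 1L, strand = "+",
                        stringsAsFactors = FALSE)
        d$keywords <- I(list(kw))
        d
      })
      pos <<- pos + len + 500L
    }
    for (a in seq_len(n_atp)) {
      uid <- uid + 1L
      sub <- sample(names(subtype_weights), 1, prob = subtype_weights)
      repl <- if (stats::runif(1) < plasmid_fraction) "plasmid" else
        "chromosome"
      r <- make_cu_atpase(sub, seed = seed * 1000 + uid, noise = noise,
                          noise_alphabet = BG_REST,
                          id = sprintf("%s_atp%02d", gid, a))
      r$genome_id <- gid; r$replicon <- repl
      r$taxon_class <- "Rhizobiales"
      prot[[length(prot) + 1]] <- r
      nt <- make_cds(r$sequence, prefs = prefs, gc_target = gc_g,
                     seed = seed * 1000 + uid)
      cds[[length(cds) + 1]] <- data.frame(
        id = r$id, sequence = nt, genome_id = gid,
        product_protein_id = r$id, stringsAsFactors = FALSE)
      repl_name <- if (repl == "plasmid") "p1" else "chr"
      add_feature(r$id, repl_name, nchar(nt),
                  c("copper-translocating", "p-type", "atpase"))
      if (sub == "P1B-1c") {
        add_feature(paste0(r$id, "_fixn"), repl_name, 900L,
                    c("cbb3-type", "cytochrome", "oxidase", "fixn"))
      }
      t_sub <- c(t_sub, sub); t_rep <- c(t_rep, repl)
      t_ids <- c(t_ids, r$id)
    }
    chap <- list()
    for (fam in c("CopZ", "CupA", "CusF")) {
      k <- sample(0:2, 1, prob = c(0.4, 0.4, 0.2))
      for (j in seq_len(k)) {
        uid <- uid + 1L
        repl <- if (stats::runif(1) < 0.35) "plasmid" else "chromosome"
        r <- make_chaperone(fam, seed = seed * 2000 + uid,
                            polymorphic = fam == "CusF",
                            id = sprintf("%s_%s%d", gid, tolower(fam), j))
        r$genome_id <- gid; r$replicon <- repl
        prot[[length(prot) + 1]] <- r
        chap[[length(chap) + 1]] <- data.frame(
          id = r$id, family = fam, replicon = repl, stringsAsFactors = FALSE)
        nt <- make_cds(r$sequence, prefs = prefs, gc_target = gc_g,
                       seed = seed * 2000 + uid)
        cds[[length(cds) + 1]] <- data.frame(
          id = r$id, sequence = nt, genome_id = gid,
          product_protein_id = r$id, stringsAsFactors = FALSE)
        add_feature(r$id, if (repl == "plasmid") "p1" else "chr",
                    nchar(nt), c("copper", "chaperone"))
      }
    }
    for (d in 1:3) {
      uid <- uid + 1L
      r <- make_background_protein(sample(150:400, 1), seed = seed * 3000 + uid,
                                   id = sprintf("%s_dec%d", gid, d))
      r$genome_id <- gid; r$replicon <- "chromosome"
      prot[[length(prot) + 1]] <- r
      nt <- make_cds(r$sequence, prefs = prefs, gc_target = gc_g,
                     seed = seed * 3000 + uid)
      cds[[length(cds) + 1]] <- data.frame(
        id = r$id, sequence = nt, genome_id = gid,
        product_protein_id = r$id, stringsAsFactors = FALSE)
      add_feature(r$id, "chr", nchar(nt), c("hypothetical", "protein"))
    }
    proteins <- do.call(rbind, lapply(prot, function(p) {
      data.frame(id = p$id, sequence = p$sequence, genome_id = p$genome_id,
                 replicon = p$replicon,
                 taxon_class = if (!is.null(p$taxon_class)) p$taxon_class
                 else "Rhizobiales",
                 stringsAsFactors = FALSE)
    }))
    genomes[[gid]] <- genome_bundle(gid, proteins, do.call(rbind, cds),
                                    do.call(rbind, ann), genome_gc = gc_g)
    truth[[gid]] <- list(
      atpases = if (length(t_ids)) data.frame(
        id = t_ids, subtype = t_sub, replicon = t_rep,
        stringsAsFactors = FALSE) else
          data.frame(id = character(), subtype = character(),
                     replicon = character()),
      chaperones = if (length(chap)) do.call(rbind, chap) else
        data.frame(id = character(), family = character(),
                   replicon = character()))
    all_prot[[gid]] <- proteins
  }
  out <- list(genomes = genomes, truth = truth,
              proteins = do.call(rbind, all_prot))
  if (!is.null(out_dir)) out$paths <- write_bundle(out, out_dir)
  out
}

#' Write a synthetic bundle to disk as FASTA/GFF3/TSV + truth JSON
#'
#' @param bundle Result of [make_bundle()].
#' @param out_dir Output directory (created).
#' @return Named list of written paths, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (gid in names(bundle$genomes)) {
    b <- bundle$genomes[[gid]]
    pf <- file.path(out_dir, paste0(gid, "_proteins.faa"))
    write_fasta(b$proteins, pf)
    cf <- file.path(out_dir, paste0(gid, "_cds.fna"))
    write_fasta(b$cds[, c("id", "sequence", "genome_id")], cf)
    gf <- file.path(out_dir, paste0(gid, ".gff3"))
    write_gff3(b$annotation, gf)
    paths[[gid]] <- c(proteins = pf, cds = cf, gff = gf)
  }
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(bundle$truth, tj, auto_unbox = TRUE, digits = NA)
  paths$truth <- tj
  invisible(paths)
}

write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(ann))) {
    writeLines(paste(ann$replicon[i], "copascan", "CDS", ann$start[i],
                     ann$end[i], ".", ann$strand[i], "0",
                     paste0("ID=", ann$feature_id[i], ";product=",
                            paste(ann$keywords[[i]], collapse = " ")),
                     sep = "\t"), con)
  }
  invisible(path)
}
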