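#' G+C content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguity codes (N etc.) are excluded
#' from both numerator and denominator to avoid bias from unresolved bases.
#'
#' @param seq Nucleotide sequence (string).
#' @return Percentage in \[0, 100\].
#' @export
gc_content <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- sum(ch %in% c("A", "C", "G", "T"))
  if (n == 0) stop("no countable (ACGT) bases in sequence")
  100 * sum(ch %in% c("G", "C")) / n
}

#' Paired t-test for gene-vs-genome G+C deviation
#'
#' Each gene's G+C is compared with its own genome context; the mean
#' difference (in percentage points), the paired t statistic, the two-sided
#' p-value and the 99% confidence interval are reported.
#'
#' @param gene_gc Per-gene G+C percentages.
#' @param genome_gc Paired per-genome G+C percentages (same length).
#' @param conf_level Confidence level for the interval (default 0.99).
#' @return List with `mean_delta`, `t`, `df`, `p_value`, `conf_int`,
#'   `degenerate` (TRUE when the differences have zero variance, in which
#'   case no p-value is produced).
#' @export
gc_deviation_test <- function(gene_gc, genome_gc, conf_level = 0.99) {
  stopifnot(length(gene_gc) == length(genome_gc), length(gene_gc) >= 3)
  d <- gene_gc - genome_gc
  if (stats::sd(d) == 0) {
    return(list(mean_delta = mean(d), t = NA_real_, df = NA_real_,
                p_value = NA_real_, conf_int = c(NA_real_, NA_real_),
                degenerate = TRUE))
  }
  tt <- stats::t.test(gene_gc, genome_gc, paired = TRUE,
                      conf.level = conf_level)
  list(mean_delta = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value,
       conf_int = as.numeric(tt$conf.int), degenerate = FALSE)
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  data.frame(codon = names(gc), aa = unname(gc), stringsAsFactors = FALSE)
}

#' Build a codon usage table from a reference CDS set
#'
#' Counts codons over all frame-complete coding sequences and derives the
#' per-amino-acid relative adaptiveness `w(codon) = freq / max synonymous
#' freq`. Stop codons are excluded; codons unseen in the reference get
#' `w = w_floor` so the CAI geometric mean never collapses to zero.
#'
#' @param cds_seqs Character vector of CDS nucleotide sequences
#'   (lengths divisible by 3).
#' @param w_floor Lower bound for relative adaptiveness (default 0.01).
#' @return Object of class `codon_usage` with `counts`, `freq`, `w`, `aa`.
#' @export
codon_usage_table <- function(cds_seqs, w_floor = 0.01) {
  ct <- codon_table()
  counts <- stats::setNames(rep(0, nrow(ct)), ct$codon)
  for (s in cds_seqs) {
    s <- toupper(s)
    if (nchar(s) %% 3 != 0) {
      warning("sequence length not divisible by 3; trailing bases dropped")
      s <- substr(s, 1, nchar(s) - nchar(s) %% 3)
    }
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cod <- cod[cod %in% ct$codon]
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  keep <- ct$aa != "*"
  w <- counts
  for (a in unique(ct$aa[keep])) {
    idx <- which(ct$aa == a)
    mx <- max(counts[idx])
    w[idx] <- if (mx > 0) counts[idx] / mx else 1
  }
  w[keep] <- pmax(w[keep], w_floor)
  w[!keep] <- NA_real_
  structure(list(counts = counts, freq = counts / max(sum(counts), 1),
                 w = w, aa = stats::setNames(ct$aa, ct$codon),
                 w_floor = w_floor),
            class = "codon_usage")
}

codons_of <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

# codons that count toward CAI: exclude stops and the single-codon amino
# acids Met (ATG) and Trp (TGG), per standard CAI practice
cai_codons <- function(cod, usage) {
  aa <- usage$aa[cod]
  cod[!is.na(aa) & aa != "*" & aa != "M" & aa != "W"]
}

#' Codon adaptation index of a gene against a reference usage table
#'
#' Geometric mean of the relative adaptiveness `w` over the gene's codons,
#' excluding stop codons and the non-degenerate Met and Trp codons.
#'
#' @param gene_seq Frame-complete CDS (string).
#' @param usage A [codon_usage_table()].
#' @return CAI in (0, 1\].
#' @export
cai <- function(gene_seq, usage) {
  cod <- cai_codons(codons_of(gene_seq), usage)
  if (length(cod) == 0) stop("gene has no countable codons for CAI")
  exp(mean(log(usage$w[cod])))
}

#' Monte-Carlo expected CAI (eCAI)
#'
#' Generates `n` random coding sequences with exactly the query's amino-acid
#' composition, drawing each codon uniformly among its synonyms, and returns
#' the upper `1 - p` quantile of their CAI distribution. A gene whose
#' CAI falls below its eCAI has codon usage atypical for its genome at
#' significance level `p`.
#'
#' @param gene_seq Frame-complete CDS.
#' @param usage Reference [codon_usage_table()].
#' @param n Number of random sequences (>= 100 enforced; default 500).
#' @param p Significance level (default 0.01).
#' @param seed RNG seed.
#' @return eCAI value in (0, 1\].
#' @export
expected_cai <- function(gene_seq, usage, n = 500, p = 0.01, seed = 1) {
  if (n < 100) stop("n must be >= 100 for a stable eCAI quantile")
  cod <- cai_codons(codons_of(gene_seq), usage)
  if (length(cod) == 0) return(1)
  aa_seq <- usage$aa[cod]
  syn <- split(names(usage$aa)[usage$aa != "*"], usage$aa[usage$aa != "*"])
  logw <- log(usage$w)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  # one uniform synonymous draw per (position, replicate), position-major
  total <- numeric(n)
  for (i in seq_along(aa_seq)) {
    s <- syn[[aa_seq[i]]]
    draw <- if (length(s) == 1) rep(s, n) else
      s[sample.int(length(s), n, replace = TRUE)]
    total <- total + logw[draw]
  }
  cais <- exp(total / length(aa_seq))
  unname(stats::quantile(cais, probs = 1 - p, type = 7))
}

#' Normalized CAI and codon-usage deviance flag
#'
#' `CAI / eCAI`; values below one flag codon usage biased away from the
#' genome's preferences (the HGT signal used alongside the G+C test).
#'
#' @inheritParams expected_cai
#' @return List with `cai`, `ecai`, `ratio`, `deviant` (ratio < 1).
#' @export
normalized_cai <- function(gene_seq, usage, n = 500, p = 0.01, seed = 1) {
  v <- cai(gene_seq, usage)
  e <- expected_cai(gene_seq, usage, n = n, p = p, seed = seed)
  list(cai = v, ecai = e, ratio = v / e, deviant = v / e < 1)
}

#' Closest homolog of a query protein in a database
#'
#' Local pairwise alignment (BLOSUM62, affine gaps) of the query against
#' every database member; the best hit by score is summarized with percent
#' identity, percent similarity (positive substitution score pairs) and
#' query coverage. The `foreign` flag is set when identity > `min_identity`,
#' similarity > `min_similarity`, coverage > `min_coverage` and the subject's
#' taxon class differs from the query's.
#'
#' @param query One-row protein records data frame (or list with `id`,
#'   `sequence`, `taxon_class`).
#' @param db Protein records data frame with `taxon_class`.
#' @param min_identity,min_similarity,min_coverage Thresholds (percent).
#' @return List with `query_id`, `subject_id`, `subject_taxon`, `identity`,
#'   `similarity`, `coverage`, `score`, `foreign`.
#' @export
closest_homolog <- function(query, db, min_identity = 50,
                            min_similarity = 70, min_coverage = 90) {
  stopifnot(nrow(db) >= 1)
  qseq <- query$sequence[1]
  best <- NULL
  for (i in seq_len(nrow(db))) {
    al <- pairwise_stats(qseq, db$sequence[i])
    if (is.null(best) || al$score > best$score) {
      best <- al
      best$subject_id <- db$id[i]
      best$subject_taxon <- if (!is.null(db$taxon_class)) db$taxon_class[i]
        else NA_character_
    }
  }
  qt <- if (!is.null(query$taxon_class)) query$taxon_class[1] else NA_character_
  foreign <- !is.na(best$subject_taxon) && !is.na(qt) &&
    best$subject_taxon != qt &&
    best$identity > min_identity && best$similarity > min_similarity &&
    best$coverage > min_coverage
  list(query_id = query$id[1], subject_id = best$subject_id,
       subject_taxon = best$subject_taxon, identity = best$identity,
       similarity = best$similarity, coverage = best$coverage,
       score = best$score, foreign = foreign)
}

.copascan_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.copascan_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .copascan_cache$BLOSUM62 <- get("BLOSUM62", envir = e)
  }
  .copascan_cache$BLOSUM62
}

# identity/similarity/coverage from a local BLOSUM62 alignment
pairwise_stats <- function(qseq, sseq, gap_open = 10, gap_extend = 0.5) {
  mat <- blosum62()
  al <- Biostrings::pairwiseAlignment(qseq, sseq, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  len <- length(pa)
  aligned <- pa != "-" & sa != "-"
  ident <- sum(pa == sa & aligned)
  pos <- sum(vapply(which(aligned), function(i) {
    mat[pa[i], sa[i]] > 0
  }, logical(1)))
  qspan <- Biostrings::width(Biostrings::pattern(al))
  list(identity = 100 * ident / len,
       similarity = 100 * pos / len,
       coverage = 100 * qspan / nchar(qseq),
       score = Biostrings::score(al))
}

#' Default metal / mobility keyword vocabulary for the cluster scan
#' @return Character vector of lowercase keywords.
#' @export
metal_keywords <- function() {
  c("copper", "heavy metal", "czc", "cus", "cop", "mer", "transposase",
    "integrase", "insertion sequence", "metal")
}

#' Scan the gene neighborhood of a focal gene for a metal/mobility cluster
#'
#' Collects annotated genes on the focal gene's replicon within `window`
#' basepairs of its boundaries and flags `in_cluster` when at least
#' `min_neighbors` of them carry product keywords from the configured
#' metal/mobility vocabulary (transporters, czc/cus/cop/mer systems,
#' transposases, insertion sequences).
#'
#' @param bundle A [genome_bundle()] with annotation.
#' @param focal_id Feature id of the focal gene.
#' @param window Window size in bp (default 75 kb, the upper bound of
#'   reported metal-resistance cluster lengths).
#' @param keywords Keyword vocabulary ([metal_keywords()]).
#' @param min_neighbors Matching neighbors needed for the flag (default 2).
#' @return List with `context` (data frame of neighbors), `in_cluster`.
#' @export
cluster_scan <- function(bundle, focal_id, window = 75000,
                         keywords = metal_keywords(), min_neighbors = 2) {
  ann <- bundle$annotation
  if (is.null(ann) || nrow(ann) == 0) stop("bundle has no annotation")
  focal <- ann[ann$feature_id == focal_id, , drop = FALSE]
  if (nrow(focal) == 0) stop("focal gene ", focal_id, " absent from annotation")
  same <- ann[ann$replicon == focal$replicon[1] &
                ann$feature_id != focal_id, , drop = FALSE]
  lo <- focal$start[1] - window
  hi <- focal$end[1] + window
  ctx <- same[same$end >= lo & same$start <= hi, , drop = FALSE]
  hit <- vapply(seq_len(nrow(ctx)), function(i) {
    kw <- ctx$keywords[[i]]
    any(vapply(keywords, function(k) {
      any(grepl(k, kw, fixed = TRUE))
    }, logical(1)))
  }, logical(1))
  list(context = ctx, n_keyword_neighbors = sum(hit),
       in_cluster = sum(hit) >= min_neighbors)
}

#' Composite horizontal-gene-transfer verdict
#'
#' A gene is an HGT candidate when its closest homolog is foreign
#' (50/70/90 identity/similarity/coverage outside the host's taxon) AND its
#' composition deviates (G+C or normalized CAI); cluster context is
#' supporting evidence only.
#'
#' @param foreign_homolog Foreign closest-homolog flag.
#' @param gc_deviant G+C deviation flag.
#' @param cai_deviant Normalized-CAI < 1 flag.
#' @param in_cluster Metal/mobility cluster flag (annotational support).
#' @return List with `candidate` and `support`.
#' @export
hgt_verdict <- function(foreign_homolog, gc_deviant, cai_deviant,
                        in_cluster = FALSE) {
  list(candidate = isTRUE(foreign_homolog) &&
         (isTRUE(gc_deviant) || isTRUE(cai_deviant)),
       support = c(foreign_homolog = isTRUE(foreign_homolog),
                   gc_deviant = isTRUE(gc_deviant),
                   cai_deviant = isTRUE(cai_deviant),
                   in_cluster = isTRUE(in_cluster)))
}

#' Full composition/HGT screen for a set of genes in a genome
#'
#' Runs the G+C comparison, CAI/eCAI, closest-homolog search and cluster
#' scan for each gene and combines them with [hgt_verdict()]. Per-gene G+C
#' deviance uses `|delta GC| >= gc_margin` points (the population-level t
#' test is reported separately by [gc_deviation_test()]).
#'
#' @param bundle A [genome_bundle()] whose `cds` are the focal genes.
#' @param db Homolog database (protein records with `taxon_class`).
#' @param usage Codon usage table of the host genome.
#' @param gc_margin Per-gene G+C deviance margin in points (default 2).
#' @param n_ecai,p_ecai eCAI Monte-Carlo parameters.
#' @param seed RNG seed.
#' @return Data frame, one row per gene, mirroring the G+C / CAI / genomic
#'   island supplementary-table layout.
#' @export
composition_screen <- function(bundle, db, usage, gc_margin = 2,
                               n_ecai = 500, p_ecai = 0.01, seed = 1) {
  cds <- bundle$cds
  prot <- bundle$proteins
  rows <- lapply(seq_len(nrow(cds)), function(i) {
    g <- cds[i, ]
    ggc <- gc_content(g$sequence)
    nc <- normalized_cai(g$sequence, usage, n = n_ecai, p = p_ecai,
                         seed = seed + i)
    pid <- if (!is.null(g$product_protein_id)) g$product_protein_id else g$id
    q <- prot[prot$id == pid, , drop = FALSE]
    hom <- if (nrow(q) == 1 && nrow(db) > 0) closest_homolog(q, db) else NULL
    clu <- if (!is.null(bundle$annotation) &&
               g$id %in% bundle$annotation$feature_id) {
      cluster_scan(bundle, g$id)
    } else list(in_cluster = FALSE, n_keyword_neighbors = 0L)
    gc_dev <- abs(ggc - bundle$genome_gc) >= gc_margin
    verdict <- hgt_verdict(!is.null(hom) && hom$foreign, gc_dev, nc$deviant,
                           clu$in_cluster)
    data.frame(
      gene = g$id, gc_gene = ggc, gc_genome = bundle$genome_gc,
      delta_gc = ggc - bundle$genome_gc,
      cai = nc$cai, ecai = nc$ecai, cai_ratio = nc$ratio,
      best_hit = if (is.null(hom)) NA_character_ else hom$subject_id,
      hit_taxon = if (is.null(hom)) NA_character_ else hom$subject_taxon,
      identity = if (is.null(hom)) NA_real_ else hom$identity,
      similarity = if (is.null(hom)) NA_real_ else hom$similarity,
      coverage = if (is.null(hom)) NA_real_ else hom$coverage,
      foreign_homolog = !is.null(hom) && hom$foreign,
      gc_deviant = gc_dev, cai_deviant = nc$deviant,
      in_cluster = clu$in_cluster,
      hgt_candidate = verdict$candidate,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
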