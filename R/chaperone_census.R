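#' Kyte-Doolittle hydropathy values
#' @return Named numeric vector over the 20 amino acids.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Detect a transmembrane helix by sliding hydropathy window
#'
#' @param seq Amino-acid sequence.
#' @param window Window length (default 19 residues).
#' @param threshold Mean Kyte-Doolittle hydropathy required (default 1.6).
#' @param max_start Latest allowed window start (default unrestricted).
#' @return Start position of the first qualifying window, or `NA`.
#' @export
find_tmh <- function(seq, window = 19L, threshold = 1.6, max_start = Inf) {
  kd <- kyte_doolittle()
  v <- kd[strsplit(seq, "")[[1]]]
  v[is.na(v)] <- 0
  if (length(v) < window) return(NA_integer_)
  cs <- cumsum(c(0, v))
  means <- (cs[(window + 1):length(cs)] - cs[seq_len(length(cs) - window)]) /
    window
  ok <- which(means > threshold)
  ok <- ok[ok <= max_start]
  if (length(ok) == 0) NA_integer_ else as.integer(ok[1])
}

profile_evalue <- function(profile, seq, db_size = 1) {
  stopifnot(!is.null(profile$calibration))
  s <- forward_score(profile, seq)$score_bits
  ex <- calibrated_excess(profile$calibration, s, nchar(seq))
  list(score_bits = s,
       evalue = db_size * gumbel_pvalue(ex, profile$calibration$mu,
                                        profile$calibration$beta))
}

#' Detect a CopZ-type cytoplasmic copper chaperone
#'
#' A hit requires a significant match to the HMA (heavy-metal-associated)
#' domain profile, the MTCXXC signature with both invariant cysteines, and a
#' small-protein length (soft bounds 50-150 residues around the observed
#' 67-114).
#'
#' @param protein One-row protein records data frame.
#' @param hma_profile Calibrated `profile_hmm` built from an HMA seed.
#' @param evalue_cutoff Profile significance cutoff (default 1e-3).
#' @param length_bounds Length acceptance interval.
#' @return A `chaperone_hit` list, or `NULL` with a reason attribute.
#' @export
detect_copz <- function(protein, hma_profile, evalue_cutoff = 1e-3,
                        length_bounds = c(50L, 150L)) {
  seq <- protein$sequence[1]
  len <- nchar(seq)
  m <- regexpr("MTC..C", seq)
  if (m < 0) return(miss("no MTCXXC motif with invariant cysteines"))
  if (len < length_bounds[1] || len > length_bounds[2]) {
    return(miss(sprintf("length %d outside [%d, %d]", len,
                        length_bounds[1], length_bounds[2])))
  }
  pe <- profile_evalue(hma_profile, seq)
  if (pe$evalue > evalue_cutoff) {
    return(miss(sprintf("HMA profile E-value %.3g above cutoff", pe$evalue)))
  }
  chaperone_hit(protein, "CopZ",
                evidence = list(motif = "MTCXXC", motif_pos = as.integer(m),
                                score_bits = pe$score_bits,
                                evalue = pe$evalue, length = len))
}

#' Detect a CupA-type membrane-anchored copper chaperone
#'
#' Requires a significant cupredoxin-domain profile match, a cupredoxin-like
#' length (soft bounds 90-170 around the observed 100-150) and an N-terminal
#' single transmembrane helix (Kyte-Doolittle mean > 1.6 over a 19-residue
#' window starting within the first 40 residues).
#'
#' @param protein One-row protein records data frame.
#' @param cupredoxin_profile Calibrated `profile_hmm`.
#' @param evalue_cutoff Profile significance cutoff.
#' @param length_bounds Length acceptance interval.
#' @return A `chaperone_hit` or `NULL`.
#' @export
detect_cupa <- function(protein, cupredoxin_profile, evalue_cutoff = 1e-3,
                        length_bounds = c(90L, 170L)) {
  seq <- protein$sequence[1]
  len <- nchar(seq)
  if (len < length_bounds[1] || len > length_bounds[2]) {
    return(miss(sprintf("length %d outside [%d, %d]", len,
                        length_bounds[1], length_bounds[2])))
  }
  tmh <- find_tmh(seq, max_start = 40L)
  if (is.na(tmh)) return(miss("no N-terminal transmembrane helix"))
  pe <- profile_evalue(cupredoxin_profile, seq)
  if (pe$evalue > evalue_cutoff) {
    return(miss(sprintf("cupredoxin profile E-value %.3g above cutoff",
                        pe$evalue)))
  }
  chaperone_hit(protein, "CupA",
                evidence = list(tmh_start = tmh, score_bits = pe$score_bits,
                                evalue = pe$evalue, length = len))
}

#' Detect a CusF-type periplasmic copper chaperone
#'
#' Requires a significant CusF profile match and the invariant copper-binding
#' residues His/Met/Met at the columns homologous to reference positions
#' 36/47/49. The five electropositive positions (23, 30, 31, 35, 50) are
#' reported as a polymorphism profile, not filtered. Length is reported but
#' not filtered (observed range 94-236).
#'
#' @param protein One-row protein records data frame.
#' @param cusf_profile Calibrated `profile_hmm` carrying a `position_map`
#'   (see [cusf_position_map()]).
#' @param evalue_cutoff Profile significance cutoff.
#' @return A `chaperone_hit` or `NULL`.
#' @export
detect_cusf <- function(protein, cusf_profile, evalue_cutoff = 1e-3) {
  if (is.null(cusf_profile$position_map)) {
    stop("cusf_profile lacks a position_map; see cusf_position_map()")
  }
  pm <- cusf_profile$position_map
  needed <- c("36", "47", "49")
  if (!all(needed %in% names(pm))) {
    stop("position_map must map reference positions 36, 47 and 49")
  }
  seq <- protein$sequence[1]
  pe <- profile_evalue(cusf_profile, seq)
  if (pe$evalue > evalue_cutoff) {
    return(miss(sprintf("CusF profile E-value %.3g above cutoff", pe$evalue)))
  }
  hit <- viterbi_align(cusf_profile, seq)
  chars <- strsplit(seq, "")[[1]]
  residue_at <- function(ref_pos) {
    ms <- pm[[as.character(ref_pos)]]
    i <- which(hit$colmap == ms)
    if (length(i) == 1) chars[i] else NA_character_
  }
  inv <- c(residue_at(36), residue_at(47), residue_at(49))
  if (is.na(inv[1]) || inv[1] != "H" || is.na(inv[2]) || inv[2] != "M" ||
      is.na(inv[3]) || inv[3] != "M") {
    return(miss(sprintf(
      "invariant residues H36/M47/M49 not conserved (observed %s/%s/%s)",
      inv[1], inv[2], inv[3])))
  }
  poly <- vapply(c(23, 30, 31, 35, 50), residue_at, character(1))
  names(poly) <- c("23", "30", "31", "35", "50")
  chaperone_hit(protein, "CusF",
                evidence = list(invariant = c(H36 = "H", M47 = "M", M49 = "M"),
                                polymorphic = poly,
                                score_bits = pe$score_bits, evalue = pe$evalue,
                                length = nchar(seq)))
}

# non-hit: reason is logged when options(copascan.verbose = TRUE)
miss <- function(reason) {
  if (isTRUE(getOption("copascan.verbose"))) message("no hit: ", reason)
  NULL
}

chaperone_hit <- function(protein, family, evidence) {
  structure(list(id = protein$id[1], family = family,
                 replicon = if (!is.null(protein$replicon))
                   protein$replicon[1] else "unknown",
                 genome_id = if (!is.null(protein$genome_id))
                   protein$genome_id[1] else NA_character_,
                 evidence = evidence),
            class = "chaperone_hit")
}

#' Map reference residue positions to profile match states
#'
#' Given the seed alignment used to build a profile and the id of a
#' designated reference row, maps 1-based residue positions of the reference
#' sequence to the corresponding match states. Absolute numbering breaks
#' under indels, so all downstream residue checks go through this map.
#'
#' @param seed The [seed_alignment()].
#' @param profile The profile built from `seed`.
#' @param ref_id Row id of the reference sequence.
#' @param positions Integer reference positions to map.
#' @return Named list: position -> match state index.
#' @export
cusf_position_map <- function(seed, profile, ref_id, positions) {
  ri <- match(ref_id, seed$ids)
  if (is.na(ri)) stop("reference id ", ref_id, " not in seed alignment")
  row <- seed$mat[ri, ]
  res_no <- cumsum(row != "-")
  match_of_col <- stats::setNames(rep(NA_integer_, seed$ncol), NULL)
  match_of_col[profile$match_cols] <- seq_len(profile$M)
  out <- list()
  for (p in positions) {
    col <- which(res_no == p & row != "-")[1]
    if (is.na(col) || is.na(match_of_col[col])) {
      stop("reference position ", p, " is not represented by a match state")
    }
    out[[as.character(p)]] <- unname(match_of_col[col])
  }
  out
}

#' Screen a proteome for all three chaperone families
#'
#' @param proteins Protein records data frame.
#' @param profiles List with calibrated `copz`, `cupa`, `cusf` profiles.
#' @return List of `chaperone_hit` objects.
#' @export
detect_chaperones <- function(proteins, profiles) {
  hits <- list()
  for (i in seq_len(nrow(proteins))) {
    p <- proteins[i, , drop = FALSE]
    for (fam in c("copz", "cupa", "cusf")) {
      h <- switch(fam,
                  copz = detect_copz(p, profiles$copz),
                  cupa = detect_cupa(p, profiles$cupa),
                  cusf = detect_cusf(p, profiles$cusf))
      if (!is.null(h)) hits[[length(hits) + 1]] <- h
    }
  }
  hits
}

format_census_cell <- function(n_chr, n_pla, n_unk = 0L) {
  parts <- character()
  if (n_chr > 0) parts <- c(parts, paste0(n_chr, "C"))
  if (n_pla > 0) parts <- c(parts, paste0(n_pla, "P"))
  if (n_unk > 0) parts <- c(parts, as.character(n_unk))
  if (length(parts) == 0) "0" else paste(parts, collapse = "/")
}

#' Parse a census cell string back into counts
#'
#' @param cell String like `"2C/1P"`, `"1"`, or `"0"`.
#' @return Named integer vector `c(chromosome, plasmid, unknown)`.
#' @export
parse_census_cell <- function(cell) {
  out <- c(chromosome = 0L, plasmid = 0L, unknown = 0L)
  if (cell == "0") return(out)
  for (part in strsplit(cell, "/", fixed = TRUE)[[1]]) {
    if (grepl("C$", part)) {
      out["chromosome"] <- out["chromosome"] + as.integer(sub("C$", "", part))
    } else if (grepl("P$", part)) {
      out["plasmid"] <- out["plasmid"] + as.integer(sub("P$", "", part))
    } else {
      out["unknown"] <- out["unknown"] + as.integer(part)
    }
  }
  out
}

#' Per-strain chaperone and Cu-ATPase census
#'
#' One row per genome with CopZ / CupA / CusF (and optionally CopA) counts
#' formatted with replicon suffixes (`2C/1P` = two chromosomal, one
#' plasmid-borne), plus the complete CopZ-CopA-CusF efflux-set flag.
#'
#' @param chaperone_hits List of `chaperone_hit` objects across all genomes.
#' @param copa_counts Named integer vector: genome id -> number of
#'   Cu-ATPases (optional but needed for the complete-set flag).
#' @param genomes Character vector of all surveyed genome ids.
#' @return Data frame with columns `genome`, `CopZ`, `CupA`, `CusF`,
#'   `CopA_n`, `complete_set`.
#' @export
chaperone_census <- function(chaperone_hits, copa_counts = NULL,
                             genomes = NULL) {
  df <- if (length(chaperone_hits)) {
    do.call(rbind, lapply(chaperone_hits, function(h) {
      data.frame(genome = h$genome_id, family = h$family,
                 replicon = h$replicon, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(genome = character(), family = character(),
               replicon = character())
  }
  if (is.null(genomes)) genomes <- sort(unique(df$genome))
  rows <- lapply(genomes, function(g) {
    cell <- function(fam) {
      sub <- df[df$genome == g & df$family == fam, , drop = FALSE]
      format_census_cell(sum(sub$replicon == "chromosome"),
                         sum(sub$replicon == "plasmid"),
                         sum(!sub$replicon %in% c("chromosome", "plasmid")))
    }
    nz <- function(fam) sum(df$genome == g & df$family == fam)
    copa_n <- if (!is.null(copa_counts) && g %in% names(copa_counts)) {
      as.integer(copa_counts[[g]])
    } else NA_integer_
    data.frame(genome = g, CopZ = cell("CopZ"), CupA = cell("CupA"),
               CusF = cell("CusF"), CopA_n = copa_n,
               complete_set = !is.na(copa_n) && copa_n >= 1 &&
                 nz("CopZ") >= 1 && nz("CusF") >= 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
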