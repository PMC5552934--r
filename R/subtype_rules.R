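#' Signature-region anchors used by the synthetic Cu-ATPase template
#'
#' Match-state spans (1-based, inclusive) for the four signature regions of a
#' Cu-transporting P1B-ATPase: the N-terminal metal-binding domain (N-MBD),
#' the TM6 ion-transduction triad (CPC/CPH/CPD), the TM7 YN(X)4P motif and
#' the TM8 selectivity pentad (MXXSS family). These coordinates are the fixed
#' template layout of [make_cu_atpase()]; for real data they are calibrated
#' once from characterized seed members and frozen in the run config.
#'
#' @return Named list of integer spans.
#' @export
cu_atpase_anchors <- function() {
  list(n_mbd = c(1L, 180L),
       tm6 = c(200L, 202L),
       tm7 = c(240L, 246L),
       tm8 = c(280L, 284L))
}

#' Extract signature-region evidence from a profile-aligned sequence
#'
#' Reads the residues mapped to each anchor's match-state span off the
#' Viterbi alignment and summarizes the motif evidence: CXXC 4-mers and
#' CXCXC (TRASH) repeats in the N-MBD, His-richness, the TM6 triad, the TM7
#' YN(X)4P flag and the TM8 pentad. A region whose anchor span is not fully
#' covered by match-emitted residues is marked absent.
#'
#' His-richness is operationalized as >= 5 histidines within any 20-residue
#' window of the N-MBD, or >= 4 consecutive histidines.
#'
#' @param hit An `hmm_hit` from [viterbi_align()].
#' @param seq The aligned amino-acid sequence.
#' @param anchors Named list of match-state spans (see [cu_atpase_anchors()]).
#' @return Object of class `motif_profile`.
#' @export
extract_regions <- function(hit, seq, anchors = cu_atpase_anchors()) {
  M <- max(hit$colmap, na.rm = TRUE)
  for (a in anchors) {
    if (a[1] < 1 || a[2] > 1e6 || a[1] > a[2]) {
      stop("malformed anchor span")
    }
  }
  chars <- strsplit(seq, "")[[1]]
  region_string <- function(span) {
    sel <- which(!is.na(hit$colmap) & hit$colmap >= span[1] &
                   hit$colmap <= span[2])
    paste(chars[sel], collapse = "")
  }
  n_mbd <- region_string(anchors$n_mbd)
  tm6 <- region_string(anchors$tm6)
  tm7 <- region_string(anchors$tm7)
  tm8 <- region_string(anchors$tm8)

  tm6_len <- anchors$tm6[2] - anchors$tm6[1] + 1L
  tm8_len <- anchors$tm8[2] - anchors$tm8[1] + 1L
  tm7_len <- anchors$tm7[2] - anchors$tm7[1] + 1L

  # n_mbd_length: number of residues preceding the first residue aligned at
  # or beyond the first TM anchor
  first_tm <- min(vapply(anchors[c("tm6", "tm7", "tm8")], `[`, 0L, 1))
  beyond <- which(!is.na(hit$colmap) & hit$colmap >= first_tm)
  n_mbd_length <- if (length(beyond)) min(beyond) - 1L else nchar(n_mbd)

  structure(list(
    n_mbd_cxxc = find_overlapping(n_mbd, "C..C"),
    his_rich = is_his_rich(n_mbd),
    his_support = max_his_window(n_mbd),
    trash_count = length(find_overlapping(n_mbd, "C.C.C")),
    tm6_triad = if (nchar(tm6) == tm6_len) tm6 else NA_character_,
    tm7_motif = nchar(tm7) == tm7_len && grepl("^YN....P$", tm7),
    tm8_pentad = if (nchar(tm8) == tm8_len) tm8 else NA_character_,
    n_mbd_length = n_mbd_length,
    fix_context = FALSE,
    absent = c(tm6 = nchar(tm6) != tm6_len, tm7 = nchar(tm7) != tm7_len,
               tm8 = nchar(tm8) != tm8_len)
  ), class = "motif_profile")
}

find_overlapping <- function(s, pattern) {
  if (nchar(s) == 0) return(character())
  m <- gregexpr(paste0("(?=(", pattern, "))"), s, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  len <- attr(m, "capture.length")[, 1]
  st <- attr(m, "capture.start")[, 1]
  substring(s, st, st + len - 1)
}

max_his_window <- function(s, window = 20L) {
  if (nchar(s) == 0) return(0L)
  h <- as.integer(strsplit(s, "")[[1]] == "H")
  if (length(h) <= window) return(sum(h))
  cs <- cumsum(h)
  max(cs[window:length(h)] - c(0, cs[seq_len(length(h) - window)]))
}

is_his_rich <- function(s, window = 20L, min_count = 5L, min_run = 4L) {
  if (nchar(s) == 0) return(FALSE)
  max_his_window(s, window) >= min_count ||
    grepl(strrep("H", min_run), s, fixed = TRUE)
}

#' Assign a Cu-ATPase subtype from its motif evidence
#'
#' Deterministic first-match rule chain over the signature motifs
#' (TM6 triad, N-MBD CXXC variants, His-richness, TRASH repeats, TM8 pentad,
#' FixI gene-neighborhood context):
#'
#' 1. TM6 `CPH` -> `P1B-3` (Cu2+ transporter)
#' 2. TM6 `CPD` -> `P1B-3a`
#' 3. TM6 `CPC`, >= 2 TRASH repeats, `CPKC`/`CPIC` in the N-MBD and an N-MBD
#'    of >= `long_nmbd` residues -> `P1B-1b`
#' 4. TM6 `CPC`, His-rich N-MBD with `CPIC` -> `P1B-1a`
#' 5. TM6 `CPC`, CXXC set within `{CAGC, CAAC, CASC}`, TM8 in
#'    `{MSGSS, MSLSS}` and FixI context -> `P1B-1c`
#' 6. TM6 `CPC` with any CXXC present -> `P1B-1`
#'
#' A TM6 triad other than CPC/CPH/CPD yields `non-copper`; anything else is
#' `unclassified`. An `MXXSS`-shaped TM8 pentad outside the five observed
#' variants is accepted for rule 6 with a warning recorded in the evidence.
#'
#' @param m A `motif_profile` (optionally with `fix_context` set).
#' @param fix_context Override for the FixI neighborhood flag.
#' @param long_nmbd N-MBD length gate for `P1B-1b` (default 120 residues).
#' @return List of class `subtype_label` with `label` and `evidence`.
#' @export
classify_subtype <- function(m, fix_context = NULL, long_nmbd = 120L) {
  stopifnot(inherits(m, "motif_profile"))
  fix <- if (!is.null(fix_context)) isTRUE(fix_context) else isTRUE(m$fix_context)
  ev <- character()
  lab <- NULL
  tm6 <- m$tm6_triad
  cxxc <- m$n_mbd_cxxc
  if (!is.na(tm6) && tm6 == "CPH") {
    lab <- "P1B-3"
    ev <- c(ev, "rule1: TM6=CPH (invariant Cu2+ triad)")
  } else if (!is.na(tm6) && tm6 == "CPD") {
    lab <- "P1B-3a"
    ev <- c(ev, "rule2: TM6=CPD (novel triad replacing CPH)")
  } else if (!is.na(tm6) && tm6 == "CPC") {
    if (m$trash_count >= 2 && any(c("CPKC", "CPIC") %in% cxxc) &&
        m$n_mbd_length >= long_nmbd) {
      lab <- "P1B-1b"
      ev <- c(ev, sprintf(
        "rule3: TM6=CPC, %d TRASH (CXCXC) repeats, %s, N-MBD length %d >= %d",
        m$trash_count,
        paste(intersect(c("CPKC", "CPIC"), cxxc), collapse = "/"),
        m$n_mbd_length, long_nmbd))
    } else if (m$his_rich && "CPIC" %in% cxxc) {
      lab <- "P1B-1a"
      ev <- c(ev, sprintf(
        "rule4: TM6=CPC, His-rich N-MBD (max %d H / 20-residue window), CPIC",
        m$his_support))
    } else if (length(cxxc) > 0 &&
               all(cxxc %in% c("CAGC", "CAAC", "CASC")) &&
               !is.na(m$tm8_pentad) &&
               m$tm8_pentad %in% c("MSGSS", "MSLSS") && fix) {
      lab <- "P1B-1c"
      ev <- c(ev, sprintf(
        "rule5: TM6=CPC, CXXC in {CAGC,CAAC,CASC} (%s), TM8=%s, FixI context",
        paste(cxxc, collapse = "/"), m$tm8_pentad))
    } else if (length(cxxc) > 0) {
      lab <- "P1B-1"
      ev <- c(ev, sprintf("rule6: TM6=CPC with N-MBD CXXC (%s)",
                          paste(cxxc, collapse = "/")))
      if (!is.na(m$tm8_pentad) &&
          grepl("^M..SS$", m$tm8_pentad) &&
          !m$tm8_pentad %in% c("MALSS", "MSAST", "MSGSS", "MSLSS", "MAMSS",
                               "MAFSS")) {
        ev <- c(ev, sprintf("warning: TM8 pentad %s accepted as MXXSS fallback",
                            m$tm8_pentad))
      }
    }
  } else if (!is.na(tm6)) {
    lab <- "non-copper"
    ev <- c(ev, sprintf("TM6 triad %s outside {CPC, CPH, CPD}", tm6))
  }
  if (is.null(lab)) {
    lab <- "unclassified"
  }
  structure(list(label = lab, evidence = ev), class = "subtype_label")
}

#' @export
print.subtype_label <- function(x, ...) {
  cat(x$label, "\n")
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Census of subtype labels across genomes
#'
#' Summarizes per-protein subtype assignments into the three occurrence
#' tables of a multireplicon survey: the per-genome copy-number histogram,
#' the percentage of genomes carrying at least one member of each subtype,
#' and the plasmid/chromosome split.
#'
#' @param labels_df Data frame with columns `id`, `genome_id`, `replicon`,
#'   `subtype` (one row per classified protein; genomes with zero Cu-ATPases
#'   must still appear in `all_genomes`).
#' @param all_genomes Character vector of every surveyed genome id.
#' @param copper_labels Labels counted as Cu-ATPases.
#' @return List with `histogram` (count, n_genomes), `subtype_pct`
#'   (subtype, n_genomes, pct), `replicon_split` (replicon, n, fraction).
#' @export
subtype_census <- function(labels_df,
                           all_genomes = unique(labels_df$genome_id),
                           copper_labels = c("P1B-1", "P1B-1a", "P1B-1b",
                                             "P1B-1c", "P1B-3", "P1B-3a")) {
  df <- labels_df[labels_df$subtype %in% copper_labels, , drop = FALSE]
  df$genome_id[is.na(df$genome_id)] <- "unknown"
  counts <- table(factor(df$genome_id, levels = all_genomes))
  hist_tab <- table(as.integer(counts))
  histogram <- data.frame(count = as.integer(names(hist_tab)),
                          n_genomes = as.integer(hist_tab))
  n <- length(all_genomes)
  subtype_pct <- do.call(rbind, lapply(copper_labels, function(s) {
    ng <- length(unique(df$genome_id[df$subtype == s]))
    data.frame(subtype = s, n_genomes = ng, pct = round(100 * ng / n))
  }))
  rep_tab <- table(factor(df$replicon,
                          levels = c("chromosome", "plasmid", "unknown")))
  replicon_split <- data.frame(
    replicon = names(rep_tab), n = as.integer(rep_tab),
    fraction = if (nrow(df) > 0) as.numeric(rep_tab) / nrow(df) else
      rep(NA_real_, 3))
  list(histogram = histogram, subtype_pct = subtype_pct,
       replicon_split = replicon_split, n_genomes = n)
}
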