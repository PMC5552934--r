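#' Read sequence records from a FASTA file
#'
#' Parses a protein or nucleotide FASTA file into a records data frame. The
#' first whitespace-separated header token is the record id; subsequent
#' `key=value` tokens are parsed into metadata columns (unknown keys are kept
#' as extra columns, bare tokens are ignored). Recognized metadata keys are
#' `genome_id`, `replicon` (chromosome/plasmid/unknown), `taxon_class`,
#' `characterized` and `substrate`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return A data frame with columns `id`, `sequence` and one column per
#'   metadata key, with attribute `alphabet`. An empty file yields an empty
#'   data frame with a warning.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) NULL)
  if (is.null(set) || length(set) == 0) {
    warning("no FASTA records in ", path)
    return(empty_records(alphabet))
  }
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicated record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  validate_alphabet(seqs, ids, alphabet)
  meta <- parse_header_metadata(headers)
  out <- data.frame(id = ids, sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  for (k in names(meta)) out[[k]] <- meta[[k]]
  if (is.null(out$genome_id)) out$genome_id <- NA_character_
  if (is.null(out$replicon)) out$replicon <- "unknown"
  out$replicon[is.na(out$replicon)] <- "unknown"
  bad <- !out$replicon %in% c("chromosome", "plasmid", "unknown")
  if (any(bad)) {
    warning("unrecognized replicon value(s) set to 'unknown': ",
            paste(unique(out$replicon[bad]), collapse = ", "))
    out$replicon[bad] <- "unknown"
  }
  attr(out, "alphabet") <- alphabet
  out
}

empty_records <- function(alphabet) {
  out <- data.frame(id = character(), sequence = character(),
                    genome_id = character(), replicon = character(),
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

# 20 amino acids plus X; DNA is strict ACGT plus N after normalization
validate_alphabet <- function(seqs, ids, alphabet) {
  allowed <- if (alphabet == "protein") "ACDEFGHIKLMNPQRSTVWYX" else "ACGTN"
  pat <- paste0("[^", allowed, "]")
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stop("empty sequence for record ", ids[i])
    m <- regexpr(pat, seqs[i])
    if (m > 0) {
      stop("illegal character '", substr(seqs[i], m, m), "' in record ",
           ids[i], " at position ", m)
    }
  }
  invisible(TRUE)
}

parse_header_metadata <- function(headers) {
  toks <- strsplit(headers, "\\s+")
  kv <- lapply(toks, function(t) {
    t <- t[-1]
    t <- t[grepl("=", t, fixed = TRUE)]
    if (length(t) == 0) return(character())
    keys <- sub("=.*$", "", t)
    vals <- sub("^[^=]*=", "", t)
    stats::setNames(vals, keys)
  })
  keys <- unique(unlist(lapply(kv, names)))
  out <- list()
  for (k in keys) {
    out[[k]] <- vapply(kv, function(x) {
      if (k %in% names(x)) x[[k]] else NA_character_
    }, character(1))
  }
  out
}

#' Write sequence records to a FASTA file
#'
#' Inverse of [read_fasta()]: metadata columns are serialized as `key=value`
#' header tokens so that a read/write round trip is information preserving.
#'
#' @param records Data frame with `id`, `sequence` and metadata columns.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  meta_cols <- setdiff(names(records), c("id", "sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    for (k in meta_cols) {
      v <- records[[k]][i]
      if (!is.na(v)) hdr <- paste0(hdr, " ", k, "=", v)
    }
    seq <- records$sequence[i]
    chunks <- substring(seq, seq(1, nchar(seq), width),
                        pmin(seq(1, nchar(seq), width) + width - 1L, nchar(seq)))
    writeLines(c(paste0(">", hdr), chunks), con)
  }
  invisible(path)
}

#' Read CDS annotation intervals from a GFF3 file
#'
#' Reads CDS features into a 1-based inclusive interval table. The `product`
#' attribute is lowercased and tokenized into a keyword bag used by the
#' cluster scan. Lines with a missing seqid or non-numeric coordinates are
#' skipped with a warning rather than aborting the run, since draft-genome
#' GFF3 files are frequently ragged.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Feature types to keep (default `"CDS"`).
#' @return Data frame with columns `feature_id`, `replicon` (the seqid),
#'   `start`, `end`, `strand` and list-column `keywords`.
#' @export
read_annotation <- function(path, feature_types = "CDS") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- logical(length(fields))
  rows <- vector("list", length(fields))
  n_skipped <- 0L
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 9L || !nzchar(f[1]) || f[1] == ".") {
      n_skipped <- n_skipped + 1L
      next
    }
    if (!f[3] %in% feature_types) next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      n_skipped <- n_skipped + 1L
      next
    }
    attrs <- parse_gff_attributes(f[9])
    fid <- attrs[["ID"]]
    if (is.null(fid)) fid <- paste0(f[1], ":", start, "-", end)
    product <- attrs[["product"]]
    kw <- if (is.null(product)) character() else {
      kw <- tolower(product)
      unique(trimws(unlist(strsplit(kw, "[ ,;/]+"))))
    }
    rows[[i]] <- list(feature_id = fid, replicon = f[1], start = start,
                      end = end, strand = f[7], keywords = list(kw))
    keep[i] <- TRUE
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " malformed GFF3 line(s) skipped in ", path)
  }
  rows <- rows[keep]
  if (length(rows) == 0L) {
    return(data.frame(feature_id = character(), replicon = character(),
                      start = integer(), end = integer(),
                      strand = character(),
                      keywords = I(list()), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    feature_id = vapply(rows, `[[`, "", "feature_id"),
    replicon = vapply(rows, `[[`, "", "replicon"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    strand = vapply(rows, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  out$keywords <- I(lapply(rows, function(r) r$keywords[[1]]))
  bad <- out$start >= out$end
  if (any(bad)) {
    warning(sum(bad), " interval(s) with start >= end skipped")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

parse_gff_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[grepl("=", parts, fixed = TRUE)]
  keys <- sub("=.*$", "", parts)
  vals <- sub("^[^=]*=", "", parts)
  stats::setNames(as.list(utils::URLdecode(vals)), trimws(keys))
}

#' Read a Newick tree, interpreting numeric internal labels as supports
#'
#' Wraps [ape::read.tree()]. Internal node labels that are numeric and fall in
#' \[0, 1\] or (1, 100\] are interpreted as branch supports (the latter are
#' rescaled to \[0, 1\]); other labels are kept as names.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree; supports, when present, are stored in the
#'   `support` attribute (NA for unlabeled nodes) and in `node.label`.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) {
    stop("Newick parse error in ", path, ": ", conditionMessage(e))
  })
  if (is.null(tree)) stop("Newick parse error in ", path)
  attr(tree, "support") <- tree_supports(tree)
  tree
}

#' Extract numeric branch supports from a tree's internal node labels
#'
#' @param tree An `ape::phylo` object.
#' @return Numeric vector over internal nodes, values in \[0, 1\], `NA` where
#'   the label is absent or is a name rather than a support.
#' @export
tree_supports <- function(tree) {
  n_int <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n_int))
  v <- suppressWarnings(as.numeric(tree$node.label))
  v[!is.na(v) & v > 1 & v <= 100] <- v[!is.na(v) & v > 1 & v <= 100] / 100
  v[!is.na(v) & (v < 0 | v > 1)] <- NA_real_
  v
}

#' Write a tree to a Newick file
#'
#' @param tree An `ape::phylo` object (supports in `node.label` are kept).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a tab-separated metadata table
#'
#' Expected columns: `id`, `genome_id`, `replicon`, `taxon_class`, and
#' optionally `characterized` and `substrate`.
#'
#' @param path Path to a TSV file with a header row.
#' @return Data frame.
#' @export
read_metadata_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "genome_id") %in% names(out))) {
    stop("metadata TSV must contain at least 'id' and 'genome_id' columns")
  }
  out
}

#' Assemble a genome bundle
#'
#' Container tying together one genome's proteins, coding sequences,
#' annotation intervals and genome-wide G+C content.
#'
#' @param genome_id Genome identifier.
#' @param proteins Protein records data frame ([read_fasta()]).
#' @param cds Coding records data frame.
#' @param annotation Annotation intervals ([read_annotation()]).
#' @param genome_gc Genome-wide G+C percentage; computed from `cds` when `NULL`.
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(genome_id, proteins, cds, annotation = NULL,
                          genome_gc = NULL) {
  if (is.null(genome_gc) && nrow(cds) > 0) {
    genome_gc <- gc_content(paste(cds$sequence, collapse = ""))
  }
  if (!is.null(annotation) && nrow(annotation) > 0 &&
      any(annotation$start >= annotation$end)) {
    stop("annotation intervals must satisfy start < end")
  }
  structure(list(genome_id = genome_id, proteins = proteins, cds = cds,
                 annotation = annotation, genome_gc = genome_gc),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle", x$genome_id, "-", nrow(x$proteins), "proteins,",
      nrow(x$cds), "CDS,",
      if (is.null(x$annotation)) 0L else nrow(x$annotation), "features,",
      "G+C", round(x$genome_gc, 1), "%\n")
  invisible(x)
}
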