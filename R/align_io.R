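# Alignment input/output and consensus construction.

#' Construct an alignment set
#'
#' @param taxa Character vector of unique taxon labels.
#' @param seqs Character vector of aligned, gapped sequences (equal width).
#' @return Object of class `alignment_set` with elements `taxa`, `seqs`
#'   (named by taxon) and `width`.
#' @export
alignment_set <- function(taxa, seqs) {
  taxa <- as.character(taxa)
  seqs <- vapply(as.character(seqs), normalize_letters, character(1),
                 USE.NAMES = FALSE)
  if (length(taxa) != length(seqs)) stop("taxa and seqs lengths differ")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  widths <- nchar(seqs)
  if (length(seqs) == 0L) stop("empty alignment")
  if (length(unique(widths)) > 1L) {
    stop("ragged alignment; widths: ",
         paste(sprintf("%s=%d", taxa, widths), collapse = ", "))
  }
  structure(list(taxa = taxa, seqs = stats::setNames(seqs, taxa),
                 width = widths[1]),
            class = "alignment_set")
}

#' Coerce to an alignment set
#' @param x An `alignment_set`, list of `gapped_seq`, or named character
#'   vector of aligned sequences.
#' @return An `alignment_set`.
#' @export
as_alignment_set <- function(x) {
  if (inherits(x, "alignment_set")) return(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "gapped_seq"))) {
    return(alignment_set(vapply(x, `[[`, character(1), "taxon"),
                         vapply(x, `[[`, character(1), "letters")))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(alignment_set(names(x), unname(x)))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("Alignment set: ", length(x$taxa), " records, width ", x$width,
      "\n", sep = "")
  show <- utils::head(x$taxa, 10)
  for (t in show) {
    s <- x$seqs[[t]]
    cat(sprintf("  %-20s %s%s\n", t, substr(s, 1, 50),
                if (nchar(s) > 50) "..." else ""))
  }
  if (length(x$taxa) > 10) cat("  ...\n")
  invisible(x)
}

#' Read an aligned sequence set
#'
#' Parses an aligned (gapped) protein sequence file. The Clustal
#' conservation line is ignored; record order is preserved and the common
#' width is validated.
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"`.
#' @return An `alignment_set`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty alignment file: ", path)
  if (format == "clustal") return(.read_clustal(path))
  aln <- seqinr::read.alignment(path, format = format, forceToLower = FALSE)
  if (is.null(aln$nb) || aln$nb < 1L) stop("no records parsed from ", path)
  seqs <- vapply(aln$seq, function(s) gsub("[[:space:]]", "", s[1]),
                 character(1))
  alignment_set(aln$nam, seqs)
}

# Tolerant Clustal reader: header line, then blocks of "name  sequence
# [column count]" rows; conservation lines (leading whitespace, or only
# * : . characters) and blank lines are skipped; blocks are concatenated
# per name in first-appearance order. Handles single-block Clustal Omega
# output, which stricter block-counting parsers reject.
.read_clustal <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1])) {
    stop("not a Clustal file (missing CLUSTAL header): ", path)
  }
  lines <- lines[-1]
  pat <- "^(\\S+)\\s+([A-Za-z.*-]+)(\\s+\\d+)?\\s*$"
  keep <- grepl(pat, lines) & !grepl("^\\s", lines) &
    !grepl("^[*:. ]+$", lines)
  nams <- sub(pat, "\\1", lines[keep])
  segs <- sub(pat, "\\2", lines[keep])
  if (!length(nams)) stop("no records parsed from ", path)
  ord <- unique(nams)
  seqs <- vapply(ord, function(nm) {
    paste(segs[nams == nm], collapse = "")
  }, character(1))
  alignment_set(ord, unname(seqs))
}

#' Write an alignment (or consensus) as aligned FASTA
#'
#' @param aln An `alignment_set` or a single `gapped_seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  if (inherits(aln, "gapped_seq")) {
    aln <- alignment_set(aln$taxon, aln$letters)
  }
  aln <- as_alignment_set(aln)
  seqinr::write.fasta(as.list(unname(aln$seqs)), names = aln$taxa,
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' Majority-rule consensus of an aligned group
#'
#' Per column, the most frequent symbol wins; the gap symbol participates in
#' the vote, so a mostly-gap column yields a gap. Ties are resolved
#' deterministically: a residue beats the gap symbol, and among tied
#' residues the alphabetically first wins.
#'
#' @param group An `alignment_set` (or coercible).
#' @param taxon Label for the consensus record.
#' @return A `gapped_seq`.
#' @export
build_consensus <- function(group, taxon = "consensus") {
  group <- as_alignment_set(group)
  mat <- do.call(rbind, strsplit(unname(group$seqs), "", fixed = TRUE))
  cons <- apply(mat, 2, function(col) {
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    res <- setdiff(top, "-")
    if (length(res)) sort(res)[1] else "-"
  })
  gapped_sequence(taxon, paste(cons, collapse = ""))
}

#' Per-position mean and scatter of encoded profiles across taxa
#'
#' The positional mean and sample standard deviation of one property's
#' number strings across taxa: flat-zero scatter marks conserved columns,
#' large scatter marks mutable regions.
#'
#' @param encoded List of equal-length numeric vectors (e.g. the same
#'   property drawn from an `encoded_set`), one per taxon; at least 2.
#' @return A data.frame with columns `position`, `mean`, `sd`.
#' @export
positional_variability <- function(encoded) {
  if (length(encoded) < 2L) {
    stop("positional variability needs at least 2 taxa (sd undefined)")
  }
  lens <- vapply(encoded, length, integer(1))
  if (length(unique(lens)) > 1L) stop("encoded vectors differ in length")
  m <- do.call(rbind, lapply(encoded, as.numeric))
  data.frame(position = seq_len(ncol(m)),
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd))
}

#' Write encoded number strings as TSV
#'
#' Long-by-row layout: `taxon`, `property`, then one column per alignment
#' position.
#'
#' @param enc An `encoded_set` from [encode_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_encoded_tsv <- function(enc, path) {
  taxa <- attr(enc, "taxa"); props <- attr(enc, "properties")
  rows <- list()
  for (t in taxa) for (p in props) {
    rows[[length(rows) + 1L]] <- data.frame(
      taxon = t, property = p,
      t(as.numeric(enc[[t]][[p]])), check.names = FALSE)
  }
  df <- do.call(rbind, rows)
  names(df) <- c("taxon", "property", paste0("pos", seq_len(attr(enc, "width"))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
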