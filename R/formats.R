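# Readers and writers for the standard formats every stage touches.
#
# Coordinate conventions: alignment blocks, specific regions, inversion
# calls and BED output are 0-based half-open; FASTA has no coordinates;
# GFF3 annotations keep the file's 1-based inclusive convention.
# Conversion happens only at file boundaries.

#' Read a FASTA file
#'
#' Residues are uppercased on read (softmasking carries no semantics in
#' this package).  Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-token
#'   of each header; the full header is kept in the `description` metadata
#'   column.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA file not found: %s", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop_format("malformed FASTA '%s': %s", path, conditionMessage(e))
  )
  if (length(x) == 0L) stop_format("FASTA file '%s' contains no records", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop_format("duplicate FASTA id '%s' in %s", ids[duplicated(ids)][1L], path)
  }
  if (any(!nzchar(ids))) stop_format("empty FASTA id in %s", path)
  x <- Biostrings::DNAStringSet(toupper(x))
  names(x) <- ids
  S4Vectors::metadata(x)$description <- setNames(headers, ids)
  x
}

#' Write sequences to FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = width)
  invisible(path)
}

GFF3_COLS <- c("seqid", "source", "type", "start", "end",
               "score", "strand", "phase", "attributes")

#' Read a GFF3 annotation file
#'
#' Comment and directive lines are tolerated.  Coordinates are kept
#' 1-based inclusive as in the file.  Rows with `start > end` are dropped
#' with a warning; non-numeric coordinates are a format error.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `seqid, source, type, start, end,
#'   score, strand, phase, attributes` (score numeric, `NA` for ".").
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_format("GFF3 file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_gff3())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) {
    stop_format("GFF3 '%s': expected 9 tab-separated columns, got %d (line %d)",
                path, length(fields[[bad[1L]]]), bad[1L])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 4L]))
  end <- suppressWarnings(as.numeric(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    stop_format("GFF3 '%s': non-numeric coordinate (line %d)",
                path, which(is.na(start) | is.na(end))[1L])
  }
  df <- data.frame(
    seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
    start = start, end = end,
    score = suppressWarnings(as.numeric(ifelse(m[, 6L] == ".", NA, m[, 6L]))),
    strand = m[, 7L], phase = m[, 8L], attributes = m[, 9L],
    stringsAsFactors = FALSE
  )
  rev_rows <- df$start > df$end
  if (any(rev_rows)) {
    warning(sprintf("GFF3 '%s': dropped %d record(s) with start > end",
                    path, sum(rev_rows)), call. = FALSE)
    df <- df[!rev_rows, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

empty_gff3 <- function() {
  data.frame(seqid = character(), source = character(), type = character(),
             start = numeric(), end = numeric(), score = numeric(),
             strand = character(), phase = character(),
             attributes = character(), stringsAsFactors = FALSE)
}

#' Write annotations to GFF3
#'
#' @param annotations A `data.frame` as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, path) {
  stopifnot(all(GFF3_COLS %in% names(annotations)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(annotations)) {
    score <- ifelse(is.na(annotations$score), ".",
                    format(annotations$score, trim = TRUE, scientific = FALSE))
    lines <- paste(annotations$seqid, annotations$source, annotations$type,
                   format(annotations$start, trim = TRUE, scientific = FALSE),
                   format(annotations$end, trim = TRUE, scientific = FALSE),
                   score, annotations$strand, annotations$phase,
                   annotations$attributes, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

BLOCK_COLS <- c("ref_seqid", "ref_start", "ref_end", "qry_seqid",
                "qry_start", "qry_end", "orientation", "pct_identity")

new_blocks <- function(ref_seqid = character(), ref_start = numeric(),
                       ref_end = numeric(), qry_seqid = character(),
                       qry_start = numeric(), qry_end = numeric(),
                       orientation = character(), pct_identity = numeric()) {
  data.frame(ref_seqid = ref_seqid, ref_start = ref_start, ref_end = ref_end,
             qry_seqid = qry_seqid, qry_start = qry_start, qry_end = qry_end,
             orientation = orientation, pct_identity = pct_identity,
             stringsAsFactors = FALSE)
}

#' Read an alignment-block table
#'
#' Two dialects are supported.  `internal_tsv` is this package's native
#' table (header `ref_seqid ref_start ref_end qry_seqid qry_start qry_end
#' orientation pct_identity`, coordinates already 0-based half-open).
#' `showcoords_tsv` is the common tab-separated `show-coords` layout
#' (`S1 E1 S2 E2 LEN1 LEN2 %IDY ref qry`, 1-based inclusive, reverse
#' orientation encoded as `S2 > E2`).  All coordinates are normalised to
#' 0-based half-open with `qry_start < qry_end`; reverse blocks get
#' `orientation = "reverse"`.
#'
#' @param path Path to the table.
#' @param dialect `"internal_tsv"` or `"showcoords_tsv"`.
#' @return A block `data.frame` (see [filter_blocks()]).
#' @export
read_alignment_blocks <- function(path, dialect = c("internal_tsv", "showcoords_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("block table not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "internal_tsv") {
    if (length(lines) <= 1L) return(new_blocks())
    df <- read.delim(text = lines, stringsAsFactors = FALSE)
    if (!all(BLOCK_COLS %in% names(df))) {
      stop_format("internal block table '%s': missing columns %s", path,
                  paste(setdiff(BLOCK_COLS, names(df)), collapse = ", "))
    }
    return(df[BLOCK_COLS])
  }
  # show-coords dialect: no header line expected; tolerate one if present
  if (length(lines) && grepl("^\\s*\\[?S1", lines[1L])) lines <- lines[-1L]
  if (length(lines) == 0L) return(new_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n != 9L)) {
    stop_format("show-coords table '%s': expected 9 columns, got %d (line %d)",
                path, n[which(n != 9L)[1L]], which(n != 9L)[1L])
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, c(1:4, 7), drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 5L)
  if (anyNA(num)) {
    stop_format("show-coords table '%s': non-numeric coordinate (line %d)",
                path, which(apply(is.na(num), 1L, any))[1L])
  }
  s1 <- num[, 1L]; e1 <- num[, 2L]; s2 <- num[, 3L]; e2 <- num[, 4L]
  rev <- s2 > e2
  new_blocks(
    ref_seqid = m[, 8L],
    ref_start = s1 - 1, ref_end = e1,
    qry_seqid = m[, 9L],
    qry_start = ifelse(rev, e2, s2) - 1,
    qry_end = ifelse(rev, s2, e2),
    orientation = ifelse(rev, "reverse", "forward"),
    pct_identity = num[, 5L]
  )
}

#' Write an alignment-block table (internal dialect)
#'
#' @param blocks Block `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_blocks <- function(blocks, path) {
  stopifnot(all(BLOCK_COLS %in% names(blocks)))
  write.table(blocks[BLOCK_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write intervals to BED (0-based half-open)
#'
#' @param df A `data.frame` with columns `seqid, start, end` and optionally
#'   a `name`/`label` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("seqid", "start", "end") %in% names(df)))
  name <- if ("name" %in% names(df)) df$name
          else if ("label" %in% names(df)) df$label
          else rep(".", nrow(df))
  if (nrow(df) == 0L) name <- character()
  out <- data.frame(df$seqid, format(df$start, trim = TRUE, scientific = FALSE),
                    format(df$end, trim = TRUE, scientific = FALSE), name)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tree to Newick text
#'
#' Bootstrap supports stored in `node.label` are emitted as internal-node
#' labels; branch lengths keep at least six significant digits.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return Newick text (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Read single-end reads from FASTQ
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return A [Biostrings::DNAStringSet] of reads.
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write reads to FASTQ with a fixed quality string
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param qual_char Quality character replicated across each read.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  quals <- Biostrings::BStringSet(strrep(qual_char, Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}
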