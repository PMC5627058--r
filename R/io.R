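#' Write a transcript annotation as GTF
#'
#' Emits one `transcript` feature per transcript plus `five_prime_utr`,
#' `CDS` and `three_prime_utr` features for coding transcripts, in
#' transcript space (the seqname is the transcript itself). Coordinates are
#' converted from the package's internal 0-based half-open convention to
#' GTF's 1-based closed convention.
#'
#' @param annotation data.frame as returned by [sim_annotation()] (columns
#'   `gene_id`, `transcript_id`, `biotype`, `length`, `utr5_len`, `cds_len`,
#'   `utr3_len`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  lines <- character(0)
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    attr9 <- sprintf('gene_id "%s"; transcript_id "%s"; biotype "%s";',
                     a$gene_id, a$transcript_id, a$biotype)
    feat <- function(type, start0, end0) {
      sprintf("%s\tmeripr\t%s\t%d\t%d\t.\t+\t.\t%s",
              a$transcript_id, type, start0 + 1L, end0, attr9)
    }
    lines <- c(lines, feat("transcript", 0L, a$length))
    if (a$biotype == "coding") {
      u <- a$utr5_len; cl <- a$cds_len
      if (u > 0L) lines <- c(lines, feat("five_prime_utr", 0L, u))
      lines <- c(lines, feat("CDS", u, u + cl))
      if (a$utr3_len > 0L)
        lines <- c(lines, feat("three_prime_utr", u + cl, a$length))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcript annotation from GTF
#'
#' Inverse of [write_gtf()]: reconstructs the annotation table from
#' `transcript` and `CDS`/UTR features. Accepts any GTF whose attribute
#' column carries `gene_id` and `transcript_id`; multiple transcripts per
#' gene are kept (see [select_longest()]).
#'
#' @param path GTF file path.
#' @return data.frame with columns `gene_id`, `transcript_id`, `biotype`,
#'   `length`, `utr5_len`, `cds_len`, `utr3_len` (`NA` for non-coding).
#' @export
read_gtf <- function(path) {
  raw <- read.table(path, sep = "\t", quote = "", comment.char = "#",
                    col.names = c("seqname", "source", "feature", "start",
                                  "end", "score", "strand", "frame", "attr"),
                    stringsAsFactors = FALSE)
  get_attr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0(key, ' "([^"]+)"'), attr))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  raw$gene_id <- get_attr(raw$attr, "gene_id")
  raw$transcript_id <- get_attr(raw$attr, "transcript_id")
  tx <- raw[raw$feature == "transcript", ]
  ann <- data.frame(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
                    stringsAsFactors = FALSE)
  ann$length <- tx$end - (tx$start - 1L)
  seg_len <- function(feature) {
    f <- raw[raw$feature == feature, ]
    lens <- tapply(f$end - (f$start - 1L), f$transcript_id, sum)
    out <- as.integer(lens[ann$transcript_id])
    ifelse(is.na(out), 0L, out)
  }
  cds <- seg_len("CDS")
  ann$biotype <- ifelse(cds > 0L, "coding", "lncRNA")
  ann$utr5_len <- ifelse(cds > 0L, seg_len("five_prime_utr"), NA_integer_)
  ann$cds_len <- ifelse(cds > 0L, cds, NA_integer_)
  ann$utr3_len <- ifelse(cds > 0L, seg_len("three_prime_utr"), NA_integer_)
  ann[, c("gene_id", "transcript_id", "biotype", "length",
          "utr5_len", "cds_len", "utr3_len")]
}

#' Write transcript sequences as FASTA
#'
#' @param sequences named character vector of ACGT strings.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write intervals as BED6
#'
#' Intervals are written 0-based half-open as in BED. The `name`, `score`
#' and `strand` columns are filled from the matching data.frame columns
#' when present, otherwise with `"."`, `0` and `"+"`.
#'
#' @param intervals data.frame with columns `transcript_id`, `start`, `end`
#'   and optionally `name`, `score`, `strand`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  name <- if ("name" %in% names(intervals)) intervals$name else rep(".", n)
  score <- if ("score" %in% names(intervals)) intervals$score else rep(0, n)
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep("+", n)
  df <- data.frame(intervals$transcript_id, intervals$start, intervals$end,
                   name, score, strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read intervals from BED
#'
#' @param path BED file path (3-6 columns).
#' @return data.frame with columns `transcript_id`, `start`, `end` and,
#'   when present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  raw <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  cols <- c("transcript_id", "start", "end", "name", "score", "strand")
  names(raw) <- cols[seq_len(ncol(raw))]
  raw
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads reads object: data.frame with columns `id`, `bases`, `quals`
#'   (`quals` as Phred+33 encoded strings, same length as `bases`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    out <- paste0("@", reads$id, "\n", reads$bases, "\n+\n", reads$quals)
    writeLines(out, con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `bases`, `quals` (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             bases = as.character(x),
             quals = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Read a gene list from a text file
#'
#' One identifier per line, or a 2+ column TSV whose first column holds the
#' identifiers. Duplicates are removed; matching downstream is
#' exact-string and case-sensitive.
#'
#' @param path text file path.
#' @param name list name; defaults to the file base name.
#' @return list with elements `name` and `gene_ids` (unique character
#'   vector).
#' @export
read_gene_list <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  list(name = name, gene_ids = unique(trimws(ids)))
}
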