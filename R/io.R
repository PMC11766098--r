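#' Read a (multi-)FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a named
#' character vector so that downstream functions can work with plain
#' strings.  Headers are truncated at the first whitespace, following the
#' usual FASTA identifier convention.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = as.integer(width))
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' Gzip-transparent.  Returns one row per read with the per-base quality
#' string kept in lockstep with the sequence.
#'
#' @param path path to a FASTQ (optionally gzipped) file.
#' @return tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  tibble(
    read_id  = sub("\\s.*$", "", names(x)),
    sequence = as.character(x),
    quality  = q
  )
}

#' Write a read table to FASTQ
#'
#' @param reads tibble with columns `read_id`, `sequence`, `quality`.
#' @param path output path; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_read_table(reads)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    path,
    format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

check_read_table <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad)) {
    stop("sequence/quality length mismatch for read(s): ",
         paste(utils::head(reads$read_id[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  invisible(reads)
}

#' Read gene features from a GFF3 file
#'
#' Imports the file with [rtracklayer::import()] and keeps features of type
#' `gene` only (1-based inclusive coordinates, per the GFF3 standard).
#'
#' @param path path to a GFF3 file.
#' @return tibble with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type == "gene", , drop = FALSE]
  ids <- df$ID
  if (is.null(ids)) ids <- df$Name
  if (is.null(ids)) ids <- rep(NA_character_, nrow(df))
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  strand <- as.character(df$strand)
  strand[strand == "*"] <- "+"
  tibble(
    gene_id = as.character(ids),
    seq_id  = as.character(df$seqnames),
    start   = df$start,
    end     = df$end,
    strand  = strand
  )
}

#' Write a gene annotation table as GFF3
#'
#' @param genes tibble with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(all(c("gene_id", "seq_id", "start", "end", "strand") %in%
                  names(genes)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(sprintf("%s\tdigiscaff\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$seq_id, as.integer(genes$start),
                       as.integer(genes$end), genes$strand, genes$gene_id),
               con)
  }
  invisible(path)
}

#' Read a flow-cell run summary table
#'
#' Expects a tab- or comma-delimited file with a header row and columns
#' `line`, `flowcell`, `input_fmoles`, `read_count`, `bases`, `n50`,
#' `file_size_gb` and optionally `pores`.  Units are explicit: `bases` and
#' `n50` are integers in bases, `file_size_gb` in gigabytes.
#'
#' @param path path to the delimited file.
#' @return tibble of validated runs.
#' @export
read_run_table <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  runs <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            na = c("", "NA"))
  req <- c("line", "flowcell", "input_fmoles", "read_count", "bases",
           "n50", "file_size_gb")
  missing_cols <- setdiff(req, names(runs))
  if (length(missing_cols)) {
    stop("run table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(runs$flowcell %in% c("MIN", "FLG"))) {
    stop("`flowcell` must be 'MIN' or 'FLG'", call. = FALSE)
  }
  num <- c("input_fmoles", "read_count", "bases", "n50", "file_size_gb")
  for (col in num) {
    v <- runs[[col]]
    if (!is.numeric(v) || any(!is.na(v) & v <= 0)) {
      stop("column `", col, "` must be positive numeric", call. = FALSE)
    }
  }
  runs
}
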