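#' Query tables
#'
#' Queries are reference-derived probe sequences used to anchor contigs
#' along a chromosome.  Two kinds exist: *gene-queries* (reference gene
#' sequences longer than a minimum span) and *ranked-queries* (fixed-length
#' genomic fragments extracted at regular spacing).  A query table is a
#' tibble with columns:
#'
#' * `query_id` — `"{seq_id}|r{rank}|{start}-{end}"` (0-based half-open),
#'   so the along-chromosome order is recoverable from FASTA headers alone;
#' * `seq_id` — source reference sequence;
#' * `start`, `end` — 0-based half-open coordinates on the source;
#' * `rank` — 0-based order along the source, contiguous per `seq_id`;
#' * `kind` — `"gene"` or `"ranked"`;
#' * `sequence` — forward-strand nucleotide string.
#'
#' @name query-table
NULL

query_id_of <- function(seq_id, rank, start, end) {
  if (any(grepl("|", seq_id, fixed = TRUE))) {
    stop("seq_id must not contain '|' (reserved for query ids)",
         call. = FALSE)
  }
  sprintf("%s|r%d|%d-%d", seq_id, as.integer(rank), as.integer(start),
          as.integer(end))
}

new_query_table <- function(query_id = character(), seq_id = character(),
                            start = integer(), end = integer(),
                            rank = integer(), kind = character(),
                            sequence = character()) {
  tibble(query_id = query_id, seq_id = seq_id, start = as.integer(start),
         end = as.integer(end), rank = as.integer(rank), kind = kind,
         sequence = sequence)
}

#' Extract gene-queries from a reference and its annotation
#'
#' Keeps annotated genes whose span is *strictly greater* than
#' `min_gene_len`, extracts their forward-strand sequence from the
#' reference (whatever the annotated strand: downstream BLAST searches find
#' minus-strand hits anyway, and no orientation is ever assigned), and
#' ranks them by start coordinate within each reference sequence.
#'
#' @param refs named character vector or `DNAStringSet` of reference
#'   sequences.
#' @param annotations data frame with columns `gene_id`, `seq_id`, `start`,
#'   `end`, `strand` (1-based inclusive, see [read_gff_genes()]).
#' @param min_gene_len minimum span in bases; genes of span exactly
#'   `min_gene_len` are excluded.
#' @return a query table (see [query-table]) with `kind = "gene"`.
#' @examples
#' ref <- c(chr = paste(rep("ACGT", 2500), collapse = ""))
#' ann <- data.frame(gene_id = "g1", seq_id = "chr", start = 11, end = 2711,
#'                   strand = "+")
#' extract_gene_queries(ref, ann)
#' @export
extract_gene_queries <- function(refs, annotations, min_gene_len = 2500L) {
  refs <- as_ref_set(refs)
  ann <- as_tibble(annotations)
  if (nrow(ann) == 0L) return(new_query_table())
  stopifnot(all(c("gene_id", "seq_id", "start", "end") %in% names(ann)))

  unknown <- !(ann$seq_id %in% names(refs))
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop("annotation `", ann$gene_id[i], "` references unknown seq_id `",
         ann$seq_id[i], "`", call. = FALSE)
  }
  len <- nchar(refs)[match(ann$seq_id, names(refs))]
  bad <- ann$start < 1L | ann$end > len | ann$start > ann$end
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("annotation `", ann$gene_id[i], "` exceeds the bounds of `",
         ann$seq_id[i], "` (", ann$start[i], "-", ann$end[i], " on length ",
         len[i], ")", call. = FALSE)
  }

  span <- ann$end - ann$start + 1L
  keep <- ann[span > min_gene_len, , drop = FALSE]
  if (nrow(keep) == 0L) return(new_query_table())
  # rank by start within each source sequence, seq_ids in reference order
  keep$seq_id <- factor(keep$seq_id, levels = names(refs))
  keep <- keep[order(keep$seq_id, keep$start, keep$end, keep$gene_id), ,
               drop = FALSE]
  rank <- stats::ave(seq_len(nrow(keep)), keep$seq_id,
                     FUN = function(i) seq_along(i) - 1L)
  seq_id <- as.character(keep$seq_id)
  start0 <- keep$start - 1L
  end0 <- keep$end
  new_query_table(
    query_id = query_id_of(seq_id, rank, start0, end0),
    seq_id = seq_id, start = start0, end = end0, rank = rank,
    kind = "gene",
    sequence = unname(substring(refs[seq_id], keep$start, keep$end))
  )
}

#' Extract ranked-queries at regular spacing
#'
#' Cuts fixed-length fragments from each reference sequence at starts
#' `0, fragment_len + spacing, 2(fragment_len + spacing), ...` so that
#' ranked-query starts form an arithmetic progression with step
#' `fragment_len + spacing`.  Only full-length fragments are emitted by
#' default, keeping the coverage denominator uniform across queries; set
#' `keep_partial = TRUE` to also emit a truncated trailing fragment.
#'
#' @param refs named character vector or `DNAStringSet`; one query list is
#'   produced per sequence, with ranks contiguous from 0 within each.
#' @param fragment_len fragment length in bases.
#' @param spacing gap between consecutive fragments in bases.
#' @param keep_partial emit the trailing partial fragment as well?
#' @return a query table with `kind = "ranked"`.
#' @export
extract_ranked_queries <- function(refs, fragment_len = 4000L,
                                   spacing = 20000L, keep_partial = FALSE) {
  refs <- as_ref_set(refs)
  fragment_len <- as.integer(fragment_len)
  spacing <- as.integer(spacing)
  if (is.na(fragment_len) || fragment_len <= 0L) {
    stop("`fragment_len` must be a positive number of bases", call. = FALSE)
  }
  if (is.na(spacing) || spacing < 0L) {
    stop("`spacing` must be >= 0", call. = FALSE)
  }
  step <- fragment_len + spacing
  out <- lapply(names(refs), function(sid) {
    L <- nchar(refs[[sid]])
    starts <- seq.int(0L, L, by = step)
    ends <- pmin(starts + fragment_len, L)
    full <- (ends - starts) == fragment_len
    keep <- if (keep_partial) (ends > starts) else full
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(new_query_table())
    rank <- seq_along(starts) - 1L
    new_query_table(
      query_id = query_id_of(sid, rank, starts, ends),
      seq_id = sid, start = starts, end = ends, rank = rank,
      kind = "ranked",
      sequence = substring(refs[[sid]], starts + 1L, ends)
    )
  })
  dplyr::bind_rows(out)
}

#' Write a query table as rank-encoded FASTA
#'
#' Headers are the `query_id`s, so [read_queries()] recovers source,
#' rank and coordinates losslessly.
#'
#' @param queries a non-empty query table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_queries <- function(queries, path) {
  if (!is.data.frame(queries) || nrow(queries) == 0L) {
    stop("`queries` must be a non-empty query table", call. = FALSE)
  }
  write_fasta(setNames(queries$sequence, queries$query_id), path)
}

#' Read a rank-encoded query FASTA back into a query table
#'
#' The `kind` of a query is not encoded in its header, so it is reported
#' as `NA`; all positional fields and the sequence round-trip exactly.
#'
#' @param path path to a FASTA written by [write_queries()].
#' @return a query table.
#' @export
read_queries <- function(path) {
  seqs <- read_fasta(path)
  parse_query_ids(names(seqs), sequence = unname(seqs))
}

# Parse "{seq_id}|r{rank}|{start}-{end}" headers into a query table.
parse_query_ids <- function(ids, sequence = NA_character_) {
  m <- regmatches(ids, regexec("^(.*)\\|r(\\d+)\\|(\\d+)-(\\d+)$", ids))
  bad <- lengths(m) != 5L
  if (any(bad)) {
    stop("malformed query id(s): ",
         paste(utils::head(ids[bad], 3L), collapse = ", "), call. = FALSE)
  }
  f <- function(k) vapply(m, `[[`, "", k)
  new_query_table(
    query_id = ids,
    seq_id = f(2L),
    start = as.integer(f(4L)),
    end = as.integer(f(5L)),
    rank = as.integer(f(3L)),
    kind = NA_character_,
    sequence = sequence
  )
}
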