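#' Split reads into fixed-length non-overlapping k-mers
#'
#' Each read of length `L` yields `floor(L / k)` children taken at offsets
#' `0, k, 2k, ...`, with the per-base qualities sliced in lockstep; the
#' trailing remainder shorter than `k` is dropped so that every emitted
#' record has exactly `k` bases (set `keep_remainder = TRUE` to emit the
#' tail as a final short record).  Child ids are `"{read_id}/p{index}"`
#' with a 1-based part index.
#'
#' @param reads read table (see [read_fastq()]) or a path to a FASTQ file.
#' @param k k-mer length in bases.
#' @param keep_remainder also emit the trailing `< k` bases?
#' @param run_len homopolymer run length for the census carried in the
#'   summary.
#' @return list with elements `kmers` (a read table) and `summary` (class
#'   `split_summary`: `n_reads_in`, `n_kmers_out`, `bases_out`,
#'   `homopolymer_fraction` — a named fraction per base A/C/G/T of full
#'   length k-mers containing a run of at least `run_len` identical
#'   bases).
#' @examples
#' r <- tibble::tibble(read_id = "r1", sequence = strrep("ACGT", 200),
#'                     quality = strrep("I", 800))
#' split_reads(r, k = 250)$summary
#' @export
split_reads <- function(reads, k = 250L, keep_remainder = FALSE,
                        run_len = 10L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  check_read_table(reads)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be >= 1", call. = FALSE)

  L <- nchar(reads$sequence)
  n_parts <- L %/% k
  rem <- L %% k
  idx <- rep.int(seq_len(nrow(reads)), n_parts)
  part <- sequence(n_parts)
  from <- (part - 1L) * k + 1L
  to <- from + k - 1L
  kmers <- tibble(
    read_id = sprintf("%s/p%d", reads$read_id[idx], part),
    sequence = substring(reads$sequence[idx], from, to),
    quality = substring(reads$quality[idx], from, to)
  )
  full_kmers <- kmers
  if (keep_remainder && any(rem > 0L)) {
    tail_idx <- which(rem > 0L)
    tails <- tibble(
      read_id = sprintf("%s/p%d", reads$read_id[tail_idx],
                        n_parts[tail_idx] + 1L),
      sequence = substring(reads$sequence[tail_idx],
                           n_parts[tail_idx] * k + 1L, L[tail_idx]),
      quality = substring(reads$quality[tail_idx],
                          n_parts[tail_idx] * k + 1L, L[tail_idx])
    )
    kmers <- dplyr::bind_rows(kmers, tails)
  }

  summary <- structure(
    list(n_reads_in = nrow(reads),
         n_kmers_out = nrow(full_kmers),
         bases_out = sum(as.numeric(n_parts)) * k,
         k = k,
         run_len = as.integer(run_len),
         homopolymer_fraction = homopolymer_census(full_kmers, run_len)),
    class = "split_summary")
  list(kmers = kmers, summary = summary)
}

#' @export
print.split_summary <- function(x, ...) {
  cat("<split_summary> ", x$n_reads_in, " reads -> ", x$n_kmers_out,
      " k-mers of ", x$k, " b (", format(x$bases_out, big.mark = ","),
      " bases)\n", sep = "")
  hp <- x$homopolymer_fraction
  cat(sprintf("  %d-base homopolymer fraction: %s\n", x$run_len,
              paste(sprintf("%s=%.2f%%", names(hp), 100 * hp),
                    collapse = " ")))
  invisible(x)
}

#' Homopolymer census over k-mers
#'
#' A k-mer counts for base B when it contains at least `run_len`
#' consecutive copies of B; each k-mer counts at most once per base,
#' however many or longer its runs are.  Nanopore basecalls are
#' error-prone inside such runs, and their weight is larger in a short
#' k-mer than in the full-length read it came from.
#'
#' @param kmers read table or character vector of sequences.
#' @param run_len minimum run length (>= 2).
#' @return named numeric vector: fraction of k-mers containing a run, per
#'   base A/C/G/T.
#' @export
homopolymer_census <- function(kmers, run_len = 10L) {
  run_len <- as.integer(run_len)
  if (is.na(run_len) || run_len < 2L) {
    stop("`run_len` must be >= 2", call. = FALSE)
  }
  seqs <- if (is.data.frame(kmers)) kmers$sequence else kmers
  bases <- c("A", "C", "G", "T")
  if (!length(seqs)) {
    return(setNames(rep(NA_real_, 4L), bases))
  }
  seqs <- toupper(seqs)
  counts <- vapply(bases, function(b) {
    sum(grepl(strrep(b, run_len), seqs, fixed = TRUE))
  }, numeric(1))
  counts / length(seqs)
}
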