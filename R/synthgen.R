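#' Simulate a genome with planted repeat families
#'
#' Generates an i.i.d. background sequence at a given GC content and
#' plants copies of each repeat family at recorded, non-overlapping
#' positions — either as a tandem block or dispersed across the sequence.
#' All generators in this module are pure functions of their parameters
#' and the seed: identical calls give identical bytes.
#'
#' @param length genome length in bases (>= 10x the largest repeat unit).
#' @param repeat_families list of families, each a list/vector with
#'   elements `unit_len` (bases), `copies` (count) and `dispersion`
#'   (`"tandem"` for adjacent copies, `"dispersed"` for copies spread over
#'   the sequence).
#' @param gc GC fraction of the background.
#' @param seed integer seed.
#' @param seq_id name of the simulated sequence.
#' @return list with `ref` (named character vector of length 1) and
#'   `truth`: a tibble of planted repeat copies (`family`, `unit_len`,
#'   `copy`, `start`, `end`, 0-based half-open).
#' @export
simulate_genome <- function(length, repeat_families = list(), gc = 0.5,
                            seed = 1L, seq_id = "chrS") {
  length <- as.integer(length)
  stopifnot(length >= 1L, gc > 0, gc < 1)
  if (base::length(repeat_families)) {
    max_unit <- max(vapply(repeat_families,
                           function(f) as.integer(f[["unit_len"]]),
                           integer(1)))
    if (length < 10L * max_unit) {
      stop("genome length must be >= 10x the largest repeat unit",
           call. = FALSE)
    }
    total <- sum(vapply(repeat_families, function(f) {
      as.integer(f[["unit_len"]]) * as.integer(f[["copies"]])
    }, integer(1)))
    if (total > length %/% 2L) {
      stop("repeat families exceed half the genome length", call. = FALSE)
    }
  }
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(probs), length, replace = TRUE, prob = probs)

  truth <- tibble(family = integer(), unit_len = integer(), copy = integer(),
                  start = integer(), end = integer())
  occupied <- IRanges::IRanges()
  for (fi in seq_along(repeat_families)) {
    f <- repeat_families[[fi]]
    unit_len <- as.integer(f[["unit_len"]])
    copies <- as.integer(f[["copies"]])
    disp <- if (is.null(f[["dispersion"]])) "dispersed" else
      as.character(f[["dispersion"]])
    unit <- sample(c("A", "C", "G", "T"), unit_len, replace = TRUE,
                   prob = probs)
    starts <- place_copies(length, unit_len, copies, disp, occupied)
    for (ci in seq_along(starts)) {
      s <- starts[ci]
      chars[(s + 1L):(s + unit_len)] <- unit
      truth <- dplyr::bind_rows(truth, tibble(
        family = fi, unit_len = unit_len, copy = ci,
        start = s, end = s + unit_len))
    }
    occupied <- c(occupied,
                  IRanges::IRanges(start = starts + 1L, width = unit_len))
  }
  list(ref = setNames(paste(chars, collapse = ""), seq_id),
       truth = truth)
}

# 0-based, non-overlapping copy placement avoiding `occupied` (1-based).
place_copies <- function(L, unit_len, copies, dispersion, occupied) {
  if (dispersion == "tandem") {
    block <- unit_len * copies
    for (try in 1:200) {
      anchor <- sample.int(L - block + 1L, 1L) - 1L
      cand <- IRanges::IRanges(anchor + 1L, width = block)
      if (!length(IRanges::findOverlaps(cand, occupied))) {
        return(anchor + unit_len * (seq_len(copies) - 1L))
      }
    }
    stop("could not place tandem repeat block without overlap",
         call. = FALSE)
  }
  starts <- integer()
  placed <- occupied
  for (ci in seq_len(copies)) {
    ok <- FALSE
    for (try in 1:200) {
      s <- sample.int(L - unit_len + 1L, 1L) - 1L
      cand <- IRanges::IRanges(s + 1L, width = unit_len)
      if (!length(IRanges::findOverlaps(cand, placed))) {
        starts <- c(starts, s)
        placed <- c(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place dispersed repeat copies without overlap",
                  call. = FALSE)
  }
  sort(starts)
}

#' Fragment a reference into a shuffled, optionally redundant contig set
#'
#' Tiles the reference with `n_contigs` segments whose boundaries are
#' jittered around an even partition, extends each segment leftwards by
#' `overlap` bases into its predecessor (emulating overlapping assembler
#' contigs), optionally re-emits a fraction of contigs as duplicates
#' (reverse-complemented half the time, emulating redundant draft
#' assemblies), and shuffles the output order.  Ground truth is recorded
#' per contig.
#'
#' @param ref named character vector of length 1 (see [simulate_genome()]).
#' @param n_contigs number of primary contigs.
#' @param overlap extension in bases of each contig into its predecessor.
#' @param dup_rate fraction of primary contigs re-emitted as duplicates.
#' @param seed integer seed.
#' @param jitter boundary jitter as a fraction of the mean contig length.
#' @return list with `contigs` (named character vector) and `truth`
#'   (tibble `contig`, `seq_id`, `start`, `end` 0-based half-open,
#'   `strand`, `is_duplicate`, `dup_of`).
#' @export
fragment_into_contigs <- function(ref, n_contigs, overlap = 0L,
                                  dup_rate = 0, seed = 1L, jitter = 0.2) {
  ref <- as_ref_set(ref)
  stopifnot(length(ref) == 1L)
  L <- nchar(ref[[1L]])
  n_contigs <- as.integer(n_contigs)
  if (n_contigs < 1L || n_contigs > L) {
    stop("cannot tile a length-", L, " sequence with ", n_contigs,
         " contigs", call. = FALSE)
  }
  set.seed(seed)
  mean_len <- L / n_contigs
  cuts <- round(seq_len(n_contigs - 1L) * mean_len +
                  stats::runif(n_contigs - 1L, -jitter, jitter) * mean_len)
  cuts <- sort(pmin(pmax(cuts, seq_len(n_contigs - 1L)),
                    L - rev(seq_len(n_contigs - 1L))))
  bounds <- c(0L, as.integer(cuts), L)
  start <- pmax(bounds[-length(bounds)] - as.integer(overlap), 0L)
  start[1L] <- 0L
  end <- bounds[-1L]

  truth <- tibble(
    contig = sprintf("tig%05d", seq_len(n_contigs)),
    seq_id = names(ref),
    start = start, end = end, strand = "+",
    is_duplicate = FALSE, dup_of = NA_character_
  )
  n_dup <- round(dup_rate * n_contigs)
  if (n_dup > 0L) {
    dup_src <- sample(truth$contig, n_dup)
    src <- truth[match(dup_src, truth$contig), , drop = FALSE]
    dup <- src
    dup$contig <- sprintf("tig%05d", n_contigs + seq_len(n_dup))
    dup$strand <- ifelse(stats::runif(n_dup) < 0.5, "+", "-")
    dup$is_duplicate <- TRUE
    dup$dup_of <- src$contig
    truth <- dplyr::bind_rows(truth, dup)
  }
  seqs <- unname(substring(ref[[1L]], truth$start + 1L, truth$end))
  flip <- truth$strand == "-"
  seqs[flip] <- revcomp(seqs[flip])
  ord <- sample.int(nrow(truth))
  truth <- truth[ord, , drop = FALSE]
  list(contigs = setNames(seqs[ord], truth$contig), truth = truth)
}

#' Simulate a non-overlapping gene annotation
#'
#' Places `n_genes` gene features without overlap; a stated fraction of
#' them is drawn shorter than 2500 bases to exercise the gene-length
#' filter of [extract_gene_queries()].
#'
#' @param ref named character vector of length 1.
#' @param n_genes number of genes.
#' @param short_frac fraction of genes with span < 2500 bases.
#' @param span_range span range (bases) for the long genes; short genes
#'   are drawn from `[500, 2400]`.
#' @param seed integer seed.
#' @return tibble `gene_id`, `seq_id`, `start`, `end`, `strand` (1-based
#'   inclusive), writable with [write_gff3()].
#' @export
simulate_annotation <- function(ref, n_genes, short_frac = 0.3,
                                span_range = c(2600L, 6000L), seed = 1L) {
  ref <- as_ref_set(ref)
  stopifnot(length(ref) == 1L)
  L <- nchar(ref[[1L]])
  n_genes <- as.integer(n_genes)
  if (n_genes == 0L) {
    return(tibble(gene_id = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  set.seed(seed)
  n_short <- round(short_frac * n_genes)
  spans <- c(
    if (n_short) sample(500:2400, n_short, replace = TRUE),
    sample(span_range[1L]:span_range[2L], n_genes - n_short, replace = TRUE)
  )
  spans <- sample(spans)  # interleave short and long genes
  slack <- L - sum(spans)
  if (slack < 0L) {
    stop("cannot place ", n_genes, " non-overlapping genes on a length-",
         L, " sequence", call. = FALSE)
  }
  # distribute the slack into n_genes + 1 gaps
  gap_points <- sort(sample.int(slack + 1L, n_genes, replace = TRUE) - 1L)
  gaps <- diff(c(0L, gap_points))
  starts0 <- cumsum(gaps) + c(0L, cumsum(spans)[-n_genes])
  tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    seq_id = names(ref),
    start = as.integer(starts0 + 1L),
    end = as.integer(starts0 + spans),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
}

#' Simulate error-free long reads
#'
#' Draws substrings of the reference with uniform qualities.  No
#' sequencing error model is applied: downstream splitting and alignment
#' tests need identity with the source, not realism.
#'
#' @param ref named character vector of length 1.
#' @param n_reads number of reads.
#' @param length_range read length range in bases, or a vector of exact
#'   lengths to sample from.
#' @param seed integer seed.
#' @param qual_char quality character applied to every base.
#' @return list with `reads` (read table, see [read_fastq()]) and `truth`
#'   (tibble `read_id`, `start` 0-based, `length`).
#' @export
simulate_reads <- function(ref, n_reads, length_range = c(500L, 20000L),
                           seed = 1L, qual_char = "I") {
  ref <- as_ref_set(ref)
  stopifnot(length(ref) == 1L, n_reads >= 1L)
  L <- nchar(ref[[1L]])
  set.seed(seed)
  lens <- if (length(length_range) == 2L) {
    sample(length_range[1L]:min(length_range[2L], L), n_reads,
           replace = TRUE)
  } else {
    sample(length_range, n_reads, replace = TRUE)
  }
  stopifnot(all(lens <= L))
  starts0 <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L,
                    integer(1))
  reads <- tibble(
    read_id = sprintf("read%05d", seq_len(n_reads)),
    sequence = unname(substring(ref[[1L]], starts0 + 1L, starts0 + lens)),
    quality = strrep(qual_char, lens)
  )
  list(reads = reads,
       truth = tibble(read_id = reads$read_id, start = starts0,
                      length = lens))
}
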