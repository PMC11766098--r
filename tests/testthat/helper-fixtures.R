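# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no binary fixtures are stored.

run_table_path <- function() {
  system.file("extdata", "flowcell_runs_gb.tsv", package = "digiscaff")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A hit-table row with sensible defaults.
make_hit <- function(query_id = "q1", subject_id = "c1", q_start = 1L,
                     q_end = 100L, s_start = 1L, s_end = 100L,
                     pct_identity = 100, mismatches = 0L, gap_opens = 0L,
                     evalue = 0, bitscore = 200) {
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    pct_identity = pct_identity,
    aln_length = abs(q_end - q_start) + 1L,
    mismatches = as.integer(mismatches), gap_opens = as.integer(gap_opens),
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    evalue = evalue, bitscore = bitscore
  )
}

# A query table of `n` abutting queries of length `len` on one reference.
make_tiled_queries <- function(n, len = 1000L, seq_id = "chr") {
  starts <- (seq_len(n) - 1L) * len
  tibble::tibble(
    query_id = sprintf("%s|r%d|%d-%d", seq_id, seq_len(n) - 1L, starts,
                       starts + len),
    seq_id = seq_id, start = as.integer(starts),
    end = as.integer(starts + len), rank = seq_len(n) - 1L,
    kind = "ranked", sequence = NA_character_
  )
}

# A matrix built directly from per-contig rank intervals, one positive
# cell per rank in [first, last].
make_interval_matrix <- function(intervals, n_ranks,
                                 tier = 0.9, len = 1000L) {
  queries <- make_tiled_queries(n_ranks, len = len)
  positives <- dplyr::bind_rows(lapply(names(intervals), function(id) {
    iv <- intervals[[id]]
    tibble::tibble(subject_id = id, rank = iv[1L]:iv[2L], tier = tier)
  }))
  m <- digiscaff:::new_contig_query_matrix(
    queries, sort(unique(positives$subject_id)), positives)
  order_contigs(m)
}

# Brute-force minimum-cardinality cover of the covered ranks by contig
# rank intervals; returns the minimum subset size, or Inf if no subset
# covers all covered ranks.
brute_force_min_cover <- function(intervals, covered_ranks) {
  ids <- names(intervals)
  best <- Inf
  for (size in seq_along(ids)) {
    if (size >= best) break
    subsets <- utils::combn(ids, size, simplify = FALSE)
    for (sub in subsets) {
      got <- unique(unlist(lapply(sub, function(id) {
        intervals[[id]][1L]:intervals[[id]][2L]
      })))
      if (all(covered_ranks %in% got)) {
        best <- size
        break
      }
    }
  }
  best
}

# Random gapless interval-cover instance: every rank in 0..(n_ranks-1)
# is covered by at least one interval.  Built by partitioning the rank
# range into random segments (guaranteeing coverage), randomly extending
# each segment, and padding with arbitrary extra intervals.
random_gapless_instance <- function(n_contigs, n_ranks) {
  k <- min(n_contigs, n_ranks)
  cuts <- if (k > 1L) sort(sample(seq_len(n_ranks - 1L), k - 1L)) else
    integer()
  seg_first <- c(0L, cuts)
  seg_last <- c(cuts - 1L, n_ranks - 1L)
  first <- pmax(0L, seg_first - sample(0:2, k, replace = TRUE))
  last <- pmin(n_ranks - 1L, seg_last + sample(0:3, k, replace = TRUE))
  n_extra <- n_contigs - k
  if (n_extra > 0L) {
    ef <- sample.int(n_ranks, n_extra, replace = TRUE) - 1L
    el <- pmin(n_ranks - 1L,
               ef + sample.int(n_ranks, n_extra, replace = TRUE) - 1L)
    first <- c(first, ef)
    last <- c(last, el)
  }
  ord <- sample.int(n_contigs)
  iv <- mapply(function(f, l) c(f, l), first[ord], last[ord],
               SIMPLIFY = FALSE)
  names(iv) <- sprintf("c%02d", seq_along(iv))
  iv
}
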