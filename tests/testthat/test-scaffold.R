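test_that("query coverage unions hit intervals without double counting", {
  q <- make_tiled_queries(1, len = 4000L)
  # exact partition
  h <- dplyr::bind_rows(
    make_hit(q$query_id, "c1", 1, 2000),
    make_hit(q$query_id, "c1", 2001, 4000)
  )
  expect_equal(compute_query_coverage(h, q)$covered_fraction, 1.0)

  # overlap is unioned, not summed
  h2 <- dplyr::bind_rows(
    make_hit(q$query_id, "c1", 1, 3000),
    make_hit(q$query_id, "c1", 2001, 4000)
  )
  cov2 <- compute_query_coverage(h2, q)
  expect_equal(cov2$covered_fraction, 1.0)
  expect_equal(cov2$n_hits, 2L)

  # single partial hit
  h3 <- make_hit(q$query_id, "c1", 1001, 2000)
  expect_equal(compute_query_coverage(h3, q)$covered_fraction, 0.25)

  # out-of-bounds interval is an input error
  expect_error(compute_query_coverage(make_hit(q$query_id, "c1", 1, 4001), q),
               "outside")
  expect_error(compute_query_coverage(make_hit("nope", "c1", 1, 10), q),
               "unknown query_id")
})

test_that("coverage is tracked per (query, subject) pair with best bitscore", {
  q <- make_tiled_queries(2, len = 1000L)
  h <- dplyr::bind_rows(
    make_hit(q$query_id[1], "c1", 1, 600, bitscore = 100),
    make_hit(q$query_id[1], "c1", 401, 1000, bitscore = 250),
    make_hit(q$query_id[1], "c2", 1, 500, bitscore = 900),
    make_hit(q$query_id[2], "c1", 1, 1000, bitscore = 50)
  )
  cov <- compute_query_coverage(h, q)
  expect_equal(nrow(cov), 3L)
  r <- cov[cov$query_id == q$query_id[1] & cov$subject_id == "c1", ]
  expect_equal(r$covered_fraction, 1.0)
  expect_equal(r$best_bitscore, 250)
  expect_equal(r$n_hits, 2L)
})

test_that("successive-threshold filtering assigns the highest tier met", {
  q <- make_tiled_queries(3)
  cov <- tibble::tibble(
    query_id = q$query_id[c(1, 2, 3)],
    subject_id = c("c1", "c1", "c2"),
    covered_fraction = c(0.95, 0.45, 0.72),
    best_bitscore = 1, n_hits = 1L
  )
  m <- filter_by_thresholds(cov, q, tiers = c(0.9, 0.8))
  expect_equal(nrow(m$positives), 1L)  # 0.45 and 0.72 fall below 0.8
  expect_equal(m$positives$tier, 0.9)

  m2 <- filter_by_thresholds(cov, q)  # default tiers down to 0.5
  expect_equal(sort(m2$positives$tier), c(0.7, 0.9))
  # columns are all queries even without positives
  expect_equal(nrow(m2$queries), 3L)

  expect_error(filter_by_thresholds(cov, q, tiers = c(0.5, 0.9)),
               "descending")
  expect_error(filter_by_thresholds(cov, q, tiers = numeric()), "descending")
})

test_that("tier assignment matches a brute-force oracle on random coverages", {
  set.seed(17)
  tiers <- c(0.9, 0.8, 0.7, 0.5)
  q <- make_tiled_queries(10)
  cov <- tibble::tibble(
    query_id = sample(q$query_id, 40, replace = TRUE),
    subject_id = sample(sprintf("c%02d", 1:8), 40, replace = TRUE),
    covered_fraction = round(runif(40, 0.3, 1), 3),
    best_bitscore = 1, n_hits = 1L
  )
  cov <- cov[!duplicated(cov[c("query_id", "subject_id")]), ]
  m <- filter_by_thresholds(cov, q, tiers)
  # oracle: exhaustive per-pair tier scan
  expected <- do.call(rbind, lapply(seq_len(nrow(cov)), function(i) {
    passed <- tiers[cov$covered_fraction[i] >= tiers]
    if (!length(passed)) return(NULL)
    data.frame(subject_id = cov$subject_id[i],
               rank = q$rank[match(cov$query_id[i], q$query_id)],
               tier = max(passed))
  }))
  expected <- expected[order(expected$subject_id, expected$rank), ]
  rownames(expected) <- NULL
  expect_equal(as.data.frame(m$positives), expected)
})

test_that("contig ordering sorts by leftmost rank with span tie-break", {
  m <- make_interval_matrix(list(cA = c(5, 9), cB = c(0, 3), cC = c(2, 6)),
                            n_ranks = 10)
  expect_equal(m$contigs, c("cB", "cC", "cA"))

  # identical leftmost rank: longer span first
  m2 <- make_interval_matrix(list(short = c(0, 3), long = c(0, 9)),
                             n_ranks = 10)
  expect_equal(m2$contigs, c("long", "short"))

  # random instances vs a sort oracle on the 3-key tuple
  set.seed(23)
  for (rep in 1:5) {
    iv <- random_gapless_instance(20, 15)
    m3 <- make_interval_matrix(iv, n_ranks = 15)
    key <- do.call(rbind, iv)
    oracle <- names(iv)[order(key[, 1], -key[, 2], names(iv))]
    expect_equal(m3$contigs, oracle)
  }
})

test_that("mapped-contigs grid round-trips and is deterministic", {
  m <- make_interval_matrix(list(cA = c(0, 1), cB = c(2, 2)), n_ranks = 3,
                            tier = 0.8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_mapped_contigs(m, f)
  lines <- readLines(f)
  # header lists query ids in increasing rank, first column is the contig
  hdr <- strsplit(lines[1], ",")[[1]]
  expect_equal(hdr[1], "contig")
  expect_equal(hdr[-1], m$queries$query_id[order(m$queries$rank)])
  # 2 contigs x 3 queries with 3 positives -> exactly 3 non-empty cells
  cells <- unlist(lapply(strsplit(lines[-1], ",", fixed = TRUE),
                         function(x) x[-1]))
  expect_equal(sum(nzchar(cells)), 3L)

  back <- read_mapped_contigs(f)
  expect_equal(back$contigs, m$contigs)
  expect_equal(as.data.frame(back$positives), as.data.frame(m$positives))
  expect_equal(back$queries$rank, m$queries$rank)

  # byte-identical on re-write (pipeline determinism)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_mapped_contigs(back, f2)
  expect_identical(readLines(f), readLines(f2))

  expect_error(write_mapped_contigs(
    digiscaff:::new_contig_query_matrix(m$queries, m$contigs, m$positives,
                                        ordered = FALSE), f), "ordered")
})

test_that("greedy scaffold selection matches the worked examples", {
  # three intervals over ranks 0-9: optimum is {[0,4],[3,9]}
  m <- make_interval_matrix(list(a = c(0, 4), b = c(3, 9), c = c(1, 5)),
                            n_ranks = 10)
  sc <- select_minimal_scaffold(m)
  expect_equal(sort(sc$selected$subject_id), c("a", "b"))
  expect_equal(nrow(sc$gaps), 0L)
  expect_equal(brute_force_min_cover(list(a = c(0, 4), b = c(3, 9),
                                          c = c(1, 5)), 0:9), 2)

  # one contig covering everything: single red row, everything else blue
  m2 <- make_interval_matrix(list(all = c(0, 9), part = c(2, 5)),
                             n_ranks = 10)
  sc2 <- select_minimal_scaffold(m2)
  expect_equal(sc2$selected$subject_id, "all")
  expect_true(all(sc2$classification$color[
    sc2$classification$subject_id == "part"] == "blue"))
  expect_true(all(sc2$classification$color[
    sc2$classification$subject_id == "all"] == "red"))

  # disjoint intervals: both selected, gap recorded
  m3 <- make_interval_matrix(list(l = c(0, 2), r = c(6, 8)), n_ranks = 9)
  sc3 <- select_minimal_scaffold(m3)
  expect_equal(sc3$selected$subject_id, c("l", "r"))
  expect_equal(as.data.frame(sc3$gaps),
               data.frame(first_rank = 3L, last_rank = 5L))

  # empty matrix -> empty scaffold with zero coverage
  empty <- digiscaff:::new_contig_query_matrix(
    make_tiled_queries(3), character(),
    tibble::tibble(subject_id = character(), rank = integer(),
                   tier = numeric()))
  sc4 <- select_minimal_scaffold(empty, ref_length = 1000)
  expect_equal(nrow(sc4$selected), 0L)
  expect_equal(sc4$coverage_pct, 0)
})

test_that("every covered rank is covered by a red contig", {
  set.seed(29)
  for (rep in 1:10) {
    iv <- random_gapless_instance(sample(3:10, 1), sample(5:15, 1))
    m <- make_interval_matrix(iv, n_ranks = max(vapply(iv, max, 0)) + 1L)
    sc <- select_minimal_scaffold(m)
    covered <- unique(m$positives$rank)
    red_ranks <- unlist(lapply(seq_len(nrow(sc$selected)), function(i) {
      sc$selected$first_rank[i]:sc$selected$last_rank[i]
    }))
    expect_true(all(covered %in% red_ranks))
    # red/blue partition the positive cells
    expect_equal(nrow(sc$classification), nrow(m$positives))
    expect_true(all(sc$classification$color %in% c("red", "blue")))
  }
})

test_that("greedy cover cardinality is optimal on gapless instances", {
  set.seed(31)
  for (rep in 1:25) {
    n_contigs <- sample(2:9, 1)
    n_ranks <- sample(4:12, 1)
    iv <- random_gapless_instance(n_contigs, n_ranks)
    m <- make_interval_matrix(iv, n_ranks = n_ranks)
    sc <- select_minimal_scaffold(m)
    expect_equal(nrow(sc$selected),
                 brute_force_min_cover(iv, 0:(n_ranks - 1L)),
                 info = sprintf("rep %d", rep))
    expect_equal(nrow(sc$gaps), 0L)
  }
})

test_that("linear coverage follows the run-span rule", {
  # exact tiling, all ranks selected -> 100%
  m <- make_interval_matrix(list(a = c(0, 9)), n_ranks = 10, len = 1000L)
  sc <- select_minimal_scaffold(m, ref_length = 10000)
  expect_equal(sc$coverage_pct, 100)

  # 9 of 10 abutting 1 kb queries covered on a 10 kb reference -> 90%
  m2 <- make_interval_matrix(list(a = c(0, 8)), n_ranks = 10, len = 1000L)
  sc2 <- select_minimal_scaffold(m2, ref_length = 10000)
  expect_equal(sc2$coverage_pct, 90)

  # disjoint runs each contribute their own span
  m3 <- make_interval_matrix(list(l = c(0, 2), r = c(6, 8)), n_ranks = 9,
                             len = 1000L)
  sc3 <- select_minimal_scaffold(m3, ref_length = 9000)
  expect_equal(sc3$coverage_pct, 100 * 6000 / 9000)
})

test_that("coverage arithmetic matches a per-base bitmap oracle", {
  set.seed(37)
  for (rep in 1:20) {
    n_ranks <- sample(5:14, 1)
    len <- 500L
    iv <- random_gapless_instance(sample(2:8, 1), n_ranks)
    # drop a random contig to create potential gaps
    if (length(iv) > 2L && runif(1) < 0.5) iv <- iv[-sample(length(iv), 1)]
    m <- make_interval_matrix(iv, n_ranks = n_ranks, len = len)
    ref_len <- n_ranks * len + sample(0:2000, 1)
    sc <- select_minimal_scaffold(m, ref_length = ref_len)

    # oracle: paint covered bases, merging runs of overlapping-or-abutting
    # selected rank intervals
    bitmap <- logical(ref_len)
    sel <- sc$selected[order(sc$selected$first_rank), ]
    if (nrow(sel)) {
      run_first <- sel$first_rank[1]; run_last <- sel$last_rank[1]
      flush <- function(f, l) {
        s <- f * len + 1L
        e <- (l + 1L) * len
        bitmap[s:e] <<- TRUE
      }
      if (nrow(sel) > 1) for (i in 2:nrow(sel)) {
        if (sel$first_rank[i] <= run_last + 1L) {
          run_last <- max(run_last, sel$last_rank[i])
        } else {
          flush(run_first, run_last)
          run_first <- sel$first_rank[i]; run_last <- sel$last_rank[i]
        }
      }
      flush(run_first, run_last)
    }
    expect_equal(sc$coverage_pct, 100 * sum(bitmap) / ref_len,
                 info = sprintf("rep %d", rep))
  }
})

test_that("repeat-region flagging finds planted high-multiplicity blocks", {
  # every query hits exactly one contig: nothing flagged
  m <- make_interval_matrix(list(a = c(0, 9)), n_ranks = 10)
  expect_equal(nrow(flag_repeat_regions(m)), 0L)

  # planted block: ranks 4-9 each hit by 5 contigs; sparse background
  iv <- c(list(bgL = c(0, 2), bgR = c(12, 14)),
          setNames(lapply(1:5, function(i) c(4, 9)),
                   sprintf("rep%d", 1:5)))
  m2 <- make_interval_matrix(iv, n_ranks = 15)
  flagged <- flag_repeat_regions(m2, window = 5, min_contigs = 4)
  expect_equal(as.data.frame(flagged),
               data.frame(first_rank = 4L, last_rank = 9L))

  # degenerate threshold flags the whole covered range
  all_flagged <- flag_repeat_regions(m, window = 5, min_contigs = 1)
  expect_equal(as.data.frame(all_flagged),
               data.frame(first_rank = 0L, last_rank = 9L))
})

test_that("windowed flagging matches a brute-force oracle", {
  set.seed(41)
  for (rep in 1:10) {
    n_ranks <- 20L
    iv <- random_gapless_instance(sample(4:10, 1), n_ranks)
    m <- make_interval_matrix(iv, n_ranks = n_ranks)
    window <- sample(3:6, 1)
    min_contigs <- sample(2:4, 1)
    got <- flag_repeat_regions(m, window, min_contigs)
    # oracle: direct definition
    counts <- vapply(0:(n_ranks - 1L), function(r) {
      length(unique(m$positives$subject_id[m$positives$rank == r]))
    }, integer(1))
    flagged <- logical(n_ranks)
    for (s in 1:(n_ranks - window + 1L)) {
      if (mean(counts[s:(s + window - 1L)]) >= min_contigs) {
        flagged[s:(s + window - 1L)] <- TRUE
      }
    }
    flagged <- flagged & counts >= 1L
    runs <- rle(flagged)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    oracle <- data.frame(first_rank = starts[keep] - 1L,
                         last_rank = ends[keep] - 1L)
    expect_equal(as.data.frame(got), oracle, info = sprintf("rep %d", rep))
  }
})

test_that("grid plots render the requested rows and title", {
  iv <- list(a = c(0, 4), b = c(3, 9), c = c(1, 5))
  m <- make_interval_matrix(iv, n_ranks = 10)
  sc <- select_minimal_scaffold(m, ref_length = 10000)

  gg <- plot_grid(m, sc)
  expect_equal(length(unique(gg$data$subject_id)), 3L)
  expect_match(gg$labels$title, sprintf("%.3f%%", sc$coverage_pct),
               fixed = TRUE)

  red <- plot_grid(m, sc, red_only = TRUE)
  expect_setequal(as.character(unique(red$data$subject_id)),
                  sc$selected$subject_id)

  f <- withr::local_tempfile(fileext = ".png")
  plot_grid(m, sc, path = f)
  expect_true(file.size(f) > 0)
})

test_that("scaffold table maps rank intervals to reference coordinates", {
  m <- make_interval_matrix(list(a = c(0, 4), b = c(3, 9)), n_ranks = 10,
                            len = 1000L)
  sc <- select_minimal_scaffold(m, ref_length = 10000)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scaffold_table(sc, m$queries, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(tab$ref_start, c(0L, 3000L))
  expect_equal(tab$ref_end, c(5000L, 10000L))
})
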