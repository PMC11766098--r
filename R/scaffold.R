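#' Per query-contig coverage from alignment hits
#'
#' For every (query, subject) pair seen in `hits`, hit intervals on the
#' query axis are unioned (overlaps are never double-counted) and divided
#' by the query length.  This collapses the redundant alignments a repeat
#' can spawn between one query and one contig into a single record per
#' pair — the "unique query per subject" filtering step.
#'
#' @param hits a hit table (see [hit-table]).
#' @param queries the query table the hits were generated from.
#' @return tibble with one row per (query_id, subject_id) pair:
#'   `covered_fraction` in (0, 1], `best_bitscore`, `n_hits`.
#' @export
compute_query_coverage <- function(hits, queries) {
  stopifnot(is.data.frame(hits), is.data.frame(queries))
  if (nrow(hits) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  covered_fraction = numeric(), best_bitscore = numeric(),
                  n_hits = integer()))
  }
  qlen <- setNames(queries$end - queries$start, queries$query_id)
  unknown <- !(hits$query_id %in% names(qlen))
  if (any(unknown)) {
    stop("hit references unknown query_id `",
         hits$query_id[which(unknown)[1L]], "`", call. = FALSE)
  }
  L <- qlen[hits$query_id]
  bad <- hits$q_start < 1L | hits$q_end > L | hits$q_start > hits$q_end
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("hit interval [", hits$q_start[i], ",", hits$q_end[i],
         "] outside [1,", L[i], "] for query `", hits$query_id[i], "`",
         call. = FALSE)
  }
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  idx <- split(seq_len(nrow(hits)), key)
  pairs <- do.call(rbind, strsplit(names(idx), "\r", fixed = TRUE))
  covered <- vapply(idx, function(i) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(hits$q_start[i], hits$q_end[i]))))
  }, numeric(1))
  out <- tibble(
    query_id = pairs[, 1L],
    subject_id = pairs[, 2L],
    covered_fraction = unname(covered / qlen[pairs[, 1L]]),
    best_bitscore = vapply(idx, function(i) max(hits$bitscore[i]),
                           numeric(1), USE.NAMES = FALSE),
    n_hits = lengths(idx, use.names = FALSE)
  )
  out[order(out$query_id, out$subject_id), , drop = FALSE]
}

#' Contig-by-query incidence matrices
#'
#' The positive-cell grid behind the mapped-contigs output: columns are
#' all queries in rank order (X-axis), rows are contigs with at least one
#' positive cell (Y-axis), and each positive cell records the successive
#' coverage threshold tier it passed.
#'
#' @param queries query table (all queries, also those without hits).
#' @param contigs ordered character vector of subject ids.
#' @param positives tibble with columns `subject_id`, `rank`, `tier`.
#' @param ordered has [order_contigs()] been applied?
#' @return an object of class `contig_query_matrix`.
#' @keywords internal
new_contig_query_matrix <- function(queries, contigs, positives,
                                    ordered = FALSE) {
  structure(list(queries = queries, contigs = contigs,
                 positives = positives, ordered = ordered),
            class = "contig_query_matrix")
}

#' @export
print.contig_query_matrix <- function(x, ...) {
  cat("<contig_query_matrix> ", length(x$contigs), " contigs x ",
      nrow(x$queries), " queries, ", nrow(x$positives),
      " positive cells", if (x$ordered) " (ordered)", "\n", sep = "")
  invisible(x)
}

#' Successive-threshold filtering into a positive-cell matrix
#'
#' A (query, contig) pair becomes a positive cell at the *highest* tier
#' its covered fraction meets; pairs below the lowest tier are discarded.
#' The default schedule `c(0.90, 0.80, 0.70, 0.50)` of query coverage is
#' fully configurable.
#'
#' @param coverages output of [compute_query_coverage()].
#' @param queries the full query table (matrix columns).
#' @param tiers strictly descending coverage fractions in (0, 1].
#' @return an (unordered) `contig_query_matrix`.
#' @export
filter_by_thresholds <- function(coverages, queries,
                                 tiers = c(0.90, 0.80, 0.70, 0.50)) {
  if (length(tiers) == 0L || any(tiers <= 0) || any(tiers > 1) ||
      is.unsorted(rev(tiers), strictly = TRUE)) {
    stop("`tiers` must be strictly descending fractions in (0, 1]",
         call. = FALSE)
  }
  stopifnot(is.data.frame(coverages), is.data.frame(queries))
  rank_of <- setNames(queries$rank, queries$query_id)
  unknown <- !(coverages$query_id %in% names(rank_of))
  if (any(unknown)) {
    stop("coverage references unknown query_id `",
         coverages$query_id[which(unknown)[1L]], "`", call. = FALSE)
  }
  tier <- vapply(coverages$covered_fraction, function(cf) {
    ok <- tiers[tiers <= cf]
    if (length(ok)) ok[1L] else NA_real_
  }, numeric(1))
  keep <- !is.na(tier)
  positives <- tibble(
    subject_id = coverages$subject_id[keep],
    rank = as.integer(rank_of[coverages$query_id[keep]]),
    tier = tier[keep]
  )
  positives <- positives[order(positives$subject_id, positives$rank), ,
                         drop = FALSE]
  queries <- queries[order(queries$rank), , drop = FALSE]
  new_contig_query_matrix(queries, sort(unique(positives$subject_id)),
                          positives)
}

contig_spans <- function(matrix) {
  p <- matrix$positives
  sp <- vapply(split(p$rank, p$subject_id), range, integer(2))
  tibble(subject_id = colnames(sp),
         first_rank = sp[1L, ], last_rank = sp[2L, ])
}

#' Order contig rows along the reference
#'
#' Rows are sorted by (leftmost positive rank ascending, rightmost
#' positive rank descending, subject id) — contigs anchored earlier on the
#' chromosome come first, and of two contigs anchored at the same rank the
#' one spanning further right wins.  Stable and deterministic.
#'
#' @param matrix a `contig_query_matrix`.
#' @return the matrix with rows reordered and `ordered = TRUE`.
#' @export
order_contigs <- function(matrix) {
  stopifnot(inherits(matrix, "contig_query_matrix"))
  if (length(matrix$contigs) == 0L) {
    matrix$ordered <- TRUE
    return(matrix)
  }
  sp <- contig_spans(matrix)
  ord <- order(sp$first_rank, -sp$last_rank, sp$subject_id)
  matrix$contigs <- sp$subject_id[ord]
  matrix$ordered <- TRUE
  matrix
}

#' Write the mapped-contigs grid
#'
#' First column holds the contig ids in row (Y-axis) order; one column per
#' query in rank order, named by `query_id`.  Positive cells carry the
#' tier they passed, all other cells are empty.  Comma-delimited;
#' re-readable losslessly with [read_mapped_contigs()].
#'
#' @param matrix an ordered `contig_query_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapped_contigs <- function(matrix, path) {
  stopifnot(inherits(matrix, "contig_query_matrix"))
  if (!matrix$ordered) {
    stop("matrix must be ordered first (see order_contigs())", call. = FALSE)
  }
  q <- matrix$queries[order(matrix$queries$rank), , drop = FALSE]
  grid <- matrix(NA_real_, nrow = length(matrix$contigs), ncol = nrow(q),
                 dimnames = list(matrix$contigs, q$query_id))
  p <- matrix$positives
  grid[cbind(match(p$subject_id, matrix$contigs), p$rank + 1L)] <- p$tier
  df <- as.data.frame(grid, optional = TRUE)
  df <- cbind(contig = rownames(grid), df)
  readr::write_csv(as_tibble(df), path, na = "")
  invisible(path)
}

#' Read a mapped-contigs grid back into a matrix object
#'
#' Query sequences are not stored in the grid, so the reconstructed query
#' table carries `NA` sequences; ranks and coordinates are recovered from
#' the column headers.
#'
#' @param path path written by [write_mapped_contigs()].
#' @return an ordered `contig_query_matrix`.
#' @export
read_mapped_contigs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = "",
                        name_repair = "minimal")
  stopifnot(names(df)[1L] == "contig")
  queries <- parse_query_ids(names(df)[-1L])
  contigs <- as.character(df$contig)
  cells <- which(!is.na(as.matrix(df[, -1L, drop = FALSE])), arr.ind = TRUE)
  positives <- tibble(
    subject_id = contigs[cells[, 1L]],
    rank = queries$rank[cells[, 2L]],
    tier = as.numeric(as.matrix(df[, -1L, drop = FALSE])[cells])
  )
  positives <- positives[order(positives$subject_id, positives$rank), ,
                         drop = FALSE]
  new_contig_query_matrix(queries, contigs, positives, ordered = TRUE)
}

#' Select a minimal complete scaffold
#'
#' Greedy furthest-reach interval cover over query ranks: starting from
#' the first rank with any positive cell, repeatedly pick the contig whose
#' positive-rank interval starts at or before the current frontier plus
#' one and extends furthest right; when no contig overlaps, record a gap
#' and restart at the next covered rank.  For gapless instances this
#' greedy rule attains the minimum-cardinality cover (the classic interval
#' covering argument).  Cells of selected contigs are classified `red`,
#' all remaining positive cells `blue` (redundant or repeat-borne).
#'
#' @param matrix a `contig_query_matrix`.
#' @param ref_length reference sequence length in bases; when supplied the
#'   linear coverage percentage is computed (see [linear_coverage_pct()]).
#' @return an object of class `minimal_scaffold` with elements `selected`
#'   (tibble `subject_id`, `first_rank`, `last_rank`, sorted by
#'   `first_rank`), `gaps` (rank intervals with no overlapping contig),
#'   `classification` (per positive cell: `red`/`blue`), and
#'   `coverage_pct`.
#' @export
select_minimal_scaffold <- function(matrix, ref_length = NULL) {
  stopifnot(inherits(matrix, "contig_query_matrix"))
  empty <- structure(
    list(selected = tibble(subject_id = character(), first_rank = integer(),
                           last_rank = integer()),
         gaps = tibble(first_rank = integer(), last_rank = integer()),
         classification = tibble(subject_id = character(), rank = integer(),
                                 color = character()),
         coverage_pct = 0),
    class = "minimal_scaffold")
  if (nrow(matrix$positives) == 0L) return(empty)

  sp <- contig_spans(matrix)
  covered <- sort(unique(matrix$positives$rank))
  target <- covered[length(covered)]
  frontier <- covered[1L] - 1L
  sel <- character()
  gaps_first <- integer(); gaps_last <- integer()

  while (frontier < target) {
    cand <- sp[sp$first_rank <= frontier + 1L & sp$last_rank > frontier, ,
               drop = FALSE]
    if (nrow(cand) == 0L) {
      nxt <- covered[covered > frontier][1L]
      gaps_first <- c(gaps_first, frontier + 1L)
      gaps_last <- c(gaps_last, nxt - 1L)
      frontier <- nxt - 1L
      next
    }
    pick <- cand[order(-cand$last_rank, cand$first_rank, cand$subject_id), ,
                 drop = FALSE][1L, ]
    sel <- c(sel, pick$subject_id)
    frontier <- pick$last_rank
  }

  selected <- sp[match(sel, sp$subject_id), , drop = FALSE]
  selected <- selected[order(selected$first_rank, selected$last_rank,
                             selected$subject_id), , drop = FALSE]
  classification <- tibble(
    subject_id = matrix$positives$subject_id,
    rank = matrix$positives$rank,
    color = ifelse(matrix$positives$subject_id %in% sel, "red", "blue")
  )
  out <- structure(
    list(selected = selected,
         gaps = tibble(first_rank = gaps_first, last_rank = gaps_last),
         classification = classification,
         coverage_pct = NA_real_),
    class = "minimal_scaffold")
  out$coverage_pct <- if (is.null(ref_length)) NA_real_ else
    linear_coverage_pct(out, matrix$queries, ref_length)
  out
}

#' @export
print.minimal_scaffold <- function(x, ...) {
  cat("<minimal_scaffold> ", nrow(x$selected), " selected contig(s), ",
      nrow(x$gaps), " gap(s)", sep = "")
  if (!is.na(x$coverage_pct)) {
    cat(sprintf(", linear coverage %.3f%%", x$coverage_pct))
  }
  cat("\n")
  invisible(x)
}

#' Linear chromosomal coverage of a scaffold selection
#'
#' Consecutive selected contigs whose rank intervals overlap or abut form
#' a run; each run covers the reference from the start of its first query
#' to the end of its last query.  The percentage is taken against the
#' full reference length, so uncovered chromosome ends and gaps between
#' runs count against it.
#'
#' @param scaffold a `minimal_scaffold`.
#' @param queries the query table (for rank-to-coordinate lookup).
#' @param ref_length reference length in bases.
#' @return coverage percentage in `[0, 100]`.
#' @export
linear_coverage_pct <- function(scaffold, queries, ref_length) {
  stopifnot(inherits(scaffold, "minimal_scaffold"), ref_length >= 1)
  sel <- scaffold$selected
  if (nrow(sel) == 0L) return(0)
  if (!all(sel$first_rank %in% queries$rank) ||
      !all(sel$last_rank %in% queries$rank)) {
    stop("selected intervals reference ranks absent from `queries`",
         call. = FALSE)
  }
  sel <- sel[order(sel$first_rank, sel$last_rank), , drop = FALSE]
  # merge into maximal runs of overlapping or abutting rank intervals
  run_first <- sel$first_rank[1L]
  run_last <- sel$last_rank[1L]
  runs <- list()
  for (i in seq_len(nrow(sel))[-1L]) {
    if (sel$first_rank[i] <= run_last + 1L) {
      run_last <- max(run_last, sel$last_rank[i])
    } else {
      runs[[length(runs) + 1L]] <- c(run_first, run_last)
      run_first <- sel$first_rank[i]
      run_last <- sel$last_rank[i]
    }
  }
  runs[[length(runs) + 1L]] <- c(run_first, run_last)

  start_of <- setNames(queries$start, queries$rank)
  end_of <- setNames(queries$end, queries$rank)
  spans <- IRanges::IRanges(
    start = vapply(runs, function(r) start_of[[as.character(r[1L])]],
                   integer(1)) + 1L,
    end = vapply(runs, function(r) end_of[[as.character(r[2L])]],
                 integer(1))
  )
  100 * sum(IRanges::width(IRanges::reduce(spans))) / ref_length
}

#' Flag repeat-rich query regions
#'
#' Repeats make many contigs light up the same queries.  Per query rank
#' the number of distinct contigs with a positive cell is counted; a
#' sliding window of `window` ranks qualifies when its mean count is at
#' least `min_contigs`, and every rank with at least one positive cell
#' inside a qualifying window is flagged.  Maximal runs of flagged ranks
#' are returned.
#'
#' @param matrix a `contig_query_matrix`.
#' @param window sliding window width in query ranks.
#' @param min_contigs minimum mean number of distinct contigs per query.
#' @return tibble with columns `first_rank`, `last_rank`.
#' @export
flag_repeat_regions <- function(matrix, window = 5L, min_contigs = 4L) {
  stopifnot(inherits(matrix, "contig_query_matrix"), window >= 1L)
  empty <- tibble(first_rank = integer(), last_rank = integer())
  if (nrow(matrix$positives) == 0L) return(empty)
  ranks <- sort(unique(matrix$queries$rank))
  counts <- vapply(ranks, function(r) {
    length(unique(matrix$positives$subject_id[matrix$positives$rank == r]))
  }, integer(1))
  w <- min(as.integer(window), length(ranks))
  csum <- cumsum(c(0L, counts))
  nwin <- length(ranks) - w + 1L
  means <- (csum[(1:nwin) + w] - csum[1:nwin]) / w
  ok <- means >= min_contigs
  in_window <- logical(length(ranks))
  for (s in which(ok)) in_window[s:(s + w - 1L)] <- TRUE
  flagged <- in_window & counts >= 1L
  if (!any(flagged)) return(empty)
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(first_rank = ranks[starts[keep]], last_rank = ranks[ends[keep]])
}

#' Plot the positive-cell grid
#'
#' Contigs on the Y-axis (top to bottom in matrix row order), query ranks
#' on the X-axis.  With a scaffold supplied, cells are colored red (the
#' minimal complete scaffold) or blue (redundant/repeat cells) and the
#' linear coverage percentage is printed in the title; without one, cells
#' are shaded by threshold tier.
#'
#' @param matrix an ordered `contig_query_matrix`.
#' @param scaffold optional `minimal_scaffold` for red/blue coloring.
#' @param path optional output image path (PNG/SVG/PDF, by extension).
#' @param red_only render only the selected (red) contigs, minimal-scaffold
#'   style.
#' @param width,height device size in inches when `path` is given.
#' @return the ggplot object, invisibly.
#' @export
plot_grid <- function(matrix, scaffold = NULL, path = NULL,
                      red_only = FALSE, width = 9, height = 6) {
  stopifnot(inherits(matrix, "contig_query_matrix"))
  if (!matrix$ordered) matrix <- order_contigs(matrix)
  p <- matrix$positives
  if (!is.null(scaffold)) {
    p <- dplyr::left_join(p, scaffold$classification,
                          by = c("subject_id", "rank"))
  } else {
    p$color <- factor(p$tier)
  }
  contigs <- matrix$contigs
  if (red_only) {
    if (is.null(scaffold)) {
      stop("`red_only` requires a scaffold", call. = FALSE)
    }
    contigs <- contigs[contigs %in% scaffold$selected$subject_id]
    p <- p[p$subject_id %in% contigs, , drop = FALSE]
  }
  p$subject_id <- factor(p$subject_id, levels = rev(contigs))
  title <- if (!is.null(scaffold) && !is.na(scaffold$coverage_pct)) {
    sprintf("Linear coverage: %.3f%%", scaffold$coverage_pct)
  } else {
    "Contig-by-query positive cells"
  }
  gg <- ggplot2::ggplot(p, ggplot2::aes(x = .data$rank, y = .data$subject_id,
                                        fill = .data$color)) +
    ggplot2::geom_tile(color = "grey85", linewidth = 0.1) +
    (if (!is.null(scaffold)) {
      ggplot2::scale_fill_manual(values = c(red = "#d7301f",
                                            blue = "#2b8cbe"),
                                 name = NULL)
    } else {
      ggplot2::scale_fill_viridis_d(name = "tier")
    }) +
    ggplot2::labs(title = title, x = "query rank", y = "contig") +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(path)) {
    ggplot2::ggsave(path, gg, width = width, height = height, dpi = 150)
  }
  invisible(gg)
}

#' Write the minimal-scaffold table
#'
#' One row per selected contig with its rank interval and the reference
#' coordinates spanned by the corresponding queries.
#'
#' @param scaffold a `minimal_scaffold`.
#' @param queries the query table.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_scaffold_table <- function(scaffold, queries, path) {
  sel <- scaffold$selected
  start_of <- setNames(queries$start, queries$rank)
  end_of <- setNames(queries$end, queries$rank)
  out <- tibble(
    contig = sel$subject_id,
    first_rank = sel$first_rank,
    last_rank = sel$last_rank,
    ref_start = as.integer(start_of[as.character(sel$first_rank)]),
    ref_end = as.integer(end_of[as.character(sel$last_rank)])
  )
  readr::write_tsv(out, path)
  invisible(path)
}
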