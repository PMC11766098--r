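#' Alignment hit tables
#'
#' An alignment hit table mirrors the standard 12-column BLAST tabular
#' format (`-outfmt 6`): `query_id`, `subject_id`, `pct_identity`,
#' `aln_length`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#' `s_end`, `evalue`, `bitscore`.  Coordinates are 1-based inclusive;
#' `q_start <= q_end` always, and `s_start > s_end` marks a hit on the
#' subject minus strand.
#'
#' @name hit-table
NULL

hit_cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
              "mismatches", "gap_opens", "q_start", "q_end", "s_start",
              "s_end", "evalue", "bitscore")

new_hit_table <- function(...) {
  args <- list(...)
  if (!length(args)) {
    args <- list(query_id = character(), subject_id = character(),
                 pct_identity = numeric(), aln_length = integer(),
                 mismatches = integer(), gap_opens = integer(),
                 q_start = integer(), q_end = integer(),
                 s_start = integer(), s_end = integer(),
                 evalue = numeric(), bitscore = numeric())
  }
  do.call(tibble, args)
}

#' Parse BLAST 12-column tabular output
#'
#' Accepts a path or a character vector of lines.  Lines starting with `#`
#' are skipped.  Malformed lines (wrong field count, unparseable numbers)
#' raise an error naming the offending line number.
#'
#' @param x path to a tabular file, or a character vector of lines.
#' @return a hit table (see [hit-table]).
#' @export
parse_tabular <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\t", x) && file.exists(x)) {
    readLines(x)
  } else {
    x
  }
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(new_hit_table())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop("line ", lineno[i], ": expected 12 tab-separated fields, found ",
         nf[i], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(col, what, integer = FALSE) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("line ", lineno[i], ": cannot parse ", what, " `", m[i, col],
           "`", call. = FALSE)
    }
    if (integer) as.integer(v) else v
  }
  new_hit_table(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = num(3L, "pct_identity"),
    aln_length = num(4L, "aln_length", TRUE),
    mismatches = num(5L, "mismatches", TRUE),
    gap_opens = num(6L, "gap_opens", TRUE),
    q_start = num(7L, "q_start", TRUE), q_end = num(8L, "q_end", TRUE),
    s_start = num(9L, "s_start", TRUE), s_end = num(10L, "s_end", TRUE),
    evalue = num(11L, "evalue"), bitscore = num(12L, "bitscore")
  )
}

#' Write a hit table in BLAST tabular format
#'
#' Percent identity is printed with three decimals as `blastn` does; the
#' remaining numeric fields keep full precision so that
#' `parse_tabular(write_tabular(x))` round-trips.
#'
#' @param hits a hit table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(hits, path) {
  stopifnot(all(hit_cols %in% names(hits)))
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   hits$aln_length, hits$mismatches, hits$gap_opens,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   as.character(hits$evalue), as.character(hits$bitscore))
  writeLines(lines, path)
  invisible(path)
}

#' Align queries to contigs with external BLAST+
#'
#' Builds a nucleotide database from the contig FASTA in a temporary
#' workspace, runs `blastn`, and parses the tabular output.  Defaults are
#' deliberately stringent (`task = "blastn"`, `evalue = 1e-10`): the
#' queries are multi-kilobase near-identical reference fragments, so weak
#' spurious hits carry no information for contig ordering.
#'
#' @param query_fasta path to the query FASTA (see [write_queries()]).
#' @param contig_fasta path to the contig FASTA.
#' @param evalue E-value cutoff passed to `blastn`.
#' @param task `blastn` task (`"blastn"`, `"megablast"`, ...).
#' @param threads number of BLAST threads.
#' @return a hit table.
#' @export
run_blast <- function(query_fasta, contig_fasta, evalue = 1e-10,
                      task = "blastn", threads = 1L) {
  for (f in c(query_fasta, contig_fasta)) {
    if (!file.exists(f) || file.size(f) == 0L) {
      stop("FASTA file missing or empty: ", f, call. = FALSE)
    }
  }
  exes <- c(makeblastdb = unname(Sys.which("makeblastdb")),
            blastn = unname(Sys.which("blastn")))
  if (any(!nzchar(exes))) {
    stop("BLAST+ executables not found on PATH: ",
         paste(names(exes)[!nzchar(exes)], collapse = ", "), call. = FALSE)
  }
  ws <- tempfile("blastdb")
  dir.create(ws)
  on.exit(unlink(ws, recursive = TRUE))
  db <- file.path(ws, "db")
  log <- system2(exes[["makeblastdb"]],
                 c("-in", shQuote(contig_fasta), "-dbtype", "nucl",
                   "-out", shQuote(db)),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(paste0(db, ".nsq")) &&
      !file.exists(paste0(db, ".00.nsq"))) {
    stop("makeblastdb failed:\n", paste(log, collapse = "\n"), call. = FALSE)
  }
  out <- system2(exes[["blastn"]],
                 c("-query", shQuote(query_fasta), "-db", shQuote(db),
                   "-task", task, "-evalue", format(evalue),
                   "-num_threads", as.integer(threads), "-outfmt", "6"),
                 stdout = TRUE, stderr = FALSE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("blastn exited with status ", status, call. = FALSE)
  }
  parse_tabular(as.character(out))
}

#' Exact-match reference aligner
#'
#' Reports maximal exact matches of length at least `min_seed` between a
#' query and a subject sequence, on both strands, as 100%-identity hits in
#' the same coordinate conventions as [parse_tabular()].  This is an
#' independent, brute-force alignment route (seed with
#' [Biostrings::matchPDict()], then extend each seed hit to its maximal
#' exact stretch) used to cross-check BLAST-derived results on synthetic
#' data; it knows nothing about BLAST scoring.
#'
#' @param query one row of a query table, or a named character vector of
#'   length 1.
#' @param subject named character vector of length 1 (the contig).
#' @param min_seed minimum reported match length in bases (>= 12).
#' @return a hit table, ordered by subject position.
#' @export
oracle_align <- function(query, subject, min_seed = 12L) {
  min_seed <- as.integer(min_seed)
  stopifnot(min_seed >= 12L)
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    qid <- query$query_id
    qs <- toupper(query$sequence)
  } else {
    stopifnot(is.character(query), length(query) == 1L)
    qid <- if (is.null(names(query))) "query" else names(query)
    qs <- toupper(unname(query))
  }
  stopifnot(is.character(subject), length(subject) == 1L)
  sid <- if (is.null(names(subject))) "subject" else names(subject)
  ss <- toupper(unname(subject))
  if (!nzchar(qs) || !nzchar(ss)) return(new_hit_table())

  plus <- find_maximal_matches(qs, ss, min_seed)
  minus <- find_maximal_matches(revcomp(qs), ss, min_seed)
  qlen <- nchar(qs)

  rows <- list()
  if (nrow(plus)) {
    rows[[1L]] <- tibble(q_start = plus$q_start,
                         q_end = plus$q_start + plus$len - 1L,
                         s_start = plus$s_start,
                         s_end = plus$s_start + plus$len - 1L,
                         len = plus$len)
  }
  if (nrow(minus)) {
    # position i on the reverse complement maps to qlen - i + 1 on the query
    rows[[2L]] <- tibble(q_start = qlen - (minus$q_start + minus$len - 1L) + 1L,
                         q_end = qlen - minus$q_start + 1L,
                         s_start = minus$s_start + minus$len - 1L,
                         s_end = minus$s_start,
                         len = minus$len)
  }
  if (!length(rows)) return(new_hit_table())
  hits <- dplyr::bind_rows(rows)
  hits <- hits[order(pmin(hits$s_start, hits$s_end), hits$q_start), ,
               drop = FALSE]
  new_hit_table(
    query_id = rep(qid, nrow(hits)), subject_id = rep(sid, nrow(hits)),
    pct_identity = rep(100, nrow(hits)), aln_length = hits$len,
    mismatches = rep(0L, nrow(hits)), gap_opens = rep(0L, nrow(hits)),
    q_start = hits$q_start, q_end = hits$q_end,
    s_start = hits$s_start, s_end = hits$s_end,
    evalue = rep(0, nrow(hits)), bitscore = as.numeric(2L * hits$len)
  )
}

# All maximal exact matches of `q` in `s` with length >= min_len.
# Seeds of length floor(min_len/2) are tiled so that every match of
# length >= min_len contains at least one seed, located in a single
# matchPDict() pass, then extended to maximality and de-duplicated.
find_maximal_matches <- function(q, s, min_len) {
  qlen <- nchar(q)
  slen <- nchar(s)
  empty <- tibble(q_start = integer(), s_start = integer(), len = integer())
  if (qlen < min_len || slen < min_len) return(empty)
  seed_len <- max(4L, min_len %/% 2L)
  stride <- min_len - seed_len + 1L
  starts <- unique(c(seq.int(1L, qlen - seed_len + 1L, by = stride),
                     qlen - seed_len + 1L))
  seeds <- substring(q, starts, starts + seed_len - 1L)

  hit_q <- integer()
  hit_s <- integer()
  if (!any(grepl("[^ACGT]", seeds))) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(s))
    st <- Biostrings::startIndex(mi)
    for (k in seq_along(st)) {
      if (length(st[[k]])) {
        hit_q <- c(hit_q, rep(starts[k], length(st[[k]])))
        hit_s <- c(hit_s, st[[k]])
      }
    }
  } else {
    for (k in seq_along(seeds)) {
      g <- gregexpr(seeds[k], s, fixed = TRUE)[[1L]]
      if (g[1L] != -1L) {
        hit_q <- c(hit_q, rep(starts[k], length(g)))
        hit_s <- c(hit_s, as.integer(g))
      }
    }
  }
  if (!length(hit_q)) return(empty)

  # extend every seed hit to its maximal exact stretch, then de-duplicate:
  # seed hits inside the same maximal match land on the same diagonal and
  # extend to the same interval
  n <- length(hit_q)
  q0 <- integer(n); s0 <- integer(n); len <- integer(n)
  for (k in seq_len(n)) {
    a <- hit_q[k]; b <- hit_s[k]
    l <- lce_left(q, s, a - 1L, b - 1L)
    r <- lce_right(q, s, a + seed_len, b + seed_len)
    q0[k] <- a - l
    s0[k] <- b - l
    len[k] <- l + seed_len + r
  }
  out <- unique(tibble(q_start = q0, s_start = s0, len = len))
  out[out$len >= min_len, , drop = FALSE]
}

# Longest common extension rightwards: length of the longest common
# prefix of x[i..] and y[j..] (1-based; 0 if out of range).  Compares in
# 64-character blocks to stay fast in pure R.
lce_right <- function(x, y, i, j, block = 64L) {
  nx <- nchar(x); ny <- nchar(y)
  ext <- 0L
  while (i + ext <= nx && j + ext <= ny) {
    w <- min(block, nx - (i + ext) + 1L, ny - (j + ext) + 1L)
    bx <- substr(x, i + ext, i + ext + w - 1L)
    by <- substr(y, j + ext, j + ext + w - 1L)
    if (bx == by) {
      ext <- ext + w
    } else {
      cx <- strsplit(bx, "", fixed = TRUE)[[1L]]
      cy <- strsplit(by, "", fixed = TRUE)[[1L]]
      ext <- ext + (which.max(cx != cy) - 1L)
      break
    }
  }
  ext
}

# Longest common extension leftwards from x[i] / y[j] inclusive going down.
lce_left <- function(x, y, i, j, block = 64L) {
  ext <- 0L
  while (i - ext >= 1L && j - ext >= 1L) {
    w <- min(block, i - ext, j - ext)
    bx <- substr(x, i - ext - w + 1L, i - ext)
    by <- substr(y, j - ext - w + 1L, j - ext)
    if (bx == by) {
      ext <- ext + w
    } else {
      cx <- rev(strsplit(bx, "", fixed = TRUE)[[1L]])
      cy <- rev(strsplit(by, "", fixed = TRUE)[[1L]])
      ext <- ext + (which.max(cx != cy) - 1L)
      break
    }
  }
  ext
}
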