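#' One-sample t-test against a reference value
#'
#' Compares repeated measurements (e.g. the five Flongle flow-cell runs)
#' with a single reference value (the one MinION run):
#' `t = (mean - reference) / (sd / sqrt(n))` with the sample standard
#' deviation (n - 1 denominator) and a two-sided p-value from the t
#' distribution with `n - 1` degrees of freedom.
#'
#' @param values numeric vector, length >= 2, with positive variance.
#' @param reference the reference value.
#' @return object of class `one_sample_t`: `n`, `sample_mean`,
#'   `reference_value`, `sd`, `t`, `df`, `p_two_sided`.
#' @examples
#' one_sample_t(c(3.8, 2.8, 4.2, 1.0, 3.1), reference = 198.7)
#' @export
one_sample_t <- function(values, reference) {
  stopifnot(is.numeric(values), is.numeric(reference),
            length(reference) == 1L)
  if (length(values) < 2L) {
    stop("need at least 2 values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: values have no variance", call. = FALSE)
  }
  ht <- stats::t.test(values, mu = reference)
  structure(
    list(n = length(values),
         sample_mean = mean(values),
         reference_value = reference,
         sd = s,
         t = unname(ht$statistic),
         df = length(values) - 1L,
         p_two_sided = ht$p.value),
    class = "one_sample_t")
}

#' @export
print.one_sample_t <- function(x, ...) {
  cat(sprintf(paste0("One-sample t-test: t = %.3f, df = %d, p = %.3g\n",
                     "  sample mean = %.4g (n = %d, sd = %.4g), ",
                     "reference = %.4g\n"),
              x$t, x$df, x$p_two_sided, x$sample_mean, x$n, x$sd,
              x$reference_value))
  invisible(x)
}

#' Base-2 logarithm of positive values
#'
#' Used before testing read and base counts, whose raw values differ by an
#' order of magnitude between flow-cell formats.
#'
#' @param values positive numeric vector.
#' @return `log2(values)`.
#' @export
log2_values <- function(values) {
  stopifnot(is.numeric(values))
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be positive and finite for log2 transform",
         call. = FALSE)
  }
  log2(values)
}

#' Paired two-sample t-test
#'
#' A one-sample t-test of the paired differences `x - y` against zero,
#' two-sided.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return object of class `paired_t`: `n_pairs`, `mean_difference`, `t`,
#'   `df`, `p_two_sided`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal lengths", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("degenerate input: all paired differences are identical",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  structure(
    list(n_pairs = length(x),
         mean_difference = mean(d),
         t = unname(ht$statistic),
         df = length(x) - 1L,
         p_two_sided = ht$p.value),
    class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.3f, df = %d, p = %.3g, mean diff = %.4g\n",
              x$t, x$df, x$p_two_sided, x$mean_difference))
  invisible(x)
}

#' Two-way repeated-measures ANOVA
#'
#' Classic univariate within-subject decomposition: every subject is
#' observed at every combination of two within-subject factors, and each
#' effect is tested against its own subject-by-effect interaction stratum
#' (`aov` with `Error(subject/(factor_a * factor_b))`).  F statistics are
#' therefore invariant to adding a per-subject constant.
#'
#' @param data data frame with columns `subject`, `factor_a`, `factor_b`,
#'   `value`; the design must be complete and balanced with exactly one
#'   observation per subject and factor combination.
#' @return tibble with one row per effect (`factor_a`, `factor_b`,
#'   `factor_a:factor_b`): `F`, `df_num`, `df_den`, `p`.
#' @export
rm_anova <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("subject", "factor_a", "factor_b", "value") %in%
                  names(data)))
  d <- data.frame(subject = factor(data$subject),
                  factor_a = factor(data$factor_a),
                  factor_b = factor(data$factor_b),
                  value = as.numeric(data$value))
  counts <- table(d$subject, d$factor_a, d$factor_b)
  if (any(counts != 1L)) {
    stop("design must be complete and balanced: exactly one observation ",
         "per subject x factor_a x factor_b cell", call. = FALSE)
  }
  fit <- stats::aov(value ~ factor_a * factor_b +
                      Error(subject / (factor_a * factor_b)), data = d)
  s <- summary(fit)
  effects <- c("factor_a", "factor_b", "factor_a:factor_b")
  rows <- lapply(effects, function(eff) {
    stratum <- s[[paste0("Error: subject:", eff)]][[1L]]
    terms <- trimws(rownames(stratum))
    i <- match(eff, terms)
    j <- match("Residuals", terms)
    tibble(effect = eff,
           F = stratum[i, "F value"],
           df_num = stratum[i, "Df"],
           df_den = stratum[j, "Df"],
           p = stratum[i, "Pr(>F)"])
  })
  out <- dplyr::bind_rows(rows)
  if (any(!is.finite(out$F))) {
    warning("degenerate design: an error stratum has zero variance",
            call. = FALSE)
  }
  out
}

#' Throughput summary of a flow-cell run table
#'
#' Derived metrics comparing a group of Flongle (`FLG`) runs with the
#' single MinION (`MIN`) reference run of the same line: total Flongle
#' bases and reads, their percentage of the MinION output, the MinION
#' share of all bases/reads/input DNA, mean Flongle DNA input, per-pore
#' Flongle output, and the contribution of the two top-performing Flongle
#' runs.
#'
#' @param runs run table (see [read_run_table()]) holding exactly one
#'   `MIN` run and at least one `FLG` run for a single line.
#' @param flg_pores_total total number of starting pores across all
#'   Flongle flow-cells (circa 50 per flow-cell).
#' @return object of class `flowcell_summary` (a named list of metrics;
#'   `..._pct` entries are percentages, bases totals in bases, per-pore
#'   output in megabases).
#' @export
table1_summary <- function(runs, flg_pores_total = 250L) {
  stopifnot(is.data.frame(runs),
            all(c("flowcell", "input_fmoles", "read_count", "bases") %in%
                  names(runs)))
  if (length(unique(runs$line)) > 1L) {
    stop("run table holds more than one line; filter to a single line ",
         "first", call. = FALSE)
  }
  min_runs <- runs[runs$flowcell == "MIN", , drop = FALSE]
  flg <- runs[runs$flowcell == "FLG", , drop = FALSE]
  if (nrow(min_runs) != 1L) {
    stop("need exactly one MIN reference run, found ", nrow(min_runs),
         call. = FALSE)
  }
  if (nrow(flg) < 1L) stop("need at least one FLG run", call. = FALSE)

  min_bases <- min_runs$bases
  min_reads <- min_runs$read_count
  flg_bases <- sum(flg$bases)
  flg_reads <- sum(flg$read_count)
  top2 <- sum(sort(flg$bases, decreasing = TRUE)[seq_len(min(2L, nrow(flg)))])

  structure(list(
    n_flg_runs = nrow(flg),
    flg_total_bases = flg_bases,
    flg_total_reads = flg_reads,
    flg_pct_of_min_bases = 100 * flg_bases / min_bases,
    min_share_bases_pct = 100 * min_bases / (min_bases + flg_bases),
    flg_share_bases_pct = 100 * flg_bases / (min_bases + flg_bases),
    min_share_reads_pct = 100 * min_reads / (min_reads + flg_reads),
    flg_mean_input_fmoles = mean(flg$input_fmoles),
    min_input_pct_of_total = 100 * min_runs$input_fmoles /
      (min_runs$input_fmoles + sum(flg$input_fmoles)),
    flg_per_pore_mb = flg_bases / 1e6 / flg_pores_total,
    top2_flg_share_of_flg_pct = 100 * top2 / flg_bases,
    top2_flg_pct_of_min_bases = 100 * top2 / min_bases
  ), class = "flowcell_summary")
}

#' @export
print.flowcell_summary <- function(x, ...) {
  cat("Flow-cell throughput summary (", x$n_flg_runs, " FLG runs vs 1 MIN",
      " reference)\n", sep = "")
  cat(sprintf("  FLG total: %.3f Gb in %.3f M reads (%.2f%% of MIN bases)\n",
              x$flg_total_bases / 1e9, x$flg_total_reads / 1e6,
              x$flg_pct_of_min_bases))
  cat(sprintf("  MIN share: %.1f%% of bases, %.1f%% of reads, %.1f%% of input fmoles\n",
              x$min_share_bases_pct, x$min_share_reads_pct,
              x$min_input_pct_of_total))
  cat(sprintf("  FLG mean input: %.3f fmoles; per-pore output %.1f Mb\n",
              x$flg_mean_input_fmoles, x$flg_per_pore_mb))
  cat(sprintf("  Top two FLG runs: %.1f%% of FLG bases (%.2f%% of MIN bases)\n",
              x$top2_flg_share_of_flg_pct, x$top2_flg_pct_of_min_bases))
  invisible(x)
}
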