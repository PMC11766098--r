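# Independent statistical oracles, shared across test files.  These never
# call the package's own routines (nor t.test/aov): closed-form two-pass
# moments and an explicit sums-of-squares partition.

oracle_one_sample_t <- function(values, reference) {
  n <- length(values)
  m <- sum(values) / n
  s2 <- sum((values - m)^2) / (n - 1)
  t <- (m - reference) / sqrt(s2 / n)
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1), mean = m, sd = sqrt(s2))
}

# Explicit SS decomposition for the balanced two-way repeated-measures
# design; each effect is tested against its subject-by-effect interaction.
oracle_rm_anova <- function(d) {
  gm <- mean(d$value)
  cell <- function(...) tapply(d$value, list(...), mean)
  ns <- nlevels(d$subject); na <- nlevels(d$factor_a)
  nb <- nlevels(d$factor_b)
  m_s <- cell(d$subject); m_a <- cell(d$factor_a); m_b <- cell(d$factor_b)
  m_sa <- cell(d$subject, d$factor_a)
  m_sb <- cell(d$subject, d$factor_b)
  m_ab <- cell(d$factor_a, d$factor_b)
  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_s <- na * nb * sum((m_s - gm)^2)
  ss_sa <- nb * sum((m_sa -
                       matrix(m_s, ns, na) -
                       matrix(m_a, ns, na, byrow = TRUE) + gm)^2)
  ss_sb <- na * sum((m_sb -
                       matrix(m_s, ns, nb) -
                       matrix(m_b, ns, nb, byrow = TRUE) + gm)^2)
  ss_ab <- ns * sum((m_ab -
                       matrix(m_a, na, nb) -
                       matrix(m_b, na, nb, byrow = TRUE) + gm)^2)
  ss_tot <- sum((d$value - gm)^2)
  ss_sab <- ss_tot - ss_s - ss_a - ss_b - ss_sa - ss_sb - ss_ab
  c(
    factor_a = (ss_a / (na - 1)) / (ss_sa / ((ns - 1) * (na - 1))),
    factor_b = (ss_b / (nb - 1)) / (ss_sb / ((ns - 1) * (nb - 1))),
    `factor_a:factor_b` = (ss_ab / ((na - 1) * (nb - 1))) /
      (ss_sab / ((ns - 1) * (na - 1) * (nb - 1)))
  )
}

# Balanced within-subject design with optional planted main effects and
# random per-subject intercepts.
make_rm_design <- function(ns = 5, na = 2, nb = 3, seed = 1,
                           effect_a = 0, effect_b = 0, noise = 1) {
  set.seed(seed)
  d <- expand.grid(subject = factor(seq_len(ns)),
                   factor_a = factor(letters[seq_len(na)]),
                   factor_b = factor(LETTERS[seq_len(nb)]))
  d$value <- rnorm(nrow(d), sd = noise) +
    effect_a * as.integer(d$factor_a) +
    effect_b * as.integer(d$factor_b) +
    rnorm(ns, sd = 2)[as.integer(d$subject)]
  d
}
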