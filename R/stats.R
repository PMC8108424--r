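# Exact small-sample statistics and printed-table summaries.

#' Freeman-Halton (Fisher) exact test for an r x c table
#'
#' Enumerates every contingency table with the observed margins and sums
#' the multivariate hypergeometric probabilities of tables no more probable
#' than the observed one (probability ordering, relative tie tolerance
#' 1e-12). Exact enumeration is used up to `max_total` observations; larger
#' tables fall back to seeded Monte Carlo (`stats::r2dtable`) when
#' `monte_carlo = TRUE`, otherwise error.
#'
#' @param counts non-negative integer matrix (>= 2 rows and columns).
#' @param max_total enumeration cap on the table total.
#' @param monte_carlo allow the Monte Carlo fallback.
#' @param n_sim,mc_seed Monte Carlo replicates and seed.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(counts, max_total = 500L, monte_carlo = FALSE,
                         n_sim = 1e5, mc_seed = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stopf("need at least a 2 x 2 table")
  R <- rowSums(counts); C <- colSums(counts); N <- sum(counts)
  if (N == 0) stopf("table is empty")
  # a zero margin leaves a single feasible table (p = 1); enumeration
  # handles it without special-casing
  log_p <- function(tab)
    sum(lgamma(R + 1)) + sum(lgamma(C + 1)) - lgamma(N + 1) -
      sum(lgamma(tab + 1))
  lp_obs <- log_p(counts)
  if (N > max_total) {
    if (!monte_carlo)
      stopf("table total %d exceeds enumeration cap %d; set monte_carlo = TRUE",
            N, max_total)
    sims <- with_seed(mc_seed, stats::r2dtable(n_sim, R, C))
    return(mean(vapply(sims, log_p, numeric(1)) <= lp_obs + 1e-12))
  }
  total <- 0
  recurse <- function(row, col_rem, acc) {
    if (row == length(R)) {
      tab <- rbind(acc, col_rem)
      if (all(col_rem >= 0)) {
        lp <- log_p(tab)
        if (lp <= lp_obs + 1e-12) total <<- total + exp(lp)
      }
      return(invisible())
    }
    # enumerate feasible rows for `row` given remaining column margins
    cells <- vector("list", length(C))
    enum_row <- function(j, rem, part) {
      if (j == length(C)) {
        if (rem <= col_rem[j]) recurse(row + 1L, col_rem - c(part, rem),
                                       rbind(acc, c(part, rem)))
        return(invisible())
      }
      for (v in 0:min(rem, col_rem[j])) enum_row(j + 1L, rem - v, c(part, v))
    }
    enum_row(1L, R[row], integer(0))
  }
  recurse(1L, C, NULL)
  min(1, total)
}

#' Two-tailed exact binomial test (doubled smaller tail)
#'
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))` under Binomial(n, p0). This
#' doubled-tail definition gives 2 * 0.5^6 = 0.03125 for 6/6 at p0 = 0.5.
#'
#' @param k successes.
#' @param n trials.
#' @param p0 null success probability.
#' @return p-value.
#' @export
binomial_two_tailed <- function(k, n, p0 = 0.5) {
  if (k < 0 || k > n) stopf("need 0 <= k <= n")
  lower <- stats::pbinom(k, n, p0)
  upper <- 1 - stats::pbinom(k - 1, n, p0)
  min(1, 2 * min(lower, upper))
}

#' Paired t summary of pre/post scores
#'
#' Improvement is `pre - post` (lower clinical score = better), so positive
#' means improved. Pairs with a missing value are excluded. The 95% CI uses
#' t quantiles with df = n - 1.
#'
#' @param pre,post numeric score vectors of equal length.
#' @return list: `n`, `mean_diff`, `sd_diff`, `t`, `df`, `ci_low`, `ci_high`,
#'   `p`.
#' @export
paired_t_summary <- function(pre, post) {
  if (length(pre) != length(post)) stopf("pre/post lengths differ")
  ok <- !is.na(pre) & !is.na(post)
  d <- pre[ok] - post[ok]
  n <- length(d)
  if (n < 2L) stopf("need >= 2 complete pairs")
  m <- mean(d); s <- stats::sd(d)
  tval <- m / (s / sqrt(n))
  q <- stats::qt(0.975, n - 1)
  list(n = n, mean_diff = m, sd_diff = s, t = tval, df = n - 1L,
       ci_low = m - q * s / sqrt(n), ci_high = m + q * s / sqrt(n),
       p = 2 * stats::pt(-abs(tval), n - 1))
}

#' Percent-change summary of pre/post scores
#'
#' Per-pair `100 * (pre - post) / pre`; mean and SD over complete pairs.
#' Errors if any pre score is zero or negative.
#'
#' @param pre,post numeric score vectors of equal length.
#' @return list: `n`, `mean_pct`, `sd_pct`, `pct` (per-pair values).
#' @export
percent_change_summary <- function(pre, post) {
  if (length(pre) != length(post)) stopf("pre/post lengths differ")
  ok <- !is.na(pre) & !is.na(post)
  pre <- pre[ok]; post <- post[ok]
  if (any(pre <= 0)) stopf("pre scores must be positive")
  pc <- 100 * (pre - post) / pre
  list(n = length(pc), mean_pct = mean(pc), sd_pct = stats::sd(pc), pct = pc)
}

# ---- packaged fixture tables -------------------------------------------

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "ppdbs")
  if (p == "") p <- file.path("inst", "extdata", name)  # devtools::load_all
  if (!file.exists(p)) stopf("fixture %s not found", name)
  p
}

#' Load the packaged per-trajectory clinical scores table
#'
#' Intraoperative pre vs. macrostimulation upper-extremity subscores
#' (UPDRS part 3 for PD, Fahn-Tolosa-Marin for ET) per recording
#' trajectory, with the experimental stimulation settings.
#'
#' @return data.frame; missing scores are `NA`.
#' @export
load_clinical_scores <- function() {
  utils::read.csv(fixture_path("clinical_scores.csv"),
                  stringsAsFactors = FALSE)
}

#' Load the packaged per-trajectory evoked-response feature table
#'
#' R1 peak/trough latencies and amplitudes, absolute/relative refractory
#' periods, and ERNA peak amplitude/latency per analyzed trajectory.
#' Cells printed as "Absent" (component not present) or "NA" (not
#' measurable) are both `NA` in the numeric columns; ERNA presence is kept
#' in the logical `erna_present` column.
#'
#' @return data.frame.
#' @export
load_evoked_features <- function() {
  df <- utils::read.csv(fixture_path("evoked_features.csv"),
                        stringsAsFactors = FALSE, na.strings = c("NA", "Absent"))
  df$erna_present <- !is.na(df$erna_amp_mv)
  df
}

#' Load the packaged STN contact-concordance table
#'
#' For the non-directional STN participants: the stimulated contact pair,
#' whether ERNA was present intraoperatively, and the cathode later chosen
#' for chronic therapy by clinicians blinded to the electrophysiology.
#'
#' @return data.frame.
#' @export
load_contact_concordance <- function() {
  utils::read.csv(fixture_path("stn_contact_concordance.csv"),
                  stringsAsFactors = FALSE)
}

#' ERNA presence contingency table by stimulation target
#'
#' Cross-tabulates ERNA presence/absence against target (STN, GPi, VIM)
#' from the evoked-feature table.
#'
#' @param evoked result of [load_evoked_features()].
#' @return integer matrix, targets x c(present, absent).
#' @export
erna_presence_counts <- function(evoked = load_evoked_features()) {
  targets <- c("STN", "GPi", "VIM")
  m <- t(vapply(targets, function(tg) {
    p <- evoked$erna_present[evoked$target == tg]
    c(present = sum(p), absent = sum(!p))
  }, integer(2)))
  m
}

#' Contact concordance counts
#'
#' A participant is concordant when ERNA presence predicts chronic contact
#' choice: ERNA present and the chronic cathode lies within the
#' intraoperative stimulation pair, or ERNA absent and the cathode lies
#' outside it.
#'
#' @param tbl result of [load_contact_concordance()].
#' @return list `k` (concordant), `n` (scored participants).
#' @export
concordance_counts <- function(tbl = load_contact_concordance()) {
  in_pair <- mapply(function(pair, cathode) {
    contacts <- strsplit(pair, "-", fixed = TRUE)[[1]]
    !is.na(cathode) && as.character(cathode) %in% contacts
  }, tbl$stim_channels, tbl$final_cathode)
  conc <- ifelse(tbl$erna_present == "Yes", in_pair, !in_pair)
  list(k = sum(conc), n = length(conc))
}

#' Column means and SDs of the evoked-feature table
#'
#' Per-column mean and SD over non-missing per-trajectory values,
#' reproducing the table's printed summary rows. Columns with a single
#' value get `NA` SD.
#'
#' @param evoked result of [load_evoked_features()] (or a compatible
#'   data.frame).
#' @param columns numeric columns to summarize (default: all feature
#'   columns).
#' @return data.frame with `column`, `n`, `mean`, `sd`.
#' @export
evoked_feature_summaries <- function(evoked = load_evoked_features(),
                                     columns = NULL) {
  if (is.null(columns))
    columns <- c("r1_peak_amp_mv", "r1_peak_lat_ms", "r1_trough_amp_mv",
                 "r1_trough_lat_ms", "arp_ms", "rrp_ms", "erna_amp_mv",
                 "erna_lat_ms")
  miss <- setdiff(columns, names(evoked))
  if (length(miss)) stopf("column absent: %s", paste(miss, collapse = ", "))
  out <- lapply(columns, function(cl) {
    v <- evoked[[cl]]; v <- v[!is.na(v)]
    data.frame(column = cl, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  })
  do.call(rbind, out)
}

#' Reproduce the printed-table statistics
#'
#' Recomputes, from the packaged fixture tables, the study-level summary
#' statistics: the Freeman-Halton exact test on ERNA presence by target,
#' the two-tailed binomial test on contact concordance, paired t summaries
#' of the PD and ET clinical subscores, the pooled percent-change summary,
#' and the evoked-feature column means.
#'
#' @return nested list of results.
#' @export
printed_stats <- function() {
  clin <- load_clinical_scores()
  evoked <- load_evoked_features()
  pd <- clin[clin$target %in% c("STN", "GPi"), ]
  et <- clin[clin$target == "VIM", ]
  conc <- concordance_counts()
  list(
    fisher_erna_by_target = list(
      counts = erna_presence_counts(evoked),
      p = fisher_exact(erna_presence_counts(evoked))),
    binomial_concordance = list(
      k = conc$k, n = conc$n,
      p = binomial_two_tailed(conc$k, conc$n, 0.5)),
    paired_t_pd = paired_t_summary(pd$pre, pd$macro_stim),
    paired_t_et = paired_t_summary(et$pre, et$macro_stim),
    percent_change = percent_change_summary(clin$pre, clin$macro_stim),
    evoked_summaries = evoked_feature_summaries(evoked))
}
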