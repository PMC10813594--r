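#' CSF stroke-volume ratio
#'
#' The ratio of aqueductal to cervical stroke volume,
#' `sv_aqu * 100 / sv_cerv` (percent): the contribution of
#' intraventricular CSF pulsatility to overall craniospinal CSF
#' pulsatility. Around 10% in healthy adults, 40-50% in normal-pressure
#' hydrocephalus.
#'
#' @param sv_aqu,sv_cerv Stroke volumes, uL per cardiac cycle
#'   (vectorized); `sv_cerv` must be positive.
#' @return Ratio in percent.
#' @export
csf_ratio <- function(sv_aqu, sv_cerv) {
  if (any(sv_cerv <= 0)) stop("sv_cerv must be positive")
  sv_aqu * 100 / sv_cerv
}

#' Percent change between two measurements
#'
#' @param before Baseline value (> 0).
#' @param after Follow-up value.
#' @return `(after - before) * 100 / before`; negative means a decrease.
#' @export
percent_change <- function(before, after) {
  if (any(before <= 0)) stop("baseline value must be positive")
  (after - before) * 100 / before
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on the paired differences `x - y`. Zero
#' differences are dropped (and counted); tied absolute differences get
#' mid-ranks. For `n <= exact_max_n` pairs the null distribution of the
#' positive-rank sum W is computed exactly over all `2^n` equally likely
#' sign assignments (via its generating function), so the p-value is
#' exact even with ties; beyond that a normal approximation with the
#' tie-robust variance `sum(r^2)/4` is used and flagged. The two-sided
#' p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y Equal-length numeric vectors of paired measurements.
#' @param exact_max_n Largest n for exact enumeration (default 20).
#' @return An object of class `paired_test_result`: `test`, `n_pairs`,
#'   `n_used`, `zeros_dropped`, `statistic` (W), `p_value`, `exact`,
#'   `normality_p` (`NA` here).
#' @export
wilcoxon_signed_rank_exact <- function(x, y, exact_max_n = 20L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (any(!is.finite(d))) stop("non-finite paired differences")
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero; the test is undefined")
  if (n < 2) stop("need at least 2 nonzero paired differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    dist <- signed_rank_distribution(r)
    # distribution over doubled rank sums (integers); observed doubled W
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist$prob[dist$sum2 <= w2])
    p_ge <- sum(dist$prob[dist$sum2 >= w2])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
    test <- "wilcoxon_signed_rank_exact"
  } else {
    e <- sum(r) / 2
    v <- sum(r^2) / 4
    z <- (w - e) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
    test <- "wilcoxon_signed_rank_normal_approx"
  }
  structure(list(test = test, n_pairs = length(x), n_used = n,
                 zeros_dropped = zeros, statistic = w, p_value = p,
                 exact = exact, normality_p = NA_real_),
            class = "paired_test_result")
}

# Exact null distribution of the positive-rank sum for ranks r (mid-ranks
# allowed). Works on doubled ranks so all sums are integers; returns the
# achievable doubled sums and their probabilities under random signs.
signed_rank_distribution <- function(r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[s+1] = number of sign assignments with sum s
  f[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
    f <- f + shifted
  }
  list(sum2 = 0:total, prob = f / sum(f))
}

#' Paired Student's t-test with a normality check
#'
#' Classical two-sided paired t-test on `x - y` (n - 1 degrees of
#' freedom), accompanied by a Shapiro-Wilk test of normality of the
#' differences. Non-normality (p < 0.05) produces a warning and is
#' reported in the result, not a refusal: the decision is left to the
#' analyst, with the signed-rank test as the distribution-free companion.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, with non-degenerate
#'   differences.
#' @return A `paired_test_result` with `normality_p` filled in.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("paired t-test needs at least 3 pairs")
  d <- x - y
  if (stats::var(d) == 0)
    stop("paired differences have zero variance; the t statistic is undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  sw <- stats::shapiro.test(d)
  if (sw$p.value < 0.05)
    warning(sprintf(paste0("paired differences look non-normal ",
                           "(Shapiro-Wilk p = %.3g); prefer the signed-rank ",
                           "test"), sw$p.value))
  structure(list(test = "paired_t", n_pairs = length(x), n_used = length(x),
                 zeros_dropped = 0L, statistic = unname(tt$statistic),
                 p_value = tt$p.value, exact = FALSE,
                 normality_p = sw$p.value),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("%s: n = %d (%d zero diffs dropped), statistic = %.4g, p = %.4g\n",
              x$test, x$n_used, x$zeros_dropped, x$statistic, x$p_value))
  if (!is.na(x$normality_p))
    cat(sprintf("  Shapiro-Wilk normality of differences: p = %.4g\n",
                x$normality_p))
  invisible(x)
}

#' Summarize a longitudinal stroke-volume cohort
#'
#' From a long per-patient table of aqueductal and cervical stroke
#' volumes at up to three timepoints, computes: the per-patient CSF
#' ratio; mean and sample SD (n - 1) of each measure at each timepoint;
#' all three pairwise comparisons (T1-T2, T2-T3, T1-T3) with both the
#' exact signed-rank and the paired t test on complete pairs; and
#' per-patient percent changes aggregated as mean, SD, min, max. The
#' ratio is averaged across patients (the mean of per-patient ratios,
#' not the ratio of means). No multiplicity correction is applied by
#' default, matching uncorrected pairwise reporting; Holm adjustment is
#' available.
#'
#' @param table Data frame with columns `patient_id`, `timepoint`
#'   (`"T1"`, `"T2"`, `"T3"`), `sv_aqu_ul`, `sv_cerv_ul` (e.g. from
#'   [generate_cohort()]).
#' @param holm Apply Holm adjustment across the pairwise p-values of each
#'   test family.
#' @return An object of class `cohort_table`: `summary` (measure x
#'   timepoint means/SDs/n), `tests` (pairwise results; `p_value` is `NA`
#'   with a `note` when a comparison is unavailable), `percent_change`
#'   (per-pair aggregates), `patients` (the wide per-patient table).
#' @export
summarize_cohort <- function(table, holm = FALSE) {
  required <- c("patient_id", "timepoint", "sv_aqu_ul", "sv_cerv_ul")
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(table$sv_aqu_ul <= 0) || any(table$sv_cerv_ul <= 0))
    stop("stroke volumes must be positive")
  table$csf_ratio <- csf_ratio(table$sv_aqu_ul, table$sv_cerv_ul)

  measures <- c(sv_aqu = "sv_aqu_ul", sv_cerv = "sv_cerv_ul",
                csf_ratio = "csf_ratio")
  tps <- c("T1", "T2", "T3")
  pats <- unique(table$patient_id)
  wide <- lapply(measures, function(col) {
    cols <- lapply(tps, function(tp) {
      sub <- table[table$timepoint == tp, ]
      sub[[col]][match(pats, sub$patient_id)]
    })
    matrix(unlist(cols), nrow = length(pats),
           dimnames = list(pats, tps))
  })

  summary_df <- do.call(rbind, lapply(names(measures), function(m) {
    do.call(rbind, lapply(tps, function(tp) {
      v <- wide[[m]][, tp]
      v <- v[!is.na(v)]
      data.frame(measure = m, timepoint = tp, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else
                   if (length(v) == 1) NA_real_ else NA_real_)
    }))
  }))
  # a degenerate single-valued cohort column still has sd 0 when n > 1
  rownames(summary_df) <- NULL

  pairs <- list(c("T1", "T2"), c("T2", "T3"), c("T1", "T3"))
  run_test <- function(fun, xa, xb) {
    tryCatch({
      res <- suppressWarnings(fun(xa, xb))
      data.frame(p_value = res$p_value, statistic = res$statistic,
                 n_used = res$n_used, note = "")
    }, error = function(e) {
      data.frame(p_value = NA_real_, statistic = NA_real_, n_used = NA_integer_,
                 note = paste("unavailable:", conditionMessage(e)))
    })
  }
  tests_df <- do.call(rbind, lapply(names(measures), function(m) {
    do.call(rbind, lapply(pairs, function(pr) {
      a <- wide[[m]][, pr[1]]; b <- wide[[m]][, pr[2]]
      ok <- !is.na(a) & !is.na(b)
      base <- data.frame(measure = m, comparison = paste(pr, collapse = "-"),
                         n_pairs = sum(ok))
      if (sum(ok) < 2) {
        return(cbind(base,
                     data.frame(test = c("wilcoxon_signed_rank_exact", "paired_t"),
                                p_value = NA_real_, statistic = NA_real_,
                                n_used = NA_integer_,
                                note = "unavailable: fewer than 2 complete pairs")))
      }
      rbind(cbind(base, test = "wilcoxon_signed_rank_exact",
                  run_test(wilcoxon_signed_rank_exact, a[ok], b[ok])),
            cbind(base, test = "paired_t", run_test(paired_t, a[ok], b[ok])))
    }))
  }))
  rownames(tests_df) <- NULL
  if (holm) {
    for (tst in unique(tests_df$test)) {
      sel <- tests_df$test == tst & !is.na(tests_df$p_value)
      tests_df$p_adjusted[sel] <- stats::p.adjust(tests_df$p_value[sel],
                                                  method = "holm")
    }
  }

  pc_df <- do.call(rbind, lapply(names(measures), function(m) {
    do.call(rbind, lapply(pairs, function(pr) {
      a <- wide[[m]][, pr[1]]; b <- wide[[m]][, pr[2]]
      ok <- !is.na(a) & !is.na(b) & a > 0
      pc <- if (any(ok)) percent_change(a[ok], b[ok]) else numeric(0)
      data.frame(measure = m, comparison = paste(pr, collapse = "-"),
                 n = length(pc),
                 mean = if (length(pc)) mean(pc) else NA_real_,
                 sd = if (length(pc) > 1) stats::sd(pc) else NA_real_,
                 min = if (length(pc)) min(pc) else NA_real_,
                 max = if (length(pc)) max(pc) else NA_real_)
    }))
  }))
  rownames(pc_df) <- NULL

  structure(list(summary = summary_df, tests = tests_df,
                 percent_change = pc_df, patients = wide),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort summary (mean +/- SD):\n")
  s <- x$summary
  for (m in unique(s$measure)) {
    row <- s[s$measure == m, ]
    cat(sprintf("  %-10s %s\n", m,
                paste(sprintf("%s: %.1f +/- %.1f", row$timepoint, row$mean,
                              row$sd), collapse = "  ")))
  }
  cat("Pairwise tests (two-sided p):\n")
  t <- x$tests
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-10s %-6s %-28s p = %s%s\n", t$measure[i], t$comparison[i],
                t$test[i],
                ifelse(is.na(t$p_value[i]), "NA", sprintf("%.4g", t$p_value[i])),
                ifelse(nzchar(t$note[i]), paste0("  [", t$note[i], "]"), "")))
  invisible(x)
}
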