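test_that("csf_ratio computes the aqueductal share in percent and validates input", {
  expect_equal(csf_ratio(500, 500), 100)
  expect_equal(csf_ratio(50, 500), 10)
  expect_equal(csf_ratio(240, 627), 240 * 100 / 627)
  expect_equal(csf_ratio(240, 627), 38.28, tolerance = 1e-3)
  expect_error(csf_ratio(100, 0), "positive")
  # scale invariance on randomized inputs
  set.seed(14)
  a <- runif(50, 10, 500); c <- runif(50, 100, 1000); k <- runif(50, 0.01, 100)
  expect_equal(csf_ratio(k * a, k * c), csf_ratio(a, c), tolerance = 1e-12)
})

test_that("percent_change is signed, zero at identity, and validates baseline", {
  expect_equal(percent_change(240, 240), 0)
  expect_equal(percent_change(240, 214), -10.8333, tolerance = 1e-4)
  expect_equal(percent_change(100, 126.14), 26.14, tolerance = 1e-10)
  expect_error(percent_change(0, 10), "positive")
})

test_that("exact signed-rank p matches hand enumeration for small n", {
  # n = 3, all differences positive and distinct: W = 6, 2/8 sign patterns
  # are as extreme in either tail, two-sided p = 0.25
  r <- wilcoxon_signed_rank_exact(c(5, 6, 7), c(1, 2, 3))
  expect_equal(r$p_value, 0.25)
  expect_equal(r$statistic, 6)
  expect_true(r$exact)
  expect_error(wilcoxon_signed_rank_exact(1:5, 1:5), "zero")
})

test_that("exact signed-rank p equals brute-force enumeration over 2^n signs", {
  set.seed(31)
  cases <- list(
    rnorm(8), rnorm(12), rnorm(14) + 0.8,
    round(rnorm(14), 0),                 # heavy ties, some zeros
    c(rep(0.5, 4), -rep(0.25, 3), rnorm(7)),  # tied magnitudes
    rnorm(14) * 100
  )
  for (d in cases) {
    x <- d; y <- rep(0, length(d))
    if (all(d == 0)) next
    r <- wilcoxon_signed_rank_exact(x, y)
    expect_equal(r$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
    expect_equal(r$n_used, sum(d != 0))
    expect_equal(r$zeros_dropped, sum(d == 0))
  }
  # agreement with stats::wilcox.test in its exact, tie-free regime
  set.seed(32)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_signed_rank_exact(x, y)$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("signed-rank p depends only on signed ranks and is symmetric in x, y", {
  set.seed(33)
  x <- rnorm(12); y <- rnorm(12)
  p0 <- wilcoxon_signed_rank_exact(x, y)$p_value
  # strictly monotone transform of the magnitudes, signs preserved
  d <- x - y
  d2 <- sign(d) * (exp(abs(d)) - 0.5)
  expect_equal(wilcoxon_signed_rank_exact(d2, rep(0, 12))$p_value, p0,
               tolerance = 1e-12)
  expect_equal(wilcoxon_signed_rank_exact(y, x)$p_value, p0, tolerance = 1e-12)
})

test_that("large-sample signed-rank falls back to a flagged normal approximation", {
  set.seed(34)
  x <- rnorm(30) + 0.5; y <- rnorm(30)
  r <- wilcoxon_signed_rank_exact(x, y)
  expect_false(r$exact)
  expect_match(r$test, "approx")
  expect_equal(r$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                  correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("paired t matches the textbook formula and reports normality", {
  set.seed(35)
  x <- rnorm(14) + 1; y <- rnorm(14)
  r <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), df = length(d) - 1)
  expect_equal(r$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r$p_value, p_hand, tolerance = 1e-10)
  expect_equal(r$normality_p, shapiro.test(d)$p.value, tolerance = 1e-12)
  # symmetric +/- pairs give t = 0, p = 1
  xs <- c(1, 2, 3, 4); ys <- c(2, 1, 4, 3)
  rs <- suppressWarnings(paired_t(xs, ys))
  expect_equal(rs$statistic, 0, tolerance = 1e-12)
  expect_equal(rs$p_value, 1, tolerance = 1e-12)
  expect_error(paired_t(1:5, 1:5), "zero variance")
  # non-normal differences warn rather than refuse
  xnn <- c(rnorm(13), 60); ynn <- rep(0, 14)
  expect_warning(paired_t(xnn, ynn), "non-normal")
})

test_that("cohort summary reproduces generator means and runs all pairwise tests", {
  tab <- generate_cohort(cohort_spec(seed = 4))
  ct <- summarize_cohort(tab)
  s <- ct$summary
  expect_equal(nrow(s), 9)  # 3 measures x 3 timepoints
  for (tp in c("T1", "T2", "T3")) {
    sub <- tab[tab$timepoint == tp, ]
    expect_equal(s$mean[s$measure == "sv_aqu" & s$timepoint == tp],
                 mean(sub$sv_aqu_ul))
    expect_equal(s$sd[s$measure == "sv_cerv" & s$timepoint == tp],
                 sd(sub$sv_cerv_ul))
    # ratio is the mean of per-patient ratios, not the ratio of means
    expect_equal(s$mean[s$measure == "csf_ratio" & s$timepoint == tp],
                 mean(csf_ratio(sub$sv_aqu_ul, sub$sv_cerv_ul)))
  }
  expect_equal(nrow(ct$tests), 18)  # 3 measures x 3 comparisons x 2 tests
  expect_true(all(ct$tests$p_value >= 0 & ct$tests$p_value <= 1, na.rm = TRUE))
  pc <- ct$percent_change
  expect_true(all(pc$min <= pc$mean & pc$mean <= pc$max))
})

test_that("degenerate and tiny cohorts mark comparisons unavailable", {
  # fully degenerate: SD = 0 and identical means, so every paired
  # difference is zero and both tests are undefined
  spfix <- cohort_spec(n_patients = 5, sv_aqu_mean = c(240, 240, 240),
                       sv_aqu_sd = c(0, 0, 0), sv_cerv_mean = c(627, 627, 627),
                       sv_cerv_sd = c(0, 0, 0), correlation = 0,
                       nonresponder_fraction = 0)
  ctf <- summarize_cohort(generate_cohort(spfix))
  expect_true(all(is.na(ctf$tests$p_value)))
  expect_true(all(grepl("unavailable", ctf$tests$note)))
  # SD = 0 with the default (distinct) means: every patient sits exactly at
  # the mean; the t-test is undefined (zero difference variance) while the
  # signed-rank test sees n identical positive differences
  sp <- cohort_spec(n_patients = 5, sv_aqu_sd = c(0, 0, 0),
                    sv_cerv_sd = c(0, 0, 0), correlation = 0,
                    nonresponder_fraction = 0)
  ct <- summarize_cohort(generate_cohort(sp))
  expect_equal(ct$summary$mean[ct$summary$measure == "sv_aqu"], c(240, 214, 193))
  expect_equal(ct$summary$sd[ct$summary$measure == "sv_aqu"], c(0, 0, 0))
  tt <- ct$tests
  expect_true(all(is.na(tt$p_value[tt$test == "paired_t"])))
  expect_true(all(grepl("unavailable", tt$note[tt$test == "paired_t"])))
  # all-positive tied differences, n = 5: two-sided p = 2 / 2^5
  expect_equal(tt$p_value[tt$test == "wilcoxon_signed_rank_exact" &
                            tt$measure == "sv_aqu"], rep(0.0625, 3))
  # single patient: no pairs to test
  one <- generate_cohort(cohort_spec(n_patients = 1, nonresponder_fraction = 0))
  ct1 <- summarize_cohort(one)
  expect_true(all(is.na(ct1$tests$p_value)))
  expect_true(all(ct1$tests$n_pairs <= 1))
})

test_that("percent-change aggregation follows the per-patient-first convention", {
  tab <- data.frame(patient_id = rep(c("a", "b"), each = 3),
                    timepoint = rep(c("T1", "T2", "T3"), 2),
                    sv_aqu_ul = c(200, 150, 100, 400, 440, 360),
                    sv_cerv_ul = c(600, 500, 400, 800, 900, 700))
  ct <- summarize_cohort(tab)
  pc <- ct$percent_change
  row <- pc[pc$measure == "sv_aqu" & pc$comparison == "T1-T2", ]
  expect_equal(row$mean, mean(c(-25, 10)))
  expect_equal(row$min, -25)
  expect_equal(row$max, 10)
})
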