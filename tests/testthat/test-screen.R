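# Screening statistics.

test_that("Welch one-way test matches the base-R oracle exactly", {
  set.seed(101)
  for (rep in 1:5) {
    k <- sample(2:5, 1)
    g <- rep(seq_len(k), times = sample(5:12, k, replace = TRUE))
    x <- rnorm(length(g), mean = g * runif(1, 0, 2),
               sd = runif(1, 0.5, 3))
    ours <- welch_anova(x, g)
    ref <- oneway.test(x ~ factor(g), var.equal = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df2, unname(ref$parameter[2]), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("two-group Welch F equals the squared Welch t statistic", {
  set.seed(102)
  x <- c(rnorm(8, 0, 1), rnorm(14, 1, 3))
  g <- rep(c("a", "b"), c(8, 14))
  ours <- welch_anova(x, g)
  tt <- t.test(x[g == "a"], x[g == "b"])
  expect_equal(ours$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ours$df2, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(ours$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("Welch test rejects degenerate groupings", {
  expect_error(welch_anova(1:10, rep(1, 10)), "at least 2")
  expect_error(welch_anova(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
  expect_error(welch_anova(rep(1, 8), rep(c("a", "b"), 4)), "variance")
})

test_that("Welch type-I error is close to nominal under the null", {
  set.seed(103)
  nrep <- 3000
  p <- vapply(seq_len(nrep), function(i)
    welch_anova(rnorm(30), rep(1:3, each = 10))$p.value, numeric(1))
  rej <- mean(p < 0.05)
  # binomial MC error at 3000 reps ~ 0.004
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("compact letters reproduce the canonical patterns", {
  gs <- c("g1", "g2", "g3")
  means <- c(g1 = 1, g2 = 2, g3 = 3)
  pm <- function(p12, p13, p23) {
    m <- diag(3); m[lower.tri(m)] <- c(p12, p13, p23)
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    dimnames(m) <- list(gs, gs); m
  }
  # all pairs differ -> a, b, c
  expect_identical(unname(letter_groups(pm(.001, .001, .001), means)),
                   c("a", "b", "c"))
  # nothing differs -> all share a
  expect_identical(unname(letter_groups(pm(.9, .9, .9), means)),
                   c("a", "a", "a"))
  # only the extremes differ -> a, ab, b
  expect_identical(unname(letter_groups(pm(.5, .01, .5), means)),
                   c("a", "ab", "b"))
  # letters ordered by mean: lowest mean always gets 'a'
  means_rev <- c(g1 = 3, g2 = 2, g3 = 1)
  expect_identical(unname(letter_groups(pm(.001, .001, .001), means_rev)),
                   c("c", "b", "a"))
})

test_that("letters are consistent with the p-matrix by brute force", {
  # over random 3-group p-matrices: same letter <=> p >= alpha is respected
  set.seed(104)
  gs <- c("x", "y", "z")
  for (rep in 1:25) {
    p <- matrix(1, 3, 3, dimnames = list(gs, gs))
    v <- runif(3)
    p[lower.tri(p)] <- v; p[upper.tri(p)] <- t(p)[upper.tri(p)]
    lt <- letter_groups(p, c(x = 1, y = 2, z = 3), alpha = 0.3)
    share <- function(i, j)
      any(strsplit(lt[i], "")[[1]] %in% strsplit(lt[j], "")[[1]])
    for (i in 1:2) for (j in (i + 1):3) {
      if (p[i, j] < 0.3) expect_false(share(i, j))
      else expect_true(share(i, j))
    }
  }
})

test_that("Bonferroni adjustment caps at one and honors the family size", {
  expect_equal(bonferroni(7.0e-7, m = 6), 4.2e-6)
  expect_identical(significance_stars(bonferroni(7.0e-7, m = 6)), "***")
  expect_identical(bonferroni(0.5, m = 6), 1)
  expect_identical(bonferroni(c(0.01, 0.2)), c(0.02, 0.4))  # m = length
  expect_identical(bonferroni(0.03, m = 1), 0.03)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
  # never decreases a p-value; agrees with p.adjust when m = length(p)
  set.seed(105)
  p <- runif(10)
  expect_true(all(bonferroni(p) >= p))
  expect_equal(bonferroni(p), p.adjust(p, "bonferroni"))
  expect_identical(significance_stars(c(5e-4, 5e-3, 0.04, 0.2)),
                   c("***", "**", "*", ""))
})

test_that("distribution summary uses the stated moment conventions", {
  x <- rep(c(-1, 0, 1), 20)
  ds <- distribution_summary(x)
  expect_equal(ds$skewness, 0, tolerance = 1e-12)
  expect_equal(ds$median, 0)
  # hand-computed moments on a fixed vector
  y <- c(1, 2, 2, 3, 10)
  dsy <- distribution_summary(y)
  m <- mean(y); m2 <- mean((y - m)^2)
  expect_equal(dsy$skewness, mean((y - m)^3) / m2^1.5, tolerance = 1e-12)
  expect_equal(dsy$kurtosis_excess, mean((y - m)^4) / m2^2 - 3,
               tolerance = 1e-12)
  expect_equal(dsy$shapiro_p, shapiro.test(y)$p.value, tolerance = 1e-12)
  expect_error(distribution_summary(c(1, 2)), "n >= 3")
  expect_true(distribution_summary(rep(1, 5))$degenerate)
})

test_that("excess kurtosis is near zero for normal samples of n = 116", {
  set.seed(106)
  g2 <- vapply(1:400, function(i)
    distribution_summary(rnorm(116))$kurtosis_excess, numeric(1))
  # E[g2] = -6/(n+1) = -0.051 at n = 116; allow 3 MC standard errors
  se <- sd(g2) / sqrt(length(g2))
  expect_lt(abs(mean(g2) + 6 / 117), 3 * se)
})

test_that("OLS bootstrap reproduces closed-form slope inference", {
  set.seed(107)
  x <- runif(29, 1, 50); y <- 2 + 0.8 * x + rnorm(29, 0, 6)
  b <- ols_bootstrap(x, y, seed = 9)
  ref <- summary(lm(y ~ x))
  expect_equal(b$slope, unname(coef(ref)[2, 1]), tolerance = 1e-12)
  expect_equal(b$intercept, unname(coef(ref)[2 - 1, 1]), tolerance = 1e-12)
  expect_equal(b$r_squared, ref$r.squared, tolerance = 1e-12)
  expect_equal(b$p_value, unname(coef(ref)[2, 4]), tolerance = 1e-12)
  # reproducible from seed; band contains the fitted line
  b2 <- ols_bootstrap(x, y, seed = 9)
  expect_identical(b$lower, b2$lower)
  expect_true(all(b$lower <= b$fit & b$fit <= b$upper))
  expect_error(ols_bootstrap(rep(1, 10), rnorm(10)), "constant")
})

test_that("collinear data give R^2 = 1 and a degenerate band", {
  x <- 1:10; y <- 3 * x - 2
  b <- ols_bootstrap(x, y, seed = 1)
  expect_equal(b$r_squared, 1)
  expect_lt(max(b$upper - b$lower), 1e-9)
})

test_that("bootstrap bands stabilize as replicates grow", {
  set.seed(108)
  x <- runif(29); y <- x + rnorm(29, 0, 0.5)
  b1 <- ols_bootstrap(x, y, n_boot = 1999, seed = 1)
  b2 <- ols_bootstrap(x, y, n_boot = 1999, seed = 2)
  b3 <- ols_bootstrap(x, y, n_boot = 19990, seed = 3)
  rng <- diff(range(y))
  # seed-to-seed wobble at N = 1999 exceeds the drift to N = 19990
  expect_lt(mean(abs(b1$lower - b3$lower)), 0.02 * rng)
  expect_lt(mean(abs(b1$upper - b3$upper)), 0.02 * rng)
  expect_lt(mean(abs(b1$lower - b2$lower)), 0.02 * rng)
})

test_that("profile correlation matches its closed-form null moment", {
  a <- c(1, 5, 9, 2, 7)
  expect_equal(profile_correlation(a, a)$r_squared, 1)
  expect_error(profile_correlation(a, rep(1, 5)), "zero-variance")
  set.seed(109)
  n <- 12
  base <- rnorm(n)
  r2s <- vapply(1:400, function(i)
    profile_correlation(base, sample(base))$r_squared, numeric(1))
  # E[R^2] = 1/(n-1) under exchangeable permutation null
  expect_equal(mean(r2s), 1 / (n - 1), tolerance = 0.25)
})

test_that("line selection ranks deterministically and counts strata", {
  em <- data.frame(line = sprintf("L%02d", 1:10),
                   ppbv_per_mg = c(5, 95, 8, 12, 3, 85, 7, 9, 2, 40))
  sel <- select_lines(em, thresholds = c(-10, 80), top_k = 3)
  expect_identical(sel$ranking$line[1], "L02")
  expect_identical(sel$top_k, c("L02", "L06", "L10"))
  expect_identical(sel$strata$n, c(6L, 2L))  # {5,8,3,7,9,2} < 10; {95,85} > 80
  # ties broken by line ID; top_k = n returns everything
  em2 <- data.frame(line = c("B", "A"), ppbv_per_mg = c(1, 1))
  s2 <- select_lines(em2, thresholds = numeric(), top_k = 2)
  expect_identical(s2$ranking$line, c("A", "B"))
  expect_identical(length(s2$top_k), 2L)
})

test_that("fold change is the exact delta-delta-Ct transform", {
  expect_identical(fold_change(0), 1)
  expect_identical(fold_change(-1), 2)
  expect_equal(fold_change(3.3219281), 0.1, tolerance = 1e-7)
  expect_equal(fold_change(log2(1 / 7)), 7, tolerance = 1e-12)
})

test_that("screen_emissions builds a letter/star table across genotypes", {
  set.seed(110)
  mk <- function(line, gt, vals)
    data.frame(vial = paste0(line, seq_along(vals)), line = line,
               genotype = gt, block = 1, fw_mg = 20, ion = "C5H9+",
               mz = 69.0699, ppbv = vals * 20, ppbv_per_mg = vals,
               below_lod = FALSE)
  em <- rbind(mk("T1", "tagged", rnorm(6, 74, 5)),
              mk("T2", "untagged", rnorm(6, 71, 5)),
              mk("C", "Col-0", rnorm(6, 0.14, 0.04)))
  res <- screen_emissions(em, family = 6)
  expect_s3_class(res, "screening_result")
  expect_identical(res$letter[res$genotype == "Col-0"], "a")
  # the two transgenic genotypes overlap: share a letter distinct from Col-0
  tg <- res$letter[res$genotype != "Col-0"]
  expect_true(all(tg == "b"))
  expect_identical(unique(res$stars), "***")
  rep <- format_screening_report(res)
  expect_identical(nrow(rep), 1L)
  expect_match(rep[["Col-0"]], "a$")
})

test_that("block-reference normalization divides out block drift", {
  em <- data.frame(vial = paste0("V", 1:8),
                   line = c("L1", "L2", "Col-0", "L3",
                            "L4", "L5", "Col-0", "L6"),
                   genotype = rep(c("transgenic", "transgenic", "Col-0",
                                    "transgenic"), 2),
                   block = rep(1:2, each = 4), fw_mg = 20,
                   ion = "C5H9+", mz = 69.0699,
                   ppbv = NA, ppbv_per_mg = c(10, 20, 1, 30, 20, 40, 2, 60),
                   below_lod = FALSE)
  out <- normalize_by_block_reference(em)
  # grand Col-0 mean = 1.5; block 1 factor 1/1.5, block 2 factor 2/1.5
  expect_equal(out$ppbv_per_mg[out$block == 1 & out$genotype != "Col-0"],
               c(10, 20, 30) * 1.5)
  expect_equal(out$ppbv_per_mg[out$block == 2 & out$genotype != "Col-0"],
               c(20, 40, 60) * 0.75)
  expect_identical(out$ppbv_per_mg_raw, em$ppbv_per_mg)
})

test_that("emission workbooks are read with schema mapping", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(`Line ID` = c("L1", "L2"),
                       `Isoprene (ppbv/mgFW)` = c(4.2, 88),
                       check.names = FALSE), path, row.names = FALSE)
  df <- read_emission_workbook(path, col_map = c(
    line = "Line ID", emission = "Isoprene (ppbv/mgFW)"))
  expect_identical(df$line, c("L1", "L2"))
  expect_identical(df$emission, c(4.2, 88))
  expect_error(read_emission_workbook(path, col_map = c(line = "nope")),
               "not found")
})
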