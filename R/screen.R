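# Screening statistics: Welch tests, compact letter display, Bonferroni,
# distribution diagnostics, bootstrap regression bands, profile
# correlations, line ranking, qPCR fold changes.

#' Welch's heteroscedastic one-way test
#'
#' Closed-form Welch (1951) statistic for comparing k group means without
#' assuming equal variances: with weights `w_i = n_i / s_i^2`,
#' `W = sum(w_i)`, weighted grand mean `xb = sum(w_i xbar_i)/W`,
#'
#'   `F = [sum(w_i (xbar_i - xb)^2) / (k-1)] /
#'        [1 + 2(k-2)/(k^2-1) * sum((1 - w_i/W)^2 / (n_i - 1))]`
#'
#' on `df1 = k - 1` and `df2 = (k^2-1) / (3 * sum((1-w_i/W)^2/(n_i-1)))`
#' (Welch-Satterthwaite) degrees of freedom.
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor/vector, same length.
#' @return List with `statistic` (F), `df1`, `df2`, `p.value`, `k`, and the
#'   per-group `means`, `sds`, `ns`.
#' @export
welch_anova <- function(values, groups) {
  groups <- factor(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  ns <- tapply(values, groups, length)
  if (any(ns < 2)) stop("every group needs n >= 2 (got n = ",
                        min(ns), " in group ",
                        names(ns)[which.min(ns)], ")")
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  if (all(vars == 0)) stop("zero variance in every group: Welch statistic undefined")
  w <- ns / vars
  if (any(!is.finite(w)))
    stop("zero within-group variance makes Welch weights infinite")
  W <- sum(w)
  xb <- sum(w * means) / W
  tmp <- sum((1 - w / W)^2 / (ns - 1))
  Fstat <- (sum(w * (means - xb)^2) / (k - 1)) /
    (1 + 2 * (k - 2) / (k^2 - 1) * tmp)
  df2 <- (k^2 - 1) / (3 * tmp)
  p <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)
  list(statistic = unname(Fstat), df1 = k - 1, df2 = unname(df2),
       p.value = unname(p), k = k,
       means = means, sds = sqrt(vars), ns = ns)
}

# Pairwise Welch p-value matrix (two-group Welch test per pair).
pairwise_welch_p <- function(values, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  p <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  diag(p) <- 1
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    sel <- groups %in% lv[c(i, j)]
    p[i, j] <- p[j, i] <- welch_anova(values[sel], droplevels(groups[sel]))$p.value
  }
  p
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: groups sharing a letter do not differ
#' pairwise at level `alpha`. Letters are assigned in order of ascending
#' group mean, so `"a"` always marks the lowest-mean stratum (the wild-type
#' reference in a typical screen). Deterministic given the p-matrix and the
#' mean ordering.
#'
#' @param p_matrix symmetric matrix of pairwise p-values with dimnames.
#' @param means named numeric vector of group means (orders the letters).
#' @param alpha significance level (default 0.05).
#' @return Named character vector of letter codes per group.
#' @export
letter_groups <- function(p_matrix, means, alpha = 0.05) {
  stopifnot(is.matrix(p_matrix),
            isTRUE(all.equal(p_matrix, t(p_matrix), tolerance = 1e-12)))
  g <- rownames(p_matrix)
  stopifnot(!is.null(g), all(g %in% names(means)))
  ord <- g[order(means[g])]
  p <- p_matrix[ord, ord, drop = FALSE]
  k <- length(ord)

  cols <- list(seq_len(k))                       # start: everyone together
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (p[i, j] >= alpha) next                   # not significant: may share
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (i %in% col && j %in% col) {
        cols[[ci]] <- setdiff(col, i)
        cols[[length(cols) + 1L]] <- setdiff(col, j)
      }
    }
    # absorb: drop columns contained in another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] %in% cols[[b]]) &&
          !(all(cols[[b]] %in% cols[[a]]) && a < b))
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by their lowest-mean member for stable lettering
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  letters_of <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(cols, function(cl) i %in% cl, logical(1)))],
           collapse = ""), character(1))
  stats::setNames(letters_of, ord)[g]
}

#' Bonferroni correction with an explicit family size
#'
#' `p_adj = min(1, m * p)`. The family size `m` is the number of compounds
#' tested (one adjusted value per compound row), which may exceed the
#' length of `p`.
#'
#' @param p numeric vector of p-values.
#' @param m family size (>= `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("family size m must be >= length(p)")
  pmin(1, m * p)
}

#' Significance stars
#'
#' Standard code: 0 '***' 0.001 '**' 0.01 '*' 0.05 '' 1.
#' @param p numeric vector of (adjusted) p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", ""), right = FALSE) |> as.character()
}

#' Distribution diagnostics of line emissions
#'
#' Median, moment-coefficient skewness `g1 = m3 / m2^1.5`, excess kurtosis
#' `g2 = m4 / m2^2 - 3` (population-moment conventions, no small-sample
#' correction; the convention is recorded in the output) and the
#' Shapiro-Wilk normality test (Royston's algorithm).
#'
#' @param x numeric vector (n >= 3).
#' @return List with `n`, `median`, `skewness`, `kurtosis_excess`,
#'   `shapiro_w`, `shapiro_p`, `convention`.
#' @export
distribution_summary <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    return(list(n = n, median = stats::median(x), skewness = NA_real_,
                kurtosis_excess = NA_real_, shapiro_w = NA_real_,
                shapiro_p = NA_real_, degenerate = TRUE,
                convention = "moment g1 = m3/m2^1.5, excess g2 = m4/m2^2 - 3"))
  }
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3
  sw <- stats::shapiro.test(x)
  list(n = n, median = stats::median(x), skewness = g1,
       kurtosis_excess = g2, shapiro_w = unname(sw$statistic),
       shapiro_p = sw$p.value, degenerate = FALSE,
       convention = "moment g1 = m3/m2^1.5, excess g2 = m4/m2^2 - 3")
}

#' Least-squares regression with bootstrap confidence band
#'
#' Closed-form OLS of `y` on `x` with the two-sided t-test on the slope,
#' followed by case-resampling bootstrap (resample (x, y) pairs with
#' replacement, default N = 1999 per the screening protocol) and a
#' pointwise percentile 2.5/97.5 band evaluated on an x-grid. Residual
#' resampling is available as an option.
#'
#' @param x predictor (e.g. transgene expression fold change).
#' @param y response (e.g. isoprene emission).
#' @param n_boot number of bootstrap replicates (default 1999).
#' @param grid_n grid points for the band (default 50).
#' @param scheme `"case"` (default) or `"residual"` resampling.
#' @param seed optional integer seed.
#' @return List of class `ols_bootstrap`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (slope t-test), `n`, `n_boot`, `grid` (x),
#'   `fit` (line on grid), `lower`, `upper` (95% band), `scheme`, `seed`.
#' @export
ols_bootstrap <- function(x, y, n_boot = 1999, grid_n = 50,
                          scheme = c("case", "residual"), seed = NULL) {
  scheme <- match.arg(scheme)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::var(x) == 0) stop("constant predictor: slope undefined")
  if (!is.null(seed)) set.seed(seed)

  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se > 0) 2 * stats::pt(abs(slope / se), n - 2, lower.tail = FALSE)
       else 0

  grid <- seq(min(x), max(x), length.out = grid_n)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  if (scheme == "case") {
    bx <- matrix(x[idx], nrow = n); by <- matrix(y[idx], nrow = n)
  } else {
    res <- y - yhat
    bx <- matrix(x, n, n_boot)
    by <- yhat + matrix(res[idx], nrow = n)
  }
  mx <- colMeans(bx); my <- colMeans(by)
  sxx_b <- colSums(bx^2) - n * mx^2
  sxy_b <- colSums(bx * by) - n * mx * my
  ok_b <- sxx_b > 0
  b1 <- sxy_b[ok_b] / sxx_b[ok_b]
  b0 <- my[ok_b] - b1 * mx[ok_b]
  lines_b <- outer(grid, b1) + matrix(b0, length(grid), sum(ok_b),
                                      byrow = TRUE)
  qs <- apply(lines_b, 1, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  fitline <- intercept + slope * grid
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_value = p, n = n, n_boot = n_boot, grid = grid,
                 fit = fitline,
                 lower = pmin(qs[1, ], fitline),
                 upper = pmax(qs[2, ], fitline),
                 scheme = scheme, seed = seed),
            class = "ols_bootstrap")
}

#' @export
print.ols_bootstrap <- function(x, ...) {
  cat(sprintf("<ols_bootstrap> y = %.4g + %.4g x, R^2 = %.4f, p = %.3g (n = %d, %s resampling, N = %d)\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n, x$scheme,
              x$n_boot))
  invisible(x)
}

#' Squared correlation between two emission profiles
#'
#' Squared Pearson correlation of two equal-length per-ion emission
#' vectors, with the two-sided t-test p-value for the hypothesis of no
#' correlation. Used to compare the whole VOC emission profile of one
#' genotype against another.
#'
#' @param a,b equal-length numeric vectors (n >= 3).
#' @return List with `r_squared`, `p_value`, `n`.
#' @export
profile_correlation <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("need n >= 3")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero-variance profile: correlation undefined")
  r <- stats::cor(a, b)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  list(r_squared = r^2, p_value = p, n = n)
}

#' Rank lines by emission and count threshold strata
#'
#' Summarizes each line by the mean over its replicate vials, ranks in
#' decreasing order (ties broken by line ID), and reports counts in
#' user-supplied strata, e.g. how many lines fall below 10 or above
#' 80 ppbv/mgFW.
#'
#' @param emissions an `emission_table` (long form) or a data.frame with
#'   columns `line` and a value column.
#' @param ion which ion to rank on (required for multi-ion tables).
#' @param value value column (default `"ppbv_per_mg"`).
#' @param thresholds named list of strata, each
#'   `list(op = "<" or ">", value = cutoff)`; or a shorthand numeric vector
#'   where negative entries mean "below |x|" and positive "above x".
#' @param top_k optionally also return the top-k line IDs.
#' @param include_reference include non-line (e.g. Col-0) rows (default
#'   FALSE).
#' @return List with `ranking` (data.frame line/emission/rank),
#'   `strata` (data.frame label/n) and `top_k` (character vector or NULL).
#' @export
select_lines <- function(emissions, ion = NULL, value = "ppbv_per_mg",
                         thresholds = c(-10, 80), top_k = NULL,
                         include_reference = FALSE) {
  df <- as.data.frame(emissions)
  if (!is.null(ion) && "ion" %in% names(df)) df <- df[df$ion == ion, ]
  if ("ion" %in% names(df) && length(unique(df$ion)) > 1)
    stop("multiple ions present: specify `ion`")
  if (!nrow(df))
    return(list(ranking = data.frame(line = character(), emission = numeric(),
                                     rank = integer()),
                strata = data.frame(label = character(), n = integer()),
                top_k = if (is.null(top_k)) NULL else character()))
  if (!include_reference && "genotype" %in% names(df))
    df <- df[df$genotype != "Col-0", ]
  agg <- stats::aggregate(df[[value]], list(line = df$line), mean)
  names(agg)[2] <- "emission"
  agg <- agg[order(-agg$emission, agg$line), ]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL

  strata <- if (is.numeric(thresholds)) {
    do.call(rbind, lapply(thresholds, function(th) {
      if (th < 0) data.frame(label = paste0("< ", -th),
                             n = sum(agg$emission < -th))
      else data.frame(label = paste0("> ", th),
                      n = sum(agg$emission > th))
    }))
  } else {
    do.call(rbind, lapply(thresholds, function(th) {
      n <- switch(th$op,
                  "<" = sum(agg$emission < th$value),
                  ">" = sum(agg$emission > th$value),
                  stop("threshold op must be '<' or '>'"))
      data.frame(label = paste(th$op, th$value), n = n)
    }))
  }
  list(ranking = agg, strata = strata,
       top_k = if (is.null(top_k)) NULL
               else agg$line[seq_len(min(top_k, nrow(agg)))])
}

#' qPCR fold change from a delta-delta-Ct value
#'
#' `fold = 2^(-ddCt)`.
#' @param ddct delta-delta-Ct value(s).
#' @return Fold change(s).
#' @export
fold_change <- function(ddct) 2^(-ddct)

#' Per-block reference normalization
#'
#' Optional drift correction using the one wild-type reference vial per
#' autosampler block: analyte values in a block are divided by that block's
#' Col-0 deviation from the grand Col-0 mean. Raw values are always kept
#' alongside (`<value>_raw`).
#'
#' @param emissions an `emission_table` (long form).
#' @param value value column to normalize (default `"ppbv_per_mg"`).
#' @param reference genotype label of the reference (default `"Col-0"`).
#' @return The table with the value column block-normalized and the raw
#'   column appended.
#' @export
normalize_by_block_reference <- function(emissions, value = "ppbv_per_mg",
                                         reference = "Col-0") {
  df <- emissions
  raw_col <- paste0(value, "_raw")
  df[[raw_col]] <- df[[value]]
  for (ion in unique(df$ion)) {
    sel <- df$ion == ion
    ref <- df[sel & df$genotype == reference, ]
    if (!nrow(ref)) next
    grand <- mean(ref[[value]], na.rm = TRUE)
    if (!is.finite(grand) || grand <= 0) next
    block_ref <- tapply(ref[[value]], ref$block, mean)
    for (b in names(block_ref)) {
      f <- block_ref[[b]] / grand
      if (is.finite(f) && f > 0)
        df[[value]][sel & df$block == as.numeric(b)] <-
          df[[value]][sel & df$block == as.numeric(b)] / f
    }
  }
  df
}

#' Per-compound screening comparison across genotypes
#'
#' For every ion in an emission table: per-genotype mean, SD and n, the
#' Welch one-way p-value across genotypes, Bonferroni-adjusted significance
#' stars (family = number of compounds by default), and compact letters
#' from pairwise Welch tests at unadjusted alpha (letters encode which
#' genotypes do not significantly differ).
#'
#' @param emissions an `emission_table` (long form).
#' @param value value column (default `"ppbv_per_mg"`).
#' @param group grouping column (default `"genotype"`).
#' @param alpha pairwise significance level for the letters (default 0.05).
#' @param family Bonferroni family size; default = number of ions tested.
#' @return data.frame of class `screening_result`: one row per ion x
#'   genotype with `mean`, `sd`, `n`, `letter`, plus per-ion `p_welch`,
#'   `p_bonferroni`, `stars`.
#' @export
screen_emissions <- function(emissions, value = "ppbv_per_mg",
                             group = "genotype", alpha = 0.05,
                             family = NULL) {
  df <- as.data.frame(emissions)
  ions <- unique(df$ion[order(df$mz)])
  if (is.null(family)) family <- length(ions)
  rows <- lapply(ions, function(ion) {
    sub <- df[df$ion == ion & is.finite(df[[value]]), ]
    w <- welch_anova(sub[[value]], sub[[group]])
    pm <- pairwise_welch_p(sub[[value]], sub[[group]])
    lt <- letter_groups(pm, w$means, alpha = alpha)
    data.frame(ion = ion, mz = sub$mz[1], genotype = names(w$means),
               mean = as.numeric(w$means), sd = as.numeric(w$sds),
               n = as.integer(w$ns), letter = unname(lt[names(w$means)]),
               p_welch = w$p.value,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  p_ion <- vapply(ions, function(i) out$p_welch[out$ion == i][1], numeric(1))
  p_adj <- bonferroni(p_ion, m = family)
  out$p_bonferroni <- p_adj[match(out$ion, ions)]
  out$stars <- significance_stars(out$p_bonferroni)
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Format a screening result as a compact report table
#'
#' One row per ion: `mean +- sd letter` per genotype, the Welch p-value and
#' the Bonferroni stars; the layout conventionally used to report VOC
#' screening comparisons.
#'
#' @param result a `screening_result` from [screen_emissions()].
#' @param digits significant digits (default 3).
#' @return data.frame, one row per ion.
#' @export
format_screening_report <- function(result, digits = 3) {
  ions <- unique(result$ion)
  gts <- unique(result$genotype)
  rows <- lapply(ions, function(ion) {
    sub <- result[result$ion == ion, ]
    cells <- vapply(gts, function(g) {
      r <- sub[sub$genotype == g, ]
      if (!nrow(r)) return(NA_character_)
      sprintf("%s ± %s %s", signif(r$mean, digits), signif(r$sd, 2),
              r$letter)
    }, character(1))
    df <- data.frame(mz = round(sub$mz[1], 4), ion = ion,
                     stringsAsFactors = FALSE)
    for (g in gts) df[[g]] <- cells[[g]]
    df$p_value <- signif(sub$p_welch[1], 2)
    df$signif <- sub$stars[1]
    df
  })
  do.call(rbind, rows)
}

#' Read a per-genotype emissions workbook
#'
#' Schema-flexible reader for supplementary emissions tables (one row per
#' line/genotype, one column per ion or a single emission column). XLSX is
#' read through readxl when installed; CSV always works. Column names are
#' mapped through `col_map`.
#'
#' @param path XLSX or CSV file.
#' @param col_map named character vector mapping canonical names
#'   (`line`, `emission`, optionally `ion`, `genotype`) to the file's
#'   column names.
#' @param sheet sheet index or name for XLSX (default 1).
#' @return data.frame with canonical column names.
#' @export
read_emission_workbook <- function(path,
                                   col_map = c(line = "line",
                                               emission = "emission"),
                                   sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package; ",
           "convert the sheet to CSV instead")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
  miss <- setdiff(unname(col_map), names(df))
  if (length(miss))
    stop("column(s) not found in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  out <- df
  for (canon in names(col_map)) out[[canon]] <- df[[col_map[[canon]]]]
  out
}
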