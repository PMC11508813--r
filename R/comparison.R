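#' Bland-Altman agreement analysis
#'
#' Concordance between two measurement methods via the distribution of
#' paired differences `d = a - b`: bias (mean difference), limits of
#' agreement `bias +/- 1.96 sd(d)`, and proportional bias assessed as the
#' correlation (with two-sided t test) of the differences against the pair
#' means — agreement holds when differences concentrate around the bias,
#' uncorrelated with magnitude.
#'
#' @param a,b numeric vectors of paired measurements (length >= 3).
#' @return an `agreement_report` list: `n`, `bias`, `sd_diff`, `loa`
#'   (length-2), `prop_bias_slope`, `prop_bias_cor`, `prop_bias_p`,
#'   `pearson_rho`, `wilcoxon_statistic`, `wilcoxon_p`, and
#'   `constant_diff` flag (differences have zero variance, so the
#'   proportional-bias correlation is undefined and reported as 0).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop_input("paired vectors differ in length")
  if (length(a) < 3) stop_input("need at least 3 pairs")
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  s <- sd(d)
  constant <- s == 0 || !is.finite(s)
  if (constant) {
    slope <- 0
    rho_d <- 0
    p_d <- NA_real_
  } else if (sd(m) == 0) {
    slope <- 0
    rho_d <- 0
    p_d <- NA_real_
  } else {
    rho_d <- cor(d, m)
    slope <- rho_d * s / sd(m)
    n <- length(d)
    tt <- rho_d * sqrt((n - 2) / max(1 - rho_d^2, .Machine$double.eps))
    p_d <- 2 * pt(-abs(tt), df = n - 2)
  }
  wx <- tryCatch(paired_wilcoxon(a, b),
                 error = function(e) list(statistic = NA_real_,
                                          p_value = NA_real_))
  structure(
    list(
      n = length(a),
      bias = bias,
      sd_diff = s,
      loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
      prop_bias_slope = slope,
      prop_bias_cor = rho_d,
      prop_bias_p = p_d,
      pearson_rho = if (sd(a) == 0 || sd(b) == 0) {
        if (s == 0) 1 else NA_real_
      } else {
        cor(a, b)
      },
      wilcoxon_statistic = wx$statistic,
      wilcoxon_p = wx$p_value,
      constant_diff = constant
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<agreement_report n=%d>\n  bias %.4f, LoA [%.4f, %.4f]\n",
      "  proportional bias r=%.3f (p=%.3g)\n",
      "  Pearson rho=%.3f, Wilcoxon V=%.1f (p=%.3g)\n"
    ),
    x$n, x$bias, x$loa[1], x$loa[2], x$prop_bias_cor, x$prop_bias_p,
    x$pearson_rho, x$wilcoxon_statistic, x$wilcoxon_p
  ))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (the original Wilcoxon convention — relevant here because
#' ruler-discretized MA1/MA2 values produce ties). For `n <= 25` without
#' ties in the absolute differences the exact null distribution is used;
#' otherwise a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param a,b numeric vectors of equal length.
#' @return list `statistic` (V, the positive-rank sum), `p_value`, `n`
#'   (pairs after zero removal), `exact` (logical).
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop_input("paired vectors differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_input("all differences are zero: test degenerate")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25 && !ties
  if (exact) {
    p <- if (v > n * (n + 1) / 4) {
      2 * (1 - psignrank(v - 1, n))
    } else {
      2 * psignrank(v, n)
    }
    p <- min(p, 1)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(2 * pnorm(-abs(z)), 1)
  }
  list(statistic = v, p_value = p, n = n, exact = exact)
}

#' ECDF superposition after bias shift
#'
#' Computes per-method empirical CDFs of the area estimates, then
#' re-evaluates each non-reference ECDF after adding its Bland-Altman bias
#' versus the reference. If methods agree up to a constant offset, the
#' shifted distributions superimpose: the Kolmogorov-style maximum vertical
#' distance drops to (near) zero.
#'
#' @param table data frame of areas, one column per method.
#' @param reference name of the reference method column.
#' @return list per non-reference method: `bias`, `D_before`, `D_after`
#'   (max vertical ECDF distances to the reference before / after shifting).
#' @export
ecdf_bias_shift <- function(table, reference) {
  if (!reference %in% names(table)) {
    stop_input("reference method '%s' not in table", reference)
  }
  methods <- setdiff(names(table), reference)
  if (length(methods) == 0) stop_input("need at least 2 methods")
  ref <- table[[reference]]
  ks_dist <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    g <- sort(unique(c(x, y)))
    fx <- vapply(g, function(v) mean(x <= v), 0)
    fy <- vapply(g, function(v) mean(y <= v), 0)
    max(abs(fx - fy))
  }
  out <- lapply(methods, function(mname) {
    m <- table[[mname]]
    keep <- !is.na(m) & !is.na(ref)
    bias <- mean(ref[keep] - m[keep])
    list(
      method = mname,
      bias = bias,
      D_before = ks_dist(ref[keep], m[keep]),
      D_after = ks_dist(ref[keep], m[keep] + bias)
    )
  })
  names(out) <- methods
  out
}

#' Cumulative-mean convergence across data shuffles
#'
#' Representativeness check for a sample of wheal areas: the values are
#' shuffled `n_shuffles` times (default 15), the running cumulative mean is
#' tracked along each permuted sequence, the curves are averaged, and the
#' standard-error decay `sd / sqrt(k)` is reported. A stabilizing mean with
#' vanishing SE indicates the sample size is representative.
#'
#' @param values numeric vector, length >= 2.
#' @param n_shuffles number of shuffles (default 15).
#' @param seed integer seed for the shuffles.
#' @return list with `k` (1..n), `mean_curve` (average cumulative mean),
#'   `se_curve` (`sd(values) / sqrt(k)`), and `curves` (the
#'   `n_shuffles x n` matrix of per-shuffle cumulative means).
#' @export
cumulative_mean_convergence <- function(values, n_shuffles = 15, seed = 1L) {
  n <- length(values)
  if (n < 2) stop_input("need at least 2 values")
  curves <- with_seed(seed, {
    t(vapply(
      seq_len(n_shuffles),
      function(i) cumsum(sample(values)) / seq_len(n),
      numeric(n)
    ))
  })
  list(
    k = seq_len(n),
    mean_curve = colMeans(curves),
    se_curve = sd(values) / sqrt(seq_len(n)),
    curves = curves
  )
}

#' Percentage-deviation study between area methods
#'
#' For each shape, the absolute percentage deviation of each method from
#' the reference, `100 * |area_method - area_ref| / area_ref`, summarized
#' per method as mean, sd, min, max. For regular shapes the reference is
#' the analytic (`Expected`) area; for irregular shapes — which have no
#' closed-form area — the pixel-proportion estimate serves as reference,
#' being invariant to the geometric contour.
#'
#' @param table data frame of areas, one column per method.
#' @param reference reference method column name.
#' @param group optional group label carried into the summary.
#' @return a `deviation_summary` data frame: one row per non-reference
#'   method with `mean_pct`, `sd_pct`, `min_pct`, `max_pct`, `n`.
#' @export
deviation_study <- function(table, reference, group = NA_character_) {
  if (!reference %in% names(table)) {
    stop_input("missing reference area column '%s'", reference)
  }
  ref <- table[[reference]]
  methods <- setdiff(names(table), reference)
  rows <- lapply(methods, function(mname) {
    m <- table[[mname]]
    keep <- !is.na(m) & !is.na(ref)
    dev <- 100 * abs(m[keep] - ref[keep]) / ref[keep]
    data.frame(
      group = group,
      method = mname,
      reference = reference,
      mean_pct = mean(dev),
      sd_pct = sd(dev),
      min_pct = min(dev),
      max_pct = max(dev),
      n = length(dev)
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("deviation_summary", "data.frame")
  out
}
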