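#' Subsampled bootstrap of the mean normalized ratio
#'
#' Repeatedly resamples `m` cells with replacement from the normalized
#' per-cell ratios and records the mean of each resample, giving `B`
#' bootstrap means; a normal distribution is then fitted to the means by
#' moment matching (`mu_hat` = their mean, `sigma_hat` = their sd). The
#' defaults — 1000 iterations of 50 cells — deliberately subsample far
#' below the acquisition depth, which makes the spread of the bootstrap
#' means much wider than the standard error of the full-sample mean;
#' the calibration consequences for downstream testing are derived in
#' the package vignette.
#'
#' @param ratios A [normalize_to_reference()] result, a
#'   [compute_ratios()] result, or a numeric vector of per-cell ratios.
#' @param B Number of bootstrap iterations (default 1000).
#' @param m Cells drawn per iteration, with replacement (default 50);
#'   `m` may exceed the number of cells. Fewer than 500 available cells
#'   triggers a warning.
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @param sample_id Optional id stored on the result (defaults to the
#'   input's id).
#' @return An object of class `bootstrap_dist`: `sample_id`, `means`
#'   (length `B`), `B`, `m`, `mu_hat`, `sigma_hat`, `seed`.
#' @export
bootstrap_means <- function(ratios, B = 1000L, m = 50L, seed = 1L,
                            sample_id = NULL) {
  rr <- as_raw_ratios(ratios)
  x <- rr$ratios
  if (length(x) == 0L) stop("cannot bootstrap an empty ratio vector",
                            call. = FALSE)
  B <- as.integer(check_scalar(B, "B", lower = 1))
  m <- as.integer(check_scalar(m, "m", lower = 1))
  seed <- as.integer(check_seed(seed))
  if (length(x) < 500L) {
    warning(sprintf("only %d cells available for %d-cell resamples",
                    length(x), m), call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(length(x), B * m, replace = TRUE)
  means <- .colMeans(x[idx], m, B)
  structure(list(
    sample_id = if (is.null(sample_id)) rr$sample_id else sample_id,
    means = means,
    B = B,
    m = m,
    mu_hat = mean(means),
    sigma_hat = stats::sd(means),
    seed = seed
  ), class = "bootstrap_dist")
}

#' @export
print.bootstrap_dist <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_dist> '%s': B=%d, m=%d, mu_hat=%.4g, sigma_hat=%.4g\n",
    x$sample_id, x$B, x$m, x$mu_hat, x$sigma_hat))
  invisible(x)
}

#' Dual one-sided test between mutant and wild-type bootstrap means
#'
#' Runs two directional tests on the same comparison of two length-`B`
#' bootstrap-mean vectors: does the mutant sit below the wild type
#' (`p_decrease`), and does it sit above (`p_increase`)? Both p-values
#' derive from one continuous statistic, so they are complementary:
#' `p_decrease + p_increase = 1` always.
#'
#' The default statistic is the Welch unequal-variance two-sample t
#' between the two mean vectors (`variant = "welch"`); a pooled-variance
#' t (`"pooled"`) and a z-test on the fitted normal parameters (`"z"`)
#' are available. Degenerate zero-variance cases are defined explicitly
#' for determinism: both vectors constant and equal gives `t = 0`,
#' `p = 0.5` each, `wt_like`; both constant but unequal gives `p = 0` in
#' the direction of the difference.
#'
#' @param mut,wt [bootstrap_means()] results computed with identical
#'   `(B, m)`.
#' @param alpha Per-direction significance cutoff (default 0.01).
#' @param variant `"welch"` (default), `"pooled"`, or `"z"`.
#' @param client Optional client label carried onto the call.
#' @return An object of class `phenotype_call`: `sample_id`, `client`,
#'   `mu_hat_mut`, `mu_hat_wt`, `t_stat`, `df`, `p_decrease`,
#'   `p_increase`, `alpha`, `category`.
#' @export
dual_one_sided_test <- function(mut, wt, alpha = 0.01,
                                variant = c("welch", "pooled", "z"),
                                client = NA_character_) {
  variant <- match.arg(variant)
  if (!inherits(mut, "bootstrap_dist") || !inherits(wt, "bootstrap_dist")) {
    stop("`mut` and `wt` must be bootstrap_means() results", call. = FALSE)
  }
  if (mut$B != wt$B || mut$m != wt$m) {
    stop(sprintf("mismatched bootstrap settings: mutant (B=%d, m=%d) vs WT (B=%d, m=%d)",
                 mut$B, mut$m, wt$B, wt$m), call. = FALSE)
  }
  alpha <- check_scalar(alpha, "alpha", lower = 0, upper = 1)
  B <- mut$B
  v1 <- stats::var(mut$means)
  v2 <- stats::var(wt$means)
  delta <- mut$mu_hat - wt$mu_hat

  # both tail probabilities are computed directly (not as 1 - p) so each
  # retains full relative precision in its own extreme tail; their sum is
  # 1 to machine precision
  if (v1 == 0 && v2 == 0) {
    if (delta == 0) {
      t_stat <- 0; df <- NA_real_; p_dec <- 0.5; p_inc <- 0.5
    } else {
      t_stat <- sign(delta) * Inf; df <- NA_real_
      p_dec <- if (delta < 0) 0 else 1
      p_inc <- 1 - p_dec
    }
  } else if (variant == "z") {
    t_stat <- delta / sqrt(v1 / B + v2 / B)
    df <- Inf
    p_dec <- stats::pnorm(t_stat)
    p_inc <- stats::pnorm(t_stat, lower.tail = FALSE)
  } else {
    if (variant == "welch") {
      se2 <- v1 / B + v2 / B
      df <- se2^2 / ((v1 / B)^2 / (B - 1) + (v2 / B)^2 / (B - 1))
    } else {
      sp2 <- ((B - 1) * v1 + (B - 1) * v2) / (2 * B - 2)
      se2 <- sp2 * (2 / B)
      df <- 2 * B - 2
    }
    t_stat <- delta / sqrt(se2)
    p_dec <- stats::pt(t_stat, df)
    p_inc <- stats::pt(t_stat, df, lower.tail = FALSE)
  }

  structure(list(
    sample_id = mut$sample_id,
    client = client,
    mu_hat_mut = mut$mu_hat,
    mu_hat_wt = wt$mu_hat,
    t_stat = unname(t_stat),
    df = unname(df),
    p_decrease = unname(p_dec),
    p_increase = unname(p_inc),
    alpha = alpha,
    category = classify(p_dec, p_inc, alpha)
  ), class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf(
    "<phenotype_call> '%s'%s: %s (t=%.3g, p_dec=%.3g, p_inc=%.3g, alpha=%g)\n",
    x$sample_id, if (is.na(x$client)) "" else paste0(" [", x$client, "]"),
    x$category, x$t_stat, x$p_decrease, x$p_increase, x$alpha))
  invisible(x)
}

#' Three-way phenotype category from complementary one-sided p-values
#'
#' `decreased` if `p_decrease < alpha`, `increased` if
#' `p_increase < alpha`, otherwise `wt_like`. For any `alpha < 0.5` the
#' first two are mutually exclusive because the p-values are
#' complementary.
#'
#' @param p_decrease,p_increase One-sided p-values in `[0, 1]`; must sum
#'   to 1 within `1e-9`.
#' @param alpha Significance cutoff (default 0.01).
#' @return `"decreased"`, `"wt_like"`, or `"increased"`.
#' @export
classify <- function(p_decrease, p_increase, alpha = 0.01) {
  for (p in list(p_decrease, p_increase)) {
    if (length(p) != 1L || !is.numeric(p) || is.na(p) || p < 0 || p > 1) {
      stop("p-values must be single numbers in [0, 1]", call. = FALSE)
    }
  }
  if (abs(p_decrease + p_increase - 1) > 1e-9) {
    stop("p_decrease and p_increase are not complementary ",
         sprintf("(sum = %.12g)", p_decrease + p_increase), call. = FALSE)
  }
  alpha <- check_scalar(alpha, "alpha", lower = 0, upper = 1)
  if (p_decrease < alpha) "decreased"
  else if (p_increase < alpha) "increased"
  else "wt_like"
}

#' Category display colours used for structure painting
#'
#' The conventional legend: decreased reporter levels gold, wild-type
#' levels light blue, increased levels white.
#' @return Named character vector mapping category to colour name.
#' @export
category_colors <- function() {
  c(decreased = "gold", wt_like = "lightblue", increased = "white")
}
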