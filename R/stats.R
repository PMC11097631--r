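# Group-comparison decision rule: KS normality gate, then parametric or
# rank-based test; star codes at 0.05 / 0.01 / 0.001.

# cached Monte-Carlo null of the Lilliefors D statistic, keyed by n.
# The naive one-sample KS test with parameters estimated from the data is
# anticonservative; the null distribution of D under estimation is
# simulated once per sample size (fixed private seed) and reused.
.lillie_cache <- new.env(parent = emptyenv())

.lillie_d <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS distance between the sample and a normal with estimated mean/sd; the
#' p-value comes from a cached Monte-Carlo null (2,000 draws per sample
#' size, fixed internal seed, so results are deterministic).
#'
#' @param x numeric sample (n >= 4)
#' @param n_sim null draws (default 2000)
#' @return list with `statistic` and `p.value`
#' @export
lilliefors_test <- function(x, n_sim = 2000) {
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0)
    return(list(statistic = NA_real_, p.value = 0))
  d <- .lillie_d(x)
  key <- paste0("n", n, "_", n_sim)
  if (is.null(.lillie_cache[[key]])) {
    .lillie_cache[[key]] <- with_seed(104729 + n, {
      vapply(seq_len(n_sim), function(i) .lillie_d(stats::rnorm(n)),
             numeric(1))
    })
  }
  null_d <- .lillie_cache[[key]]
  list(statistic = d,
       p.value = (1 + sum(null_d >= d)) / (n_sim + 1))
}

star_code <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Compare two groups with the normality-gated decision rule
#'
#' Both groups are tested for normality (Lilliefors-corrected KS by
#' default, naive KS selectable). If both pass at `alpha_normal`, a
#' two-tailed paired or unpaired t test is used; otherwise a Wilcoxon
#' signed rank test (paired) or Mann-Whitney U test (unpaired). Summaries
#' are mean +- SEM. No multiple-testing correction is applied anywhere.
#'
#' @param a,b numeric samples (n >= 3 each; equal lengths when paired)
#' @param paired logical
#' @param normality `"lilliefors"` (default) or `"ks"`
#' @param alpha_normal normality test level (default 0.05)
#' @return object of class `comparison_result`: list with `summary`
#'   (data.frame mean/sem/n/normal_p per group), `test`, `statistic`, `p`,
#'   `stars`
#' @export
compare_groups <- function(a, b, paired = FALSE,
                           normality = c("lilliefors", "ks"),
                           alpha_normal = 0.05) {
  normality <- match.arg(normality)
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal lengths")
  norm_p <- function(x) {
    if (stats::sd(x) == 0) return(0)
    if (normality == "lilliefors") lilliefors_test(x)$p.value
    else suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  pa <- norm_p(a); pb <- norm_p(b)
  both_normal <- pa >= alpha_normal && pb >= alpha_normal
  if (paired && all(a == b)) {
    warning("all paired values identical; degenerate comparison")
    test <- if (both_normal) "paired t" else "Wilcoxon signed rank"
    stat <- NA_real_; p <- 1
  } else if (both_normal) {
    tt <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
    test <- if (paired) "paired t" else "unpaired t"
    stat <- unname(tt$statistic); p <- tt$p.value
  } else if (paired) {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    test <- "Wilcoxon signed rank"
    stat <- unname(wt$statistic); p <- wt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    test <- "Mann-Whitney U"
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(
    summary = data.frame(group = c("a", "b"),
                         mean = c(mean(a), mean(b)),
                         sem = c(sem(a), sem(b)),
                         n = c(length(a), length(b)),
                         normal_p = c(pa, pb)),
    test = test, statistic = stat, p = p, stars = star_code(p)),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("a: %.4g +- %.4g (n = %d); b: %.4g +- %.4g (n = %d)\n",
              s$mean[1], s$sem[1], s$n[1], s$mean[2], s$sem[2], s$n[2]))
  cat(sprintf("%s: p = %.4g %s\n", x$test, x$p, x$stars))
  invisible(x)
}
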