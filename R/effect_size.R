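#' Pooled standard deviation of two samples
#'
#' \eqn{\sigma_p = \sqrt{((n_1-1)\sigma^2(x_1) + (n_2-1)\sigma^2(x_2)) /
#' (n_1+n_2-2)}}, with \eqn{\sigma^2} the unbiased (n-1) sample variance.
#'
#' @param x1,x2 numeric vectors, each of length >= 2.
#' @return Pooled standard deviation.
#' @export
pooled_sd <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2)
    stop("pooled_sd requires at least 2 observations per group")
  sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
         (n1 + n2 - 2))
}

#' Signed pooled-SD effect size (male minus female)
#'
#' The standardized mean difference
#' \eqn{r = (\mu(x_{male}) - \mu(x_{female})) / \sigma_p}. Negative values
#' mean women score higher on the indicator.
#'
#' @param x_male,x_female numeric vectors of indicator values per group.
#' @return Effect size in pooled-SD units; `NaN` when the pooled SD is zero
#'   (undefined effect).
#' @export
effect_size <- function(x_male, x_female) {
  sp <- pooled_sd(x_male, x_female)
  if (sp == 0) return(NaN)
  (mean(x_male) - mean(x_female)) / sp
}

#' Subsampled effect-size comparison of two groups
#'
#' Draws `n_subsamples` random half-size subsamples without replacement from
#' each group (floor(n/2) per group), computes the signed effect size on
#' each pair, and summarizes the resulting distribution by its mean and
#' 5th/95th percentiles. Halving both groups equalizes the influence of the
#' two unequal class sizes on the standard deviations. The difference is
#' deemed significant when the central 90% percentile interval excludes
#' zero.
#'
#' @param x_male,x_female numeric vectors, each of length >= 4; `NA`s are
#'   dropped first.
#' @param n_subsamples number of subsample pairs (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param indicator optional indicator name carried in the result.
#' @return Object of class `effect_size_distribution`: list with
#'   `indicator`, `r_samples`, `mean_r`, `p5`, `p95`, `significant`,
#'   `n_subsamples`.
#' @export
subsample_comparison <- function(x_male, x_female, n_subsamples = 1000L,
                                 seed = NULL, indicator = NA_character_) {
  x_male <- x_male[!is.na(x_male)]
  x_female <- x_female[!is.na(x_female)]
  n_m <- length(x_male); n_f <- length(x_female)
  if (n_m < 4 || n_f < 4)
    stop("subsample_comparison requires at least 4 observations per group")
  if (!is.null(seed)) set.seed(seed)
  k_m <- n_m %/% 2L
  k_f <- n_f %/% 2L
  r <- vapply(seq_len(n_subsamples), function(i) {
    effect_size(x_male[sample.int(n_m, k_m)],
                x_female[sample.int(n_f, k_f)])
  }, numeric(1))
  q <- unname(stats::quantile(r, c(0.05, 0.95), na.rm = TRUE))
  structure(list(indicator = indicator,
                 r_samples = r,
                 mean_r = mean(r, na.rm = TRUE),
                 p5 = q[1], p95 = q[2],
                 significant = q[1] > 0 || q[2] < 0,
                 n_subsamples = n_subsamples,
                 subsample_sizes = c(male = k_m, female = k_f)),
            class = "effect_size_distribution")
}

#' @export
print.effect_size_distribution <- function(x, ...) {
  cat(sprintf(
    "<effect size> %s: mean r = %+.3f [5%%: %+.3f, 95%%: %+.3f]%s\n",
    ifelse(is.na(x$indicator), "(unnamed)", x$indicator),
    x$mean_r, x$p5, x$p95,
    if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Subsampled effect sizes for every column of a feature table
#'
#' @param features data frame of numeric indicator columns, rows named by
#'   participant id.
#' @param labels named gender vector (`"F"`/`"M"`) covering the rows.
#' @param n_subsamples,seed passed to [subsample_comparison()]; each
#'   indicator gets its own derived seed so results do not depend on column
#'   order.
#' @return Data frame with one row per indicator: `indicator`, `mean_r`,
#'   `p5`, `p95`, `significant`.
#' @export
effect_size_table <- function(features, labels, n_subsamples = 1000L,
                              seed = NULL) {
  labels <- labels[rownames(features)]
  res <- lapply(seq_along(features), function(j) {
    x <- features[[j]]
    s <- if (is.null(seed)) NULL else seed + j
    xm <- x[labels == "M"]; xf <- x[labels == "F"]
    # indicators observed in fewer than 4 participants per class cannot be
    # subsampled; they are reported as missing rather than failing the run
    if (sum(!is.na(xm)) < 4 || sum(!is.na(xf)) < 4)
      return(data.frame(indicator = names(features)[j], mean_r = NA_real_,
                        p5 = NA_real_, p95 = NA_real_, significant = NA))
    d <- subsample_comparison(xm, xf, n_subsamples = n_subsamples,
                              seed = s, indicator = names(features)[j])
    data.frame(indicator = d$indicator, mean_r = d$mean_r, p5 = d$p5,
               p95 = d$p95, significant = d$significant)
  })
  do.call(rbind, res)
}
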