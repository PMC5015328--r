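#' Median-of-ratios size factors
#'
#' Classical estimator: for each sample j,
#' `s_j = median_i K_ij / (prod_v K_iv)^(1/m)`, the median taken over genes
#' with strictly positive counts in every sample (no pseudocount).
#'
#' @param counts integer count matrix, genes x samples.
#' @return named numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has positive counts in every sample; ",
         "filter samples or add a pseudocount before normalization")
  }
  lk <- log(counts[all_pos, , drop = FALSE])
  log_geo <- rowMeans(lk)
  s <- exp(apply(lk - log_geo, 2L, stats::median))
  stats::setNames(s, colnames(counts))
}

#' Divide counts by size factors
#'
#' @param counts count matrix, genes x samples.
#' @param s size factors from [size_factors()].
#' @return real-valued normalized matrix `q_ij = K_ij / s_j`.
#' @export
normalize_counts <- function(counts, s) {
  if (length(s) != ncol(counts)) stop("length(s) must equal ncol(counts)")
  if (any(s <= 0)) stop("size factors must be positive")
  if (!is.null(names(s)) && !is.null(colnames(counts))) {
    s <- s[colnames(counts)]
  }
  sweep(counts, 2L, s, "/")
}

#' Per-side replicate-mean expression profiles
#'
#' Averages normalized counts over replicates within each (side, time)
#' cell, giving each gene one ordered profile per side (one value per time
#' point, ascending time). These profiles are the input to the concordance,
#' trend and clustering stages.
#'
#' @param normalized normalized count matrix (genes x samples).
#' @param design validated design data frame (`sample`, `side`, `time`,
#'   `replicate`).
#' @return list of class `expression_profiles` with per-side genes x times
#'   matrices (`oral`, `physa`) and the ordered `time_points`.
#' @export
side_profiles <- function(normalized, design) {
  validate_design(design, normalized)
  tp <- sort(unique(design$time))
  sides <- c("oral", "physa")
  prof <- lapply(sides, function(sd) {
    m <- matrix(NA_real_, nrow(normalized), length(tp),
                dimnames = list(rownames(normalized), paste0("t", tp)))
    for (k in seq_along(tp)) {
      cols <- design$sample[design$side == sd & design$time == tp[k]]
      if (!length(cols)) stop(sprintf("design cell (%s, %g h) is empty",
                                      sd, tp[k]))
      m[, k] <- rowMeans(normalized[, cols, drop = FALSE])
    }
    m
  })
  names(prof) <- sides
  structure(c(prof, list(time_points = tp)), class = "expression_profiles")
}

#' Estimate gene-wise negative-binomial dispersions
#'
#' Method-of-moments estimator pooled over replicated (side, time) cells of
#' normalized counts: `alpha_raw = max(0, (pooled_var - mean) / mean^2)`,
#' followed by a least-squares fit of the mean-dispersion trend
#' `alpha_fit(mu) = a0 + a1 / mu` over genes, and the conservative working
#' value `alpha = max(alpha_raw, alpha_fit(mu))` per gene.
#'
#' @param counts raw count matrix.
#' @param s size factors.
#' @param design validated design.
#' @return data frame of class `dispersion_estimates` with columns `gene`,
#'   `base_mean`, `alpha_raw`, `alpha_fit`, `alpha`.
#' @export
estimate_dispersions <- function(counts, s, design) {
  q <- normalize_counts(counts, s)
  cell <- interaction(design$side, design$time, drop = TRUE)
  reps <- table(cell)
  if (!any(reps >= 2L)) {
    stop("dispersion unidentifiable: no (side, time) cell has >= 2 replicates")
  }
  ss <- numeric(nrow(q))
  df <- 0L
  for (cl in names(reps)[reps >= 2L]) {
    cols <- design$sample[cell == cl]
    sub <- q[, cols, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(cols) - 1L
  }
  v <- ss / df
  mu <- rowMeans(q)
  alpha_raw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  ok <- mu > 0
  fit <- stats::lm.fit(cbind(1, 1 / mu[ok]), alpha_raw[ok])
  a0 <- max(0, fit$coefficients[1L])
  a1 <- max(0, fit$coefficients[2L])
  alpha_fit <- ifelse(mu > 0, a0 + a1 / mu, 0)
  out <- data.frame(gene = rownames(q), base_mean = mu,
                    alpha_raw = alpha_raw, alpha_fit = alpha_fit,
                    alpha = pmax(alpha_raw, alpha_fit),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "trend_coef") <- c(a0 = a0, a1 = a1)
  class(out) <- c("dispersion_estimates", "data.frame")
  out
}
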