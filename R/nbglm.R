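# Log-link negative-binomial GLM with fixed dispersion, fitted by
# Fisher-scoring IRLS with log size factors as offsets. Working weights
# w = mu / (1 + alpha * mu); alpha = 0 reduces to the Poisson GLM.

nb_loglik <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-12)
  if (alpha < 1e-12) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
}

#' Fit a negative-binomial GLM to one gene
#'
#' Iteratively reweighted least squares for the log-link NB model with a
#' fixed dispersion `alpha` and offsets `log(s)`. Convergence is declared
#' when the largest coefficient update falls below `tol` (default 1e-8)
#' within `maxit` iterations.
#'
#' @param y integer counts for one gene (one value per sample).
#' @param s per-sample size factors (used as multiplicative offsets).
#' @param X model matrix (e.g. intercept + side for the reduced model,
#'   intercept + side + time factors for the full model).
#' @param alpha fixed NB dispersion (`Var = mu + alpha mu^2`); 0 gives a
#'   Poisson fit.
#' @param init_mu optional initial fitted means; defaults to `y + 0.5`.
#'   The LRT driver initializes from (side, time) cell means with
#'   pseudocount 0.5.
#' @param tol convergence tolerance on coefficient updates.
#' @param maxit maximum IRLS iterations.
#' @return list with `coefficients`, `fitted`, `loglik`, `deviance`,
#'   `converged`, `iterations`.
#' @export
fit_nb_glm <- function(y, s, X, alpha, init_mu = NULL,
                       tol = 1e-8, maxit = 100L) {
  if (all(y == 0)) stop("all-zero gene: likelihood undefined")
  off <- log(s)
  if (is.null(init_mu)) init_mu <- y + 0.5
  eta <- pmin(pmax(log(pmax(init_mu, 0.5)), -30), 30)
  beta <- rep(Inf, ncol(X))
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    wx <- X * w
    beta_new <- tryCatch(
      solve(crossprod(X, wx), crossprod(wx, z)),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- pmin(pmax(drop(X %*% beta) + off, -30), 30)
    if (is.finite(delta) && delta < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- exp(eta)
  ll <- nb_loglik(y, mu, alpha)
  ll_sat <- nb_loglik(y, pmax(y, 1e-12), alpha)
  list(coefficients = if (all(is.finite(beta))) stats::setNames(beta, colnames(X)) else NULL,
       fitted = mu,
       loglik = ll,
       deviance = 2 * (ll_sat - ll),
       converged = converged,
       iterations = it)
}

#' Benjamini-Hochberg adjustment with missing-value handling
#'
#' Classical step-up BH over the non-missing p-values (missing entries are
#' excluded from the number of tests m and reinserted as missing).
#'
#' @param pvalues numeric vector in `[0, 1]`, `NA` allowed.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- pvalues
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Likelihood-ratio screen for a time effect
#'
#' For each gene, fits a full NB GLM (intercept + side + time factors) and
#' a reduced NB GLM (intercept + side) with the gene's working dispersion,
#' and tests whether adding the time factors improves the fit:
#' `LRT = 2 (l_full - l_reduced)`, referred to a chi-square distribution
#' with (number of time points - 1) degrees of freedom. P-values are
#' BH-adjusted; genes with `padj < alpha_level` are flagged as
#' differentially expressed (time-responsive). Genes with zero counts in
#' every sample are excluded from testing and reported as untested;
#' non-converged fits yield a missing p-value and do not enter the BH
#' correction.
#'
#' @param counts raw count matrix (genes x samples).
#' @param s size factors.
#' @param design validated design data frame.
#' @param dispersions result of [estimate_dispersions()] (or a numeric
#'   vector of per-gene dispersions in matrix row order).
#' @param alpha_level significance level on the adjusted p-value
#'   (default 0.05).
#' @return data frame of class `time_effect_result` with columns `gene`,
#'   `base_mean`, `lrt_stat`, `df`, `pvalue`, `padj`, `de_flag`, `tested`,
#'   `converged`.
#' @export
lrt_time_effect <- function(counts, s, design, dispersions,
                            alpha_level = 0.05) {
  validate_design(design, counts)
  if (alpha_level < 0 || alpha_level > 1) stop("alpha_level must be in [0, 1]")
  design <- design[match(colnames(counts), design$sample), ]
  alpha <- if (inherits(dispersions, "data.frame")) {
    stats::setNames(dispersions$alpha, dispersions$gene)[rownames(counts)]
  } else {
    rep_len(dispersions, nrow(counts))
  }
  tp <- sort(unique(design$time))
  side_f <- factor(design$side, levels = c("oral", "physa"))
  time_f <- factor(design$time, levels = tp)
  X_full <- stats::model.matrix(~ side_f + time_f)
  X_red <- stats::model.matrix(~ side_f)
  df_test <- length(tp) - 1L
  sfac <- if (!is.null(names(s))) s[colnames(counts)] else s

  cell <- interaction(design$side, design$time, drop = TRUE)
  side_cell <- factor(design$side)

  n <- nrow(counts)
  stat <- rep(NA_real_, n)
  pval <- rep(NA_real_, n)
  tested <- rep(FALSE, n)
  conv <- rep(NA, n)
  base_mean <- rowMeans(normalize_counts(counts, sfac))

  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    init_full <- stats::ave(y, cell) + 0.5
    init_red <- stats::ave(y, side_cell) + 0.5
    f_full <- fit_nb_glm(y, sfac, X_full, alpha[i], init_mu = init_full)
    f_red <- fit_nb_glm(y, sfac, X_red, alpha[i], init_mu = init_red)
    tested[i] <- TRUE
    conv[i] <- f_full$converged && f_red$converged
    if (conv[i]) {
      stat[i] <- max(0, 2 * (f_full$loglik - f_red$loglik))
      pval[i] <- stats::pchisq(stat[i], df = df_test, lower.tail = FALSE)
    }
  }

  padj <- bh_adjust(pval)
  out <- data.frame(gene = rownames(counts),
                    base_mean = base_mean,
                    lrt_stat = stat,
                    df = ifelse(tested, df_test, NA_integer_),
                    pvalue = pval,
                    padj = padj,
                    de_flag = !is.na(padj) & padj < alpha_level,
                    tested = tested,
                    converged = conv,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha_level") <- alpha_level
  attr(out, "time_points") <- tp
  class(out) <- c("time_effect_result", "data.frame")
  out
}

#' @export
print.time_effect_result <- function(x, ...) {
  a <- attr(x, "alpha_level")
  cat(sprintf("Negative-binomial LRT for a time effect (full: side + time; reduced: side)\n"))
  cat(sprintf("  %d genes; %d tested; %d DE at padj < %g (%.1f%% of tested)\n",
              nrow(x), sum(x$tested), sum(x$de_flag),
              a, 100 * sum(x$de_flag) / max(1L, sum(x$tested))))
  invisible(x)
}

#' @export
summary.time_effect_result <- function(object, ...) {
  a <- attr(object, "alpha_level")
  res <- list(n_genes = nrow(object),
              n_tested = sum(object$tested),
              n_untested = sum(!object$tested),
              n_unconverged = sum(object$tested & !is.na(object$converged) &
                                    !object$converged),
              n_de = sum(object$de_flag),
              alpha_level = a,
              df = object$df[which(object$tested)[1L]])
  class(res) <- "summary.time_effect_result"
  res
}

#' @export
print.summary.time_effect_result <- function(x, ...) {
  cat("Time-effect LRT summary\n")
  cat(sprintf("  genes: %d (tested %d, untested %d, non-converged %d)\n",
              x$n_genes, x$n_tested, x$n_untested, x$n_unconverged))
  cat(sprintf("  chi-square df: %d\n", x$df))
  cat(sprintf("  DE genes (padj < %g): %d\n", x$alpha_level, x$n_de))
  invisible(x)
}
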