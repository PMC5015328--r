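#' Hypergeometric category over-representation
#'
#' Tests each annotation term for over-representation of a study gene set
#' within a background set. For a term with `K` background members, a study
#' set of size `n` drawn from a background of size `N`, and `k` study hits,
#' the upper-tail hypergeometric probability `P[X >= k]` is computed
#' exactly; fold enrichment is `(k/n) / (K/N)`. P-values are BH-adjusted
#' across the tested terms (those with at least one study hit); terms with
#' no study hit are reported untested.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param categories data frame of (`gene`, `term`) pairs (see
#'   [read_category_map()]); genes outside the background are ignored.
#' @param alpha significance level applied to the adjusted p-value.
#' @return data frame of class `enrichment_result`, sorted by ascending
#'   adjusted p-value, with columns `term`, `study_hits`, `study_size`,
#'   `background_hits`, `background_size`, `fold_enrichment`, `pvalue`,
#'   `padj`, `significant`.
#' @export
enrich <- function(study, background, categories, alpha = 0.05) {
  study <- unique(study)
  background <- unique(background)
  off <- setdiff(study, background)
  if (length(off)) {
    stop("study gene(s) absent from background: ",
         paste(off, collapse = ", "))
  }
  categories <- categories[categories$gene %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(study)
  terms <- sort(unique(categories$term))
  K <- vapply(terms, function(t) {
    length(unique(categories$gene[categories$term == t]))
  }, integer(1))
  k <- vapply(terms, function(t) {
    sum(unique(categories$gene[categories$term == t]) %in% study)
  }, integer(1))
  fold <- ifelse(K > 0, (k / n) / (K / N), NA_real_)
  tested <- k >= 1L
  p <- rep(NA_real_, length(terms))
  p[tested] <- stats::phyper(k[tested] - 1L, K[tested], N - K[tested], n,
                             lower.tail = FALSE)
  padj <- bh_adjust(p)
  out <- data.frame(term = terms, study_hits = k, study_size = n,
                    background_hits = K, background_size = N,
                    fold_enrichment = fold, pvalue = p, padj = padj,
                    significant = !is.na(padj) & padj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$padj, out$pvalue, out$term, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  a <- attr(x, "alpha")
  cat(sprintf("Hypergeometric enrichment: %d terms (%d tested), %d significant at padj < %g\n",
              nrow(x), sum(!is.na(x$pvalue)), sum(x$significant), a))
  top <- utils::head(x[!is.na(x$pvalue), ], 5L)
  if (nrow(top)) {
    print.data.frame(top[, c("term", "study_hits", "background_hits",
                             "fold_enrichment", "pvalue", "padj")],
                     digits = 3, row.names = FALSE)
  }
  invisible(x)
}
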