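#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2)`, with moments using
#' the n denominator (Lin's original definition; with 4-point profiles the
#' n vs n-1 choice is material). Both profiles constant and equal gives 1;
#' both constant and unequal gives 0; one constant profile is handled by
#' the formula (zero covariance).
#'
#' @param x,y numeric vectors of equal length >= 2 with finite entries.
#' @return concordance in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 2L) stop("profiles must have length >= 2")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("profiles must contain only finite values")
  }
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(1)  # both constant with equal means
  2 * cxy / denom
}

#' Concordance-based low-concordance (polarized) calls
#'
#' Computes Lin's CCC between the oral and physal time profiles of every
#' gene and flags differentially expressed genes whose concordance falls
#' strictly below the cutoff (default 0.6) as low-concordance, the
#' operational definition of side-specific expression. Non-DE genes carry
#' their CCC but no flag.
#'
#' @param profiles [side_profiles()] result.
#' @param de_flags logical vector (per gene, in profile row order) marking
#'   DE genes; `NULL` treats every gene as eligible.
#' @param cutoff concordance cutoff (strict `<`).
#' @param transform `"linear"` (replicate-mean normalized counts, the
#'   default) or `"log2p1"` (`log2(x + 1)` before the CCC).
#' @return data frame with `gene`, `ccc`, `low_concordance_flag` (`NA` for
#'   non-DE genes).
#' @export
classify_concordance <- function(profiles, de_flags = NULL, cutoff = 0.6,
                                 transform = c("linear", "log2p1")) {
  transform <- match.arg(transform)
  o <- profiles$oral
  p <- profiles$physa
  if (is.null(o) || is.null(p)) stop("profiles must carry both sides")
  if (transform == "log2p1") {
    o <- log2(o + 1)
    p <- log2(p + 1)
  }
  ccc <- vapply(seq_len(nrow(o)), function(i) lin_ccc(o[i, ], p[i, ]),
                numeric(1))
  if (is.null(de_flags)) de_flags <- rep(TRUE, nrow(o))
  flag <- ifelse(de_flags, ccc < cutoff, NA)
  data.frame(gene = rownames(o), ccc = ccc, low_concordance_flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

trend_of_profile <- function(a, fold) {
  r <- a[-1L] / a[1L]
  if (all(r >= fold)) "always_up"
  else if (all(1 / r >= fold)) "always_down"
  else "other"
}

#' Always-up / always-down / other trend taxonomy
#'
#' A gene is `always_up` on a side if every post-cut time point is at least
#' `fold` (default 1.6) times hour 0, `always_down` if every time point is
#' at least `fold` times lower, and `other` otherwise (inclusive
#' thresholds). The per-gene side category is `both` when the same trend
#' holds on both sides and `oral_only` / `physa_only` when a trend holds on
#' exactly one side; genes trending on neither side (or discordantly, up
#' one side and down the other) carry no category.
#'
#' @param profiles [side_profiles()] result.
#' @param fold fold-change threshold (>= 1).
#' @param pseudocount added to every profile value before ratios.
#' @return data frame with `gene`, `trend_oral`, `trend_physa`,
#'   `side_trend_category`.
#' @export
trend_labels <- function(profiles, fold = 1.6, pseudocount = 1) {
  ao <- profiles$oral + pseudocount
  ap <- profiles$physa + pseudocount
  to <- apply(ao, 1L, trend_of_profile, fold = fold)
  tp <- apply(ap, 1L, trend_of_profile, fold = fold)
  cat_of <- function(a, b) {
    if (a != "other" && a == b) "both"
    else if (a != "other" && b == "other") "oral_only"
    else if (b != "other" && a == "other") "physa_only"
    else NA_character_
  }
  data.frame(gene = rownames(ao), trend_oral = to, trend_physa = tp,
             side_trend_category = mapply(cat_of, to, tp, USE.NAMES = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Consecutive-interval up/down calls
#'
#' Compares each time point with the previous one: a gene is `up` over an
#' interval when the ratio reaches `fold`, `down` when it falls to
#' `1/fold`, and `flat` otherwise. Also tallies genes per (side, interval,
#' direction), the per-interval summary of transcriptome-wide change.
#'
#' @inheritParams trend_labels
#' @return list with `calls` (per-side character matrices, genes x
#'   intervals) and `counts` (data frame `side`, `interval`, `direction`,
#'   `n`). Intervals are labelled `"t0-t8"` style.
#' @export
interval_changes <- function(profiles, fold = 1.6, pseudocount = 1) {
  tp <- profiles$time_points
  labels <- sprintf("t%g-t%g", tp[-length(tp)], tp[-1L])
  call_side <- function(m) {
    a <- m + pseudocount
    r <- a[, -1L, drop = FALSE] / a[, -ncol(a), drop = FALSE]
    out <- matrix("flat", nrow(r), ncol(r),
                  dimnames = list(rownames(m), labels))
    out[r >= fold] <- "up"
    out[r <= 1 / fold] <- "down"
    out
  }
  calls <- list(oral = call_side(profiles$oral),
                physa = call_side(profiles$physa))
  counts <- do.call(rbind, lapply(names(calls), function(sd) {
    do.call(rbind, lapply(seq_along(labels), function(k) {
      data.frame(side = sd, interval = labels[k],
                 direction = c("up", "down", "flat"),
                 n = c(sum(calls[[sd]][, k] == "up"),
                       sum(calls[[sd]][, k] == "down"),
                       sum(calls[[sd]][, k] == "flat")),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(calls = calls, counts = counts)
}

#' Side-of-higher-activity and maximal-change summaries
#'
#' Per gene: the side expressed higher at a strict majority of time points
#' (ties broken by the larger profile sum, then reported as `"tie"`); the
#' hour, side and signed log2 magnitude of the largest absolute log2 change
#' of any time point relative to hour 0; and the same for consecutive
#' intervals (the interval reported by its end hour). Ties in the argmax
#' are broken deterministically: oral before physa, then the earlier hour.
#'
#' @inheritParams trend_labels
#' @return data frame with `gene`, `higher_activity_side`,
#'   `tmax_vs_t0_hour`, `tmax_vs_t0_side`, `tmax_vs_t0_log2fc`,
#'   `interval_max_hour`, `interval_max_side`, `interval_max_log2fc`.
#' @export
change_summaries <- function(profiles, pseudocount = 1) {
  tp <- profiles$time_points
  nt <- length(tp)
  ao <- profiles$oral + pseudocount
  ap <- profiles$physa + pseudocount
  n <- nrow(ao)

  n_oral_higher <- rowSums(ao > ap)
  n_physa_higher <- rowSums(ap > ao)
  has <- ifelse(n_oral_higher > nt / 2, "oral",
                ifelse(n_physa_higher > nt / 2, "physa",
                       ifelse(rowSums(ao) > rowSums(ap), "oral",
                              ifelse(rowSums(ap) > rowSums(ao), "physa",
                                     "tie"))))

  pick_max <- function(l2o, l2p, hours) {
    # candidates ordered oral-first then ascending hour: first max wins
    cand_l2 <- cbind(l2o, l2p)
    cand_side <- rep(c("oral", "physa"), each = length(hours))
    cand_hour <- rep(hours, 2L)
    idx <- max.col(abs(cand_l2), ties.method = "first")
    data.frame(hour = cand_hour[idx], side = cand_side[idx],
               log2fc = cand_l2[cbind(seq_len(nrow(cand_l2)), idx)],
               stringsAsFactors = FALSE)
  }

  vs0 <- pick_max(log2(ao[, -1L, drop = FALSE] / ao[, 1L]),
                  log2(ap[, -1L, drop = FALSE] / ap[, 1L]),
                  tp[-1L])
  ivl <- pick_max(log2(ao[, -1L, drop = FALSE] / ao[, -nt, drop = FALSE]),
                  log2(ap[, -1L, drop = FALSE] / ap[, -nt, drop = FALSE]),
                  tp[-1L])

  data.frame(gene = rownames(ao),
             higher_activity_side = has,
             tmax_vs_t0_hour = vs0$hour,
             tmax_vs_t0_side = vs0$side,
             tmax_vs_t0_log2fc = vs0$log2fc,
             interval_max_hour = ivl$hour,
             interval_max_side = ivl$side,
             interval_max_log2fc = ivl$log2fc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the per-gene polarization record table
#'
#' Combines the DE screen, concordance calls, trend labels and max-change
#' summaries into the standard per-gene results table (one row per gene,
#' the columns written by [write_results_table()]).
#'
#' @param profiles [side_profiles()] result.
#' @param de_result [lrt_time_effect()] result (matching gene order).
#' @param annotation optional named character vector of free-text gene
#'   annotations.
#' @param cutoff,transform passed to [classify_concordance()].
#' @param fold,pseudocount passed to the trend and summary rules.
#' @return data frame with the standard result columns.
#' @export
polarize <- function(profiles, de_result, annotation = NULL,
                     cutoff = 0.6, fold = 1.6, pseudocount = 1,
                     transform = "linear") {
  genes <- rownames(profiles$oral)
  stopifnot(identical(genes, de_result$gene))
  conc <- classify_concordance(profiles, de_flags = de_result$de_flag,
                               cutoff = cutoff, transform = transform)
  trends <- trend_labels(profiles, fold = fold, pseudocount = pseudocount)
  sums <- change_summaries(profiles, pseudocount = pseudocount)
  ann <- if (is.null(annotation)) rep("", length(genes)) else {
    unname(annotation[genes])
  }
  data.frame(gene = genes,
             annotation = ifelse(is.na(ann), "", ann),
             lrt_stat = de_result$lrt_stat,
             pvalue = de_result$pvalue,
             padj = de_result$padj,
             de_flag = de_result$de_flag,
             ccc = conc$ccc,
             low_concordance_flag = conc$low_concordance_flag,
             higher_activity_side = sums$higher_activity_side,
             tmax_vs_t0_hour = sums$tmax_vs_t0_hour,
             tmax_vs_t0_side = sums$tmax_vs_t0_side,
             tmax_vs_t0_log2fc = sums$tmax_vs_t0_log2fc,
             interval_max_hour = sums$interval_max_hour,
             interval_max_side = sums$interval_max_side,
             interval_max_log2fc = sums$interval_max_log2fc,
             trend_oral = trends$trend_oral,
             trend_physa = trends$trend_physa,
             side_trend_category = trends$side_trend_category,
             row.names = NULL, stringsAsFactors = FALSE)
}
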