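#' Configure a synthetic two-sided regeneration time course
#'
#' Builds a validated configuration for [simulate_counts()]. The defaults
#' emulate the design of the regeneration study the package targets:
#' 2 regeneration sides (oral, physa) x 4 time points (0, 8, 24, 72 h) x
#' 2 replicates = 16 samples, negative-binomial counts with a gene-wise
#' dispersion trend and per-sample size factors, and planted gene classes
#' with known ground truth.
#'
#' @param n_genes number of genes to simulate.
#' @param time_points strictly increasing hours, must include 0.
#' @param n_replicates replicates per (side, time) cell.
#' @param class_proportions named fractions over the five gene classes
#'   `null`, `shared`, `oral_specific`, `physa_specific`, `complex`;
#'   must sum to 1.
#' @param baseline_log_mean_range interval on the natural-log scale from
#'   which per-gene baseline means are drawn (uniform in log).
#' @param effect_size_log2 magnitude (log2) of each step of the planted
#'   temporal random-walk trajectories.
#' @param dispersion_params named `c(a0, a1)` of the gene dispersion trend
#'   `alpha = a0 + a1 / mu` evaluated at the gene's baseline mean.
#' @param size_factor_range interval for per-sample library-size
#'   multipliers, drawn log-uniformly.
#' @param down_bias probability that a trajectory step goes down; 0.5 gives
#'   symmetric up/down dynamics.
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   simulations.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_counts()], [simulate_annotation()]
#' @export
simulation_config <- function(n_genes = 5000,
                              time_points = c(0, 8, 24, 72),
                              n_replicates = 2,
                              class_proportions = c(null = 0.60,
                                                    shared = 0.20,
                                                    oral_specific = 0.08,
                                                    physa_specific = 0.08,
                                                    complex = 0.04),
                              baseline_log_mean_range = c(log(50), log(500)),
                              effect_size_log2 = 2,
                              dispersion_params = c(a0 = 0.05, a1 = 1),
                              size_factor_range = c(0.7, 1.4),
                              down_bias = 0.5,
                              seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1 ||
      n_genes != round(n_genes)) {
    stop("invalid configuration: 'n_genes' must be a positive integer")
  }
  if (length(time_points) < 2L || any(diff(time_points) <= 0)) {
    stop("invalid configuration: 'time_points' must be strictly increasing")
  }
  if (time_points[1L] != 0) {
    stop("invalid configuration: 'time_points' must include 0 as the first point")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1 ||
      n_replicates != round(n_replicates)) {
    stop("invalid configuration: 'n_replicates' must be a positive integer")
  }
  classes <- c("null", "shared", "oral_specific", "physa_specific", "complex")
  if (!setequal(names(class_proportions), classes)) {
    stop("invalid configuration: 'class_proportions' must be named over {",
         paste(classes, collapse = ", "), "}")
  }
  class_proportions <- class_proportions[classes]
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    stop("invalid configuration: 'class_proportions' must be non-negative and sum to 1")
  }
  for (fld in c("baseline_log_mean_range", "size_factor_range")) {
    rng <- get(fld)
    if (length(rng) != 2L || rng[1L] > rng[2L]) {
      stop("invalid configuration: '", fld, "' must be an interval lower <= upper")
    }
  }
  if (any(size_factor_range <= 0)) {
    stop("invalid configuration: 'size_factor_range' must be positive")
  }
  if (effect_size_log2 < 0) {
    stop("invalid configuration: 'effect_size_log2' must be >= 0")
  }
  if (!setequal(names(dispersion_params), c("a0", "a1")) ||
      any(dispersion_params < 0)) {
    stop("invalid configuration: 'dispersion_params' must be named c(a0, a1), both >= 0")
  }
  if (down_bias < 0 || down_bias > 1) {
    stop("invalid configuration: 'down_bias' must be in [0, 1]")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         time_points = as.numeric(time_points),
         n_replicates = as.integer(n_replicates),
         sides = c("oral", "physa"),
         class_proportions = class_proportions,
         baseline_log_mean_range = baseline_log_mean_range,
         effect_size_log2 = effect_size_log2,
         dispersion_params = dispersion_params[c("a0", "a1")],
         size_factor_range = size_factor_range,
         down_bias = down_bias,
         seed = as.integer(seed)),
    class = "simulation_config")
}

# Largest-remainder apportionment of n items to fractions p (sums to 1).
largest_remainder <- function(n, p) {
  exact <- n * p
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    frac <- exact - base
    # stable: ties broken by position order
    add <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Simulate a negative-binomial count matrix with planted gene classes
#'
#' Draws raw counts for the 2-side x multi-time x replicate design under a
#' negative-binomial model `Var = mu + alpha * mu^2`, with per-sample size
#' factors applied multiplicatively to the true means. Temporal signal is
#' planted per gene class as a piecewise-constant log2 random walk:
#' `null` genes are flat on both sides, `shared` genes follow the same
#' trajectory on both sides, `oral_specific` / `physa_specific` genes move
#' only on the named side, and `complex` genes follow mirrored
#' (sign-crossing) trajectories on the two sides.
#'
#' @param config a [simulation_config()] object.
#'
#' @return A list of class `polarseq_sim` with components
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples.}
#'     \item{design}{data frame with columns `sample`, `side`, `time`,
#'       `replicate`.}
#'     \item{truth}{ground truth: per-gene `class`, per-gene `dispersion`
#'       and `baseline_mean`, per-sample `size_factors`, and `true_means`,
#'       a genes x sides x times array of true (unscaled) means.}
#'   }
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("'config' must be created by simulation_config()")
  }
  set.seed(config$seed)
  n <- config$n_genes
  tp <- config$time_points
  nt <- length(tp)
  sides <- config$sides

  class_n <- largest_remainder(n, config$class_proportions)
  cls <- rep(names(config$class_proportions), class_n)
  gene_ids <- sprintf("g%05d", seq_len(n))
  names(cls) <- gene_ids

  blr <- config$baseline_log_mean_range
  baseline <- exp(stats::runif(n, blr[1L], blr[2L]))
  a <- config$dispersion_params
  alpha <- unname(a["a0"] + a["a1"] / baseline)

  # planted log2 trajectories: random-walk steps of fixed magnitude
  step_sign <- matrix(
    sample(c(-1, 1), n * (nt - 1L), replace = TRUE,
           prob = c(config$down_bias, 1 - config$down_bias)),
    nrow = n)
  traj <- cbind(0, t(apply(step_sign * config$effect_size_log2, 1L, cumsum)))

  d_oral <- matrix(0, n, nt)
  d_physa <- matrix(0, n, nt)
  d_oral[cls %in% c("shared", "oral_specific", "complex"), ] <-
    traj[cls %in% c("shared", "oral_specific", "complex"), , drop = FALSE]
  d_physa[cls == "shared", ] <- traj[cls == "shared", , drop = FALSE]
  d_physa[cls == "physa_specific", ] <- traj[cls == "physa_specific", , drop = FALSE]
  d_physa[cls == "complex", ] <- -traj[cls == "complex", , drop = FALSE]

  true_means <- array(0, dim = c(n, 2L, nt),
                      dimnames = list(gene_ids, sides, paste0("t", tp)))
  true_means[, 1L, ] <- baseline * 2^d_oral
  true_means[, 2L, ] <- baseline * 2^d_physa

  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        time = tp, side = sides,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("side", "time", "replicate")]
  design$sample <- sprintf("%s_t%g_r%d", design$side, design$time,
                           design$replicate)
  design <- design[, c("sample", "side", "time", "replicate")]
  ns <- nrow(design)

  sfr <- config$size_factor_range
  size_factors <- exp(stats::runif(ns, log(sfr[1L]), log(sfr[2L])))
  names(size_factors) <- design$sample

  counts <- matrix(0L, n, ns, dimnames = list(gene_ids, design$sample))
  poislike <- alpha <= 0
  for (j in seq_len(ns)) {
    side_idx <- match(design$side[j], sides)
    t_idx <- match(design$time[j], tp)
    mu <- true_means[, side_idx, t_idx] * size_factors[j]
    y <- numeric(n)
    if (any(poislike)) y[poislike] <- stats::rpois(sum(poislike), mu[poislike])
    if (any(!poislike)) {
      y[!poislike] <- stats::rnbinom(sum(!poislike), mu = mu[!poislike],
                                     size = 1 / alpha[!poislike])
    }
    counts[, j] <- as.integer(y)
  }

  structure(
    list(counts = counts,
         design = design,
         truth = list(class = cls,
                      true_means = true_means,
                      baseline_mean = stats::setNames(baseline, gene_ids),
                      dispersion = stats::setNames(alpha, gene_ids),
                      size_factors = size_factors)),
    class = "polarseq_sim")
}

#' @export
print.polarseq_sim <- function(x, ...) {
  cat("Synthetic regeneration time-course dataset\n")
  cat(sprintf("  %d genes x %d samples (%d sides x %d time points x %d replicates)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$design$side)),
              length(unique(x$design$time)),
              max(x$design$replicate)))
  tab <- table(x$truth$class)
  cat("  gene classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a toy gene-to-category annotation with planted enrichment
#'
#' Generates a GO-style gene/term map for enrichment testing. A fraction of
#' terms is "enriched": their member genes are sampled with odds weighted
#' towards side-specific-class genes; the remaining terms draw genes
#' uniformly.
#'
#' @param truth the `truth` component of a [simulate_counts()] result (or
#'   the full `polarseq_sim` object).
#' @param n_terms number of terms to create.
#' @param enriched_term_fraction fraction of terms with planted enrichment.
#' @param seed RNG seed.
#' @param term_size genes per term.
#' @param odds_ratio sampling-odds multiplier for side-specific-class genes
#'   within enriched terms.
#'
#' @return list with `map` (data frame of `gene`, `term` pairs) and
#'   `enriched_terms` (character vector of truly-enriched term ids).
#' @export
simulate_annotation <- function(truth, n_terms, enriched_term_fraction,
                                seed = 1L, term_size = 50L, odds_ratio = 8) {
  if (inherits(truth, "polarseq_sim")) truth <- truth$truth
  if (n_terms < 1) stop("invalid configuration: 'n_terms' must be >= 1")
  if (enriched_term_fraction < 0 || enriched_term_fraction > 1) {
    stop("invalid configuration: 'enriched_term_fraction' must be in [0, 1]")
  }
  set.seed(seed)
  genes <- names(truth$class)
  term_size <- min(term_size, length(genes))
  n_enriched <- round(enriched_term_fraction * n_terms)
  term_ids <- sprintf("term%03d", seq_len(n_terms))
  enriched <- term_ids[seq_len(n_enriched)]
  w_enriched <- ifelse(truth$class %in% c("oral_specific", "physa_specific"),
                       odds_ratio, 1)
  pick <- function(weights) sample(genes, term_size, prob = weights)
  members <- lapply(term_ids, function(tid) {
    if (tid %in% enriched) pick(w_enriched) else sample(genes, term_size)
  })
  map <- data.frame(gene = unlist(members),
                    term = rep(term_ids, lengths(members)),
                    stringsAsFactors = FALSE)
  list(map = map, enriched_terms = enriched)
}
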