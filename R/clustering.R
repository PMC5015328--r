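#' Log2 transform and gene-wise z-scoring for clustering
#'
#' Zeros are converted to 1 before the log2 transform, then each gene row
#' is centered to mean zero and scaled to unit standard deviation. Rows
#' constant after the transform have no defined z-score and are excluded
#' with a warning.
#'
#' @param normalized normalized count matrix (genes x samples or genes x
#'   time points), values >= 0.
#' @return z-scored matrix; excluded gene ids in attribute `"excluded"`.
#' @export
preprocess_for_clustering <- function(normalized) {
  if (any(normalized < 0)) stop("normalized values must be >= 0")
  x <- normalized
  x[x == 0] <- 1
  l <- log2(x)
  sds <- apply(l, 1L, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    warning(sprintf("excluding %d gene(s) constant after log2 transform",
                    sum(!keep)))
  }
  l <- l[keep, , drop = FALSE]
  z <- (l - rowMeans(l)) / sds[keep]
  attr(z, "excluded") <- rownames(normalized)[!keep]
  z
}

#' Hierarchical clustering with Pearson dissimilarity and complete linkage
#'
#' Items (genes or samples) are clustered on `d = 1 - r` where `r` is the
#' Pearson correlation between item vectors; agglomeration uses complete
#' linkage. If `k` is given the tree is cut into exactly `k` clusters.
#'
#' @param mat numeric matrix (genes in rows, samples in columns), already
#'   preprocessed for gene-wise clustering.
#' @param axis `"genes"` (cluster rows) or `"samples"` (cluster columns).
#' @param k optional number of clusters to cut the tree into.
#' @return list of class `hier_clustering` with the `hclust` tree, the
#'   `clusters` assignment (or `NULL`), `axis` and `k`.
#' @export
hierarchical_cluster <- function(mat, axis = c("genes", "samples"),
                                 k = NULL) {
  axis <- match.arg(axis)
  m <- if (axis == "samples") t(mat) else mat
  if (nrow(m) < 2L) stop("need at least 2 items to cluster")
  if (!is.null(k) && (k < 1L || k > nrow(m))) {
    stop("k must be between 1 and the number of items")
  }
  d <- stats::as.dist(1 - stats::cor(t(m)))
  tree <- stats::hclust(d, method = "complete")
  clusters <- if (!is.null(k)) stats::cutree(tree, k = k) else NULL
  structure(list(tree = tree, clusters = clusters, axis = axis, k = k),
            class = "hier_clustering")
}

#' @export
print.hier_clustering <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (%s axis): %d items, Pearson dissimilarity, complete linkage\n",
              x$axis, length(x$tree$order)))
  if (!is.null(x$clusters)) {
    cat(sprintf("  cut into k = %d clusters of sizes %s\n", x$k,
                paste(table(x$clusters), collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a linkage tree as Newick
#'
#' @param clustering a [hierarchical_cluster()] result (or `hclust` tree).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_newick <- function(clustering, path) {
  tree <- if (inherits(clustering, "hier_clustering")) clustering$tree
          else clustering
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

# All sign trajectories over the consecutive intervals of a time grid;
# profile values are the cumulative sums (starting at 0).
candidate_profiles <- function(n_times) {
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), n_times - 1L),
                                 KEEP.OUT.ATTRS = FALSE))
  colnames(signs) <- NULL
  values <- cbind(0, t(apply(signs, 1L, cumsum)))
  list(signs = signs, values = values,
       shape = apply(signs, 1L, paste, collapse = ","))
}

# rows standardized to zero mean, unit Euclidean norm; constant rows -> 0
row_unitize <- function(m) {
  c_ <- m - rowMeans(m)
  nrm <- sqrt(rowSums(c_^2))
  nrm[nrm == 0] <- Inf
  c_ / nrm
}

# per-row random permutation of the columns of m, vectorized
permute_rows <- function(m) {
  n <- nrow(m); p <- ncol(m)
  # sort cell indices by row then a random key: each block of p consecutive
  # entries of ord holds one row's cells in random order
  ord <- order(rep(seq_len(n), p), stats::runif(n * p))
  out <- t(matrix(m[ord], nrow = p))
  dimnames(out) <- dimnames(m)
  out
}

#' Model-profile clustering of short time-series profiles
#'
#' A simplified short-time-series (STEM-style) partition clustering:
#' candidate model profiles are all sign trajectories over the consecutive
#' intervals (27 profiles for 4 time points); when there are more
#' candidates than `max_profiles`, the most mutually distant subset is kept
#' by greedy farthest-point selection on profile correlation (the flat
#' profile is always retained as the starting point). Each gene is assigned
#' to the candidate maximizing the Pearson correlation with its
#' standardized profile (ties to the lower profile id; constant genes go to
#' the flat profile). Profile significance is a permutation test shuffling
#' time labels within each gene and comparing observed assignment counts to
#' the permutation distribution, BH-corrected across profiles.
#'
#' @param profile_mat genes x time points matrix of per-side profiles
#'   (e.g. one side of a [side_profiles()] result).
#' @param max_profiles maximum number of model profiles (default 20).
#' @param n_permutations permutations for the significance test.
#' @param seed RNG seed for the permutations.
#' @param transform `"log2p1"` (default) applies `log2(x + 1)` before
#'   standardizing, so that multiplicative expression changes become the
#'   linear shapes the sign-trajectory profiles describe; `"linear"` uses
#'   the profiles as given.
#' @return list of class `profile_clustering` with `profiles` (id, shape,
#'   one value column per time point), `assignment` (gene, profile_id),
#'   `counts`, `pvalue`, `padj` per profile.
#' @export
profile_cluster <- function(profile_mat, max_profiles = 20L,
                            n_permutations = 1000L, seed = 1L,
                            transform = c("log2p1", "linear")) {
  transform <- match.arg(transform)
  if (transform == "log2p1") {
    if (any(profile_mat < 0)) stop("log2p1 transform needs values >= 0")
    profile_mat <- log2(profile_mat + 1)
  }
  nt <- ncol(profile_mat)
  if (nt < 3L) stop("profile clustering needs >= 3 time points")
  cand <- candidate_profiles(nt)
  m <- nrow(cand$values)
  flat_id <- which(rowSums(abs(cand$signs)) == 0)

  keep <- seq_len(m)
  if (m > max_profiles) {
    cu <- row_unitize(cand$values)
    dmat <- 1 - tcrossprod(cu)         # flat row -> distance 1 to all
    sel <- flat_id
    while (length(sel) < max_profiles) {
      mind <- apply(dmat[, sel, drop = FALSE], 1L, min)
      mind[sel] <- -Inf
      sel <- c(sel, which.max(mind))   # which.max ties -> lower id
    }
    keep <- sort(sel)
  }
  values <- cand$values[keep, , drop = FALSE]
  shapes <- cand$shape[keep]
  ids <- sprintf("P%02d", keep)
  flat_pos <- match(flat_id, keep)

  cu <- row_unitize(values)
  gz <- row_unitize(profile_mat)
  corr <- tcrossprod(gz, cu)
  constant <- rowSums(gz != 0) == 0
  if (!is.na(flat_pos) && any(constant)) {
    corr[constant, ] <- 0
    corr[constant, flat_pos] <- 1
  }
  assign_idx <- max.col(corr, ties.method = "first")
  obs <- tabulate(assign_idx, nbins = nrow(values))

  set.seed(seed)
  exceed <- integer(nrow(values))
  for (b in seq_len(n_permutations)) {
    pz <- permute_rows(gz)
    pc <- tcrossprod(pz, cu)
    if (!is.na(flat_pos) && any(constant)) {
      pc[constant, ] <- 0
      pc[constant, flat_pos] <- 1
    }
    cnt <- tabulate(max.col(pc, ties.method = "first"),
                    nbins = nrow(values))
    exceed <- exceed + (cnt >= obs)
  }
  pval <- (1 + exceed) / (1 + n_permutations)
  padj <- bh_adjust(pval)

  profiles <- data.frame(profile_id = ids, shape = shapes,
                         stringsAsFactors = FALSE)
  profiles <- cbind(profiles,
                    stats::setNames(as.data.frame(values),
                                    paste0("v", seq_len(nt))))
  structure(
    list(profiles = profiles,
         assignment = data.frame(gene = rownames(profile_mat),
                                 profile_id = ids[assign_idx],
                                 row.names = NULL, stringsAsFactors = FALSE),
         counts = stats::setNames(obs, ids),
         pvalue = stats::setNames(pval, ids),
         padj = stats::setNames(padj, ids)),
    class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("Model-profile clustering: %d genes over %d model profiles\n",
              nrow(x$assignment), nrow(x$profiles)))
  top <- order(-x$counts)[seq_len(min(5L, length(x$counts)))]
  for (i in top) {
    cat(sprintf("  %s (%s): %d genes, padj = %.3g\n",
                names(x$counts)[i], x$profiles$shape[i], x$counts[i],
                x$padj[i]))
  }
  invisible(x)
}
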