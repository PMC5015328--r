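# Tabular interchange: TSV only (tab-separated, UTF-8, "." decimal).

RESULT_COLUMNS <- c("gene", "annotation", "lrt_stat", "pvalue", "padj",
                    "de_flag", "ccc", "low_concordance_flag",
                    "higher_activity_side", "tmax_vs_t0_hour",
                    "tmax_vs_t0_side", "tmax_vs_t0_log2fc",
                    "interval_max_hour", "interval_max_side",
                    "interval_max_log2fc", "trend_oral", "trend_physa",
                    "side_trend_category")

#' Read a raw count matrix from TSV
#'
#' First column holds gene identifiers, remaining columns one sample each
#' (header row of sample ids). Entries must be non-negative integers.
#'
#' @param path path to a tab-separated file.
#' @return integer matrix with gene ids as row names and sample ids as
#'   column names.
#' @export
read_count_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("count matrix must have at least 2 sample columns")
  gene_ids <- as.character(tab[[1L]])
  sample_ids <- colnames(tab)[-1L]
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop("duplicated sample column(s): ", paste(unique(dup_s), collapse = ", "))
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) {
    stop("duplicated gene id(s): ", paste(unique(dup_g), collapse = ", "))
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m)))
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric count at row %d (gene %s, sample %s)",
                 bad[1L, 1L], gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  bad <- which(m < 0 | m != round(m) | is.na(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid count at row %d: gene %s, sample %s (value %s); counts must be non-negative integers",
      bad[1L, 1L], gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
      format(m[bad[1L, , drop = FALSE]])))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' Read and validate a sample design table
#'
#' Expects columns `sample`, `side`, `time`, `replicate`. Side labels are
#' normalized case-insensitively to `oral` / `physa`; time is parsed as a
#' number of hours. Sample ids must match the count matrix columns exactly.
#'
#' @param path path to the design TSV.
#' @param count_matrix matrix returned by [read_count_matrix()] (or any
#'   matrix with sample column names).
#' @return validated design data frame.
#' @export
read_design <- function(path, count_matrix) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "side", "time", "replicate")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) stop("design is missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- d[, need]
  d$sample <- as.character(d$sample)
  d$side <- tolower(as.character(d$side))
  bad_side <- setdiff(unique(d$side), c("oral", "physa"))
  if (length(bad_side)) {
    stop("unknown side label(s): ", paste(bad_side, collapse = ", "),
         " (expected oral or physa)")
  }
  d$time <- as.numeric(d$time)
  if (anyNA(d$time)) stop("non-numeric time value in design")
  d$replicate <- as.integer(d$replicate)
  if (any(d$replicate < 1L)) stop("replicate must be an integer >= 1")
  validate_design(d, count_matrix)
  d
}

validate_design <- function(design, counts) {
  extra <- setdiff(design$sample, colnames(counts))
  if (length(extra)) {
    stop("design sample(s) absent from count matrix: ",
         paste(extra, collapse = ", "))
  }
  missing <- setdiff(colnames(counts), design$sample)
  if (length(missing)) {
    stop("count-matrix sample(s) absent from design: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(design$sample)) {
    stop("duplicated sample id(s) in design: ",
         paste(unique(design$sample[duplicated(design$sample)]),
               collapse = ", "))
  }
  if (length(unique(design$time)) < 2L) {
    stop("design must contain at least 2 distinct time points")
  }
  cells <- table(design$side, design$time)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("design cell (%s, %s h) has no sample",
                 rownames(cells)[empty[1L]], colnames(cells)[empty[2L]]))
  }
  invisible(design)
}

#' Read a gene-to-category annotation map
#'
#' Two-column TSV of (gene, term) pairs, optionally with a header row named
#' `gene` / `term`. Duplicate pairs are rejected.
#'
#' @param path path to the category TSV.
#' @return data frame with columns `gene` and `term`.
#' @export
read_category_map <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1L,
                             stringsAsFactors = FALSE)
  has_header <- identical(tolower(as.character(first[1L, 1L])), "gene")
  m <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(m) < 2L) stop("category map must have two columns: gene, term")
  m <- m[, 1:2]
  colnames(m) <- c("gene", "term")
  m$gene <- as.character(m$gene)
  m$term <- as.character(m$term)
  if (anyDuplicated(m)) stop("duplicated (gene, term) pair(s) in category map")
  m
}

#' Write the per-gene results table
#'
#' Emits the combined DE + polarization record per gene as TSV with a
#' stable column order, sorted by ascending adjusted p-value then gene id
#' (missing padj last).
#'
#' @param records data frame carrying at least the standard result columns
#'   (`gene`, `annotation`, `lrt_stat`, `pvalue`, `padj`, `de_flag`, `ccc`,
#'   `low_concordance_flag`, trend and max-change summaries).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results_table <- function(records, path) {
  miss <- setdiff(RESULT_COLUMNS, colnames(records))
  if (length(miss)) stop("records are missing column(s): ",
                         paste(miss, collapse = ", "))
  records <- records[, RESULT_COLUMNS, drop = FALSE]
  ord <- order(records$padj, records$gene, na.last = TRUE)
  records <- records[ord, , drop = FALSE]
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path path to the results TSV.
#' @return data frame in the standard column order.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

write_count_matrix <- function(counts, path) {
  out <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
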