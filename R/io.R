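#' Read an expression matrix and sample sheet from TSV files
#'
#' The matrix TSV has genes in rows (first column `gene_id`) and samples
#' in columns; the sample sheet TSV has columns `sample_id`, `condition`,
#' `zt`, `replicate`. Every matrix column must be covered by a sample
#' sheet row. Samples are re-ordered to (condition, zt, replicate).
#'
#' @param matrixPath path to the gene x sample abundance TSV.
#' @param sheetPath path to the sample-sheet TSV.
#' @return a validated [CircadianExperiment-class].
#' @export
readExpressionMatrix <- function(matrixPath, sheetPath) {
  mat <- utils::read.delim(matrixPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (colnames(mat)[1] != "gene_id")
    stop("schema error: first matrix column must be 'gene_id'")
  if (anyDuplicated(mat$gene_id))
    stop("data error: duplicate gene id in matrix")
  sheet <- utils::read.delim(sheetPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "zt", "replicate")
  if (!all(need %in% colnames(sheet)))
    stop("schema error: sample sheet must have columns ",
         paste(need, collapse = ", "))
  samples <- colnames(mat)[-1]
  missing <- setdiff(samples, sheet$sample_id)
  if (length(missing))
    stop("schema error: matrix column(s) without sample-sheet row: ",
         paste(missing, collapse = ", "))
  sheet <- sheet[match(samples, sheet$sample_id), ]
  vals <- as.matrix(mat[, -1, drop = FALSE])
  if (anyNA(vals)) stop("data error: missing abundance values")
  if (any(vals < 0)) stop("data error: negative abundance value")
  rownames(vals) <- mat$gene_id
  CircadianExperiment(vals, condition = sheet$condition, zt = sheet$zt,
                      replicate = sheet$replicate)
}

#' Write a CircadianExperiment as matrix + sample-sheet TSVs
#'
#' @param ce a [CircadianExperiment-class].
#' @param matrixPath,sheetPath output TSV paths.
#' @param truthPath optional path for the planted ground-truth TSV
#'   (written only when the object carries one).
#' @return invisibly, the paths written.
#' @export
writeExpressionMatrix <- function(ce, matrixPath, sheetPath,
                                  truthPath = NULL) {
  .writeTsv(data.frame(gene_id = rownames(ce), abundance(ce),
                       check.names = FALSE), matrixPath)
  .writeTsv(data.frame(sample_id = colnames(ce),
                       condition = condition(ce), zt = zt(ce),
                       replicate = replicateId(ce)), sheetPath)
  paths <- c(matrixPath, sheetPath)
  tr <- geneTruth(ce)
  if (!is.null(truthPath) && !is.null(tr)) {
    .writeTsv(as.data.frame(tr), truthPath)
    paths <- c(paths, truthPath)
  }
  invisible(paths)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read / write a plain-text gene list (one id per line)
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname readGeneList
#' @param genes character vector of gene ids to write.
#' @export
writeGeneList <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Expression filter for two-group comparisons
#'
#' A gene is comparable between two groups when both group abundances are
#' strictly positive and at least one reaches 1 (FPKM-like scale):
#' `(a > 0 AND b > 0) AND (a >= 1 OR b >= 1)`. This excludes genes too
#' lowly expressed for a meaningful fold change. The rule is symmetric in
#' its two arguments.
#'
#' @param a,b nonnegative per-gene abundances (typically group means) of
#'   equal length.
#' @return logical mask, `TRUE` where the gene passes.
#' @examples
#' filterExpressed(c(0.5, 0, 1.0), c(0.5, 10, 0.2))  # FALSE FALSE TRUE
#' @export
filterExpressed <- function(a, b) {
  if (length(a) != length(b))
    stop("data error: groups have different lengths")
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("data error: abundances must be nonnegative")
  (a > 0 & b > 0) & (a >= 1 | b >= 1)
}

#' Per-cell summaries (mean abundance per gene, condition and ZT)
#'
#' @param ce a [CircadianExperiment-class].
#' @return a [S4Vectors::DataFrame] with columns `gene_id`, `condition`,
#'   `zt`, `mean_abundance`, `n` (replicate count in the cell).
#' @export
cellSummaries <- function(ce) {
  cd <- SummarizedExperiment::colData(ce)
  key <- paste(cd$condition, cd$zt, sep = "|")
  cells <- unique(key)
  ab <- abundance(ce)
  out <- lapply(cells, function(k) {
    idx <- key == k
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    DataFrame(gene_id = rownames(ab), condition = parts[1],
              zt = as.numeric(parts[2]),
              mean_abundance = unname(rowMeans(ab[, idx, drop = FALSE])),
              n = sum(idx))
  })
  res <- do.call(rbind, out)
  res[order(res$gene_id, res$condition, res$zt), ]
}
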