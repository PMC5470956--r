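#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.CONDITIONS <- c("sham", "tumor")

.EFFECTS <- c("none", "uniform_up", "uniform_down", "phase_advance",
              "phase_delay", "amplitude_change", "rhythm_loss",
              "day_night_reversal")

#' Container for a two-condition circadian expression time course
#'
#' `CircadianExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with the sample-sheet
#' covariates every stage of the pipeline relies on: `condition`
#' (\code{"sham"} or \code{"tumor"}), `zt` (zeitgeber time, hours in
#' \[0, 24)) and `replicate` (replicate identifier within a condition x ZT
#' cell). The single assay, `"abundance"`, holds nonnegative FPKM-like
#' values with genes in rows and samples in columns.
#'
#' Validity requires: a nonnegative, finite, non-missing abundance assay;
#' unique gene and sample identifiers; the three covariate columns present
#' with `condition` restricted to sham/tumor and `zt` in \[0, 24); and at
#' least one replicate in every (condition, zt) cell declared by the
#' sample sheet.
#'
#' @seealso [CircadianExperiment()] (constructor), [readExpressionMatrix()],
#'   [simulateExperiment()]
#' @export
setClass("CircadianExperiment", contains = "SummarizedExperiment")

setValidity("CircadianExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (anyNA(a) || any(!is.finite(a)))
      msg <- c(msg, "abundance values must be finite and non-missing")
    else if (any(a < 0))
      msg <- c(msg, "abundance values must be nonnegative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  need <- c("condition", "zt", "replicate")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, sprintf("colData must contain columns: %s",
                          paste(need, collapse = ", ")))
  } else {
    if (!all(cd$condition %in% .CONDITIONS))
      msg <- c(msg, "condition must be 'sham' or 'tumor'")
    if (!is.numeric(cd$zt) || any(cd$zt < 0 | cd$zt >= 24))
      msg <- c(msg, "zt must be numeric hours in [0, 24)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CircadianExperiment
#'
#' @param abundance numeric gene x sample matrix of nonnegative abundances
#'   (FPKM-like scale) with gene row names and sample column names.
#' @param condition character vector, one of `"sham"`/`"tumor"` per sample.
#' @param zt numeric zeitgeber times in hours, one per sample, in \[0, 24).
#' @param replicate replicate identifiers, one per sample.
#' @param rowData optional per-gene annotation [S4Vectors::DataFrame]
#'   (e.g. the simulation ground truth).
#'
#' @return a validated [CircadianExperiment-class] object with samples
#'   ordered by (condition, zt, replicate).
#' @examples
#' m <- matrix(1:12 + 0, nrow = 2,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' ce <- CircadianExperiment(m,
#'   condition = rep(c("sham", "tumor"), each = 3),
#'   zt = rep(c(2, 10, 18), 2), replicate = rep("r1", 6))
#' @export
CircadianExperiment <- function(abundance, condition, zt, replicate,
                                rowData = NULL) {
  abundance <- as.matrix(abundance)
  cd <- DataFrame(condition = as.character(condition),
                  zt = as.numeric(zt),
                  replicate = as.character(replicate),
                  row.names = colnames(abundance))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), colData = cd)
  if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
  ord <- order(cd$condition, cd$zt, cd$replicate)
  obj <- methods::new("CircadianExperiment", se[, ord])
  methods::validObject(obj)
  obj
}

#' @describeIn CircadianExperiment-class the abundance assay matrix.
#' @param object,x a `CircadianExperiment`.
#' @export
abundance <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @describeIn CircadianExperiment-class per-sample condition labels.
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname CircadianExperiment-class
#' @export
setMethod("condition", "CircadianExperiment",
          function(x) SummarizedExperiment::colData(x)$condition)

#' @describeIn CircadianExperiment-class per-sample zeitgeber times (hours).
#' @export
setGeneric("zt", function(x) standardGeneric("zt"))

#' @rdname CircadianExperiment-class
#' @export
setMethod("zt", "CircadianExperiment",
          function(x) SummarizedExperiment::colData(x)$zt)

#' @describeIn CircadianExperiment-class per-sample replicate identifiers.
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))

#' @rdname CircadianExperiment-class
#' @export
setMethod("replicateId", "CircadianExperiment",
          function(x) SummarizedExperiment::colData(x)$replicate)

#' @describeIn CircadianExperiment-class planted per-gene ground truth
#'   (simulated objects only; `NULL` otherwise).
#' @export
geneTruth <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"effect" %in% colnames(rd)) return(NULL)
  rd
}

setMethod("show", "CircadianExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("CircadianExperiment: %d genes x %d samples\n",
              nrow(object), ncol(object)))
  for (cc in unique(cd$condition)) {
    zz <- cd$zt[cd$condition == cc]
    cat(sprintf("  %-6s %d samples, ZT {%s}, %s replicates/cell\n", cc,
                sum(cd$condition == cc),
                paste(sort(unique(zz)), collapse = ","),
                paste(unique(range(table(zz))), collapse = "-")))
  }
  if (!is.null(geneTruth(object)))
    cat("  planted ground truth in rowData (see geneTruth())\n")
  invisible(NULL)
})

# Grids of distinct ZTs per condition; stops if a condition is absent.
.conditionZts <- function(ce, cond) {
  if (!cond %in% condition(ce))
    stop("condition '", cond, "' not present in the experiment")
  sort(unique(zt(ce)[condition(ce) == cond]))
}
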