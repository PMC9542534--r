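#' Construct a sample-by-taxon count table
#'
#' The raw-input container of the pipeline: an integer matrix of amplicon
#' read counts (samples as rows), taxon lineage annotations, and per-sample
#' sequencing metadata (run id, cohort, protocol flags). Provenance flags
#' record which processing steps have already been applied so that
#' non-idempotent steps (blank subtraction) cannot be repeated.
#'
#' @param counts integer matrix, samples x taxa, with dimnames.
#' @param lineage data.frame with columns \code{taxon}, \code{class},
#'   \code{order}, \code{family}, \code{genus}; one row per taxon column.
#' @param samples data.frame with columns \code{sample_id}, \code{run},
#'   \code{cohort}; one row per count row.
#' @return object of class \code{qmp_counts}.
#' @export
count_table <- function(counts, lineage = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample rownames and taxon colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in count table")
  if (anyDuplicated(colnames(counts)))
    stop("taxon ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  if (is.null(lineage)) {
    lineage <- data.frame(taxon = colnames(counts), class = "", order = "",
                          family = "", genus = colnames(counts),
                          stringsAsFactors = FALSE)
  }
  lineage <- lineage[match(colnames(counts), lineage$taxon), , drop = FALSE]
  if (anyNA(lineage$taxon))
    stop("every taxon in the count matrix needs a lineage row")
  # lineage consistency: a genus maps to exactly one family
  gg <- lineage[nzchar(lineage$genus), ]
  if (nrow(gg) && any(tapply(gg$family, gg$genus,
                             function(f) length(unique(f))) > 1))
    stop("inconsistent lineage: a genus maps to more than one family")
  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(counts), run = "run1",
                          cohort = "cohortA", stringsAsFactors = FALSE)
  }
  samples <- samples[match(rownames(counts), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stop("every sample in the count matrix needs a metadata row")
  structure(list(counts = counts, lineage = lineage, samples = samples,
                 provenance = list(blanks_subtracted = FALSE,
                                   rare_filter = NULL, coverage_cutoff = NULL)),
            class = "qmp_counts")
}

#' @export
print.qmp_counts <- function(x, ...) {
  cat(sprintf("<qmp_counts> %d samples x %d taxa (total reads %.3g)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  flags <- x$provenance
  cat(sprintf("  blanks subtracted: %s; rare-read filter: %s; coverage cutoff: %s\n",
              flags$blanks_subtracted,
              if (is.null(flags$rare_filter)) "none" else flags$rare_filter,
              if (is.null(flags$coverage_cutoff)) "none" else
                paste(names(flags$coverage_cutoff), flags$coverage_cutoff,
                      sep = "=", collapse = ", ")))
  invisible(x)
}
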