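#' Subtract blank-control contaminant reads
#'
#' For every taxon observed in a run's negative controls (PCR or extraction
#' blanks), removes its blank read count "in corresponding numbers" from all
#' samples of that run: by default the per-run mean blank count is subtracted
#' unscaled from every sample of the run, floored at zero. Taxa reduced to
#' zero in all samples are dropped. The step is deliberately non-idempotent,
#' so re-application to an already blank-corrected table is refused via the
#' provenance flag.
#'
#' @param counts a \code{\link{count_table}} of study samples.
#' @param blanks a \code{count_table} of blank controls sharing run ids with
#'   the samples they correct.
#' @param method \code{"mean"} subtracts the per-run mean blank count of each
#'   taxon; \code{"depth_proportional"} scales that mean by the ratio of each
#'   sample's total reads to the mean blank total before subtracting.
#' @return blank-corrected \code{count_table}.
#' @export
subtract_blank_contaminants <- function(counts, blanks,
                                        method = c("mean",
                                                   "depth_proportional")) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "qmp_counts"), inherits(blanks, "qmp_counts"))
  if (isTRUE(counts$provenance$blanks_subtracted))
    stop("blank contaminants were already subtracted from this table; ",
         "re-application would subtract them twice")
  m <- counts$counts
  for (r in unique(counts$samples$run)) {
    in_run <- counts$samples$run == r
    bl <- blanks$counts[blanks$samples$run == r, , drop = FALSE]
    if (nrow(bl) == 0) {
      warning("no blank control for run '", r, "'; samples passed through")
      next
    }
    bmean <- colMeans(bl)
    hit <- which(bmean > 0)
    if (!length(hit)) next
    if (method == "mean") {
      sub <- matrix(rep(bmean[hit], each = sum(in_run)), sum(in_run))
    } else {
      scale <- rowSums(m[in_run, , drop = FALSE]) / mean(rowSums(bl))
      sub <- outer(scale, bmean[hit])
    }
    m[in_run, hit] <- pmax(0, round(m[in_run, hit, drop = FALSE] - sub))
  }
  keep <- colSums(m) > 0
  out <- counts
  out$counts <- m[, keep, drop = FALSE]
  out$lineage <- counts$lineage[keep, , drop = FALSE]
  out$provenance$blanks_subtracted <- TRUE
  out
}

#' Exclude rare reads as potentially erroneous
#'
#' Zeroes, within each sequencing run, every taxon whose total read count in
#' that run falls below \code{min_count}. Mirrors the practice of excluding
#' reads occurring fewer than 10-50 times depending on run size; the exact
#' threshold is left to the caller (optionally per run).
#'
#' @param counts a \code{\link{count_table}}.
#' @param min_count single threshold, or named vector of thresholds per run.
#' @return filtered \code{count_table}.
#' @export
filter_rare_reads <- function(counts, min_count = 10) {
  stopifnot(inherits(counts, "qmp_counts"), all(min_count >= 1))
  m <- counts$counts
  for (r in unique(counts$samples$run)) {
    thr <- if (length(min_count) > 1) {
      if (!r %in% names(min_count)) stop("no rare-read threshold for run ", r)
      min_count[[r]]
    } else min_count
    in_run <- counts$samples$run == r
    tot <- colSums(m[in_run, , drop = FALSE])
    m[in_run, tot < thr] <- 0L
  }
  out <- counts
  out$counts <- m
  out$provenance$rare_filter <- min_count
  out
}

#' Remove samples below their cohort's coverage cutoff
#'
#' Samples whose total read count is below the cutoff of their cohort are
#' removed (e.g. 2000 reads for a deeply sequenced cohort and 120 for a
#' low-biomass one). The cutoff is inclusive: a sample with exactly the
#' cutoff total is retained. Removals are recorded with reasons in the
#' \code{removed} attribute.
#'
#' @param counts a \code{\link{count_table}}.
#' @param cutoff_per_cohort named numeric vector, cutoff per cohort label.
#' @return filtered \code{count_table} with attribute \code{removed}.
#' @export
apply_coverage_cutoff <- function(counts,
                                  cutoff_per_cohort = c(HELMi = 2000,
                                                        Jorvi = 120)) {
  stopifnot(inherits(counts, "qmp_counts"))
  coh <- counts$samples$cohort
  missing <- setdiff(unique(coh), names(cutoff_per_cohort))
  if (length(missing))
    stop("no coverage cutoff for cohort(s): ", paste(missing, collapse = ", "))
  tot <- rowSums(counts$counts)
  cut <- cutoff_per_cohort[coh]
  keep <- tot >= cut
  removed <- data.frame(sample_id = counts$samples$sample_id[!keep],
                        total_reads = tot[!keep], cutoff = cut[!keep],
                        reason = rep("total reads below cohort coverage cutoff",
                                     sum(!keep)),
                        stringsAsFactors = FALSE)
  out <- counts
  out$counts <- counts$counts[keep, , drop = FALSE]
  out$samples <- counts$samples[keep, , drop = FALSE]
  out$provenance$coverage_cutoff <- cutoff_per_cohort
  attr(out, "removed") <- removed
  out
}

#' Relative abundance matrix
#'
#' Per-sample proportions of reads; no copy-number correction is applied
#' (relative profiles are conventionally reported uncorrected).
#'
#' @param counts a \code{\link{count_table}} or a numeric matrix
#'   (samples x taxa).
#' @return matrix of proportions whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  m <- if (inherits(counts, "qmp_counts")) counts$counts else as.matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  sweep(m, 1, tot, "/")
}

#' Resolve per-taxon 16S copy numbers with rank fallback
#'
#' Matches each taxon against an rrnDB-style table (name, rank, mean16S):
#' exact genus match first, then family, order, class, and finally the global
#' mean of the table. The source rank used is recorded per taxon.
#'
#' @param lineage data.frame with columns taxon, class, order, family, genus.
#' @param copy_numbers data.frame(name, rank, mean16S).
#' @return data.frame(taxon, copy_number, source).
#' @export
resolve_copy_numbers <- function(lineage, copy_numbers) {
  global <- mean(copy_numbers$mean16S)
  lookup <- function(name, rank) {
    hit <- copy_numbers$mean16S[copy_numbers$name == name &
                                  copy_numbers$rank == rank]
    if (length(hit)) hit[1] else NA_real_
  }
  res <- lapply(seq_len(nrow(lineage)), function(i) {
    for (rk in c("genus", "family", "order", "class")) {
      nm <- lineage[[rk]][i]
      if (nzchar(nm)) {
        v <- lookup(nm, rk)
        if (!is.na(v)) return(list(v, rk))
      }
    }
    list(global, "global-mean")
  })
  data.frame(taxon = lineage$taxon,
             copy_number = vapply(res, function(x) x[[1]], numeric(1)),
             source = vapply(res, function(x) x[[2]], character(1)),
             stringsAsFactors = FALSE)
}

#' qPCR-anchored absolute abundance profile with copy-number correction
#'
#' Quantitative microbiota profiling: scales each sample's relative profile
#' by its qPCR total 16S load to obtain uncorrected absolute abundances
#' (16S copies/g feces), then divides each taxon by its mean 16S rRNA gene
#' copy number to approximate cell densities (cells/g). Samples lacking a
#' qPCR measurement are excluded with a logged reason.
#'
#' @param counts a QC-filtered \code{\link{count_table}}.
#' @param qpcr data.frame(sample_id, copies_per_g), copies_per_g > 0.
#' @param copy_numbers rrnDB-style data.frame(name, rank, mean16S); defaults
#'   to the built-in table.
#' @return object of class \code{qmp_profile} with matrices \code{relative}
#'   (proportions), \code{uncorrected} (copies/g) and \code{corrected}
#'   (cells/g), the per-taxon copy-number sources, lineage, sample metadata
#'   and provenance.
#' @export
absolute_profile <- function(counts, qpcr, copy_numbers = default_copy_numbers()) {
  stopifnot(inherits(counts, "qmp_counts"))
  idx <- match(counts$samples$sample_id, qpcr$sample_id)
  has_q <- !is.na(idx) & !is.na(qpcr$copies_per_g[idx])
  excluded <- counts$samples$sample_id[!has_q]
  if (length(excluded))
    message(length(excluded), " sample(s) without qPCR value excluded")
  load <- qpcr$copies_per_g[idx[has_q]]
  if (any(load <= 0)) stop("non-positive qPCR load")
  m <- counts$counts[has_q, , drop = FALSE]
  rel <- relative_abundance(m)
  uncorrected <- rel * load
  cn <- resolve_copy_numbers(counts$lineage, copy_numbers)
  corrected <- sweep(uncorrected, 2, cn$copy_number, "/")
  structure(list(relative = rel, uncorrected = uncorrected,
                 corrected = corrected, load = setNames(load, rownames(m)),
                 copy_source = cn, lineage = counts$lineage,
                 samples = counts$samples[has_q, , drop = FALSE],
                 rank = "genus",
                 provenance = c(counts$provenance,
                                list(excluded_no_qpcr = excluded))),
            class = "qmp_profile")
}

#' @export
print.qmp_profile <- function(x, ...) {
  cat(sprintf("<qmp_profile> %d samples x %d taxa at %s level\n",
              nrow(x$corrected), ncol(x$corrected), x$rank))
  cat(sprintf("  load range %.3g-%.3g 16S copies/g; copy numbers from %s\n",
              min(x$load), max(x$load),
              paste(unique(x$copy_source$source), collapse = "/")))
  invisible(x)
}

#' Aggregate a profile or matrix to a higher taxonomic rank
#'
#' Sums abundances of taxa sharing the requested rank; taxa with no
#' assignment at that rank are pooled into \code{"unclassified-<rank>"}.
#'
#' @param profile a \code{qmp_profile}, or a numeric matrix (samples x taxa)
#'   if \code{lineage} is supplied.
#' @param rank one of \code{"class"}, \code{"order"}, \code{"family"},
#'   \code{"genus"}.
#' @param lineage lineage table when \code{profile} is a bare matrix.
#' @return aggregated object of the same kind.
#' @export
aggregate_rank <- function(profile, rank, lineage = NULL) {
  rank <- match.arg(rank, c("class", "order", "family", "genus"))
  if (inherits(profile, "qmp_profile")) {
    lin <- profile$lineage
    grp <- ifelse(nzchar(lin[[rank]]), lin[[rank]],
                  paste0("unclassified-", rank))
    agg <- function(m) {
      out <- t(rowsum(t(m), grp))
      out[, unique(grp), drop = FALSE]
    }
    out <- profile
    out$relative <- agg(profile$relative)
    out$uncorrected <- agg(profile$uncorrected)
    out$corrected <- agg(profile$corrected)
    ranks <- c("class", "order", "family", "genus")
    keepcols <- ranks[seq_len(match(rank, ranks))]
    lin2 <- unique(data.frame(taxon = grp,
                              lin[, keepcols, drop = FALSE],
                              stringsAsFactors = FALSE))
    lin2 <- lin2[!duplicated(lin2$taxon), , drop = FALSE]
    out$lineage <- lin2[match(colnames(out$corrected), lin2$taxon), ,
                        drop = FALSE]
    out$copy_source <- NULL
    out$rank <- rank
    return(out)
  }
  if (is.null(lineage)) stop("lineage required to aggregate a bare matrix")
  grp <- ifelse(nzchar(lineage[[rank]][match(colnames(profile),
                                             lineage$taxon)]),
                lineage[[rank]][match(colnames(profile), lineage$taxon)],
                paste0("unclassified-", rank))
  t(rowsum(t(as.matrix(profile)), grp))
}

#' Abundance matrix of a profile on a chosen scale
#'
#' @param profile a \code{qmp_profile}.
#' @param scale \code{"absolute"} (copy-number corrected cells/g),
#'   \code{"copies"} (uncorrected 16S copies/g) or \code{"relative"}
#'   (proportions).
#' @return numeric matrix, samples x taxa.
#' @export
profile_matrix <- function(profile, scale = c("absolute", "copies",
                                              "relative")) {
  scale <- match.arg(scale)
  switch(scale, absolute = profile$corrected, copies = profile$uncorrected,
         relative = profile$relative)
}
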