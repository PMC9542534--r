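#' Write / read the canonical count-table TSV
#'
#' Canonical interchange dialect: samples as rows; first columns
#' \code{sample_id}, \code{run}, \code{cohort}; remaining columns one per
#' taxon, named by the semicolon-delimited lineage
#' \code{class;order;family;genus}.
#'
#' @param x a \code{\link{count_table}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_count_tsv <- function(x, path) {
  stopifnot(inherits(x, "qmp_counts"))
  lin <- x$lineage
  colnm <- paste(lin$class, lin$order, lin$family, lin$genus, sep = ";")
  df <- data.frame(x$samples[, c("sample_id", "run", "cohort")],
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:3)] <- colnm
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# parse "class;order;family;genus" strings; short lineages are padded with
# empty levels (warning), bare names are taken as genus
parse_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  short <- lengths(parts) < 4 & grepl(";", x, fixed = TRUE)
  if (any(short))
    warning("lineage with missing levels padded: ",
            paste(utils::head(x[short], 3), collapse = ", "))
  out <- t(vapply(parts, function(p) {
    p <- c(p, rep("", 4 - length(p)))[1:4]
    p
  }, character(4)))
  bare <- !grepl(";", x, fixed = TRUE)
  lin <- data.frame(class = out[, 1], order = out[, 2], family = out[, 3],
                    genus = out[, 4], stringsAsFactors = FALSE)
  if (any(bare)) {
    lin$genus[bare] <- x[bare]
    lin$class[bare] <- lin$order[bare] <- lin$family[bare] <- ""
  }
  taxon <- ifelse(nzchar(lin$genus), lin$genus,
                  ifelse(nzchar(lin$family), lin$family,
                         ifelse(nzchar(lin$order), lin$order, lin$class)))
  # disambiguate taxa that collapse to the same terminal name
  taxon[duplicated(taxon)] <- paste0(taxon[duplicated(taxon)], ".",
                                     seq_len(sum(duplicated(taxon))))
  cbind(taxon = taxon, lin)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in ", path)
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  bad <- which(m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer count at sample '%s', taxon '%s'",
                 df$sample_id[bad[1, 1]], colnames(m)[bad[1, 2]]))
  lin <- parse_lineage(colnames(m))
  colnames(m) <- lin$taxon
  rownames(m) <- df$sample_id
  count_table(m, lin, df[, 1:3])
}

#' Write / read a count table as BIOM-style JSON
#'
#' Read-only convenience for BIOM v1 (JSON) tables via the \pkg{biomformat}
#' package; the writer exists to round-trip the same data for format parity
#' checks. Taxon lineages travel in the observation metadata
#' (\code{taxonomy}) and run/cohort in the sample metadata.
#'
#' @param x a \code{\link{count_table}}.
#' @param path file path.
#' @return \code{path} (writer) or a \code{count_table} (reader).
#' @export
write_count_biom <- function(x, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required for BIOM input/output")
  lin <- x$lineage
  obs <- data.frame(taxonomy = paste(lin$class, lin$order, lin$family,
                                     lin$genus, sep = ";"),
                    row.names = lin$taxon, stringsAsFactors = FALSE)
  smp <- data.frame(run = x$samples$run, cohort = x$samples$cohort,
                    row.names = x$samples$sample_id, stringsAsFactors = FALSE)
  b <- biomformat::make_biom(t(x$counts), observation_metadata = obs,
                             sample_metadata = smp)
  biomformat::write_biom(b, path)
  invisible(path)
}

#' @rdname write_count_biom
#' @export
read_count_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required for BIOM input/output")
  b <- biomformat::read_biom(path)
  m <- t(as(biomformat::biom_data(b), "matrix"))
  m <- round(m)
  storage.mode(m) <- "integer"
  om <- biomformat::observation_metadata(b)
  # column names are not preserved in BIOM v1 metadata: take the first
  # column as the semicolon lineage string
  taxo <- if (is.data.frame(om)) as.character(om[[1]])
          else vapply(om, function(r) paste(unlist(r), collapse = ";"),
                      character(1))
  lin <- parse_lineage(taxo)
  colnames(m) <- lin$taxon
  sm <- biomformat::sample_metadata(b)
  samples <- data.frame(sample_id = rownames(m),
                        run = as.character(sm[[1]]),
                        cohort = as.character(sm[[2]]),
                        stringsAsFactors = FALSE)
  count_table(m, lin, samples)
}

#' Write simple TSV tables of the pipeline
#'
#' @param df data.frame.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
}

#' Write all tables of a simulated cohort to a directory
#'
#' Emits the canonical TSVs (counts, blanks, qPCR, copy numbers, metadata,
#' well-being) and the ground truth as JSON.
#'
#' @param sim a \code{\link{simulate_cohort}} result.
#' @param dir output directory (created if needed).
#' @return named vector of file paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = write_count_tsv(sim$counts, file.path(dir, "counts.tsv")),
    blanks = write_count_tsv(sim$blanks, file.path(dir, "blanks.tsv")),
    qpcr = write_tsv(sim$qpcr, file.path(dir, "qpcr.tsv")),
    copy_numbers = write_tsv(sim$copy_numbers,
                             file.path(dir, "copy_numbers.tsv")),
    metadata = write_tsv(sim$metadata, file.path(dir, "metadata.tsv")),
    wellbeing = write_tsv(sim$wellbeing, file.path(dir, "wellbeing.tsv")))
  truth <- sim$truth
  truth$true_cells <- NULL; truth$true_copies <- NULL  # large matrices: TSV
  write_tsv(data.frame(sample_id = names(sim$truth$true_load),
                       true_load = sim$truth$true_load),
            file.path(dir, "true_load.tsv"))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  paths
}

#' Run the full analysis pipeline
#'
#' Chains profiling (blank subtraction, rare-read filter, coverage cutoff,
#' absolute profiles), cohort design, differential abundance, ordination and
#' mediation on either a simulated cohort or files on disk, writing every
#' stage's outputs plus a provenance record into a run directory. Any stage
#' failure aborts with the stage name.
#'
#' @param config list (or path to a JSON/YAML file) with optional entries:
#'   \code{seed} (used when simulating; default 1), \code{sim} (a
#'   \code{sim_config} or TRUE for defaults), \code{inputs} (named paths:
#'   counts, blanks, qpcr, copy_numbers, metadata, wellbeing), \code{cutoffs}
#'   (named per-cohort coverage cutoffs), \code{min_count} (rare-read
#'   threshold), \code{prevalence}, \code{alpha}, \code{fdr}, \code{cap},
#'   \code{pseudocount}, \code{scale} ("absolute" or "relative"),
#'   \code{da_rank}, \code{mediation} (list of list(outcome, timepoint)),
#'   \code{stages} (character subset of c("da","ordination","mediation")).
#' @param out_dir run directory; default a timestamped directory under
#'   \code{tempdir()}.
#' @return the run directory path, invisibly; outputs live inside it.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the yaml package is required for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- list(
    seed = 1, sim = TRUE, inputs = NULL,
    cutoffs = c(HELMi = 2000, Jorvi = 120), min_count = 10,
    prevalence = 0.30, alpha = 0.05, fdr = 0.1, cap = 5, pseudocount = 1,
    scale = "absolute", da_rank = "family",
    mediation = list(list(outcome = "defecation_rate", timepoint = 6)),
    stages = c("da", "ordination", "mediation"))
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(),
                         paste0("qmp_run_", format(Sys.time(),
                                                   "%Y%m%d_%H%M%S")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log <- character(0)

  ## ---- inputs ------------------------------------------------------------
  input_hashes <- NULL
  if (!is.null(cfg$inputs)) {
    ins <- cfg$inputs
    if (cfg$scale == "absolute" &&
        (is.null(ins$qpcr) || !file.exists(ins$qpcr)))
      stop("pipeline stage 'inputs' failed: absolute-scale stages requested ",
           "but qPCR file is missing: ",
           if (is.null(ins$qpcr)) "<not given>" else ins$qpcr, call. = FALSE)
    counts <- stage("inputs", read_count_tsv(ins$counts))
    blanks <- if (!is.null(ins$blanks)) stage("inputs",
                                              read_count_tsv(ins$blanks))
    qpcr <- if (!is.null(ins$qpcr)) stage("inputs", read_tsv(ins$qpcr))
    copy_numbers <- if (!is.null(ins$copy_numbers))
      stage("inputs", read_tsv(ins$copy_numbers)) else default_copy_numbers()
    metadata <- stage("inputs", read_tsv(ins$metadata))
    wellbeing <- if (!is.null(ins$wellbeing)) stage("inputs",
                                                    read_tsv(ins$wellbeing))
    input_hashes <- tools::md5sum(unlist(ins[!vapply(ins, is.null,
                                                     logical(1))]))
  } else {
    simcfg <- if (inherits(cfg$sim, "qmp_sim_config")) cfg$sim
              else sim_config(seed = cfg$seed)
    sim <- stage("simulate", simulate_cohort(simcfg))
    counts <- sim$counts; blanks <- sim$blanks; qpcr <- sim$qpcr
    copy_numbers <- sim$copy_numbers; metadata <- sim$metadata
    wellbeing <- sim$wellbeing
    stage("simulate", write_sim(sim, file.path(out_dir, "simulated_input")))
  }

  ## ---- profiling ---------------------------------------------------------
  prof <- stage("profiling", {
    ct <- counts
    if (!is.null(blanks))
      ct <- suppressWarnings(subtract_blank_contaminants(ct, blanks))
    ct <- filter_rare_reads(ct, cfg$min_count)
    ct <- apply_coverage_cutoff(ct, unlist(cfg$cutoffs))
    if (is.null(qpcr)) {
      if (cfg$scale == "absolute")
        stop("qPCR table required for absolute-scale analysis")
      log <- c(log, "relative-only mode: no qPCR; proportions analyzed")
      rel <- relative_abundance(ct)
      structure(list(relative = rel, uncorrected = rel, corrected = rel,
                     load = setNames(rep(NA_real_, nrow(rel)),
                                     rownames(rel)),
                     copy_source = NULL, lineage = ct$lineage,
                     samples = ct$samples, rank = "genus",
                     provenance = ct$provenance), class = "qmp_profile")
    } else absolute_profile(ct, qpcr, copy_numbers)
  })
  write_tsv(data.frame(sample_id = rownames(prof$corrected),
                       prof$corrected, check.names = FALSE),
            file.path(out_dir, "profile_absolute.tsv"))
  write_tsv(data.frame(sample_id = rownames(prof$relative),
                       prof$relative, check.names = FALSE),
            file.path(out_dir, "profile_relative.tsv"))

  ## ---- cohort ------------------------------------------------------------
  cohort <- stage("cohort", {
    md <- metadata
    if (!"group" %in% names(md))
      md$group <- assign_study_group(md$birth_mode, md$antibiotic)
    if (!"abx_class" %in% names(md) && "antibiotic" %in% names(md))
      md$abx_class <- antibiotic_class(md$antibiotic)
    censor_postnatal_antibiotics(md, cfg$treatments)
  })
  write_tsv(cohort, file.path(out_dir, "cohort.tsv"))

  results <- list()
  if ("da" %in% cfg$stages) {
    da <- stage("differential_abundance",
                qmp_da(prof, cohort, rank = cfg$da_rank, scale = cfg$scale,
                       prevalence = cfg$prevalence, alpha = cfg$alpha,
                       fdr = cfg$fdr, cap = cfg$cap))
    write_tsv(da$results, file.path(out_dir, "da_results.tsv"))
    dm <- da_matrix(da)
    if (nrow(dm$log10_fc))
      write_tsv(data.frame(taxon = rownames(dm$log10_fc), dm$log10_fc,
                           check.names = FALSE),
                file.path(out_dir, "da_fold_change_matrix.tsv"))
    results$da <- da
  }
  if ("ordination" %in% cfg$stages) {
    ord <- stage("ordination", {
      o <- pcoa_pearson(prof, scale = if (cfg$scale == "absolute")
        "absolute" else "relative", pseudocount = cfg$pseudocount)
      tests <- do.call(rbind, lapply(sort(unique(cohort$age_weeks)),
                                     function(tp) {
        t <- tryCatch(test_group_separation(o, cohort, tp),
                      error = function(e) NULL)
        if (is.null(t)) return(NULL)
        t$age_weeks <- tp
        t
      }))
      list(ord = o, tests = tests, med = median_trajectories(o, cohort))
    })
    write_tsv(data.frame(sample_id = rownames(ord$ord$points),
                         ord$ord$points),
              file.path(out_dir, "pcoa_coordinates.tsv"))
    write_tsv(data.frame(eigenvalue = ord$ord$eig),
              file.path(out_dir, "pcoa_eigenvalues.tsv"))
    if (!is.null(ord$tests))
      write_tsv(ord$tests, file.path(out_dir, "pcoa_group_tests.tsv"))
    write_tsv(ord$med, file.path(out_dir, "pcoa_median_trajectories.tsv"))
    results$ordination <- ord
  }
  if ("mediation" %in% cfg$stages && !is.null(wellbeing)) {
    if (cfg$scale != "absolute")
      log <- c(log, "mediation run on proportions: absolute loads unavailable")
    paths <- stage("mediation", lapply(cfg$mediation, function(mspec) {
      path_model(prof, cohort, wellbeing, mspec$outcome, mspec$timepoint,
                 prevalence = cfg$prevalence, alpha = cfg$alpha)
    }))
    flat <- do.call(rbind, lapply(paths, function(p)
      data.frame(outcome = p$outcome, timepoint = p$timepoint,
                 variance_explained = p$variance_explained,
                 n_mediators = nrow(p$mediators),
                 mediated_terms = paste(
                   p$exposure_terms$term[p$exposure_terms$mediated],
                   collapse = ","), stringsAsFactors = FALSE)))
    write_tsv(flat, file.path(out_dir, "mediation_summary.tsv"))
    jsonlite::write_json(
      lapply(paths, function(p) list(
        outcome = p$outcome, timepoint = p$timepoint,
        variance_explained = p$variance_explained,
        exposure_terms = p$exposure_terms, mediators = p$mediators,
        edges = p$edges)),
      file.path(out_dir, "mediation_paths.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE, dataframe = "rows")
    results$mediation <- paths
  }

  prov <- list(package_version = as.character(utils::packageVersion("qmpinfant")),
               r_version = R.version.string,
               config = cfg[setdiff(names(cfg), "sim")],
               input_md5 = as.list(input_hashes), log = log)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, force = TRUE, null = "null")
  invisible(out_dir)
}
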