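#' Read a genes-by-samples expression matrix from a tab-delimited file
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column. Non-numeric cells and ragged rows raise errors naming the
#' offending row and column. Duplicate gene rows are collapsed by their mean
#' with a message, mirroring mean collapsing of probe sets that map to one
#' gene.
#'
#' @param path tab-delimited file path.
#' @return Numeric matrix, genes in rows (unique, whitespace-stripped ids),
#'   samples in columns.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (!nrow(tab) || ncol(tab) < 2)
    stop("empty or column-less matrix file: ", path)
  ids <- trimws(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, as.numeric, numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(vals),
                dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !(toupper(as.matrix(vals)) %in%
                                c("NA", "NAN", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at data row %d, column '%s' in %s",
                 bad[1, 1] + 1L, colnames(vals)[bad[1, 2]], path))
  if (anyDuplicated(ids)) {
    n_dup <- length(ids) - length(unique(ids))
    message(sprintf("read_matrix: collapsed %d duplicate gene row(s) by mean",
                    n_dup))
    num <- rowsum(num, group = ids, reorder = FALSE) /
      as.vector(table(factor(ids, levels = unique(ids))))
    ids <- unique(ids)
  }
  rownames(num) <- ids
  message(sprintf("read_matrix: %d genes x %d samples from %s",
                  nrow(num), ncol(num), path))
  num
}

#' Write a genes-by-samples matrix as tab-delimited text
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path; parent directories are created.
#' @param id_col header name for the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, id_col = "gene_id") {
  dir_create_logged(dirname(path))
  # %.17g round-trips doubles exactly, so re-reading reproduces the matrix
  chr <- matrix(sprintf("%.17g", mat), nrow = nrow(mat),
                dimnames = dimnames(mat))
  df <- data.frame(rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tidy result table with a metadata sidecar
#'
#' Rows are ordered deterministically (by `sample_id` then `drug` when those
#' columns exist) and a `<path>.meta.json` sidecar records the metadata, the
#' package version and an md5 hash of the metadata content, so identical
#' configurations yield byte-identical outputs.
#'
#' @param table `data.frame` to write.
#' @param path output TSV path.
#' @param metadata named list recorded in the sidecar (seeds, thresholds,
#'   configuration).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, metadata = list()) {
  stopifnot(is.data.frame(table))
  ord_cols <- intersect(c("sample_id", "drug"), names(table))
  if (length(ord_cols))
    table <- table[do.call(order, table[ord_cols]), , drop = FALSE]
  dir_create_logged(dirname(path))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- c(metadata,
            list(package_version = as.character(
              utils::packageVersion("drscore"))))
  meta$config_hash <- md5_of(meta)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

md5_of <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

dir_create_logged <- function(dir) {
  if (!nzchar(dir) || dir == ".") return(invisible(dir))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  invisible(dir)
}

#' Build a pipeline run configuration
#'
#' Collects every knob of a full pipeline run. Either `simulate` is a
#' [sim_config()] (synthetic mode: the study is generated in-memory) or the
#' input paths `profile`, `cohort` and optionally `clinical`/`ic50` point at
#' TSV files on disk. All thresholds and the seed are recorded verbatim in
#' every output's metadata sidecar.
#'
#' @param out_dir output directory.
#' @param simulate optional [sim_config()] for synthetic mode.
#' @param profile,cohort,clinical,ic50 input file paths (file mode).
#' @param n_perm permutations for DRS normalization.
#' @param clamp profile trim bound.
#' @param seed root seed for every randomized stage.
#' @param null_mode permutation-null aggregation, see [normalize_pdrs()].
#' @param min_overlap smallest acceptable signature/cohort gene overlap.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = NULL, profile = NULL,
                       cohort = NULL, clinical = NULL, ic50 = NULL,
                       n_perm = 1000, clamp = 20, seed = 1,
                       null_mode = "absolute", min_overlap = 50) {
  if (is.null(simulate) && (is.null(profile) || is.null(cohort)))
    stop("either a simulate config or profile+cohort paths are required")
  structure(list(out_dir = out_dir, simulate = simulate, profile = profile,
                 cohort = cohort, clinical = clinical, ic50 = ic50,
                 n_perm = n_perm, clamp = clamp, seed = as.integer(seed),
                 null_mode = null_mode, min_overlap = min_overlap),
            class = "run_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulate:`
#' mapping is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(run_config, y)
}

#' Run the full pipeline: signature, scoring, downstream analyses
#'
#' Executes profile building (or loading), cohort scoring, and whichever
#' downstream stages have inputs: survival at the DRS = 0 split plus a
#' univariate Cox fit when a clinical table is present, the IC50 correlation
#' screen when a drug-response table is present, and burden classification
#' when the clinical table carries a `burden` column. Missing inputs skip
#' their stage with a logged notice. A `manifest.json` listing every output
#' file and its md5 hash is written last; identical configurations
#' reproduce the manifest byte for byte.
#'
#' @param config a [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir_create_logged(out)
  meta_common <- list(seed = config$seed, n_perm = config$n_perm,
                      clamp = config$clamp, null_mode = config$null_mode,
                      min_overlap = config$min_overlap)
  stage <- "inputs"
  results <- list()
  tryCatch({
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      cfg <- config$simulate
      pairs <- simulate_drug_experiment(cfg)
      profile <- average_replicates(
        lapply(pairs, build_profile, clamp = config$clamp))
      cohort <- simulate_cohort(cfg)
      expr <- cohort$expr
      outc <- simulate_outcomes(cohort$truth)
      clinical <- outc$clinical
      ic50 <- outc$ic50
      write_profile(profile, file.path(out, "profile.tsv"))
      write_matrix(expr, file.path(out, "cohort.tsv"))
      utils::write.table(clinical, file.path(out, "clinical.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_matrix(ic50, file.path(out, "ic50.tsv"), id_col = "cell_line")
      results$truth <- cohort$truth
    } else {
      stage <- "load"
      profile <- read_profile(config$profile)
      expr <- read_matrix(config$cohort)
      clinical <- if (!is.null(config$clinical))
        utils::read.delim(config$clinical, stringsAsFactors = FALSE)
      else NULL
      ic50 <- if (!is.null(config$ic50)) read_matrix(config$ic50) else NULL
    }

    stage <- "score"
    drs_tab <- score_cohort(expr, profile, n_perm = config$n_perm,
                            seed = config$seed,
                            min_overlap = config$min_overlap,
                            null_mode = config$null_mode)
    if (all(is.na(drs_tab$drs)))
      stop("no sample could be scored: ", drs_tab$note[1])
    write_results(drs_tab, file.path(out, "drs.tsv"), meta_common)
    results$drs <- drs_tab

    if (!is.null(clinical)) {
      stage <- "survival"
      m <- match(clinical$sample_id, drs_tab$sample_id)
      drs_vec <- drs_tab$drs[m]
      groups <- stratify_at_zero(drs_vec)
      km <- km_logrank(clinical, groups)
      cox <- cox_univariate(clinical, drs_vec)
      surv_tab <- data.frame(
        analysis = c("logrank_at_zero", "cox_univariate"),
        statistic = c(km$chisq, cox$coef),
        p_value = c(km$p_value, cox$p_value),
        n = c(sum(km$n), cox$n))
      write_results(surv_tab, file.path(out, "survival.tsv"), meta_common)
      results$survival <- list(km = km, cox = cox)
      if ("burden" %in% names(clinical)) {
        stage <- "classify"
        cls <- classify_rcb(drs_vec, factor(clinical$burden,
                                            levels = c("low", "high")),
                            seed = config$seed)
        write_results(data.frame(analysis = "rcb_classification",
                                 auc = cls$auc,
                                 n = nrow(cls$predictions)),
                      file.path(out, "classification.tsv"), meta_common)
        results$classification <- cls
      }
    } else {
      message("run_pipeline: no clinical table; skipping survival stage")
    }

    if (!is.null(ic50)) {
      stage <- "screen"
      drs_named <- stats::setNames(drs_tab$drs, drs_tab$sample_id)
      scr <- drug_screen(drs_named[rownames(ic50)], ic50)
      write_results(scr$results, file.path(out, "screen.tsv"), meta_common)
      results$screen <- scr
    } else {
      message("run_pipeline: no IC50 table; skipping screen stage")
    }
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  stage <- "manifest"
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    config = meta_common,
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(file.path(out, f))))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
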