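#' Construct a treated/control expression pair
#'
#' Bundles one replicate of a drug treatment experiment: a treated and a
#' control log2 expression vector over the same ordered gene universe,
#' together with the drug, cell line and concentration labels. Rows with a
#' missing value in either vector are dropped with a warning; genes present
#' in only one vector raise an error naming the offenders.
#'
#' @param gene_ids character vector of gene identifiers (one per row).
#' @param treated,control numeric log2 expression vectors named or aligned to
#'   `gene_ids`. If named, they are matched by name; unnamed vectors must
#'   already be in `gene_ids` order.
#' @param drug_name,cell_line character labels.
#' @param concentration nonnegative numeric treatment concentration.
#' @param conc_unit unit label for `concentration` (default `"uM"`).
#' @return An object of class `expression_pair` with components `gene_ids`,
#'   `treated`, `control`, `drug_name`, `cell_line`, `concentration`,
#'   `conc_unit`.
#' @export
expression_pair <- function(gene_ids, treated, control,
                            drug_name = "drug", cell_line = "cell",
                            concentration = 1, conc_unit = "uM") {
  gene_ids <- trimws(as.character(gene_ids))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers; collapse them first (see read_matrix)")
  align <- function(x, what) {
    if (!is.null(names(x))) {
      missing_ids <- setdiff(gene_ids, names(x))
      extra_ids <- setdiff(names(x), gene_ids)
      if (length(missing_ids) || length(extra_ids))
        stop(sprintf("gene sets of %s and gene_ids differ (missing: %s; extra: %s)",
                     what,
                     paste(utils::head(missing_ids, 5), collapse = ","),
                     paste(utils::head(extra_ids, 5), collapse = ",")))
      x <- x[gene_ids]
    }
    if (length(x) != length(gene_ids))
      stop(sprintf("%s has %d values for %d genes", what, length(x),
                   length(gene_ids)))
    as.numeric(x)
  }
  treated <- align(treated, "treated")
  control <- align(control, "control")
  keep <- is.finite(treated) & is.finite(control)
  if (!all(keep)) {
    warning(sprintf("dropping %d gene(s) with missing values", sum(!keep)))
    gene_ids <- gene_ids[keep]
    treated <- treated[keep]
    control <- control[keep]
  }
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      concentration < 0)
    stop("concentration must be a single nonnegative number")
  structure(
    list(gene_ids = gene_ids, treated = treated, control = control,
         drug_name = as.character(drug_name),
         cell_line = as.character(cell_line),
         concentration = concentration, conc_unit = as.character(conc_unit)),
    class = "expression_pair")
}

#' Per-gene log2 ratios of treatment versus control
#'
#' Inputs are already on the log2 scale, so the log2 ratio is the elementwise
#' difference `treated - control`. Genes with identical treated and control
#' values map to exactly zero.
#'
#' @param pair an [expression_pair()].
#' @return Named numeric vector of signed log2 ratios, aligned to
#'   `pair$gene_ids`.
#' @export
compute_log_ratios <- function(pair) {
  stopifnot(inherits(pair, "expression_pair"))
  stats::setNames(pair$treated - pair$control, pair$gene_ids)
}

#' Map log2 ratios to signed, trimmed significance scores
#'
#' The ratios are z-transformed across genes (population standard deviation),
#' converted to two-sided normal tail p-values, -log10 transformed, trimmed
#' to `[-clamp, clamp]`, and re-signed by the ratio so that positive scores
#' mark the up-regulated group and negative scores the down-regulated group.
#'
#' @param ratios numeric vector of signed log2 ratios (length >= `min_genes`).
#' @param clamp positive bound for trimming, default 20.
#' @param min_genes minimum number of genes required, default 3.
#' @return Numeric vector of scores in `[-clamp, clamp]`, same names/order as
#'   `ratios`. `sign(score) == sign(ratio)` for every gene.
#' @export
ratios_to_scores <- function(ratios, clamp = 20, min_genes = 3) {
  if (length(ratios) < min_genes)
    stop(sprintf("need at least %d genes, got %d", min_genes, length(ratios)))
  if (anyNA(ratios)) stop("ratios contain missing values")
  mu <- mean(ratios)
  sigma <- sqrt(mean((ratios - mu)^2))
  if (sigma == 0)
    stop("all ratios identical: z-scores are undefined")
  z <- (ratios - mu) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  sign(ratios) * pmin(-log10(p), clamp)
}

#' Construct a drug treatment profile
#'
#' A per-gene signed score bounded to `[-clamp, clamp]` for one
#' drug/cell-line/concentration, the weight source for DRS scoring.
#'
#' @param gene_ids character identifiers.
#' @param score numeric signed scores, one per gene, in `[-clamp, clamp]`.
#' @param drug_name,cell_line,concentration,conc_unit labels.
#' @param n_replicates_averaged how many replicate profiles were averaged.
#' @param clamp the trim bound the scores obey (default 20).
#' @return Object of class `drug_profile`.
#' @export
drug_profile <- function(gene_ids, score, drug_name = "drug",
                         cell_line = "cell", concentration = 1,
                         conc_unit = "uM", n_replicates_averaged = 1L,
                         clamp = 20) {
  gene_ids <- trimws(as.character(gene_ids))
  score <- as.numeric(score)
  if (length(gene_ids) != length(score))
    stop("gene_ids and score lengths differ")
  if (anyNA(score)) stop("scores contain missing values")
  if (any(abs(score) > clamp + 1e-9))
    stop(sprintf("scores outside [-%g, %g]", clamp, clamp))
  structure(
    list(gene_ids = gene_ids, score = stats::setNames(score, gene_ids),
         drug_name = as.character(drug_name),
         cell_line = as.character(cell_line),
         concentration = concentration, conc_unit = as.character(conc_unit),
         n_replicates_averaged = as.integer(n_replicates_averaged),
         clamp = clamp),
    class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat(sprintf("drug_profile: %s @ %g %s in %s\n", x$drug_name,
              x$concentration, x$conc_unit, x$cell_line))
  cat(sprintf("  %d genes (%d up, %d down), %d replicate(s) averaged\n",
              length(x$gene_ids), sum(x$score > 0), sum(x$score < 0),
              x$n_replicates_averaged))
  invisible(x)
}

#' Build a drug treatment profile from one treated/control pair
#'
#' Runs the full signature construction for one replicate: log2 ratios,
#' z-transform to two-sided p-values, -log10, trim to `[-clamp, clamp]`,
#' sign restored from the ratio.
#'
#' @param pair an [expression_pair()].
#' @inheritParams ratios_to_scores
#' @return A [drug_profile()].
#' @export
build_profile <- function(pair, clamp = 20, min_genes = 3) {
  scores <- ratios_to_scores(compute_log_ratios(pair), clamp = clamp,
                             min_genes = min_genes)
  drug_profile(pair$gene_ids, scores, drug_name = pair$drug_name,
               cell_line = pair$cell_line, concentration = pair$concentration,
               conc_unit = pair$conc_unit, n_replicates_averaged = 1L,
               clamp = clamp)
}

#' Average replicate drug treatment profiles
#'
#' Profiles are intersected on their common gene universe (dropped genes are
#' reported) and the trimmed scores averaged gene-wise. Averaging bounded
#' scores keeps the result within the trim bound.
#'
#' @param profiles list of [drug_profile()] objects sharing drug and cell
#'   line.
#' @return A single [drug_profile()] with `n_replicates_averaged` set to the
#'   total replicate count.
#' @export
average_replicates <- function(profiles) {
  if (!length(profiles)) stop("no profiles to average")
  stopifnot(all(vapply(profiles, inherits, logical(1), "drug_profile")))
  drugs <- unique(vapply(profiles, `[[`, character(1), "drug_name"))
  cells <- unique(vapply(profiles, `[[`, character(1), "cell_line"))
  if (length(drugs) > 1 || length(cells) > 1)
    stop("profiles mix drugs or cell lines: ",
         paste(drugs, collapse = ","), " / ", paste(cells, collapse = ","))
  common <- Reduce(intersect, lapply(profiles, `[[`, "gene_ids"))
  if (!length(common)) stop("profiles have disjoint gene sets")
  n_union <- length(Reduce(union, lapply(profiles, `[[`, "gene_ids")))
  if (n_union > length(common))
    message(sprintf("average_replicates: %d gene(s) not shared by all replicates dropped",
                    n_union - length(common)))
  mat <- vapply(profiles, function(p) p$score[common],
                numeric(length(common)))
  mat <- matrix(mat, nrow = length(common))
  nrep <- sum(vapply(profiles, `[[`, integer(1), "n_replicates_averaged"))
  drug_profile(common, rowMeans(mat), drug_name = drugs, cell_line = cells,
               concentration = profiles[[1]]$concentration,
               conc_unit = profiles[[1]]$conc_unit,
               n_replicates_averaged = nrep, clamp = profiles[[1]]$clamp)
}

#' Keep only the profiles at the highest treatment concentration
#'
#' Expression changes are assumed to saturate at high dose, so only the
#' profiles at the maximum observed concentration are carried forward; ties
#' are all retained (and typically averaged afterwards).
#'
#' @param profiles list of [drug_profile()] objects for one drug/cell line.
#' @return Sub-list of `profiles` at the maximum concentration.
#' @export
select_highest_concentration <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  units <- unique(vapply(profiles, `[[`, character(1), "conc_unit"))
  if (length(units) > 1)
    stop("mixed concentration units without conversion: ",
         paste(units, collapse = ","))
  conc <- vapply(profiles, `[[`, numeric(1), "concentration")
  profiles[conc == max(conc)]
}

#' Write a drug treatment profile as a two-column TSV
#'
#' Writes `gene_id`, `score` plus a JSON sidecar (`<path>.meta.json`) with the
#' drug, cell line, concentration and replicate count.
#'
#' @param profile a [drug_profile()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "drug_profile"))
  dir_create_logged(dirname(path))
  utils::write.table(
    data.frame(gene_id = profile$gene_ids,
               score = sprintf("%.17g", unname(profile$score))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- profile[c("drug_name", "cell_line", "concentration", "conc_unit",
                    "n_replicates_averaged", "clamp")]
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a drug treatment profile written by [write_profile()]
#'
#' @param path TSV path; the `.meta.json` sidecar is read if present.
#' @return A [drug_profile()].
#' @export
read_profile <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "score") %in% names(tab)))
    stop("profile file must have columns gene_id and score: ", path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  drug_profile(tab$gene_id, tab$score,
               drug_name = meta$drug_name %||% "drug",
               cell_line = meta$cell_line %||% "cell",
               concentration = meta$concentration %||% 1,
               conc_unit = meta$conc_unit %||% "uM",
               n_replicates_averaged = meta$n_replicates_averaged %||% 1L,
               clamp = meta$clamp %||% 20)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
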