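#' Convert a drug treatment profile into signature weights
#'
#' The signed, trimmed scores in `[-clamp, clamp]` are mapped linearly onto
#' two weight vectors in `[0, 1]`: `d_up = max(score, 0)/clamp` for the
#' up-regulated group and `d_dn = max(-score, 0)/clamp` for the
#' down-regulated group. A gene carries weight in at most one group; a score
#' at the trim bound saturates at weight 1.
#'
#' @param profile a [drug_profile()].
#' @return Object of class `drs_signature`: `gene_ids`, `d_up`, `d_dn`,
#'   plus the originating labels.
#' @export
weights_from_profile <- function(profile) {
  stopifnot(inherits(profile, "drug_profile"))
  s <- unname(profile$score)
  if (all(s == 0)) stop("all-zero profile: no signature")
  d_up <- pmax(s, 0) / profile$clamp
  d_dn <- pmax(-s, 0) / profile$clamp
  if (sum(d_up) == 0 || sum(d_dn) == 0)
    stop("signature needs nonempty up- and down-regulated groups")
  structure(
    list(gene_ids = profile$gene_ids,
         d_up = stats::setNames(d_up, profile$gene_ids),
         d_dn = stats::setNames(d_dn, profile$gene_ids),
         drug_name = profile$drug_name, cell_line = profile$cell_line),
    class = "drs_signature")
}

#' Foreground and background running sums
#'
#' Over a gene list sorted by sample expression, the foreground function
#' accumulates the weighted expression magnitudes `|g_j d_j|` and the
#' background function the complement-weighted magnitudes `|g_j (1 - d_j)|`,
#' each normalized by its total so both end at 1:
#' \deqn{f(i) = \sum_{j \le i} |g_j d_j| / \sum_{j \le n} |g_j d_j|, \qquad
#'       b(i) = \sum_{j \le i} |g_j (1-d_j)| / \sum_{j \le n} |g_j (1-d_j)|}
#'
#' @param g_sorted numeric sample expression values sorted descending.
#' @param d numeric weights in `[0, 1]` aligned to `g_sorted`.
#' @return List with nondecreasing vectors `f` and `b`, both ending at 1.
#' @export
running_sums <- function(g_sorted, d) {
  n <- length(g_sorted)
  if (length(d) != n) stop("g_sorted and d lengths differ")
  wf <- abs(g_sorted * d)
  wb <- abs(g_sorted * (1 - d))
  tf <- sum(wf)
  tb <- sum(wb)
  if (tf == 0 || tb == 0)
    stop("degenerate signature: a running-sum denominator is zero")
  list(f = cumsum(wf) / tf, b = cumsum(wb) / tb)
}

#' Pre-DRS: maximal excursion of the foreground minus background sums
#'
#' The positive part is the largest positive deviation `f(i) - b(i)` (floored
#' at 0), the negative part the most negative deviation (capped at 0); the
#' pre-DRS is whichever has the larger magnitude, with ties going to the
#' negative part. Always in `[-1, 1]`.
#'
#' @param f,b running-sum vectors from [running_sums()].
#' @return List: `value`, `pdrs_pos`, `pdrs_neg`, `i_max`, `i_min`.
#' @export
pdrs <- function(f, b) {
  if (length(f) != length(b)) stop("f and b lengths differ")
  dd <- f - b
  i_max <- which.max(dd)
  i_min <- which.min(dd)
  pos <- max(dd[i_max], 0)
  neg <- min(dd[i_min], 0)
  value <- if (pos > abs(neg)) pos else neg
  list(value = value, pdrs_pos = pos, pdrs_neg = neg,
       i_max = i_max, i_min = i_min)
}

# pre-DRS for one weight vector against an already-sorted sample
.pdrs_for <- function(g_sorted, d) {
  rs <- running_sums(g_sorted, d)
  pdrs(rs$f, rs$b)
}

# Null pre-DRS values by permuting gene labels of the sample profile.
# Permuting g and re-sorting is equivalent to permuting d against the fixed
# sorted g, which avoids re-sorting inside the loop.
.null_pdrs <- function(g_sorted, d_list, n_perm, seed) {
  n <- length(g_sorted)
  abs_g <- abs(g_sorted)
  out <- lapply(d_list, function(d) numeric(n_perm))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      perm <- sample.int(n)
      for (j in seq_along(d_list)) {
        dp <- d_list[[j]][perm]
        wf <- abs_g * dp
        wb <- abs_g * (1 - dp)
        tf <- sum(wf)
        tb <- sum(wb)
        if (tf == 0 || tb == 0)
          stop("degenerate signature in permutation null")
        dd <- cumsum(wf) / tf - cumsum(wb) / tb
        mx <- max(dd)
        mn <- min(dd)
        pos <- max(mx, 0)
        neg <- min(mn, 0)
        out[[j]][k] <- if (pos > abs(neg)) pos else neg
      }
    }
  })
  out
}

#' Normalize an observed pre-DRS against its permutation null
#'
#' Divides the observed pre-DRS by a magnitude drawn from the null pre-DRS
#' distribution obtained by permuting the genes of the sample profile. In
#' `"absolute"` mode (default) the divisor is the mean absolute null value;
#' in `"sign_matched"` mode a positive observed value is divided by the mean
#' of the positive nulls and a negative one by the mean magnitude of the
#' negative nulls. An observed value of 0 stays 0.
#'
#' @param observed observed pre-DRS.
#' @param null_values numeric vector of null pre-DRS values.
#' @param mode `"absolute"` or `"sign_matched"`.
#' @return Normalized score (signed real).
#' @export
normalize_pdrs <- function(observed, null_values,
                           mode = c("absolute", "sign_matched")) {
  mode <- match.arg(mode)
  if (observed == 0) return(0)
  divisor <- if (mode == "absolute") {
    mean(abs(null_values))
  } else if (observed > 0) {
    pos <- null_values[null_values > 0]
    if (length(pos)) mean(pos) else 0
  } else {
    neg <- null_values[null_values < 0]
    if (length(neg)) mean(abs(neg)) else 0
  }
  if (!is.finite(divisor) || divisor == 0)
    stop("degenerate permutation null (zero mean magnitude)")
  observed / divisor
}

#' Score one sample against a drug signature
#'
#' The sample profile is intersected with the signature's gene universe,
#' sorted by expression in descending order (ties broken by gene identifier
#' for reproducibility), and the running-sum pre-DRS is computed separately
#' for the up- and down-regulated weight vectors. Each pre-DRS is normalized
#' against its gene-permutation null, and the final score is
#' `drs = drs_up - drs_dn`. A positive DRS means the sample's expression
#' pattern resembles the drug-induced (pathway-inhibited) pattern.
#'
#' @param g named numeric vector of cohort-standardized expression for one
#'   sample (names are gene identifiers).
#' @param signature a [weights_from_profile()] result.
#' @param n_perm number of gene permutations for the null (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param min_overlap smallest acceptable gene-universe intersection.
#' @param null_mode passed to [normalize_pdrs()].
#' @param sample_id label recorded in the result.
#' @param return_null if `TRUE`, attach the null pre-DRS vectors.
#' @return List of class `drs_result`: `sample_id`, `pdrs_up`, `pdrs_dn`,
#'   `drs_up`, `drs_dn`, `drs`, `i_max`/`i_min` per group, `n_genes`,
#'   `n_perm`, `seed`; plus `null_up`/`null_dn` when requested.
#' @export
score_sample <- function(g, signature, n_perm = 1000, seed = 1,
                         min_overlap = 50,
                         null_mode = c("absolute", "sign_matched"),
                         sample_id = "sample", return_null = FALSE) {
  stopifnot(inherits(signature, "drs_signature"))
  null_mode <- match.arg(null_mode)
  if (is.null(names(g))) stop("sample profile g must be named by gene")
  common <- intersect(names(g), signature$gene_ids)
  if (length(common) < min_overlap)
    stop(sprintf(
      "gene overlap too small: %d common of %d sample / %d signature genes (need >= %d)",
      length(common), length(g), length(signature$gene_ids), min_overlap))
  gg <- g[common]
  ord <- order(-gg, common)          # descending expression, stable on id
  gg <- as.numeric(gg[ord])
  d_up <- as.numeric(signature$d_up[common][ord])
  d_dn <- as.numeric(signature$d_dn[common][ord])

  up <- .pdrs_for(gg, d_up)
  dn <- .pdrs_for(gg, d_dn)
  nulls <- .null_pdrs(gg, list(up = d_up, dn = d_dn), n_perm, seed)
  drs_up <- normalize_pdrs(up$value, nulls$up, mode = null_mode)
  drs_dn <- normalize_pdrs(dn$value, nulls$dn, mode = null_mode)
  res <- list(sample_id = sample_id,
              pdrs_up = up$value, pdrs_dn = dn$value,
              drs_up = drs_up, drs_dn = drs_dn,
              drs = drs_up - drs_dn,
              i_max_up = up$i_max, i_min_up = up$i_min,
              i_max_dn = dn$i_max, i_min_dn = dn$i_min,
              n_genes = length(common), n_perm = n_perm, seed = seed)
  if (return_null) {
    res$null_up <- nulls$up
    res$null_dn <- nulls$dn
  }
  class(res) <- "drs_result"
  res
}

#' Standardize a cohort matrix gene-wise
#'
#' Centers and scales each gene (row) to mean 0, sd 1 across samples, the
#' scale on which "highly expressed" is meaningful relative to the cohort.
#' Genes with zero variance are set to all-zero with a message.
#'
#' @param expr numeric matrix, genes in rows, samples in columns.
#' @return Matrix of the same shape.
#' @export
standardize_cohort <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  mu <- rowMeans(expr)
  sd_ <- apply(expr, 1, stats::sd)
  flat <- sd_ == 0 | !is.finite(sd_)
  if (any(flat)) {
    message(sprintf("standardize_cohort: %d zero-variance gene(s) set to 0",
                    sum(flat)))
    sd_[flat] <- 1
  }
  out <- (expr - mu) / sd_
  out[flat, ] <- 0
  out
}

#' Score every sample of a cohort against one or more drug profiles
#'
#' The cohort is standardized gene-wise, then each (sample, profile) pair is
#' scored with [score_sample()]. Per-sample seeds are derived from the root
#' seed plus a hash of the sample's expression values, so results are
#' reproducible, invariant to column order, and identical samples receive
#' identical scores. Per-sample
#' failures are flagged in the `note` column rather than dropped.
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @param profiles a [drug_profile()] or list of them.
#' @param n_perm,seed,min_overlap,null_mode passed to [score_sample()].
#' @param standardize standardize gene-wise first (default `TRUE`).
#' @return `data.frame` in long format, one row per (sample, drug):
#'   `sample_id`, `drug`, `cell_line`, `pdrs_up`, `pdrs_dn`, `drs_up`,
#'   `drs_dn`, `drs`, `n_genes`, `n_perm`, `seed`, `note`.
#' @export
score_cohort <- function(expr, profiles, n_perm = 1000, seed = 1,
                         min_overlap = 50,
                         null_mode = c("absolute", "sign_matched"),
                         standardize = TRUE) {
  null_mode <- match.arg(null_mode)
  if (inherits(profiles, "drug_profile")) profiles <- list(profiles)
  stopifnot(is.matrix(expr),
            !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (standardize) expr <- standardize_cohort(expr)
  sigs <- lapply(profiles, weights_from_profile)
  n_samp <- ncol(expr)
  rows <- vector("list", length(profiles) * n_samp)
  k <- 0L
  for (p in seq_along(profiles)) {
    sig <- sigs[[p]]
    for (s in seq_len(n_samp)) {
      k <- k + 1L
      sid <- colnames(expr)[s]
      # seed derived from root seed + sample content: identical samples get
      # identical permutation streams, and scoring is column-order invariant
      samp_seed <- (seed + p * 131L + content_seed(expr[, s])) %%
        .Machine$integer.max
      res <- tryCatch(
        score_sample(expr[, s], sig, n_perm = n_perm, seed = samp_seed,
                     min_overlap = min_overlap, null_mode = null_mode,
                     sample_id = sid),
        error = function(e) e)
      rows[[k]] <- if (inherits(res, "error")) {
        data.frame(sample_id = sid, drug = sig$drug_name,
                   cell_line = sig$cell_line,
                   pdrs_up = NA_real_, pdrs_dn = NA_real_,
                   drs_up = NA_real_, drs_dn = NA_real_, drs = NA_real_,
                   n_genes = NA_integer_, n_perm = n_perm, seed = samp_seed,
                   note = conditionMessage(res),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(sample_id = sid, drug = sig$drug_name,
                   cell_line = sig$cell_line,
                   pdrs_up = res$pdrs_up, pdrs_dn = res$pdrs_dn,
                   drs_up = res$drs_up, drs_dn = res$drs_dn, drs = res$drs,
                   n_genes = res$n_genes, n_perm = n_perm, seed = samp_seed,
                   note = "", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Deterministic integer hash of a numeric vector (md5 of its full-precision
# text form), used to derive per-sample permutation seeds.
content_seed <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(format(unname(x), digits = 17), tmp)
  strtoi(substr(unname(tools::md5sum(tmp)), 1, 7), 16L)
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
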