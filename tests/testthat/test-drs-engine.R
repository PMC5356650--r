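test_that("weights map linearly from trimmed scores", {
  p <- drug_profile(c("a", "b", "c"), c(20, -10, 0))
  w <- weights_from_profile(p)
  expect_equal(unname(w$d_up), c(1, 0, 0))
  expect_equal(unname(w$d_dn), c(0, 0.5, 0))
  # at most one group per gene
  expect_true(all(w$d_up * w$d_dn == 0))

  expect_error(weights_from_profile(drug_profile("a", 0)), "all-zero")
  expect_error(weights_from_profile(drug_profile(c("a", "b"), c(1, 2))),
               "nonempty")
})

test_that("running sums reproduce the hand-computed toy and end at 1", {
  rs <- running_sums(c(3, 2, 1), c(1, 0, 0))
  expect_equal(rs$f, c(1, 1, 1))
  expect_equal(rs$b, c(0, 2 / 3, 1))

  # equal weights make foreground and background identical
  rs2 <- running_sums(c(5, -1, 0.5, -2), rep(0.5, 4))
  expect_equal(rs2$f, rs2$b)

  set.seed(7)
  for (i in 1:20) {
    inst <- random_instance(sample(3:20, 1))
    rs <- running_sums(inst$g, inst$d)
    expect_equal(rs$f[length(rs$f)], 1)
    expect_equal(rs$b[length(rs$b)], 1)
    expect_true(all(diff(rs$f) >= -1e-15) && all(diff(rs$b) >= -1e-15))
  }

  expect_error(running_sums(c(1, 1), c(0, 0)), "degenerate")
  expect_error(running_sums(c(1, 1), c(1, 1)), "degenerate")
})

test_that("pre-DRS picks the dominant excursion and lies in [-1, 1]", {
  r <- pdrs(c(1, 1, 1), c(0, 2 / 3, 1))
  expect_equal(r$value, 1)
  expect_equal(r$i_max, 1L)
  expect_equal(r$pdrs_neg, 0)

  r0 <- pdrs(c(0.2, 0.7, 1), c(0.2, 0.7, 1))
  expect_equal(r0$value, 0)

  # positive excursion larger in magnitude wins
  r1 <- pdrs(c(0.7, 0.3, 1), c(0.1, 0.5, 1))
  expect_equal(r1$pdrs_pos, 0.6)
  expect_equal(r1$pdrs_neg, -0.2)
  expect_equal(r1$value, 0.6)

  set.seed(8)
  for (i in 1:50) {
    inst <- random_instance(sample(3:12, 1))
    rs <- running_sums(inst$g, inst$d)
    expect_true(abs(pdrs(rs$f, rs$b)$value) <= 1)
  }
})

test_that("vectorized engine matches the brute-force loop oracle", {
  set.seed(11)
  for (i in 1:40) {
    inst <- random_instance(sample(3:12, 1))
    rs <- running_sums(inst$g, inst$d)
    brs <- brute_running_sums(inst$g, inst$d)
    expect_equal(rs$f, brs$f, tolerance = 1e-12)
    expect_equal(rs$b, brs$b, tolerance = 1e-12)
    expect_equal(pdrs(rs$f, rs$b)$value, brute_pdrs(inst$g, inst$d),
                 tolerance = 1e-12)
  }
})

test_that("pre-DRS is invariant to positive rescaling of expression", {
  set.seed(12)
  for (i in 1:10) {
    inst <- random_instance(10)
    v1 <- pdrs(running_sums(inst$g, inst$d)$f,
               running_sums(inst$g, inst$d)$b)$value
    for (c_ in c(0.001, 7, 1e6)) {
      rs <- running_sums(c_ * inst$g, inst$d)
      expect_equal(pdrs(rs$f, rs$b)$value, v1, tolerance = 1e-12)
    }
  }
})

test_that("a lone weighted gene moved up the ranking never loses pre-DRS", {
  set.seed(13)
  for (t in 1:20) {
    n <- 9
    g <- sort(abs(stats::rnorm(n)) + 0.05, decreasing = TRUE)
    w <- stats::runif(1, 0.2, 1)
    vals <- sapply(seq_len(n), function(pos) {
      d <- numeric(n)
      d[pos] <- w
      r <- running_sums(g, d)
      pdrs(r$f, r$b)$pdrs_pos
    })
    # earlier position = higher rank; pdrs_pos nonincreasing along positions
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("permutation normalization divides by the null magnitude", {
  expect_equal(normalize_pdrs(0.5, c(0.25, -0.25)), 2)
  expect_equal(normalize_pdrs(0, c(0.5, 0.9)), 0)
  expect_equal(normalize_pdrs(-0.3, c(0.1, -0.2, 0.3)), -1.5)
  # sign-matched mode uses only same-signed nulls
  expect_equal(normalize_pdrs(0.5, c(0.25, -0.75), mode = "sign_matched"), 2)
  expect_error(normalize_pdrs(0.5, c(0, 0)), "degenerate")
})

test_that("sample scoring is seed-deterministic and gene-order invariant", {
  prof <- toy_profile()
  sig <- weights_from_profile(prof)
  set.seed(21)
  g <- stats::setNames(stats::rnorm(60), prof$gene_ids)
  r1 <- score_sample(g, sig, n_perm = 50, seed = 5, min_overlap = 10)
  r2 <- score_sample(g, sig, n_perm = 50, seed = 5, min_overlap = 10)
  expect_identical(r1$drs, r2$drs)

  shuffled <- g[sample(names(g))]
  r3 <- score_sample(shuffled, sig, n_perm = 50, seed = 5, min_overlap = 10)
  expect_identical(r1$drs, r3$drs)

  r4 <- score_sample(g, sig, n_perm = 50, seed = 6, min_overlap = 10)
  expect_false(identical(r1$drs, r4$drs))
})

test_that("concordant samples score positive and their mirrors negative", {
  prof <- toy_profile(n_genes = 80, n_up = 15, n_dn = 15)
  sig <- weights_from_profile(prof)
  # up-weighted genes at the top of the expression ranking, down at bottom
  g <- stats::setNames(seq(3, -3, length.out = 80), prof$gene_ids)
  conc <- score_sample(g, sig, n_perm = 100, seed = 3, min_overlap = 10)
  expect_gt(conc$drs, 0)
  disc <- score_sample(-g, sig, n_perm = 100, seed = 3, min_overlap = 10)
  expect_lt(disc$drs, 0)
  # bounds on the unnormalized parts
  expect_true(abs(conc$pdrs_up) <= 1 && abs(conc$pdrs_dn) <= 1)
  expect_lt(conc$drs_up * disc$drs_up, 0)
})

test_that("shuffled samples score near zero on average", {
  prof <- toy_profile(n_genes = 200, n_up = 20, n_dn = 20)
  sig <- weights_from_profile(prof)
  set.seed(31)
  vals <- replicate(60, {
    g <- stats::setNames(stats::rnorm(200), sample(prof$gene_ids))
    score_sample(g, sig, n_perm = 50, seed = sample.int(1e6, 1),
                 min_overlap = 10)$drs
  })
  expect_lt(abs(mean(vals)), 0.25)
})

test_that("cohort scoring is complete, consistent, and flags failures", {
  prof <- toy_profile(n_genes = 60, n_up = 10, n_dn = 10)
  profs <- list(prof,
                drug_profile(prof$gene_ids, unname(prof$score) / 2,
                             drug_name = "half"),
                drug_profile(prof$gene_ids, -unname(prof$score),
                             drug_name = "mirror"))
  set.seed(41)
  expr <- matrix(stats::rnorm(60 * 10), nrow = 60,
                 dimnames = list(prof$gene_ids, sprintf("s%02d", 1:10)))
  tab <- score_cohort(expr, profs, n_perm = 30, seed = 2, min_overlap = 10)
  expect_equal(nrow(tab), 30)
  expect_setequal(unique(tab$drug), c("toy_drug", "half", "mirror"))
  expect_true(all(tab$note == ""))
  expect_equal(tab$drs, tab$drs_up - tab$drs_dn)

  # identical samples get identical scores per profile
  expr_id <- matrix(rep(expr[, 1], 4), nrow = 60,
                    dimnames = list(prof$gene_ids, paste0("r", 1:4)))
  tab_id <- suppressMessages(
    score_cohort(expr_id, prof, n_perm = 30, seed = 2, min_overlap = 10,
                 standardize = FALSE))
  expect_equal(length(unique(tab_id$drs)), 1)

  # an unsalvageable sample is flagged, not dropped
  expr_bad <- expr
  expr_bad[, 3] <- 0
  tab_bad <- suppressMessages(
    score_cohort(expr_bad, prof, n_perm = 30, seed = 2, min_overlap = 10,
                 standardize = FALSE))
  expect_equal(nrow(tab_bad), 10)
  expect_match(tab_bad$note[3], "degenerate")
  expect_true(is.na(tab_bad$drs[3]))
})

test_that("gene-wise standardization centers and scales the cohort", {
  set.seed(51)
  expr <- matrix(stats::rnorm(200, mean = 5, sd = 3), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  z <- standardize_cohort(expr)
  expect_equal(unname(rowMeans(z)), rep(0, 20))
  expect_equal(unname(apply(z, 1, stats::sd)), rep(1, 20))
  expr[1, ] <- 7
  expect_message(z2 <- standardize_cohort(expr), "zero-variance")
  expect_equal(unname(z2[1, ]), rep(0, 10))
})
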