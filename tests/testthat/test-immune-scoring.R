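test_that("population scores are marker means on log2 scale", {
  genes <- c("FOXP3", "CD8A", "CD8B")
  vals <- matrix(c(3, 5, 1,
                   4, 6, 2), nrow = 3,
                 dimnames = list(NULL, c("s1", "s2")))
  expr <- toy_expr(genes, vals)
  mm <- tibble::tibble(
    population = c("Treg cells", "CD8+ T cells", "CD8+ T cells"),
    gene = c("FOXP3", "CD8A", "CD8B"))
  sc <- score_populations(expr, mm)
  m <- immunoscape:::wide_to_matrix(sc, "population")
  # single-marker population equals that gene's row
  expect_equal(m["Treg cells", ], c(s1 = 3, s2 = 4))
  # multi-marker population is the arithmetic mean of log2 values
  expect_equal(m["CD8+ T cells", ], c(s1 = 3, s2 = 4))

  # constant markers give a constant score
  expr_c <- toy_expr(genes, matrix(7, 3, 2,
                                   dimnames = list(NULL, c("s1", "s2"))))
  sc_c <- score_populations(expr_c, mm)
  expect_true(all(immunoscape:::wide_to_matrix(sc_c, "population") == 7))

  # absent markers are dropped with a warning; empty populations error
  mm2 <- dplyr::bind_rows(mm, tibble::tibble(population = "NK cells",
                                             gene = "NCR1"))
  expect_error(expect_warning(score_populations(expr, mm2), "NCR1"),
               "NK cells")
})

test_that("the default map scores 14 populations with the canonical cytotoxic set", {
  mm <- default_marker_map()
  cytotoxic <- sort(c("PRF1", "GZMA", "GZMB", "GZMH", "GNLY", "CTSW",
                      "KLRB1", "KLRD1", "KLRK1", "NKG7"))
  expect_identical(sort(mm$gene[mm$population == "Cytotoxic cells"]),
                   cytotoxic)
  expect_identical(sort(mm$gene[mm$population == "CD8+ T cells"]),
                   c("CD8A", "CD8B"))
  sim <- small_cohort(seed = 41)
  sc <- score_populations(normalize_counts(sim$counts))
  expect_equal(nrow(sc), 14)
})

test_that("score linearity: a log2 shift of a population's markers shifts its score exactly", {
  sim <- small_cohort(seed = 42)
  expr <- normalize_counts(sim$counts)
  sc0 <- score_populations(expr)
  treg_markers <- default_marker_map() |>
    dplyr::filter(population == "Treg cells") |>
    dplyr::pull(gene)
  shifted <- expr
  rows <- shifted$gene %in% treg_markers
  for (s in immunoscape:::sample_ids(shifted, "gene")) {
    shifted[rows, s] <- shifted[rows, s] + 1.5
  }
  sc1 <- score_populations(shifted)
  m0 <- immunoscape:::wide_to_matrix(sc0, "population")
  m1 <- immunoscape:::wide_to_matrix(sc1, "population")
  expect_equal(m1["Treg cells", ], m0["Treg cells", ] + 1.5)
  expect_equal(m1["NK cells", ], m0["NK cells", ])
  # and the total-TIL score moves by delta / n_populations
  til0 <- til_score(sc0)$til
  til1 <- til_score(sc1)$til
  expect_equal(til1, til0 + 1.5 / 14)
})

test_that("TIL score reduces to single components and respects configuration", {
  m <- matrix(rnorm(42), nrow = 14,
              dimnames = list(paste0("P", 1:14), paste0("s", 1:3)))
  sc <- toy_scores(m)
  expect_equal(til_score(sc, "P3")$til, unname(m["P3", ]))
  expect_equal(til_score(sc)$til, unname(colMeans(m)))
  expect_error(til_score(sc, character(0)), "empty")
  expect_error(til_score(sc, "P99"), "unknown")
})

test_that("immunological distance is the Manhattan metric", {
  m <- matrix(c(rep(0, 14), rep(1, 14), rep(0, 13), 1), nrow = 14,
              dimnames = list(paste0("P", 1:14), c("a", "b", "c")))
  d <- immune_distance(toy_scores(m))
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 14)  # all-zeros vs all-ones
  expect_equal(d["a", "c"], 1)   # single-population unit difference

  # metric axioms on random score matrices
  set.seed(7)
  for (i in 1:5) {
    mm <- matrix(rnorm(14 * 8), nrow = 14,
                 dimnames = list(paste0("P", 1:14), paste0("s", 1:8)))
    dd <- immune_distance(toy_scores(mm))
    expect_equal(dd, t(dd))
    expect_true(all(diag(dd) == 0))
    expect_true(all(dd >= 0))
    for (k in 1:8) {
      lhs <- dd[1, 2]
      expect_lte(lhs, dd[1, k] + dd[k, 2] + 1e-12)
    }
    expect_equal(dd["s1", "s2"], oracle_manhattan(mm[, 1], mm[, 2]))
  }
})

test_that("closeness test behaves under symmetry, construction and swap", {
  md <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    subgroup = c(rep("ALK", 4), rep("NEG", 8)),
    icb_response = c(rep(NA, 4), rep("LTR", 4), rep("RP", 4)))

  # reference groups with identical profiles: all differences 0, p = 1
  m <- matrix(0, nrow = 14, ncol = 12,
              dimnames = list(paste0("P", 1:14), md$sample_id))
  m[, 1:4] <- rnorm(14 * 4)
  ct <- closeness_test(toy_scores(m), md, "ALK")
  expect_equal(ct$samples$diff, rep(0, 4))
  expect_equal(ct$p_value, 1)

  # query at ref-A's profile, ref-B displaced by 2 in one population:
  # every query sample is strictly closer to A
  m2 <- matrix(0, nrow = 14, ncol = 12,
               dimnames = dimnames(m))
  m2[1, md$icb_response %in% "RP"] <- 2
  ct2 <- closeness_test(toy_scores(m2), md, "ALK")
  expect_true(all(ct2$samples$diff < 0))

  # swapping the references negates the per-sample differences
  ct3 <- closeness_test(toy_scores(m2), md, "ALK",
                        ref_a = "RP", ref_b = "LTR")
  expect_equal(ct3$samples$diff, -ct2$samples$diff)

  expect_error(closeness_test(toy_scores(m2), md, "EGFR"), "nonempty")
})

test_that("PD-L1 readout extracts CD274 and errors when absent", {
  expr <- toy_expr(c("CD274", "OTHER"),
                   matrix(c(5, 1, 5, 2), nrow = 2,
                          dimnames = list(NULL, c("s1", "s2"))))
  p <- pdl1_expression(expr)
  expect_equal(p$pdl1, c(5, 5))
  expect_error(pdl1_expression(toy_expr("OTHER",
    matrix(1, 1, 2, dimnames = list(NULL, c("s1", "s2"))))), "CD274")
})

test_that("a shared latent factor induces positive PD-L1 / cytotoxic correlation", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    f <- rnorm(n)
    feats <- rbind(`PD-L1` = f + rnorm(n, 0, 0.5),
                   Cytotoxic = f + rnorm(n, 0, 0.5),
                   Unrelated = rnorm(n))
    colnames(feats) <- paste0("s", 1:n)
    tab <- dplyr::bind_cols(tibble::tibble(feature = rownames(feats)),
                            tibble::as_tibble(feats))
    res <- spearman_panel(tab, "PD-L1")
    res$rho[res$feature == "Cytotoxic"] > 0
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("sample permutation permutes score columns identically", {
  sim <- small_cohort(seed = 44)
  expr <- normalize_counts(sim$counts)
  sc <- score_populations(expr)
  ids <- immunoscape:::sample_ids(expr, "gene")
  perm <- rev(ids)
  expr_p <- expr[, c("gene", "probe_class", perm)]
  class(expr_p) <- class(expr)
  sc_p <- score_populations(expr_p)
  expect_identical(sc_p[, c("population", ids)][, -1], sc[, -1])
})
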