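test_that("signed fold change matches its closed form and conventions", {
  expect_equal(signed_fc(c(3, 5), c(2, 4)), 2)        # d = 1
  expect_equal(signed_fc(1:3, 1:3), 1)                # d = 0
  d <- -log2(2.1)
  expect_equal(signed_fc(rep(d, 3), rep(0, 3)), -2.1) # paper-style sign
  # antisymmetry and the |FC| >= 1 floor on random inputs
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1))
    fab <- signed_fc(a, b); fba <- signed_fc(b, a)
    expect_gte(abs(fab), 1)
    if (fab != 1) expect_equal(fab, -fba) else expect_equal(fba, 1)
    expect_equal(abs(fab), abs(fba))
  }
  expect_error(signed_fc(numeric(0), 1), "nonempty")
})

test_that("Kruskal-Wallis omnibus handles shifts, identity and degeneracy", {
  g <- rep(c("a", "b", "c"), each = 10)
  set.seed(4)
  x <- rnorm(30)
  r1 <- kruskal_omnibus(x, g)
  r2 <- kruskal_omnibus(x, g)
  expect_identical(r1$statistic, r2$statistic)
  expect_equal(r1$df, 2)

  x_shift <- x; x_shift[1:10] <- x_shift[1:10] + 1000
  expect_lt(kruskal_omnibus(x_shift, g)$p_value, 0.01)

  deg <- kruskal_omnibus(rep(5, 30), g)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(kruskal_omnibus(x, rep("a", 30)), "2 nonempty")
})

test_that("Kruskal-Wallis p agrees with a permutation oracle on random inputs", {
  # group sizes chosen large enough that the chi-square approximation
  # error is far below the oracle's Monte-Carlo error
  set.seed(13)
  for (i in 1:2) {
    x <- rnorm(300)
    g <- rep(c("a", "b", "c"), each = 100)
    res <- kruskal_omnibus(x, g)
    orc <- oracle_kw_perm(x, g, B = 2e4)
    se <- max(sqrt(orc$p * (1 - orc$p) / 2e4), 1e-4)
    expect_lt(abs(res$p_value - orc$p), 3 * se)
    expect_equal(res$statistic, orc$h, tolerance = 1e-10)
  }
})

test_that("Wilcoxon p equals full enumeration for small samples", {
  # the canonical fully separated case: U = 0, p = 2/20
  expect_equal(wilcoxon_pair(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical multisets give p = 1 and swapping groups changes nothing
  expect_equal(wilcoxon_pair(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(6)
  for (i in 1:15) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- rnorm(na); b <- rnorm(nb)
    expect_equal(wilcoxon_pair(a, b), oracle_wilcox_exact(a, b),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_pair(a, b), wilcoxon_pair(b, a))
  }
})

test_that("BH adjustment equals the brute-force step-up rule exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(8)
  for (n in c(3, 17, 1000)) {
    p <- runif(n)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("population analysis has the contracted shape and grouping modes", {
  sim <- small_cohort(seed = 61)
  sc <- score_populations(normalize_counts(sim$counts))
  md <- sim$metadata

  res <- test_populations(sc, md)
  expect_equal(nrow(res), 14 * 3)   # 14 populations x 3 pairwise contrasts
  expect_true(all(res$q_omnibus >= res$p_omnibus - 1e-15))
  expect_true(all(abs(res$fc) >= 1))

  res4 <- test_populations(sc, md, mode = "four_group")
  expect_setequal(unique(c(res4$group_a, res4$group_b)),
                  c("ALK", "EGFR", "LTR", "RP"))   # IR excluded
  expect_equal(nrow(res4), 14 * 6)
  # four-group contrasts exclude the IR samples entirely
  expect_equal(unique(res4$n_a[res4$group_a == "LTR"]), 4)

  res_s <- suppressWarnings(test_populations(sc, md, strata = "smoking"))
  expect_true("stratum" %in% names(res_s))
  expect_setequal(unique(res_s$stratum),
                  unique(md$smoking[!is.na(md$smoking)]))
})

test_that("gene analysis orders by omnibus p with stable ties and controls q >= p", {
  sim <- small_cohort(seed = 62)
  expr <- normalize_counts(sim$counts)
  res <- test_genes(expr, sim$metadata)
  expect_equal(dplyr::n_distinct(res$feature), 200)
  ord <- order(res$p_omnibus, res$feature)
  expect_identical(res$feature, res$feature[ord])
  expect_true(all(res$q_omnibus >= res$p_omnibus - 1e-15))
})

test_that("planted differential genes are detected with correct sign", {
  # plant a 3-fold shift on one population's markers and check the
  # marker genes surface in the gene-level lists
  contrasts <- tibble::tibble(population = "Cytotoxic cells",
                              group_a = "ALK", group_b = "NEG", fc = 3)
  sim <- small_cohort(seed = 63, contrasts = contrasts)
  expr <- normalize_counts(sim$counts)
  res <- test_genes(expr, sim$metadata)
  markers <- default_marker_map()
  cyto <- markers$gene[markers$population == "Cytotoxic cells"]
  hits <- de_features(res, "ALK", "NEG")
  expect_gte(length(intersect(cyto, hits)), 5)
  sub <- res[res$feature %in% cyto & res$group_a == "ALK" &
               res$group_b == "NEG", ]
  expect_true(all(sub$fc > 1))
})

test_that("set decomposition obeys set algebra including the 12/11/5 shape", {
  d1 <- set_decomposition(paste0("g", 1:12), paste0("h", 1:11))
  expect_equal(unname(d1$counts), c(12, 11, 0))
  d2 <- set_decomposition(c("g1", "g2", "g3"), c("g3", "g4"))
  expect_equal(unname(d2$counts), c(2, 1, 1))
  a <- c(paste0("x", 1:12), paste0("s", 1:5))
  b <- c(paste0("y", 1:11), paste0("s", 1:5))
  d3 <- set_decomposition(a, b)
  expect_equal(unname(d3$counts), c(12, 11, 5))
  expect_setequal(d3$shared, paste0("s", 1:5))
})

test_that("gene-set summaries count DE members per contrast", {
  contrasts <- tibble::tibble(population = "Cytotoxic cells",
                              group_a = "ALK", group_b = "NEG", fc = 3)
  sim <- small_cohort(seed = 64, contrasts = contrasts)
  res <- test_genes(normalize_counts(sim$counts), sim$metadata)
  markers <- default_marker_map()
  cyto <- markers$gene[markers$population == "Cytotoxic cells"]
  gs <- gene_set_summary(res, cyto)
  expect_equal(gs$set_size, 10)
  n_alk_neg <- gs$counts$n_de[gs$counts$group_a == "ALK" &
                                gs$counts$group_b == "NEG"]
  expect_gte(n_alk_neg, 5)
  expect_named(gs$decomposition$counts,
               c("exclusive_a", "exclusive_b", "shared"))
  expect_warning(gene_set_summary(res, "ABSENT_GENE"), "intersect")
})

test_that("spearman panel matches closed forms and flags constants", {
  set.seed(9)
  x <- rnorm(20)
  feats <- rbind(anchor = x, mono_down = -2 * x + 3, flat = rep(1, 20))
  colnames(feats) <- paste0("s", 1:20)
  tab <- dplyr::bind_cols(tibble::tibble(feature = rownames(feats)),
                          tibble::as_tibble(feats))
  res <- spearman_panel(tab, "anchor")
  expect_equal(res$rho[res$feature == "mono_down"], -1)
  expect_true(res$constant[res$feature == "flat"])
  expect_true(is.na(res$rho[res$feature == "flat"]))
  expect_error(spearman_panel(tab, "nope"), "not found")

  # null distribution: 95th percentile of |rho| across independent
  # features is close to the theoretical null quantile at n = 114
  set.seed(10)
  null_feats <- matrix(rnorm(401 * 114), nrow = 401,
                       dimnames = list(c("anchor", paste0("f", 1:400)),
                                       paste0("s", 1:114)))
  null_tab <- dplyr::bind_cols(
    tibble::tibble(feature = rownames(null_feats)),
    tibble::as_tibble(null_feats))
  null_res <- spearman_panel(null_tab, "anchor")
  # sd of Spearman rho under the null is ~ 1/sqrt(n - 1)
  expect_equal(unname(quantile(abs(null_res$rho), 0.95)),
               qnorm(0.975) / sqrt(113), tolerance = 0.15)
})
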