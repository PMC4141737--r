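peptide_row <- function(protein = "P1", residues = 10, sequence = "AAAYAAA",
                        n_phospho = 1L, n_proline = 0L, replicate = 1L,
                        ratios = c(1, 1, 1, 1)) {
  data.frame(protein = protein, residues = residues, sequence = sequence,
             n_phospho = n_phospho, n_proline = n_proline,
             replicate = replicate, t5 = ratios[1], t15 = ratios[2],
             t30 = ratios[3], t60 = ratios[4], stringsAsFactors = FALSE)
}

test_that("proline-conversion correction follows (1-f)^(-n_proline)", {
  tab <- peptide_row(n_proline = 0L, ratios = c(1, 2, 3, 4))
  expect_identical(correct_proline(tab, 0.2), tab)       # no prolines
  tab2 <- peptide_row(n_proline = 2L, ratios = c(1, 2, 3, 4))
  expect_identical(correct_proline(tab2, 0), tab2)       # correction off
  out <- correct_proline(tab2, 0.1)
  expect_equal(out$t5, 1 / 0.81)
  expect_equal(out$t60, 4 / 0.81)
  expect_error(correct_proline(tab2, 1), "\\[0, 1\\)")
})

test_that("site collapse keeps the least modified peptide with documented tie-breaks", {
  tab <- rbind(peptide_row(sequence = "AAAYAAA", n_phospho = 1L),
               peptide_row(sequence = "AAAYAASSS", n_phospho = 2L))
  out <- collapse_to_sites(tab)
  expect_identical(out$sequence, "AAAYAAA")
  ## single record collapses to itself
  one <- peptide_row()
  expect_identical(collapse_to_sites(one), one)
  ## tie at n_phospho = 1: the 9-mer beats the 12-mer
  tie <- rbind(peptide_row(sequence = "AAAYAAAAAAAQ", n_phospho = 1L),
               peptide_row(sequence = "DDDYDDDDD", n_phospho = 1L))
  expect_identical(collapse_to_sites(tie)$sequence, "DDDYDDDDD")
  ## lexicographic tie-break at equal length
  lex <- rbind(peptide_row(sequence = "BBBYBBBBB", n_phospho = 1L),
               peptide_row(sequence = "AAAYAAAAA", n_phospho = 1L))
  expect_identical(collapse_to_sites(lex)$sequence, "AAAYAAAAA")
})

test_that("replicate averaging uses available values and records counts", {
  tab <- rbind(peptide_row(replicate = 1L, ratios = c(2, NA, 1, 2)),
               peptide_row(replicate = 2L, ratios = c(NA, NA, 3, 4)))
  out <- average_replicates(tab)
  expect_identical(out$t5, 2)      # one replicate only
  expect_true(is.na(out$sd_t5))
  expect_true(is.na(out$t15))      # missing in all replicates
  expect_identical(out$n_t15, 0L)
  expect_identical(out$t60, 3)     # mean of 2 and 4
  expect_identical(out$n_t60, 2L)
  expect_equal(out$sd_t60, sqrt(2))
  allna <- peptide_row(ratios = rep(NA_real_, 4))
  expect_error(average_replicates(allna), "no ratio values")
})

test_that("regulation filtering applies the two-fold rule with direction and timing", {
  courses <- rbind(
    data.frame(site = "up", protein = "P1", residues = 1,
               t5 = 1.2, t15 = 1.5, t30 = 2.0, t60 = 1.8),
    data.frame(site = "down", protein = "P2", residues = 2,
               t5 = 0.9, t15 = 0.6, t30 = 0.5, t60 = 0.55),
    data.frame(site = "flat", protein = "P3", residues = 3,
               t5 = 1.1, t15 = 0.8, t30 = 1.3, t60 = 1.4))
  out <- filter_regulated(courses, threshold = 2)
  expect_setequal(out$site, c("up", "down"))
  expect_identical(out$direction[out$site == "up"], "up")
  expect_identical(out$earliest_s[out$site == "up"], 30)
  expect_identical(out$direction[out$site == "down"], "down")
  expect_identical(out$earliest_s[out$site == "down"], 30)
  ## boundary semantics: >= by default, > when strict
  expect_true("up" %in% filter_regulated(courses, 2)$site)
  expect_false("up" %in% filter_regulated(courses, 2, strict = TRUE)$site)
  expect_error(filter_regulated(courses, 1), "exceed 1")
})

test_that("the regulated set shrinks monotonically in the threshold", {
  set.seed(5150)
  for (rep in 1:5) {
    g <- generate_ratio_table(generator_config(n_sites = 80L, seed = rep))
    courses <- average_replicates(collapse_to_sites(g$table))
    sets <- lapply(c(1.5, 2, 3), function(th)
      filter_regulated(courses, threshold = th)$site)
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
  }
})

test_that("fuzzy c-means recovers well-separated archetypes and is deterministic", {
  set.seed(11)
  mk <- function(site, mu) data.frame(
    site = site, protein = site, residues = 1,
    t5 = 2^(mu[1]), t15 = 2^(mu[2]), t30 = 2^(mu[3]), t60 = 2^(mu[4]))
  up <- do.call(rbind, lapply(1:10, function(i)
    mk(paste0("u", i), c(1.5, 1.8, 2, 2) + stats::rnorm(4, 0, 0.05))))
  dn <- do.call(rbind, lapply(1:10, function(i)
    mk(paste0("d", i), c(-0.8, -1.2, -1.5, -1.6) + stats::rnorm(4, 0, 0.05))))
  courses <- rbind(up, dn)
  fcm <- cluster_fuzzy_cmeans(courses, c = 2, seed = 4)
  expect_true(all(rowSums(fcm$membership) - 1 < 1e-9))
  lab_up <- fcm$hard[startsWith(fcm$sites, "u")]
  lab_dn <- fcm$hard[startsWith(fcm$sites, "d")]
  expect_identical(length(unique(lab_up)), 1L)
  expect_identical(length(unique(lab_dn)), 1L)
  expect_false(unique(lab_up) == unique(lab_dn))
  fcm2 <- cluster_fuzzy_cmeans(courses, c = 2, seed = 4)
  expect_identical(fcm$membership, fcm2$membership)
  expect_error(cluster_fuzzy_cmeans(courses[1, ], c = 2), "at least")
})

test_that("PCA classification separates decreasing, fast and delayed courses", {
  set.seed(21)
  mk <- function(site, mu) data.frame(
    site = site, protein = site, residues = 1,
    t5 = 2^(mu[1]), t15 = 2^(mu[2]), t30 = 2^(mu[3]), t60 = 2^(mu[4]))
  fast <- do.call(rbind, lapply(1:6, function(i)
    mk(paste0("f", i), c(1.7, 2, 2, 2) + stats::rnorm(4, 0, 0.05))))
  slow <- do.call(rbind, lapply(1:6, function(i)
    mk(paste0("s", i), c(0.1, 0.4, 1.2, 2) + stats::rnorm(4, 0, 0.05))))
  down <- do.call(rbind, lapply(1:6, function(i)
    mk(paste0("d", i), c(-0.7, -1.1, -1.5, -1.6) + stats::rnorm(4, 0, 0.05))))
  cls <- assign_pca_classes(rbind(fast, slow, down), seed = 5)
  expect_identical(sort(unique(cls)), c(1L, 2L, 3L))
  expect_true(all(cls[startsWith(names(cls), "d")] == 3L))
  expect_true(all(cls[startsWith(names(cls), "f")] == 1L))
  expect_true(all(cls[startsWith(names(cls), "s")] == 2L))
  expect_error(assign_pca_classes(fast[1:2, ]), "at least 3")
})

test_that("enrichment matches the hypergeometric tail and applies the filters", {
  ## 5 cluster proteins (3 with term X), 20 background (2 with X)
  cluster <- paste0("c", 1:5)
  background <- paste0("b", 1:20)
  ann <- data.frame(protein = c("c1", "c2", "c3", "b1", "b2"),
                    term = "X", stringsAsFactors = FALSE)
  out <- enrich_terms(cluster, background, ann, filter = FALSE)
  p_oracle <- stats::phyper(3 - 1, 5, 20, 5, lower.tail = FALSE)
  expect_equal(out$p[out$term == "X"], p_oracle)
  expect_identical(out$a + out$b + out$c + out$d, 25L)

  ## a term occurring once in the cluster is never significant
  ann1 <- rbind(ann, data.frame(protein = c("c1", "b3"), term = "Y"))
  out1 <- enrich_terms(cluster, background, ann1, filter = FALSE)
  expect_false(out1$significant[out1$term == "Y"])
  expect_false("Y" %in% enrich_terms(cluster, background, ann1)$term)

  expect_error(enrich_terms(cluster, c(cluster[1], background), ann),
               "disjoint")
  expect_error(enrich_terms(character(0), background, ann), "non-empty")
})

test_that("Benjamini-Hochberg adjustment reproduces the hand example", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  ## and adjusted p never falls below raw p inside enrich_terms output
  set.seed(31)
  cluster <- paste0("c", 1:6)
  background <- paste0("b", 1:15)
  ann <- data.frame(
    protein = sample(c(cluster, background), 30, replace = TRUE),
    term = sample(paste0("T", 1:5), 30, replace = TRUE))
  out <- enrich_terms(cluster, background, ann, filter = FALSE)
  expect_true(all(out$p_adj >= out$p - 1e-12))
})
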