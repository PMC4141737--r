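## SILAC phosphoproteomic time-course pipeline: ratio correction,
## least-modified-peptide collapse, replicate averaging, fold-change
## regulation filtering, fuzzy c-means clustering, PCA-based site
## classification and term enrichment.
##
## Tables are plain data frames.  A phosphopeptide table has one row per
## (peptide, replicate) with columns protein, residues, sequence,
## n_phospho, n_proline, replicate, and ratio columns t5/t15/t30/t60
## (fold change vs 0 s; NA = not detected).

RATIO_COLS <- c("t5", "t15", "t30", "t60")
RATIO_TIMES <- c(5, 15, 30, 60)

#' Read a phosphopeptide ratio table
#'
#' @param path Tab-delimited file with columns \code{protein},
#'   \code{residues}, \code{sequence}, \code{n_phospho}, \code{n_proline},
#'   \code{replicate}, \code{t5}, \code{t15}, \code{t30}, \code{t60}.
#'   Lines starting with \code{#} are ignored.
#' @return The table as a data frame.
#' @export
read_phospho_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein", "residues", "sequence", "n_phospho", "n_proline",
            "replicate", RATIO_COLS)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("phosphopeptide table is missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- vapply(RATIO_COLS, function(cc) any(df[[cc]] <= 0, na.rm = TRUE), TRUE)
  if (any(bad))
    stop("abundance ratios must be positive where present")
  df
}

#' Correct ratios for arginine-to-proline conversion
#'
#' In SILAC, partial conversion of heavy arginine to heavy proline
#' depresses the measured heavy/light ratio of proline-containing
#' peptides.  With conversion fraction \code{f}, each ratio is multiplied
#' by \eqn{(1-f)^{-n_{proline}}}; the default \code{f = 0} leaves the
#' table unchanged so the correction is auditable and off unless
#' configured.
#'
#' @param table A phosphopeptide table.
#' @param f Conversion fraction in \[0, 1).
#' @return The corrected table.
#' @export
correct_proline <- function(table, f = 0) {
  if (f < 0 || f >= 1) stop("conversion fraction must be in [0, 1)")
  if (f == 0) return(table)
  fac <- (1 - f)^(-table$n_proline)
  for (cc in RATIO_COLS) table[[cc]] <- table[[cc]] * fac
  table
}

site_id <- function(table) paste0(table$protein, "_", table$residues)

#' Collapse peptides to one record per site
#'
#' When a pTyr site is covered by several peptides, the least modified
#' peptide (minimal \code{n_phospho}) is used for its dynamics; ties are
#' broken by the shortest, then lexicographically smallest, sequence.
#' All replicate rows of the winning peptide are retained.
#'
#' @param table A phosphopeptide table.
#' @return The collapsed table (one peptide per site).
#' @export
collapse_to_sites <- function(table) {
  sid <- site_id(table)
  keep <- unlist(lapply(split(seq_len(nrow(table)), sid), function(idx) {
    sub <- table[idx, ]
    o <- order(sub$n_phospho, nchar(sub$sequence), sub$sequence)
    winner <- sub$sequence[o[1]]
    idx[sub$sequence == winner & sub$n_phospho == sub$n_phospho[o[1]]]
  }))
  out <- table[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Average ratios over biological replicates
#'
#' @param table A collapsed phosphopeptide table.
#' @return A site time-course data frame: one row per site with columns
#'   \code{site}, \code{protein}, \code{residues}, mean ratios
#'   (\code{t5}..\code{t60}), standard deviations (\code{sd_*}, NA when
#'   fewer than two replicates contributed) and replicate counts
#'   (\code{n_*}).
#' @export
average_replicates <- function(table) {
  sid <- site_id(table)
  rows <- lapply(split(seq_len(nrow(table)), sid), function(idx) {
    sub <- table[idx, ]
    if (all(is.na(unlist(sub[RATIO_COLS]))))
      stop("site ", site_id(sub)[1], " has no ratio values at any time point")
    out <- data.frame(site = site_id(sub)[1], protein = sub$protein[1],
                      residues = sub$residues[1], stringsAsFactors = FALSE)
    for (cc in RATIO_COLS) {
      v <- sub[[cc]][!is.na(sub[[cc]])]
      out[[cc]] <- if (length(v) > 0L) mean(v) else NA_real_
      out[[paste0("sd_", cc)]] <- if (length(v) >= 2L) stats::sd(v) else NA_real_
      out[[paste0("n_", cc)]] <- length(v)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter sites showing regulated dynamics
#'
#' A site is regulated when its mean ratio at any time point is at least
#' \code{threshold} or at most \code{1/threshold} (boundary included by
#' default; set \code{strict = TRUE} for a strict inequality).
#'
#' @param courses A site time-course data frame from
#'   [average_replicates()].
#' @param threshold Fold-change threshold (> 1; default 2).
#' @param strict Use strict inequalities instead of \code{>=}/\code{<=}.
#' @param keep_all Return all sites with a \code{regulated} flag instead
#'   of only the regulated subset.
#' @return Data frame with columns \code{site}, \code{protein},
#'   \code{regulated}, \code{direction} (up/down/mixed/none) and
#'   \code{earliest_s} (earliest qualifying time, NA if none).
#' @export
filter_regulated <- function(courses, threshold = 2, strict = FALSE,
                             keep_all = FALSE) {
  if (threshold <= 1) stop("threshold must exceed 1")
  cmp_up <- if (strict) function(x) x > threshold else function(x) x >= threshold
  cmp_dn <- if (strict) function(x) x < 1 / threshold else function(x) x <= 1 / threshold
  m <- as.matrix(courses[RATIO_COLS])
  up <- !is.na(m) & cmp_up(m)
  dn <- !is.na(m) & cmp_dn(m)
  any_up <- rowSums(up) > 0
  any_dn <- rowSums(dn) > 0
  regulated <- any_up | any_dn
  direction <- ifelse(any_up & any_dn, "mixed",
               ifelse(any_up, "up", ifelse(any_dn, "down", "none")))
  qual <- up | dn
  earliest <- apply(qual, 1L, function(r)
    if (any(r)) RATIO_TIMES[which(r)[1]] else NA_real_)
  out <- data.frame(site = courses$site, protein = courses$protein,
                    regulated = regulated, direction = direction,
                    earliest_s = earliest, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (keep_all) out else out[out$regulated, , drop = FALSE]
}

## log2 + per-site z-score standardization of a course matrix; profiles
## are anchored at the t = 0 baseline (ratio 1, log2 ratio 0) so that
## rise timing is retained after z-scoring
standardize_courses <- function(m, anchor_baseline = TRUE) {
  if (anchor_baseline) m <- cbind(t0 = 1, m)
  lm2 <- log2(m)
  mu <- rowMeans(lm2)
  sdv <- apply(lm2, 1L, stats::sd)
  if (any(sdv == 0))
    stop("degenerate input: flat profile(s) cannot be standardized")
  (lm2 - mu) / sdv
}

#' Fuzzy c-means clustering of regulated time courses
#'
#' Profiles are log2-transformed and z-scored per site, then clustered
#' with the fuzzy c-means algorithm (fuzzifier \code{m}).  Initial
#' centers are drawn from the data under the given seed, making the
#' result deterministic.  Sites with missing mean ratios at any time
#' point are dropped (fuzzy c-means needs complete profiles).
#'
#' @param courses Site time-course data frame (typically the regulated
#'   subset).
#' @param c Number of clusters (default 4).
#' @param m Fuzzifier (default 2).
#' @param seed Seed for center initialization.
#' @param tol Convergence tolerance on the membership change.
#' @param max_iter Iteration cap.
#' @return An \code{fcm_result}: list with \code{membership} (site-by-
#'   cluster matrix, rows summing to 1), \code{hard} (argmax labels),
#'   \code{centers}, \code{sites} and \code{settings}.
#' @export
cluster_fuzzy_cmeans <- function(courses, c = 4, m = 2, seed = 1L,
                                 tol = 1e-6, max_iter = 500L) {
  mat <- as.matrix(courses[RATIO_COLS])
  rownames(mat) <- courses$site
  complete <- stats::complete.cases(mat)
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < c)
    stop("need at least ", c, " complete profiles, got ", nrow(mat))
  z <- standardize_courses(mat)
  uz <- unique(z)
  if (nrow(uz) < c)
    stop("degenerate input: fewer than ", c, " distinct profiles")
  set.seed(seed)
  centers <- uz[sample.int(nrow(uz), c), , drop = FALSE]
  fit <- e1071::cmeans(z, centers = centers, m = m, iter.max = max_iter,
                       method = "cmeans", control = list(reltol = tol))
  membership <- fit$membership
  rownames(membership) <- rownames(z)
  structure(list(membership = membership,
                 hard = apply(membership, 1L, which.max),
                 centers = fit$centers, sites = rownames(z),
                 settings = list(c = c, m = m, seed = seed, tol = tol,
                                 max_iter = max_iter)),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("fcm_result: %d sites in %d clusters (m = %g, seed = %d); sizes: %s\n",
              length(x$hard), x$settings$c, x$settings$m, x$settings$seed,
              paste(tabulate(x$hard, x$settings$c), collapse = "/")))
  invisible(x)
}

#' Assign model-site classes from PCA of time courses
#'
#' Standardized log2 courses are projected on their first two principal
#' components and partitioned with seeded k-means (k = 3).  Clusters are
#' mapped to site classes by centroid semantics: the cluster whose mean
#' course decreases is class 3; of the increasing clusters, the one with
#' the earlier half-rise is class 1 and the other class 2.
#'
#' @param courses Site time-course data frame (relative ratios), n >= 3
#'   complete profiles.
#' @param seed Seed for k-means initialization.
#' @return Named integer vector of class labels (1, 2 or 3) per site.
#' @export
assign_pca_classes <- function(courses, seed = 1L) {
  mat <- as.matrix(courses[RATIO_COLS])
  rownames(mat) <- courses$site
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 3L) stop("need at least 3 complete profiles")
  z <- standardize_courses(mat)
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(scores, centers = 3L, nstart = 25L)
  ## centroid semantics on mean log2 courses (relative to baseline 1)
  lm2 <- log2(mat)
  endval <- vapply(1:3, function(k)
    mean(lm2[km$cluster == k, ncol(lm2), drop = FALSE]), 0)
  cls <- integer(3)
  down <- which.min(endval)
  cls[down] <- 3L
  ups <- setdiff(1:3, down)
  half_rise <- vapply(ups, function(k) {
    v <- colMeans(lm2[km$cluster == k, , drop = FALSE])
    v <- c(0, v)                       # baseline log2 ratio is 0 at t = 0
    tt <- c(0, RATIO_TIMES)
    target <- (max(v) + v[1]) / 2
    i <- which(v >= target)[1]
    if (i == 1L) return(0)
    tt[i - 1L] + (tt[i] - tt[i - 1L]) * (target - v[i - 1L]) / (v[i] - v[i - 1L])
  }, 0)
  cls[ups[order(half_rise)]] <- c(1L, 2L)
  out <- cls[km$cluster]
  names(out) <- rownames(mat)
  out
}

## One-sided (over-representation) Fisher exact test on the 2x2 table
##   a = cluster with term, b = cluster without,
##   c = background with term, d = background without.
fisher_greater <- function(a, b, c, d) {
  ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                           alternative = "greater")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Term over-representation in a cluster
#'
#' One-sided Fisher's exact test of each annotation term in a cluster's
#' proteins against a background of detected-but-unregulated proteins,
#' with Benjamini-Hochberg adjustment across terms.  Following the
#' two-occurrence rule, only terms present at least \code{min_count}
#' times in the cluster (and, with \code{filter = TRUE}, adjusted
#' p < \code{alpha}) are reported as significant.
#'
#' @param cluster_proteins Character vector of proteins in the cluster.
#' @param background_proteins Character vector of background proteins
#'   (disjoint from the cluster).
#' @param annotations Data frame with columns \code{protein}, \code{term}.
#' @param min_count Minimum occurrences of a term in the cluster
#'   (default 2).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param filter Return only significant rows (default TRUE).
#' @return Data frame with columns \code{term}, \code{a}, \code{b},
#'   \code{c}, \code{d} (the 2x2 table: cluster/background x with/without
#'   term), \code{odds_ratio}, \code{p}, \code{p_adj},
#'   \code{significant}.
#' @export
enrich_terms <- function(cluster_proteins, background_proteins, annotations,
                         min_count = 2L, alpha = 0.05, filter = TRUE) {
  cluster_proteins <- unique(cluster_proteins)
  background_proteins <- unique(background_proteins)
  if (length(cluster_proteins) == 0L || length(background_proteins) == 0L)
    stop("cluster and background must be non-empty")
  if (length(intersect(cluster_proteins, background_proteins)) > 0L)
    stop("cluster and background must be disjoint")
  terms <- unique(annotations$term[annotations$protein %in%
                                     c(cluster_proteins, background_proteins)])
  if (length(terms) == 0L)
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  rows <- lapply(terms, function(tm) {
    with_term <- unique(annotations$protein[annotations$term == tm])
    a <- sum(cluster_proteins %in% with_term)
    b <- length(cluster_proteins) - a
    cc <- sum(background_proteins %in% with_term)
    d <- length(background_proteins) - cc
    ft <- fisher_greater(a, b, cc, d)
    data.frame(term = tm, a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$a >= min_count & out$p_adj < alpha
  out <- out[order(out$p_adj, out$p, out$term), ]
  rownames(out) <- NULL
  if (filter) out[out$significant, , drop = FALSE] else out
}
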