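## Synthetic-data generators with planted ground truth.
##
## (a) Phosphopeptide ratio tables with the statistical structure of a
##     three-replicate SILAC pTyr time course: four temporal archetypes,
##     multiplicative log-normal measurement noise, and independent
##     per-replicate detection dropout producing partial replicate
##     overlap.
## (b) Model-simulated "measured" site courses with known generating
##     parameters, for parameter-recovery experiments.

#' Temporal archetype profiles
#'
#' Mean log2 ratios at \{5, 15, 30, 60\} s for the four regulated
#' archetypes plus the unregulated profile.  Regulated archetypes reach
#' the fold-change threshold \code{theta}: fast-up by 5 s, slow-up by
#' 30 s, down below \code{1/theta}, transient above \code{theta} at
#' 5--15 s but back below it by 60 s; the unregulated profile stays
#' strictly inside \code{(1/theta, theta)}.
#'
#' @param theta Regulation threshold the profiles are calibrated against
#'   (default 2).
#' @return Matrix of mean log2 ratios, rows named by archetype.
#' @export
archetype_profiles <- function(theta = 2) {
  lt <- log2(theta)
  m <- rbind(
    "fast-up"     = lt * c(1.80, 2.00, 2.00, 2.00),
    "slow-up"     = lt * c(0.10, 0.40, 1.20, 2.00),
    "down"        = lt * c(-0.80, -1.30, -1.60, -1.80),
    "transient"   = lt * c(1.80, 1.20, 0.40, 0.00),
    "unregulated" = lt * c(0.00, 0.10, -0.10, 0.00))
  colnames(m) <- RATIO_COLS
  m
}

#' Generator configuration
#'
#' @param n_sites Number of pTyr sites.
#' @param frac_regulated Fraction of sites drawn from regulated
#'   archetypes.
#' @param weights Mixture weights over the four regulated archetypes
#'   (fast-up, slow-up, down, transient).
#' @param replicates Number of biological replicates (default 3).
#' @param sigma Log-normal measurement noise SD in log2 units
#'   (default 0.3).
#' @param detect_prob Per-replicate, per-time-point detection probability
#'   (independent dropout; default 0.8).
#' @param theta Regulation threshold the archetypes are calibrated to.
#' @param seed Seed making the table reproducible.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_sites = 700L, frac_regulated = 0.2,
                             weights = c(0.3, 0.3, 0.2, 0.2),
                             replicates = 3L, sigma = 0.3,
                             detect_prob = 0.8, theta = 2, seed = 3L) {
  stopifnot(n_sites >= 1, frac_regulated >= 0, frac_regulated <= 1,
            length(weights) == 4L, all(weights >= 0), replicates >= 1,
            sigma >= 0, detect_prob >= 0, detect_prob <= 1, theta > 1)
  structure(list(n_sites = as.integer(n_sites),
                 frac_regulated = frac_regulated,
                 weights = weights / sum(weights),
                 replicates = as.integer(replicates), sigma = sigma,
                 detect_prob = detect_prob, theta = theta,
                 seed = as.integer(seed)),
            class = "generator_config")
}

random_peptide <- function(n_pro) {
  aa <- c("A", "D", "E", "F", "G", "I", "K", "L", "N", "Q", "S", "T", "V", "Y")
  len <- sample(8:18, 1L)
  s <- sample(aa, len, replace = TRUE)
  if (n_pro > 0) s[sample.int(len, n_pro)] <- "P"
  paste(s, collapse = "")
}

#' Generate a synthetic phosphopeptide ratio table
#'
#' Each site is assigned an archetype; each replicate and time point
#' emits \code{ratio = 2^(archetype log2 mean + Normal(0, sigma))} with
#' probability \code{detect_prob} (otherwise NA).  Replicate rows with
#' no detected value are omitted, reproducing the partial overlap of
#' peptides across replicate experiments.  Peptide metadata
#' (\code{n_phospho}, \code{n_proline}, sequence) is included so the
#' upstream correction and collapse steps have something to act on.
#'
#' @param config A [generator_config()].
#' @return List with \code{table} (phosphopeptide table) and
#'   \code{truth} (per-site \code{archetype} and \code{regulated} flag).
#' @export
generate_ratio_table <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- config$n_sites
  n_reg <- round(n * config$frac_regulated)
  arche <- archetype_profiles(config$theta)
  reg_names <- rownames(arche)[1:4]
  assign <- c(sample(reg_names, n_reg, replace = TRUE, prob = config$weights),
              rep("unregulated", n - n_reg))
  assign <- sample(assign)                     # shuffle site order
  protein <- sprintf("PROT%04d", seq_len(n))
  residue <- sample(50:900, n, replace = TRUE)
  n_pro <- stats::rpois(n, 1.2)
  n_phos <- 1L + stats::rbinom(n, 1L, 0.15)
  seqs <- vapply(n_pro, random_peptide, "")

  rows <- vector("list", n * config$replicates)
  k <- 0L
  for (i in seq_len(n)) {
    mu <- arche[assign[i], ]
    for (r in seq_len(config$replicates)) {
      vals <- 2^(mu + stats::rnorm(4L, 0, config$sigma))
      detected <- stats::runif(4L) < config$detect_prob
      vals[!detected] <- NA_real_
      if (all(is.na(vals))) next
      k <- k + 1L
      rows[[k]] <- data.frame(protein = protein[i], residues = residue[i],
                              sequence = seqs[i], n_phospho = n_phos[i],
                              n_proline = n_pro[i], replicate = r,
                              t5 = vals[1], t15 = vals[2], t30 = vals[3],
                              t60 = vals[4], stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows[seq_len(k)])
  truth <- data.frame(site = paste0(protein, "_", residue),
                      protein = protein, archetype = assign,
                      regulated = assign != "unregulated",
                      stringsAsFactors = FALSE)
  list(table = table, truth = truth)
}

#' Simulate a noisy "measured" dataset from a model
#'
#' Runs the model under the protocol, converts each observable to a
#' relative time course, applies multiplicative log-normal noise
#' (\code{sigma} log2 units) to the post-stimulus points, and returns
#' the courses together with the generating parameters, enabling
#' parameter-recovery experiments.
#'
#' @param spec A \code{model_spec}.
#' @param params The generating parameter values (returned untouched as
#'   the recovery target).
#' @param protocol A \code{sim_protocol}.
#' @param sigma Per-measurement noise SD in log2 units.
#' @param seed Seed for both simulation and noise.
#' @param sites Observables to keep (default: all).
#' @param replicates Number of independent noisy replicate measurements
#'   averaged per point (default 1; the emulated study design is
#'   triplicate).
#' @return List with \code{courses} (data frame site, time_s, value) and
#'   \code{params}.
#' @export
generate_truth_dataset <- function(spec, params, protocol, sigma = 0.1,
                                   seed = 1L, sites = NULL,
                                   replicates = 1L) {
  ens <- average_runs(simulate_ensemble(
    spec, sim_protocol(t_eq = protocol$t_eq, grid = protocol$grid,
                       n_runs = protocol$n_runs, seed = seed,
                       stimulus = protocol$stimulus)))
  obs <- colnames(ens$mean)
  if (!is.null(sites)) obs <- intersect(obs, sites)
  set.seed(seed + 1L)
  rows <- lapply(obs, function(o) {
    tc <- relative_timecourse(ens, o)
    noise <- rowMeans(matrix(
      2^stats::rnorm(length(tc$values) * replicates, 0, sigma),
      ncol = replicates))
    noise[tc$times == 0] <- 1            # the baseline point stays exactly 1
    data.frame(site = o, time_s = tc$times, value = tc$values * noise,
               stringsAsFactors = FALSE)
  })
  list(courses = do.call(rbind, rows), params = params)
}
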