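## Parameter estimation against site-level time courses: a least-squares
## objective on log2 relative phosphorylation under common random
## numbers, a coarse grid search, and quasi-Newton (variable metric)
## refinement with bounds.  Parameters come in three classes:
## literature-fixed (never varied), derived (expressions over other
## parameters), and fitted (positivity-only or box-bounded).

#' Parameter specification table
#'
#' @param name Parameter names.
#' @param class One of \code{"fixed"}, \code{"derived"}, \code{"fitted"}
#'   per parameter.
#' @param value Numeric value (fixed), expression string over other
#'   parameter names (derived), or starting value (fitted).
#' @param lower,upper Bounds for fitted parameters; \code{lower = 0},
#'   \code{upper = Inf} means positivity-only (optimized in log space).
#' @return A \code{parameter_spec} data frame.
#' @export
parameter_spec <- function(name, class, value, lower = 0, upper = Inf) {
  stopifnot(length(name) == length(class), length(value) == length(name),
            all(class %in% c("fixed", "derived", "fitted")))
  structure(data.frame(name = name, class = class,
                       value = as.character(value),
                       lower = rep_len(lower, length(name)),
                       upper = rep_len(upper, length(name)),
                       stringsAsFactors = FALSE),
            class = c("parameter_spec", "data.frame"))
}

#' Read a parameter table from delimited text
#' @param path Tab-delimited file with columns \code{name}, \code{class},
#'   \code{value}, \code{lower}, \code{upper}.
#' @return A \code{parameter_spec}.
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  parameter_spec(df$name, df$class, df$value, df$lower, df$upper)
}

#' Resolve derived parameters into a full numeric table
#'
#' Evaluates derived-parameter expressions in dependency order;
#' literature-fixed values pass through; fitted values are taken from
#' \code{fitted_values}.  Cyclic definitions are reported by name.
#'
#' @param pspec A \code{parameter_spec}.
#' @param fitted_values Named numeric vector supplying every
#'   \code{fitted} parameter.
#' @return Named numeric vector over all parameters.
#' @export
resolve_derived <- function(pspec, fitted_values = numeric(0)) {
  env <- new.env(parent = baseenv())
  for (i in which(pspec$class == "fixed"))
    assign(pspec$name[i], as.numeric(pspec$value[i]), envir = env)
  for (i in which(pspec$class == "fitted")) {
    nm <- pspec$name[i]
    v <- if (nm %in% names(fitted_values)) fitted_values[[nm]]
         else as.numeric(pspec$value[i])
    if (is.na(v)) stop("no value for fitted parameter '", nm, "'")
    assign(nm, v, envir = env)
  }
  pending <- which(pspec$class == "derived")
  while (length(pending) > 0L) {
    progressed <- FALSE
    still <- integer(0)
    for (i in pending) {
      val <- tryCatch(eval(parse(text = pspec$value[i]), envir = env),
                      error = function(e) NULL)
      if (is.null(val)) {
        still <- c(still, i)
      } else {
        assign(pspec$name[i], val, envir = env)
        progressed <- TRUE
      }
    }
    if (!progressed)
      stop("cyclic or unresolvable derived parameter(s): ",
           paste(pspec$name[still], collapse = " -> "))
    pending <- still
  }
  out <- vapply(pspec$name, function(nm) get(nm, envir = env), 0)
  names(out) <- pspec$name
  out
}

#' Build a least-squares objective over fitted parameters
#'
#' The objective simulates the model at the proposed parameters
#' (averaging \code{n_runs} runs with the \emph{same} seeds on every
#' evaluation -- common random numbers, which makes the stochastic
#' objective quasi-deterministic for descent) and sums squared
#' differences between log2 simulated relative phosphorylation and log2
#' measured mean ratio over all sites and grid times.
#'
#' @param builder Function mapping a named parameter vector to a
#'   \code{model_spec}.
#' @param data Data frame with columns \code{site}, \code{time_s},
#'   \code{value} (relative ratios); every site must be a model
#'   observable.
#' @param protocol A \code{sim_protocol} (its \code{n_runs}/\code{seed}
#'   are overridden by \code{n_runs}/\code{base_seed}).
#' @param n_runs Runs averaged per evaluation.
#' @param base_seed Base seed shared by all evaluations.
#' @param eps Pseudocount for log2 of zero relative values.
#' @return Function \code{f(theta) -> numeric}.
#' @export
build_objective <- function(builder, data, protocol, n_runs = 50L,
                            base_seed = 1L, eps = 0.05) {
  sites <- unique(data$site)
  force(builder); force(protocol)
  function(theta) {
    spec <- builder(theta)
    miss <- setdiff(sites, vapply(spec$observables, `[[`, "", "name"))
    if (length(miss) > 0L)
      stop("data site(s) without a model observable: ",
           paste(miss, collapse = ", "))
    pr <- sim_protocol(t_eq = protocol$t_eq, grid = protocol$grid,
                       n_runs = n_runs, seed = base_seed,
                       stimulus = protocol$stimulus)
    ens <- average_runs(simulate_ensemble(spec, pr))
    total <- 0
    for (s in sites) {
      tc <- relative_timecourse(ens, s)
      d <- data[data$site == s, ]
      simv <- tc$values[match(d$time_s, tc$times)]
      total <- total + sum((log2(simv + eps) - log2(d$value + eps))^2)
    }
    total
  }
}

#' Coarse grid search
#'
#' Evaluates the objective at every point of the Cartesian grid (under
#' common seeds) and returns the minimizer; ties are broken by the first
#' point in enumeration order.
#'
#' @param objective Function from [build_objective()] (or any function of
#'   a named parameter vector).
#' @param grid Named list of candidate values per fitted parameter.
#' @return A \code{fit_result} with \code{stage = "grid"}.
#' @export
grid_search <- function(objective, grid) {
  stopifnot(length(grid) > 0L, all(lengths(grid) > 0L))
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  vals <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    theta <- unlist(pts[i, , drop = FALSE])
    vals[i] <- objective(theta)
  }
  best <- which.min(vals)            # first minimum in enumeration order
  structure(list(par = unlist(pts[best, , drop = FALSE]),
                 value = vals[best], stage = "grid",
                 evaluations = nrow(pts), grid_values = vals),
            class = "fit_result")
}

#' Quasi-Newton refinement
#'
#' Variable-metric (BFGS-family) descent from a starting point with
#' finite-difference gradients on the fixed-seed objective.
#' Box-bounded parameters use L-BFGS-B; positivity-only parameters
#' (\code{lower = 0}, \code{upper = Inf}) are optimized on the log
#' scale.  The returned point never has a worse objective than the
#' start.
#'
#' @param objective Objective function of a named parameter vector.
#' @param start Named numeric starting point (e.g. the grid minimizer).
#' @param lower,upper Bounds, recycled over parameters.
#' @param maxit Iteration cap.
#' @param factr L-BFGS-B convergence factor (coarser than machine
#'   precision because the objective is Monte Carlo averaged).
#' @return A \code{fit_result} with \code{stage = "refined"}.
#' @export
refine <- function(objective, start, lower = 0, upper = Inf, maxit = 25L,
                   factr = 1e9) {
  n <- length(start)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(start < lower | start > upper))
    stop("starting point violates the bounds")
  f0 <- objective(start)
  if (!is.finite(f0)) stop("objective is not finite at the start")
  logscale <- lower <= 0 & !is.finite(upper)
  tr <- function(x) ifelse(logscale, log(x), x)
  inv <- function(y) {
    x <- ifelse(logscale, exp(y), y)
    pmin(pmax(x, lower), upper)        # projection for numerical safety
  }
  wrapped <- function(y) {
    v <- objective(setNames(inv(y), names(start)))
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  lo <- ifelse(logscale, -Inf, lower)
  hi <- ifelse(logscale, Inf, upper)
  opt <- stats::optim(tr(start), wrapped, method = "L-BFGS-B",
                      lower = lo, upper = hi,
                      control = list(maxit = maxit, factr = factr,
                                     ndeps = rep(0.05, n)))
  par <- setNames(inv(opt$par), names(start))
  val <- opt$value
  if (val > f0) { par <- start; val <- f0 }   # never worse than the start
  structure(list(par = par, value = val, stage = "refined",
                 evaluations = unname(opt$counts[1]),
                 convergence = opt$convergence, start_value = f0),
            class = "fit_result")
}

#' Grid search followed by refinement
#'
#' Runs the coarse grid search, then quasi-Newton refinement from each
#' of the \code{n_starts} best grid points (multistart guards against a
#' refinement stalling in the basin of a single coarse grid cell), and
#' returns the best refined result.
#'
#' @inheritParams grid_search
#' @inheritParams refine
#' @param n_starts Number of best grid points used as refinement starts.
#' @return A \code{fit_result} with \code{stage = "refined"}; its
#'   objective value never exceeds the grid stage's.
#' @export
fit_parameters <- function(objective, grid, lower = 0, upper = Inf,
                           maxit = 25L, n_starts = 3L) {
  g <- grid_search(objective, grid)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  starts <- order(g$grid_values)[seq_len(min(n_starts, nrow(pts)))]
  best <- NULL
  evals <- 0L
  for (s in starts) {
    r <- refine(objective, unlist(pts[s, , drop = FALSE]),
                lower = lower, upper = upper, maxit = maxit)
    evals <- evals + r$evaluations
    if (is.null(best) || r$value < best$value) best <- r
  }
  if (best$value > g$value) { best$par <- g$par; best$value <- g$value }
  best$evaluations <- evals
  best$grid <- g
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): objective %.6g after %d evaluations\n",
              x$stage, x$value, x$evaluations))
  print(x$par)
  invisible(x)
}

## ---- a small ligand-induced phosphorylation cycle used in recovery ------

#' Toy ligand-induced phosphorylation cycle
#'
#' A minimal two-parameter model for fitting experiments: a substrate
#' with one phosphosite, a weak basal kinase activity setting the
#' unstimulated baseline, stimulus-driven phosphorylation at rate
#' \code{k_stim} (per ligand-substrate pair) once the ligand is
#' injected, and dephosphorylation at \code{k_dephos}.
#'
#' @param k_stim Stimulus-driven phosphorylation rate (events/s/pair).
#' @param k_dephos Dephosphorylation rate (1/s).
#' @param k_basal Basal phosphorylation rate (1/s).
#' @param n_s Substrate copies.
#' @return A \code{model_spec} with observable \code{pS}; stimulate with
#'   species \code{"L(s)"}.
#' @export
toy_cycle_model <- function(k_stim, k_dephos, k_basal = 0.01, n_s = 500L) {
  parse_model(c(
    "begin parameters",
    sprintf("k_stim %.15g", k_stim),
    sprintf("k_dephos %.15g", k_dephos),
    sprintf("k_basal %.15g", k_basal),
    "end parameters",
    "begin molecule types", "L(s)", "S(y~U~P)", "end molecule types",
    "begin seed species", sprintf("S(y~U) %d", as.integer(n_s)),
    "end seed species",
    "begin observables", "Molecules pS S(y~P)", "end observables",
    "begin reaction rules",
    "stim: L(s) + S(y~U) -> L(s) + S(y~P) k_stim",
    "basal: S(y~U) -> S(y~P) k_basal",
    "dephos: S(y~P) -> S(y~U) k_dephos",
    "end reaction rules"))
}

#' Two-dose parameter-recovery experiment on the toy cycle
#'
#' Generates noisy relative phosphorylation courses from the toy
#' ligand-induced cycle at known parameters under two stimulus doses
#' (which breaks the amplitude/timescale correlation between the two
#' rate constants), then re-estimates the parameters by coarse grid
#' search plus quasi-Newton refinement on the summed common-random-
#' numbers objective.
#'
#' @param truth Named vector with \code{k_stim} and \code{k_dephos}.
#' @param n_runs Runs averaged per objective evaluation (and used to
#'   generate the data).
#' @param sigma Per-measurement noise SD in log2 units; each data point
#'   averages three noisy replicate measurements, mirroring the
#'   triplicate experimental design.
#' @param seed Base seed for data generation and common random numbers.
#' @param doses Ligand copy numbers of the two stimulation conditions.
#' @return List with \code{fit} (the refined \code{fit_result}),
#'   \code{truth} and \code{rel_error} (per-parameter absolute relative
#'   error).
#' @export
toy_recovery_experiment <- function(truth = c(k_stim = 3e-4, k_dephos = 0.06),
                                    n_runs = 50L, sigma = 0.1, seed = 11L,
                                    doses = c(60L, 300L)) {
  grid_t <- c(0, 2.5, 5, 10, 15, 20, 30, 45, 60)
  mk <- function(th) toy_cycle_model(th[["k_stim"]], th[["k_dephos"]])
  objs <- lapply(seq_along(doses), function(i) {
    pr <- sim_protocol(t_eq = 100, grid = grid_t, n_runs = n_runs,
                       seed = seed,
                       stimulus = list(list(species = "L(s)",
                                            count = as.integer(doses[i]))))
    dat <- generate_truth_dataset(mk(truth), truth, pr, sigma = sigma,
                                  seed = seed + 1000L * i, replicates = 3L)
    build_objective(mk, dat$courses, pr, n_runs = n_runs,
                    base_seed = seed + 1000L * i)
  })
  objective <- function(th) sum(vapply(objs, function(f) f(th), 0))
  fit <- fit_parameters(objective,
                        grid = list(k_stim = 10^seq(-4, -2.5, by = 0.5),
                                    k_dephos = 10^seq(-2, -0.5, by = 0.5)))
  list(fit = fit, truth = truth,
       rel_error = abs(fit$par[names(truth)] - truth) / truth)
}
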