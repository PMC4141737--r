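## Network-free stochastic simulation: R-side compilation of a model_spec
## into the integer-coded form consumed by the C++ kinetic Monte Carlo
## engine, plus user-facing simulate/equilibrate/step/count wrappers.

BOND_ANYSTATUS <- -9L
BOND_NONE <- -1L
BOND_SOME <- -2L

## ---- compilation --------------------------------------------------------

type_index <- function(spec) {
  setNames(seq_along(spec$molecule_types) - 1L, names(spec$molecule_types))
}

comp_index <- function(spec, type) {
  setNames(seq_along(spec$molecule_types[[type]]$components) - 1L,
           names(spec$molecule_types[[type]]$components))
}

state_index <- function(spec, type, comp) {
  st <- spec$molecule_types[[type]]$components[[comp]]$states
  setNames(seq_along(st) - 1L, st)
}

encode_pattern <- function(spec, pat) {
  ti <- type_index(spec)
  n <- length(pat)
  ptype <- integer(n)
  pcomps <- vector("list", n)
  bonds <- list()  # label -> list of c(pmol, comp)
  for (i in seq_len(n)) {
    m <- pat[[i]]
    ptype[i] <- ti[[m$type]]
    ci <- comp_index(spec, m$type)
    rows <- matrix(0L, nrow = length(m$components), ncol = 3)
    for (k in seq_along(m$components)) {
      cn <- names(m$components)[k]
      cc <- m$components[[k]]
      si <- if (is.na(cc$state)) -1L else state_index(spec, m$type, cn)[[cc$state]]
      b <- cc$bond
      bi <- if (identical(b, "none")) BOND_NONE
            else if (identical(b, "some")) BOND_SOME
            else if (identical(b, "any")) BOND_ANYSTATUS
            else {
              lab <- as.character(b)
              bonds[[lab]] <- c(bonds[[lab]], list(c(i - 1L, ci[[cn]])))
              as.integer(b)
            }
      rows[k, ] <- c(ci[[cn]], si, bi)
    }
    pcomps[[i]] <- rows
  }
  bm <- matrix(0L, nrow = length(bonds), ncol = 4)
  r <- 1L
  for (lab in names(bonds)) {
    e <- bonds[[lab]]
    bm[r, ] <- c(e[[1]], e[[2]])
    r <- r + 1L
  }
  plan <- pattern_plan(n, bm)
  list(ptype = ptype, pcomps = pcomps, plan = plan, bonds = bm,
       auto = pattern_automorphisms(pat))
}

## Visit order: each pattern molecule after the first must be reachable from
## an earlier one through a labelled bond (connected site-graph patterns).
pattern_plan <- function(n, bondmat) {
  if (n == 1L) return(matrix(0L, nrow = 0, ncol = 4))
  placed <- c(TRUE, rep(FALSE, n - 1L))
  plan <- matrix(0L, nrow = 0, ncol = 4)
  repeat {
    progressed <- FALSE
    for (r in seq_len(nrow(bondmat))) {
      a <- bondmat[r, 1]; ca <- bondmat[r, 2]
      b <- bondmat[r, 3]; cb <- bondmat[r, 4]
      if (placed[a + 1L] && !placed[b + 1L]) {
        plan <- rbind(plan, c(b, a, ca, cb))
        placed[b + 1L] <- TRUE; progressed <- TRUE
      } else if (placed[b + 1L] && !placed[a + 1L]) {
        plan <- rbind(plan, c(a, b, cb, ca))
        placed[a + 1L] <- TRUE; progressed <- TRUE
      }
    }
    if (all(placed)) break
    if (!progressed)
      stop("pattern molecules must be connected through explicit bond labels")
  }
  storage.mode(plan) <- "integer"
  plan
}

## Automorphism order of a pattern: permutations of its molecules that
## preserve type, every component constraint, and the labelled bond set.
pattern_automorphisms <- function(pat) {
  n <- length(pat)
  if (n == 1L) return(1L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  strip <- function(m) {  # constraints without bond labels
    cc <- lapply(m$components, function(x)
      list(state = x$state,
           bond = if (is.numeric(x$bond) || is.integer(x$bond)) "labelled" else x$bond))
    list(type = m$type, components = cc[order(names(cc))])
  }
  bonds <- pattern_bond_pairs(pat)
  bond_key <- function(i, ci, j, cj) {
    a <- paste(i, ci); b <- paste(j, cj)
    paste(sort(c(a, b)), collapse = "::")
  }
  bset <- sort(vapply(bonds, function(pr)
    bond_key(pr[[1]][["mol"]], pr[[1]][["comp"]], pr[[2]][["mol"]], pr[[2]][["comp"]]), ""))
  count <- 0L
  stripped <- lapply(pat, strip)
  for (p in perms(seq_len(n))) {
    ok <- all(vapply(seq_len(n), function(i)
      identical(stripped[[i]], stripped[[p[i]]]), TRUE))
    if (ok) {
      pb <- sort(vapply(bonds, function(pr)
        bond_key(p[as.integer(pr[[1]][["mol"]])], pr[[1]][["comp"]],
                 p[as.integer(pr[[2]][["mol"]])], pr[[2]][["comp"]]), ""))
      ok <- identical(pb, bset)
    }
    if (ok) count <- count + 1L
  }
  count
}

encode_seed <- function(spec, pat, count) {
  ti <- type_index(spec)
  n <- length(pat)
  types <- integer(n)
  states <- vector("list", n)
  bonds <- list()
  for (i in seq_len(n)) {
    m <- pat[[i]]
    types[i] <- ti[[m$type]]
    def <- spec$molecule_types[[m$type]]$components
    sv <- integer(length(def))
    for (k in seq_along(def)) {
      cn <- names(def)[k]
      if (length(def[[k]]$states) == 0L) {
        sv[k] <- -1L
      } else {
        sv[k] <- state_index(spec, m$type, cn)[[m$components[[cn]]$state]]
      }
      b <- m$components[[cn]]$bond
      if (is.numeric(b) || is.integer(b)) {
        lab <- as.character(b)
        bonds[[lab]] <- c(bonds[[lab]], list(c(i - 1L, k - 1L)))
      }
    }
    states[[i]] <- sv
  }
  bm <- matrix(0L, nrow = length(bonds), ncol = 4)
  for (r in seq_along(bonds)) bm[r, ] <- c(bonds[[r]][[1]], bonds[[r]][[2]])
  list(types = types, states = states, bonds = bm, count = as.integer(count))
}

#' Compile a model to the engine's internal form
#'
#' Resolves names to integer codes, deduplicates rule and observable
#' patterns, precomputes the bond-following embedding plan and the
#' automorphism order of every pattern.  Called internally by the
#' simulation wrappers; exposed because the compiled form is reusable
#' across runs.
#'
#' @param spec A validated \code{model_spec}.
#' @return An opaque list understood by the C++ engine.
#' @export
compile_model <- function(spec) {
  pat_tab <- list()     # encoded patterns
  pat_src <- list()     # parsed pattern objects (for identity tests)
  add_pattern <- function(pat) {
    for (k in seq_along(pat_src))
      if (identical(unclass(pat_src[[k]]), unclass(pat))) return(k - 1L)
    pat_src[[length(pat_src) + 1L]] <<- pat
    pat_tab[[length(pat_tab) + 1L]] <<- encode_pattern(spec, pat)
    length(pat_tab) - 1L
  }

  rules <- vector("list", length(spec$rules))
  for (ri in seq_along(spec$rules)) {
    r <- spec$rules[[ri]]
    pids <- vapply(r$reactants, add_pattern, 0L)
    same <- length(pids) == 2L &&
      identical(unclass(r$reactants[[1]]), unclass(r$reactants[[2]]))
    sizes <- vapply(r$reactants, length, 0L)
    locate <- function(flat_mol) {
      off <- 0L
      for (pi in seq_along(sizes)) {
        if (flat_mol <= off + sizes[pi]) return(c(pi - 1L, flat_mol - off - 1L))
        off <- off + sizes[pi]
      }
      stop("internal: bad flat molecule index")
    }
    if (r$type == "set_state") {
      a <- r$action
      lc <- locate(a$mol)
      ty <- r$reactants[[lc[1] + 1L]][[lc[2] + 1L]]$type
      act <- c(lc, comp_index(spec, ty)[[a$comp]],
               state_index(spec, ty, a$comp)[[a$to]])
      type_code <- 0L
    } else {
      a <- r$action
      l1 <- locate(as.integer(a$a[["mol"]])); l2 <- locate(as.integer(a$b[["mol"]]))
      t1 <- r$reactants[[l1[1] + 1L]][[l1[2] + 1L]]$type
      t2 <- r$reactants[[l2[1] + 1L]][[l2[2] + 1L]]$type
      act <- c(l1, comp_index(spec, t1)[[a$a[["comp"]]]],
               l2, comp_index(spec, t2)[[a$b[["comp"]]]])
      type_code <- if (r$type == "bind") 1L else 2L
    }
    rules[[ri]] <- list(type = type_code, k = unname(spec$parameters[[r$rate]]),
                        pats = pids, same = same, act = as.integer(act),
                        name = r$name)
  }

  obs <- lapply(spec$observables, function(ob)
    list(name = ob$name, pats = vapply(ob$patterns, add_pattern, 0L)))

  seeds <- lapply(spec$seed_species, function(s)
    encode_seed(spec, s$pattern, s$count))

  structure(list(
    types = lapply(spec$molecule_types, function(mt) length(mt$components)),
    patterns = pat_tab, rules = rules, obs = obs, seeds = seeds,
    type_names = names(spec$molecule_types),
    rule_names = vapply(spec$rules, `[[`, "", "name")
  ), class = "compiled_model")
}

## ---- mixtures -----------------------------------------------------------

#' @export
print.kmc_mixture <- function(x, ...) {
  cat(sprintf("kmc_mixture: %d molecules (%s), %d bonds, t = %g s\n",
              length(x$types), paste(names(sort(-table(x$types)))[1:min(3, length(unique(x$types)))],
                                     collapse = ", "),
              nrow(x$bonds), x$time))
  invisible(x)
}

#' Build a mixture from explicit molecules
#'
#' A mixture is the particle state of the simulator: a multiset of molecule
#' instances with per-component states and pairwise bonds.
#'
#' @param spec The \code{model_spec} the molecules belong to.
#' @param species Character vector of fully specified species patterns
#'   (as in the seed species block), each optionally repeated via
#'   \code{counts}.
#' @param counts Integer vector of copy numbers (recycled to
#'   \code{length(species)}).
#' @return An object of class \code{kmc_mixture} with elements
#'   \code{types}, \code{states}, \code{bonds} (data frame), \code{time}.
#' @export
make_mixture <- function(spec, species, counts = 1L) {
  counts <- rep_len(as.integer(counts), length(species))
  types <- character(0)
  states <- list()
  bonds <- data.frame(mol1 = integer(0), comp1 = character(0),
                      mol2 = integer(0), comp2 = character(0))
  for (k in seq_along(species)) {
    pat <- parse_pattern(species[[k]])
    rep <- validate_model(local({
      s <- spec; s$seed_species <- list(list(pattern = pat, count = 1L));
      s$rules <- list(); s$observables <- list(); s
    }))
    if (nrow(rep) > 0L)
      stop("invalid species '", species[[k]], "': ", rep$message[1])
    for (cc in seq_len(counts[k])) {
      base <- length(types)
      for (m in pat) {
        types <- c(types, m$type)
        states[[length(states) + 1L]] <- vapply(m$components, function(x)
          if (is.na(x$state)) NA_character_ else x$state, "")
      }
      prs <- pattern_bond_pairs(pat)
      for (pr in prs) {
        bonds <- rbind(bonds, data.frame(
          mol1 = base + as.integer(pr[[1]][["mol"]]), comp1 = pr[[1]][["comp"]],
          mol2 = base + as.integer(pr[[2]][["mol"]]), comp2 = pr[[2]][["comp"]]))
      }
    }
  }
  structure(list(types = types, states = states, bonds = bonds, time = 0),
            class = "kmc_mixture")
}

encode_mixture <- function(spec, mix) {
  ti <- type_index(spec)
  n <- length(mix$types)
  types <- integer(n)
  states <- vector("list", n)
  for (i in seq_len(n)) {
    ty <- mix$types[[i]]
    types[i] <- ti[[ty]]
    def <- spec$molecule_types[[ty]]$components
    sv <- integer(length(def))
    for (k in seq_along(def)) {
      cn <- names(def)[k]
      if (length(def[[k]]$states) == 0L) sv[k] <- -1L
      else sv[k] <- state_index(spec, ty, cn)[[mix$states[[i]][[cn]]]]
    }
    states[[i]] <- sv
  }
  bm <- matrix(0L, nrow = nrow(mix$bonds), ncol = 4)
  for (r in seq_len(nrow(mix$bonds))) {
    t1 <- mix$types[[mix$bonds$mol1[r]]]; t2 <- mix$types[[mix$bonds$mol2[r]]]
    bm[r, ] <- c(mix$bonds$mol1[r] - 1L, comp_index(spec, t1)[[mix$bonds$comp1[r]]],
                 mix$bonds$mol2[r] - 1L, comp_index(spec, t2)[[mix$bonds$comp2[r]]])
  }
  list(types = types, states = states, bonds = bm)
}

decode_mixture <- function(spec, enc, time = 0) {
  tn <- names(spec$molecule_types)
  n <- length(enc$types)
  types <- tn[enc$types + 1L]
  states <- vector("list", n)
  for (i in seq_len(n)) {
    def <- spec$molecule_types[[types[i]]]$components
    sv <- setNames(rep(NA_character_, length(def)), names(def))
    for (k in seq_along(def)) {
      si <- enc$states[[i]][k]
      if (si >= 0L) sv[k] <- def[[k]]$states[si + 1L]
    }
    states[[i]] <- sv
  }
  bm <- enc$bonds
  bonds <- data.frame(mol1 = integer(0), comp1 = character(0),
                      mol2 = integer(0), comp2 = character(0))
  if (nrow(bm) > 0L) {
    comp_name <- function(mi, ci)
      names(spec$molecule_types[[types[mi + 1L]]]$components)[ci + 1L]
    bonds <- data.frame(
      mol1 = bm[, 1] + 1L,
      comp1 = vapply(seq_len(nrow(bm)), function(r) comp_name(bm[r, 1], bm[r, 2]), ""),
      mol2 = bm[, 3] + 1L,
      comp2 = vapply(seq_len(nrow(bm)), function(r) comp_name(bm[r, 3], bm[r, 4]), ""))
  }
  structure(list(types = types, states = states, bonds = bonds, time = time),
            class = "kmc_mixture")
}

## ---- protocols ----------------------------------------------------------

#' Define a simulation protocol
#'
#' @param t_eq Equilibration duration in seconds (simulated before the
#'   stimulus to reach the unstimulated steady state); must be positive.
#' @param grid Strictly increasing observation times in seconds; by
#'   convention the stimulus is injected at t = 0 and the default grid is
#'   \code{c(0, 5, 15, 30, 60)}.
#' @param n_runs Number of independent runs for ensemble averaging.
#' @param seed Base seed; run r uses \code{seed + r - 1}.
#' @param stimulus A list of \code{list(species =, count =)} entries
#'   injected at t = 0 (may be empty).
#' @return A \code{sim_protocol} object.
#' @export
sim_protocol <- function(t_eq = 500, grid = c(0, 5, 15, 30, 60),
                         n_runs = 100L, seed = 1L, stimulus = list()) {
  stopifnot(t_eq > 0, all(diff(grid) > 0), n_runs >= 1)
  structure(list(t_eq = t_eq, grid = grid, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), stimulus = stimulus),
            class = "sim_protocol")
}

#' Read a simulation protocol from a YAML config file
#' @param path Path to a YAML file with fields \code{t_eq}, \code{grid},
#'   \code{n_runs}, \code{seed} and \code{stimulus} (a list of
#'   \code{species}/\code{count} pairs).
#' @return A \code{sim_protocol}.
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  sim_protocol(t_eq = y$t_eq, grid = as.numeric(y$grid),
               n_runs = y$n_runs, seed = y$seed,
               stimulus = lapply(y$stimulus, function(s)
                 list(species = s$species, count = as.integer(s$count))))
}

#' Write a simulation protocol to a YAML config file
#' @param protocol A \code{sim_protocol}.
#' @param path Output path.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}

encode_stimulus <- function(spec, stimulus) {
  lapply(stimulus, function(s)
    encode_seed(spec, parse_pattern(s$species), s$count))
}

## ---- simulation wrappers ------------------------------------------------

MAX_EVENTS <- 2e8

#' Run one stochastic trajectory
#'
#' Equilibrates the model without stimulus for \code{protocol$t_eq} seconds
#' (finding the unstimulated steady state), injects the stimulus species at
#' t = 0, and records every observable at each grid time.  Identical
#' \code{(spec, protocol, seed)} give bit-identical results.
#'
#' @param spec A validated \code{model_spec} (or a \code{compiled_model}).
#' @param protocol A \code{sim_protocol}.
#' @param seed Integer seed for this run.
#' @return A \code{kmc_trajectory}: list with \code{times}, \code{counts}
#'   (time-by-observable matrix), \code{seed} and \code{n_events}.
#' @export
simulate_model <- function(spec, protocol, seed = protocol$seed) {
  cm <- compile_model(spec)
  stim <- encode_stimulus(spec, protocol$stimulus)
  set.seed(seed)
  res <- cpp_simulate(cm, protocol$t_eq, protocol$grid, stim, MAX_EVENTS)
  structure(list(times = res$times, counts = res$counts, seed = seed,
                 n_events = res$n_events),
            class = "kmc_trajectory")
}

#' Run an ensemble of trajectories
#'
#' The model is compiled once and re-simulated \code{protocol$n_runs}
#' times; run r uses seed \code{protocol$seed + r - 1}.
#'
#' @inheritParams simulate_model
#' @return A list of \code{kmc_trajectory} objects.
#' @export
simulate_ensemble <- function(spec, protocol) {
  cm <- compile_model(spec)
  stim <- encode_stimulus(spec, protocol$stimulus)
  lapply(seq_len(protocol$n_runs), function(r) {
    seed <- protocol$seed + r - 1L
    set.seed(seed)
    res <- cpp_simulate(cm, protocol$t_eq, protocol$grid, stim, MAX_EVENTS)
    structure(list(times = res$times, counts = res$counts, seed = seed,
                   n_events = res$n_events),
              class = "kmc_trajectory")
  })
}

#' Equilibrate a model to its unstimulated steady state
#'
#' Simulates for \code{protocol$t_eq} seconds without stimulus and returns
#' the resulting particle mixture; its time is reset to 0 so that the
#' pre-stimulus observation can be taken from it.
#'
#' @inheritParams simulate_model
#' @return A \code{kmc_mixture}.
#' @export
equilibrate <- function(spec, protocol, seed = protocol$seed) {
  if (length(protocol$stimulus) > 0L) {
    stim_types <- vapply(protocol$stimulus, function(s)
      parse_pattern(s$species)[[1]]$type, "")
    seed_types <- unlist(lapply(spec$seed_species, function(s)
      vapply(s$pattern, `[[`, "", "type")))
    if (any(stim_types %in% seed_types))
      stop("stimulus species must be absent from the seed species")
  }
  cm <- compile_model(spec)
  set.seed(seed)
  enc <- cpp_equilibrate(cm, protocol$t_eq, MAX_EVENTS)
  decode_mixture(spec, enc, time = 0)
}

#' Continue simulating an explicit mixture
#'
#' @param spec The \code{model_spec}.
#' @param mixture A \code{kmc_mixture} (e.g. from [equilibrate()]).
#' @param t_end Duration in seconds.
#' @param record_times Times at which observables are recorded.
#' @param seed Integer seed.
#' @return List with \code{times}, \code{counts}, \code{mixture} (final
#'   state) and \code{n_events}.
#' @export
run_mixture <- function(spec, mixture, t_end, record_times = numeric(0),
                        seed = 1L) {
  cm <- compile_model(spec)
  set.seed(seed)
  res <- cpp_run_mixture(cm, encode_mixture(spec, mixture), t_end,
                         as.numeric(record_times), MAX_EVENTS)
  res$mixture <- decode_mixture(spec, res$mixture, time = mixture$time + t_end)
  res
}

#' Perform a single kinetic Monte Carlo step
#'
#' Draws the waiting time from Exponential(total propensity), picks a rule
#' with probability proportional to its propensity, transforms one randomly
#' chosen embedding, and returns the updated mixture.  When no rule
#' applies, the mixture is returned unchanged with \code{quiescent = TRUE}
#' (the caller advances to the next observation time).
#'
#' @param spec The \code{model_spec}.
#' @param mixture A \code{kmc_mixture}.
#' @param seed Optional seed set before drawing.
#' @return List with \code{tau}, \code{rule} (name or \code{NA}),
#'   \code{quiescent}, \code{null_event} and \code{mixture}.
#' @export
kmc_step <- function(spec, mixture, seed = NULL) {
  cm <- compile_model(spec)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_step(cm, encode_mixture(spec, mixture))
  out <- list(tau = res$tau, quiescent = res$quiescent,
              rule = if (is.na(res$rule)) NA_character_ else cm$rule_names[res$rule],
              null_event = isTRUE(res$null_event),
              mixture = decode_mixture(spec, res$mixture,
                                       time = mixture$time +
                                         if (is.finite(res$tau)) res$tau else 0))
  out
}

#' Rule propensities in a mixture
#'
#' Unimolecular rules contribute k times the number of matches of their
#' reactant pattern; bimolecular rules k times the product of the two match
#' counts, with n(n-1) ordered pairings when both reactant patterns are
#' identical.  Match counts are embedding counts divided by the pattern's
#' automorphism order.
#'
#' @param spec The \code{model_spec}.
#' @param mixture A \code{kmc_mixture}.
#' @param rule Optional rule name; when omitted all propensities are
#'   returned as a named vector (events/s).
#' @return Numeric vector of propensities.
#' @export
rule_propensity <- function(spec, mixture, rule = NULL) {
  cm <- compile_model(spec)
  v <- cpp_propensities(cm, encode_mixture(spec, mixture))
  names(v) <- cm$rule_names
  if (is.null(rule)) v else v[[rule]]
}

#' Count embeddings of a pattern in a mixture
#'
#' Counts maps of the pattern site-graph into the mixture site-graph that
#' respect molecule types, component states and bonds.  With
#' \code{symmetry = TRUE} (the mass-action convention used for
#' propensities) the raw embedding count is divided by the pattern's
#' automorphism order, so a symmetric homodimer pattern matches a single
#' dimer once rather than twice.
#'
#' @param spec The \code{model_spec} declaring the molecule types.
#' @param mixture A \code{kmc_mixture}.
#' @param pattern A pattern string (e.g. \code{"A(b!1).B(a!1)"}) or a
#'   parsed \code{bngl_pattern}.
#' @param symmetry Divide by the automorphism order (default TRUE).
#' @return A nonnegative count.
#' @export
count_embeddings <- function(spec, mixture, pattern, symmetry = TRUE) {
  pat <- if (inherits(pattern, "bngl_pattern")) pattern else parse_pattern(pattern)
  s2 <- spec
  s2$rules <- list()
  s2$observables <- list(list(name = ".q", patterns = list(pat)))
  s2$seed_species <- list()
  cm <- compile_model(s2)
  v <- cpp_count_pattern(cm, encode_mixture(spec, mixture),
                         cm$obs[[1]]$pats[[1]])
  if (symmetry) unname(v[["matches"]]) else unname(v[["raw"]])
}

#' Observable counts in a mixture
#' @inheritParams rule_propensity
#' @return Named numeric vector of observable counts.
#' @export
observe_mixture <- function(spec, mixture) {
  cm <- compile_model(spec)
  drop(cpp_observe(cm, encode_mixture(spec, mixture)))
}

## ---- trajectory utilities ----------------------------------------------

#' Average an ensemble of trajectories
#'
#' @param trajectories List of \code{kmc_trajectory} objects sharing grid
#'   and observables.
#' @return A \code{kmc_ensemble}: list with \code{times}, \code{mean} and
#'   \code{sd} (time-by-observable matrices) and \code{n_runs}.
#' @export
average_runs <- function(trajectories) {
  stopifnot(length(trajectories) >= 1L)
  t0 <- trajectories[[1]]$times
  for (tr in trajectories) {
    if (!isTRUE(all.equal(tr$times, t0)))
      stop("trajectories do not share an observation grid")
    if (!identical(colnames(tr$counts), colnames(trajectories[[1]]$counts)))
      stop("trajectories do not share observables")
  }
  arr <- simplify2array(lapply(trajectories, `[[`, "counts"))
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L),
                                           dimnames = c(dimnames(arr), list(NULL)))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (dim(arr)[3] >= 2L) apply(arr, c(1, 2), stats::sd) else mu * 0
  structure(list(times = t0, mean = mu, sd = sdv,
                 n_runs = length(trajectories)),
            class = "kmc_ensemble")
}

#' Export an averaged trajectory as delimited text
#'
#' Long format with columns \code{time_s}, \code{observable}, \code{mean},
#' \code{sd}, \code{n_runs}.
#'
#' @param ensemble A \code{kmc_ensemble} from [average_runs()].
#' @param path Output TSV path; when \code{NULL} the data frame is
#'   returned instead.
#' @export
export_trajectory <- function(ensemble, path = NULL) {
  obs <- colnames(ensemble$mean)
  df <- do.call(rbind, lapply(seq_along(obs), function(j)
    data.frame(time_s = ensemble$times, observable = obs[j],
               mean = ensemble$mean[, j], sd = ensemble$sd[, j],
               n_runs = ensemble$n_runs)))
  rownames(df) <- NULL
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @export
print.kmc_trajectory <- function(x, ...) {
  cat(sprintf("kmc_trajectory: %d observables over t = %s s (seed %d, %g events)\n",
              ncol(x$counts), paste(range(x$times), collapse = ".."),
              x$seed, x$n_events))
  invisible(x)
}

#' @export
print.kmc_ensemble <- function(x, ...) {
  cat(sprintf("kmc_ensemble: %d runs, %d observables, grid {%s} s\n",
              x$n_runs, ncol(x$mean), paste(x$times, collapse = ", ")))
  invisible(x)
}
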