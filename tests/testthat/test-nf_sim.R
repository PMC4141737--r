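spec_ab <- ab_binding_model()

test_that("embedding counts match the documented conventions on small cases", {
  ## three free A molecules
  mix3 <- make_mixture(spec_ab, "A(b)", 3L)
  expect_identical(count_embeddings(spec_ab, mix3, "A(b)"), 3)
  ## one A-B dimer
  dim1 <- make_mixture(spec_ab, "A(b!1).B(a!1)", 1L)
  expect_identical(count_embeddings(spec_ab, dim1, "A(b!+)"), 1)
  expect_identical(count_embeddings(spec_ab, dim1, "A(b!1).B(a!1)"), 1)
  ## symmetric homodimer: raw embeddings 2, symmetry-corrected matches 1
  spec_aa <- parse_model(c(
    "begin parameters", "k 1", "end parameters",
    "begin molecule types", "A(a)", "end molecule types",
    "begin seed species", "A(a) 2", "end seed species",
    "begin observables", "Molecules d A(a!1).A(a!1)", "end observables",
    "begin reaction rules", "b: A(a) + A(a) -> A(a!1).A(a!1) k",
    "end reaction rules"))
  homo <- make_mixture(spec_aa, "A(a!1).A(a!1)", 1L)
  expect_identical(count_embeddings(spec_aa, homo, "A(a!1).A(a!1)",
                                    symmetry = FALSE), 2)
  expect_identical(count_embeddings(spec_aa, homo, "A(a!1).A(a!1)"), 1)
})

test_that("embedding counts agree with brute-force enumeration on random mixtures", {
  spec <- embed_test_spec()
  patterns <- c("A(a)", "A(a!+)", "A(x~P!?)", "A(a!1).B(b!1)",
                "B(y~U,b!1).A(a!1)", "A(a!1).A(a!1)", "C(c!+)",
                "B(b!1).C(c!1)")
  set.seed(7031)
  for (rep in 1:25) {
    mix <- random_mixture(spec, n_mol = sample(4:12, 1L))
    for (p in patterns) {
      raw <- count_embeddings(spec, mix, p, symmetry = FALSE)
      expect_identical(raw, as.numeric(brute_force_embeddings(mix, p)),
                       info = paste("pattern", p))
    }
  }
})

test_that("rule propensities follow mass action over match counts", {
  ## unimolecular: k = 0.5 with 10 matches
  spec <- decay_model(k = 0.5, n = 10L)
  mix <- make_mixture(spec, "A(y~P)", 10L)
  expect_identical(unname(rule_propensity(spec, mix, "decay")), 5)
  ## bimolecular: k = 2 with 3 free A and 4 free B
  spec2 <- ab_binding_model(kon = 2, koff = 1, nA = 3L, nB = 4L)
  mix2 <- make_mixture(spec2, c("A(b)", "B(a)"), c(3L, 4L))
  expect_identical(unname(rule_propensity(spec2, mix2, "bind")), 24)
  ## zero matches
  mix0 <- make_mixture(spec, "A(y~U)", 4L)
  expect_identical(unname(rule_propensity(spec, mix0, "decay")), 0)
})

test_that("a single kinetic Monte Carlo step fires the only possible event", {
  spec <- decay_model(k = 0.5, n = 1L)
  mix <- make_mixture(spec, "A(y~P)", 1L)
  st <- kmc_step(spec, mix, seed = 5)
  expect_false(st$quiescent)
  expect_identical(st$rule, "decay")
  expect_identical(unname(st$mixture$states[[1]][["y"]]), "U")
  ## quiescent mixture: no applicable rule
  st0 <- kmc_step(spec, st$mixture, seed = 6)
  expect_true(st0$quiescent)
  expect_identical(st0$mixture$states, st$mixture$states)
})

test_that("rule selection frequencies are proportional to propensities", {
  ## two unimolecular rules with propensity ratio 1:3 acting on disjoint pools
  spec <- parse_model(c(
    "begin parameters", "k1 0.1", "k2 0.3", "end parameters",
    "begin molecule types", "A(x~U~P)", "B(x~U~P)", "end molecule types",
    "begin seed species", "A(x~U) 10", "B(x~U) 10", "end seed species",
    "begin observables", "Molecules aP A(x~P)", "end observables",
    "begin reaction rules",
    "slow: A(x~U) -> A(x~P) k1", "fast: B(x~U) -> B(x~P) k2",
    "end reaction rules"))
  mix <- make_mixture(spec, c("A(x~U)", "B(x~U)"), c(10L, 10L))
  set.seed(88)
  n <- 1500L
  fired <- character(n)
  for (i in seq_len(n)) fired[i] <- kmc_step(spec, mix)$rule
  f <- mean(fired == "slow")
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(f - 0.25), 3 * se)
})

test_that("simulation reproduces analytic exponential decay", {
  spec <- decay_model(k = 0.1, n = 1000L)
  pr <- sim_protocol(t_eq = 1e-6, grid = c(0, 10), n_runs = 50L, seed = 2,
                     stimulus = list())
  ens <- average_runs(simulate_ensemble(spec, pr))
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / 1000 / 50)
  expect_lt(abs(ens$mean[2, "A_P"] / 1000 - p), 3 * se)
})

test_that("reversible binding relaxes to the ODE equilibrium", {
  skip_if_not_installed("deSolve")
  kon <- 1e-3; koff <- 0.5; nA <- 200; nB <- 150
  ode_eq <- deSolve::ode(
    y = c(AB = 0), times = c(0, 500),
    func = function(t, y, p) {
      list(kon * (nA - y[1]) * (nB - y[1]) - koff * y[1])
    }, parms = NULL)[2, "AB"]
  spec <- ab_binding_model(kon, koff, nA, nB)
  pr <- sim_protocol(t_eq = 1e-6, grid = c(0, 100, 120, 140, 160, 180, 200),
                     n_runs = 40L, seed = 5, stimulus = list())
  ens <- average_runs(simulate_ensemble(spec, pr))
  late <- ens$mean[4:7, "AB"]
  mc_se <- mean(ens$sd[4:7, "AB"]) / sqrt(ens$n_runs)
  expect_lt(abs(mean(late) - ode_eq), 4 * mc_se)
})

test_that("a fixed seed gives bit-identical trajectories", {
  spec <- ab_binding_model()
  pr <- sim_protocol(t_eq = 5, grid = c(0, 5, 15, 30, 60), n_runs = 1L,
                     seed = 3, stimulus = list())
  t1 <- simulate_model(spec, pr, seed = 17)
  t2 <- simulate_model(spec, pr, seed = 17)
  expect_identical(t1$counts, t2$counts)
  t3 <- simulate_model(spec, pr, seed = 18)
  expect_false(identical(t1$counts, t3$counts))
})

test_that("no-rule models stay at their seed values and equilibrate trivially", {
  spec <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "A(y~U~P)", "end molecule types",
    "begin seed species", "A(y~P) 25", "end seed species",
    "begin observables", "Molecules A_P A(y~P)", "end observables",
    "begin reaction rules", "end reaction rules"))
  pr <- sim_protocol(t_eq = 10, grid = c(0, 5, 15), n_runs = 1L, seed = 1,
                     stimulus = list())
  tr <- simulate_model(spec, pr, seed = 1)
  expect_true(all(tr$counts[, "A_P"] == 25))
  mix <- equilibrate(spec, pr, seed = 1)
  expect_identical(length(mix$types), 25L)
  expect_true(all(vapply(mix$states, function(s) s[["y"]] == "P", TRUE)))
})

test_that("equilibration reaches a stationary state of a constitutive cycle", {
  spec <- parse_model(c(
    "begin parameters", "kp 0.05", "ku 0.1", "end parameters",
    "begin molecule types", "A(y~U~P)", "end molecule types",
    "begin seed species", "A(y~U) 300", "end seed species",
    "begin observables", "Molecules A_P A(y~P)", "end observables",
    "begin reaction rules",
    "p: A(y~U) -> A(y~P) kp", "u: A(y~P) -> A(y~U) ku",
    "end reaction rules"))
  ## doubling the equilibration time leaves the t = 0 observation unchanged
  ## within Monte Carlo error (occupancy kp/(kp+ku) = 1/3)
  m1 <- vapply(1:30, function(r) {
    pr <- sim_protocol(t_eq = 100, grid = 0, n_runs = 1L, seed = r,
                       stimulus = list())
    simulate_model(spec, pr, seed = r)$counts[1, "A_P"]
  }, 0)
  m2 <- vapply(1:30, function(r) {
    pr <- sim_protocol(t_eq = 200, grid = 0, n_runs = 1L, seed = 100 + r,
                       stimulus = list())
    simulate_model(spec, pr, seed = 100 + r)$counts[1, "A_P"]
  }, 0)
  se <- sqrt(stats::var(m1) / 30 + stats::var(m2) / 30)
  expect_lt(abs(mean(m1) - mean(m2)), 4 * se)
  expect_lt(abs(mean(m1) - 100), 4 * sqrt(stats::var(m1) / 30) + 2)
})

test_that("run averaging returns the arithmetic mean and SD per grid time", {
  mk <- function(v) structure(list(times = c(0, 5), seed = 1, n_events = 0,
                                   counts = matrix(v, nrow = 2, ncol = 1,
                                                   dimnames = list(NULL, "x"))),
                              class = "kmc_trajectory")
  ens <- average_runs(list(mk(c(2, 2)), mk(c(4, 4))))
  expect_identical(unname(ens$mean[, "x"]), c(3, 3))
  expect_equal(unname(ens$sd[, "x"]), rep(sqrt(2), 2))
  one <- average_runs(list(mk(c(7, 9))))
  expect_identical(unname(one$mean[, "x"]), c(7, 9))
  expect_identical(unname(one$sd[, "x"]), c(0, 0))
  bad <- mk(c(1, 1)); bad$times <- c(0, 6)
  expect_error(average_runs(list(mk(c(1, 1)), bad)), "grid")
})

test_that("per-protein copy numbers are conserved along a trajectory", {
  params <- default_tcr_params()
  spec <- build_tcr_model(params)
  pr <- tcr_protocol(params, t_eq = 50, n_runs = 1L, seed = 4)
  mix0 <- equilibrate(spec, pr, seed = 4)
  counts0 <- table(mix0$types)
  seeds <- setNames(
    vapply(spec$seed_species, `[[`, 0L, "count"),
    vapply(spec$seed_species, function(s) s$pattern[[1]]$type, ""))
  expect_identical(as.integer(counts0[names(seeds)]), unname(as.integer(seeds)))
  res <- run_mixture(spec, mix0, t_end = 30, record_times = c(0, 30), seed = 9)
  counts1 <- table(res$mixture$types)
  expect_identical(counts1[names(counts0)], counts0[names(counts0)])
})
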