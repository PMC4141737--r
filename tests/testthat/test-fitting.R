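test_that("derived parameters resolve in dependency order and cycles are named", {
  ps <- parameter_spec(
    name = c("k_on", "K_a", "k_off"),
    class = c("fixed", "fixed", "derived"),
    value = c("1e-3", "1e-1", "k_on / K_a"))
  out <- resolve_derived(ps)
  expect_equal(out[["k_off"]], 1e-2)
  ## no derived parameters: the table passes through
  ps2 <- parameter_spec(c("a", "b"), c("fixed", "fitted"), c("2", "3"))
  expect_identical(resolve_derived(ps2, c(b = 4)), c(a = 2, b = 4))
  expect_identical(resolve_derived(ps2), c(a = 2, b = 3))
  ## cycle detection names the offenders
  ps3 <- parameter_spec(c("a", "b"), c("derived", "derived"),
                        c("b + 1", "a + 1"))
  expect_error(resolve_derived(ps3), "cyclic.*a.*b")
})

test_that("parameter tables round-trip through delimited text", {
  ps <- parameter_spec(c("k1", "k2", "k3"), c("fixed", "fitted", "derived"),
                       c("0.5", "1", "k1 * k2"), lower = c(0, 0.1, 0),
                       upper = c(Inf, 10, Inf))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(ps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ps2 <- read_parameter_table(path)
  expect_equal(as.data.frame(ps2), as.data.frame(ps))
})

test_that("grid search returns the enumerated minimizer", {
  f <- function(th) (th[["x"]] - 3)^2
  g <- grid_search(f, list(x = 0:5))
  expect_identical(unname(g$par[["x"]]), 3L)
  expect_identical(g$value, 0)
  expect_identical(g$stage, "grid")
  expect_identical(g$evaluations, 6L)
  ## 2-D separable quadratic: nearest grid point to the analytic minimum
  f2 <- function(th) (th[["x"]] - 1.2)^2 + (th[["y"]] + 0.4)^2
  g2 <- grid_search(f2, list(x = seq(-2, 2, 1), y = seq(-2, 2, 1)))
  expect_identical(unname(g2$par), c(1, 0))
  ## ties break to the first point in enumeration order
  g3 <- grid_search(function(th) 0 * th[["x"]], list(x = c(7, 8, 9)))
  expect_identical(unname(g3$par[["x"]]), 7)
  expect_error(grid_search(f, list()), "length")
})

test_that("quasi-Newton refinement descends to the minimum and never worsens", {
  f <- function(th) (th[["x"]] - 3)^2
  r <- refine(f, c(x = 2.5), lower = 0.1, upper = 10)
  expect_lt(abs(r$par[["x"]] - 3), 1e-3)
  expect_identical(r$stage, "refined")
  ## starting at the minimum returns it
  r0 <- refine(f, c(x = 3), lower = 0.1, upper = 10)
  expect_identical(r0$value, 0)
  expect_equal(unname(r0$par[["x"]]), 3)
  ## positivity-only parameters are optimized in log space
  rp <- refine(f, c(x = 0.5))
  expect_lt(abs(rp$par[["x"]] - 3), 1e-2)
  ## Rosenbrock from (0, 0): the refined value improves on the start
  rosen <- function(th) (1 - th[["x"]])^2 + 100 * (th[["y"]] - th[["x"]]^2)^2
  rr <- refine(rosen, c(x = 0, y = 0), lower = -2, upper = 2, maxit = 50)
  expect_lt(rr$value, rosen(c(x = 0, y = 0)))
  expect_lte(rr$value, rr$start_value)
  expect_error(refine(f, c(x = 20), lower = 0, upper = 10), "bounds")
})

test_that("the simulation objective is deterministic, additive and calibrated", {
  truth <- c(k_stim = 3e-4, k_dephos = 0.06)
  pr <- sim_protocol(t_eq = 50, grid = c(0, 5, 15, 30, 60), n_runs = 15L,
                     seed = 3,
                     stimulus = list(list(species = "L(s)", count = 150L)))
  mk <- function(th) toy_cycle_model(th[["k_stim"]], th[["k_dephos"]])
  dat <- generate_truth_dataset(mk(truth), truth, pr, sigma = 0, seed = 3)
  obj <- build_objective(mk, dat$courses, pr, n_runs = 15L, base_seed = 3)
  v1 <- obj(truth)
  expect_identical(v1, obj(truth))            # common random numbers
  ## data generated noiselessly from the model at truth: objective ~ 0
  expect_lt(v1, 1e-9)
  ## duplicated data doubles the objective
  dat2 <- rbind(dat$courses, dat$courses)
  obj2 <- build_objective(mk, dat2, pr, n_runs = 15L, base_seed = 3)
  expect_equal(obj2(truth), 2 * v1)
  ## a misspecified rate scores worse under paired seeds
  off <- truth; off[["k_stim"]] <- truth[["k_stim"]] * 10
  expect_gt(obj(off), v1)
  ## a data site without a model observable raises
  bad <- dat$courses; bad$site <- "nonexistent"
  objb <- build_objective(mk, bad, pr, n_runs = 5L, base_seed = 3)
  expect_error(objb(truth), "without a model observable")
})
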