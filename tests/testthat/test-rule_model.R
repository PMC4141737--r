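test_that("the smallest well-formed models parse to the expected structure", {
  m <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "A(y~U~P)", "end molecule types",
    "begin seed species", "A(y~U) 10", "end seed species",
    "begin observables", "end observables",
    "begin reaction rules", "end reaction rules"))
  expect_s3_class(m, "model_spec")
  expect_length(m$molecule_types, 1L)
  expect_length(m$seed_species, 1L)
  expect_identical(m$seed_species[[1]]$count, 10L)
  expect_length(m$rules, 0L)

  m2 <- parse_model(c(
    "begin parameters", "k1 5", "end parameters",
    "begin molecule types", "A(y~U~P)", "end molecule types",
    "begin seed species", "A(y~U) 10", "end seed species",
    "begin observables", "end observables",
    "begin reaction rules", "flip: A(y~U) -> A(y~P) k1",
    "end reaction rules"))
  expect_identical(m2$parameters[["k1"]], 5)
  r <- m2$rules[[1]]
  expect_identical(r$type, "set_state")
  expect_identical(r$rate, "k1")
  expect_identical(r$action$comp, "y")
  expect_identical(r$action$to, "P")
})

test_that("parse/write round-trips are exact for generated specs", {
  set.seed(421)
  for (i in 1:20) {
    s <- random_model_spec()
    txt <- write_model(s)
    s2 <- parse_model(txt)
    expect_identical(write_model(s2), txt)
    ## and semantic equality of the canonical forms
    expect_equal(parse_model(write_model(s2)), s2)
  }
})

test_that("bind and unbind transformations are inferred from rule sides", {
  m <- ab_binding_model()
  types <- vapply(m$rules, `[[`, "", "type")
  expect_setequal(types, c("bind", "unbind"))
  bind <- m$rules[[which(types == "bind")]]
  expect_length(bind$reactants, 2L)
  expect_identical(bind$action$a[["comp"]], "b")
  expect_identical(bind$action$b[["comp"]], "a")
})

test_that("unknown constructs and malformed rules raise with line numbers", {
  base <- c("begin parameters", "k 1", "end parameters",
            "begin molecule types", "A(y~U~P)", "end molecule types",
            "begin seed species", "A(y~U) 5", "end seed species",
            "begin observables", "end observables")
  expect_error(parse_model(c("begin compartments", "end compartments")),
               "unknown block")
  expect_error(parse_model(c(base, "begin reaction rules",
                             "r: A(y~U) <-> A(y~P) k", "end reaction rules")),
               "reversible")
  expect_error(parse_model(c(base, "begin reaction rules",
                             "r: A(y~U) -> A(y~P) 0.5", "end reaction rules")),
               "parameter symbol")
  expect_error(parse_model(c(base, "begin reaction rules",
                             "r: A(y~U) -> 0 k", "end reaction rules")),
               "not supported|conserved")
  expect_error(parse_model(sub("A\\(y~U\\) 5", "A(y~U) -5", base)),
               "egative")
  expect_error(parse_model(sub("A\\(y~U\\) 5", "A(y~U) 2.5", base)),
               "integer")
  ## two simultaneous changes are not an elementary rule
  expect_error(parse_model(c(base, "begin reaction rules",
                             "r: A(y~U) + A(y~U) -> A(y~P) + A(y~P) k",
                             "end reaction rules")),
               "exactly one elementary change")
})

test_that("validate_model reports dangling references without raising", {
  ok <- ab_binding_model()
  expect_identical(nrow(validate_model(ok)), 0L)

  bad <- ok
  bad$parameters <- bad$parameters["koff"]     # delete kon
  rep <- validate_model(bad)
  expect_identical(nrow(rep), 1L)
  expect_match(rep$message, "kon")

  bad2 <- ok
  bad2$observables[[1]]$patterns[[1]][[1]]$type <- "Zz"
  rep2 <- validate_model(bad2)
  expect_gt(nrow(rep2), 0L)
  expect_match(rep2$message[1], "Zz")
})

test_that("randomly corrupted specs yield exactly the planted violation", {
  set.seed(99)
  for (i in 1:10) {
    s <- random_model_spec()
    drop <- sample(names(s$parameters), 1L)
    s$parameters <- s$parameters[setdiff(names(s$parameters), drop)]
    rep <- validate_model(s)
    used <- vapply(s$rules, `[[`, "", "rate")
    if (drop %in% used) {
      expect_true(all(grepl(drop, rep$message)))
      expect_identical(nrow(rep), sum(used == drop))
    } else {
      expect_identical(nrow(rep), 0L)
    }
  }
})

test_that("pattern syntax covers states, bonds and wildcards", {
  p <- parse_pattern("A(y~P,b!1).B(a!1,c!+,d!?)")
  expect_length(p, 2L)
  expect_identical(p[[1]]$components$y$state, "P")
  expect_identical(p[[1]]$components$b$bond, 1L)
  expect_identical(p[[2]]$components$c$bond, "some")
  expect_identical(p[[2]]$components$d$bond, "any")
  expect_error(parse_pattern("A(b!1)"), "exactly twice")
})
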