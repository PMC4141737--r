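params <- default_tcr_params()
model <- build_tcr_model(params)

test_that("the built model is valid and matches the site roster", {
  expect_identical(nrow(validate_model(model)), 0L)
  roster <- tcr_site_roster()
  measured <- roster[roster$measured, ]
  expect_identical(nrow(measured), 16L)
  expect_identical(length(unique(measured$protein)), 10L)
  obs_names <- vapply(model$observables, `[[`, "", "name")
  expect_true(all(roster$observable %in% obs_names))
  ## ten measured proteins + seven additional signaling proteins
  proteins <- setdiff(names(model$molecule_types), "Lig")
  expect_identical(length(proteins), 17L)
  additional <- setdiff(proteins, unique(measured$protein))
  expect_identical(length(additional), 7L)
  expect_setequal(additional,
                  c("CD3E", "CD247", "CD28", "CSK", "NCK", "GRAP2", "LCP2"))
})

test_that("disabling the shortcut removes only the NCK-CD3E binding rules", {
  m2 <- build_tcr_model(params, shortcut_enabled = FALSE)
  r1 <- vapply(model$rules, `[[`, "", "name")
  r2 <- vapply(m2$rules, `[[`, "", "name")
  expect_setequal(setdiff(r1, r2), c("nck_cd3e_on", "nck_cd3e_off"))
  shared <- intersect(r1, r2)
  expect_identical(model$rules[match(shared, r1)], m2$rules[match(shared, r2)])
  ## feedback toggle removes the four PTPN6 catalytic rules
  m3 <- build_tcr_model(params, ptpn6_feedback_enabled = FALSE)
  r3 <- vapply(m3$rules, `[[`, "", "name")
  expect_setequal(setdiff(r1, r3),
                  c("shp1_y192", "shp1_y163", "shp1_dok1", "shp1_dok2"))
  expect_error(build_tcr_model(params[-1]), "missing parameter")
})

test_that("knockdowns zero the protein's copy number and are idempotent", {
  kd <- apply_knockdown(model, "PTPN6")
  get_count <- function(spec, prot) {
    for (s in spec$seed_species)
      if (s$pattern[[1]]$type == prot) return(s$count)
    NA_integer_
  }
  expect_identical(get_count(kd, "PTPN6"), 0L)
  others <- setdiff(names(model$molecule_types), c("PTPN6", "Lig"))
  for (p in others)
    expect_identical(get_count(kd, p), get_count(model, p))
  expect_identical(apply_knockdown(kd, "PTPN6"), kd)
  expect_identical(kd$rules, model$rules)
  expect_error(apply_knockdown(model, "NOSUCH"), "unknown protein")
})

test_that("relative time courses normalize by the unstimulated baseline", {
  ens <- structure(list(times = c(0, 5, 15, 30, 60),
                        mean = matrix(c(10, 10, 20, 40, 40), ncol = 1,
                                      dimnames = list(NULL, "s1")),
                        sd = matrix(0, 5, 1), n_runs = 1L),
                   class = "kmc_ensemble")
  tc <- relative_timecourse(ens, "s1")
  expect_identical(tc$values, c(1, 1, 2, 4, 4))
  ## zero baseline uses the documented pseudocount rule
  ens0 <- structure(list(times = c(0, 5),
                         mean = matrix(c(0, 5), ncol = 1,
                                       dimnames = list(NULL, "s1")),
                         sd = matrix(0, 2, 1), n_runs = 1L),
                    class = "kmc_ensemble")
  tc0 <- relative_timecourse(ens0, "s1", eps = 0.5)
  expect_identical(tc0$values, c(1, 11))
  ## an external baseline makes genotypes comparable
  tcx <- relative_timecourse(ens, "s1", baseline = 20)
  expect_identical(tcx$values[1], 0.5)
})

test_that("cumulative phosphorylation is the trapezoidal area", {
  tc <- function(v, t = c(0, 5, 15, 30, 60))
    structure(list(site = "s", times = t, values = v),
              class = "relative_timecourse")
  expect_identical(cumulative_auc(tc(rep(1, 5))), 60)
  expect_identical(cumulative_auc(tc(seq(0, 2, length.out = 5),
                                     t = seq(0, 60, length.out = 5))), 60)
  expect_identical(cumulative_auc(tc(c(1, 1, 2, 4, 4))), 185)
  expect_identical(cumulative_auc(tc(c(1, 1, 2, 4, 4)), window = c(0, 30)), 65)
  expect_error(cumulative_auc(tc(rep(1, 5)), window = c(0, 90)), "window")
})

test_that("endpoint scaling divides by the 60-s value and is idempotent", {
  tc <- structure(list(site = "s", times = c(5, 30, 60), values = c(2, 4, 8)),
                  class = "relative_timecourse")
  sc <- scale_to_endpoint(tc)
  expect_identical(sc$values, c(0.25, 0.5, 1))
  expect_identical(scale_to_endpoint(sc)$values, sc$values)
  tc$values <- c(0, 0, 0)
  expect_error(scale_to_endpoint(tc), "zero")
})

test_that("half-rise times interpolate the first crossing", {
  tc <- structure(list(site = "s", times = c(0, 10, 20),
                       values = c(1, 1, 3)), class = "relative_timecourse")
  expect_identical(half_rise_time(tc), 15)
  flat <- structure(list(site = "s", times = c(0, 10), values = c(2, 1)),
                    class = "relative_timecourse")
  expect_true(is.na(half_rise_time(flat)))
})

test_that("site classes follow the roster", {
  expect_identical(site_class_of(protein = "CD3G", residue = 171), 1L)
  expect_identical(site_class_of(protein = "ZAP70", residue = 493), 2L)
  expect_identical(site_class_of(protein = "LCK", residue = 192), 3L)
  expect_error(site_class_of(protein = "LCK", residue = 9999), "unknown site")
})
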