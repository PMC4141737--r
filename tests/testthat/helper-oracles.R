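# Independent oracles and generators shared across tests.

## Brute-force subgraph monomorphism count: enumerate every injective map
## of pattern molecules onto mixture molecules and check all constraints
## directly on the kmc_mixture representation.  Written independently of
## the engine's anchored bond-following algorithm.
brute_force_embeddings <- function(mixture, pattern) {
  pat <- if (inherits(pattern, "bngl_pattern")) pattern else parse_pattern(pattern)
  n <- length(pat)
  m <- length(mixture$types)
  if (m < n) return(0L)
  bond_partner <- function(mol, comp) {
    b <- mixture$bonds
    i <- which(b$mol1 == mol & b$comp1 == comp)
    if (length(i) > 0) return(c(b$mol2[i[1]], b$comp2[i[1]]))
    i <- which(b$mol2 == mol & b$comp2 == comp)
    if (length(i) > 0) return(c(b$mol1[i[1]], b$comp1[i[1]]))
    NULL
  }
  check_assign <- function(map) {
    for (k in seq_len(n)) {
      pm <- pat[[k]]
      mol <- map[k]
      if (mixture$types[[mol]] != pm$type) return(FALSE)
      for (cn in names(pm$components)) {
        pc <- pm$components[[cn]]
        if (!is.na(pc$state) &&
            !identical(unname(mixture$states[[mol]][[cn]]), pc$state))
          return(FALSE)
        partner <- bond_partner(mol, cn)
        if (identical(pc$bond, "none") && !is.null(partner)) return(FALSE)
        if (identical(pc$bond, "some") && is.null(partner)) return(FALSE)
        if (is.numeric(pc$bond) || is.integer(pc$bond)) {
          if (is.null(partner)) return(FALSE)
          ## find the other end of this pattern bond label
          other <- NULL
          for (k2 in seq_len(n)) for (cn2 in names(pat[[k2]]$components)) {
            b2 <- pat[[k2]]$components[[cn2]]$bond
            if ((is.numeric(b2) || is.integer(b2)) && b2 == pc$bond &&
                !(k2 == k && cn2 == cn)) other <- c(k2, cn2)
          }
          if (is.null(other)) return(FALSE)
          if (partner[1] != map[as.integer(other[1])] ||
              partner[2] != other[2]) return(FALSE)
        }
      }
    }
    TRUE
  }
  count <- 0L
  idx <- seq_len(m)
  rec <- function(map) {
    k <- length(map) + 1L
    if (k > n) {
      if (check_assign(map)) count <<- count + 1L
      return(invisible())
    }
    for (cand in setdiff(idx, map)) rec(c(map, cand))
  }
  rec(integer(0))
  count
}

## adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

## a small two-type model used throughout the simulator tests
ab_binding_model <- function(kon = 1e-3, koff = 0.5, nA = 200L, nB = 150L) {
  parse_model(c(
    "begin parameters",
    sprintf("kon %.15g", kon), sprintf("koff %.15g", koff),
    "end parameters",
    "begin molecule types", "A(b)", "B(a)", "end molecule types",
    "begin seed species",
    sprintf("A(b) %d", nA), sprintf("B(a) %d", nB),
    "end seed species",
    "begin observables",
    "Molecules AB A(b!1).B(a!1)", "Molecules Afree A(b)",
    "end observables",
    "begin reaction rules",
    "bind: A(b) + B(a) -> A(b!1).B(a!1) kon",
    "unbind: A(b!1).B(a!1) -> A(b) + B(a) koff",
    "end reaction rules"))
}

decay_model <- function(k = 0.1, n = 1000L) {
  parse_model(c(
    "begin parameters", sprintf("k %.15g", k), "end parameters",
    "begin molecule types", "A(y~U~P)", "end molecule types",
    "begin seed species", sprintf("A(y~P) %d", n), "end seed species",
    "begin observables", "Molecules A_P A(y~P)", "end observables",
    "begin reaction rules", "decay: A(y~P) -> A(y~U) k",
    "end reaction rules"))
}

## model types used for random-mixture embedding tests
embed_test_spec <- function() {
  parse_model(c(
    "begin parameters", "k 1", "end parameters",
    "begin molecule types", "A(a,x~U~P)", "B(b,y~U~P)", "C(c)",
    "end molecule types",
    "begin seed species", "A(a,x~U) 1", "end seed species",
    "begin observables", "Molecules nA A(a!?)", "end observables",
    "begin reaction rules", "r: A(x~U) -> A(x~P) k", "end reaction rules"))
}

## random mixture over the embed_test_spec types: random states, random
## bonds among compatible free components (A.a-B.b, A.a-A.a, B.b-C.c)
random_mixture <- function(spec, n_mol = 10L) {
  types <- sample(c("A", "B", "C"), n_mol, replace = TRUE)
  species <- vapply(seq_len(n_mol), function(i) {
    switch(types[i],
           A = sprintf("A(a,x~%s)", sample(c("U", "P"), 1)),
           B = sprintf("B(b,y~%s)", sample(c("U", "P"), 1)),
           C = "C(c)")
  }, "")
  mix <- make_mixture(spec, species, counts = 1L)
  comp_of <- c(A = "a", B = "b", C = "c")
  free <- seq_len(n_mol)
  n_bonds <- sample(0:(n_mol %/% 2), 1L)
  for (b in seq_len(n_bonds)) {
    if (length(free) < 2L) break
    pair <- sample(free, 2L)
    ok <- (mix$types[pair[1]] %in% c("A", "B")) ||
      (mix$types[pair[2]] %in% c("A", "B"))
    ## allow any pairing; the matcher only cares about the site graph
    mix$bonds <- rbind(mix$bonds, data.frame(
      mol1 = pair[1], comp1 = unname(comp_of[mix$types[pair[1]]]),
      mol2 = pair[2], comp2 = unname(comp_of[mix$types[pair[2]]])))
    free <- setdiff(free, pair)
    if (!ok) next
  }
  mix
}

## random valid model specs for the parser round-trip property
random_model_spec <- function() {
  n_extra <- sample(0:2, 1)
  type_lines <- c("A(a,x~U~P)", "B(b,y~U~P)",
                  c("C(c)", "D(d,z~U~P~Q)", "E(e1,e2)")[seq_len(n_extra)])
  type_names <- sub("\\(.*", "", type_lines)
  seeds <- c("A(a,x~U) 50", "B(b,y~P) 30",
             c("C(c) 10", "D(d,z~Q) 5", "E(e1,e2) 7")[seq_len(n_extra)])
  pars <- c("k1 0.5", "k2 1.5e-3", "k3 2")
  rules <- c("r1: A(x~U) -> A(x~P) k1",
             "r2: A(a) + B(b) -> A(a!1).B(b!1) k2",
             "r3: A(a!1).B(b!1) -> A(a) + B(b) k3")
  if (sample(c(TRUE, FALSE), 1))
    rules <- c(rules, "r4: B(y~P) + A(x~P) -> B(y~P) + A(x~U) k1")
  obs <- c("Molecules xP A(x~P!?)", "Molecules dimer A(a!1).B(b!1)")
  if (sample(c(TRUE, FALSE), 1)) obs <- sample(obs)
  parse_model(c("begin parameters", sample(pars), "end parameters",
                "begin molecule types", sample(type_lines), "end molecule types",
                "begin seed species", sample(seeds), "end seed species",
                "begin observables", obs, "end observables",
                "begin reaction rules", sample(rules), "end reaction rules"))
}
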