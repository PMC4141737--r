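## Rule-based model representation and a reader/writer for a BNGL subset.
##
## The dialect covers exactly what elementary rule-based signaling models
## need: parameters, molecule types with stateful components, fully
## specified seed species, pattern observables, and mass-action reaction
## rules whose transformation is one of bind / unbind / set_state.
## Compartments, functional rate laws and synthesis/degradation arrows are
## rejected loudly rather than skipped.

BLOCK_NAMES <- c("parameters", "molecule types", "seed species",
                 "observables", "reaction rules")

#' Parse a BNGL-subset model description
#'
#' Reads a rule-based kinetic model written in a subset of the BioNetGen
#' language (blocks \code{begin parameters} / \code{molecule types} /
#' \code{seed species} / \code{observables} / \code{reaction rules} ...
#' \code{end}).  Molecule components may declare state alphabets
#' (\code{y~U~P}); patterns may constrain states (\code{~U}) and bonds
#' (\code{!1} explicit, \code{!+} bound to anything, \code{!?} unconstrained;
#' a component written without a bond mark is required to be unbound, and an
#' omitted component is unconstrained).  Rules are irreversible mass-action
#' arrows \code{reactants -> products rate_symbol}; the transformation is
#' inferred by diffing the two sides and must be exactly one bond formation,
#' one bond deletion, or one component state change.  Unknown constructs
#' (compartments, functions, \code{<->}) raise an error with a line number.
#'
#' @param text Character scalar holding the model source, or a character
#'   vector of lines.
#' @return A validated object of class \code{model_spec}: a list with
#'   elements \code{molecule_types}, \code{parameters} (named numeric),
#'   \code{seed_species}, \code{rules} and \code{observables}.
#' @seealso [write_model()], [validate_model()], [read_model()]
#' @examples
#' m <- parse_model(c(
#'   "begin parameters", "k1 0.5", "end parameters",
#'   "begin molecule types", "A(y~U~P)", "end molecule types",
#'   "begin seed species", "A(y~U) 10", "end seed species",
#'   "begin observables", "Molecules A_P A(y~P)", "end observables",
#'   "begin reaction rules", "r1: A(y~U) -> A(y~P) k1", "end reaction rules"))
#' length(m$rules)
#' @export
parse_model <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  raw <- sub("#.*$", "", lines)
  raw <- trimws(raw)

  spec <- empty_model_spec()
  block <- NULL
  for (i in seq_along(raw)) {
    ln <- raw[[i]]
    if (!nzchar(ln)) next
    if (grepl("^begin\\s+", ln)) {
      bn <- trimws(sub("^begin\\s+", "", ln))
      if (!is.null(block))
        stop(sprintf("line %d: 'begin %s' inside open block '%s'", i, bn, block))
      if (!bn %in% BLOCK_NAMES)
        stop(sprintf("line %d: unknown block '%s' (supported: %s)",
                     i, bn, paste(BLOCK_NAMES, collapse = ", ")))
      block <- bn
      next
    }
    if (grepl("^end\\b", ln)) {
      bn <- trimws(sub("^end\\s*", "", ln))
      if (is.null(block))
        stop(sprintf("line %d: 'end' outside of any block", i))
      if (nzchar(bn) && bn != block)
        stop(sprintf("line %d: 'end %s' does not close block '%s'", i, bn, block))
      block <- NULL
      next
    }
    if (is.null(block))
      stop(sprintf("line %d: statement outside of any block: '%s'", i, ln))
    spec <- switch(block,
      "parameters"     = parse_parameter_line(spec, ln, i),
      "molecule types" = parse_moltype_line(spec, ln, i),
      "seed species"   = parse_seed_line(spec, ln, i),
      "observables"    = parse_observable_line(spec, ln, i),
      "reaction rules" = parse_rule_line(spec, ln, i))
  }
  if (!is.null(block))
    stop(sprintf("unterminated block '%s' at end of input", block))

  rep <- validate_model(spec)
  if (nrow(rep) > 0L)
    stop("invalid model:\n", paste0("  - ", rep$message, collapse = "\n"))
  spec
}

#' Read a BNGL-subset model from a file
#' @param path Path to a plain-text model file.
#' @return A validated \code{model_spec}, as from [parse_model()].
#' @export
read_model <- function(path) parse_model(readLines(path, warn = FALSE))

empty_model_spec <- function() {
  structure(list(molecule_types = list(), parameters = numeric(0),
                 seed_species = list(), rules = list(), observables = list()),
            class = "model_spec")
}

parse_parameter_line <- function(spec, ln, i) {
  tok <- strsplit(ln, "\\s+")[[1]]
  if (length(tok) != 2L)
    stop(sprintf("line %d: expected 'name value' in parameters block", i))
  val <- suppressWarnings(as.numeric(tok[2]))
  if (is.na(val))
    stop(sprintf("line %d: parameter value '%s' is not numeric", i, tok[2]))
  if (val < 0)
    stop(sprintf("line %d: parameter '%s' is negative", i, tok[1]))
  spec$parameters[[tok[1]]] <- val
  spec
}

parse_moltype_line <- function(spec, ln, i) {
  tok <- strsplit(ln, "\\s+")[[1]]
  def <- tok[1]
  loc <- NA_character_
  if (length(tok) == 2L) {
    if (!tok[2] %in% c("E", "M", "C"))
      stop(sprintf("line %d: location tag must be one of E, M, C", i))
    loc <- tok[2]
  } else if (length(tok) > 2L) {
    stop(sprintf("line %d: too many tokens in molecule type declaration", i))
  }
  m <- regmatches(def, regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\(([^)]*)\\))?$", def))[[1]]
  if (length(m) == 0L || !nzchar(m[2]))
    stop(sprintf("line %d: malformed molecule type '%s'", i, def))
  name <- m[2]
  comps <- list()
  body <- m[4]
  if (!is.na(body) && nzchar(body)) {
    for (cs in strsplit(body, ",", fixed = TRUE)[[1]]) {
      cs <- trimws(cs)
      parts <- strsplit(cs, "~", fixed = TRUE)[[1]]
      cname <- parts[1]
      if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", cname))
        stop(sprintf("line %d: malformed component '%s'", i, cs))
      states <- if (length(parts) > 1L) parts[-1] else character(0)
      if (cname %in% names(comps))
        stop(sprintf("line %d: duplicate component '%s' in '%s'", i, cname, name))
      comps[[cname]] <- list(name = cname, states = states)
    }
  }
  if (name %in% names(spec$molecule_types))
    stop(sprintf("line %d: duplicate molecule type '%s'", i, name))
  spec$molecule_types[[name]] <- list(name = name, components = comps,
                                      location = loc)
  spec
}

parse_seed_line <- function(spec, ln, i) {
  m <- regexec("^(\\S+)\\s+(\\S+)$", ln)
  g <- regmatches(ln, m)[[1]]
  if (length(g) == 0L)
    stop(sprintf("line %d: expected 'species count' in seed species block", i))
  cnt <- suppressWarnings(as.numeric(g[3]))
  if (is.na(cnt) || cnt != round(cnt))
    stop(sprintf("line %d: copy number '%s' is not an integer", i, g[3]))
  if (cnt < 0)
    stop(sprintf("line %d: negative copy number", i))
  pat <- parse_pattern(g[2], line = i)
  spec$seed_species[[length(spec$seed_species) + 1L]] <-
    list(pattern = pat, count = as.integer(cnt))
  spec
}

parse_observable_line <- function(spec, ln, i) {
  tok <- strsplit(ln, "\\s+")[[1]]
  if (length(tok) < 3L || tok[1] != "Molecules")
    stop(sprintf("line %d: expected 'Molecules name pattern ...'", i))
  pats <- lapply(tok[-(1:2)], parse_pattern, line = i)
  spec$observables[[length(spec$observables) + 1L]] <-
    list(name = tok[2], patterns = pats)
  spec
}

parse_rule_line <- function(spec, ln, i) {
  if (grepl("<->", ln, fixed = TRUE))
    stop(sprintf("line %d: reversible rules ('<->') are not supported; write two rules", i))
  name <- NA_character_
  body <- ln
  nm <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
  if (length(nm) > 0L) { name <- nm[2]; body <- nm[3] }
  sides <- strsplit(body, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop(sprintf("line %d: rule must contain exactly one '->'", i))
  rhs_tok <- strsplit(trimws(sides[2]), "\\s+")[[1]]
  if (length(rhs_tok) < 2L)
    stop(sprintf("line %d: rule is missing a rate constant symbol", i))
  rate <- rhs_tok[length(rhs_tok)]
  if (grepl("^[0-9.+-]", rate))
    stop(sprintf("line %d: rate must be a parameter symbol, got '%s'", i, rate))
  prod_txt <- paste(rhs_tok[-length(rhs_tok)], collapse = " ")
  reactants <- parse_side(trimws(sides[1]), i)
  products <- parse_side(prod_txt, i)
  act <- infer_transformation(reactants, products, i)
  if (is.na(name)) name <- sprintf("rule_%d", length(spec$rules) + 1L)
  spec$rules[[length(spec$rules) + 1L]] <-
    list(name = name, reactants = reactants, rate = rate,
         type = act$type, action = act$action)
  spec
}

parse_side <- function(txt, line) {
  if (txt == "0")
    stop(sprintf("line %d: synthesis/degradation ('0') is not supported", line))
  ## '+' separates reactant patterns; '!+' inside a pattern is a bond mark
  parts <- strsplit(gsub("\\s+", "", txt), "(?<!!)\\+", perl = TRUE)[[1]]
  lapply(parts, parse_pattern, line = line)
}

#' Parse a single site-graph pattern
#'
#' @param txt Pattern text, e.g. \code{"A(y~P,b!1).B(a!1)"}.
#' @param line Line number used in error messages.
#' @return An object of class \code{bngl_pattern}: a list of molecule atoms,
#'   each with \code{type} and a named \code{components} list whose entries
#'   carry \code{state} (\code{NA} = unconstrained) and \code{bond}
#'   (\code{"none"}, \code{"some"}, \code{"any"}, or an integer label).
#' @export
parse_pattern <- function(txt, line = NA_integer_) {
  where <- if (is.na(line)) "" else sprintf("line %d: ", line)
  txt <- gsub("\\s+", "", txt)
  mols <- strsplit(txt, ".", fixed = TRUE)[[1]]
  out <- lapply(mols, function(mt) {
    g <- regmatches(mt, regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\(([^)]*)\\))?$", mt))[[1]]
    if (length(g) == 0L || !nzchar(g[2]))
      stop(sprintf("%smalformed molecule pattern '%s'", where, mt))
    comps <- list()
    if (!is.na(g[4]) && nzchar(g[4])) {
      for (cs in strsplit(g[4], ",", fixed = TRUE)[[1]]) {
        cg <- regmatches(cs, regexec(
          "^([A-Za-z_][A-Za-z0-9_]*)(~([A-Za-z0-9_]+))?(!([0-9]+|\\+|\\?))?$", cs))[[1]]
        if (length(cg) == 0L)
          stop(sprintf("%smalformed component pattern '%s'", where, cs))
        state <- if (nzchar(cg[4])) cg[4] else NA_character_
        bond <- if (!nzchar(cg[6])) "none"
                else if (cg[6] == "+") "some"
                else if (cg[6] == "?") "any"
                else as.integer(cg[6])
        if (cg[2] %in% names(comps))
          stop(sprintf("%scomponent '%s' mentioned twice in '%s'", where, cg[2], mt))
        comps[[cg[2]]] <- list(state = state, bond = bond)
      }
    }
    list(type = g[2], components = comps)
  })
  pat <- structure(out, class = "bngl_pattern")
  labs <- pattern_bond_labels(pat)
  bad <- names(labs)[labs != 2L]
  if (length(bad) > 0L)
    stop(sprintf("%sbond label(s) %s must appear exactly twice in '%s'",
                 where, paste(bad, collapse = ", "), txt))
  pat
}

pattern_bond_labels <- function(pat) {
  labs <- integer(0)
  for (m in pat) for (cc in m$components)
    if (is.numeric(cc$bond) || is.integer(cc$bond)) {
      k <- as.character(cc$bond)
      labs[k] <- if (k %in% names(labs)) labs[[k]] + 1L else 1L
    }
  labs
}

## Bond pairs of one pattern as a list of ((mol, comp), (mol, comp)),
## with molecule indices offset by `offset` (for flattening rule sides).
pattern_bond_pairs <- function(pat, offset = 0L) {
  ends <- list()
  for (mi in seq_along(pat)) {
    cps <- pat[[mi]]$components
    for (cn in names(cps)) {
      b <- cps[[cn]]$bond
      if (is.numeric(b) || is.integer(b)) {
        k <- as.character(b)
        ends[[k]] <- c(ends[[k]], list(c(mol = mi + offset, comp = cn)))
      }
    }
  }
  lapply(ends, function(e) e[order(vapply(e, function(x) as.integer(x[["mol"]]), 1L))])
}

## Infer the single elementary transformation from reactant/product sides.
infer_transformation <- function(reactants, products, line) {
  rmol <- do.call(c, lapply(reactants, function(p) unclass(p)))
  pmol <- do.call(c, lapply(products, function(p) unclass(p)))
  if (length(rmol) != length(pmol))
    stop(sprintf("line %d: molecules are not conserved across '->' (synthesis/degradation is out of scope)", line))
  for (k in seq_along(rmol))
    if (rmol[[k]]$type != pmol[[k]]$type)
      stop(sprintf("line %d: molecule %d changes type across '->'; keep reactant order in products", line, k))

  state_changes <- list()
  for (k in seq_along(rmol)) {
    rc <- rmol[[k]]$components; pc <- pmol[[k]]$components
    for (cn in union(names(rc), names(pc))) {
      rs <- if (cn %in% names(rc)) rc[[cn]]$state else NA_character_
      ps <- if (cn %in% names(pc)) pc[[cn]]$state else NA_character_
      if (!identical(rs, ps)) {
        if (is.na(rs) || is.na(ps))
          stop(sprintf("line %d: component '%s' must carry an explicit state on both sides of a state-change rule", line, cn))
        state_changes[[length(state_changes) + 1L]] <-
          list(mol = k, comp = cn, from = rs, to = ps)
      }
    }
  }

  roff <- 0L; rpairs <- list()
  for (p in reactants) { rpairs <- c(rpairs, pattern_bond_pairs(p, roff)); roff <- roff + length(p) }
  poff <- 0L; ppairs <- list()
  for (p in products) { ppairs <- c(ppairs, pattern_bond_pairs(p, poff)); poff <- poff + length(p) }
  key <- function(pr) paste(pr[[1]]["mol"], pr[[1]]["comp"], pr[[2]]["mol"], pr[[2]]["comp"], sep = "|")
  rk <- vapply(rpairs, key, ""); pk <- vapply(ppairs, key, "")
  new_bonds <- ppairs[!pk %in% rk]
  del_bonds <- rpairs[!rk %in% pk]

  n_changes <- length(state_changes) + length(new_bonds) + length(del_bonds)
  if (n_changes != 1L)
    stop(sprintf("line %d: rule must perform exactly one elementary change (found %d)", line, n_changes))

  if (length(state_changes) == 1L) {
    list(type = "set_state", action = state_changes[[1]])
  } else if (length(new_bonds) == 1L) {
    b <- new_bonds[[1]]
    list(type = "bind", action = list(a = b[[1]], b = b[[2]]))
  } else {
    b <- del_bonds[[1]]
    list(type = "unbind", action = list(a = b[[1]], b = b[[2]]))
  }
}

## ---- writer -------------------------------------------------------------

format_pattern <- function(pat) {
  ## renumber bond labels in order of first appearance
  labs <- character(0)
  fmt_mol <- function(m) {
    cs <- vapply(names(m$components), function(cn) {
      cc <- m$components[[cn]]
      s <- if (!is.na(cc$state)) paste0("~", cc$state) else ""
      b <- cc$bond
      bs <- if (identical(b, "none")) ""
            else if (identical(b, "some")) "!+"
            else if (identical(b, "any")) "!?"
            else {
              k <- as.character(b)
              if (!k %in% labs) labs[[length(labs) + 1L]] <<- k
              paste0("!", match(k, labs))
            }
      paste0(cn, s, bs)
    }, "")
    paste0(m$type, "(", paste(cs, collapse = ","), ")")
  }
  paste(vapply(pat, fmt_mol, ""), collapse = ".")
}

## Reconstruct product side text from reactants + action.
format_rule <- function(rule) {
  prods <- rule$reactants
  flat_index <- function(k) {
    off <- 0L
    for (pi in seq_along(prods)) {
      if (k <= off + length(prods[[pi]])) return(c(pi, k - off))
      off <- off + length(prods[[pi]])
    }
    stop("internal: bad molecule index in rule action")
  }
  if (rule$type == "set_state") {
    a <- rule$action
    ix <- flat_index(a$mol)
    prods[[ix[1]]][[ix[2]]]$components[[a$comp]]$state <- a$to
    lhs <- paste(vapply(rule$reactants, format_pattern, ""), collapse = " + ")
    rhs <- paste(vapply(prods, format_pattern, ""), collapse = " + ")
  } else if (rule$type == "bind") {
    a <- rule$action
    ia <- flat_index(as.integer(a$a[["mol"]])); ib <- flat_index(as.integer(a$b[["mol"]]))
    ## join the two reactant patterns into one product complex
    lab <- 999L
    prods[[ia[1]]][[ia[2]]]$components[[a$a[["comp"]]]]$bond <- lab
    prods[[ib[1]]][[ib[2]]]$components[[a$b[["comp"]]]]$bond <- lab
    if (ia[1] == ib[1]) {
      joined <- prods
    } else {
      merged <- structure(c(unclass(prods[[ia[1]]]), unclass(prods[[ib[1]]])),
                          class = "bngl_pattern")
      joined <- prods[-c(ia[1], ib[1])]
      joined <- c(list(merged), joined)
    }
    lhs <- paste(vapply(rule$reactants, format_pattern, ""), collapse = " + ")
    rhs <- paste(vapply(joined, format_pattern, ""), collapse = " + ")
  } else { # unbind
    a <- rule$action
    ia <- flat_index(as.integer(a$a[["mol"]])); ib <- flat_index(as.integer(a$b[["mol"]]))
    stopifnot(ia[1] == ib[1])
    pat <- prods[[ia[1]]]
    pat[[ia[2]]]$components[[a$a[["comp"]]]]$bond <- "none"
    pat[[ib[2]]]$components[[a$b[["comp"]]]]$bond <- "none"
    split <- split_pattern_components(pat)
    lhs <- paste(vapply(rule$reactants, format_pattern, ""), collapse = " + ")
    rest <- prods[-ia[1]]
    rhs <- paste(vapply(c(split, rest), format_pattern, ""), collapse = " + ")
  }
  sprintf("%s: %s -> %s %s", rule$name, lhs, rhs, rule$rate)
}

## Split a pattern into connected components via its labelled bonds.
split_pattern_components <- function(pat) {
  n <- length(pat)
  if (n == 1L) return(list(pat))
  adj <- matrix(FALSE, n, n)
  pairs <- pattern_bond_pairs(pat)
  for (pr in pairs) {
    i <- as.integer(pr[[1]][["mol"]]); j <- as.integer(pr[[2]][["mol"]])
    adj[i, j] <- TRUE; adj[j, i] <- TRUE
  }
  comp <- rep(0L, n); cc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cc <- cc + 1L
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v] != 0L) next
      comp[v] <- cc
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  lapply(seq_len(cc), function(k)
    structure(unclass(pat)[comp == k], class = "bngl_pattern"))
}

#' Serialize a model to BNGL-subset text
#'
#' Emits canonical text: parameters, molecule types, observables and rules
#' sorted alphabetically by name, seed species by their formatted pattern,
#' and bond labels renumbered from 1 in order of appearance.  The output
#' re-parses to an equivalent model, which makes round-trips testable.
#'
#' @param spec A \code{model_spec}.
#' @param path Optional path; when given, the text is also written to disk.
#' @return The model text as a character vector of lines, invisibly when
#'   \code{path} is given.
#' @export
write_model <- function(spec, path = NULL) {
  out <- character(0)
  emit <- function(...) out <<- c(out, ...)

  emit("begin parameters")
  for (nm in sort(names(spec$parameters)))
    emit(sprintf("  %s %.15g", nm, spec$parameters[[nm]]))
  emit("end parameters", "", "begin molecule types")
  for (nm in sort(names(spec$molecule_types))) {
    mt <- spec$molecule_types[[nm]]
    cs <- vapply(mt$components, function(cc)
      paste0(cc$name, paste0(rep("~", length(cc$states)), cc$states, collapse = "")), "")
    loc <- if (!is.na(mt$location)) paste0(" ", mt$location) else ""
    emit(sprintf("  %s(%s)%s", nm, paste(cs, collapse = ","), loc))
  }
  emit("end molecule types", "", "begin seed species")
  seeds <- vapply(spec$seed_species, function(s) format_pattern(s$pattern), "")
  for (k in order(seeds))
    emit(sprintf("  %s %d", seeds[[k]], spec$seed_species[[k]]$count))
  emit("end seed species", "", "begin observables")
  onames <- vapply(spec$observables, `[[`, "", "name")
  for (k in order(onames)) {
    ob <- spec$observables[[k]]
    emit(sprintf("  Molecules %s %s", ob$name,
                 paste(vapply(ob$patterns, format_pattern, ""), collapse = " ")))
  }
  emit("end observables", "", "begin reaction rules")
  rnames <- vapply(spec$rules, `[[`, "", "name")
  for (k in order(rnames))
    emit(paste0("  ", format_rule(spec$rules[[k]])))
  emit("end reaction rules")

  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

## ---- validation ---------------------------------------------------------

#' Validate a model specification
#'
#' Collects, rather than raises, all structural violations: dangling
#' type/component/state/parameter references, duplicate names, malformed
#' bonds, under-specified seed species, non-integer or negative copy
#' numbers, and empty observables.
#'
#' @param spec A \code{model_spec} (possibly invalid).
#' @return A data frame with columns \code{kind}, \code{where},
#'   \code{message}; zero rows if and only if the model is valid.
#' @export
validate_model <- function(spec) {
  v <- list()
  bad <- function(kind, where, fmt, ...)
    v[[length(v) + 1L]] <<- data.frame(kind = kind, where = where,
                                       message = sprintf(fmt, ...))

  mt <- spec$molecule_types
  if (anyDuplicated(names(mt)))
    bad("duplicate", "molecule types", "duplicate molecule type name(s): %s",
        paste(unique(names(mt)[duplicated(names(mt))]), collapse = ", "))
  if (anyDuplicated(names(spec$parameters)))
    bad("duplicate", "parameters", "duplicate parameter name(s)")
  if (any(spec$parameters < 0))
    bad("value", "parameters", "negative parameter(s): %s",
        paste(names(spec$parameters)[spec$parameters < 0], collapse = ", "))

  check_pattern <- function(pat, where, need_full = FALSE) {
    for (m in pat) {
      if (!m$type %in% names(mt)) {
        bad("reference", where, "unknown molecule type '%s'", m$type)
        next
      }
      def <- mt[[m$type]]$components
      for (cn in names(m$components)) {
        if (!cn %in% names(def)) {
          bad("reference", where, "molecule '%s' has no component '%s'", m$type, cn)
          next
        }
        st <- m$components[[cn]]$state
        if (!is.na(st) && !st %in% def[[cn]]$states)
          bad("reference", where, "'%s' is not a state of %s.%s", st, m$type, cn)
        if (need_full && length(def[[cn]]$states) > 0L && is.na(st))
          bad("seed", where, "seed species must fix the state of %s.%s", m$type, cn)
      }
      if (need_full) {
        missing <- setdiff(names(def), names(m$components))
        if (length(missing) > 0L)
          bad("seed", where, "seed species must mention all components of %s (missing: %s)",
              m$type, paste(missing, collapse = ", "))
        for (cn in names(m$components)) {
          b <- m$components[[cn]]$bond
          if (identical(b, "some") || identical(b, "any"))
            bad("seed", where, "seed species bonds must be explicit in %s.%s", m$type, cn)
        }
      }
    }
  }

  for (k in seq_along(spec$seed_species)) {
    s <- spec$seed_species[[k]]
    check_pattern(s$pattern, sprintf("seed species %d", k), need_full = TRUE)
    if (s$count < 0) bad("value", sprintf("seed species %d", k), "negative copy number")
  }
  rn <- vapply(spec$rules, `[[`, "", "name")
  if (anyDuplicated(rn))
    bad("duplicate", "reaction rules", "duplicate rule name(s): %s",
        paste(unique(rn[duplicated(rn)]), collapse = ", "))
  for (r in spec$rules) {
    for (p in r$reactants) check_pattern(p, sprintf("rule %s", r$name))
    if (!r$rate %in% names(spec$parameters))
      bad("reference", sprintf("rule %s", r$name),
          "rate symbol '%s' is not a declared parameter", r$rate)
    if (r$type == "set_state") {
      a <- r$action
      flat <- do.call(c, lapply(r$reactants, unclass))
      if (a$mol <= length(flat)) {
        ty <- flat[[a$mol]]$type
        if (ty %in% names(mt)) {
          def <- mt[[ty]]$components
          if (a$comp %in% names(def) && !a$to %in% def[[a$comp]]$states)
            bad("reference", sprintf("rule %s", r$name),
                "target state '%s' not in alphabet of %s.%s", a$to, ty, a$comp)
        }
      }
    }
  }
  on <- vapply(spec$observables, `[[`, "", "name")
  if (anyDuplicated(on))
    bad("duplicate", "observables", "duplicate observable name(s): %s",
        paste(unique(on[duplicated(on)]), collapse = ", "))
  for (ob in spec$observables) {
    if (length(ob$patterns) == 0L)
      bad("observable", sprintf("observable %s", ob$name), "observable has no pattern")
    for (p in ob$patterns)
      check_pattern(p, sprintf("observable %s", ob$name))
  }

  if (length(v) == 0L)
    return(data.frame(kind = character(0), where = character(0),
                      message = character(0)))
  do.call(rbind, v)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %d molecule types, %d parameters, %d seed species, %d rules, %d observables\n",
              length(x$molecule_types), length(x$parameters),
              length(x$seed_species), length(x$rules), length(x$observables)))
  invisible(x)
}
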