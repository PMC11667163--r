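#' Parse an atom-mapped reaction network
#'
#' Reads the plain-text reaction grammar: one reaction per line,
#' `id: MET.comp (atoms) + ... -> ...` (or `<->` for reversible reactions),
#' with one lower-case letter per carbon. Atom letters must be unique within
#' each side and, for any reaction with species on both sides, the multiset
#' of letters must balance. Directive lines: `#symmetric`, `#dilution`,
#' `#ratio a b r` (constrains net flux a = r * net flux b), `#sink`; other
#' `#` lines are comments. Compartment defaults to `c` when omitted;
#' compartments `x`, `f` and `s` are network-boundary compartments.
#'
#' @param text Character scalar (whole document) or vector of lines.
#' @return Object of class `flux_network`.
#' @export
parse_network <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  reactions <- list()
  symmetric <- character()
  dilution <- character()
  sinks <- character()
  ratios <- data.frame(a = character(), b = character(), ratio = numeric(),
                       stringsAsFactors = FALSE)
  perr <- function(ln, msg) stop(sprintf("line %d: %s", ln, msg), call. = FALSE)

  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      parts <- strsplit(line, "[[:space:]]+")[[1]]
      key <- parts[1]
      if (key == "#symmetric") symmetric <- c(symmetric, species_key(parts[-1]))
      else if (key == "#dilution") dilution <- c(dilution, species_key(parts[-1]))
      else if (key == "#sink") sinks <- c(sinks, species_key(parts[-1]))
      else if (key == "#ratio") {
        if (length(parts) != 4L) perr(ln, "#ratio needs: #ratio flux_a flux_b value")
        ratios <- rbind(ratios, data.frame(a = parts[2], b = parts[3],
                                           ratio = as.numeric(parts[4]),
                                           stringsAsFactors = FALSE))
      }
      next
    }
    m <- regexec("^([A-Za-z0-9_]+):(.*)$", line)[[1]]
    if (m[1] == -1) perr(ln, "expected 'id: reaction'")
    id <- regmatches(line, list(m))[[1]][2]
    body <- regmatches(line, list(m))[[1]][3]
    reversible <- grepl("<->", body, fixed = TRUE)
    sides <- strsplit(body, "<->|->")[[1]]
    if (length(sides) != 2L) perr(ln, "expected one '->' or '<->'")
    parse_side <- function(s) {
      s <- trimws(s)
      if (!nzchar(s)) return(list())
      terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
      lapply(terms, function(tm) {
        tmx <- regexec("^([A-Za-z0-9_]+)(\\.([A-Za-z0-9]+))?[[:space:]]*\\(([a-z]+)\\)$", tm)[[1]]
        if (tmx[1] == -1) perr(ln, paste0("cannot parse term '", tm, "'"))
        g <- regmatches(tm, list(tmx))[[1]]
        comp <- if (nzchar(g[4])) g[4] else "c"
        list(met = g[2], comp = comp, atoms = g[5])
      })
    }
    reactants <- parse_side(sides[1])
    products <- parse_side(sides[2])
    if (id %in% vapply(reactions, `[[`, "", "id")) perr(ln, paste0("duplicate reaction id '", id, "'"))
    side_letters <- function(side) unlist(lapply(side, function(o) strsplit(o$atoms, "")[[1]]))
    rl <- side_letters(reactants); pl <- side_letters(products)
    if (anyDuplicated(rl)) perr(ln, "duplicate atom label on reactant side")
    if (anyDuplicated(pl)) perr(ln, "duplicate atom label on product side")
    if (length(reactants) && length(products) &&
        !identical(sort(rl), sort(pl))) {
      perr(ln, sprintf("unbalanced atom map in '%s' (reactants: %s; products: %s)",
                       id, paste(sort(rl), collapse = ""), paste(sort(pl), collapse = "")))
    }
    reactions[[length(reactions) + 1L]] <- list(
      id = id, reactants = reactants, products = products,
      reversible = reversible, line = ln)
  }
  net <- structure(list(reactions = reactions, symmetric = unique(symmetric),
                        dilution = unique(dilution), sinks = unique(sinks),
                        ratios = ratios,
                        boundary_compartments = c("x", "f", "s")),
                   class = "flux_network")
  # per-metabolite carbon-count consistency
  cc <- species_carbons(net)
  net <- classify_reactions(net)
  net
}

species_key <- function(x) {
  ifelse(grepl(".", x, fixed = TRUE), x, paste0(x, ".c"))
}

occ_key <- function(o) paste0(o$met, ".", o$comp)

#' @export
print.flux_network <- function(x, ...) {
  sp <- species_table(x)
  cat(sprintf("flux_network: %d reactions (%d reversible), %d species (%d balanced)\n",
              length(x$reactions),
              sum(vapply(x$reactions, `[[`, TRUE, "reversible")),
              nrow(sp), sum(sp$balanced)))
  if (nrow(x$ratios)) {
    cat("fixed ratios:", paste(sprintf("%s = %g * %s", x$ratios$a, x$ratios$ratio, x$ratios$b),
                               collapse = "; "), "\n")
  }
  if (length(x$symmetric)) cat("symmetric:", paste(x$symmetric, collapse = ", "), "\n")
  invisible(x)
}

# carbon count per species, validating consistency
species_carbons <- function(net) {
  cc <- new.env(parent = emptyenv())
  for (r in net$reactions) {
    for (o in c(r$reactants, r$products)) {
      k <- occ_key(o); n <- nchar(o$atoms)
      prev <- cc[[k]]
      if (!is.null(prev) && prev != n) {
        stop(sprintf("carbon-count mismatch for %s: %d vs %d (reaction %s)",
                     k, prev, n, r$id), call. = FALSE)
      }
      cc[[k]] <- n
    }
  }
  unlist(as.list(cc))
}

#' Species summary table
#'
#' @param net A `flux_network`.
#' @return Data frame: species, compartment, carbons, n_producing,
#'   n_consuming, balanced. A species is balanced (subject to steady-state
#'   mass balance) when it is produced and consumed by at least one reaction
#'   each, or lives in an internal compartment.
#' @export
species_table <- function(net) {
  cc <- species_carbons(net)
  keys <- names(cc)
  np <- nc <- stats::setNames(integer(length(keys)), keys)
  for (r in net$reactions) {
    for (o in r$reactants) nc[occ_key(o)] <- nc[occ_key(o)] + 1L
    for (o in r$products) np[occ_key(o)] <- np[occ_key(o)] + 1L
  }
  comp <- sub("^.*\\.", "", keys)
  internal <- !(comp %in% net$boundary_compartments)
  balanced <- (np > 0 & nc > 0) | internal
  data.frame(species = keys, compartment = comp, carbons = as.integer(cc[keys]),
             n_producing = as.integer(np), n_consuming = as.integer(nc),
             internal = internal, balanced = balanced,
             stringsAsFactors = FALSE, row.names = NULL)
}

classify_reactions <- function(net) {
  sp <- species_table(net)
  src <- sp$species[sp$n_producing == 0L]
  snk <- sp$species[sp$n_consuming == 0L]
  for (i in seq_along(net$reactions)) {
    r <- net$reactions[[i]]
    rk <- vapply(r$reactants, occ_key, "")
    pk <- vapply(r$products, occ_key, "")
    kind <- "internal"
    if (any(rk %in% net$dilution)) {
      kind <- if (all(rk %in% net$dilution)) "dilution" else "internal"
    }
    if (kind == "internal" && length(rk) && all(rk %in% setdiff(src, net$dilution))) kind <- "uptake"
    if (kind == "internal" && length(pk) && any(pk %in% net$sinks)) kind <- "biomass-sink"
    if (kind == "internal" && length(pk) && all(pk %in% snk)) kind <- "secretion"
    net$reactions[[i]]$kind <- kind
  }
  net
}

#' Serialize a network back to its text format
#'
#' @param net A `flux_network`.
#' @return Character scalar in the reaction grammar; `parse_network()` of the
#'   result reproduces the network.
#' @export
serialize_network <- function(net) {
  dir_line <- function(tag, v) if (length(v)) paste(tag, paste(v, collapse = " ")) else NULL
  side <- function(occs) paste(vapply(occs, function(o)
    sprintf("%s.%s (%s)", o$met, o$comp, o$atoms), ""), collapse = " + ")
  rx <- vapply(net$reactions, function(r) {
    sprintf("%s: %s %s %s", r$id, side(r$reactants),
            if (r$reversible) "<->" else "->", side(r$products))
  }, "")
  ratio_lines <- if (nrow(net$ratios)) {
    sprintf("#ratio %s %s %g", net$ratios$a, net$ratios$b, net$ratios$ratio)
  } else NULL
  paste(c(dir_line("#symmetric", net$symmetric),
          dir_line("#dilution", net$dilution),
          dir_line("#sink", net$sinks),
          ratio_lines, rx), collapse = "\n")
}

#' Stoichiometric matrix over balanced species
#'
#' @param net A `flux_network`.
#' @return Matrix (balanced species x reactions) of net stoichiometric
#'   coefficients; one column per reaction (net flux).
#' @export
stoichiometry <- function(net) {
  sp <- species_table(net)
  bal <- sp$species[sp$balanced]
  S <- matrix(0, length(bal), length(net$reactions),
              dimnames = list(bal, vapply(net$reactions, `[[`, "", "id")))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    for (o in r$reactants) {
      k <- occ_key(o)
      if (k %in% bal) S[k, j] <- S[k, j] - 1
    }
    for (o in r$products) {
      k <- occ_key(o)
      if (k %in% bal) S[k, j] <- S[k, j] + 1
    }
  }
  S
}

#' Validate a parsed network
#'
#' Checks atom balance, dead-end species, reachability of every balanced
#' species from a boundary substrate, CO2 reincorporation, and whether a
#' strictly positive feasible net-flux vector exists.
#'
#' @param net A `flux_network`.
#' @return List of class `network_validation` with elements `atom_balance`
#'   (character of failures), `dead_ends`, `unreachable`, `warnings`,
#'   `feasible` (logical), `ok`.
#' @export
validate_network <- function(net) {
  sp <- species_table(net)
  failures <- character()  # parse_network already rejects unbalanced maps
  dead <- sp$species[sp$internal & (sp$n_producing == 0L | sp$n_consuming == 0L)]
  warnings <- character()
  # labeled CO2 must not re-enter carboxylation reactions: every consumed CO2
  # species must be a declared dilution inflow, not a produced pool
  co2 <- sp$species[grepl("^CO2\\.", sp$species)]
  for (k in co2) {
    row <- sp[sp$species == k, ]
    if (row$n_consuming > 0 && !(k %in% net$dilution)) {
      warnings <- c(warnings, sprintf(
        "%s is consumed by carboxylation but is not a dilution inflow; labeled CO2 would reincorporate, contradicting the dilution assumption", k))
    }
  }
  reach <- reachable_species(net)
  unreachable <- setdiff(sp$species[sp$balanced], reach)
  feas <- tryCatch(!is.null(find_feasible_flux(net)), error = function(e) FALSE)
  structure(list(atom_balance = failures, dead_ends = dead,
                 unreachable = unreachable, warnings = warnings,
                 feasible = feas,
                 ok = !length(failures) && !length(dead) && feas),
            class = "network_validation")
}

#' @export
print.network_validation <- function(x, ...) {
  cat("network validation:", if (x$ok) "OK" else "PROBLEMS FOUND", "\n")
  if (length(x$atom_balance)) cat(" atom balance:", x$atom_balance, sep = "\n  ")
  if (length(x$dead_ends)) cat(" dead ends:", paste(x$dead_ends, collapse = ", "), "\n")
  if (length(x$unreachable)) cat(" unreachable:", paste(x$unreachable, collapse = ", "), "\n")
  for (w in x$warnings) cat(" warning:", w, "\n")
  cat(" positive feasible flux:", x$feasible, "\n")
  invisible(x)
}

# species reachable (carbon-wise) from boundary source species
reachable_species <- function(net) {
  sp <- species_table(net)
  reach <- sp$species[sp$n_producing == 0L]  # sources
  repeat {
    added <- FALSE
    for (r in net$reactions) {
      rk <- vapply(r$reactants, occ_key, "")
      pk <- vapply(r$products, occ_key, "")
      if (length(rk) && all(rk %in% reach)) {
        new <- setdiff(pk, reach)
        if (length(new)) { reach <- c(reach, new); added <- TRUE }
      }
      if (r$reversible && length(pk) && all(pk %in% reach)) {
        new <- setdiff(rk, reach)
        if (length(new)) { reach <- c(reach, new); added <- TRUE }
      }
    }
    if (!added) break
  }
  reach
}

#' Free-flux parameterization of the net-flux space
#'
#' Computes an orthonormal basis N of the null space of the stoichiometric
#' matrix augmented with the fixed-ratio constraint rows, so that any
#' assignment `net = N %*% w` satisfies steady-state mass balance and all
#' ratio constraints exactly.
#'
#' @param net A `flux_network`.
#' @return List of class `flux_basis`: `N` (reactions x d), `d`, `reactions`,
#'   `S` (the augmented constraint matrix).
#' @export
free_flux_basis <- function(net) {
  S <- stoichiometry(net)
  rid <- colnames(S)
  if (nrow(net$ratios)) {
    for (i in seq_len(nrow(net$ratios))) {
      row <- stats::setNames(numeric(length(rid)), rid)
      row[net$ratios$a[i]] <- 1
      row[net$ratios$b[i]] <- -net$ratios$ratio[i]
      S <- rbind(S, row)
    }
  }
  qt <- qr(t(S))
  rank <- qt$rank
  d <- ncol(S) - rank
  if (d == 0L) stop("network admits no nonzero balanced flux (trivial null space)")
  N <- qr.Q(qt, complete = TRUE)[, (rank + 1):ncol(S), drop = FALSE]
  rownames(N) <- rid
  structure(list(N = N, d = d, reactions = rid, S = S), class = "flux_basis")
}

#' Reconstruct a full net-flux vector from free coordinates
#'
#' @param basis A `flux_basis`.
#' @param w Numeric vector of length `basis$d`.
#' @return Named net-flux vector over all reactions.
#' @export
flux_from_free <- function(basis, w) {
  v <- drop(basis$N %*% w)
  names(v) <- basis$reactions
  v
}

# solve for free coordinates that give prescribed values on a pin set of
# reactions; pins must number exactly d and select an invertible block
pin_fluxes <- function(basis, pins) {
  stopifnot(length(pins) == basis$d)
  A <- basis$N[names(pins), , drop = FALSE]
  if (abs(det(A)) < 1e-12) stop("pin set does not determine the flux space")
  w <- solve(A, as.numeric(pins))
  flux_from_free(basis, w)
}

#' Find a strictly positive feasible net-flux vector
#'
#' Linear program: maximize the minimum flux margin t subject to mass balance,
#' ratio constraints, `net >= t` for irreversible reactions and an upper box
#' bound. Returns NULL when no strictly positive solution exists.
#'
#' @param net A `flux_network`.
#' @param box Upper bound on fluxes during the search.
#' @return Named net-flux vector, or NULL.
#' @export
find_feasible_flux <- function(net, box = 1000) {
  basis <- free_flux_basis(net)
  rid <- basis$reactions
  rev <- reversible_ids(net)
  irrev <- setdiff(rid, rev)
  nR <- length(rid)
  # variables: x = v + box (so x >= 0 allows reversible nets down to -box), t
  ii <- match(irrev, rid)
  A2 <- matrix(0, length(ii), nR + 1)
  A2[cbind(seq_along(ii), ii)] <- 1
  A2[, nR + 1] <- -1
  b2 <- rep(box, length(ii))          # v_i >= t
  A1 <- diag(nR + 1)                  # upper box
  b1 <- c(rep(2 * box, nR), box)
  A3 <- cbind(basis$S, 0)
  b3 <- drop(basis$S %*% rep(box, nR))
  # flip equality rows with negative rhs (simplex() requires b3 >= 0)
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, ]
  b3[neg] <- -b3[neg]
  sol <- tryCatch(
    boot::simplex(a = c(numeric(nR), 1), A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = TRUE),
    error = function(e) NULL)
  if (is.null(sol) || sol$solved != 1) return(NULL)
  t <- sol$soln[nR + 1]
  if (!is.finite(t) || t <= 1e-9) return(NULL)
  v <- sol$soln[seq_len(nR)] - box
  names(v) <- rid
  v
}

reversible_ids <- function(net) {
  vapply(Filter(function(r) r$reversible, net$reactions), `[[`, "", "id")
}

reaction_ids <- function(net) vapply(net$reactions, `[[`, "", "id")

#' The shipped reference adipocyte network
#'
#' Parses the atom-mapped core model distributed with the package:
#' glucose uptake, lumped glycolysis, an oxidative PPP branch fixed at 0.3%
#' of glucose uptake, lactate/alanine secretion, compartmentalized pyruvate
#' with PDH and PC, malic-enzyme pyruvate cycling, the full TCA cycle with
#' symmetric succinate and fumarate, the citrate shuttle to cytosolic
#' acetyl-CoA, glutamine/glutamate medium pools with simultaneous uptake and
#' secretion, BCKDH-gated leucine/valine/isoleucine oxidation, propionyl-CoA
#' anaplerosis, and fatty acid synthesis sinks for C16:0, C15:0 and C17:0.
#'
#' @return A `flux_network`.
#' @export
reference_adipocyte_network <- function() {
  path <- system.file("extdata", "networks", "adipocyte_core.txt",
                      package = "adipoflux", mustWork = TRUE)
  parse_network(readLines(path))
}

#' Measured fragments of the reference network
#'
#' The metabolite fragments whose corrected MIDs enter the flux fit:
#' pyruvate, the TCA intermediates, intracellular and extracellular
#' glutamine, glutamate, leucine, ketoisocaproate, valine, and the fatty
#' acids C15:0, C16:0 and C17:0.
#'
#' @return Data frame with columns `species` (MET.comp key) and `carbons`.
#' @export
reference_measured_fragments <- function() {
  data.frame(
    species = c("PYR.c", "CIT.m", "AKG.m", "SUC.m", "FUM.m", "MAL.m",
                "GLN.c", "GLN.x", "GLU.c", "LEU.c", "KIC.c", "VAL.c",
                "C150.s", "C160.s", "C170.s"),
    carbons = c(3L, 6L, 5L, 4L, 4L, 4L, 5L, 5L, 5L, 6L, 6L, 5L, 15L, 16L, 17L),
    stringsAsFactors = FALSE)
}
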