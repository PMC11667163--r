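#' Tracer specification
#'
#' @param substrate Species key of the labeled substrate (e.g. `"GLC.x"`).
#' @param positions Integer vector of 13C-labeled carbon positions.
#' @param purity Isotopic enrichment per labeled position (default 0.99).
#' @param fraction Fractional abundance of the tracer in the total substrate
#'   pool (1 = full replacement).
#' @param name Display name.
#' @return Object of class `tracer_spec`.
#' @export
tracer_spec <- function(substrate, positions, purity = 0.99, fraction = 1,
                        name = substrate) {
  stopifnot(purity >= 0, purity <= 1, fraction >= 0, fraction <= 1,
            all(positions >= 1))
  structure(list(substrate = species_key(substrate),
                 positions = as.integer(positions),
                 purity = purity, fraction = fraction, name = name),
            class = "tracer_spec")
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat(sprintf("tracer %s: %s labeled at C%s (purity %.3g, fraction %.3g)\n",
              x$name, x$substrate, paste(x$positions, collapse = ","),
              x$purity, x$fraction))
  invisible(x)
}

# MID of an input (boundary source) species EMU under a tracer
tracer_input_mid <- function(tracer, species, idx) {
  n <- length(idx)
  unlab <- c(1, numeric(n))
  if (is.null(tracer) || species != tracer$substrate) return(unlab)
  lab <- 1
  for (pos in idx) {
    p <- if (pos %in% tracer$positions) tracer$purity else 0
    lab <- convolve_dist(lab, c(1 - p, p))
  }
  tracer$fraction * lab + (1 - tracer$fraction) * unlab
}

emu_key <- function(species, idx) {
  sprintf("%s[%s]", species, paste(idx, collapse = ","))
}

# directed reactions with symmetric-reactant expansion: list of
# (flux_index, weight, reactants, products); flux indices follow
# directed_fluxes() layout (forward for all reactions, then backward for
# reversible ones)
directed_variants <- function(net) {
  rid <- reaction_ids(net)
  rev <- reversible_ids(net)
  out <- list()
  expand_sym <- function(occs) {
    variants <- list(list(w = 1, occs = occs))
    for (i in seq_along(occs)) {
      if (occ_key(occs[[i]]) %in% net$symmetric) {
        variants <- unlist(lapply(variants, function(v) {
          flipped <- v$occs
          flipped[[i]]$atoms <- paste(rev(strsplit(flipped[[i]]$atoms, "")[[1]]),
                                      collapse = "")
          list(list(w = v$w / 2, occs = v$occs),
               list(w = v$w / 2, occs = flipped))
        }), recursive = FALSE)
      }
    }
    variants
  }
  add <- function(fi, reactants, products) {
    for (v in expand_sym(reactants)) {
      out[[length(out) + 1L]] <<- list(fi = fi, w = v$w,
                                       reactants = v$occs, products = products)
    }
  }
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    add(j, r$reactants, r$products)
  }
  for (j in seq_along(rev)) {
    r <- net$reactions[[match(rev[j], rid)]]
    add(length(rid) + j, r$products, r$reactants)
  }
  out
}

parse_targets <- function(net, targets) {
  cc <- species_carbons(net)
  if (is.character(targets)) {
    targets <- lapply(targets, function(k) {
      m <- regexec("^([^\\[]+)(\\[([0-9,]+)\\])?$", k)[[1]]
      g <- regmatches(k, list(m))[[1]]
      sp <- species_key(g[2])
      idx <- if (nzchar(g[4])) as.integer(strsplit(g[4], ",")[[1]]) else seq_len(cc[[sp]])
      list(species = sp, idx = sort(idx))
    })
  }
  for (tg in targets) {
    if (is.null(cc[[tg$species]])) stop("unknown species: ", tg$species)
    if (any(tg$idx > cc[[tg$species]]) || !length(tg$idx)) {
      stop("atom indices out of range for ", tg$species)
    }
  }
  targets
}

#' Decompose a network into the EMU reaction system
#'
#' Traces the atoms of the target fragments backwards through the atom maps,
#' producing for every elementary metabolite unit (EMU) its formation terms
#' (same-size transfers, convolutions of smaller EMUs, and boundary substrate
#' inputs), organised into size-ordered linear systems. Reactions consuming a
#' rotationally symmetric metabolite are expanded into the two atom
#' orientations at half weight each.
#'
#' @param net A `flux_network`.
#' @param targets Character vector of species keys (`"MET.comp"` for the full
#'   carbon backbone, or `"MET.comp[1,2]"` for an atom subset).
#' @return Object of class `emu_system`.
#' @export
emu_decompose <- function(net, targets) {
  targets <- parse_targets(net, targets)
  sp <- species_table(net)
  state <- sp$species[sp$n_producing > 0L]
  dv <- directed_variants(net)
  # index directed variants by produced species
  prod_index <- list()
  for (vi in seq_along(dv)) {
    for (oi in seq_along(dv[[vi]]$products)) {
      k <- occ_key(dv[[vi]]$products[[oi]])
      prod_index[[k]] <- rbind(prod_index[[k]], c(vi, oi))
    }
  }
  emus <- list()     # key -> list(species, idx)
  terms <- list()    # key -> list of production terms
  queue <- list()
  push <- function(tg) queue[[length(queue) + 1L]] <<- tg
  for (tg in targets) {
    if (!(tg$species %in% state)) {
      stop("target ", tg$species, " is a boundary substrate, not simulated")
    }
    push(tg)
  }
  while (length(queue)) {
    E <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    key <- emu_key(E$species, E$idx)
    if (!is.null(emus[[key]])) next
    emus[[key]] <- E
    pidx <- prod_index[[E$species]]
    if (is.null(pidx)) stop("EMU ", key, " has no producing reaction")
    tlist <- list()
    for (ri in seq_len(nrow(pidx))) {
      v <- dv[[pidx[ri, 1]]]
      o <- v$products[[pidx[ri, 2]]]
      atoms <- strsplit(o$atoms, "")[[1]]
      sel <- atoms[E$idx]
      sources <- list()
      found <- 0L
      for (ro in v$reactants) {
        ra <- strsplit(ro$atoms, "")[[1]]
        pos <- which(ra %in% sel)
        if (length(pos)) {
          sk <- occ_key(ro)
          sources[[length(sources) + 1L]] <- list(
            species = sk, idx = pos, is_input = !(sk %in% state))
          found <- found + length(pos)
        }
      }
      if (found != length(sel)) {
        stop("atoms of ", key, " cannot be traced through reaction ",
             reaction_ids(net)[if (v$fi <= length(net$reactions)) v$fi else NA],
             " (boundary creation)")
      }
      for (s in sources) if (!s$is_input) push(list(species = s$species, idx = s$idx))
      tlist[[length(tlist) + 1L]] <- list(fi = v$fi, w = v$w, sources = sources)
    }
    terms[[key]] <- tlist
  }
  # assemble size levels; every EMU (state and boundary-input) gets an
  # integer slot so evaluation avoids string lookups
  sizes <- vapply(emus, function(e) length(e$idx), integer(1))
  ord_keys <- names(emus)[order(sizes, names(emus))]
  state_id <- stats::setNames(seq_along(ord_keys), ord_keys)
  n_state <- length(ord_keys)
  input_keys <- character(0)
  input_meta <- list()
  input_id <- function(species, idx) {
    key <- emu_key(species, idx)
    k <- match(key, input_keys)
    if (is.na(k)) {
      input_keys[length(input_keys) + 1L] <<- key
      input_meta[[length(input_meta) + 1L]] <<- list(species = species, idx = idx)
      k <- length(input_keys)
    }
    n_state + k
  }
  nflux <- length(net$reactions) + length(reversible_ids(net))
  levels <- list()
  for (s in sort(unique(sizes))) {
    keys <- sort(names(emus)[sizes == s])
    n <- length(keys)
    row_of <- stats::setNames(seq_len(n), keys)
    Ai <- Aj <- Af <- Ax <- numeric(0)
    Bi <- Bk <- Bf <- Bx <- numeric(0)
    conv <- list()        # per input column: integer ids of its part EMUs
    conv_desc <- character(0)
    for (key in keys) {
      i <- row_of[[key]]
      for (t in terms[[key]]) {
        Ai <- c(Ai, i); Aj <- c(Aj, i); Af <- c(Af, t$fi); Ax <- c(Ax, -t$w)
        if (length(t$sources) == 1L && !t$sources[[1]]$is_input) {
          skey <- emu_key(t$sources[[1]]$species, t$sources[[1]]$idx)
          Ai <- c(Ai, i); Aj <- c(Aj, row_of[[skey]])
          Af <- c(Af, t$fi); Ax <- c(Ax, t$w)
        } else {
          ids <- vapply(t$sources, function(x) {
            if (x$is_input) input_id(x$species, x$idx)
            else unname(state_id[emu_key(x$species, x$idx)])
          }, integer(1))
          ids <- sort(ids)
          desc <- paste(ids, collapse = "*")
          k <- match(desc, conv_desc)
          if (is.na(k)) {
            conv[[length(conv) + 1L]] <- ids
            conv_desc[length(conv_desc) + 1L] <- desc
            k <- length(conv)
          }
          Bi <- c(Bi, i); Bk <- c(Bk, k); Bf <- c(Bf, t$fi); Bx <- c(Bx, t$w)
        }
      }
    }
    MA <- as.matrix(Matrix::sparseMatrix(i = Ai + (Aj - 1) * n, j = Af, x = Ax,
                                         dims = c(n * n, nflux)))
    MB <- if (length(Bi)) {
      as.matrix(Matrix::sparseMatrix(i = Bi + (Bk - 1) * n, j = Bf, x = Bx,
                                     dims = c(n * length(conv), nflux)))
    } else NULL
    levels[[length(levels) + 1L]] <- list(
      size = s, keys = keys, n = n, MA = MA, MB = MB, conv = conv,
      rows = unname(state_id[keys]))
  }
  target_ids <- vapply(targets, function(tg) {
    unname(state_id[emu_key(tg$species, tg$idx)])
  }, integer(1))
  structure(list(net = net, levels = levels,
                 targets = targets, target_ids = target_ids,
                 inputs = input_meta, n_state = n_state,
                 rev_ids = reversible_ids(net),
                 n_emus = length(emus)),
            class = "emu_system")
}

#' @export
print.emu_system <- function(x, ...) {
  cat(sprintf("emu_system: %d EMUs in %d size levels (sizes %s)\n",
              x$n_emus, length(x$levels),
              paste(vapply(x$levels, `[[`, 0L, "size"), collapse = ", ")))
  invisible(x)
}

#' Evaluate an EMU system: simulate steady-state MIDs
#'
#' Solves the flux-weighted EMU balance equations size level by size level.
#'
#' @param sys An `emu_system` from [emu_decompose()].
#' @param fluxes A `flux_vector`.
#' @param tracer A `tracer_spec`, or NULL for fully unlabeled substrates.
#' @param singular `"error"` (default) reports a singular balance system
#'   (zero-flux trapped cycle) as an error; `"ridge"` regularizes the
#'   diagonal and continues, which keeps the objective smooth during
#'   optimization over near-degenerate flux vectors.
#' @return Named list of MID vectors, one per target.
#' @export
emu_evaluate <- function(sys, fluxes, tracer = NULL,
                         singular = c("error", "ridge")) {
  singular <- match.arg(singular)
  vdir <- directed_fluxes(fluxes, sys$rev_ids)
  input_mids <- lapply(sys$inputs, function(p) {
    tracer_input_mid(tracer, p$species, p$idx)
  })
  out <- tryCatch(
    emu_eval_core(sys$levels, vdir, input_mids, sys$n_state, sys$target_ids,
                  singular == "ridge"),
    error = function(e) {
      msg <- conditionMessage(e)
      sz <- regmatches(msg, regexpr("[0-9]+$", msg))
      keys <- ""
      if (length(sz)) {
        lev <- Filter(function(l) l$size == as.integer(sz), sys$levels)
        if (length(lev)) keys <- paste0(" (zero-flux trapped cycle among: ",
                                        paste(lev[[1]]$keys, collapse = ", "), ")")
      }
      stop(msg, keys, call. = FALSE)
    })
  names(out) <- vapply(sys$targets, function(tg) emu_key(tg$species, tg$idx), "")
  out
}

#' Simulate steady-state MIDs for a flux vector and tracer
#'
#' Convenience wrapper: decomposes the network for the requested targets and
#' evaluates the EMU balance system. For repeated evaluation (fitting), build
#' the system once with [emu_decompose()] and call [emu_evaluate()].
#'
#' @inheritParams emu_decompose
#' @inheritParams emu_evaluate
#' @return Named list of MID vectors.
#' @export
simulate_mids <- function(net, fluxes, tracer, targets) {
  sys <- emu_decompose(net, targets)
  emu_evaluate(sys, fluxes, tracer)
}
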