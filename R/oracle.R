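#' Brute-force positional isotopomer simulation
#'
#' Verification oracle for [simulate_mids()]: solves the full positional
#' isotopomer balance of every network species by damped Gauss-Seidel fixed
#' point (condensation reactions make the balance bilinear), then
#' marginalizes the joint distributions to MIDs. Deliberately independent of
#' the EMU machinery: it enumerates all 2^n labeling states per species and
#' handles symmetric metabolites by averaging the two atom orientations of
#' the consumed distribution. Only usable on small networks.
#'
#' @inheritParams simulate_mids
#' @param tol Fixed-point convergence tolerance (max abs change).
#' @param max_iter Iteration cap.
#' @param max_states Guard on the total number of positional isotopomers.
#' @return Named list of MID vectors, one per target.
#' @export
brute_force_isotopomer_sim <- function(net, fluxes, tracer, targets,
                                       tol = 1e-13, max_iter = 20000,
                                       max_states = 2^16) {
  targets <- parse_targets(net, targets)
  sp <- species_table(net)
  cc <- stats::setNames(sp$carbons, sp$species)
  state <- sp$species[sp$n_producing > 0L]
  inputs <- setdiff(sp$species, state)
  if (sum(2^cc[state]) > max_states) {
    stop("network too large for brute-force isotopomer enumeration")
  }
  rid <- reaction_ids(net)
  rev <- reversible_ids(net)
  vdir <- directed_fluxes(fluxes, rev)

  # directed reactions without symmetric expansion; orientation averaging is
  # applied to the consumed distribution instead
  dirs <- list()
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    dirs[[length(dirs) + 1L]] <- list(fi = j, from = r$reactants, to = r$products)
    if (r$reversible) {
      dirs[[length(dirs) + 1L]] <- list(fi = length(rid) + match(r$id, rev),
                                        from = r$products, to = r$reactants)
    }
  }

  bit_at <- function(s, pos) bitwAnd(bitwShiftR(s, pos - 1L), 1L)
  reverse_states <- function(n) {
    # index map for reversing the atom order of an n-carbon species
    vapply(0:(2^n - 1L), function(s) {
      sum(vapply(seq_len(n), function(p) bit_at(s, p) * 2^(n - p), 0))
    }, 0) + 1L
  }

  dist <- list()
  for (k in state) dist[[k]] <- c(1, numeric(2^cc[[k]] - 1L))
  for (k in inputs) {
    n <- cc[[k]]
    d <- numeric(2^n)
    if (!is.null(tracer) && k == tracer$substrate) {
      p <- ifelse(seq_len(n) %in% tracer$positions, tracer$purity, 0)
      lab <- vapply(0:(2^n - 1L), function(s) {
        prod(ifelse(vapply(seq_len(n), bit_at, 0L, s = s) == 1L, p, 1 - p))
      }, 0)
      d <- tracer$fraction * lab
      d[1] <- d[1] + (1 - tracer$fraction)
    } else {
      d[1] <- 1
    }
    dist[[k]] <- d
  }

  symrev <- lapply(stats::setNames(nm = intersect(net$symmetric, names(cc))),
                   function(k) reverse_states(cc[[k]]))
  get_dist <- function(k) {
    d <- dist[[k]]
    if (k %in% net$symmetric) (d + d[symrev[[k]]]) / 2 else d
  }

  # precompute per (directed reaction, product occurrence): for each reactant
  # occurrence, its marginal positions and product-bit offsets
  plans <- list()
  for (di in seq_along(dirs)) {
    dr <- dirs[[di]]
    for (oi in seq_along(dr$to)) {
      o <- dr$to[[oi]]
      pk <- occ_key(o)
      if (!(pk %in% state)) next
      patoms <- strsplit(o$atoms, "")[[1]]
      srcs <- list()
      for (ro in dr$from) {
        ra <- strsplit(ro$atoms, "")[[1]]
        rpos <- which(ra %in% patoms)
        if (!length(rpos)) next
        ppos <- match(ra[rpos], patoms)
        k <- 2^length(rpos)
        # marginalization map: reactant state -> sub-state over rpos
        sub <- vapply(0:(2^length(ra) - 1L), function(s) {
          sum(vapply(seq_along(rpos), function(j) bit_at(s, rpos[j]) * 2^(j - 1), 0))
        }, 0)
        off <- vapply(0:(k - 1L), function(sv) {
          sum(vapply(seq_along(ppos), function(j) bit_at(sv, j) * 2^(ppos[j] - 1), 0))
        }, 0)
        srcs[[length(srcs) + 1L]] <- list(key = occ_key(ro), sub = sub, off = off)
      }
      plans[[length(plans) + 1L]] <- list(fi = dr$fi, product = pk,
                                          nstates = 2^cc[[pk]], srcs = srcs)
    }
  }
  plan_by_product <- split(seq_along(plans), vapply(plans, `[[`, "", "product"))

  contrib <- function(plan) {
    acc <- c(1, numeric(plan$nstates - 1L))
    for (s in plan$srcs) {
      d <- get_dist(s$key)
      msub <- as.numeric(rowsum(d, s$sub))
      acc_new <- numeric(plan$nstates)
      nz <- which(acc != 0)
      for (sv in seq_along(msub)) {
        if (msub[sv] == 0) next
        acc_new[nz + s$off[sv]] <- acc_new[nz + s$off[sv]] + acc[nz] * msub[sv]
      }
      acc <- acc_new
    }
    acc
  }

  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (k in state) {
      idxs <- plan_by_product[[k]]
      if (is.null(idxs)) next
      total <- 0
      acc <- numeric(2^cc[[k]])
      for (pi in idxs) {
        v <- vdir[plans[[pi]]$fi]
        acc <- acc + v * contrib(plans[[pi]])
        total <- total + v
      }
      newd <- acc / total
      delta <- max(delta, max(abs(newd - dist[[k]])))
      dist[[k]] <- newd
    }
    if (delta < tol) break
  }
  if (delta >= tol) warning("isotopomer fixed point did not fully converge (delta = ",
                            signif(delta, 3), ")")

  out <- lapply(targets, function(tg) {
    d <- dist[[tg$species]]
    n <- cc[[tg$species]]
    wt <- vapply(0:(2^n - 1L), function(s) {
      sum(vapply(tg$idx, bit_at, 0L, s = s))
    }, 0)
    as.numeric(rowsum(d, wt))
  })
  names(out) <- vapply(targets, function(tg) emu_key(tg$species, tg$idx), "")
  out
}
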