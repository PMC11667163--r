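#' Tracer experiment: measured MIDs and exchange rates
#'
#' Bundles one labeling experiment for the joint flux fit: the tracer, the
#' corrected MIDs of the measured fragments (replicates as rows), and the
#' measured extracellular rates expressed as linear combinations of network
#' net fluxes.
#'
#' @param tracer A [tracer_spec].
#' @param mids Named list (names = species keys); each element a list with
#'   `values` (matrix, replicates x mass channels) and `sd` (scalar or
#'   vector per channel).
#' @param rates List of rate measurements: each a list with `name`, `coef`
#'   (named numeric over reaction ids, e.g. `c(v_gln_up = 1, v_gln_sec = -1)`),
#'   `value` and `sd`.
#' @return Object of class `tracer_experiment`.
#' @export
tracer_experiment <- function(tracer, mids, rates = list()) {
  stopifnot(inherits(tracer, "tracer_spec"))
  for (nm in names(mids)) {
    m <- mids[[nm]]
    if (!is.matrix(m$values)) mids[[nm]]$values <- matrix(m$values, nrow = 1)
    if (any(m$sd <= 0)) stop("measurement SDs must be positive (", nm, ")")
  }
  for (r in rates) if (r$sd <= 0) stop("rate SDs must be positive (", r$name, ")")
  structure(list(tracer = tracer, mids = mids, rates = rates),
            class = "tracer_experiment")
}

# number of independent measurements: mass channels above M0 per fragment
# per replicate, plus rate measurements
count_measurements <- function(experiments) {
  n <- 0L
  for (e in experiments) {
    for (m in e$mids) n <- n + nrow(m$values) * (ncol(m$values) - 1L)
    n <- n + length(e$rates)
  }
  n
}

# shared machinery for the SSR objective over the free-flux parameterization
make_mfa_objective <- function(net, experiments, basis = free_flux_basis(net),
                               penalty = 30) {
  cc <- species_carbons(net)
  frag_species <- unique(unlist(lapply(experiments, function(e) names(e$mids))))
  sys <- emu_decompose(net, frag_species)
  key_of <- stats::setNames(
    vapply(frag_species, function(s) emu_key(s, seq_len(cc[[s]])), ""),
    frag_species)
  rid <- basis$reactions
  rev <- reversible_ids(net)
  irrev_idx <- which(!(rid %in% rev))
  d <- basis$d
  n_ex <- length(rev)
  rate_coef <- lapply(experiments, function(e) lapply(e$rates, function(r) {
    list(idx = match(names(r$coef), rid), coef = as.numeric(r$coef),
         value = r$value, sd = r$sd)
  }))
  theta_to_flux <- function(theta) {
    w <- theta[seq_len(d)]
    b <- theta[d + seq_len(n_ex)]
    vnet <- drop(basis$N %*% w)
    names(vnet) <- rid
    ex <- b / (1 - b)
    names(ex) <- rev
    structure(list(net = vnet, exchange = ex), class = "flux_vector")
  }
  # per-experiment precomputations: boundary-input MIDs depend only on the
  # tracer, and measured values are stored transposed for residual assembly
  target_keys <- vapply(sys$targets, function(tg) emu_key(tg$species, tg$idx), "")
  exp_pre <- lapply(experiments, function(e) {
    list(input_mids = lapply(sys$inputs, function(p) {
           tracer_input_mid(e$tracer, p$species, p$idx)
         }),
         frag_idx = match(key_of[names(e$mids)], target_keys),
         tvals = lapply(e$mids, function(m) t(m$values)),
         sds = lapply(e$mids, `[[`, "sd"))
  })
  resid_meas <- function(fl) {
    vdir <- directed_fluxes(fl, sys$rev_ids)
    out <- vector("list", length(experiments) * 8L)
    j <- 0L
    for (ei in seq_along(experiments)) {
      pre <- exp_pre[[ei]]
      sim <- emu_eval_core(sys$levels, vdir, pre$input_mids, sys$n_state,
                           sys$target_ids, TRUE)
      for (fi in seq_along(pre$frag_idx)) {
        j <- j + 1L
        out[[j]] <- as.numeric((pre$tvals[[fi]] - sim[[pre$frag_idx[fi]]]) /
                                 pre$sds[[fi]])
      }
      for (rt in rate_coef[[ei]]) {
        j <- j + 1L
        out[[j]] <- (sum(rt$coef * fl$net[rt$idx]) - rt$value) / rt$sd
      }
    }
    unlist(out[seq_len(j)], use.names = FALSE)
  }
  resid_full <- function(theta) {
    fl <- theta_to_flux(theta)
    if (any(!is.finite(fl$net))) return(rep(1e6, n_resid))
    r <- tryCatch(resid_meas(fl), error = function(e) NULL)
    if (is.null(r)) {
      # simulation failure: return large residuals that still grow with the
      # infeasibility so the optimizer has a direction back
      viol <- sum(pmax(0, -fl$net[irrev_idx]))
      return(rep(1e3 * (1 + viol / max(1, max(abs(fl$net)))), n_resid))
    }
    c(r, penalty * pmax(0, -fl$net[irrev_idx]))
  }
  n_resid <- count_measurements(experiments) +
    sum(vapply(experiments, function(e)
      sum(vapply(e$mids, function(m) nrow(m$values), 0L)), 0L)) +
    length(irrev_idx)
  flux_to_theta <- function(fl) {
    ex <- fl$exchange[rev]
    c(drop(crossprod(basis$N, fl$net[rid])), ex / (1 + ex))
  }
  list(net = net, sys = sys, basis = basis, d = d, n_ex = n_ex, rev = rev,
       rid = rid, irrev_idx = irrev_idx,
       theta_to_flux = theta_to_flux, flux_to_theta = flux_to_theta,
       resid_meas = resid_meas, resid_full = resid_full,
       n_meas = count_measurements(experiments))
}

#' Variance-weighted sum of squared residuals
#'
#' SSR between simulated and measured MIDs plus extracellular rates, each
#' residual scaled by its measurement SD.
#'
#' @param net A `flux_network`.
#' @param fluxes A `flux_vector`.
#' @param experiments List of [tracer_experiment]s.
#' @param system Optional pre-built `emu_system` covering the measured
#'   fragments (avoids re-decomposing the network on repeated calls with
#'   the same measurement layout).
#' @return Scalar SSR.
#' @export
ssr <- function(net, fluxes, experiments, system = NULL) {
  if (is.null(system)) {
    obj <- make_mfa_objective(net, experiments)
    return(sum(obj$resid_meas(fluxes)^2))
  }
  cc <- species_carbons(net)
  total <- 0
  for (e in experiments) {
    sim <- emu_evaluate(system, fluxes, e$tracer)
    for (nm in names(e$mids)) {
      m <- e$mids[[nm]]
      smid <- sim[[emu_key(nm, seq_len(cc[[nm]]))]]
      total <- total + sum((sweep(m$values, 2, smid) / m$sd)^2)
    }
    for (r in e$rates) {
      pred <- sum(r$coef * fluxes$net[names(r$coef)])
      total <- total + ((pred - r$value) / r$sd)^2
    }
  }
  total
}

# hit-and-run sampling of a random feasible net-flux vector
sample_feasible_net <- function(basis, irrev_idx, v0, steps = 25, box = 5000) {
  v <- v0
  N <- basis$N
  for (s in seq_len(steps)) {
    dir <- drop(N %*% stats::rnorm(ncol(N)))
    lo <- -Inf; hi <- Inf
    for (i in irrev_idx) {
      if (abs(dir[i]) < 1e-12) next
      bound <- -v[i] / dir[i]
      if (dir[i] > 0) lo <- max(lo, bound) else hi <- min(hi, bound)
    }
    act <- which(abs(dir) > 1e-12)
    bb <- c((box - v[act]) / dir[act], (-box - v[act]) / dir[act])
    hi <- min(hi, suppressWarnings(min(bb[bb > 0])))
    lo <- max(lo, suppressWarnings(max(bb[bb < 0])))
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo) next
    span <- hi - lo
    t <- stats::runif(1, lo + 0.05 * span, hi - 0.05 * span)
    v <- v + t * dir
  }
  v
}

#' Estimate fluxes by joint nonlinear least squares
#'
#' Minimizes the variance-weighted SSR between simulated and measured MIDs
#' and rates over all tracer experiments simultaneously, using bounded
#' Levenberg-Marquardt from `n_restarts` random feasible starting points and
#' keeping the best solution. Net fluxes are parameterized in the null space
#' of the stoichiometric and ratio constraints (always exactly balanced);
#' exchanges are optimized through the bounded transform x/(1+x).
#'
#' @param net A `flux_network`.
#' @param experiments List of [tracer_experiment]s.
#' @param n_restarts Number of random restarts (default 20).
#' @param seed RNG seed recorded in the result.
#' @param alpha Significance level of the chi-squared goodness-of-fit test.
#' @param maxiter Levenberg-Marquardt iteration cap per restart.
#' @param start Optional `flux_vector` used as one additional start.
#' @param n_hops Basin-hopping polish rounds after the restarts: seeded
#'   perturbations of the incumbent best solution, re-optimized and kept
#'   when they improve the SSR (default 8; 0 disables).
#' @return Object of class `mfa_fit`: `fluxes` (best [flux_vector]), `ssr`,
#'   `dof`, `chi2_interval`, `accepted`, `restarts`, `restart_ssr`, `seed`.
#' @export
fit_fluxes <- function(net, experiments, n_restarts = 20, seed = NULL,
                       alpha = 0.01, maxiter = 60, start = NULL,
                       n_hops = 8) {
  if (!is.null(seed)) set.seed(seed)
  obj <- make_mfa_objective(net, experiments)
  v0 <- find_feasible_flux(net)
  if (is.null(v0)) stop("network admits no strictly positive feasible flux")
  lower <- c(rep(-Inf, obj$d), rep(1e-6, obj$n_ex))
  upper <- c(rep(Inf, obj$d), rep(0.999, obj$n_ex))
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-10, ptol = 1e-10)
  # random starts: hit-and-run sample of a feasible net-flux vector, then a
  # linear least-squares snap onto the measured rates (rates are linear in
  # the free coordinates, so this costs one small solve and leaves all
  # rate-orthogonal directions random); exchanges are log-uniform
  rate_rows <- list()
  rate_vals <- numeric(0)
  for (e in experiments) for (r in e$rates) {
    row <- numeric(length(obj$rid))
    row[match(names(r$coef), obj$rid)] <- as.numeric(r$coef)
    rate_rows[[length(rate_rows) + 1L]] <- (row %*% obj$basis$N) / r$sd
    rate_vals <- c(rate_vals, r$value / r$sd)
  }
  R <- do.call(rbind, rate_rows)
  Rpinv <- if (length(rate_rows)) {
    sv <- svd(R)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  } else NULL
  snap <- function(w) {
    if (is.null(Rpinv)) return(w)
    w + drop(Rpinv %*% (rate_vals - drop(R %*% w)))
  }
  w0 <- drop(crossprod(obj$basis$N, v0))
  starts <- lapply(seq_len(n_restarts), function(i) {
    vi <- sample_feasible_net(obj$basis, obj$irrev_idx, v0)
    w <- snap(drop(crossprod(obj$basis$N, vi)))
    # blend back toward the interior point until irreversible fluxes are
    # strictly positive (the snap can overshoot the feasible cone)
    lam <- 1
    repeat {
      vw <- drop(obj$basis$N %*% (lam * w + (1 - lam) * w0))
      if (all(vw[obj$irrev_idx] > 0.02 * abs(v0[obj$irrev_idx])) || lam < 0.05) break
      lam <- lam * 0.7
    }
    ex <- 10^stats::runif(obj$n_ex, -1, 3)  # log-uniform exchanges in [0.1, 1000]
    # the frozen first stage starts below full scrambling, where the
    # objective still has exchange sensitivity
    c(lam * w + (1 - lam) * w0, pmin(ex / (1 + ex), 0.95))
  })
  run_lm <- function(par, fn, lo, up, iters) {
    f <- tryCatch(
      suppressWarnings(utils::capture.output(out <- minpack.lm::nls.lm(
        par = par, lower = lo, upper = up, fn = fn,
        control = minpack.lm::nls.lm.control(maxiter = iters,
                                             ftol = 1e-10, ptol = 1e-10)))),
      error = function(e) NULL)
    if (is.null(f)) NULL else out
  }
  # two-stage local search: net fluxes first with exchanges frozen (the
  # full-scrambling plateau at large exchange is a strong local attractor),
  # then everything free
  optimize_from <- function(theta0) {
    wbound <- 1e6
    w1 <- run_lm(theta0[seq_len(obj$d)],
                 function(w) obj$resid_full(c(w, theta0[obj$d + seq_len(obj$n_ex)])),
                 rep(-wbound, obj$d), rep(wbound, obj$d), iters = 40L)
    th <- if (is.null(w1) || any(!is.finite(w1$par))) theta0
          else c(w1$par, theta0[obj$d + seq_len(obj$n_ex)])
    f <- run_lm(th, obj$resid_full, lower, upper, iters = maxiter)
    if (is.null(f) || any(!is.finite(f$par))) NULL else f$par
  }
  if (!is.null(start)) starts <- c(list(obj$flux_to_theta(start)), starts)
  best <- NULL
  restart_ssr <- rep(Inf, length(starts))
  safe_ssr <- function(theta) {
    tryCatch(sum(obj$resid_meas(obj$theta_to_flux(theta))^2),
             error = function(e) Inf)
  }
  for (i in seq_along(starts)) {
    theta <- optimize_from(starts[[i]])
    if (is.null(theta)) next
    s <- safe_ssr(theta)
    restart_ssr[i] <- s
    if (is.finite(s) && (is.null(best) || s < best$ssr)) {
      best <- list(theta = theta, ssr = s)
    }
  }
  if (is.null(best)) stop("no restart converged; per-restart SSRs: ",
                          paste(signif(restart_ssr, 3), collapse = ", "))
  # basin-hopping polish: seeded perturbations of the incumbent best,
  # re-optimized with the same two-stage search; escapes the shallow local
  # minima that persist when some tracers carry little label information
  if (n_hops > 0) {
    scale_w <- max(abs(best$theta[seq_len(obj$d)]))
    for (hop in seq_len(n_hops)) {
      th <- best$theta
      # alternate small and large perturbations so a poor incumbent can
      # still be escaped
      hop_sd <- if (hop %% 3 == 0) 0.30 else 0.10
      w <- th[seq_len(obj$d)] + stats::rnorm(obj$d, 0, hop_sd * scale_w)
      b0 <- pmin(pmax(th[obj$d + seq_len(obj$n_ex)], 0.01), 0.99)
      b <- pmin(pmax(stats::plogis(stats::qlogis(b0) +
                                     stats::rnorm(obj$n_ex, 0, 1.5)),
                     0.05), 0.95)
      theta <- optimize_from(c(w, b))
      if (is.null(theta)) next
      s <- safe_ssr(theta)
      if (s < best$ssr) best <- list(theta = theta, ssr = s)
    }
  }
  dof <- obj$n_meas - (obj$d + obj$n_ex)
  gof <- chi2_goodness_of_fit(best$ssr, dof, alpha = alpha)
  structure(list(fluxes = obj$theta_to_flux(best$theta), theta = best$theta,
                 ssr = best$ssr, dof = dof, n_meas = obj$n_meas,
                 chi2_interval = gof$interval, accepted = gof$accepted,
                 alpha = alpha, restarts = length(starts),
                 restart_ssr = restart_ssr, seed = seed, objective = obj),
            class = "mfa_fit")
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat(sprintf("mfa_fit: SSR = %.3f on %d dof (accept interval [%.2f, %.2f] at alpha = %g): %s\n",
              x$ssr, x$dof, x$chi2_interval[1], x$chi2_interval[2], x$alpha,
              if (x$accepted) "ACCEPTED" else "REJECTED"))
  cat(sprintf("best of %d restarts (SSR range %.3f .. %.3f)\n",
              x$restarts, min(x$restart_ssr), suppressWarnings(max(x$restart_ssr[is.finite(x$restart_ssr)]))))
  print(utils::head(format_flux_table(x$fluxes), 12), row.names = FALSE)
  invisible(x)
}

#' Chi-squared goodness-of-fit test
#'
#' Two-sided acceptance interval for the SSR of a weighted least-squares
#' fit: `[qchisq(alpha/2, dof), qchisq(1 - alpha/2, dof)]`.
#'
#' @param fit An `mfa_fit`, or a numeric SSR.
#' @param dof Degrees of freedom (taken from the fit when omitted).
#' @param alpha Significance level (default 0.01).
#' @return List: `ssr`, `dof`, `interval`, `accepted`.
#' @export
chi2_goodness_of_fit <- function(fit, dof = NULL, alpha = 0.01) {
  if (inherits(fit, "mfa_fit")) {
    s <- fit$ssr
    if (is.null(dof)) dof <- fit$dof
  } else s <- fit
  if (is.null(dof) || dof < 1) stop("dof must be >= 1 (over-parameterized model)")
  interval <- c(stats::qchisq(alpha / 2, dof), stats::qchisq(1 - alpha / 2, dof))
  list(ssr = s, dof = dof, interval = interval,
       accepted = s >= interval[1] && s <= interval[2])
}

# stateful profiler for one reaction: returns a function(value, maxiter)
# giving the re-optimized SSR with that reaction's net flux pinned, warm
# starting from the previous profile point (continuation); `theta0` sets the
# initial state (defaults to the fit's optimum)
make_profiler <- function(fit, reaction, theta0 = fit$theta) {
  obj <- fit$objective
  a <- obj$basis$N[reaction, ]
  qa <- qr(matrix(a))
  Z <- qr.Q(qa, complete = TRUE)[, -1, drop = FALSE]  # null space of a
  lower <- c(rep(-Inf, obj$d - 1L), rep(1e-6, obj$n_ex))
  upper <- c(rep(Inf, obj$d - 1L), rep(0.999, obj$n_ex))
  cur <- theta0
  function(value, maxiter = 25) {
    w0 <- a * value / sum(a^2)
    u0 <- drop(crossprod(Z, cur[seq_len(obj$d)] - w0))
    par0 <- c(u0, pmin(pmax(cur[obj$d + seq_len(obj$n_ex)], 1e-6), 0.999))
    resid_u <- function(p) {
      wfull <- w0 + drop(Z %*% p[seq_len(obj$d - 1L)])
      obj$resid_full(c(wfull, p[obj$d - 1L + seq_len(obj$n_ex)]))
    }
    ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-9,
                                       ptol = 1e-9)
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(par = par0, lower = lower,
                                          upper = upper, fn = resid_u,
                                          control = ctrl)),
      error = function(e) NULL)
    if (is.null(res)) return(Inf)
    p <- res$par
    wfull <- w0 + drop(Z %*% p[seq_len(obj$d - 1L)])
    theta <- c(wfull, p[obj$d - 1L + seq_len(obj$n_ex)])
    cur <<- theta
    tryCatch(sum(obj$resid_meas(obj$theta_to_flux(theta))^2),
             error = function(e) Inf)
  }
}

# profiled SSR with one net flux pinned to `value`. By default warm starts
# from the fitted optimum with short continuation; `start` (a flux_vector,
# e.g. a known ground truth satisfying the pin) replaces the warm start.
profile_ssr <- function(fit, reaction, value, maxiter = 25, start = NULL,
                        steps = 4) {
  if (!is.null(start)) {
    prof <- make_profiler(fit, reaction, theta0 = fit$objective$flux_to_theta(start))
    return(prof(value, maxiter = maxiter))
  }
  prof <- make_profiler(fit, reaction)
  v0 <- fit$fluxes$net[[reaction]]
  path <- seq(v0, value, length.out = steps + 1L)[-1]
  s <- Inf
  for (v in path) {
    s <- prof(v, maxiter = if (v == value) maxiter else 10L)
  }
  s
}

#' Profile-likelihood confidence interval for one net flux
#'
#' Steps the chosen reaction's net flux away from its optimum, re-optimizing
#' all other free parameters, until the SSR exceeds
#' `SSR_min + qchisq(confidence, 1)` (3.84 for 95%), then refines the
#' crossing by bisection. Unidentifiable directions are reported as
#' unbounded (`-Inf`/`Inf`) with a flag.
#'
#' @param fit An `mfa_fit`.
#' @param reaction Reaction id.
#' @param confidence Confidence level (default 0.95).
#' @param max_steps Cap on expansion steps per side.
#' @param maxiter LM iteration cap per profile point.
#' @return List of class `flux_ci`: `reaction`, `estimate`, `lower`, `upper`,
#'   `threshold`, `flags`.
#' @export
flux_confidence_interval <- function(fit, reaction, confidence = 0.95,
                                     max_steps = 18, maxiter = 25) {
  stopifnot(reaction %in% names(fit$fluxes$net))
  vstar <- fit$fluxes$net[[reaction]]
  thr <- fit$ssr + stats::qchisq(confidence, 1)
  irrev <- !(reaction %in% fit$objective$rev)
  scale <- max(abs(vstar), 1)
  flags <- character(0)
  one_side <- function(sgn) {
    prof <- make_profiler(fit, reaction)   # continuation along this side
    delta <- 0.04 * scale
    prev_v <- vstar
    for (k in seq_len(max_steps)) {
      v <- vstar + sgn * delta
      if (irrev && v < 0) v <- 0
      s <- prof(v, maxiter = maxiter)
      if (s > thr) {
        # bisect between prev_v (below threshold) and v (above)
        lo_v <- prev_v; hi_v <- v
        for (j in 1:6) {
          mid_v <- (lo_v + hi_v) / 2
          sm <- prof(mid_v, maxiter = maxiter)
          if (sm > thr) hi_v <- mid_v else lo_v <- mid_v
        }
        return((lo_v + hi_v) / 2)
      }
      if (irrev && v == 0) return(0)      # profile reaches zero below threshold
      prev_v <- v
      delta <- delta * 1.8
    }
    flags <<- c(flags, sprintf("%s bound unbounded within search range",
                               if (sgn < 0) "lower" else "upper"))
    sgn * Inf
  }
  lower <- one_side(-1)
  upper <- one_side(1)
  structure(list(reaction = reaction, estimate = vstar, lower = lower,
                 upper = upper, threshold = thr, confidence = confidence,
                 flags = flags),
            class = "flux_ci")
}

#' @export
print.flux_ci <- function(x, ...) {
  cat(sprintf("%s: %.4g  %g%% CI [%.4g, %.4g]%s\n", x$reaction, x$estimate,
              100 * x$confidence, x$lower, x$upper,
              if (length(x$flags)) paste0("  (", paste(x$flags, collapse = "; "), ")") else ""))
  invisible(x)
}

#' Write a fit result to JSON and a net (exchange) flux table
#'
#' @param fit An `mfa_fit`.
#' @param json_path,csv_path Output paths (NULL to skip).
#' @return Invisibly, the list serialized to JSON.
#' @export
write_fit <- function(fit, json_path = NULL, csv_path = NULL) {
  out <- list(ssr = fit$ssr, dof = fit$dof,
              chi2_interval = fit$chi2_interval, accepted = fit$accepted,
              alpha = fit$alpha, restarts = fit$restarts, seed = fit$seed,
              net = as.list(fit$fluxes$net),
              exchange = as.list(fit$fluxes$exchange))
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(format_flux_table(fit$fluxes), csv_path, row.names = FALSE)
  }
  invisible(out)
}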