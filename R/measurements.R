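#' Mass isotopomer distribution (MID)
#'
#' Constructs a corrected mass isotopomer distribution: the vector of
#' fractional abundances M0..Mn of a fragment whose backbone carries
#' `n_backbone` tracer-relevant carbons. Fractions must be non-negative and
#' sum to one (tolerance 1e-9).
#'
#' @param fractions Numeric vector of length `n_backbone + 1`.
#' @param metabolite,fragment Optional identifiers.
#' @param n_backbone Number of backbone carbons (default inferred from length).
#' @param sd Per-channel measurement standard deviation; recycled. The default
#'   0.003 mol fraction is typical GC-MS precision.
#' @return Object of class `mid`.
#' @export
mid <- function(fractions, metabolite = NA_character_, fragment = NA_character_,
                n_backbone = length(fractions) - 1L, sd = 0.003) {
  fractions <- as.numeric(fractions)
  if (any(fractions < -1e-12)) stop("MID fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("MID fractions must sum to 1")
  if (length(fractions) != n_backbone + 1L) {
    stop("MID length must be n_backbone + 1")
  }
  structure(
    list(metabolite = metabolite, fragment = fragment,
         n_backbone = as.integer(n_backbone),
         fractions = pmax(fractions, 0),
         sd = rep_len(as.numeric(sd), length(fractions))),
    class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("MID %s%s (n = %d): %s\n",
              ifelse(is.na(x$metabolite), "", x$metabolite),
              ifelse(is.na(x$fragment), "", paste0("/", x$fragment)),
              x$n_backbone,
              paste(sprintf("%.4f", x$fractions), collapse = " ")))
  invisible(x)
}

mid_fractions <- function(x) if (inherits(x, "mid")) x$fractions else as.numeric(x)

#' Natural-abundance correction matrix
#'
#' Builds the square matrix mapping a corrected backbone-labeling distribution
#' to the observed GC-MS mass distribution of a derivatized fragment. Column
#' j (j = 0..n_backbone) is the predicted observed distribution when exactly j
#' backbone carbons are 13C and every remaining atom (including derivatization
#' C, H, N, O, Si, S) follows natural isotope abundance. Columns sum to at
#' most 1 because the observed window is truncated at `n_channels` masses.
#'
#' @param formula Elemental formula of the complete measured fragment,
#'   including derivatization atoms, e.g. `"C6H12O3NSi"`.
#' @param n_backbone Number of tracer-relevant backbone carbons.
#' @param n_channels Number of observed mass channels (rows); defaults to
#'   `n_backbone + 1`.
#' @param abundances Isotope table, see [natural_abundances()].
#' @return `n_channels` x `(n_backbone + 1)` matrix.
#' @export
correction_matrix <- function(formula, n_backbone,
                              n_channels = n_backbone + 1L,
                              abundances = natural_abundances()) {
  counts <- parse_formula(formula)
  if (is.na(counts["C"]) || counts["C"] < n_backbone) {
    stop("n_backbone exceeds carbon count of formula ", formula)
  }
  unknown <- setdiff(names(counts), names(abundances))
  if (length(unknown)) stop("no abundance data for element(s): ",
                            paste(unknown, collapse = ", "))
  max_shift <- n_channels - 1L
  # distribution of all atoms that are never tracer-labeled
  base <- 1
  for (el in names(counts)) {
    k <- counts[[el]] - if (el == "C") n_backbone else 0L
    if (k > 0) base <- convolve_dist(base, element_dist(abundances[[el]], k, max_shift))
  }
  base <- base[seq_len(min(length(base), max_shift + 1L))]
  natC <- abundances$C
  M <- matrix(0, n_channels, n_backbone + 1L)
  for (j in 0:n_backbone) {
    # j fixed 13C backbone carbons shift everything up by j; the other
    # n_backbone - j backbone carbons follow natural abundance
    col <- base
    if (n_backbone - j > 0) {
      col <- convolve_dist(col, element_dist(natC, n_backbone - j, max_shift))
    }
    idx <- seq_along(col) + j
    keep <- idx <= n_channels
    M[idx[keep], j + 1L] <- col[keep]
  }
  M
}

#' Correct an observed mass distribution for natural isotope abundance
#'
#' Solves `observed = correction_matrix %*% corrected` by non-negative least
#' squares and renormalizes the solution to the probability simplex, yielding
#' the backbone MID in corrected space.
#'
#' @param raw Observed mass distribution (length >= `n_backbone + 1`); need
#'   not be normalized. Small negative noise entries (> `-neg_tol`) are
#'   clipped; larger ones are an error.
#' @param formula,n_backbone,abundances See [correction_matrix()].
#' @param neg_tol Tolerance for negative raw entries (default 0.01).
#' @inheritParams mid
#' @return A [mid] object.
#' @export
correct_mid <- function(raw, formula, n_backbone,
                        metabolite = NA_character_, fragment = NA_character_,
                        sd = 0.003, neg_tol = 0.01,
                        abundances = natural_abundances()) {
  raw <- as.numeric(raw)
  if (length(raw) < n_backbone + 1L) stop("raw vector shorter than n_backbone + 1")
  if (all(raw == 0)) stop("all-zero raw mass distribution")
  if (any(raw < -neg_tol * max(raw))) stop("raw distribution has large negative entries")
  raw <- pmax(raw, 0)
  M <- correction_matrix(formula, n_backbone, n_channels = length(raw),
                         abundances = abundances)
  x <- pracma::lsqnonneg(M, raw)$x
  if (sum(x) <= 0) stop("degenerate correction solution")
  mid(x / sum(x), metabolite = metabolite, fragment = fragment,
      n_backbone = n_backbone, sd = sd)
}

#' Mole percent enrichment
#'
#' MPE = 100 * sum(Mi * i) / n over the backbone carbons of a fragment: the
#' average fractional 13C labeling of the backbone, in percent.
#'
#' @param x A [mid] object or numeric fraction vector M0..Mn.
#' @return Scalar percent in `[0, 100]`.
#' @export
mpe <- function(x) {
  f <- mid_fractions(x)
  n <- length(f) - 1L
  if (n < 1L) stop("MPE undefined for a fragment with no backbone carbons")
  100 * sum(f * (0:n)) / n
}

#' Extracellular exchange rate from medium concentrations
#'
#' Converts fresh/spent medium concentrations into a per-well uptake or
#' secretion flux: `uptake = (fresh - spent) * volume / hours`, secretion the
#' negative. With `direction = "auto"` the sign of the concentration change
#' picks the direction.
#'
#' @param species Species name.
#' @param fresh_conc,spent_conc Concentrations in nmol/ul.
#' @param volume_ul Medium volume per well (ul).
#' @param hours Elapsed time (h), > 0.
#' @param direction `"auto"`, `"uptake"` or `"secretion"`.
#' @return One-row data frame with the signed flux in nmol/well/h; `flux` is
#'   positive for consumption when `direction = "uptake"` and positive for
#'   release when `direction = "secretion"`.
#' @export
exchange_rate <- function(species, fresh_conc, spent_conc, volume_ul, hours,
                          direction = c("auto", "uptake", "secretion")) {
  direction <- match.arg(direction)
  stopifnot(hours > 0, fresh_conc >= 0, spent_conc >= 0, volume_ul > 0)
  uptake <- (fresh_conc - spent_conc) * volume_ul / hours
  if (direction == "auto") direction <- if (uptake >= 0) "uptake" else "secretion"
  flux <- if (direction == "uptake") uptake else -uptake
  data.frame(species = species, fresh_conc = fresh_conc, spent_conc = spent_conc,
             volume_ul = volume_ul, hours = hours, direction = direction,
             flux = flux, stringsAsFactors = FALSE)
}

#' Desaturation index
#'
#' Ratio of monounsaturated to saturated fatty acid abundance:
#' C16:1/C16:0 and C18:1/C18:0.
#'
#' @param fa_totals Named numeric vector of FA abundances; must contain
#'   `C16:1`, `C16:0`, `C18:1`, `C18:0`.
#' @return Named numeric vector of the two ratios.
#' @export
desaturation_index <- function(fa_totals) {
  need <- c("C16:1", "C16:0", "C18:1", "C18:0")
  miss <- setdiff(need, names(fa_totals))
  if (length(miss)) stop("missing fatty acid(s): ", paste(miss, collapse = ", "))
  if (fa_totals[["C16:0"]] <= 0 || fa_totals[["C18:0"]] <= 0) {
    stop("saturated FA abundances must be positive")
  }
  c("C16:1/C16:0" = unname(fa_totals[["C16:1"]] / fa_totals[["C16:0"]]),
    "C18:1/C18:0" = unname(fa_totals[["C18:1"]] / fa_totals[["C18:0"]]))
}

#' Absolute de novo lipogenesis
#'
#' Combines the ISA fraction-newly-synthesized D of each fatty acid with its
#' pool size to give the molar amount synthesized over the tracing window.
#'
#' @param fraction_new Named numeric vector of D values in `[0, 1]`.
#' @param pool_nmol Named numeric vector of pool sizes (nmol), same names.
#' @return List with `per_fa` (named nmol vector) and `total`.
#' @export
absolute_dnl <- function(fraction_new, pool_nmol) {
  stopifnot(all(names(fraction_new) %in% names(pool_nmol)))
  if (any(fraction_new < 0 | fraction_new > 1)) stop("D values must be in [0, 1]")
  if (any(pool_nmol < 0)) stop("pool sizes must be non-negative")
  per <- fraction_new * pool_nmol[names(fraction_new)]
  list(per_fa = per, total = sum(per))
}

#' Read / write MID tables
#'
#' CSV format: columns `metabolite, fragment, formula, n_backbone, m0...mk`
#' and optionally `sd0...sdk`. Trailing channels beyond `n_backbone + 1` may
#' be NA for short fragments.
#'
#' @param path File path.
#' @return List of [mid] objects (named `metabolite`).
#' @export
read_mid_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  scols <- grep("^sd[0-9]+$", names(df), value = TRUE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    n <- df$n_backbone[i]
    f <- as.numeric(df[i, mcols[seq_len(n + 1)]])
    s <- if (length(scols) >= n + 1) as.numeric(df[i, scols[seq_len(n + 1)]]) else 0.003
    mid(f / sum(f), metabolite = df$metabolite[i], fragment = df$fragment[i],
        n_backbone = n, sd = s)
  })
  names(out) <- df$metabolite
  out
}

#' @rdname read_mid_table
#' @param mids List of [mid] objects.
#' @export
write_mid_table <- function(mids, path) {
  kmax <- max(vapply(mids, function(m) m$n_backbone, integer(1)))
  rows <- lapply(mids, function(m) {
    f <- c(m$fractions, rep(NA, kmax - m$n_backbone))
    s <- c(m$sd, rep(NA, kmax - m$n_backbone))
    c(list(metabolite = m$metabolite, fragment = m$fragment,
           n_backbone = m$n_backbone),
      stats::setNames(as.list(f), paste0("m", 0:kmax)),
      stats::setNames(as.list(s), paste0("sd", 0:kmax)))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an exchange-rate table
#'
#' CSV with columns `species, fresh_conc, spent_conc, volume_ul, hours` and
#' optionally `direction`.
#'
#' @param path File path.
#' @return Data frame of [exchange_rate()] results, one row per species.
#' @export
read_rates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dir <- if ("direction" %in% names(df)) df$direction else rep("auto", nrow(df))
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    exchange_rate(df$species[i], df$fresh_conc[i], df$spent_conc[i],
                  df$volume_ul[i], df$hours[i], dir[i])
  }))
}
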