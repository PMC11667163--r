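#' Flux vector: net and exchange values
#'
#' A flux assignment for a network: one net value per reaction (negative only
#' for reversible reactions) and one non-negative exchange value per
#' reversible reaction. Reversible reactions are reported in the
#' net(exchange) convention; forward and backward fluxes are
#' `max(net, 0) + exchange` and `max(-net, 0) + exchange`.
#'
#' @param net_values Named numeric vector over all reactions (nmol/well/h).
#' @param exchange Named numeric vector over reversible reactions (>= 0);
#'   missing entries default to 0.
#' @param network The `flux_network` (used for validation).
#' @param check Validate balance/irreversibility (default TRUE).
#' @param tol Balance tolerance relative to the largest flux.
#' @return Object of class `flux_vector` with elements `net`, `exchange`.
#' @export
flux_vector <- function(net_values, exchange = NULL, network = NULL,
                        check = !is.null(network), tol = 1e-6) {
  if (!is.null(network)) {
    rid <- reaction_ids(network)
    stopifnot(all(rid %in% names(net_values)))
    net_values <- net_values[rid]
    rev <- reversible_ids(network)
    ex <- stats::setNames(numeric(length(rev)), rev)
    if (!is.null(exchange)) {
      bad <- setdiff(names(exchange), rev)
      if (length(bad)) stop("exchange given for irreversible reaction(s): ",
                            paste(bad, collapse = ", "))
      ex[names(exchange)] <- exchange
    }
    if (check) {
      if (any(ex < 0)) stop("exchange fluxes must be non-negative")
      irrev <- setdiff(rid, rev)
      if (any(net_values[irrev] < -tol * max(abs(net_values)))) {
        stop("negative net flux on irreversible reaction(s): ",
             paste(irrev[net_values[irrev] < 0], collapse = ", "))
      }
      S <- stoichiometry(network)
      resid <- max(abs(S %*% net_values))
      if (resid > tol * max(1, max(abs(net_values)))) {
        stop(sprintf("flux vector violates mass balance (max |S v| = %g)", resid))
      }
      if (nrow(network$ratios)) {
        for (i in seq_len(nrow(network$ratios))) {
          a <- net_values[network$ratios$a[i]]
          b <- net_values[network$ratios$b[i]]
          if (abs(a - network$ratios$ratio[i] * b) > tol * max(1, abs(b))) {
            stop("flux vector violates fixed ratio ", network$ratios$a[i])
          }
        }
      }
    }
  } else {
    ex <- if (is.null(exchange)) stats::setNames(numeric(0), character(0)) else exchange
  }
  structure(list(net = net_values, exchange = ex), class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("flux_vector:", length(x$net), "net fluxes,",
      length(x$exchange), "exchanges\n")
  df <- format_flux_table(x)
  print(utils::head(df, 15), row.names = FALSE)
  if (nrow(df) > 15) cat("...", nrow(df) - 15, "more\n")
  invisible(x)
}

#' Format fluxes in the net (exchange) reporting convention
#'
#' @param fluxes A `flux_vector`.
#' @return Data frame with columns reaction, net, exchange, label.
#' @export
format_flux_table <- function(fluxes) {
  rid <- names(fluxes$net)
  ex <- fluxes$exchange[rid]
  lab <- ifelse(is.na(ex), sprintf("%.3g", fluxes$net),
                sprintf("%.3g (%.3g)", fluxes$net, ex))
  data.frame(reaction = rid, net = unname(fluxes$net),
             exchange = unname(ex), label = lab,
             stringsAsFactors = FALSE, row.names = NULL)
}

# directed flux vector for EMU balances: forward fluxes for all reactions,
# then backward fluxes for reversible ones, floored to keep balances regular
directed_fluxes <- function(fluxes, rev_ids, floor = 1e-12) {
  net <- fluxes$net
  ex <- stats::setNames(numeric(length(net)), names(net))
  ex[names(fluxes$exchange)] <- fluxes$exchange
  fwd <- pmax(net, 0) + ex
  bwd <- (pmax(-net, 0) + ex)[rev_ids]
  pmax(c(fwd, bwd), floor)
}
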