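#' Natural isotope abundance table
#'
#' Fractional abundances of the stable isotopes of the elements occurring in
#' GC-MS metabolite fragments (backbone plus methoxyamine/TBDMS or methyl-ester
#' derivatization atoms). Positions within each vector are mass shifts
#' 0, +1, +2, ... relative to the lightest isotope. Values are the NIST
#' standard atomic compositions.
#'
#' @return Named list of numeric abundance vectors (C, H, N, O, Si, S).
#' @export
natural_abundances <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
}

#' Parse an elemental formula string
#'
#' @param formula Formula such as `"C9H19O3Si"` (counts of 1 may be omitted).
#' @return Named integer vector of atom counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  rx <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(rx))[[1]]
  if (sum(attr(rx, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9]*$", "", tokens)
  ct <- sub("^[A-Z][a-z]?", "", tokens)
  ct <- ifelse(ct == "", 1L, as.integer(ct))
  counts <- tapply(ct, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

# open (full) discrete convolution of two probability vectors
convolve_dist <- function(x, y) {
  nx <- length(x); ny <- length(y)
  out <- numeric(nx + ny - 1L)
  for (i in seq_len(nx)) {
    idx <- i:(i + ny - 1L)
    out[idx] <- out[idx] + x[i] * y
  }
  out
}

# distribution of mass shifts for `count` atoms of one element, truncated
element_dist <- function(abund, count, max_shift) {
  out <- 1
  for (i in seq_len(count)) {
    out <- convolve_dist(out, abund)
    if (length(out) > max_shift + 1L) out <- out[seq_len(max_shift + 1L)]
  }
  out
}
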