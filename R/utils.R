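# Internal helpers: seed streams, bin validation, logging.

# Derive a child seed from a master seed and an integer key, keeping the
# result inside the 32-bit signed range R's set.seed() accepts. A fixed
# multiplicative hash keeps streams for distinct keys decoupled, so adding
# candidates (e.g. Rep values) never perturbs another candidate's draws.
.childSeed <- function(seed, key) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m) * 48271 + (abs(as.numeric(key)) %% m) * 16807
  as.integer(x %% (m - 1)) + 1L
}

# Five-bin confidence table validation: bins must partition [50, 100]
# contiguously (lower inclusive, upper exclusive, final upper inclusive).
.checkBins <- function(bins) {
  need <- c("label", "lower", "upper")
  if (!is.data.frame(bins) || !all(need %in% names(bins)))
    return("bins must be a data.frame with label, lower, upper")
  if (nrow(bins) != 5L)
    return("exactly five confidence bins required")
  b <- bins[order(bins$lower), ]
  if (b$lower[1] != 50 || b$upper[nrow(b)] != 100)
    return("bins must span [50, 100]")
  if (any(b$upper <= b$lower))
    return("each bin must have upper > lower")
  if (any(abs(b$lower[-1] - b$upper[-nrow(b)]) > 1e-12))
    return("bins must be contiguous (no gaps or overlaps)")
  TRUE
}

#' Default proximity-percentage confidence bins
#'
#' Five uniform decade bins over the attainable percentage range
#' \[50, 100\]: the winning class's percentage is at least 50 by
#' construction. The top bin is the "hard hit" category.
#'
#' @return data.frame with columns label, lower, upper.
#' @export
defaultConfidenceBins <- function() {
  data.frame(
    label = c("uncertain", "weak", "moderate", "strong", "hard hit"),
    lower = c(50, 60, 70, 80, 90),
    upper = c(60, 70, 80, 90, 100))
}

# Minimal run logger: collect timestamped lines, optionally echo.
.newLog <- function(verbose = FALSE) {
  lines <- character()
  list(
    add = function(...) {
      line <- sprintf(...)
      lines <<- c(lines, line)
      if (verbose) message(line)
      invisible(line)
    },
    dump = function() lines)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
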