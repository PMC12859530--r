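#' Pulsed-gradient spin-echo acquisition protocol
#'
#' b-values with their repeat counts and the gradient timing of the PGSE
#' sequence. The effective diffusion time is \code{Delta - delta/3}.
#'
#' @param b_values strictly increasing b-values, s/mm^2.
#' @param repeats positive integer repeat count per b-value.
#' @param delta gradient lobe duration, ms.
#' @param Delta gradient lobe separation, ms (must exceed \code{delta}).
#' @param direction unit 3-vector diffusion direction.
#' @return Object of class \code{acquisition_protocol}.
#' @export
acquisition_protocol <- function(b_values, repeats = rep(1L, length(b_values)),
                                 delta = 7, Delta = 25,
                                 direction = c(0, 1, 0)) {
  b_values <- as.numeric(b_values)
  repeats <- as.integer(repeats)
  if (length(repeats) != length(b_values))
    stop("repeats must align with b_values")
  if (any(diff(b_values) <= 0)) stop("b_values must be strictly increasing")
  if (any(repeats < 1L)) stop("repeats must be >= 1")
  if (!(delta < Delta)) stop("delta must be < Delta")
  direction <- direction / sqrt(sum(direction^2))
  structure(
    list(b_values = b_values, repeats = repeats,
         delta = delta, Delta = Delta, direction = direction),
    class = "acquisition_protocol"
  )
}

#' Default rat-brain DWI protocol
#'
#' Eight b-values 18--6013 s/mm^2 along a single (Y) direction with the four
#' highest b repeated 2x/4x/8x/12x for averaging, gradient duration/separation
#' 7/25 ms.
#'
#' @return \code{acquisition_protocol}.
#' @export
default_protocol <- function() {
  acquisition_protocol(
    b_values = c(18, 113, 513, 1013, 2013, 3013, 4513, 6013),
    repeats  = c(1L, 1L, 1L, 1L, 2L, 4L, 8L, 12L),
    delta = 7, Delta = 25, direction = c(0, 1, 0)
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("acquisition_protocol:", length(x$b_values), "b-values,",
      sum(x$repeats), "volumes; delta/Delta =", x$delta, "/", x$Delta, "ms\n")
  invisible(x)
}

# effective diffusion time, ms
diffusion_time <- function(protocol) protocol$Delta - protocol$delta / 3

#' Write / read a b-table sidecar
#'
#' Tab-separated table with columns \code{b} (s/mm^2) and \code{repeats};
#' rows in acquisition order.
#'
#' @param protocol \code{acquisition_protocol}.
#' @param path file path.
#' @return \code{read_btable} returns an \code{acquisition_protocol} (with
#'   default gradient timing unless columns \code{delta}/\code{Delta} are
#'   present).
#' @export
write_btable <- function(protocol, path) {
  df <- data.frame(b = protocol$b_values, repeats = protocol$repeats,
                   delta = protocol$delta, Delta = protocol$Delta)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_btable
#' @export
read_btable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("b", "repeats") %in% names(df)))
    stop("b-table must have columns 'b' and 'repeats'")
  if (any(diff(df$b) <= 0))
    stop("non-monotone b at row ", which(diff(df$b) <= 0)[1] + 1)
  acquisition_protocol(
    b_values = df$b, repeats = df$repeats,
    delta = if ("delta" %in% names(df)) df$delta[1] else 7,
    Delta = if ("Delta" %in% names(df)) df$Delta[1] else 25
  )
}

#' Normalized decay curve
#'
#' @param b b-values, s/mm^2.
#' @param S signals; normalized in-place to S[1] = 1.
#' @param se optional Monte-Carlo standard errors (scaled with S).
#' @return Object of class \code{decay_curve}.
#' @export
decay_curve <- function(b, S, se = NULL) {
  stopifnot(length(b) == length(S))
  if (!is.null(se)) se <- se / S[1]
  S <- S / S[1]
  structure(list(b = as.numeric(b), S = as.numeric(S), se = se),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat("decay_curve over", length(x$b), "b-values; S(b_max) =",
      signif(x$S[length(x$S)], 4), "\n")
  invisible(x)
}
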