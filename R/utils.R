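#' @keywords internal
#' @useDynLib conceptgraph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Rating scale endpoints used throughout: a rating of +7 means maximal
## relatedness, -7 maximal opposition, 0 no relation.
RATING_MIN <- -7L
RATING_MAX <- 7L
RATING_LEVELS <- RATING_MIN:RATING_MAX

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one root seed. Per-edge (and
#' per-stage) substreams are derived by hashing the root seed together with
#' string/integer tags, so results do not depend on the order in which edges
#' are evaluated.
#'
#' @param seed integer root seed.
#' @param ... character or integer tags naming the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime; products stay below 2^53
  h <- as.double(seed) %% m
  for (part in unlist(list(...), use.names = FALSE)) {
    if (is.character(part)) {
      codes <- utf8ToInt(part)
      v <- sum(codes * seq_along(codes)) %% m
    } else {
      v <- as.double(part) %% m
    }
    h <- (h * 48271 + v + 1) %% m
  }
  as.integer(h)
}

## stop() with sprintf formatting
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## squeeze whitespace + lowercase; used for case-insensitive source matching
normalize_source <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}
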