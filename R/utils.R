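#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor coef lm median optim pnorm pt qnorm quantile rnorm
#'   runif sd predict qt var wilcox.test mad setNames complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

# Structured condition helpers ------------------------------------------------

dh_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "dothisto_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

dh_assert <- function(cond, class, message, ...) {
  if (!isTRUE(cond)) dh_error(class, message, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Hierarchical sub-stream seeds: every source of randomness in the package is
# derived from one integer seed via (subject index, modality) offsets, so each
# stage is independently reproducible.  Large co-prime multipliers keep the
# (seed, subject, modality) triples from colliding within any realistic run.
substream_seed <- function(seed, subject = 0L, modality = 0L) {
  s <- (as.double(seed) %% 2147483647) +
    7919 * as.double(subject) + 104729 * as.double(modality)
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
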