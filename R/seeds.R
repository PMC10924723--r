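#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically folds a master seed together with an arbitrary set of
#' integer or character tags (scenario index, replicate number, stage name,
#' ...) into a single integer seed below 2^31. Used throughout the package so
#' that each stage of a simulation pipeline can be re-run independently while
#' remaining reproducible from one master seed.
#'
#' @param master Integer master seed.
#' @param ... Additional integer or character tags.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "tree", 18L)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  to_int <- function(x) {
    if (is.character(x)) {
      # stable fold of the character codes
      cc <- utf8ToInt(paste(x, collapse = "|"))
      sum(cc * seq_along(cc)) %% 2147483647
    } else {
      v <- as.numeric(x) %% 2147483647
      sum(v * seq_along(v)) %% 2147483647
    }
  }
  parts <- c(as.numeric(master) %% 2147483647,
             vapply(list(...), to_int, numeric(1)))
  s <- 0
  for (p in parts) {
    # multiplier kept small so s * 69069 + p stays exactly representable
    s <- (s * 69069 + p + 1) %% 2147483647
  }
  as.integer(s)
}

# Run an expression with a locally-set RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
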