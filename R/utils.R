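#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom tibble as_tibble
#' @importFrom ggplot2 autoplot
NULL

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
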