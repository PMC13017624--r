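#' @keywords internal
"_PACKAGE"

#' @useDynLib divnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rexp optim sd median quantile setNames var
#' @importFrom utils head tail
NULL

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(...) {
  stop(structure(class = c("divnn_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("divnn_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Test whether a pruning result was rejected
#'
#' [prune_extinct()] and the batch simulators flag trees that cannot be
#' completed to a crown-conditioned reconstructed phylogeny (all tips extinct,
#' or one of the two crown lineages left no extant descendant). Rejection is
#' data, not an error; this predicate identifies such results.
#'
#' @param x Any object.
#' @return `TRUE` for a rejection marker, `FALSE` otherwise.
#' @export
is_rejected <- function(x) inherits(x, "divnn_rejected")

rejected <- function(reason) {
  structure(NA, class = "divnn_rejected", reason = reason)
}

#' @export
print.divnn_rejected <- function(x, ...) {
  cat("<rejected tree:", attr(x, "reason"), ">\n")
  invisible(x)
}
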