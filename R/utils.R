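# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_scalobp <- function(msg, class) {
  stop(structure(class = c(class, "scalobp_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Set the number of BLAS threads
#'
#' Pins the OpenBLAS thread pool. One thread is the deterministic mode used
#' for reproducible training runs, and is also fastest on single-CPU hosts,
#' where OpenBLAS otherwise oversubscribes its default pool. Called with
#' `n = 1` when the package loads.
#'
#' @param n Number of threads.
#' @return `TRUE` (invisibly) if the BLAS honoured the request.
#' @export
set_blas_threads <- function(n = 1L) {
  invisible(.set_blas_threads_cpp(as.integer(n)))
}

.onLoad <- function(libname, pkgname) {
  .set_blas_threads_cpp(1L)
  invisible()
}
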