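# Internal helpers: classed errors, seed management, run log, channel math.

oct_error <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("octbrain_", class), "octbrain_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded operations do not perturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Every random draw in the pipeline derives from one master seed through
#' named stage offsets, so a single integer reproduces a full run.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @param index optional integer offset within the stage.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  s <- (abs(as.numeric(master)) + 7919 * h + 104729 * as.numeric(index)) %%
    (2^31 - 2)
  as.integer(s) + 1L
}

# ---- run log -----------------------------------------------------------

.oct_log_env <- new.env(parent = emptyenv())
.oct_log_env$entries <- list()

log_event <- function(level, stage, msg, ...) {
  entry <- list(time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                level = level, stage = stage, message = sprintf(msg, ...))
  .oct_log_env$entries[[length(.oct_log_env$entries) + 1L]] <- entry
  if (level == "warning") warning(entry$message, call. = FALSE)
  invisible(entry)
}

#' Retrieve or reset the in-memory run log
#'
#' @param reset if `TRUE`, clear the log after returning it.
#' @return a data frame with columns time, level, stage, message.
#' @export
run_log <- function(reset = FALSE) {
  e <- .oct_log_env$entries
  df <- if (length(e) == 0) {
    data.frame(time = character(), level = character(), stage = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(e, function(x)
      data.frame(x, stringsAsFactors = FALSE)))
  }
  if (reset) .oct_log_env$entries <- list()
  df
}

# small ReLU used on modest-sized tensors; the batch forward/backward path
# uses the single-pass C++ kernels instead
relu <- function(x) {
  x[x < 0] <- 0
  x
}
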