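# Internal helpers: classed conditions and scoped RNG.

stop_prognode <- function(class, message, ..., call. = FALSE) {
  cond <- structure(
    class = c(paste0("prognode_", class), "prognode_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

extdata_path <- function(file) {
  system.file("extdata", file, package = "prognode", mustWork = TRUE)
}
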