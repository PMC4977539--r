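# Internal helpers: argument checks and reproducible, state-preserving RNG.

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  if (integerish && abs(x - round(x)) > 1e-8)
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(x)
}

# Run `code` under `set.seed(seed)` without disturbing the caller's RNG
# stream; seed = NULL leaves the global stream untouched (and advancing).
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    .check_number(seed, "seed", integerish = TRUE)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Hierarchical sub-seed: one user-facing top seed, deterministic distinct
# streams per stage.  Kept strictly below 2^31 (R integers are 32-bit).
.derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 2147483629 * 31 + offset * 999331) %%
               2147483629) + 1L
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
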