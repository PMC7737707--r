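# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pheno <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_pheno("`%s` must be a single finite number, got %s", name,
               paste(deparse(x), collapse = ""))
  if (positive && x <= 0)
    stop_pheno("`%s` must be > 0, got %g", name, x)
  if (!is.null(min) && x < min)
    stop_pheno("`%s` must be >= %g, got %g", name, min, x)
  invisible(x)
}

# Concentration unit handling. Layouts store molar internally; the interface
# accepts micromolar (the screen's working unit) and converts.
CONC_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

to_molar <- function(x, unit = "uM") {
  if (!unit %in% names(CONC_FACTORS))
    stop_pheno("unknown concentration unit '%s' (use one of %s)",
               unit, paste(names(CONC_FACTORS), collapse = ", "))
  x * CONC_FACTORS[[unit]]
}

from_molar <- function(x, unit = "uM") x / CONC_FACTORS[[unit]]

# Deterministic 31-bit seed derived from an experiment seed and a string key
# (plate/well). Multiplicative congruential mixing keeps everything within
# double-exact integer range.
derive_seed <- function(seed, ...) {
  key <- paste(..., sep = ":")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Run an expression with a local RNG state so generators do not disturb the
# caller's random stream.
with_seed <- function(seed, expr) {
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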