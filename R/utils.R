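#' gqfret: smFRET burst analysis of G-quadruplex conformational ensembles
#'
#' Synthetic PIE photon-stream simulation, fixed-bin burst search, corrected
#' FRET efficiency/stoichiometry, Gaussian-mixture species decomposition,
#' conformational-selection binding-isotherm fitting, and Boltzmann
#' melting-curve analysis.
#'
#' @keywords internal
"_PACKAGE"

# Run `expr` under a private RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-stream seed from (master seed, index); stays below 2^31.
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L)
  (as.double(master) %% 2147483647 * 48271 + 10007 * as.double(index)) %% 2147483629
}

# FNV-1a hash of an R object's serialized bytes; hex string used as run metadata.
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30  # keep in int range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop_domain <- function(msg, class) {
  stop(structure(class = c(class, "gqfret_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a finite numeric scalar", name),
                "gqfret_domain_error")
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop_domain(sprintf("'%s' = %g outside valid range", name, x),
                "gqfret_domain_error")
  invisible(x)
}
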