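# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

flip_strand <- function(alleles) unname(.COMPLEMENT[alleles])

# A/T and G/C pairs cannot be strand-resolved from allele labels alone.
is_palindromic <- function(a1, a2) a1 == flip_strand(a2)

mr_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "mrmetab_error", "error", "condition")))
}

stop_config <- function(msg) mr_stop(msg, "mrmetab_config_error")
stop_input <- function(msg) mr_stop(msg, "mrmetab_input_error")
stop_analysis <- function(msg) mr_stop(msg, "mrmetab_analysis_error")

# Run `code` under a temporary RNG state when `seed` is given; the caller's
# RNG stream is untouched either way.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seeds: one master seed fans out to per-component
# seeds so adding components never perturbs earlier ones. Kept < 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483563L * 40014 + as.numeric(k) * 40692 + 1) %% 2147483563)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

fmt_sci <- function(p) formatC(p, format = "e", digits = 2)
fmt_num <- function(x, digits = 2) formatC(round(x, digits), format = "f", digits = digits)
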