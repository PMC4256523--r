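# internal helpers shared across modules

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# user's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-purpose substreams from one master seed: adding a
# downstream purpose (or another source within a purpose) never perturbs an
# earlier one. Offsets are fixed; all arithmetic stays below 2^31.
sub_seed <- function(seed, purpose, index = 0L) {
  offsets <- c(truth = 11L, observations = 23L, panel = 37L,
               stage1 = 53L, stage2 = 71L, draws = 89L, pipeline = 101L)
  if (!purpose %in% names(offsets)) {
    stop("unknown seed purpose: ", purpose, call. = FALSE)
  }
  base <- (as.double(seed) * 1009 + offsets[[purpose]] * 9973 + index * 31L)
  as.integer(base %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# numeric formatting used by the reporting tables: plain 3 decimals for
# ordinary magnitudes, scientific with 3 significant digits for values that
# would round to 0.000 but are not exactly zero
format_coef <- function(x, digits = 3) {
  formatC(round(x, digits), format = "f", digits = digits)
}

format_bound <- function(x, digits = 3) {
  if (is.na(x)) return(NA_character_)
  if (x != 0 && abs(x) < 10^(-digits) / 2) {
    formatC(x, format = "e", digits = 3)
  } else {
    format_coef(x, digits)
  }
}

format_p <- function(p, digits = 3) {
  r <- round(p, digits)
  if (r == 0) "0" else formatC(r, format = "f", digits = digits)
}
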