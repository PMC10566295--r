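# internal helpers shared across modules

#' Derive a reproducible child seed from a master seed and context labels
#'
#' Mixes the master seed with an arbitrary number of integer or character
#' components into a single 31-bit seed, so that every cell of a factorial
#' design and every cross-validation repeat gets its own deterministic RNG
#' stream, independent of execution order.
#'
#' @param master integer master seed.
#' @param ... integers or character labels identifying the context
#'   (e.g. model name, density, repeat index).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  acc <- as.double(master) %% m
  for (part in list(...)) {
    if (is.character(part)) {
      part <- sum(utf8ToInt(paste(part, collapse = "|")) *
                    seq_len(nchar(paste(part, collapse = "|")))) %% m
    }
    for (p in as.double(part)) {
      # multiplicative mix; products stay < 2^53 so doubles are exact
      acc <- (acc * 48271 + (p %% m) + 1) %% m
    }
  }
  as.integer(acc)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed vocabulary of panel subgroups
subgroup_levels <- function() c("NSS", "SS", "TST", "MIXED")
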