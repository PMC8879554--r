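#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# fail with a consistent error class so callers can condition on it
stop_mitonet <- function(msg, class = "mitonet_error") {
  rlang::abort(msg, class = c(class, "mitonet_error"))
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_mitonet(sprintf("`%s` must be a single number.", name))
  }
  if (strict_min && x <= min) {
    stop_mitonet(sprintf("`%s` must be > %s (got %s).", name, min, x))
  }
  if (!strict_min && x < min) {
    stop_mitonet(sprintf("`%s` must be >= %s (got %s).", name, min, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, min = min)
  if (x != as.integer(x)) {
    stop_mitonet(sprintf("`%s` must be an integer (got %s).", name, x))
  }
  invisible(as.integer(x))
}

# Deterministically spawn sub-seeds from a master seed without touching
# the caller's RNG state. Kept below 2^31 so they stay valid R integers.
spawn_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# FNV-1a 32-bit hash of a string, reported as 8 hex digits. Used to stamp
# output files with a configuration fingerprint.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor on 16-bit halves (bitwXor needs values below 2^31)
    lo <- bitwXor(h %% 65536, b %% 65536)
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    # 32-bit modular multiply by the FNV prime, kept within double precision
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

pkg_version <- function() {
  as.character(utils::packageVersion("mitonet"))
}
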