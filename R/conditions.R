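## Structured conditions: every error raised by the package carries a class
## from this small vocabulary so callers (and the CLI) can map failures to
## config / data / io categories without matching message strings.

cac_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cac_error", "error"), call = call))
}

cac_config_error   <- function(msg) cac_error(msg, "cac_config_error")
cac_data_error     <- function(msg) cac_error(msg, "cac_data_error")
cac_io_error       <- function(msg) cac_error(msg, "cac_io_error")
cac_parse_error    <- function(msg) cac_error(msg, c("cac_parse_error", "cac_data_error"))
cac_format_error   <- function(msg) cac_error(msg, c("cac_format_error", "cac_data_error"))
cac_geometry_error <- function(msg) cac_error(msg, c("cac_geometry_error", "cac_data_error"))
cac_layout_error   <- function(msg) cac_error(msg, c("cac_layout_error", "cac_data_error"))
cac_degenerate_error <- function(msg) cac_error(msg, c("cac_degenerate_error", "cac_data_error"))

## Run code with a temporary RNG state seeded from `seed`, restoring the
## caller's .Random.seed afterwards (so seeded helpers do not disturb the
## session's random stream).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    cac_config_error("seed must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic fan-out of a master seed to per-(atom, spin) sub-seeds.
## Lehmer-style mixing kept in exact double arithmetic (< 2^53), result in
## [1, 2^31 - 2] so it is always a valid set.seed()/ranger seed.
derive_seed <- function(master, atom_index, spin_index) {
  m <- 2147483647
  a <- as.double(master) %% m
  a <- (a * 48271) %% m
  a <- (a + (as.double(atom_index) + 1) * 100003 + as.double(spin_index) * 29) %% m
  a <- (a * 48271) %% m
  as.integer(a %% (m - 1)) + 1L
}
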