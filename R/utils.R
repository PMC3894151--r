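# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit hash of a string, used to attach reproducible
# per-conformer noise streams to conformer ids.
string_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Condition constructors used by the command-line front end to map failures
# onto exit statuses (1 = usage, 2 = data).
usage_error <- function(msg) {
  structure(class = c("gpconf_usage_error", "error", "condition"),
            list(message = msg, call = NULL))
}

data_error <- function(msg) {
  structure(class = c("gpconf_data_error", "error", "condition"),
            list(message = msg, call = NULL))
}

stop_usage <- function(...) stop(usage_error(paste0(...)))
stop_data <- function(...) stop(data_error(paste0(...)))

#' Kilojoules per kilocalorie
#'
#' Energies are carried in kJ/mol throughout the package; this constant is
#' exposed for reporting in kcal/mol (1 kcal/mol = 4.184 kJ/mol).
#'
#' @export
KJ_PER_KCAL <- 4.184
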