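# internal helpers shared across the package

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
# All exported stochastic functions funnel their `seed` through here so that a
# call never perturbs the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stage-specific seed from a master seed so pipeline stages can be
# rerun independently.  Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, ratings = 211L, sample = 307L, silver = 401L,
    model1 = 503L, model2 = 601L, model3 = 701L, bootstrap = 809L,
    generic = 907L
  )
  off <- offsets[[match.arg(stage, names(offsets))]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

#' Normalize a diagnosis code
#'
#' Uppercases the code and strips dots, so `"F60.3"` and `"f603"` both become
#' `"F603"`.  All rule matching in the package operates on normalized codes.
#'
#' @param code character vector of raw diagnosis codes.
#' @return character vector of normalized codes.
#' @export
#' @examples
#' normalize_code(c("F60.3", "f32.9"))
normalize_code <- function(code) {
  gsub(".", "", toupper(trimws(as.character(code))), fixed = TRUE)
}

# 3-character ICD-10-CM category prefix of a normalized code
icd10_prefix <- function(code) substr(code, 1L, 3L)

# TRUE where the code's 3-char prefix lies in an inclusive range like F01-F09
in_prefix_range <- function(code, from, to) {
  p <- icd10_prefix(code)
  nchar(code) >= 3L & p >= from & p <= to
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# largest-remainder apportionment of n into parts proportional to w (>= 0)
largest_remainder <- function(w, n) {
  stopifnot(n >= 0, all(w >= 0), sum(w) > 0)
  quota <- n * w / sum(w)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    rem <- quota - base
    # deterministic tie-break: larger remainder first, then earlier index
    ord <- order(-rem, seq_along(w))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
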