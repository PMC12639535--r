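# Internal helpers: deterministic string hashing for per-unit RNG substreams,
# unit canonicalization for dose/time matching, and small validators.

# 31-bit FNV-style string hash. Used to derive independent, order-invariant
# RNG substreams: the stream for a signature depends only on (seed, id), never
# on the position of the id in the table.
hash31 <- function(x) {
  vapply(x, function(s) {
    h <- 2166136261
    for (ch in utf8ToInt(enc2utf8(s))) {
      h <- (bitwXor(as.integer(h %% 2147483648), ch) * 16777619) %% 2147483648
    }
    as.integer(h %% 2147483647)
  }, integer(1), USE.NAMES = FALSE)
}

# Combine a user seed with a unit id into a substream seed (< 2^31).
substream_seed <- function(seed, id) {
  as.integer((as.double(seed) + as.double(hash31(as.character(id)))) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Canonicalize dose and time annotations
#'
#' Signature metadata in the wild spells units inconsistently ("10 uM",
#' "10uM", "10 µM"; "24 h", "24h", "24 hr"). Condition filtering matches on
#' the canonical token: lower case, no internal whitespace, micro sign folded
#' to "u", "hr"/"hrs" folded to "h".
#'
#' @param x character vector of dose or time annotations.
#' @return character vector of canonical tokens.
#' @examples
#' canonical_unit(c("10 µM", "10uM", "24 hr"))
#' @export
canonical_unit <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", "", x)
  x <- gsub("µ|μ", "u", x)
  x <- gsub("hrs?$", "h", x)
  x
}

stop_bad_arg <- function(msg, ...) abort(sprintf(msg, ...), class = "orthoscreen_error")

check_trinary <- function(x, what = "calls") {
  bad <- !x %in% c(-1L, 0L, 1L)
  if (any(bad)) {
    stop_bad_arg("%s must take values in {-1, 0, +1}; found %s",
                 what, paste(unique(x[bad])[1:min(3, sum(bad))], collapse = ", "))
  }
  invisible(x)
}
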