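`%||%` <- function(a, b) if (is.null(a)) b else a

# radix sort: locale-independent, so artifact ordering is stable across machines
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

#' Canonical variable identifier from a free-text label
#'
#' Folds to lowercase ASCII, collapses every run of non-alphanumeric
#' characters to a single underscore and strips leading/trailing
#' underscores, giving a stable, human-auditable id used for cross-map
#' matching.
#'
#' @param x character vector of labels.
#' @return character vector of slugs.
#' @examples
#' slugify("Body weight")     # "body_weight"
#' slugify("Stress-Eating")   # "stress_eating"
#' @export
slugify <- function(x) {
  x <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x[is.na(x)] <- ""
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Normalize a label for matching
#'
#' Lowercases, strips punctuation, collapses whitespace and removes a
#' trivial plural "s" from the final token (never from a double-s ending,
#' so "stress" survives). Used by the synonym table and fuzzy matching.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_label <- function(x) {
  x <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x[is.na(x)] <- ""
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(x)
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    last <- toks[length(toks)]
    if (nchar(last) >= 3 && grepl("[^s]s$", last)) {
      toks[length(toks)] <- sub("s$", "", last)
    }
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic 31-bit seed derived from a master seed and a string key.
# Kept below 2^31 - 1; arithmetic stays within double precision.
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer((h + (seed %% m) * 7919) %% m)
}
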