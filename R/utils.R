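# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
trim_id <- function(x) {
  # identifiers are case-sensitive but whitespace-trimmed (exact joins)
  trimws(as.character(x))
}

#' Match domain names against case-insensitive glob patterns
#'
#' Vocabulary matching used throughout the classifier: a domain name matches a
#' vocabulary if it equals (case-insensitively) any pattern, where patterns may
#' contain the shell wildcards `*` and `?`.
#'
#' @param names character vector of domain family names.
#' @param patterns character vector of glob patterns.
#' @return logical vector, one element per name.
#' @keywords internal
match_domain <- function(names, patterns) {
  if (length(names) == 0L) return(logical(0))
  if (length(patterns) == 0L) return(rep(FALSE, length(names)))
  rx <- paste0("(?:", paste(utils::glob2rx(patterns), collapse = ")|(?:"), ")")
  grepl(rx, names, ignore.case = TRUE)
}

# Evaluate an expression with a temporary RNG state seeded from `seed`,
# restoring the caller's RNG afterwards. Keeps generators reproducible
# without clobbering the session seed.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
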