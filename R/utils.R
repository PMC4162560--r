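#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Canonical token used for all compound-identity comparisons: exact id match
# after trimming and case-folding. Names are never used for matching.
norm_token <- function(x) tolower(trimws(x))

# Split a semicolon-joined field into a character vector (empty -> chr(0)).
split_semis <- function(x) {
  out <- lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character())
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  lapply(out, function(v) v[nzchar(v)])
}

join_semis <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

# Run code under a temporary RNG seed, restoring prior RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic lexicographic ordering independent of locale.
lex_order <- function(...) order(..., method = "radix")
lex_sort <- function(x) sort(x, method = "radix")
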