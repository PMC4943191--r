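# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state so seeded
#' package functions do not perturb the user's random stream. A `NULL` seed
#' evaluates the expression with the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

# single finite nonnegative number
check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single finite nonnegative number", name),
         call. = FALSE)
  invisible(x)
}

check_enum <- function(x, choices, name) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices))
    stop(sprintf("'%s' must be one of: %s (got %s)", name,
                 paste(choices, collapse = ", "),
                 deparse(substitute(x))), call. = FALSE)
  x
}

GENOME_TYPES <- c("mitochondrial", "nuclear", "chloroplast")
TAXON_GROUPS <- c("bird", "invertebrate", "reptile", "mammal", "amphibian",
                  "plant")
DIRECTIONS <- c("mainland_to_island", "island_to_mainland")
GENETIC_CODES <- c("standard", "vertebrate_mitochondrial",
                   "invertebrate_mitochondrial", "plant_plastid")
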