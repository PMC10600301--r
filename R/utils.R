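# Internal helpers: error conditions, seeded RNG scopes, parameter-tree algebra.

wf_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "wf_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

wf_config_error <- function(msg, ...) wf_error("wf_config_error", msg, ...)
wf_data_error <- function(msg, ...) wf_error("wf_data_error", msg, ...)
wf_training_error <- function(msg, ...) wf_error("wf_training_error", msg, ...)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream label, keeping the
# result a valid 32-bit integer. Distinct labels give distinct streams, so
# e.g. adding a subject never perturbs the other subjects' draws.
derive_seed <- function(seed, ...) {
  labels <- c(...)
  h <- as.double(seed) %% 2147483647
  for (lab in labels) {
    for (ch in utf8ToInt(as.character(lab))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

# ---- parameter trees (nested lists with numeric leaves) ---------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_flatten <- function(tree) {
  if (!is.list(tree)) return(list(tree))
  unlist(lapply(tree, tree_flatten), recursive = FALSE)
}

n_parameters <- function(tree) sum(vapply(tree_flatten(tree), length, 1L))

# sample() without the length-1 surprise
sample_from <- function(pool, n, replace = FALSE) {
  pool[sample.int(length(pool), n, replace = replace)]
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
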