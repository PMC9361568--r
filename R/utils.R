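#' @importFrom stats approx median optim quantile rbinom rbeta rexp rpois runif
#'   sd cor cutree hclust as.dist uniroot qpois setNames
#' @importFrom utils read.table write.table head tail
NULL

# data.table is used via :: only; declare awareness so [.data.table keeps
# data.table semantics inside this namespace.
.datatable.aware <- TRUE

# column names used non-standardly inside data.table j-expressions
utils::globalVariables(c("sample_a", "hap_a", "sample_b", "hap_b", "chrom",
                         "start", "end", "score", "length_cm", "founder_id",
                         "gap_fill_cm"))

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# All stochastic operations in the package funnel through this helper so that
# a seed argument implies bit-identical output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage label, staying below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

# Merge adjacent run-length intervals that carry the same value.
# starts: sorted interval starts; values parallel vector. Returns list(starts, values).
collapse_runs <- function(starts, values) {
  if (length(starts) <= 1L) return(list(starts = starts, values = values))
  keep <- c(TRUE, values[-1L] != values[-length(values)])
  list(starts = starts[keep], values = values[keep])
}
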