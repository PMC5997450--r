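# Shared helpers: controlled vocabularies, RNG scoping, logging.

POLARITY_LEVELS <- c("rostrad-sensitive", "caudad-sensitive", "undetermined")
AP_LEVELS <- c("anterior", "posterior", "unresolved")
AGE_LEVELS <- c("0-5h", "5-15h", ">15h", "unknown")
MATURE_AGES <- c("5-15h", ">15h")
KIND_LEVELS <- c("afferent", "efferent", "unclassified")
# preference labels: sensitivity groups, or positional groups when bundle
# polarity is uninformative (trilobite / Notch specimens)
PREF_LEVELS <- c("rostrad", "caudad", "anterior", "posterior", "unassigned")
GENOTYPE_LEVELS <- c("wild-type", "trilobite", "notch-overexpression")

#' Standard error of the mean
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return `sd(x)/sqrt(n)`, or `NA` when fewer than two values remain.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Significance stars for p values
#'
#' Star coding at the conventional 0.05 / 0.01 / 0.001 levels.
#'
#' @param p Numeric vector of p values.
#' @return Character vector: `"***"`, `"**"`, `"*"`, or `"ns"`.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

nm_log <- function(level, ...) {
  threshold <- getOption("neuromast.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build an empty data.frame with the given column name -> class spec.
empty_df <- function(spec) {
  cols <- lapply(spec, function(cl) vector(cl, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}
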