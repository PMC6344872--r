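#' @importFrom stats rmultinom rpois runif setNames wilcox.test
#' @importFrom utils head read.delim read.table write.table
#' @import data.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so that seeded package functions do not disturb
#' the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  force(code)
}

# n random DNA strings of the given length, i.i.d. uniform over {A,C,G,T}
random_dna <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# pyrimidine (C/T) fraction of each string
pyrimidine_fraction <- function(seq) {
  n <- nchar(seq)
  py <- n - nchar(gsub("[CTct]", "", seq))
  ifelse(n > 0, py / n, NA_real_)
}

assert_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: '%s')",
                 what, seq[which(bad)[1]]), call. = FALSE)
  }
  invisible(seq)
}

# split equal-length strings into a character matrix (one row per string)
seq_to_matrix <- function(seq) {
  len <- unique(nchar(seq))
  if (length(len) != 1) stop("sequences must have equal length", call. = FALSE)
  matrix(unlist(strsplit(seq, "", fixed = TRUE), use.names = FALSE),
         ncol = len, byrow = TRUE)
}

# 0-based substring helper: bases [start, end) of `seq`
substr0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# derive a stage seed from a master seed, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 37 + offset * 1009) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
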