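# internal helpers shared across modules

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# residues that never support a call (alignment gap / unknown)
NO_CALL <- c("-", "X")

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "humsub_error", "error")))
}

#' Round half away from zero
#'
#' Commercial rounding: `0.5 -> 1`, `-0.5 -> -1`, unlike [base::round()]
#' which rounds half to even.  Used wherever a real-valued quantity
#' (weight map output, spherical-model cutoff) is frozen to an integer.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run code under a temporary RNG seed, restoring global RNG state after.
# All generators take an explicit seed and route through this, so no call
# disturbs (or depends on) the caller's random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic TSV writer (no quoting surprises, no row names)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    ...)
}
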