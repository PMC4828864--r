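#' Read an NCBI-style amino-acid score matrix
#'
#' Parses the whitespace-delimited square matrix format used for BLOSUM
#' and PAM matrices (`#` comment lines, a header row of residue letters,
#' one labelled row per residue).  Extra rows/columns beyond the 20
#' amino acids (B, Z, X, `*`) are dropped.
#'
#' @param path matrix text file.
#' @param name label for the matrix (defaults to the file name).
#' @return 20 x 20 symmetric integer matrix with residue dimnames and a
#'   `name` attribute.
#' @export
read_score_matrix <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- matrix(NA_integer_, length(rows), length(header),
              dimnames = list(vapply(rows, `[`, character(1), 1L), header))
  for (i in seq_along(rows))
    m[i, ] <- as.integer(rows[[i]][-1])
  keep <- intersect(rownames(m), AA_ALPHABET)
  m <- m[keep, keep, drop = FALSE]
  if (!identical(sort(rownames(m)), sort(AA_ALPHABET)))
    abort("matrix does not cover the 20-residue alphabet",
          "humsub_invalid_matrix")
  if (!isTRUE(all.equal(m, t(m))))
    abort("score matrix must be symmetric", "humsub_invalid_matrix")
  attr(m, "name") <- if (is.null(name)) basename(path) else name
  m
}

#' Bundled substitution score matrices
#'
#' The standard BLOSUM100 matrix (estimated from blocks of sequences at
#' >= 99% identity, so its scores reflect exchange rates between very
#' closely related proteins — the human/chimpanzee regime) and, for
#' ranking-robustness checks, the everyday BLOSUM62.
#'
#' @return 20 x 20 symmetric integer score matrix.
#' @export
blosum100 <- function() {
  read_score_matrix(system.file("extdata", "BLOSUM100.txt",
                                package = "humsub", mustWork = TRUE),
                    name = "BLOSUM100")
}

#' @rdname blosum100
#' @export
blosum62 <- function() {
  read_score_matrix(system.file("extdata", "BLOSUM62.txt",
                                package = "humsub", mustWork = TRUE),
                    name = "BLOSUM62")
}

#' Convert a score matrix into exchange-rareness weights
#'
#' Maps each off-diagonal score `s` to an integer weight so that the
#' most common exchanges (highest scores) get the minimum weight 3 and
#' the least common exchange (lowest score) the maximum weight 15.
#'
#' Two calibrations are offered:
#' \describe{
#'   \item{`affine` (default)}{`weight = clamp(round(intercept + slope * s),
#'     3, 15)`.  The frozen defaults `intercept = 5`, `slope = -1` were
#'     fit once against the 12 published PCDHB11 pair weights (see
#'     [pcdhb11_substitutions()]) and reproduce all 12 exactly on the
#'     bundled BLOSUM100.  On that matrix the least common exchange
#'     (score -10) maps to 15 and the handful of most-exchangeable pairs
#'     (scores 2..4) map to the floor weight 3.}
#'   \item{`rank`}{off-diagonal scores are first replaced by their ranks
#'     (average ties), then mapped linearly so the highest rank gives 3
#'     and the lowest 15.  Use this for exchangeability/rate matrices
#'     (e.g. JTT-derived) whose numeric scale differs from log-odds
#'     scores.}
#' }
#' Rounding is half-away-from-zero in both modes.
#'
#' @param matrix score matrix as returned by [read_score_matrix()].
#' @param method calibration, `"affine"` or `"rank"`.
#' @param slope,intercept affine calibration constants.
#' @param range weight range, default `c(3, 15)`.
#' @return object of class `weight_table`: list with `weights` (20 x 20
#'   symmetric integer matrix, diagonal `NA`), `alphabet`, `matrix_name`
#'   and `calibration`.
#' @export
derive_weights <- function(matrix, method = c("affine", "rank"),
                           slope = -1, intercept = 5, range = c(3L, 15L)) {
  method <- match.arg(method)
  aa <- rownames(matrix)
  off <- matrix[row(matrix) != col(matrix)]
  if (length(unique(off)) < 2L)
    abort("constant off-diagonal matrix: weight range is degenerate",
          "humsub_degenerate_matrix")
  if (method == "affine") {
    w <- round_half_away(intercept + slope * matrix)
  } else {
    r <- matrix
    r[] <- rank(matrix, ties.method = "average")
    rmax <- max(r[row(r) != col(r)]); rmin <- min(r[row(r) != col(r)])
    w <- round_half_away(range[1] + (range[2] - range[1]) * (rmax - r) / (rmax - rmin))
  }
  w <- pmin(pmax(w, range[1]), range[2])
  diag(w) <- NA_integer_
  structure(list(weights = w, alphabet = aa,
                 matrix_name = attr(matrix, "name"),
                 calibration = list(method = method, slope = slope,
                                    intercept = intercept, range = range)),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  off <- x$weights[!is.na(x$weights)]
  cat(sprintf("exchange-rareness weights from %s (%s calibration): range %d..%d\n",
              x$matrix_name %||% "matrix", x$calibration$method,
              min(off), max(off)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up the weight of an amino-acid exchange
#'
#' @param weights a `weight_table` from [derive_weights()].
#' @param a,b single residues (order irrelevant; the table is symmetric).
#' @return integer weight in the calibrated range.
#' @export
exchange_weight <- function(weights, a, b) {
  stopifnot(inherits(weights, "weight_table"))
  if (!all(c(a, b) %in% weights$alphabet))
    abort(sprintf("residue pair (%s, %s) not covered by the weight table",
                  a, b), "humsub_missing_pair")
  if (a == b)
    abort("identical residues are not an exchange", "humsub_missing_pair")
  weights$weights[a, b]
}

#' Score one protein from its fixed substitutions
#'
#' @param subs substitution data.frame (`ancestral`, `human` columns, as
#'   produced by [find_fixed_substitutions()]); may have zero rows.
#' @param length protein length in residues (>= 1).
#' @param weights a `weight_table`.
#' @param protein optional protein id carried into the result.
#' @return one-row data.frame with `protein`, `n_subst`, `length`,
#'   `subst_per_length`, `weighted_sum`, `weighted_per_length`.
#' @export
score_protein <- function(subs, length, weights, protein = NA_character_) {
  stopifnot(length >= 1L)
  n <- nrow(subs)
  ws <- if (n == 0L) 0L else
    sum(vapply(seq_len(n), function(i)
      exchange_weight(weights, subs$ancestral[i], subs$human[i]),
      numeric(1)))
  data.frame(protein = protein,
             n_subst = n,
             length = as.integer(length),
             subst_per_length = n / length,
             weighted_sum = ws,
             weighted_per_length = ws / length,
             stringsAsFactors = FALSE)
}

#' Rank proteins by a score column
#'
#' Stable descending sort; ties are broken by substitution count
#' (descending), then protein id (ascending).  Per-length ratios are
#' recomputed from the integer columns before sorting, so rankings do
#' not depend on rounded printed values.
#'
#' @param scores data.frame of protein scores (rows as from
#'   [score_protein()]).
#' @param key ranking key.
#' @return `scores` reordered, with a 1-based `rank` column prepended.
#' @export
rank_proteins <- function(scores,
                          key = c("weighted_per_length", "n_subst",
                                  "subst_per_length", "weighted_sum")) {
  key <- match.arg(key)
  scores$subst_per_length <- scores$n_subst / scores$length
  scores$weighted_per_length <- scores$weighted_sum / scores$length
  ord <- order(-scores[[key]], -scores$n_subst, scores$protein)
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Spearman correlation between two rankings
#'
#' @param r1,r2 character vectors giving the same set of ids in two
#'   orders.
#' @return Spearman rank correlation in `[-1, 1]`.
#' @export
compare_rankings <- function(r1, r2) {
  if (anyDuplicated(r1) || anyDuplicated(r2) ||
      !setequal(r1, r2) || length(r1) != length(r2))
    abort("rankings must order the same id set", "humsub_mismatched_ids")
  stats::cor(seq_along(r1), match(r1, r2), method = "spearman")
}
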