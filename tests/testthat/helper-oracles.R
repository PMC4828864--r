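# Independent oracles: deliberately naive re-implementations used to
# cross-check the package's vectorised code paths.

# per-column double-loop substitution scan
brute_scan <- function(panel, mode = "unanimous") {
  hum <- strsplit(unname(panel$human), "")
  out <- strsplit(unname(panel$outgroup), "")
  ref <- hum[[1]]
  hits <- list()
  pos <- 0L
  for (j in seq_len(panel$length)) {
    if (ref[j] != "-") pos <- pos + 1L
    col_h <- vapply(hum, `[`, character(1), j)
    col_o <- vapply(out, `[`, character(1), j)
    if (any(c(col_h, col_o) %in% c("-", "X"))) next
    if (length(unique(col_h)) != 1L) next
    if (mode == "unanimous") {
      if (length(unique(col_o)) != 1L) next
      anc <- col_o[1]
    } else {
      tab <- table(col_o)
      if (max(tab) < 2L) next
      anc <- names(tab)[which.max(tab)]
    }
    if (col_h[1] == anc) next
    hits[[length(hits) + 1L]] <- data.frame(position = pos, ancestral = anc,
                                            human = col_h[1],
                                            stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(position = integer(), ancestral = character(),
                      human = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# exhaustive perpendicular-distance search over the candidate bins
brute_triangle <- function(h) {
  nz <- which(h > 0)
  lo <- nz[1] - 1L; hi <- nz[length(nz)] - 1L
  peak <- which.max(h) - 1L
  if (lo == hi) return(lo)
  right <- (hi - peak) >= (peak - lo)
  end <- if (right) hi else lo
  if (end == peak) return(peak)
  x1 <- peak; y1 <- h[peak + 1L]; x2 <- end; y2 <- h[end + 1L]
  best <- NA_integer_; bestd <- -Inf
  bins <- if (right) seq(peak + 1L, end - 1L) else seq(peak - 1L, end + 1L)
  for (b in bins) {  # scanned outward from the peak: first max wins
    d <- abs((y2 - y1) * b - (x2 - x1) * h[b + 1L] + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
    if (d > bestd) { bestd <- d; best <- b }
  }
  min(max(best + if (right) 1L else -1L, 0L), 255L)
}

# random unimodal-ish histogram with a background spike and a tail
random_histogram <- function(seed) {
  set.seed(seed)
  h <- numeric(256)
  peak <- sample(5:80, 1)
  h[peak + 1] <- sample(500:5000, 1)
  tail_len <- sample(40:170, 1)
  tail_bins <- peak + seq_len(min(tail_len, 255 - peak))
  h[tail_bins + 1] <- sort(rpois(length(tail_bins), 30), decreasing = TRUE) +
    rpois(length(tail_bins), 3)
  lumps <- sample(tail_bins, min(3, length(tail_bins)))
  h[lumps + 1] <- h[lumps + 1] + sample(50:200, length(lumps), replace = TRUE)
  h
}

# queue-based flood fill component areas (8- or 4-connectivity)
flood_fill_areas <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8L)
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  areas <- integer()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- matrix(c(i, j), ncol = 2)
    seen[i, j] <- TRUE
    area <- 0L
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      area <- area + 1L
      for (k in seq_len(nrow(nb))) {
        x <- p[1] + nb[k, 1]; y <- p[2] + nb[k, 2]
        if (x >= 1 && x <= nr && y >= 1 && y <= nc &&
            mask[x, y] && !seen[x, y]) {
          seen[x, y] <- TRUE
          queue <- rbind(queue, c(x, y))
        }
      }
    }
    areas <- c(areas, area)
  }
  sort(areas)
}

# random small panel spec with planted substitutions
random_panel_spec <- function(seed, max_len = 60L, rate = NULL) {
  set.seed(seed)
  len <- sample(10:max_len, 1)
  n_plant <- sample(0:min(4, len), 1)
  pos <- sort(sample(len, n_plant))
  anc <- sample(humsub:::AA_ALPHABET, n_plant, replace = TRUE)
  hum <- vapply(anc, function(a)
    sample(setdiff(humsub:::AA_ALPHABET, a), 1), character(1))
  planted <- if (n_plant) data.frame(position = pos, ancestral = anc,
                                     human = unname(hum),
                                     stringsAsFactors = FALSE)
  panel_spec(protein_length = len,
             n_human_haplotypes = sample(c(2L, 5L, 20L), 1),
             planted_substitutions = planted,
             polymorphism_rate = if (is.null(rate)) sample(c(0, 0.01, 0.05), 1)
             else rate,
             seed = seed + 1000L)
}

# minimal TSV reader used by tests to recount written stage outputs
read_tsv2 <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}
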