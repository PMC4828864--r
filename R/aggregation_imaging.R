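# Quantification of cell-aggregation assay micrographs: triangle
# auto-thresholding, connected-component cluster areas, spherical-model
# cell-count cutoffs, size-class fractions, reference-normalised
# adhesive strength and two-channel mixed-cluster fractions.

#' Triangle auto-threshold of a 256-bin intensity histogram
#'
#' Geometric triangle method: a line is drawn from the histogram peak to
#' the far end of the nonzero range on the longer-tail side; the
#' threshold is the bin between them whose point `(bin, count)` lies
#' farthest (perpendicular distance) from that line, offset by one bin
#' toward the tail.  Conventions, frozen and documented: the peak is the
#' first maximal bin; the tail is the side with the larger peak-to-end
#' distance (tie: the brighter side); among equidistant bins the one
#' nearest the peak wins.
#'
#' @param histogram numeric vector of 256 non-negative counts for
#'   intensity bins 0..255.
#' @return threshold bin value in 0..255.  With a right (bright) tail,
#'   pixels strictly above the threshold are foreground.
#' @export
triangle_threshold <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0))
    abort("histogram must be 256 non-negative counts",
          "humsub_invalid_histogram")
  nz <- which(histogram > 0)
  if (!length(nz))
    abort("all-zero histogram", "humsub_empty_histogram")
  lo <- nz[1] - 1L; hi <- nz[length(nz)] - 1L      # bin values, 0-based
  peak <- which.max(histogram) - 1L
  if (lo == hi) return(lo)                          # single occupied bin
  right <- (hi - peak) >= (peak - lo)               # tie -> brighter side
  end <- if (right) hi else lo
  if (end == peak) return(peak)                     # peak sits at the end
  bins <- if (right) seq(peak + 1L, end - 1L) else seq(end + 1L, peak - 1L)
  if (!length(bins)) return(peak)
  # perpendicular distance from (b, h[b]) to the peak--end line
  x1 <- peak; y1 <- histogram[peak + 1L]
  x2 <- end;  y2 <- histogram[end + 1L]
  d <- abs((y2 - y1) * bins - (x2 - x1) * histogram[bins + 1L] +
             x2 * y1 - y2 * x1) / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  # scan outward from the peak so equidistant bins resolve nearest-peak
  ord <- order(abs(bins - peak))
  best <- bins[ord][which.max(d[ord])]
  thr <- best + if (right) 1L else -1L
  min(max(thr, 0L), 255L)
}

#' Histogram and threshold mask of an 8-bit channel image
#'
#' Convenience wrapper: builds the 256-bin histogram of an integer image
#' (values 0..255), applies [triangle_threshold()] and returns the
#' foreground mask.  Assumes dark background / bright cells, the
#' fluorescence convention.
#'
#' @param img integer matrix with values in 0..255.
#' @return list with `threshold` and logical `mask`.
#' @export
threshold_image <- function(img) {
  stopifnot(is.matrix(img), all(img >= 0 & img <= 255))
  h <- tabulate(as.integer(img) + 1L, nbins = 256L)
  thr <- triangle_threshold(h)
  list(threshold = thr, mask = img > thr)
}

# Connected-component labelling.  EBImage::bwlabel is 4-connected; for
# the default 8-connectivity, labels touching diagonally are merged with
# a union-find pass over diagonal neighbour pairs.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 4L || max(lab) == 0L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Extract cluster areas from a binary mask
#'
#' Connected components (8-connected by default, as in common
#' particle-analysis defaults; 4-connectivity available) with pixel area
#' at least `min_area`.
#'
#' @param mask logical or 0/1 matrix.
#' @param min_area minimum component area in pixels (default 100).
#' @param connectivity 8 or 4.
#' @return data.frame with `cluster` (label) and `area` (pixels).
#' @export
extract_clusters <- function(mask, min_area = 100L, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L)
    return(data.frame(cluster = integer(), area = integer()))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  data.frame(cluster = keep, area = as.integer(areas[keep]))
}

#' Spherical-model area cutoff for an N-cell cluster
#'
#' A cluster of `n_cells` close-packed cells is modelled as a sphere, so
#' its projected image area scales as the 2/3 power of cell count:
#' `round(single_cell_area * n_cells^(2/3))`.  With the 150 px single
#' cell this gives the canonical cutoffs 696 px (10 cells) and 1448 px
#' (30 cells).
#'
#' @param single_cell_area area of one cell in pixels.
#' @param n_cells cell count (>= 1).
#' @return area cutoff in pixels (integer-valued).
#' @examples
#' cell_count_cutoff(150, 10)  # 696
#' cell_count_cutoff(150, 30)  # 1448
#' @export
cell_count_cutoff <- function(single_cell_area, n_cells) {
  stopifnot(single_cell_area > 0, all(n_cells >= 1))
  round_half_away(single_cell_area * n_cells^(2 / 3))
}

#' Single-cell area as the mode of control cluster areas
#'
#' Histograms the areas of clusters from a control (non-adhesive)
#' condition and returns the centre of the most populated bin; ties go
#' to the smaller bin.
#'
#' @param control_areas cluster areas in pixels.
#' @param bin_width histogram bin width in pixels (default 10).
#' @return bin centre in pixels.
#' @export
mode_single_cell_area <- function(control_areas, bin_width = 10) {
  stopifnot(length(control_areas) >= 1, bin_width > 0)
  idx <- floor(control_areas / bin_width)
  tab <- table(idx)
  best <- min(as.integer(names(tab)[tab == max(tab)]))
  (best + 0.5) * bin_width
}

#' Classify cluster areas into size classes and summarise
#'
#' Size classes follow the spherical-model cutoffs: small `< 10` cells,
#' medium `10--30` cells (closed interval in area), large `> 30` cells.
#' `fraction_ge10`, the proportion of clusters with at least 10 cells,
#' is the per-condition adhesion readout.
#'
#' @param areas cluster areas in pixels (already min-area filtered).
#' @param single_cell_area single-cell area in pixels (default 150).
#' @return object of class `condition_summary`: list with `n_clusters`,
#'   `fraction_small`, `fraction_medium`, `fraction_large`,
#'   `fraction_ge10`, and the `cutoffs` used.
#' @export
classify_and_summarize <- function(areas, single_cell_area = 150) {
  if (!length(areas))
    abort("no cluster areas to summarise", "humsub_empty_clusters")
  c10 <- cell_count_cutoff(single_cell_area, 10)
  c30 <- cell_count_cutoff(single_cell_area, 30)
  small <- areas < c10
  large <- areas > c30
  medium <- !small & !large
  n <- length(areas)
  structure(list(n_clusters = n,
                 fraction_small = sum(small) / n,
                 fraction_medium = sum(medium) / n,
                 fraction_large = sum(large) / n,
                 fraction_ge10 = sum(medium | large) / n,
                 cutoffs = c(cells10 = c10, cells30 = c30)),
            class = "condition_summary")
}

#' Size class of each cluster area
#'
#' @inheritParams classify_and_summarize
#' @return character vector: `"small"`, `"medium"` or `"large"`.
#' @export
size_class <- function(areas, single_cell_area = 150) {
  c10 <- cell_count_cutoff(single_cell_area, 10)
  c30 <- cell_count_cutoff(single_cell_area, 30)
  ifelse(areas < c10, "small", ifelse(areas > c30, "large", "medium"))
}

#' Adhesive strength relative to a reference condition
#'
#' Ratio of `fraction_ge10` between a condition and its same-day,
#' same-fluorophore strongly-adhesive reference (PCDHGA3-style control),
#' removing day-to-day transfection variation.
#'
#' @param summary,reference `condition_summary` objects (or bare
#'   `fraction_ge10` numbers).
#' @return ratio (1 = as adhesive as the reference).
#' @export
adhesive_strength <- function(summary, reference) {
  f <- function(x) if (inherits(x, "condition_summary")) x$fraction_ge10 else x
  s <- f(summary); r <- f(reference)
  if (r <= 0)
    abort("reference condition has zero fraction of >=10-cell clusters",
          "humsub_zero_reference")
  s / r
}

#' Fraction of clusters mixing the green and red populations
#'
#' The two channel masks are combined (logical OR), connected components
#' of the union at least `min_area` pixels are enumerated, and each is
#' tested for overlap with each single-channel mask.  Mixed clusters —
#' containing thresholded pixels of both channels — indicate adhesion
#' between the two transfected populations.
#'
#' @param green_mask,red_mask logical matrices of equal shape.
#' @param min_area minimum union-component area (default 100).
#' @param connectivity 8 or 4.
#' @return proportion in `[0, 1]`, with attributes `n_clusters` and
#'   `n_mixed`.
#' @export
mixed_fraction <- function(green_mask, red_mask, min_area = 100L,
                           connectivity = 8L) {
  if (!identical(dim(green_mask), dim(red_mask)))
    abort("channel masks must have identical shape", "humsub_shape_mismatch")
  union <- green_mask | red_mask
  lab <- label_components(union, connectivity)
  if (max(lab) == 0L)
    abort("no clusters in the union mask", "humsub_empty_clusters")
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  if (!length(keep))
    abort("no clusters pass the minimum area", "humsub_empty_clusters")
  gl <- unique(lab[green_mask & lab > 0L])
  rl <- unique(lab[red_mask & lab > 0L])
  mixed <- sum(keep %in% gl & keep %in% rl)
  structure(mixed / length(keep),
            n_clusters = length(keep), n_mixed = mixed)
}

#' Statistical comparison of assay conditions
#'
#' For per-day normalised adhesive strengths: one-way ANOVA over
#' conditions followed by Tukey HSD on all pairwise contrasts.  For
#' two-channel mixing data: two-way ANOVA of the mixed fraction on the
#' identities of the two cell populations (with interaction), plus, in
#' each subpanel defined by the first population, linear-model contrasts
#' of every second population against a named control level with
#' Bonferroni correction.
#'
#' @param strengths data.frame with columns `condition` and `strength`
#'   (one row per replicate), or `NULL`.
#' @param mixing data.frame with columns `pop1`, `pop2`,
#'   `mixed_fraction`, or `NULL`.
#' @param control control level of `pop2` for the subpanel contrasts
#'   (required with `mixing`).
#' @return list with elements `anova` (F, p, Tukey table) and/or
#'   `mixing` (two-way ANOVA table and subpanel contrast table with raw
#'   and Bonferroni-adjusted p-values).
#' @export
condition_tests <- function(strengths = NULL, mixing = NULL, control = NULL) {
  out <- list()
  if (!is.null(strengths)) {
    strengths$condition <- factor(strengths$condition)
    if (nlevels(strengths$condition) < 2L ||
        min(table(strengths$condition)) < 2L)
      abort("need >= 2 conditions with >= 2 replicates each",
            "humsub_insufficient_replicates")
    fit <- stats::aov(strength ~ condition, data = strengths)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$condition
    out$anova <- list(
      F = an$`F value`[1], p = an$`Pr(>F)`[1],
      tukey = data.frame(contrast = rownames(tk),
                         diff = tk[, "diff"],
                         p_adj = tk[, "p adj"],
                         row.names = NULL, stringsAsFactors = FALSE))
  }
  if (!is.null(mixing)) {
    if (is.null(control))
      abort("mixing analysis needs a named control level", "humsub_no_control")
    mixing$pop1 <- factor(mixing$pop1)
    mixing$pop2 <- factor(mixing$pop2)
    if (nlevels(mixing$pop2) < 2L)
      abort("need >= 2 conditions with >= 2 replicates each",
            "humsub_insufficient_replicates")
    fit2 <- stats::aov(mixed_fraction ~ pop1 * pop2, data = mixing)
    an2 <- summary(fit2)[[1]]
    contrasts <- do.call(rbind, lapply(levels(mixing$pop1), function(p1) {
      sub <- mixing[mixing$pop1 == p1, , drop = FALSE]
      sub$pop2 <- stats::relevel(factor(as.character(sub$pop2)), ref = control)
      if (nlevels(sub$pop2) < 2L) return(NULL)
      cf <- summary(stats::lm(mixed_fraction ~ pop2, data = sub))$coefficients
      cf <- cf[grep("^pop2", rownames(cf)), , drop = FALSE]
      data.frame(subpanel = p1,
                 contrast = paste(sub("^pop2", "", rownames(cf)),
                                  "vs", control),
                 estimate = cf[, "Estimate"],
                 p = cf[, "Pr(>|t|)"],
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
    if (!is.null(contrasts) && nrow(contrasts)) {
      # Bonferroni within each subpanel, as for the per-subpanel panels
      contrasts$p_adj <- unlist(lapply(split(contrasts$p, contrasts$subpanel),
                                       stats::p.adjust, method = "bonferroni"),
                                use.names = FALSE)
      contrasts <- contrasts[order(contrasts$subpanel, contrasts$contrast), ]
      rownames(contrasts) <- NULL
    }
    out$mixing <- list(anova = data.frame(term = trimws(rownames(an2)),
                                          F = an2$`F value`,
                                          p = an2$`Pr(>F)`,
                                          row.names = NULL,
                                          stringsAsFactors = FALSE),
                       contrasts = contrasts)
  }
  out
}

#' Read / write an 8-bit grayscale channel image as PNG
#'
#' @param path PNG file.
#' @return integer matrix with values 0..255.
#' @export
read_channel_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' @rdname read_channel_png
#' @param img integer matrix, values 0..255.
#' @export
write_channel_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0L), 255L) / 255, path)
  invisible(path)
}
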