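# Seeded synthetic inputs with the statistical structure the pipeline
# assumes: ortholog panels with planted fixed substitutions, variant
# tables with known per-class totals, annotation tables, and two-channel
# cluster images obeying the spherical N^(2/3) area law with known
# ground truth.  Every generator takes an explicit seed and leaves the
# caller's RNG untouched.

#' Specification of a synthetic ortholog panel
#'
#' @param protein_length protein length in residues.
#' @param n_human_haplotypes number of human haplotype sequences
#'   (default 100, the panel size of the source comparison).
#' @param outgroup_names labels of the 3 outgroup species.
#' @param planted_substitutions data.frame (`position`, `ancestral`,
#'   `human`) of fixed differences to plant, or `NULL`.
#' @param polymorphism_rate per-site probability that a human haplotype
#'   carries a non-consensus residue at a non-planted site.
#' @param seed integer seed.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(protein_length, n_human_haplotypes = 100L,
                       outgroup_names = c("PTR", "PAB", "MML"),
                       planted_substitutions = NULL,
                       polymorphism_rate = 0, seed = 1L) {
  if (protein_length < 1L)
    abort("protein_length must be >= 1", "humsub_invalid_spec")
  if (n_human_haplotypes < 1L)
    abort("need at least one human haplotype", "humsub_invalid_spec")
  if (length(outgroup_names) != 3L)
    abort("exactly 3 outgroup names required", "humsub_invalid_spec")
  if (polymorphism_rate < 0 || polymorphism_rate > 1)
    abort("polymorphism_rate must be in [0, 1]", "humsub_invalid_spec")
  ps <- planted_substitutions
  if (is.null(ps))
    ps <- data.frame(position = integer(), ancestral = character(),
                     human = character(), stringsAsFactors = FALSE)
  if (nrow(ps)) {
    if (anyDuplicated(ps$position))
      abort("planted positions must be unique", "humsub_invalid_spec")
    if (any(ps$position < 1L | ps$position > protein_length))
      abort("planted position out of range", "humsub_invalid_spec")
    if (any(ps$ancestral == ps$human))
      abort("planted ancestral and human residues must differ",
            "humsub_invalid_spec")
    if (!all(c(ps$ancestral, ps$human) %in% AA_ALPHABET))
      abort("planted residues must be standard amino acids",
            "humsub_invalid_spec")
  }
  structure(list(protein_length = as.integer(protein_length),
                 n_human_haplotypes = as.integer(n_human_haplotypes),
                 outgroup_names = outgroup_names,
                 planted_substitutions = ps,
                 polymorphism_rate = polymorphism_rate,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a synthetic ortholog panel
#'
#' Draws a random consensus backbone, plants the specified fixed
#' differences (all human haplotypes carry the human residue, all
#' outgroups the ancestral one), and sprinkles haplotype-level
#' polymorphism at the given rate on non-planted sites only — so
#' planted fixation is never eroded by noise.  For negative tests,
#' `break_fixation = TRUE` flips the first haplotype to a third residue
#' at the first planted site, destroying its fixation.
#'
#' @param spec a [panel_spec()].
#' @param protein protein label.
#' @param break_fixation flip one haplotype at one planted site.
#' @return an [ortholog_panel].
#' @export
gen_ortholog_panel <- function(spec, protein = "synthetic",
                               break_fixation = FALSE) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    L <- spec$protein_length
    nh <- spec$n_human_haplotypes
    consensus <- sample(AA_ALPHABET, L, replace = TRUE)
    ps <- spec$planted_substitutions
    anc <- consensus; hum_base <- consensus
    if (nrow(ps)) {
      anc[ps$position] <- ps$ancestral
      hum_base[ps$position] <- ps$human
    }
    hum <- matrix(rep(hum_base, each = nh), nrow = nh)
    if (spec$polymorphism_rate > 0) {
      open <- setdiff(seq_len(L), ps$position)
      if (length(open)) {
        flip <- matrix(stats::runif(nh * length(open)) < spec$polymorphism_rate,
                       nrow = nh)
        idx <- which(flip, arr.ind = TRUE)
        if (nrow(idx)) {
          cols <- open[idx[, 2]]
          repl <- vapply(cols, function(j)
            sample(setdiff(AA_ALPHABET, hum_base[j]), 1L), character(1))
          hum[cbind(idx[, 1], cols)] <- repl
        }
      }
    }
    if (break_fixation) {
      if (!nrow(ps))
        abort("break_fixation needs at least one planted site",
              "humsub_invalid_spec")
      p1 <- ps$position[1]
      hum[1, p1] <- setdiff(AA_ALPHABET, c(ps$ancestral[1], ps$human[1]))[1]
    }
    human_seqs <- apply(hum, 1L, paste, collapse = "")
    names(human_seqs) <- sprintf("HUM_%03d", seq_len(nh))
    anc_seq <- paste(anc, collapse = "")
    out <- setNames(rep(anc_seq, 3L), spec$outgroup_names)
    ortholog_panel(protein, human_seqs, out)
  })
}

#' Generate a synthetic per-variant table
#'
#' One row per variant, with consequence classes drawn so per-gene class
#' totals equal `class_counts` exactly; row order is shuffled under the
#' seed.
#'
#' @param class_counts named list: for each gene, a named integer vector
#'   of counts over the consequence classes `missense`, `nonsense`,
#'   `stop_lost`, `frameshift`, `synonymous`, `intron`, `other`.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `class`.
#' @export
gen_variant_table <- function(class_counts, seed = 1L) {
  rows <- lapply(names(class_counts), function(g) {
    cc <- class_counts[[g]]
    bad <- setdiff(names(cc), VARIANT_CLASSES)
    if (length(bad))
      abort(paste0("unknown consequence class(es): ",
                   paste(bad, collapse = ", ")), "humsub_unknown_class")
    if (any(cc < 0))
      abort("class counts must be >= 0", "humsub_invalid_spec")
    data.frame(gene = g, class = rep(names(cc), times = cc),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(data.frame(gene = character(),
                                               class = character(),
                                               stringsAsFactors = FALSE))))
  if (nrow(df))
    df <- with_seed(seed, df[sample.int(nrow(df)), , drop = FALSE])
  rownames(df) <- NULL
  df
}

#' Build an annotation table from explicit entries
#'
#' Normalises and validates entries into the annotation-table layout
#' that [read_annotations()] / [write_annotations()] round-trip.
#'
#' @param entries data.frame with `id`, `accession` and `terms` (list
#'   column of character vectors, or pipe-joined strings).
#' @return annotation data.frame with pipe-joined `terms`.
#' @export
gen_go_table <- function(entries) {
  stopifnot(all(c("id", "accession", "terms") %in% names(entries)))
  if (anyDuplicated(entries$id))
    abort("annotation ids must be unique", "humsub_duplicate_id")
  if (any(nchar(entries$accession) < 3L))
    abort("accession codes must have >= 3 characters", "humsub_invalid_spec")
  terms <- if (is.list(entries$terms))
    vapply(entries$terms, paste, character(1), collapse = "|")
  else as.character(entries$terms)
  data.frame(id = entries$id, accession = entries$accession, terms = terms,
             stringsAsFactors = FALSE)
}

#' Random annotation entries for filter testing
#'
#' Draws proteins with random 6-character accession codes (first three
#' letters define the family) and random GO term sets from a pool that
#' mixes membrane terms, qualifying neural terms and excluded
#' near-misses, at controllable rates.
#'
#' @param n number of proteins.
#' @param seed integer seed.
#' @param p_membrane probability a protein carries a membrane term.
#' @param p_neural probability it carries a qualifying neural term.
#' @param p_excluded probability it carries an excluded neural-like term.
#' @param n_families approximate number of accession families.
#' @return entries data.frame suitable for [gen_go_table()].
#' @export
random_annotation_entries <- function(n, seed = 1L, p_membrane = 0.5,
                                      p_neural = 0.5, p_excluded = 0.2,
                                      n_families = max(1L, n %/% 4L)) {
  neural_pool <- c("neuron projection", "axon guidance", "synapse assembly",
                   "dendrite morphogenesis", "nervous system development")
  excluded_pool <- c("synaptonemal complex", "axonemal dynein complex",
                     "dendritic cell differentiation",
                     "neuron migration in enteric nervous system")
  other_pool <- c("cytoplasm", "nucleus", "protein binding", "ion transport")
  with_seed(seed, {
    fam <- replicate(n_families,
                     paste(sample(LETTERS, 3L, replace = TRUE), collapse = ""))
    acc <- paste0(sample(fam, n, replace = TRUE),
                  sprintf("%03d", sample.int(999L, n, replace = TRUE)))
    terms <- lapply(seq_len(n), function(i) {
      t <- sample(other_pool, sample.int(2L, 1L))
      if (stats::runif(1) < p_membrane) t <- c(t, MEMBRANE_TERMS[sample.int(2L, 1L)])
      if (stats::runif(1) < p_neural) t <- c(t, sample(neural_pool, 1L))
      if (stats::runif(1) < p_excluded) t <- c(t, sample(excluded_pool, 1L))
      unique(t)
    })
    data.frame(id = sprintf("PROT%04d", seq_len(n)),
               accession = acc,
               terms = I(terms),
               stringsAsFactors = FALSE)
  })
}

#' Specification of a synthetic two-channel cluster image
#'
#' @param image_size image side length in pixels (square image).
#' @param single_cell_area projected area of one cell in pixels
#'   (default 150).
#' @param cluster_count number of clusters to place.
#' @param cell_count_distribution named list: `name` one of
#'   `"geometric"` (zero-truncated, parameter `prob`) or `"fixed"`
#'   (parameter `value`); cells per cluster.
#' @param channel_mix_rate probability a cluster contains cells of both
#'   channels.
#' @param background_level,foreground_level 8-bit intensities
#'   (foreground must exceed background).
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param seed integer seed.
#' @return object of class `image_spec`.
#' @export
image_spec <- function(image_size = 512L, single_cell_area = 150,
                       cluster_count = 20L,
                       cell_count_distribution = list(name = "geometric",
                                                      prob = 0.15),
                       channel_mix_rate = 0,
                       background_level = 20, foreground_level = 220,
                       noise_sd = 2, seed = 1L) {
  if (single_cell_area <= 0)
    abort("single_cell_area must be > 0", "humsub_invalid_spec")
  if (channel_mix_rate < 0 || channel_mix_rate > 1)
    abort("channel_mix_rate must be in [0, 1]", "humsub_invalid_spec")
  if (foreground_level <= background_level)
    abort("foreground_level must exceed background_level",
          "humsub_invalid_spec")
  if (!cell_count_distribution$name %in% c("geometric", "fixed"))
    abort("unknown cell count distribution", "humsub_invalid_spec")
  structure(list(image_size = as.integer(image_size),
                 single_cell_area = single_cell_area,
                 cluster_count = as.integer(cluster_count),
                 cell_count_distribution = cell_count_distribution,
                 channel_mix_rate = channel_mix_rate,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "image_spec")
}

# draw cells-per-cluster counts under the spec's distribution
draw_cell_counts <- function(dist, n) {
  switch(dist$name,
         geometric = 1L + stats::rgeom(n, dist$prob),  # zero-truncated
         fixed = rep(as.integer(dist$value), n))
}

# Exact-area disk rasterisation: the `area` pixels nearest the centre
# (ties resolved by row then column) form the cluster, so every
# ground-truth area matches round(single_cell_area * N^(2/3)) exactly.
disk_pixels <- function(cx, cy, area) {
  r <- ceiling(sqrt(area / pi)) + 2L
  xs <- (cx - r):(cx + r); ys <- (cy - r):(cy + r)
  grid <- expand.grid(x = xs, y = ys)
  d2 <- (grid$x - cx)^2 + (grid$y - cy)^2
  ord <- order(d2, grid$x, grid$y)
  grid[ord[seq_len(area)], ]
}

#' Generate a synthetic two-channel cluster image with ground truth
#'
#' Places non-overlapping disk-shaped clusters whose pixel areas follow
#' the spherical law `round(single_cell_area * N^(2/3))` for drawn cell
#' count `N`.  Each cluster belongs to the green or red channel, or —
#' with probability `channel_mix_rate` — to both (its pixels are split
#' between the channels).  Gaussian noise is added and intensities are
#' clamped to 0..255.
#'
#' @param spec an [image_spec()].
#' @param max_attempts placement attempts per cluster before giving up.
#' @return list with integer matrices `green` and `red` (0..255) and
#'   `truth`: data.frame (`cluster`, `cx`, `cy`, `n_cells`, `area`,
#'   `has_green`, `has_red`).
#' @export
gen_cluster_image <- function(spec, max_attempts = 500L) {
  stopifnot(inherits(spec, "image_spec"))
  with_seed(spec$seed, {
    S <- spec$image_size
    n <- spec$cluster_count
    ncell <- draw_cell_counts(spec$cell_count_distribution, n)
    areas <- as.integer(round_half_away(spec$single_cell_area * ncell^(2 / 3)))
    radii <- sqrt(areas / pi)
    # place largest first; centres kept far enough apart that 8-connected
    # components never merge (gap >= 2 px between disk boundaries)
    ord <- order(-areas)
    cx <- cy <- numeric(n)
    for (k in ord) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        m <- ceiling(radii[k]) + 3
        x <- stats::runif(1, m, S - m); y <- stats::runif(1, m, S - m)
        prev <- ord[seq_len(which(ord == k) - 1L)]
        if (!length(prev) ||
            all(sqrt((cx[prev] - x)^2 + (cy[prev] - y)^2) >
                radii[prev] + radii[k] + 4)) {
          cx[k] <- x; cy[k] <- y; placed <- TRUE; break
        }
      }
      if (!placed)
        abort(sprintf("could not place cluster of area %d in a %d x %d image",
                      areas[k], S, S), "humsub_placement_failed")
    }
    mixed <- stats::runif(n) < spec$channel_mix_rate
    solo_green <- stats::runif(n) < 0.5
    green <- matrix(FALSE, S, S); red <- matrix(FALSE, S, S)
    truth <- data.frame(cluster = seq_len(n),
                        cx = round(cx), cy = round(cy),
                        n_cells = ncell, area = areas,
                        has_green = mixed | solo_green,
                        has_red = mixed | !solo_green)
    for (k in seq_len(n)) {
      px <- disk_pixels(round(cx[k]), round(cy[k]), areas[k])
      idx <- cbind(px$x, px$y)
      if (mixed[k]) {
        # split by x-coordinate: left part green, right part red,
        # both halves guaranteed non-empty
        cut <- stats::median(px$x)
        g <- px$x <= cut
        if (all(g)) g[which.max(px$x)] <- FALSE
        if (!any(g)) g[which.min(px$x)] <- TRUE
        green[idx[g, , drop = FALSE]] <- TRUE
        red[idx[!g, , drop = FALSE]] <- TRUE
      } else if (solo_green[k]) {
        green[idx] <- TRUE
      } else {
        red[idx] <- TRUE
      }
    }
    render <- function(mask) {
      base <- ifelse(mask, spec$foreground_level, spec$background_level)
      noisy <- base + stats::rnorm(length(base), 0, spec$noise_sd)
      matrix(as.integer(pmin(pmax(round(noisy), 0), 255)), S, S)
    }
    list(green = render(green), red = render(red), truth = truth)
  })
}

#' Cell-count size class from a cluster area
#'
#' Inverse of the spherical model at the published class boundaries:
#' `"small"` below the 10-cell cutoff, `"medium"` up to the 30-cell
#' cutoff, `"large"` beyond.
#'
#' @param area cluster area(s) in pixels.
#' @param single_cell_area single-cell area in pixels.
#' @return character vector of size classes.
#' @export
cell_count_from_area <- function(area, single_cell_area = 150) {
  size_class(area, single_cell_area)
}
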