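test_that("triangle threshold matches the exhaustive distance oracle", {
  # single spike + monotone tail
  h <- numeric(256)
  h[11] <- 1000
  h[12:201] <- round(seq(300, 1, length.out = 190))
  expect_equal(triangle_threshold(h), brute_triangle(h))
  # assorted seeded histograms
  for (seed in 1:25) {
    rh <- random_histogram(seed)
    expect_equal(triangle_threshold(rh), brute_triangle(rh),
                 label = paste("seed", seed))
  }
})

test_that("two-level images threshold strictly between the two levels", {
  set.seed(5)
  img <- matrix(20L, 64, 64)
  img[10:25, 10:25] <- 220L
  h <- tabulate(as.integer(img) + 1L, nbins = 256)
  thr <- triangle_threshold(h)
  expect_gt(thr, 20)
  expect_lt(thr, 220)
  tm <- threshold_image(img)
  expect_equal(sum(tm$mask), 16 * 16)
})

test_that("triangle threshold is deterministic on symmetric histograms", {
  h <- numeric(256)
  h[91:111] <- dnorm(seq(-2, 2, length.out = 21)) * 1000  # symmetric bump
  t1 <- triangle_threshold(h)
  expect_identical(t1, triangle_threshold(h))
  expect_gt(t1, 100)  # tie resolved toward the brighter side
  expect_error(triangle_threshold(numeric(256)),
               class = "humsub_empty_histogram")
  one <- numeric(256); one[43] <- 10
  expect_equal(triangle_threshold(one), 42)  # single occupied bin
})

test_that("cluster extraction enforces the minimum area", {
  mask <- matrix(FALSE, 40, 40)
  mask[2:11, 2:6] <- TRUE              # 50 px
  mask[20:34, 20:29] <- TRUE           # 150 px
  cl <- extract_clusters(mask, min_area = 100)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$area, 150L)
  expect_equal(nrow(extract_clusters(matrix(FALSE, 5, 5))), 0L)
})

test_that("component areas equal the flood-fill oracle at both connectivities", {
  set.seed(12)
  for (i in 1:5) {
    mask <- matrix(runif(45 * 45) < 0.35, 45, 45)
    for (conn in c(8L, 4L)) {
      got <- sort(extract_clusters(mask, min_area = 1, connectivity = conn)$area)
      expect_equal(got, flood_fill_areas(mask, conn),
                   label = paste("iter", i, "conn", conn))
    }
  }
})

test_that("diagonal touches merge under 8- but not 4-connectivity", {
  mask <- matrix(FALSE, 6, 6)
  mask[2, 2] <- TRUE; mask[3, 3] <- TRUE
  expect_equal(extract_clusters(mask, min_area = 1, connectivity = 8)$area, 2L)
  expect_equal(extract_clusters(mask, min_area = 1, connectivity = 4)$area,
               c(1L, 1L))
})

test_that("spherical cutoffs hit the published values and scale correctly", {
  expect_equal(cell_count_cutoff(150, 10), 696)
  expect_equal(cell_count_cutoff(150, 30), 1448)
  expect_equal(cell_count_cutoff(123, 1), 123)
  # strictly increasing in cell count, linear in single-cell area
  cuts <- cell_count_cutoff(150, 1:40)
  expect_true(all(diff(cuts) > 0))
  expect_equal(cell_count_cutoff(300, 10), 2 * round(2 * 150 * 10^(2 / 3)) / 2,
               tolerance = 1e-9)
  expect_equal(cell_count_cutoff(2 * 150, 8), 2 * cell_count_cutoff(150, 8))
})

test_that("mode cluster size picks the heaviest histogram bin", {
  set.seed(3)
  areas <- c(round(rnorm(300, 150, 4)), round(rnorm(40, 700, 30)))
  m <- mode_single_cell_area(areas)
  expect_lte(abs(m - 150), 5)
  expect_equal(mode_single_cell_area(37), 35)   # single area: its bin centre
  # bimodal with a known heavier mode
  bi <- c(rep(100, 30), rep(400, 70))
  expect_equal(mode_single_cell_area(bi), 405)
  # tie broken toward the smaller bin
  tie <- c(rep(100, 10), rep(400, 10))
  expect_equal(mode_single_cell_area(tie), 105)
})

test_that("size classes partition areas at the 696/1448 boundaries", {
  s <- classify_and_summarize(c(150, 700, 1500), 150)
  expect_equal(s$fraction_small, 1 / 3)
  expect_equal(s$fraction_medium, 1 / 3)
  expect_equal(s$fraction_large, 1 / 3)
  expect_equal(s$fraction_ge10, 2 / 3)
  expect_equal(s$fraction_small + s$fraction_medium + s$fraction_large, 1,
               tolerance = 1e-9)
  all_small <- classify_and_summarize(c(100, 200, 695), 150)
  expect_equal(all_small$fraction_small, 1)
  expect_equal(all_small$fraction_ge10, 0)
  # boundary convention: medium is closed at both cutoffs
  expect_equal(size_class(c(695, 696, 1448, 1449), 150),
               c("small", "medium", "medium", "large"))
  expect_error(classify_and_summarize(numeric(0)),
               class = "humsub_empty_clusters")
})

test_that("adhesive strength is the ratio of >=10-cell fractions", {
  expect_equal(adhesive_strength(0.2, 0.4), 0.5)
  s <- classify_and_summarize(c(150, 700, 1500), 150)
  expect_equal(adhesive_strength(s, s), 1.0)
  expect_error(adhesive_strength(0.2, 0), class = "humsub_zero_reference")
})

test_that("mixed fraction handles the degenerate layouts and is symmetric", {
  g <- matrix(FALSE, 60, 60); r <- matrix(FALSE, 60, 60)
  g[2:13, 2:13] <- TRUE                       # green-only, 144 px
  r[30:41, 30:41] <- TRUE                     # red-only, 144 px
  expect_equal(as.numeric(mixed_fraction(g, r)), 0)
  both_g <- g | r                             # every cluster has both
  expect_equal(as.numeric(mixed_fraction(both_g, both_g)), 1)
  mf1 <- mixed_fraction(g, r); mf2 <- mixed_fraction(r, g)
  expect_equal(as.numeric(mf1), as.numeric(mf2))
  expect_error(mixed_fraction(g, matrix(FALSE, 10, 10)),
               class = "humsub_shape_mismatch")
  expect_error(mixed_fraction(matrix(FALSE, 20, 20), matrix(FALSE, 20, 20)),
               class = "humsub_empty_clusters")
})

test_that("touching green and red blobs form one mixed union cluster", {
  g <- matrix(FALSE, 40, 40); r <- matrix(FALSE, 40, 40)
  g[5:16, 5:16] <- TRUE
  r[5:16, 17:28] <- TRUE   # adjacent: union is a single component
  mf <- mixed_fraction(g, r)
  expect_equal(as.numeric(mf), 1)
  expect_equal(attr(mf, "n_clusters"), 1L)
})

test_that("condition tests separate distinct means and not duplicated ones", {
  set.seed(44)
  strengths <- data.frame(
    condition = rep(c("none", "weak", "strong"), each = 4),
    strength = c(rnorm(4, 0.1, 0.05), rnorm(4, 0.5, 0.05),
                 rnorm(4, 1.0, 0.05)))
  rep_ <- condition_tests(strengths = strengths)
  expect_lt(rep_$anova$p, 0.05)
  expect_true(all(rep_$anova$tukey$p_adj < 0.05))
  # a condition duplicated under two labels: its Tukey contrast is ~1
  set.seed(45)
  base <- rnorm(8, 0.5, 0.05)
  dup <- data.frame(condition = rep(c("a", "b", "c"), each = 4),
                    strength = c(base[1:4], base[1:4], rnorm(4, 1.2, 0.05)))
  rep2 <- condition_tests(strengths = dup)
  ab <- rep2$anova$tukey$p_adj[rep2$anova$tukey$contrast == "b-a"]
  expect_gt(ab, 0.95)
  expect_error(condition_tests(strengths = data.frame(condition = "x",
                                                      strength = 1)),
               class = "humsub_insufficient_replicates")
})

test_that("mixing analysis reports two-way effects and Bonferroni contrasts", {
  set.seed(46)
  pops <- c("ctrl", "B11", "GA3")
  grid <- expand.grid(pop1 = pops, pop2 = pops, rep = 1:6,
                      stringsAsFactors = FALSE)
  # mutual adhesion only for matching protocadherins
  mu <- ifelse(grid$pop1 == grid$pop2 & grid$pop1 != "ctrl", 0.6, 0.05)
  grid$mixed_fraction <- pmin(pmax(rnorm(nrow(grid), mu, 0.04), 0), 1)
  rep_ <- condition_tests(mixing = grid, control = "ctrl")
  an <- rep_$mixing$anova
  expect_lt(an$p[an$term == "pop1:pop2"], 1e-4)
  cons <- rep_$mixing$contrasts
  expect_true(all(c("p", "p_adj") %in% names(cons)))
  expect_true(all(cons$p_adj >= cons$p - 1e-12))
  # in the B11 subpanel, B11-vs-ctrl is significant after correction
  hit <- cons$p_adj[cons$subpanel == "B11" & grepl("^B11", cons$contrast)]
  expect_lt(hit, 0.01)
  expect_error(condition_tests(mixing = grid),
               class = "humsub_no_control")
})

test_that("channel images round-trip through 8-bit PNG", {
  set.seed(50)
  img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  path <- tempfile(fileext = ".png")
  on.exit(unlink(path))
  write_channel_png(img, path)
  expect_equal(read_channel_png(path), img)
})
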