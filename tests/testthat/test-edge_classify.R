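grid_vals <- c(-0.3, -0.1, -0.04, 0, 0.04, 0.1, 0.3)

test_that("band_sign applies the open noise band with inclusive boundaries", {
  expect_identical(band_sign(0.04), "Z")   # inside the band: effectively zero
  expect_identical(band_sign(0.05), "P")   # boundary counts as meaningful
  expect_identical(band_sign(-0.05), "N")
  expect_identical(band_sign(-0.2), "N")
  expect_identical(band_sign(c(0.3, 0, -0.049)), c("P", "Z", "Z"))
  expect_error(band_sign(0.1, threshold = 0), "positive")
  expect_error(band_sign(NA_real_), "finite")
})

test_that("band_sign mirrors under negation (P <-> N, Z fixed)", {
  z <- seq(-0.3, 0.3, by = 0.01)
  mirrored <- chartr("PN", "NP", band_sign(z))
  expect_identical(band_sign(-z), mirrored)
})

test_that("cross-sectional classification matches the enumerated decision table", {
  grid <- expand.grid(mean_a = grid_vals, mean_b = grid_vals)
  got <- classify_cross_sectional(grid$mean_a, grid$mean_b,
                                  rep(TRUE, nrow(grid)))
  want <- mapply(cross_sectional_oracle, grid$mean_a, grid$mean_b)
  expect_identical(got, unname(want))
  # spec examples
  expect_identical(classify_cross_sectional(0.3, 0.1, TRUE),
                   "stronger_positive_in_A")
  expect_identical(classify_cross_sectional(-0.3, -0.1, TRUE),
                   "stronger_negative_in_A")
  expect_identical(classify_cross_sectional(0.02, -0.01, TRUE),
                   "indeterminate")
  # double-match tie-breaks: larger |mean| wins, positive preferred on ties
  expect_identical(classify_cross_sectional(0.1, -0.3, TRUE),
                   "stronger_negative_in_B")
  expect_identical(classify_cross_sectional(0.3, -0.1, TRUE),
                   "stronger_positive_in_A")
  expect_identical(classify_cross_sectional(0.2, -0.2, TRUE),
                   "stronger_positive_in_A")
  # non-significant edges get the sentinel
  expect_identical(classify_cross_sectional(0.3, 0.1, FALSE), "not_classified")
})

test_that("longitudinal classification matches the enumerated decision table", {
  grid <- expand.grid(mean_pre = grid_vals, mean_post = grid_vals)
  got <- classify_longitudinal(grid$mean_pre, grid$mean_post,
                               rep(TRUE, nrow(grid)))
  want <- mapply(longitudinal_oracle, grid$mean_pre, grid$mean_post)
  expect_identical(got, unname(want))
  expect_identical(classify_longitudinal(0.1, 0.3, TRUE), "more_positive")
  expect_identical(classify_longitudinal(-0.1, -0.3, TRUE), "more_negative")
  expect_identical(classify_longitudinal(0.04, -0.04, TRUE), "indeterminate")
  expect_identical(classify_longitudinal(0.2, -0.2, TRUE), "sign_transition")
  expect_identical(classify_longitudinal(0.3, 0.04, TRUE), "less_positive")
  expect_identical(classify_longitudinal(-0.3, -0.04, TRUE), "less_negative")
})

test_that("categories partition every significant set", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(5:80, 1)
    ma <- rnorm(n, sd = 0.2); mb <- rnorm(n, sd = 0.2)
    sig <- runif(n) < 0.6
    cats <- classify_cross_sectional(ma, mb, sig)
    expect_identical(sum(cats != "not_classified"), sum(sig))
    tally <- count_categories(cats, levels = fccontrast:::CROSS_SECTIONAL_CATEGORIES)
    expect_identical(sum(tally$count), sum(sig))
    cats_l <- classify_longitudinal(ma, mb, sig)
    tally_l <- count_categories(cats_l, levels = fccontrast:::LONGITUDINAL_CATEGORIES)
    expect_identical(sum(tally_l$count), sum(sig))
  }
})

test_that("count_categories computes counts and proportions", {
  tally <- count_categories(c("stronger_positive_in_A", "stronger_positive_in_A",
                              "stronger_positive_in_B", "indeterminate"))
  expect_equal(tally$count[tally$category == "stronger_positive_in_A"], 2L)
  expect_equal(tally$proportion[tally$category == "stronger_positive_in_A"], 0.5)
  expect_equal(sum(tally$proportion), 1)
  empty <- count_categories(character(0))
  expect_equal(sum(empty$count), 0L)
})

test_that("pair aggregation fills symmetric cells and conserves totals", {
  meta <- region_meta(
    region_id = 0:3, name = paste0("r", 0:3),
    hemisphere = c("Left", "Right", "Left", "Right"),
    lobe = c("Frontal", "Limbic", "Temporal", "Frontal"),
    network = c("Default Mode", "Salience", "Auditory", "Visual")
  )
  # 2 Frontal-Limbic edges, 1 Frontal-Temporal, 1 Frontal-Frontal (diagonal)
  edges <- data.frame(edge_i = c(0L, 3L, 0L, 0L), edge_j = c(1L, 1L, 2L, 3L),
                      weight = c(1, 2, 3, 4))
  pt <- aggregate_pairs(edges, meta, "lobe")
  expect_equal(pt$count["Frontal", "Limbic"], 2L)
  expect_equal(pt$count["Limbic", "Frontal"], 2L)
  expect_equal(pt$count["Frontal", "Temporal"], 1L)
  expect_equal(pt$count["Frontal", "Frontal"], 1L)
  ut <- upper.tri(pt$count, diag = TRUE)
  expect_equal(sum(pt$count[ut]), nrow(edges))
  expect_equal(sum(pt$weight[ut]), sum(edges$weight))
  expect_error(aggregate_pairs(data.frame(edge_i = 0L, edge_j = 9L, weight = 1),
                               meta, "lobe"), "unknown region_id")
})

test_that("aggregation conserves counts and weight at every level", {
  set.seed(42)
  meta <- make_parcellation(20, seed = 6)
  for (rep in 1:10) {
    n_edges <- sample(1:40, 1)
    et <- edge_table(20)
    pick <- sample(nrow(et), n_edges)
    edges <- data.frame(et[pick, ], weight = runif(n_edges))
    for (lv in c("hemisphere", "lobe", "network")) {
      pt <- aggregate_pairs(edges, meta, lv)
      expect_equal(pt$count, t(pt$count))
      ut <- upper.tri(pt$count, diag = TRUE)
      expect_equal(sum(pt$count[ut]), n_edges)
      expect_equal(sum(pt$weight[ut]), sum(edges$weight), tolerance = 1e-12)
    }
  }
})

test_that("hub table satisfies star-graph and handshake identities", {
  meta <- make_parcellation(8, seed = 7)
  star <- data.frame(edge_i = c(0L, 0L, 0L), edge_j = c(1L, 2L, 3L),
                     weight = c(1, 1, 1))
  hubs <- hub_table(star, meta)
  expect_equal(hubs$n_connections[hubs$region_id == 0], 3L)
  expect_true(all(hubs$n_connections[hubs$region_id != 0] == 1L))
  expect_equal(hubs$region_id[1], 0L)  # sorted by degree descending
  expect_equal(sum(hubs$n_connections), 2L * nrow(star))

  expect_equal(nrow(hub_table(star[0, ], meta)), 0L)

  # handshake on a random 20-edge fixture; strongest partner by brute force
  set.seed(43)
  et <- edge_table(8)
  pick <- sample(nrow(et), 20)
  edges <- data.frame(et[pick, ], weight = runif(20))
  hubs2 <- hub_table(edges, meta)
  expect_equal(sum(hubs2$n_connections), 40L)
  for (k in seq_len(nrow(hubs2))) {
    id <- hubs2$region_id[k]
    touching <- edges[edges$edge_i == id | edges$edge_j == id, ]
    expect_equal(hubs2$n_connections[k], nrow(touching))
    expect_equal(hubs2$total_weight[k], sum(touching$weight), tolerance = 1e-12)
    best <- touching[which.max(touching$weight), ]
    expect_equal(hubs2$strongest_partner[k],
                 if (best$edge_i == id) best$edge_j else best$edge_i)
  }
})

test_that("chord export writes each unordered pair once and round-trips", {
  meta <- region_meta(
    region_id = 0:3, name = paste0("r", 0:3),
    hemisphere = rep(c("Left", "Right"), 2),
    lobe = c("Frontal", "Limbic", "Temporal", "Frontal"),
    network = rep("Visual", 4)
  )
  edges <- data.frame(edge_i = c(0L, 3L, 0L), edge_j = c(1L, 1L, 2L),
                      weight = c(1, 2, 3))
  pt <- aggregate_pairs(edges, meta, "lobe")
  f <- tempfile(fileext = ".tsv")
  export_chord_table(pt, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 2)  # Frontal-Limbic and Frontal-Temporal
  for (k in seq_len(nrow(back))) {
    expect_equal(back$count[k], pt$count[back$from_label[k], back$to_label[k]])
    expect_equal(back$weight[k], pt$weight[back$from_label[k], back$to_label[k]],
                 tolerance = 1e-12)
  }
  # empty table: header-only file
  empty <- aggregate_pairs(edges[0, ], meta, "lobe")
  f2 <- tempfile(fileext = ".tsv")
  export_chord_table(empty, f2)
  expect_equal(nrow(read.delim(f2)), 0)
  expect_length(readLines(f2), 1L)
})

test_that("classify_edges joins categories with region labels", {
  set.seed(44)
  meta <- make_parcellation(10, seed = 8)
  a <- cohort_around(rep(0.4, 45), 6, 10, sd = 0.05, prefix = "a")
  b <- cohort_around(rep(0.1, 45), 6, 10, sd = 0.05, prefix = "b")
  con <- edgewise_group_contrast(a, b)
  cls <- classify_edges(con, meta)
  expect_equal(nrow(cls), sum(con$significant))
  expect_true(all(cls$category == "stronger_positive_in_A"))
  expect_true(all(cls$lobe_i %in% LOBES) && all(cls$network_j %in% NETWORKS))
})
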