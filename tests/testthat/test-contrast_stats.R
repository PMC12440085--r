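test_that("bh_fdr reproduces the hand-computed step-up and its edge cases", {
  res <- bh_fdr(c(0.01, 0.02, 0.04, 0.5))
  expect_equal(res$q, c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_identical(res$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(rep(1, 5))$q, rep(1, 5))
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  expect_equal(bh_fdr(0.3)$q, 0.3)  # m = 1 identity
  expect_error(bh_fdr(c(0.1, 1.2)), "invalid p-value")
  expect_error(bh_fdr(c(0.1, NA)), "invalid p-value")
})

test_that("bh_fdr agrees with a from-definition step-up oracle", {
  set.seed(21)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)$q
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone non-decreasing along sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("grouped_bh_fdr applies BH independently within labels", {
  p4 <- c(0.01, 0.02, 0.04, 0.5)
  q4 <- c(0.04, 0.04, 0.04 * 4 / 3, 0.5)
  res <- grouped_bh_fdr(c(p4, p4), rep(c("g1", "g2"), each = 4))
  expect_equal(res$q, c(q4, q4), tolerance = 1e-12)
  # degenerate grouping equals plain BH
  expect_equal(grouped_bh_fdr(p4, rep("all", 4))$q, bh_fdr(p4)$q)
  # singleton groups leave p unchanged
  expect_equal(grouped_bh_fdr(p4, letters[1:4])$q, p4)
  expect_error(grouped_bh_fdr(p4, "a"), "same length")
})

test_that("pooled t on the 2-vs-2 fixture matches the closed-form t(2) CDF", {
  tt <- interaction_delta_test(c(0.2, 0.4), c(0.0, 0.2))
  expect_equal(tt$statistic, sqrt(2), tolerance = 1e-10)
  expect_equal(tt$df, 2)
  p_closed <- 2 * (1 - pt2_closed_form(sqrt(2)))
  expect_equal(tt$p, p_closed, tolerance = 1e-12)
  expect_equal(tt$p, 0.2928932, tolerance = 1e-4)
})

test_that("vectorized t engine agrees with stats::t.test per column", {
  set.seed(22)
  a <- matrix(rnorm(8 * 12), 8, 12)
  b <- matrix(rnorm(6 * 12, sd = 1.4), 6, 12)
  student <- fccontrast:::two_sample_t(a, b, "student")
  welch <- fccontrast:::two_sample_t(a, b, "welch")
  for (k in seq_len(12)) {
    ref_s <- t.test(a[, k], b[, k], var.equal = TRUE)
    ref_w <- t.test(a[, k], b[, k], var.equal = FALSE)
    expect_equal(student$p[k], ref_s$p.value, tolerance = 1e-12)
    expect_equal(student$statistic[k], unname(ref_s$statistic), tolerance = 1e-12)
    expect_equal(welch$p[k], ref_w$p.value, tolerance = 1e-12)
    expect_equal(welch$df[k], unname(ref_w$parameter), tolerance = 1e-9)
  }
})

test_that("degenerate zero-variance columns follow the documented p rules", {
  a <- matrix(c(1, 1, 1, 1), 2, 2)  # both columns constant at 1
  b <- matrix(c(1, 1, 2, 2), 2, 2)  # col 1 equal means, col 2 different
  expect_warning(tt <- fccontrast:::two_sample_t(a, b), "zero pooled variance")
  expect_equal(tt$p[1], 1)
  expect_equal(tt$p[2], .Machine$double.xmin)
  expect_true(all(tt$degenerate))
})

test_that("edgewise contrast computes delta_z, p and q per edge", {
  # one edge, A z-values {0.2, 0.4}, B {0.0, 0.2}: the hand t(2) fixture
  fc_a <- list(fc_from_edges(rep(0.2, 3), 3, "a1"),
               fc_from_edges(rep(0.4, 3), 3, "a2"))
  fc_b <- list(fc_from_edges(rep(0.0, 3), 3, "b1"),
               fc_from_edges(rep(0.2, 3), 3, "b2"))
  con <- edgewise_group_contrast(fc_a, fc_b)
  expect_equal(nrow(con), 3)
  expect_equal(con$delta_z, rep(0.2, 3), tolerance = 1e-12)
  expect_equal(con$p, rep(0.2928932, 3), tolerance = 1e-6)
  expect_equal(con$q, bh_oracle(con$p), tolerance = 1e-12)
  expect_identical(attr(con, "n_a"), 2L)
  expect_error(edgewise_group_contrast(fc_a[1], fc_b), "at least 2")
})

test_that("identical groups yield zero delta and no significant edges", {
  set.seed(23)
  grp <- cohort_around(rnorm(10, sd = 0.3), 4, 5)
  con <- edgewise_group_contrast(grp, grp)
  expect_equal(con$delta_z, rep(0, 10))
  expect_false(any(con$significant))
})

test_that("swapping conditions negates delta_z and preserves p", {
  set.seed(24)
  a <- cohort_around(rnorm(10, sd = 0.3), 5, 5, prefix = "a")
  b <- cohort_around(rnorm(10, sd = 0.3), 5, 5, prefix = "b")
  con_ab <- edgewise_group_contrast(a, b)
  con_ba <- edgewise_group_contrast(b, a)
  expect_equal(con_ab$delta_z, -con_ba$delta_z, tolerance = 1e-12)
  expect_equal(con_ab$p, con_ba$p, tolerance = 1e-12)
  expect_equal(con_ab$weight, con_ba$weight, tolerance = 1e-12)
})

test_that("contrast is invariant to subject order within a group", {
  set.seed(25)
  a <- cohort_around(rnorm(6, sd = 0.3), 6, 4, prefix = "a")
  b <- cohort_around(rnorm(6, sd = 0.3), 4, 4, prefix = "b")
  con1 <- edgewise_group_contrast(a, b)
  con2 <- edgewise_group_contrast(a[sample(6)], b[sample(4)])
  expect_equal(con1$p, con2$p, tolerance = 1e-12)
  expect_equal(con1$delta_z, con2$delta_z, tolerance = 1e-12)
})

test_that("subject_change is entrywise post - pre and validates pairing", {
  set.seed(26)
  pre <- random_fc(4, "s1")
  post <- random_fc(4, "s1")
  ch <- subject_change(pre, post)
  expect_equal(ch$z[1, 2], post$z[1, 2] - pre$z[1, 2])
  expect_equal(subject_change(pre, pre)$z[upper.tri(pre$z)], rep(0, 6))
  # antisymmetry
  expect_equal(subject_change(post, pre)$z, -ch$z)
  other <- random_fc(4, "s2")
  expect_error(subject_change(pre, other), "subject mismatch")
})

test_that("treatment contrast implements the difference-in-differences arithmetic", {
  n_regions <- 4; n_edges <- 6
  mk <- function(val, id) fc_from_edges(rep(val, n_edges), n_regions, id)
  # treated: 0.1 -> 0.3 for all subjects; control: 0.2 -> 0.2
  t_pre <- list(mk(0.1, "t1"), mk(0.1, "t2"))
  t_post <- list(mk(0.3, "t1"), mk(0.3, "t2"))
  c_pre <- list(mk(0.2, "c1"), mk(0.2, "c2"))
  c_post <- list(mk(0.2, "c1"), mk(0.2, "c2"))
  con <- suppressWarnings(treatment_contrast(t_pre, t_post, c_pre, c_post))
  expect_equal(con$delta_z, rep(0.2, n_edges), tolerance = 1e-12)
  expect_identical(attr(con, "contrast_kind"), "longitudinal")

  set.seed(27)
  rand <- function(id) random_fc(4, id)
  tp <- lapply(paste0("t", 1:3), rand); tq <- lapply(paste0("t", 1:3), rand)
  cp <- lapply(paste0("c", 1:3), rand); cq <- lapply(paste0("c", 1:3), rand)
  base <- treatment_contrast(tp, tq, cp, cq)
  # global baseline shift of every subject's pre AND post cancels
  shift <- function(fc, c) fc_matrix(fc$subject_id, fc$z + c)
  shifted <- treatment_contrast(lapply(tp, shift, 0.7), lapply(tq, shift, 0.7),
                                lapply(cp, shift, 0.7), lapply(cq, shift, 0.7))
  expect_equal(base$delta_z, shifted$delta_z, tolerance = 1e-12)
  expect_equal(base$p, shifted$p, tolerance = 1e-12)
  # arm swap negates the effect
  swapped <- treatment_contrast(cp, cq, tp, tq)
  expect_equal(base$delta_z, -swapped$delta_z, tolerance = 1e-12)
  expect_equal(base$p, swapped$p, tolerance = 1e-12)
  # compositionality: identical to the group contrast of change matrices
  ch_t <- Map(subject_change, tp, tq)
  ch_c <- Map(subject_change, cp, cq)
  direct <- edgewise_group_contrast(ch_t, ch_c, contrast_kind = "longitudinal")
  expect_identical(base$p, direct$p)
  expect_identical(base$delta_z, direct$delta_z)
  expect_identical(base$q, direct$q)
  # unpaired subject is reported by name
  expect_error(treatment_contrast(tp, tq[c(1, 2)], cp, cq), "t3")
})

test_that("significance weight is |delta_z| * (1 - q) with the stated limits", {
  expect_equal(significance_weight(0.2, 0.01), 0.198)
  expect_equal(significance_weight(0.5, 1), 0)
  expect_equal(significance_weight(-0.3, 0.2), significance_weight(0.3, 0.2))
  expect_true(significance_weight(0.3, 0.01, "neglog10q") > 0)
  expect_error(significance_weight(0.1, 1.5), "invalid q")
})

test_that("change-score t equals the 2x2 repeated-measures ANOVA interaction", {
  set.seed(28)
  for (rep in 1:50) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    pre_a <- rnorm(na); post_a <- pre_a + rnorm(na, mean = 0.3)
    pre_b <- rnorm(nb); post_b <- pre_b + rnorm(nb)
    p_pkg <- interaction_delta_test(post_a - pre_a, post_b - pre_b)$p
    df <- data.frame(
      y = c(pre_a, post_a, pre_b, post_b),
      subject = factor(c(rep(paste0("a", 1:na), 2), rep(paste0("b", 1:nb), 2))),
      time = factor(c(rep("pre", na), rep("post", na),
                      rep("pre", nb), rep("post", nb))),
      group = factor(rep(c("a", "b"), c(2 * na, 2 * nb)))
    )
    fit <- stats::aov(y ~ group * time + Error(subject), data = df)
    tab <- summary(fit)[["Error: Within"]][[1]]
    p_aov <- tab["group:time", "Pr(>F)"]
    expect_equal(p_pkg, p_aov, tolerance = 1e-10)
  }
})

test_that("identical arms hit the degenerate p = 1 rule", {
  expect_equal(interaction_delta_test(c(0.1, 0.1), c(0.1, 0.1))$p, 1)
})

test_that("per-lobe-pair FDR family stratifies the adjustment", {
  set.seed(29)
  meta <- make_parcellation(8, seed = 5)
  a <- lapply(1:4, function(k) random_fc(8, paste0("a", k)))
  b <- lapply(1:4, function(k) random_fc(8, paste0("b", k)))
  con_all <- edgewise_group_contrast(a, b, fdr_family = "all_edges")
  con_str <- edgewise_group_contrast(a, b, fdr_family = "per_lobe_pair",
                                     meta = meta)
  expect_equal(con_all$p, con_str$p, tolerance = 1e-12)  # same tests
  et <- edge_table(8)
  lab <- paste(pmin(meta$lobe[et$edge_i + 1], meta$lobe[et$edge_j + 1]),
               pmax(meta$lobe[et$edge_i + 1], meta$lobe[et$edge_j + 1]),
               sep = "|")
  expect_equal(con_str$q, grouped_bh_fdr(con_all$p, lab)$q, tolerance = 1e-12)
  expect_error(edgewise_group_contrast(a, b, fdr_family = "per_lobe_pair"),
               "metadata")
})

test_that("contrast TSV export keeps the deterministic edge order", {
  set.seed(30)
  a <- lapply(1:3, function(k) random_fc(5, paste0("a", k)))
  b <- lapply(1:3, function(k) random_fc(5, paste0("b", k)))
  con <- edgewise_group_contrast(a, b)
  f <- tempfile(fileext = ".tsv")
  write_contrast(con, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 10)
  expect_equal(back$edge_i, con$edge_i)
  expect_equal(back$delta_z, con$delta_z, tolerance = 1e-10)
  expect_equal(edge_index(back$edge_i, back$edge_j, 5), seq_len(10) - 1L)
})
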