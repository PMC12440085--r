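# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately written as a separate code path from the
# package implementation (explicit enumeration, closed forms, base-R model
# fits) so agreement is evidence, not tautology.

# Closed-form Student-t CDF with 2 degrees of freedom:
# F(x) = 1/2 + x / (2 * sqrt(2) * sqrt(1 + x^2/2))
pt2_closed_form <- function(x) 0.5 + x / (2 * sqrt(2) * sqrt(1 + x^2 / 2))

# Hand pooled-variance two-sample t on two vectors; returns two-sided p.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# Brute-force BH step-up, written from the definition (sort, running min of
# p_(k) * m / k from the top, cap at 1, map back).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, ps[k] * m / k)
    q[k] <- running
  }
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# Decision-table oracle for the cross-sectional directional categories,
# enumerated case by case from the banded-sign semantics: the category names
# the group whose out-of-band connectivity drives the difference; a
# clear-positive vs clear-negative conflict goes to the larger |mean|,
# positive preferred on an exact tie.
cross_sectional_oracle <- function(mean_a, mean_b, threshold = 0.05) {
  s <- function(z) if (z >= threshold) "P" else if (z <= -threshold) "N" else "Z"
  sa <- s(mean_a); sb <- s(mean_b)
  key <- paste(sa, sb, if (mean_a > mean_b) ">" else if (mean_a < mean_b) "<" else "=")
  switch(key,
    "Z Z >" = , "Z Z <" = , "Z Z =" = "indeterminate",
    "P P >" = "stronger_positive_in_A",
    "P P <" = "stronger_positive_in_B",
    "P Z >" = "stronger_positive_in_A",
    "Z P <" = "stronger_positive_in_B",
    "N N >" = "stronger_negative_in_B",
    "N N <" = "stronger_negative_in_A",
    "Z N >" = "stronger_negative_in_B",
    "N Z <" = "stronger_negative_in_A",
    "P N >" = if (abs(mean_b) > abs(mean_a)) "stronger_negative_in_B"
              else "stronger_positive_in_A",
    "N P <" = if (abs(mean_a) > abs(mean_b)) "stronger_negative_in_A"
              else "stronger_positive_in_B",
    # equal means (cannot arise at a significant edge) and any leftover
    "indeterminate"
  )
}

# Decision-table oracle for the longitudinal four-bar categories plus the
# sign-transition and indeterminate cases.
longitudinal_oracle <- function(mean_pre, mean_post, threshold = 0.05) {
  s <- function(z) if (z >= threshold) "P" else if (z <= -threshold) "N" else "Z"
  sp <- s(mean_pre); sq <- s(mean_post)
  d <- mean_post - mean_pre
  if ((sp == "P" && sq == "N") || (sp == "N" && sq == "P")) return("sign_transition")
  if (sp == "Z" && sq == "Z") return("indeterminate")
  if (sq == "P" && d > 0 && sp %in% c("P", "Z")) return("more_positive")
  if (sp == "P" && d < 0 && sq %in% c("P", "Z")) return("less_positive")
  if (sq == "N" && d < 0 && sp %in% c("N", "Z")) return("more_negative")
  if (sp == "N" && d > 0 && sq %in% c("N", "Z")) return("less_negative")
  "indeterminate"
}

# Build an fc_matrix from a vector of upper-triangle z values (edge_index
# order) for a given region count.
fc_from_edges <- function(z_values, n_regions, subject_id = "s") {
  m <- matrix(0, n_regions, n_regions)
  k <- 0L
  for (i in seq_len(n_regions - 1L)) {
    for (j in (i + 1L):n_regions) {
      k <- k + 1L
      m[i, j] <- m[j, i] <- z_values[k]
    }
  }
  diag(m) <- NA_real_
  fc_matrix(subject_id, m)
}

# Random symmetric fc_matrix fixture.
random_fc <- function(n_regions, subject_id = "s", sd = 0.3) {
  n_edges <- n_regions * (n_regions - 1L) / 2L
  fc_from_edges(rnorm(n_edges, sd = sd), n_regions, subject_id)
}

# Small cross-sectional cohort of fc matrices around group-specific edge
# means, for contrast tests that need controlled group structure.
cohort_around <- function(mean_edges, n_subjects, n_regions, sd = 0.1,
                          prefix = "s") {
  lapply(seq_len(n_subjects), function(k) {
    fc_from_edges(mean_edges + rnorm(length(mean_edges), sd = sd),
                  n_regions, sprintf("%s_%02d", prefix, k))
  })
}
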