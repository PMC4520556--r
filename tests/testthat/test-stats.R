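test_that("pearson handles exact linear relations and rejects degenerate input", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(3, 6)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("pearson matches the direct product-moment formula on a fixed table", {
  x <- c(0.3, 1, 3, 10, 30, 50, 12, 7)
  y <- c(41, 52, 97, 284, 826, 1366, 330, 205)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y)$r, r_direct, tolerance = 1e-12)
})

test_that("ICC(A,1) reproduces an independent reference on a fixed 6x3 table", {
  m <- rbind(c(620.4, 655.2, 638.9), c(702.1, 687.3, 715.8),
             c(559.0, 572.6, 548.2), c(641.7, 628.4, 660.3),
             c(733.9, 748.1, 722.6), c(588.5, 601.2, 579.7))
  r <- icc_a1(m)
  # frozen from pingouin.intraclass_corr (two-way random, absolute
  # agreement, single rater) on the same table
  expect_equal(r$icc, 0.955339133968867, tolerance = 1e-12)
  expect_equal(r$p, 4.25281017932864e-07, tolerance = 1e-9)
  expect_equal(round(r$ci_low, 2), 0.84)
  expect_equal(round(r$ci_high, 2), 0.99)
})

test_that("ICC(A,1) equals a brute-force ANOVA oracle on random tables", {
  withr::with_seed(71, {
    for (rep in 1:12) {
      m <- matrix(rnorm(18, 500, 60), nrow = 6) +
        rep(rnorm(3, 0, 20), each = 6)
      expect_equal(icc_a1(m)$icc, icc_a1_aov_oracle(m), tolerance = 1e-10)
    }
  })
})

test_that("ICC(A,1) limits: perfect agreement, null tables, degenerate tables", {
  base <- c(410, 520, 630, 740, 850, 960)
  near_dup <- cbind(base, base + 1e-9, base - 1e-9)
  expect_gt(icc_a1(near_dup)$icc, 0.999999)
  withr::with_seed(5, {
    null_iccs <- replicate(300, icc_a1(matrix(rnorm(18), 6, 3))$icc)
  })
  expect_lt(abs(mean(null_iccs)), 0.08)
  degen <- icc_a1(matrix(5, 4, 3))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$icc))
})

test_that("ICC(A,1) is invariant under common affine maps but penalises per-column shifts", {
  withr::with_seed(9, m <- matrix(rnorm(24, 600, 70), 8, 3) +
                     rep(rnorm(8, 0, 50), times = 3))
  r0 <- icc_a1(m)$icc
  expect_equal(icc_a1(m + 123.4)$icc, r0, tolerance = 1e-10)
  expect_equal(icc_a1(m * 3.7)$icc, r0, tolerance = 1e-10)
  shifted <- m + rep(c(0, 80, -80), each = nrow(m))
  expect_lt(icc_a1(shifted)$icc, r0)
})

test_that("ICC estimator is consistent at n = 30 for known variance components", {
  sd_b <- 76; sd_w <- 35.62
  theo <- sd_b^2 / (sd_b^2 + sd_w^2)
  withr::with_seed(31, {
    iccs <- replicate(250, {
      subj <- rnorm(30, 651, sd_b)
      icc_a1(sapply(1:3, function(j) subj + rnorm(30, 0, sd_w)))$icc
    })
  })
  expect_lt(abs(mean(iccs) - theo), 0.02)
})

test_that("agreement labels follow the conventional ICC boundaries", {
  expect_equal(icc_agreement_label(c(0.2, 0.49, 0.5, 0.69, 0.7, 0.95)),
               c("poor", "poor", "fair", "fair",
                 "good-to-strong", "good-to-strong"))
})

test_that("variation coefficients: direct arithmetic, scale invariance, exclusions", {
  vc <- variation_coefficient(rbind(c(90, 100, 110), c(200, 200, 200)))
  expect_equal(vc$per_subject$vc, c(10, 0))
  m <- rbind(c(90, 100, 110), c(9, 10, 11))
  both <- variation_coefficient(m)
  expect_equal(both$per_subject$vc[1], both$per_subject$vc[2])
  expect_warning(
    out <- variation_coefficient(rbind(c(90, 100, 110), c(-5, 0, 5))),
    "non-positive"
  )
  expect_equal(out$n_excluded, 1)
  expect_equal(nrow(out$per_subject), 1)
})

test_that("exact Wilcoxon matches hand-enumerated one-sided extremes", {
  # all-decrease, no ties: p = 2 / 2^n
  w5 <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
  expect_equal(w5$p, 0.0625)
  expect_equal(w5$w, 15)
  w6 <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), 0:5)
  expect_equal(w6$p, 0.03125)
  # balanced +1/-1 pattern sits at the null centre
  bal <- wilcoxon_signed_rank(c(10, 9, 10, 9), c(9, 10, 9, 10))
  expect_equal(bal$p, 1)
})

test_that("exact Wilcoxon equals the 2^n enumeration oracle, with and without ties", {
  withr::with_seed(17, {
    for (n in c(4, 6, 8, 10)) {
      for (rep in 1:4) {
        d <- round(rnorm(n, 0.3, 1), 1) # rounding induces occasional ties
        d <- ifelse(d == 0, 0.5, d)
        p_pkg <- wilcoxon_signed_rank(d, rep(0, n))$p
        expect_equal(p_pkg, wilcoxon_enum_oracle(d), tolerance = 1e-12,
                     info = paste("n =", n, "rep", rep))
      }
    }
  })
})

test_that("exact Wilcoxon agrees with stats::wilcox.test when no ties are present", {
  withr::with_seed(23, {
    d <- rnorm(12, 0.4, 1)
  })
  p_ref <- stats::wilcox.test(d, exact = TRUE)$p.value
  expect_equal(wilcoxon_signed_rank(d, rep(0, 12))$p, p_ref,
               tolerance = 1e-12)
})

test_that("Wilcoxon guards: zero differences excluded, degenerate input rejected", {
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "zero")
  r <- wilcoxon_signed_rank(c(1, 5, 6, 7), c(1, 2, 3, 4))
  expect_equal(r$n, 3)
  big <- wilcoxon_signed_rank(1:30 + 0.5, 1:30 - rep(c(1, -0.4), 15))
  expect_match(big$method, "normal")
})

test_that("median displacement reproduces the repositioning worked example", {
  expect_equal(median_displacement(c(20, 50, 75, 20, 100)), 50)
  expect_equal(median_displacement(42), 42)
  expect_equal(median_displacement(c(10, 20, 30, 40)), 25)
})

test_that("repeatability tables drop incomplete subjects", {
  m <- rbind(c(1, 2, 3), c(4, NA, 6), c(7, 8, 9))
  tab <- repeatability_table(m)
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "n_dropped"), 1)
  expect_error(repeatability_table(rbind(c(1, NA), c(NA, 2), c(3, 4))),
               ">= 2 complete subjects")
})
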