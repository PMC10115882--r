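test_that("Hodges-Lehmann equals the brute-force pairwise-difference median", {
  h <- hodges_lehmann(c(1, 2), c(0, 1))
  expect_equal(h$estimate, 1)
  expect_equal(hodges_lehmann(c(5, 5, 5), c(5, 5))$estimate, 0)
  set.seed(41)
  for (i in 1:60) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- rnorm(nx); y <- rnorm(ny, 0.5)
    h <- hodges_lehmann(x, y)
    expect_equal(h$estimate, hl_brute(x, y))
    expect_true(h$ci_low <= h$estimate && h$estimate <= h$ci_high)
    # shift invariance
    c0 <- runif(1, -2, 2)
    expect_equal(hodges_lehmann(x + c0, y)$estimate, h$estimate + c0,
                 tolerance = 1e-12)
  }
  expect_error(hodges_lehmann(1, c(1, 2)), class = "sg_empty_group")
})

test_that("Hodges-Lehmann CI matches the exact Mann-Whitney construction", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(4:8, 1)); y <- rnorm(sample(4:8, 1), 1)
    h <- hodges_lehmann(x, y)
    w <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE, exact = TRUE))
    expect_equal(h$estimate, unname(w$estimate), tolerance = 1e-9)
    expect_equal(c(h$ci_low, h$ci_high), as.numeric(w$conf.int),
                 tolerance = 1e-9)
  }
})

test_that("Benjamini-Hochberg matches the brute-force step-up", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.04), 0.04)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  set.seed(43)
  for (i in 1:40) {
    p <- runif(sample(1:12, 1))^2
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_brute(p))
    expect_true(all(adj >= p - 1e-15))          # never decreases
    expect_true(all(adj <= 1))
    # monotone: order of adjusted follows order of raw
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    # smallest p's rejection decision matches the oracle at alpha = 0.05
    expect_equal(min(adj) < 0.05, min(bh_brute(p)) < 0.05)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), class = "sg_invalid_p")
})

test_that("bootstrap median pairs: determinism, symmetry, degenerate groups", {
  g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(9, 10, 11, 12))
  r1 <- bootstrap_median_pairs(g, B = 600, seed = 99)
  r2 <- bootstrap_median_pairs(g, B = 600, seed = 99)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3)
  expect_true(all(r1$p_adj >= r1$p_raw - 1e-15))
  # order reflection: p is invariant when the two groups swap roles
  ra <- bootstrap_median_pairs(list(x = g$a, y = g$c), B = 600, seed = 7)
  rb <- bootstrap_median_pairs(list(x = g$c, y = g$a), B = 600, seed = 7)
  expect_equal(ra$p_raw, rb$p_raw)
  expect_equal(ra$estimate, -rb$estimate)
  # identical constant groups -> p_raw = 1
  rc <- bootstrap_median_pairs(list(u = rep(4, 4), v = rep(4, 4)),
                               B = 600, seed = 1)
  expect_equal(rc$p_raw, 1)
  # fully separated constant groups -> floor at 1/B = 2 * (0.5/B)
  rd <- bootstrap_median_pairs(list(u = rep(10, 4), v = rep(0, 4)),
                               B = 600, seed = 1)
  expect_equal(rd$p_raw, 1 / 600)
  expect_error(bootstrap_median_pairs(g, B = 100, seed = 1),
               class = "sg_bootstrap_too_small")
  expect_error(bootstrap_median_pairs(g, B = 600),
               class = "sg_seed_required")
})

test_that("row_medians matches apply(median)", {
  set.seed(44)
  for (nc in c(3, 4, 7)) {
    m <- matrix(rnorm(50 * nc), ncol = nc)
    expect_equal(row_medians(m), apply(m, 1, median))
  }
})

test_that("Cohen's d: pooled sd, antisymmetry, degenerate flag", {
  expect_equal(cohens_d(c(0, 2), c(-1, 1)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 1)), 0)
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  res <- collect_qc(cohens_d(rep(1, 3), rep(2, 3)))
  expect_equal(res$value, -Inf)
  expect_equal(res$qc$what, "infinite_effect_size")
})

test_that("compact letter display separates exactly the significant pairs", {
  cmp <- data.frame(group1 = c("a", "a", "b"), group2 = c("b", "c", "c"),
                    p_adj = c(0.01, 0.20, 0.03))
  lt <- significance_letters(cmp)
  shares <- function(u, v) {
    any(strsplit(lt[[u]], "")[[1]] %in% strsplit(lt[[v]], "")[[1]])
  }
  expect_false(shares("a", "b"))
  expect_true(shares("a", "c"))
  expect_false(shares("b", "c"))
  # no significant differences -> everyone shares one letter
  cmp$p_adj <- 0.5
  expect_equal(unname(significance_letters(cmp)), rep("a", 3))
  # all different -> all letters distinct
  cmp$p_adj <- 0.001
  lt2 <- significance_letters(cmp)
  expect_equal(length(unique(lt2)), 3)
})
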