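test_that("equal group means give F = 0, p = 1", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  a <- one_way_anova(g)
  expect_equal(a$F, 0, tolerance = 1e-12)
  expect_equal(a$p, 1, tolerance = 1e-12)
})

test_that("ANOVA F matches the brute-force sums-of-squares oracle", {
  for (seed in 1:8) {
    g <- withr::with_seed(seed, list(a = rnorm(3, 100, 10),
                                     b = rnorm(4, 150, 10),
                                     c = rnorm(3, 130, 10)))
    expect_equal(one_way_anova(g)$F, brute_force_F(g), tolerance = 1e-10)
  }
})

test_that("well-separated groups are strongly significant", {
  g <- withr::with_seed(2, list(a = rnorm(3, 100, 5), b = rnorm(3, 200, 5),
                                c = rnorm(3, 300, 5)))
  a <- one_way_anova(g)
  expect_lt(a$p, 0.001)
  tk <- tukey_hsd(g)
  expect_true(all(tk$reject))
  expect_identical(unname(compact_letters(tk)), c("a", "b", "c"))
})

test_that("identical groups and vanishing shifts are not rejected", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  tk <- tukey_hsd(same)
  expect_equal(tk$diff, 0)
  expect_false(tk$reject)
  # shift one group by a hundredth of the pooled SD
  g <- withr::with_seed(3, {
    base <- rnorm(5, 100, 10)
    list(a = base, b = base + 0.01 * stats::sd(base))
  })
  expect_false(tukey_hsd(g)$reject)
})

test_that("tukey p-values agree with stats::TukeyHSD", {
  g <- withr::with_seed(4, list(a = rnorm(3, 100, 20), b = rnorm(3, 130, 20),
                                c = rnorm(3, 160, 20)))
  tk <- tukey_hsd(g)
  y <- unlist(g)
  grp <- factor(rep(names(g), lengths(g)))
  ref <- stats::TukeyHSD(stats::aov(y ~ grp))$grp
  expect_equal(tk$p, unname(ref[, "p adj"]), tolerance = 1e-8)
  expect_equal(tk$diff, unname(ref[, "diff"]), tolerance = 1e-10)
})

test_that("compact letters cover the canonical configurations", {
  mk <- function(g1, g2, reject, means) {
    d <- data.frame(group1 = g1, group2 = g2,
                    diff = NA_real_, q = NA_real_, p = NA_real_,
                    reject = reject)
    attr(d, "means") <- means
    d
  }
  all_pairs4 <- utils::combn(c("A", "B", "C", "D"), 2)
  # nothing rejected: one shared letter
  none <- mk(all_pairs4[1, ], all_pairs4[2, ], rep(FALSE, 6),
             c(A = 1, B = 2, C = 3, D = 4))
  expect_identical(unname(compact_letters(none)), rep("a", 4))
  # everything rejected: one letter each
  all6 <- mk(all_pairs4[1, ], all_pairs4[2, ], rep(TRUE, 6),
             c(A = 1, B = 2, C = 3, D = 4))
  expect_identical(unname(compact_letters(all6)), c("a", "b", "c", "d"))
  # chain: A != C, A ~ B, B ~ C
  chain <- mk(c("A", "A", "B"), c("B", "C", "C"), c(FALSE, TRUE, FALSE),
              c(A = 1, B = 2, C = 3))
  expect_identical(compact_letters(chain),
                   c(A = "a", B = "ab", C = "b"))
})

test_that("letters re-derive exactly the non-rejected pairs", {
  for (seed in 1:10) {
    g <- withr::with_seed(seed, {
      mu <- runif(4, 80, 320)
      stats::setNames(lapply(mu, function(m) rnorm(3, m, 25)),
                      c("w5", "w10", "w20", "w40"))
    })
    tk <- tukey_hsd(g)
    lett <- compact_letters(tk)
    share <- function(a, b) {
      any(strsplit(lett[[a]], "")[[1]] %in% strsplit(lett[[b]], "")[[1]])
    }
    for (j in seq_len(nrow(tk))) {
      expect_identical(share(tk$group1[j], tk$group2[j]), !tk$reject[j])
    }
  }
})

test_that("censored values are excluded with a warning and small groups error", {
  g <- list(a = c(100, 110, NA), b = c(200, 210, 190))
  expect_warning(a <- one_way_anova(g), "censored")
  expect_identical(unname(a$n), c(2L, 3L))
  expect_error(suppressWarnings(one_way_anova(list(a = c(1, NA), b = c(1, 2)))),
               "at least 2 usable values")
  expect_error(one_way_anova(list(a = c(1, 2))), "at least 2 groups")
})

test_that("compare_t50 assembles ANOVA, Tukey and letters consistently", {
  tab <- withr::with_seed(6, data.frame(
    blend = rep(c("BDF5", "BDF20", "BDF40"), each = 3),
    t50 = c(rnorm(3, 250, 10), rnorm(3, 110, 10), rnorm(3, 100, 10))))
  cmp <- compare_t50(tab)
  expect_s3_class(cmp, "group_comparison")
  expect_lt(cmp$anova$p, 0.01)
  expect_identical(sort(names(cmp$letters)), sort(unique(tab$blend)))
  # slowest blend carries its own letter
  expect_false(grepl(cmp$letters[["BDF40"]], cmp$letters[["BDF5"]], fixed = TRUE))
  expect_output(print(cmp), "one-way ANOVA")
})
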