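test_that("jackknife of the mean reproduces the sample and classical SE exactly", {
  x <- c(2, 4, 6)
  j <- jackknife(x, mean)
  expect_equal(sort(j$pseudovalues), c(2, 4, 6))
  expect_equal(j$estimate, 4)
  expect_equal(j$se, 2 / sqrt(3))
  # identity holds for arbitrary samples: jackknife SE of a linear
  # statistic equals sd(x)/sqrt(n)
  set.seed(31)
  for (i in 1:5) {
    y <- rnorm(sample(5:40, 1))
    jy <- jackknife(y, mean)
    expect_equal(jy$se, sd(y) / sqrt(length(y)), tolerance = 1e-12)
    expect_equal(jy$estimate, mean(y), tolerance = 1e-12)
  }
})

test_that("cohort pseudovalues match an independently coded leave-one-out loop", {
  cohort <- bind_recs(
    rec("a", trans = c(1.5, 2.0, 3.5, 5.0), death = 12,
        eggs = c(0, 0, 2, 3, 1, 0, 0)),
    rec("b", trans = c(1.5, 2.5, 4.0, 5.5), death = 14,
        eggs = c(0, 1, 2, 2, 2, 1, 0, 0)),
    rec("c", trans = c(2.0, 2.5, 4.0, 6.0), death = 13,
        eggs = c(0, 0, 0, 3, 2, 1, 0)),
    rec("d", trans = c(1.5, 2.0, 3.0, 4.5), death = 10,
        eggs = c(0, 2, 2, 1, 0, 0)),
    rec("e", trans = c(1.5), died = "larva", sex = "unknown"),
    rec("f", trans = c(1.5, 2.0, 3.5, 5.0), sex = "male")
  )
  pff <- 0.55
  j <- jackknife_parameter(cohort, "rm", pff)

  # brute-force loop written directly against the primitives
  n <- nrow(cohort)
  theta_all <- intrinsic_rate(build_life_table(cohort, pff))
  phi_oracle <- numeric(n)
  for (i in seq_len(n)) {
    theta_i <- intrinsic_rate(build_life_table(cohort[-i, ], pff))
    phi_oracle[i] <- n * theta_all - (n - 1) * theta_i
  }
  expect_equal(j$theta_all, theta_all, tolerance = 1e-10)
  expect_equal(j$pseudovalues, phi_oracle, tolerance = 1e-10)
  expect_equal(j$se, sd(phi_oracle) / sqrt(n), tolerance = 1e-10)
  expect_equal(j$n, n)
})

test_that("identical individuals give equal pseudovalues and zero SE", {
  cohort <- bind_recs(
    rec("a", death = 9, eggs = c(0, 2, 2, 0)),
    rec("b", death = 9, eggs = c(0, 2, 2, 0)),
    rec("c", death = 9, eggs = c(0, 2, 2, 0)),
    rec("d", death = 9, eggs = c(0, 2, 2, 0))
  )
  j <- jackknife_parameter(cohort, "R0", 0.5)
  expect_equal(diff(range(j$pseudovalues)), 0, tolerance = 1e-12)
  expect_equal(j$se, 0, tolerance = 1e-12)
})

test_that("degenerate leave-one-out replicates are excluded with a warning", {
  # only one reproducing female: removing her kills every replicate's
  # reproduction except hers
  cohort <- bind_recs(
    rec("f1", death = 9, eggs = c(0, 2, 2, 0)),
    rec("f2", death = 9, eggs = c(0, 0, 0, 0)),
    rec("f3", death = 9, eggs = c(0, 0, 0, 0)),
    rec("f4", death = 9, eggs = c(0, 0, 0, 0))
  )
  expect_warning(j <- jackknife_parameter(cohort, "R0", 0.5), "excluded")
  expect_equal(j$n, 3)
  expect_equal(j$n_excluded, 1)
})

test_that("compare_diets matches the pooled t oracle and is antisymmetric", {
  fake <- function(label, phi) {
    structure(list(parameter_name = "rm", diet_label = label,
                   theta_all = mean(phi), pseudovalues = phi,
                   estimate = mean(phi), se = sd(phi) / sqrt(length(phi)),
                   n = length(phi), n_excluded = 0L),
              class = "jackknife_estimate")
  }
  a <- fake("A", c(1, 2, 3))
  b <- fake("B", c(4, 5, 6))
  cmp <- compare_diets(a, b)
  expect_equal(cmp$difference, -3)
  expect_equal(cmp$t_statistic, -3.674235, tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p_value, 0.021312, tolerance = 1e-4)
  # agreement with stats::t.test pooled form
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(cmp$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-12)
  # antisymmetry
  rev <- compare_diets(b, a)
  expect_equal(rev$difference, -cmp$difference)
  expect_equal(rev$t_statistic, -cmp$t_statistic)
  expect_equal(rev$p_value, cmp$p_value)
  # identical sets: no difference
  same <- compare_diets(a, fake("C", c(1, 2, 3)))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  # mismatched parameters refused
  b2 <- b
  b2$parameter_name <- "R0"
  expect_error(compare_diets(a, b2), "mismatch")
})

test_that("pseudovalue mean tracks the full-cohort estimate on a large cohort", {
  cfg <- small_config(n = 500, seed = 17)
  recs <- generate_cohort(cfg)
  j <- jackknife_parameter(recs, "rm", cfg$progeny_female_fraction)
  expect_lt(abs(j$estimate - j$theta_all), 2 * j$se)
})

test_that("letter groups reproduce the standard displays and a brute-force oracle", {
  est <- c(pollen = 0.139, prey1 = 0.160, prey2 = 0.166)
  cmp <- function(p12, p13, p23) {
    data.frame(diet_a = c("prey1", "prey1", "prey2"),
               diet_b = c("prey2", "pollen", "pollen"),
               p_value = c(p12, p13, p23), stringsAsFactors = FALSE)
  }
  # all pairs significant: a, b, c by ascending estimate
  expect_equal(letter_groups(cmp(0.01, 0.01, 0.01), est),
               c(pollen = "a", prey1 = "b", prey2 = "c"))
  # one non-significant pair shares a letter (the a/b/b pattern)
  expect_equal(letter_groups(cmp(0.2, 0.01, 0.01), est),
               c(pollen = "a", prey1 = "b", prey2 = "b"))

  # brute-force oracle on 3 groups: two diets share a letter iff p > alpha
  share <- function(lab, i, j) {
    any(strsplit(lab[i], "")[[1]] %in% strsplit(lab[j], "")[[1]])
  }
  set.seed(12)
  for (i in 1:50) {
    p <- runif(3)
    lab <- letter_groups(cmp(p[1], p[2], p[3]), est, alpha = 0.05)
    want <- c(p[1] > 0.05, p[2] > 0.05, p[3] > 0.05)
    got <- c(share(lab, "prey1", "prey2"),
             share(lab, "prey1", "pollen"),
             share(lab, "prey2", "pollen"))
    expect_equal(got, want, info = paste("p =", paste(round(p, 3), collapse = ",")))
  }
})
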