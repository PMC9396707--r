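test_that("Kruskal-Wallis H matches the hand rank formula and degenerates cleanly", {
  kw <- kruskal_wallis(c(1, 2, 3, 10, 11, 12, 20, 21, 22),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p.value, pchisq(7.2, 2, lower.tail = FALSE))

  flat <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z (tie-free)", {
  set.seed(8)
  x <- rnorm(9); y <- rnorm(12) + 0.5
  H <- kruskal_wallis(c(x, y), rep(c("a", "b"), c(9, 12)))$statistic
  U <- sum(rank(c(x, y))[1:9]) - 9 * 10 / 2
  z <- (U - 9 * 12 / 2) / sqrt(9 * 12 * (9 + 12 + 1) / 12)
  expect_equal(H, z^2)
})

test_that("pairwise Mann-Whitney separates distant groups and letters them", {
  v <- c(1:10, 101:110)
  g <- rep(c("lo", "hi"), each = 10)
  res <- pairwise_mwu_letters(v, g, exact_max = 10)
  expect_lt(attr(res, "pmat")["lo", "hi"], 0.001)
  expect_setequal(unname(res$letters), c("a", "b"))

  same <- pairwise_mwu_letters(c(rnorm(8), rnorm(8)), rep(c("x", "y"), each = 8))
  if (attr(same, "pmat")["x", "y"] >= 0.05)
    expect_equal(unname(same$letters), c("a", "a"))
})

test_that("letter displays agree with the pairwise decisions on random data", {
  set.seed(21)
  for (i in 1:50) {
    g <- rep(letters[1:5], each = 8)
    v <- rnorm(40) + rep(runif(5, 0, 3), each = 8)
    res <- pairwise_mwu_letters(v, g)
    pm <- attr(res, "pmat")
    for (a in 1:4) for (b in (a + 1):5) {
      share <- length(intersect(strsplit(res$letters[a], "")[[1]],
                                strsplit(res$letters[b], "")[[1]])) > 0
      expect_equal(share, pm[a, b] >= 0.05)
    }
    expect_true(all(nchar(res$letters) >= 1))
  }
})

test_that("identically distributed groups usually share one letter", {
  set.seed(31)
  share <- 0; N <- 200
  for (i in 1:N) {
    res <- pairwise_mwu_letters(rnorm(20), rep(c("a", "b"), each = 10))
    share <- share + all(res$letters == "a")
  }
  expect_gte(share / N, 0.9)
})

test_that("a Holm adjustment is available but off by default", {
  v <- c(1:10, 8:17, 101:110)
  g <- rep(c("a", "b", "c"), each = 10)
  raw <- pairwise_mwu(v, g)
  holm <- pairwise_mwu(v, g, p_adjust = "holm")
  expect_true(all(holm >= raw, na.rm = TRUE))
})

test_that("sequential ANOVA: one balanced factor reduces to the squared t", {
  set.seed(5)
  d <- data.frame(y = rnorm(20), f = rep(c("a", "b"), each = 10))
  tab <- anova_sequential(y ~ f, d)
  tt <- t.test(y ~ f, d, var.equal = TRUE)
  expect_equal(tab$statistic[1], unname(tt$statistic)^2)
  expect_equal(tab$p.value[1], tt$p.value)
})

test_that("sequential ANOVA matches a QR projection oracle on unbalanced data", {
  set.seed(6)
  d <- data.frame(f1 = factor(sample(letters[1:3], 40, TRUE)),
                  f2 = factor(sample(c("u", "v"), 40, TRUE)))
  d$y <- rnorm(40) + as.integer(d$f1) + 0.5 * (d$f2 == "v")
  tab <- anova_sequential(y ~ f1 * f2, d)

  # oracle: residual sum of squares of nested least-squares fits
  rss <- function(form) sum(qr.resid(qr(model.matrix(form, d)), d$y)^2)
  ss <- c(rss(~1) - rss(~f1), rss(~f1) - rss(~f1 + f2),
          rss(~f1 + f2) - rss(~f1 + f2 + f1:f2), rss(~f1 + f2 + f1:f2))
  expect_equal(tab$sum_sq, ss, tolerance = 1e-8)

  total_ss <- sum((d$y - mean(d$y))^2)
  expect_equal(sum(tab$sum_sq), total_ss)
  expect_equal(tab$statistic[1:3],
               (tab$sum_sq[1:3] / tab$df[1:3]) / tab$mean_sq[4])
})

test_that("constant responses give zero sums of squares", {
  d <- data.frame(y = rep(2, 12), f = rep(c("a", "b"), 6))
  tab <- suppressWarnings(anova_sequential(y ~ f, d))  # perfect-fit warning
  expect_equal(tab$sum_sq, c(0, 0))
})

test_that("aliased designs are rejected with the offending term named", {
  d <- data.frame(y = rnorm(10), f1 = factor(rep(c("a", "b"), each = 5)),
                  f2 = factor(rep(c("u", "v"), each = 5)))
  expect_error(anova_sequential(y ~ f1 + f2, d), "aliased")
})

test_that("repeated-measures ANOVA reproduces a hand-computed 2x2 panel", {
  d <- data.frame(subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
                  geno = rep(c("A", "A", "B", "B"), each = 2),
                  day = rep(c("d1", "d2"), 4),
                  y = c(3, 5, 4, 8, 10, 11, 12, 15))
  tab <- rm_anova(d, "y", "subject", "geno", "day")

  # hand decomposition: subject means 4, 6, 10.5, 13.5; grand mean 8.5
  sm <- c(4, 6, 10.5, 13.5); gm <- 8.5
  ss_geno <- 2 * 2 * (mean(sm[1:2]) - gm)^2 + 2 * 2 * (mean(sm[3:4]) - gm)^2
  ss_subj_within <- 2 * sum((sm[1:2] - mean(sm[1:2]))^2) +
                    2 * sum((sm[3:4] - mean(sm[3:4]))^2)
  expect_equal(tab$sum_sq[tab$term == "geno"], ss_geno)
  expect_equal(tab$sum_sq[tab$stratum == "between" & tab$term == "Residuals"],
               ss_subj_within)
  expect_equal(tab$sum_sq[tab$term == "day"],
               sum(4 * (tapply(d$y, d$day, mean) - gm)^2))
  expect_equal(sum(tab$sum_sq), sum((d$y - gm)^2))
})

test_that("a within factor with identical values contributes zero SS", {
  d <- data.frame(subject = rep(paste0("s", 1:6), each = 2),
                  geno = rep(c("A", "B"), each = 6),
                  day = rep(c("d1", "d2"), 6),
                  y = rep(c(1, 4, 2, 6, 3, 5), each = 2))
  tab <- rm_anova(d, "y", "subject", "geno", "day")
  expect_equal(tab$sum_sq[tab$term == "day"], 0)
})

test_that("incomplete subjects are dropped with a warning; tiny groups error", {
  d <- data.frame(subject = c(rep(paste0("s", 1:5), each = 2), "s6"),
                  geno = c(rep(c("A", "A", "B", "B", "A"), each = 2), "B"),
                  day = c(rep(c("d1", "d2"), 5), "d1"),
                  y = rnorm(11))
  expect_warning(tab <- rm_anova(d, "y", "subject", "geno", "day"),
                 "incomplete")
  expect_equal(attr(tab, "dropped_subjects"), "s6")

  d2 <- d[d$subject %in% c("s1", "s2", "s3"), ]
  expect_error(suppressWarnings(rm_anova(d2, "y", "subject", "geno", "day")),
               "2 complete subjects")
})

test_that("repeated-measures p-values are uniform under the null", {
  set.seed(99)
  ps <- replicate(400, {
    d <- expand.grid(subject = paste0("s", 1:10), day = c("d1", "d2", "d3"))
    d$geno <- rep(rep(c("A", "B"), each = 5), 3)
    d$y <- rnorm(10)[as.integer(d$subject)] + rnorm(30)
    tab <- rm_anova(d, "y", "subject", "geno", "day")
    tab$p.value[tab$term == "day"]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Greenhouse-Geisser epsilon is reported and bounded", {
  set.seed(12)
  d <- expand.grid(subject = paste0("s", 1:12), day = paste0("d", 1:4))
  d$geno <- rep(rep(c("A", "B"), each = 6), 4)
  d$y <- rnorm(48)
  tab <- rm_anova(d, "y", "subject", "geno", "day")
  eps <- attr(tab, "gg_epsilon")
  expect_true(eps > 1 / 3 - 1e-9 && eps <= 1 + 1e-9)  # bounds for k = 4
})

test_that("Shapiro-Wilk wrapper behaves at its edges", {
  sw <- normality_check(qnorm(ppoints(50)))
  expect_gt(sw$statistic, 0.99)

  set.seed(3)
  bimodal <- c(rnorm(40, -4, 0.3), rnorm(40, 4, 0.3))
  expect_lt(normality_check(bimodal)$p.value, 0.01)

  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "3 <= n")
})
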