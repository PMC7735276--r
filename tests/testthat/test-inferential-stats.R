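# Brute-force nested ANOVA sums of squares for balanced designs: category SS
# from category means, population-within-category SS from population means,
# residual from within-population deviations, every term over the residual
# mean square. On balanced data all sum-of-squares types coincide, so this
# is an independent oracle for the model-matrix implementation.
brute_force_nested <- function(y, category, population) {
  gm <- mean(y)
  ss_cat <- sum(tapply(y, category, function(v) length(v) * (mean(v) - gm)^2))
  cat_of <- tapply(as.character(category), population, `[`, 1)
  pop_means <- tapply(y, population, mean)
  pop_n <- tapply(y, population, length)
  cat_means <- tapply(y, category, mean)
  ss_pop <- sum(pop_n * (pop_means - cat_means[cat_of])^2)
  ss_res <- sum((y - pop_means[as.character(population)])^2)
  df_cat <- length(unique(category)) - 1
  df_pop <- length(unique(population)) - length(unique(category))
  df_res <- length(y) - length(unique(population))
  ms_res <- ss_res / df_res
  list(F_cat = (ss_cat / df_cat) / ms_res,
       F_pop = (ss_pop / df_pop) / ms_res,
       df = c(df_cat, df_pop, df_res))
}

test_that("nested ANOVA matches the brute-force oracle on balanced data", {
  set.seed(101)
  for (i in 1:5) {
    d <- balanced_nested(n_per_pop = 5, cat_effect = runif(1, 0, 2),
                         pop_sd = runif(1, 0, 1))
    a <- nested_anova(d$y, d$category, d$population)
    bf <- brute_force_nested(d$y, d$category, d$population)
    expect_equal(a$F[a$term == "category"], bf$F_cat, tolerance = 1e-10)
    expect_equal(a$F[a$term == "population(category)"], bf$F_pop,
                 tolerance = 1e-10)
    expect_equal(a$df_den, rep(bf$df[3], 2))
  }
})

test_that("nested ANOVA handles unbalanced population counts per category", {
  set.seed(102)
  category <- rep(c("core", "front"), times = c(30, 40))
  population <- c(rep(c("c1", "c2", "c3"), each = 10),
                  rep(c("f1", "f2", "f3", "f4"), each = 10))
  y <- rnorm(70) + (category == "front") * 1.5
  a <- nested_anova(y, category, population)
  expect_equal(a$df_num, c(1L, 5L))
  expect_equal(a$df_den, c(63L, 63L))
  expect_lt(a$p[1], 0.001)
})

test_that("constant responses give F = 0", {
  d <- balanced_nested(4)
  a <- nested_anova(rep(3.2, nrow(d)), d$category, d$population)
  expect_equal(a$F, c(0, 0))
  expect_equal(a$p, c(1, 1))
})

test_that("single population per category collapses to one-way ANOVA (F = t^2)", {
  set.seed(103)
  y <- c(rnorm(12), rnorm(15, 1))
  category <- rep(c("a", "b"), c(12, 15))
  a <- nested_anova(y, category, category)
  tt <- t.test(y ~ category, var.equal = TRUE)
  expect_equal(a$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(nrow(a), 1L)
  # mixed design: degenerate nesting
  expect_error(
    nested_anova(y, category, c(rep("p1", 12), rep(c("p2", "p3"), c(8, 7)))),
    "nesting degeneracy")
})

test_that("planted category effects are detected with high power", {
  set.seed(104)
  hits <- mean(replicate(200, {
    d <- balanced_nested(n_per_pop = 20, cat_effect = 3)
    nested_anova(d$y, d$category, d$population)$p[1] < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("parallel trait profiles show no category x trait interaction", {
  set.seed(111)
  n <- 120
  category <- rep(c("A", "B"), each = n / 2)
  base <- matrix(rnorm(n * 5), n, 5)
  parallel <- base + ifelse(category == "B", 2.5, 0)   # common shift
  a <- manova_traits_interaction(parallel, category)
  expect_gt(a$p, 0.001)
  expect_equal(attr(a, "df_interaction"), 4L)
  # planted non-parallel shift on one trait: strong interaction
  warped <- base; warped[category == "B", 3] <- warped[category == "B", 3] + 1.5
  a2 <- manova_traits_interaction(warped, category)
  expect_lt(a2$p, 1e-6)
})

test_that("profile-analysis MANOVA detects non-parallel shifts with power", {
  set.seed(112)
  hits <- mean(replicate(100, {
    n <- 300
    category <- rep(c("A", "B"), each = n / 2)
    Y <- matrix(rnorm(n * 7), n, 7)
    Y[category == "B", 1] <- Y[category == "B", 1] + 0.5
    manova_traits_interaction(Y, category)$p < 0.05
  }))
  expect_gt(hits, 0.8)
})

test_that("MANOVA refuses more trait contrasts than residual df", {
  Y <- matrix(rnorm(6 * 8), 6, 8)
  expect_error(manova_traits_interaction(Y, rep(c("A", "B"), 3)),
               "rank deficiency")
})

test_that("backward elimination recovers a planted model", {
  set.seed(121)
  x1 <- rnorm(200); x2 <- rnorm(200)
  y <- 2 * x1 + rnorm(200)
  r <- backward_eliminate(y, data.frame(x1 = x1, x2 = x2))
  expect_equal(r$retained$term, "x1")
  expect_equal(r$eliminated, "x2")
  expect_equal(r$retained$beta, 2, tolerance = 0.2)
})

test_that("elimination order does not depend on predictor ordering", {
  set.seed(122)
  X <- data.frame(a = rnorm(150), b = rnorm(150), c = rnorm(150))
  y <- 1.5 * X$a + 0.8 * X$b + rnorm(150)
  r1 <- backward_eliminate(y, X)
  r2 <- backward_eliminate(y, X[, c("c", "b", "a")])
  expect_setequal(r1$retained$term, r2$retained$term)
})

test_that("a single strong predictor is retained with an empty trace", {
  set.seed(123)
  x <- rnorm(100); y <- 3 * x + rnorm(100)
  r <- backward_eliminate(y, data.frame(x = x))
  expect_equal(r$retained$term, "x")
  expect_lt(r$retained$p, 1e-6)
  expect_length(r$eliminated, 0L)
})

test_that("collinear predictors are named in the error", {
  set.seed(124)
  x <- rnorm(50)
  expect_error(backward_eliminate(rnorm(50),
                                  data.frame(u = x, w = 2 * x, z = rnorm(50))),
               "collinearity: predictors '[uw]' and '[uw]'")
  expect_error(backward_eliminate(rnorm(4), data.frame(a = rnorm(4),
                                                       b = rnorm(4))),
               "n > number of predictors")
})

test_that("pearson_corr matches its definition and planted correlations", {
  x <- 1:20
  expect_equal(pearson_corr(x, x)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_error(pearson_corr(x, rep(1, 20)), "zero variance")
  expect_error(pearson_corr(1:2, 2:1), "at least 3")
  # planted rho = 0.67 at n = 89 is recovered on average
  set.seed(131)
  rho <- 0.67
  rhat <- replicate(1000, {
    x <- rnorm(89); y <- rho * x + sqrt(1 - rho^2) * rnorm(89)
    pearson_corr(x, y)$r
  })
  expect_lt(abs(mean(rhat) - rho), 0.02)
})

test_that("null p-values are uniform (Kolmogorov-Smirnov)", {
  set.seed(132)
  p_pear <- replicate(2000, pearson_corr(rnorm(15), rnorm(15))$p)
  expect_gt(stats::ks.test(p_pear, "punif")$p.value, 0.01)
  p_anova <- replicate(2000, {
    d <- balanced_nested(4)
    nested_anova(d$y, d$category, d$population)$p[1]
  })
  expect_gt(stats::ks.test(p_anova, "punif")$p.value, 0.01)
})
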