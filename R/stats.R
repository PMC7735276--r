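#' Nested analysis of variance
#'
#' Fixed-effects ANOVA of `y ~ invasion_category + population(category)`
#' with population a nested fixed factor tested, like the category effect,
#' against the residual mean square. Sums of squares are Type III on a
#' sigma-restricted (sum-contrast) design: the design matrix carries one
#' sum-contrast column for the category and, for each category, sum
#' contrasts among its own populations, which stays full-rank even when the
#' number of populations differs between categories; each term's SS is the
#' increase in residual SS when its columns are dropped from the full model.
#' On balanced designs this coincides with the classical nested ANOVA table.
#'
#' @param y numeric response, one value per animal.
#' @param category factor-like with >= 2 levels. Each level should contain
#'   >= 2 populations; if every level holds exactly one population the model
#'   collapses to a one-way ANOVA on category, while a mixed design (one
#'   category with a single population, others with several) is a nesting
#'   degeneracy and raises an error.
#' @param population factor-like population labels (globally unique, each
#'   nested in one category), >= 2 observations each.
#' @return A data.frame (class `anova_result`) with columns `term`,
#'   `df_num`, `df_den`, `F`, `p`.
#' @export
nested_anova <- function(y, category, population) {
  category <- factor(category)
  population <- factor(population)
  if (length(unique(paste(category, population))) != nlevels(population))
    stop("each population must be nested within exactly one category")
  tab <- table(unique(data.frame(category, population))$category)
  one_pop_each <- all(tab == 1L)
  if (!one_pop_each && any(tab < 2L))
    stop("nesting degeneracy: category '",
         names(tab)[which(tab < 2L)[1]],
         "' contains a single population while others contain several")
  if (any(table(population) < 2L))
    stop("every population needs >= 2 observations")
  n <- length(y)
  # sum-contrast columns for category
  Xc <- stats::model.matrix(~ category,
                            contrasts.arg = list(category = "contr.sum"))[, -1,
                                                                          drop = FALSE]
  # within-category sum contrasts for populations; when every category has a
  # single population the nested term vanishes and the model collapses to a
  # one-way ANOVA on category
  Xp <- NULL
  if (!one_pop_each) {
    for (lev in levels(category)) {
      pops <- sort(unique(as.character(population[category == lev])))
      if (length(pops) < 2L) next
      C <- stats::contr.sum(length(pops))
      cols <- matrix(0, n, ncol(C))
      for (j in seq_along(pops)) {
        rows <- which(as.character(population) == pops[j])
        cols[rows, ] <- matrix(C[j, ], length(rows), ncol(C), byrow = TRUE)
      }
      Xp <- cbind(Xp, cols)
    }
  }
  X_full <- cbind(1, Xc, Xp)
  rss <- function(X) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  rss_full <- rss(X_full)
  df_den <- n - ncol(X_full)
  if (df_den < 1L) stop("no residual degrees of freedom")
  ms_res <- rss_full / df_den
  term_row <- function(term, drop_cols, df_num) {
    ss <- rss(X_full[, -drop_cols, drop = FALSE]) - rss_full
    tot <- sum((y - mean(y))^2)
    if (tot <= 1e-12 * max(1, mean(y)^2)) {
      F <- 0; p <- 1                      # constant response: no variation
    } else {
      F <- (ss / df_num) / ms_res
      p <- stats::pf(F, df_num, df_den, lower.tail = FALSE)
    }
    data.frame(term = term, df_num = df_num, df_den = df_den, F = F, p = p)
  }
  cat_cols <- 1L + seq_len(ncol(Xc))
  out <- term_row("category", cat_cols, ncol(Xc))
  if (!is.null(Xp)) {
    pop_cols <- 1L + ncol(Xc) + seq_len(ncol(Xp))
    out <- rbind(out, term_row("population(category)", pop_cols, ncol(Xp)))
  }
  class(out) <- c("anova_result", class(out))
  out
}

#' Category-by-trait interaction (profile analysis MANOVA)
#'
#' Tests whether multi-trait mean profiles are parallel between invasion
#' categories, treating the traits as a repeated measure: the trait matrix
#' is reduced to within-subject successive-difference contrasts and the
#' between-subject category effect on those contrasts is tested
#' multivariately. A non-zero effect means the categories differ by
#' different amounts on different traits - the category x trait
#' interaction. Wilks' lambda is the default statistic (Pillai available).
#' An optional nested population factor is partialled into the model.
#'
#' @param traits n x p numeric matrix (p >= 2) of trait values or residual
#'   shape scores; complete rows only.
#' @param category factor-like, >= 2 levels.
#' @param population optional nested population labels.
#' @param statistic `"Wilks"` or `"Pillai"`.
#' @return A data.frame (class `anova_result`) with the approximate F, its
#'   degrees of freedom, the p-value and the test statistic value; the
#'   conventional numerator df (traits - 1) x (categories - 1) is attached
#'   as attribute `df_interaction`.
#' @export
manova_traits_interaction <- function(traits, category, population = NULL,
                                      statistic = c("Wilks", "Pillai")) {
  statistic <- match.arg(statistic)
  traits <- as.matrix(traits)
  if (anyNA(traits)) stop("trait matrix must have complete rows")
  p <- ncol(traits)
  if (p < 2L) stop("need at least 2 traits")
  category <- factor(category)
  n <- nrow(traits)
  # within-subject successive-difference contrasts
  C <- diff(diag(p))            # (p-1) x p, rows trait_{j+1} - trait_j
  D <- traits %*% t(C)
  k <- nlevels(category)
  df_res <- n - k - if (is.null(population))
    0L else (length(unique(population)) - k)
  if (p - 1L > df_res)
    stop("rank deficiency: more trait contrasts than residual degrees of ",
         "freedom")
  if (is.null(population)) {
    full <- stats::lm(D ~ category)
    red <- stats::lm(D ~ 1)
  } else {
    population <- factor(population)
    full <- stats::lm(D ~ category + population)
    red <- stats::lm(D ~ population)
  }
  a <- stats::anova(red, full, test = statistic)
  stat <- a[[statistic]][2]
  out <- data.frame(term = "category:trait",
                    df_num = a$`num Df`[2], df_den = a$`den Df`[2],
                    F = a$`approx F`[2], p = a$`Pr(>F)`[2],
                    statistic = statistic, value = stat)
  attr(out, "df_interaction") <- (p - 1L) * (k - 1L)
  class(out) <- c("anova_result", class(out))
  out
}

#' Backward-elimination multiple regression
#'
#' Fits the full ordinary-least-squares model and repeatedly removes the
#' predictor with the largest p-value at or above `stay_threshold`,
#' refitting after each removal, until every remaining predictor is below
#' the threshold. Ties in p-value are broken by removing the later column
#' first. The removal order is recorded.
#'
#' @param y numeric response.
#' @param predictors data.frame or named matrix of candidate predictors;
#'   `n > ncol + 2` required.
#' @param stay_threshold p-value a term must beat to stay (default 0.05).
#' @return A list of class `regression_result`: `retained` (data.frame
#'   `term`, `beta`, `se`, `t`, `p`), `eliminated` (removal order),
#'   `stay_threshold`, `model` (the final `lm`).
#' @export
backward_eliminate <- function(y, predictors, stay_threshold = 0.05) {
  predictors <- as.data.frame(predictors)
  if (length(y) <= ncol(predictors) + 2L)
    stop("need n > number of predictors + 2")
  qrX <- qr(cbind(1, as.matrix(predictors)))
  if (qrX$rank < ncol(predictors) + 1L) {
    cm <- abs(stats::cor(predictors))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    stop("collinearity: predictors '", colnames(cm)[worst[1]], "' and '",
         colnames(cm)[worst[2]], "' are linearly dependent")
  }
  dat <- data.frame(.y = y, predictors, check.names = FALSE)
  terms_left <- names(predictors)
  trace <- character(0)
  repeat {
    fit <- stats::lm(stats::reformulate(sprintf("`%s`", terms_left), ".y"),
                     data = dat)
    coefs <- summary(fit)$coefficients
    rn <- gsub("`", "", rownames(coefs))
    pv <- coefs[match(terms_left, rn), 4]
    worst <- max(pv)
    if (worst < stay_threshold) break
    drop_idx <- max(which(pv == worst))     # tie: later column first
    trace <- c(trace, terms_left[drop_idx])
    terms_left <- terms_left[-drop_idx]
    if (length(terms_left) == 0L) {
      fit <- stats::lm(.y ~ 1, data = dat)
      coefs <- NULL
      break
    }
  }
  retained <- if (length(terms_left)) {
    coefs <- summary(fit)$coefficients
    rn <- gsub("`", "", rownames(coefs))
    idx <- match(terms_left, rn)
    data.frame(term = terms_left, beta = coefs[idx, 1], se = coefs[idx, 2],
               t = coefs[idx, 3], p = coefs[idx, 4], row.names = NULL)
  } else data.frame(term = character(0), beta = numeric(0), se = numeric(0),
                    t = numeric(0), p = numeric(0))
  structure(list(retained = retained, eliminated = trace,
                 stay_threshold = stay_threshold, model = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> retained ", nrow(x$retained), " term(s)",
      if (length(x$eliminated))
        paste0("; eliminated: ", paste(x$eliminated, collapse = " > ")),
      "\n", sep = "")
  if (nrow(x$retained)) print(x$retained, digits = 3)
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return A list of class `correlation_result`: `r`, `n`, `p` (two-sided
#'   t-test).
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(x),
                 p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, n = %d, p = %.4g\n",
              x$r, x$n, x$p))
  invisible(x)
}
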