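#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom. When every value is identical the statistic is
#' 0 and p = 1 (the tie-correction denominator degenerates).
#'
#' @param values Numeric response.
#' @param group Grouping factor (>= 2 nonempty groups, total n >= 3).
#' @return List with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(values, group) {
  group <- factor(group)
  if (anyNA(values)) stop("values must not contain NA")
  if (nlevels(group) < 2L) stop(">= 2 groups required")
  if (any(table(group) == 0L)) stop("empty group")
  if (length(values) < 3L) stop("total n must be >= 3")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = nlevels(group) - 1L, p.value = 1))
  kt <- stats::kruskal.test(values, group)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Pairwise two-sided Mann-Whitney U tests
#'
#' Exact p-values when both groups have at most `exact_max` observations and
#' the pair is tie-free; otherwise the normal approximation with continuity
#' and tie correction.
#'
#' @param values Numeric response.
#' @param group Grouping factor.
#' @param exact_max Largest per-group n for which the exact distribution is
#'   used (default 8).
#' @param p_adjust Multiplicity adjustment passed to [stats::p.adjust()];
#'   `"none"` by default (raw per-pair p-values).
#' @return Symmetric matrix of p-values (diagonal `NA`).
#' @export
pairwise_mwu <- function(values, group, exact_max = 8, p_adjust = "none") {
  group <- factor(group)
  g <- levels(group)
  if (length(g) < 2L) stop(">= 2 groups required")
  pmat <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  pairs <- utils::combn(length(g), 2L)
  praw <- apply(pairs, 2L, function(ij) {
    x <- values[group == g[ij[1L]]]
    y <- values[group == g[ij[2L]]]
    tie_free <- !anyDuplicated(c(x, y))
    ex <- length(x) <= exact_max && length(y) <= exact_max && tie_free
    suppressWarnings(stats::wilcox.test(x, y, exact = ex,
                                        correct = TRUE)$p.value)
  })
  praw <- stats::p.adjust(praw, method = p_adjust)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    pmat[i, j] <- pmat[j, i] <- praw[k]
  }
  pmat
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: starting from one letter covering all groups,
#' each significant pair splits every letter containing both members, and
#' letters whose group set is contained in another's are absorbed. Two groups
#' share a letter iff their pairwise p-value is >= `alpha`.
#'
#' @param pmat Symmetric p-value matrix with group names as dimnames.
#' @param alpha Significance level (default 0.05).
#' @return List of class `epg_letters`: `letters` (named character vector)
#'   and `alpha`.
#' @export
letter_display <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  stopifnot(!is.null(g), nrow(pmat) == ncol(pmat))
  cols <- list(rep(TRUE, length(g)))
  pairs <- utils::combn(length(g), 2L)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    if (!is.na(pmat[i, j]) && pmat[i, j] < alpha) {
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          newcols <- c(newcols, list(a, b))
        } else newcols <- c(newcols, list(col))
      }
      ## absorb: drop any letter whose set is a subset of another's
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
        if (a != b && keep[a] && keep[b] &&
            all(newcols[[b]][newcols[[a]]]) &&
            (sum(newcols[[a]]) < sum(newcols[[b]]) || a > b))
          keep[a] <- FALSE
      }
      cols <- newcols[keep]
    }
  }
  ord <- order(vapply(cols, function(c) which(c)[1L], 1L))
  cols <- cols[ord]
  lab <- vapply(seq_along(g), function(i)
    paste(letters[which(vapply(cols, `[`, TRUE, i))], collapse = ""), "")
  structure(list(letters = stats::setNames(lab, g), alpha = alpha),
            class = "epg_letters")
}

#' @export
print.epg_letters <- function(x, ...) {
  cat(sprintf("Compact letter display (alpha = %g): groups sharing a letter do not differ\n",
              x$alpha))
  print(x$letters)
  invisible(x)
}

#' Pairwise Mann-Whitney tests with compact letters
#'
#' @inheritParams pairwise_mwu
#' @param alpha Significance level for the letter display.
#' @return An `epg_letters` object carrying the p-value matrix as attribute
#'   `pmat`.
#' @export
pairwise_mwu_letters <- function(values, group, alpha = 0.05,
                                 exact_max = 8, p_adjust = "none") {
  pmat <- pairwise_mwu(values, group, exact_max = exact_max,
                       p_adjust = p_adjust)
  out <- letter_display(pmat, alpha)
  attr(out, "pmat") <- pmat
  out
}

#' Sequential (Type I) analysis of variance
#'
#' Fits a linear model and decomposes the corrected total sum of squares
#' sequentially in the order the terms appear in the formula, so that
#' degrees of freedom and sums of squares are additive even for unbalanced
#' designs.
#'
#' @param formula Model formula, e.g. `y ~ genotype * condition`.
#' @param data Data frame.
#' @return Data frame of class `epg_anova` with columns `term`, `df`,
#'   `sum_sq`, `mean_sq`, `statistic`, `p.value` (residual row last).
#' @export
anova_sequential <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(fit))) {
    tl <- attr(stats::terms(fit), "term.labels")
    asg <- attr(stats::model.matrix(fit), "assign")
    aliased_terms <- unique(tl[asg[is.na(stats::coef(fit))]])
    aliased_main <- aliased_terms[!grepl(":", aliased_terms)]
    if (length(aliased_main))
      stop("rank-deficient design: aliased term(s) ",
           paste(aliased_main, collapse = ", "))
  }
  at <- stats::anova(fit)
  out <- data.frame(term = rownames(at), df = at$Df, sum_sq = at$`Sum Sq`,
                    mean_sq = at$`Mean Sq`, statistic = at$`F value`,
                    p.value = at$`Pr(>F)`, stringsAsFactors = FALSE)
  out$term[out$term == "Residuals"] <- "Residuals"
  class(out) <- c("epg_anova", "data.frame")
  out
}

#' Two-way repeated-measures analysis of variance
#'
#' Univariate mixed decomposition with a between-subject stratum (the
#' between factor tested against subject-within-group error) and a
#' within-subject stratum (the within factor and its interaction with the
#' between factor tested against the subject-by-within residual). Subjects
#' not observed at every within-factor level are dropped with a warning.
#' The Greenhouse-Geisser epsilon for the within-stratum tests is computed
#' and attached as attribute `gg_epsilon` (uncorrected p-values are primary).
#'
#' @param data Data frame in long format.
#' @param response,subject,between,within Column names (strings).
#' @return `epg_anova` data frame with an extra `stratum` column.
#' @export
rm_anova <- function(data, response, subject, between, within) {
  d <- data.frame(y = data[[response]], subj = factor(data[[subject]]),
                  b = factor(data[[between]]), w = factor(data[[within]]))
  if (anyNA(d)) stop("missing values in response or design columns")
  k <- nlevels(d$w)
  complete <- names(which(tapply(as.integer(d$w), d$subj, function(w)
    length(unique(w)) == k && length(w) == k)))
  dropped <- setdiff(levels(d$subj), complete)
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " subject(s) with incomplete panels: ",
            paste(dropped, collapse = ", "))
    d <- droplevels(d[d$subj %in% complete, ])
  }
  if (any(table(unique(d[c("subj", "b")])$b) < 2L))
    stop("each between-group needs >= 2 complete subjects")
  fit <- stats::aov(y ~ b * w + Error(subj), data = d)
  sm <- summary(fit)
  grab <- function(stratum_name, tab) {
    tab <- tab[[1L]]
    data.frame(stratum = stratum_name, term = trimws(rownames(tab)),
               df = tab$Df, sum_sq = tab$`Sum Sq`, mean_sq = tab$`Mean Sq`,
               statistic = if ("F value" %in% names(tab)) tab$`F value`
                           else NA_real_,
               p.value = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)`
                         else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(grab("between", sm[["Error: subj"]]),
               grab("within", sm[["Error: Within"]]))
  rename <- c(b = between, w = within, "b:w" = paste0(between, ":", within))
  out$term <- ifelse(out$term %in% names(rename), rename[out$term], out$term)
  class(out) <- c("epg_anova", "data.frame")
  attr(out, "gg_epsilon") <- gg_epsilon(d)
  attr(out, "dropped_subjects") <- dropped
  out
}

## Greenhouse-Geisser epsilon from the pooled within-group covariance of the
## subject-by-within-level response matrix.
gg_epsilon <- function(d) {
  k <- nlevels(d$w)
  if (k < 2L) return(NA_real_)
  wide <- stats::reshape(d[order(d$subj, d$w), ],
                         idvar = "subj", timevar = "w",
                         v.names = "y", direction = "wide",
                         drop = "b")
  grp <- d$b[match(wide$subj, d$subj)]
  Y <- as.matrix(wide[, -1L, drop = FALSE])
  Yc <- Y - apply(Y, 2L, function(col) stats::ave(col, grp))
  S <- crossprod(Yc) / (nrow(Y) - nlevels(grp))
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))
  M <- t(C) %*% S %*% C
  (sum(diag(M)))^2 / ((k - 1) * sum(M^2))
}

#' Shapiro-Wilk normality check for model residuals
#'
#' @param residuals Numeric vector, 3 <= n <= 5000, nonconstant.
#' @return List with `statistic` (W) and `p.value`.
#' @export
normality_check <- function(residuals) {
  n <- length(residuals)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(residuals) == 0) stop("constant residual vector")
  sw <- stats::shapiro.test(residuals)
  list(statistic = unname(sw$statistic), p.value = sw$p.value)
}
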