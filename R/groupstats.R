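#' Variance-stabilising transforms for endpoint data
#'
#' `log1p` (ln(x + 1)) for enzyme/physiological measurements and the
#' arcsine square root for percentage/proportion data (values must already
#' be on the 0-1 scale; divide percentages by 100 first).
#'
#' @param values numeric vector.
#' @param kind `"none"`, `"log1p"` or `"arcsine_sqrt"`.
#' @return transformed numeric vector.
#' @export
apply_transform <- function(values, kind = c("none", "log1p", "arcsine_sqrt")) {
  kind <- match.arg(kind)
  switch(kind,
         none = values,
         log1p = log1p(values),
         arcsine_sqrt = {
           if (any(values < 0 | values > 1, na.rm = TRUE))
             stop("arcsine_sqrt requires values in [0, 1]")
           asin(sqrt(values))
         })
}

#' Screen one-way ANOVA assumptions for an endpoint table
#'
#' Shapiro-Wilk normality test on the residuals (value minus group mean;
#' per-group testing is powerless at the replicate counts typical of these
#' designs) and the median-centred Levene test for homogeneity of variance
#' across treatments, both at alpha = 0.05 two-tailed. When the tests are
#' undefined (e.g. all values identical) the screen is reported as
#' non-assessable, which routes the comparison to the nonparametric branch.
#'
#' @param table data.frame with columns `treatment` and `value` (one
#'   endpoint at a time).
#' @param alpha significance level for the screens.
#' @return list with `shapiro_p`, `levene_p`, `assessable`, `pass`.
#' @export
screen_assumptions <- function(table, alpha = 0.05) {
  g <- factor(table$treatment)
  v <- table$value
  if (nlevels(g) < 2) stop("need at least 2 treatments")
  if (any(tabulate(g) < 2)) stop("need at least 2 replicates per treatment")
  resid <- v - stats::ave(v, g)
  sh <- tryCatch(stats::shapiro.test(resid)$p.value,
                 error = function(e) NA_real_)
  lv <- tryCatch(car::leveneTest(v ~ g, center = stats::median)[1, "Pr(>F)"],
                 error = function(e) NA_real_)
  assessable <- is.finite(sh) && is.finite(lv)
  list(shapiro_p = sh, levene_p = lv, assessable = assessable,
       pass = assessable && sh >= alpha && lv >= alpha)
}

# Dunn's post hoc test after Kruskal-Wallis: pairwise z statistics on mean
# ranks with the tie correction, two-sided p-values.
.dunn_test <- function(value, group) {
  g <- factor(group)
  N <- length(value)
  rk <- rank(value)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rk <- tapply(rk, g, mean)
  n_g <- tabulate(g)
  lev <- levels(g)
  pairs <- utils::combn(seq_along(lev), 2)
  z <- p <- numeric(ncol(pairs))
  lab <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[i] + 1 / n_g[j]))
    z[k] <- (mean_rk[i] - mean_rk[j]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
    lab[k] <- paste(lev[i], lev[j], sep = "-")
  }
  data.frame(pair = lab, statistic = z, p_raw = p,
             p_adj = stats::p.adjust(p, method = "holm"),
             stringsAsFactors = FALSE)
}

# Compact letter display by insert-and-absorb on the adjusted pairwise
# p-values: groups sharing a letter are not significantly different.
# Columns are ordered by their alphabetically-first member for
# deterministic letter assignment.
.cld <- function(levels_, pair_df, alpha = 0.05) {
  k <- length(levels_)
  cols <- list(seq_len(k))
  sig <- pair_df[pair_df$p_adj < alpha, , drop = FALSE]
  for (row in seq_len(nrow(sig))) {
    ij <- match(strsplit(sig$pair[row], "-", fixed = TRUE)[[1]], levels_)
    i <- ij[1]; j <- ij[2]
    newcols <- list()
    for (col in cols) {
      if (i %in% col && j %in% col) {
        newcols <- c(newcols, list(setdiff(col, i)), list(setdiff(col, j)))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb: drop any column contained in another
    keep <- rep(TRUE, length(newcols))
    for (x in seq_along(newcols)) {
      for (y in seq_along(newcols)) {
        if (x != y && keep[y] &&
            all(newcols[[x]] %in% newcols[[y]]) &&
            (length(newcols[[x]]) < length(newcols[[y]]) || x > y)) {
          keep[x] <- FALSE
          break
        }
      }
    }
    cols <- newcols[keep]
  }
  ord <- order(vapply(cols, function(c) min(levels_[c]), character(1)))
  cols <- cols[ord]
  letters_out <- rep("", k)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) {
      letters_out[g] <- paste0(letters_out[g], letters[ci])
    }
  }
  stats::setNames(letters_out, levels_)
}

#' Assumption-screened group comparison for one endpoint
#'
#' Implements the decision procedure used for replicate-level endpoint
#' tables: screen the raw values (residual Shapiro-Wilk + median-centred
#' Levene); if the screen fails (or is non-assessable), apply the
#' configured transform and re-screen; if the (possibly transformed) data
#' pass, run one-way ANOVA with Tukey's HSD, otherwise fall back to the
#' Kruskal-Wallis test with Dunn's post hoc comparisons under the Holm
#' adjustment. Group letters are assigned by compact letter display on the
#' adjusted pairwise p-values (ties broken alphabetically by treatment
#' label).
#'
#' @param table data.frame with columns `treatment`, `value` (a single
#'   endpoint); extra columns are ignored.
#' @param transform transform to attempt when the raw screen fails:
#'   `"log1p"` (measurements, the default) or `"arcsine_sqrt"`
#'   (proportions), or `"none"` to disable.
#' @param alpha significance level (default 0.05, two-tailed).
#' @return An object of class `"comparison_result"`: list with
#'   `test_used`, `transform_used`, `assumptions` (raw and, if attempted,
#'   transformed screens), `omnibus` (statistic, df, p), `pairwise`
#'   (data.frame `pair, statistic, p_raw, p_adj`), `letters`,
#'   `group_means`.
#' @export
compare_groups <- function(table, transform = c("log1p", "arcsine_sqrt", "none"),
                           alpha = 0.05) {
  transform <- match.arg(transform)
  g <- factor(table$treatment)
  if (nlevels(g) < 2) stop("need at least 2 treatment groups")
  v0 <- table$value

  if (stats::sd(v0) == 0) {
    # degenerate: no variation anywhere, so no evidence of any difference
    lev <- levels(g)
    pairs <- utils::combn(lev, 2, paste, collapse = "-")
    pw <- data.frame(pair = pairs, statistic = 0, p_raw = 1, p_adj = 1,
                     stringsAsFactors = FALSE)
    out <- list(
      test_used = "KruskalWallis+Dunn-Holm", transform_used = "none",
      assumptions = list(raw = list(shapiro_p = NA_real_,
                                    levene_p = NA_real_,
                                    assessable = FALSE, pass = FALSE),
                         transformed = NULL),
      omnibus = list(statistic = 0, df = nlevels(g) - 1, p = 1),
      pairwise = pw, letters = .cld(lev, pw, alpha),
      group_means = tapply(v0, g, mean), alpha = alpha)
    class(out) <- "comparison_result"
    return(out)
  }

  scr_raw <- screen_assumptions(data.frame(treatment = g, value = v0), alpha)
  used <- "none"
  v <- v0
  scr_tr <- NULL
  scr <- scr_raw
  if (!scr_raw$pass && transform != "none") {
    vt <- apply_transform(v0, transform)
    scr_tr <- screen_assumptions(data.frame(treatment = g, value = vt), alpha)
    if (scr_tr$assessable) {
      used <- transform
      v <- vt
      scr <- scr_tr
    }
  }

  if (scr$pass) {
    fit <- stats::aov(v ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    pairs <- data.frame(
      pair = rownames(tk), statistic = tk[, "diff"],
      p_raw = tk[, "p adj"], p_adj = tk[, "p adj"],
      stringsAsFactors = FALSE, row.names = NULL)
    omnibus <- list(statistic = an[1, "F value"], df = an[1, "Df"],
                    p = an[1, "Pr(>F)"])
    test_used <- "ANOVA+TukeyHSD"
  } else {
    kw <- stats::kruskal.test(v, g)
    pairs <- .dunn_test(v, g)
    omnibus <- list(statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p = kw$p.value)
    test_used <- "KruskalWallis+Dunn-Holm"
  }
  out <- list(
    test_used = test_used,
    transform_used = used,
    assumptions = list(raw = scr_raw, transformed = scr_tr),
    omnibus = omnibus,
    pairwise = pairs,
    letters = .cld(levels(g), pairs, alpha),
    group_means = tapply(v0, g, mean),
    alpha = alpha
  )
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Group comparison:", x$test_used,
      "(transform:", x$transform_used, ")\n")
  cat(sprintf("  omnibus statistic = %.4f, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$p))
  means <- x$group_means
  for (g in names(means)) {
    cat(sprintf("  %-6s mean = %10.4f  %s\n", g, means[[g]], x$letters[[g]]))
  }
  invisible(x)
}

#' Compare every endpoint in a long-format endpoint table
#'
#' Applies [compare_groups()] per endpoint and returns a flat summary
#' suitable for TSV export: the branch taken, omnibus p, and the letter
#' grouping of each treatment.
#'
#' @param endpoints data.frame `endpoint, treatment, replicate, value`.
#' @param transform passed to [compare_groups()].
#' @param alpha significance level.
#' @return list of `"comparison_result"` keyed by endpoint, with a
#'   `summary` attribute (data.frame).
#' @export
compare_endpoints <- function(endpoints, transform = "log1p", alpha = 0.05) {
  eps <- split(endpoints, endpoints$endpoint)
  res <- lapply(eps, compare_groups, transform = transform, alpha = alpha)
  summ <- do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    data.frame(endpoint = nm, test_used = r$test_used,
               transform_used = r$transform_used,
               omnibus_p = r$omnibus$p,
               treatment = names(r$letters),
               mean = as.numeric(r$group_means[names(r$letters)]),
               letters = unname(r$letters),
               stringsAsFactors = FALSE)
  }))
  attr(res, "summary") <- summ
  res
}
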