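# Group-comparison statistics on per-animal summaries: two-way ANOVA
# (age x stress, Type II SS), Mann-Whitney U, Kruskal-Wallis,
# two-sample Kolmogorov-Smirnov, Pearson correlation, and eCDF tables.
# The unit of analysis is the animal: every measure is averaged by animal
# before any test.  Standard machinery (wilcox.test, kruskal.test,
# ks.test, cor.test, lm + car::Anova) sits behind these wrappers; the
# wrappers pin down the conventions (U = min(Ux, Uy); exact Mann-Whitney
# p for n <= 8 without ties; asymptotic KS p) so results are reproducible
# across platforms.

#' Two-way analysis of variance (age x stress)
#'
#' Fits `value ~ age * stress` and reports Type II sums of squares by
#' default (cohorts are allowed to be mildly unbalanced); Type I/III are
#' selectable.  Per-term F and p are returned for the two main effects
#' and the interaction.  Terms with zero between-group sum of squares
#' report F = 0; a perfect fit (zero residual variance with nonzero
#' effect SS) is flagged `degenerate` with infinite F.
#'
#' @param values numeric response, one entry per animal.
#' @param age,stress factor labels, same length as `values`; at least two
#'   levels each and at least one observation per crossed cell.
#' @param ss_type sums-of-squares type: 2 (default), 1 or 3.
#' @return data.frame with rows `age`, `stress`, `age:stress`: `df`,
#'   `sumsq`, `F`, `p`; attributes `n`, `degenerate`.
#' @export
two_way_anova <- function(values, age, stress, ss_type = 2) {
  stopifnot(length(values) == length(age), length(values) == length(stress))
  keep <- complete.cases(values, age, stress)
  values <- values[keep]
  age <- factor(age)[keep, drop = TRUE]
  stress <- factor(stress)[keep, drop = TRUE]
  if (nlevels(age) < 2 || nlevels(stress) < 2)
    stop("both factors need at least two levels", call. = FALSE)
  cells <- table(age, stress)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("unbalanced design: empty cell age=%s, stress=%s",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]),
         call. = FALSE)
  }
  dat <- data.frame(value = values, age = age, stress = stress)
  fit <- lm(value ~ age * stress, data = dat)
  terms_out <- c("age", "stress", "age:stress")
  rss <- sum(fit$residuals^2)
  df_res <- fit$df.residual

  ss <- if (ss_type == 1) {
    a1 <- stats::anova(fit)
    setNames(a1[terms_out, "Sum Sq"], terms_out)
  } else {
    # car::Anova refuses a zero residual sum of squares; sequential SS
    # are exact there (the perfect-fit case only arises for balanced
    # noise-free constructions, where all SS types coincide)
    a2 <- suppressWarnings(tryCatch(
      car::Anova(fit, type = ss_type, singular.ok = TRUE),
      error = function(e) stats::anova(fit)))
    setNames(a2[terms_out, "Sum Sq"], terms_out)
  }
  dfs <- c(age = nlevels(age) - 1L, stress = nlevels(stress) - 1L,
           "age:stress" = (nlevels(age) - 1L) * (nlevels(stress) - 1L))
  ms_res <- if (df_res > 0) rss / df_res else NaN
  Fv <- numeric(3)
  pv <- numeric(3)
  degenerate <- FALSE
  for (i in 1:3) {
    s <- ss[i]
    if (!is.finite(s) || s <= 1e-12) {
      Fv[i] <- 0; pv[i] <- 1
    } else if (!is.finite(ms_res) || ms_res <= 1e-12) {
      Fv[i] <- Inf; pv[i] <- 0; degenerate <- TRUE
    } else {
      Fv[i] <- (s / dfs[i]) / ms_res
      pv[i] <- pf(Fv[i], dfs[i], df_res, lower.tail = FALSE)
    }
  }
  out <- data.frame(term = terms_out, df = as.integer(dfs), sumsq = unname(ss),
                    F = Fv, p = pv, row.names = NULL)
  attr(out, "n") <- length(values)
  attr(out, "degenerate") <- degenerate
  attr(out, "ss_type") <- ss_type
  out
}

#' Mann-Whitney U test
#'
#' Reports the smaller of the two U statistics (min(Ux, Uy) convention,
#' midranks for ties).  The p-value is exact when both samples have at
#' most 8 observations and there are no ties, otherwise the tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y numeric samples (nonempty).
#' @return one-row data.frame: `test`, `statistic`, `U`, `p`, `n1`, `n2`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 <= 8 && n2 <= 8 && !ties)
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  ux <- unname(wt$statistic)          # number of (x_i > y_j) pairs (midranks)
  u <- min(ux, n1 * n2 - ux)
  data.frame(test = "mann_whitney_u", statistic = "U", U = u,
             p = unname(wt$p.value), n1 = n1, n2 = n2,
             method = if (exact) "exact" else "normal")
}

#' Kruskal-Wallis rank test
#'
#' @param groups list of numeric samples (>= 2 nonempty groups).
#' @return one-row data.frame: `H` (tie-corrected), `df`, `p`
#'   (chi-square).  All-identical data across groups gives H = 0.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 0L) > 0))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (length(unique(values)) == 1L) {
    return(data.frame(test = "kruskal_wallis", statistic = "H", H = 0,
                      df = length(groups) - 1L, p = 1,
                      n = length(values)))
  }
  kt <- kruskal.test(values, g)
  data.frame(test = "kruskal_wallis", statistic = "H",
             H = unname(kt$statistic), df = unname(kt$parameter),
             p = unname(kt$p.value), n = length(values))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = max |eCDF_x - eCDF_y| with the asymptotic p-value (ties tolerated,
#' warning suppressed; eCDF comparisons are the intended use).
#'
#' @param x,y numeric samples (nonempty).
#' @return one-row data.frame: `D`, `p`, `n1`, `n2`.
#' @export
ks_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) > 0, length(y) > 0)
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  data.frame(test = "ks", statistic = "D", D = unname(kt$statistic),
             p = unname(kt$p.value), n1 = length(x), n2 = length(y))
}

#' Pearson correlation with two-sided t-based p-value
#'
#' Pairs with a missing value in either vector are dropped (pairwise
#' deletion), matching how partially observed covariates such as spine
#' densities are handled.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs
#'   and nonzero variance in both.
#' @return one-row data.frame: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  data.frame(test = "pearson", statistic = "r", r = unname(ct$estimate),
             p = unname(ct$p.value), n = length(x))
}

#' Empirical cumulative distribution function as a point table
#'
#' Right-continuous step function evaluated at the distinct sample
#' values; the final cumulative fraction is 1.
#'
#' @param values nonempty numeric vector.
#' @return data.frame with columns `value` (ascending) and `fraction`.
#' @export
ecdf_table <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) > 0)
  v <- sort(unique(values))
  data.frame(value = v,
             fraction = cumsum(tabulate(match(sort(values), v))) /
               length(values))
}

#' Aggregate image-level results into per-animal summaries
#'
#' One row per animal: each measure is the mean over that animal's
#' images (soma volume the mean over its microglial cells), the unit of
#' analysis for all group statistics.  Animals with zero classified
#' microglia get `NA` (not zero) for microglia-derived measures.
#'
#' @param cells cell table rows from [classify_cells()] for all images.
#' @param image_summaries rows from [image_gr_summary()] for all images.
#' @param manifest data.frame mapping `image_id` to `animal_id`, `age`,
#'   `stress`; every image must appear.
#' @param covariates optional per-animal data.frame (keyed `animal_id`)
#'   of external covariates, e.g. spine densities; merged by animal.
#' @return data.frame, one row per animal.
#' @export
per_animal_summary <- function(cells, image_summaries, manifest,
                               covariates = NULL) {
  if (!all(image_summaries$image_id %in% manifest$image_id))
    stop("image without manifest entry: ",
         paste(setdiff(image_summaries$image_id, manifest$image_id),
               collapse = ", "), call. = FALSE)
  key <- manifest[!duplicated(manifest$animal_id),
                  c("animal_id", "age", "stress")]
  im <- merge(image_summaries[setdiff(names(image_summaries), "animal_id")],
              manifest[, c("image_id", "animal_id")], by = "image_id")
  measures <- c("n_microglia", "n_high_gr_nuclei", "microglia_volume",
                "astrocyte_volume", "nonnuclear_gr_microglia",
                "nonnuclear_gr_astrocyte")
  agg <- aggregate(im[measures], by = list(animal_id = im$animal_id), mean)
  # soma: average over the animal's microglial cells (animal resolved
  # through the manifest, so cell tables need not carry animal ids)
  cells <- merge(cells[setdiff(names(cells), "animal_id")],
                 manifest[, c("image_id", "animal_id")], by = "image_id")
  mic <- cells[cells$cell_type == "microglia", , drop = FALSE]
  soma <- if (nrow(mic))
    aggregate(list(mean_soma_volume = mic$soma_volume),
              by = list(animal_id = mic$animal_id), mean)
  else data.frame(animal_id = character(0), mean_soma_volume = numeric(0))
  out <- merge(agg, soma, by = "animal_id", all.x = TRUE)
  # zero classified microglia => microglial measures are missing, not zero
  none <- out$n_microglia == 0
  out$nonnuclear_gr_microglia[none] <- NA_real_
  out$mean_soma_volume[none] <- NA_real_
  out <- merge(key, out, by = "animal_id")
  if (!is.null(covariates))
    out <- merge(out, covariates, by = "animal_id", all.x = TRUE)
  out[order(out$animal_id), , drop = FALSE]
}

#' Group statistics over an animal summary table
#'
#' Runs the two-way age x stress ANOVA for each measure (when both
#' factors have two or more levels and all crossed cells are populated),
#' plus young-vs-aged Mann-Whitney and KS tests, and Pearson correlations
#' against any supplied covariate columns.
#'
#' @param summary_df output of [per_animal_summary()].
#' @param measures measure columns to test.
#' @param covariate_cols columns to correlate with each measure.
#' @return data.frame of test results (one row per measure x test x term).
#' @export
group_statistics <- function(summary_df,
                             measures = c("microglia_volume", "n_microglia",
                                          "mean_soma_volume",
                                          "nonnuclear_gr_microglia",
                                          "nonnuclear_gr_astrocyte",
                                          "astrocyte_volume",
                                          "n_high_gr_nuclei"),
                             covariate_cols = NULL) {
  rows <- list()
  two_ages <- length(unique(summary_df$age)) >= 2
  for (m in intersect(measures, names(summary_df))) {
    v <- summary_df[[m]]
    ok <- !is.na(v)
    if (sum(ok) < 4) next
    can_anova <- two_ages && length(unique(summary_df$stress[ok])) >= 2 &&
      all(table(summary_df$age[ok], summary_df$stress[ok]) > 0)
    if (can_anova) {
      an <- two_way_anova(v[ok], summary_df$age[ok], summary_df$stress[ok])
      rows[[length(rows) + 1L]] <-
        data.frame(measure = m, test = "two_way_anova", term = an$term,
                   statistic = "F", value = an$F, p = an$p,
                   n = sum(ok))
    }
    if (two_ages) {
      xa <- v[ok & summary_df$age == "young"]
      ya <- v[ok & summary_df$age == "aged"]
      if (length(xa) && length(ya)) {
        mw <- mann_whitney_u(xa, ya)
        ks <- ks_test(xa, ya)
        rows[[length(rows) + 1L]] <-
          data.frame(measure = m, test = c("mann_whitney_u", "ks"),
                     term = "age", statistic = c("U", "D"),
                     value = c(mw$U, ks$D), p = c(mw$p, ks$p), n = sum(ok))
      }
    }
    for (cv in intersect(covariate_cols %||% character(0), names(summary_df))) {
      ok2 <- ok & !is.na(summary_df[[cv]])
      if (sum(ok2) >= 3 && sd(v[ok2]) > 0 && sd(summary_df[[cv]][ok2]) > 0) {
        pr <- pearson_r(v[ok2], summary_df[[cv]][ok2])
        rows[[length(rows) + 1L]] <-
          data.frame(measure = m, test = "pearson", term = cv,
                     statistic = "r", value = pr$r, p = pr$p, n = pr$n)
      }
    }
  }
  if (!length(rows))
    return(data.frame(measure = character(0), test = character(0),
                      term = character(0), statistic = character(0),
                      value = numeric(0), p = numeric(0), n = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
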