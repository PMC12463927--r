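#' Route a two-group comparison to a parametric or rank test
#'
#' Student's t-test is used only when Shapiro-Wilk finds no evidence
#' against normality in *both* groups (p > alpha in each) and Levene's
#' test (mean-centered) finds no evidence of unequal variances; otherwise
#' the Mann-Whitney U test. Samples too small or too degenerate for
#' Shapiro-Wilk route to Mann-Whitney with a warning.
#'
#' @param x,y the two samples.
#' @param alpha gate level for the normality/variance checks (default 0.05).
#' @return `"student_t"` or `"mann_whitney"`.
#' @export
routeTest <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) {
    warning("sample too small for Shapiro-Wilk; routing to Mann-Whitney")
    return("mann_whitney")
  }
  swp <- function(v) tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
  px <- swp(x); py <- swp(y)
  if (is.na(px) || is.na(py)) {
    warning("Shapiro-Wilk unavailable (degenerate sample); routing to Mann-Whitney")
    return("mann_whitney")
  }
  if (px <= alpha || py <= alpha) return("mann_whitney")
  lev <- tryCatch({
    d <- data.frame(v = c(x, y),
                    g = factor(rep(c("x", "y"), c(length(x), length(y)))))
    car::leveneTest(v ~ g, data = d, center = "mean")[["Pr(>F)"]][1]
  }, error = function(e) NA_real_)
  if (is.na(lev)) {
    warning("Levene test unavailable; routing to Mann-Whitney")
    return("mann_whitney")
  }
  if (lev > alpha) "student_t" else "mann_whitney"
}

#' Pooled-variance t statistic from group summaries
#'
#' `t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2))` with
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` — the classical
#' independent-samples (Student) t computed from printed means and SDs.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return the t statistic.
#' @examples
#' tFromSummary(26.70, 1.38, 20, 19.91, 2.98, 21)  # about 9.28
#' @export
tFromSummary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) return(0)
    stop("zero pooled variance with unequal means: t undefined")
  }
  (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_p` with the same pooled SD as
#' [tFromSummary()]. With `x` the MCI sample and `y` the NC sample,
#' positive values mean MCI > NC.
#'
#' @param x,y the two samples (each n >= 2).
#' @return the effect size.
#' @export
cohensD <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both groups need n >= 2")
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) stop("zero pooled SD: effect size undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Cliff's delta
#'
#' `(#{x_i > y_j} - #{x_i < y_j}) / (n_x * n_y)`, computed exactly over all
#' pairs. Ranges over [-1, 1]; with `x` the MCI sample, positive values
#' mean MCI values tend to exceed NC values.
#'
#' @param x,y the two samples (non-empty).
#' @return the effect size in [-1, 1].
#' @export
cliffsDelta <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  mean(sign(outer(x, y, `-`)))
}

#' Pearson chi-square for a 2x2 table
#'
#' `sum (O - E)^2 / E` over the four cells, *without* continuity
#' correction.
#'
#' @param tab 2x2 matrix of counts.
#' @return the chi-square statistic.
#' @examples
#' chiSquare2x2(matrix(c(12, 15, 8, 6), 2))  # about 0.595
#' @export
chiSquare2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("tab must be 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: expected counts undefined")
  unname(chisq.test(tab, correct = FALSE)$statistic)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR q-values, `q_(i) = min_{j >= i} (p_(j) * m / j)` clipped to
#' 1, returned in input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bhFdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return list with `r`, `p` and `n`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (var(x) == 0 || var(y) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# run the routed two-group test for one unit; returns a one-row data.frame
routed_comparison <- function(x, y, alpha) {
  const <- length(unique(c(x, y))) == 1L
  route <- if (const) "mann_whitney" else
    suppressWarnings(routeTest(x, y, alpha))
  if (route == "student_t") {
    tt <- t.test(x, y, var.equal = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
    eff <- cohensD(x, y); etype <- "cohens_d"
  } else {
    if (const) { stat <- NA_real_; p <- 1 } else {
      wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    eff <- cliffsDelta(x, y); etype <- "cliffs_delta"
  }
  dm <- mean(x) - mean(y)
  data.frame(test = route, statistic = stat, p = p, effect = eff,
             effect_type = etype,
             direction = if (dm > 0) "MCI>NC" else if (dm < 0) "MCI<NC" else "MCI=NC",
             stringsAsFactors = FALSE)
}

#' Electrode- or edge-wise two-group comparison with FDR
#'
#' For every unit (electrode, or directed source-target edge) and band:
#' route the MCI-vs-NC comparison by normality and variance checks, run
#' Student's t or Mann-Whitney U, compute the matching effect size
#' (Cohen's d or Cliff's delta; positive = MCI > NC), then apply
#' Benjamini-Hochberg FDR within each family. The default family is all
#' units of one band (the per-band multiple-comparison scope of
#' electrode-wise and edge-wise maps).
#'
#' @param tbl long-format table with columns `subject_id`, `group`, `band`,
#'   a value column, and either `electrode` or `source` + `target`.
#' @param value name of the value column (default `"power"`, use e.g.
#'   `"thresholded"` for connectivity tables).
#' @param alpha significance level for `significant = q < alpha`
#'   (default 0.05); also the routing gate level.
#' @param familyBy columns defining each FDR family (default `"band"`).
#' @return data.frame with one row per unit x band: unit columns, `band`,
#'   `test`, `statistic`, `p`, `q`, `effect`, `effect_type`, `direction`,
#'   `significant`.
#' @export
compareGroups <- function(tbl, value = "power", alpha = 0.05,
                          familyBy = "band") {
  need <- c("subject_id", "group", "band", value)
  if (!all(need %in% names(tbl)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  unitCols <- if ("electrode" %in% names(tbl)) "electrode"
              else if (all(c("source", "target") %in% names(tbl))) c("source", "target")
              else stop("table must have an 'electrode' or 'source'+'target' unit column")
  if (!all(EEG_GROUPS %in% tbl$group)) stop("both groups (NC, MCI) are required")
  cnt <- table(unique(tbl[c("subject_id", "group")])$group)
  if (any(cnt[EEG_GROUPS] < 2)) stop("insufficient data: need >= 2 subjects per group")

  keyFac <- interaction(tbl[c(unitCols, "band")], drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(tbl)), keyFac)
  rows <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    sub <- tbl[idx[[i]], ]
    x <- sub[[value]][sub$group == "MCI"]
    y <- sub[[value]][sub$group == "NC"]
    if (length(x) < 2 || length(y) < 2)
      stop("insufficient data for unit ", gsub("\r", "/", names(idx)[i]))
    rows[[i]] <- cbind(sub[1, c(unitCols, "band"), drop = FALSE],
                       routed_comparison(x, y, alpha))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fam <- interaction(out[, familyBy, drop = FALSE], drop = TRUE)
  out$q <- NA_real_
  for (f in levels(fam)) out$q[fam == f] <- bhFdr(out$p[fam == f])
  out$significant <- out$q < alpha
  cols <- c(unitCols, "band", "test", "statistic", "p", "q", "effect",
            "effect_type", "direction", "significant")
  out[, cols]
}

#' Correlate connectivity edges with MoCA scores
#'
#' Pearson correlation between each edge's value and the subjects' MoCA
#' scores, pooled across both groups (one row per edge x band).
#'
#' @param connTbl long connectivity table (as from
#'   [cohortConnectivityTable()]) with a `moca` column.
#' @param value name of the value column (default `"value"`).
#' @param edges optional data.frame(band, source, target) restricting which
#'   edges to correlate (e.g. the significant ones); default all.
#' @return data.frame with columns `band`, `source`, `target`, `r`, `p`,
#'   `n`.
#' @export
correlateWithMoca <- function(connTbl, value = "value", edges = NULL) {
  need <- c("subject_id", "moca", "band", "source", "target", value)
  if (!all(need %in% names(connTbl)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (is.null(edges)) edges <- unique(connTbl[c("band", "source", "target")])
  rows <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    sub <- connTbl[connTbl$band == edges$band[i] &
                   connTbl$source == edges$source[i] &
                   connTbl$target == edges$target[i], ]
    ok <- is.finite(sub[[value]]) & is.finite(sub$moca)
    r <- tryCatch(pearsonR(sub[[value]][ok], sub$moca[ok]),
                  error = function(e) list(r = NA_real_, p = NA_real_,
                                           n = sum(ok)))
    rows[[i]] <- data.frame(band = edges$band[i], source = edges$source[i],
                            target = edges$target[i], r = r$r, p = r$p,
                            n = r$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
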