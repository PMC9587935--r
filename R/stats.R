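#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits a fully within-participant ANOVA (up to three crossed within
#' factors, balanced complete design) and reports, for every main effect and
#' interaction, the F statistic, degrees of freedom, p value, generalized
#' eta squared, and - for effects involving a factor with more than two
#' levels - the Greenhouse-Geisser epsilon with sphericity-corrected
#' (fractional) degrees of freedom and p value. Two-level factors are
#' sphericity-trivial, so no correction is applied to them.
#'
#' Sums of squares come from the classical univariate partition
#' (`stats::aov` with an `Error(id/...)` stratification). Generalized eta
#' squared uses the observed-variance denominator: the effect sum of squares
#' divided by itself plus all subject-related error sums of squares
#' (the subject stratum plus every within-stratum residual).
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric dependent-variable column.
#' @param id Name of the participant identifier column.
#' @param within Character vector (1-3) of within-participant factor columns.
#' @return A data frame of class `"loc3d_anova"`: columns `term`, `df1`,
#'   `df2`, `SS`, `SS_err`, `F`, `p`, `ges`, `gg_epsilon`, `df1_gg`,
#'   `df2_gg`, `p_gg`, `correction`.
#' @export
#' @examples
#' d <- expand.grid(id = factor(1:6), cond = c("a", "b"))
#' d$y <- rnorm(nrow(d)) + (d$cond == "b")
#' rm_anova(d, "y", "id", "cond")
rm_anova <- function(data, dv, id, within) {
  stopifnot(is.data.frame(data), dv %in% names(data), id %in% names(data),
            all(within %in% names(data)), length(within) >= 1L,
            length(within) <= 3L)
  d <- data.frame(.y = as.numeric(data[[dv]]), .id = factor(data[[id]]))
  for (w in within) d[[w]] <- factor(data[[w]])
  if (any(!is.finite(d$.y))) stop("dependent variable must be finite", call. = FALSE)
  n_id <- nlevels(d$.id)
  if (n_id < 3L) stop("at least 3 participants are required", call. = FALSE)

  ## balanced complete design check, with explicit cell listing
  cells <- table(d[c(".id", within)])
  if (any(cells == 0L)) {
    miss <- which(cells == 0L, arr.ind = TRUE)
    lab <- apply(miss, 1, function(i)
      paste(mapply(function(dim, lev) dimnames(cells)[[dim]][lev],
                   seq_along(i), i), collapse = ":"))
    stop("missing cells in the within-participant design: ",
         paste(utils::head(lab, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(unique(as.vector(cells))) != 1L)
    stop("design is unbalanced: unequal trial counts per cell", call. = FALSE)
  ## collapse replicates to cell means (classical repeated-measures layout)
  d <- stats::aggregate(d[".y"], by = d[c(".id", within)], FUN = mean)

  rhs <- paste(within, collapse = "*")
  form <- stats::as.formula(
    sprintf(".y ~ %s + Error(.id/(%s))", rhs, rhs))
  fit <- stats::aov(form, data = d)
  strata <- summary(fit)

  ## collect (term, SS, df) and each stratum's residual
  rows <- list()
  resid_ss <- 0
  for (s in seq_along(strata)) {
    tab <- strata[[s]][[1L]]
    terms_here <- trimws(rownames(tab))
    res_k <- which(terms_here == "Residuals")
    for (k in seq_along(terms_here)) {
      if (k %in% res_k) {
        resid_ss <- resid_ss + tab[k, "Sum Sq"]
      } else {
        rows[[terms_here[k]]] <- list(
          SS = tab[k, "Sum Sq"], df1 = tab[k, "Df"],
          SS_err = tab[res_k[1L], "Sum Sq"],
          df2 = tab[res_k[1L], "Df"])
      }
    }
  }

  total_ss <- sum(vapply(rows, `[[`, numeric(1), "SS")) + resid_ss
  out <- do.call(rbind, lapply(names(rows), function(term) {
    r <- rows[[term]]
    if (r$SS <= 1e-12 * max(1e-300, total_ss)) {
      ## a numerically null effect (e.g. identical condition means per
      ## participant) is reported as F = 0 even when its error stratum is
      ## also degenerate
      Fv <- 0; p <- 1
    } else {
      Fv <- (r$SS / r$df1) / (r$SS_err / r$df2)
      p <- stats::pf(Fv, r$df1, r$df2, lower.tail = FALSE)
    }
    eps <- if (r$df1 > 1L) gg_epsilon(d, term, within) else 1
    corrected <- r$df1 > 1L
    data.frame(term = term, df1 = r$df1, df2 = r$df2, SS = r$SS,
               SS_err = r$SS_err, F = Fv, p = p,
               ges = r$SS / (r$SS + resid_ss),
               gg_epsilon = eps,
               df1_gg = eps * r$df1, df2_gg = eps * r$df2,
               p_gg = stats::pf(Fv, eps * r$df1, eps * r$df2,
                                lower.tail = FALSE),
               correction = if (corrected) "GG" else "none",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("loc3d_anova", "data.frame")
  out
}

## Greenhouse-Geisser epsilon for one effect: project the participant x cell
## matrix (averaged over factors not in the term) onto the term's orthonormal
## contrasts and apply the standard trace formula
gg_epsilon <- function(d, term, within) {
  fac <- strsplit(term, ":", fixed = TRUE)[[1L]]
  agg <- stats::aggregate(d[".y"], by = d[c(".id", fac)], FUN = mean)
  agg <- agg[do.call(order, agg[c(fac, ".id")]), ]
  n <- nlevels(agg$.id)
  Y <- matrix(agg$.y, nrow = n)  # participants x cells, cells in factor order
  M <- Reduce(function(A, B) kronecker(A, B),
              lapply(fac, function(f) orthonormal_contrasts(nlevels(agg[[f]]))))
  E <- t(M) %*% stats::cov(Y) %*% M
  df <- ncol(M)
  eps <- sum(diag(E))^2 / (df * sum(E * E))
  min(1, max(1 / df, eps))
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), `/`)
}

#' @export
print.loc3d_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA\n")
  for (i in seq_len(nrow(x))) {
    if (x$correction[i] == "GG")
      cat(sprintf("  %-28s F(%.2f, %.2f) = %.2f, p = %.4g (GG, eps = %.3f), ges = %.3f\n",
                  x$term[i], x$df1_gg[i], x$df2_gg[i], x$F[i], x$p_gg[i],
                  x$gg_epsilon[i], x$ges[i]))
    else
      cat(sprintf("  %-28s F(%d, %d) = %.2f, p = %.4g, ges = %.3f\n",
                  x$term[i], x$df1[i], x$df2[i], x$F[i], x$p[i], x$ges[i]))
  }
  invisible(x)
}

#' Holm-Bonferroni adjustment
#'
#' Step-down Holm adjustment of a family of p values (monotone, capped at
#' 1); a thin wrapper over `stats::p.adjust(method = "holm")` kept as the
#' package's single point of configuration for multiplicity correction.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same length.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau with a two-sided p value, as used to relate
#' head-movement propensity to the localization benefit of active listening.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A list of class `"loc3d_stat"`: `statistic = "tau"`, `value`,
#'   `p`, `n`.
#' @export
kendall_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  structure(list(statistic = "tau", value = unname(ct$estimate),
                 p = ct$p.value, n = length(x)),
            class = "loc3d_stat")
}

#' @export
print.loc3d_stat <- function(x, ...) {
  cat(sprintf("%s = %.3f, p = %.4g (n = %d)\n", x$statistic, x$value, x$p, x$n))
  invisible(x)
}

#' Planned paired condition contrasts with Holm adjustment
#'
#' Compares the two listening conditions within each stratum of `by` (e.g.
#' within each antero-posterior sector) using paired t tests on the
#' per-participant cell values, and Holm-adjusts the p values within this
#' contrast family. Group means with standard errors over participants are
#' reported for each condition.
#'
#' Degenerate families are handled explicitly: if the paired differences are
#' identically zero the contrast is reported with t = 0, p = 1; if they are
#' constant but non-zero (zero variance of differences), the contrast is
#' flagged `degenerate` with an undefined p.
#'
#' @param data Long data frame of per-participant cell values.
#' @param dv Dependent-variable column name.
#' @param id Participant column name.
#' @param condition Two-level factor column name.
#' @param by Optional character vector of stratifying columns.
#' @return A data frame of class `"loc3d_contrast"`: one row per stratum with
#'   the condition means +- SE, `diff`, `t`, `df`, `p`, `p_holm`,
#'   `degenerate`.
#' @export
condition_contrast <- function(data, dv, id, condition, by = NULL) {
  stopifnot(dv %in% names(data), id %in% names(data),
            condition %in% names(data), all(by %in% names(data)))
  lev <- sort(unique(as.character(data[[condition]])))
  if (length(lev) != 2L)
    stop("`condition` must have exactly 2 levels", call. = FALSE)
  strata <- if (is.null(by)) list(`all` = seq_len(nrow(data)))
  else split(seq_len(nrow(data)),
             interaction(data[by], drop = TRUE, lex.order = TRUE, sep = " "))
  one <- function(idx) {
    dd <- data[idx, ]
    w1 <- dd[dd[[condition]] == lev[1], ]
    w2 <- dd[dd[[condition]] == lev[2], ]
    ids <- intersect(w1[[id]], w2[[id]])
    if (length(ids) != nrow(w1) || length(ids) != nrow(w2) || length(ids) < 2L)
      stop("unpaired data: each participant needs one value per condition",
           call. = FALSE)
    v1 <- w1[[dv]][match(ids, w1[[id]])]
    v2 <- w2[[dv]][match(ids, w2[[id]])]
    dif <- v1 - v2
    n <- length(dif)
    degenerate <- FALSE
    if (stats::sd(dif) <= 1e-10 * max(1, abs(mean(dif)))) {
      if (all(abs(dif) < 1e-12)) { tv <- 0; p <- 1 } else { tv <- NA_real_; p <- NA_real_; degenerate <- TRUE }
    } else {
      tt <- stats::t.test(v1, v2, paired = TRUE)
      tv <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(mean_1 = mean(v1), se_1 = stats::sd(v1) / sqrt(n),
               mean_2 = mean(v2), se_2 = stats::sd(v2) / sqrt(n),
               diff = mean(dif), t = tv, df = n - 1L, p = p,
               degenerate = degenerate)
  }
  out <- do.call(rbind, lapply(strata, one))
  out <- cbind(data.frame(stratum = names(strata), stringsAsFactors = FALSE), out)
  out$p_holm <- holm_adjust(out$p)
  attr(out, "conditions") <- lev
  rownames(out) <- NULL
  class(out) <- c("loc3d_contrast", "data.frame")
  out
}

#' @export
print.loc3d_contrast <- function(x, ...) {
  lev <- attr(x, "conditions")
  cat(sprintf("Paired contrasts: %s vs %s (Holm-adjusted)\n", lev[1], lev[2]))
  for (i in seq_len(nrow(x))) {
    if (isTRUE(x$degenerate[i]))
      cat(sprintf("  %-16s %.2f vs %.2f  [degenerate: zero-variance differences]\n",
                  x$stratum[i], x$mean_1[i], x$mean_2[i]))
    else
      cat(sprintf("  %-16s %.1f +- %.1f vs %.1f +- %.1f, t(%d) = %.2f, p = %.4g, p_holm = %.4g\n",
                  x$stratum[i], x$mean_1[i], x$se_1[i], x$mean_2[i], x$se_2[i],
                  x$df[i], x$t[i], x$p[i], x$p_holm[i]))
  }
  invisible(x)
}
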