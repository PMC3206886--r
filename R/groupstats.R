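# The 2x2 inferential layer: two-way ANOVA per metric, FDR control,
# Tukey post-hoc contrasts, age-controlled partial correlations, and the
# vectorized edge-level ANOVA on Fisher-z weights.

.checkCells <- function(sex, disease, minPerCell = 2) {
  sex <- factor(sex); disease <- factor(disease)
  if (nlevels(sex) != 2 || nlevels(disease) != 2)
    stop("sex and disease must each have exactly two levels")
  tab <- table(sex, disease)
  if (any(tab < minPerCell))
    stop("every sex x disease cell needs at least ", minPerCell, " subjects")
  list(sex = sex, disease = disease)
}

#' Two-way ANOVA on a network metric
#'
#' Models sex (male vs. female) and disease state (patient vs. control)
#' simultaneously, returning F and p for both main effects and the
#' interaction plus the four cell means and SDs. Unbalanced cells (the
#' 18-vs-20 design) are handled with Type II sums of squares by default
#' (invariant to factor order; appropriate in the absence of higher-order
#' terms), with Type III available.
#'
#' @param values numeric vector, one metric value per subject.
#' @param sex,disease two-level factors (or coercible vectors) with at
#'   least two subjects in every cell.
#' @param ssType \code{"II"} (default) or \code{"III"}.
#' @return List of class \code{"anovaResult"}: \code{table} (term, F, p)
#'   and \code{cells} (cell means and SDs). A zero-variance response
#'   returns F = 0, p = 1 by convention.
#' @export
twoWayAnova <- function(values, sex, disease, ssType = c("II", "III")) {
  ssType <- match.arg(ssType)
  f <- .checkCells(sex, disease)
  stopifnot(length(values) == length(f$sex))
  cells <- stats::aggregate(values,
                            by = list(sex = f$sex, disease = f$disease),
                            FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  cells <- data.frame(sex = cells$sex, disease = cells$disease,
                      mean = cells$x[, "mean"], sd = cells$x[, "sd"],
                      n = cells$x[, "n"])
  terms <- c("sex", "disease", "sex:disease")
  if (stats::sd(values) == 0) {
    tab <- data.frame(term = terms, F = 0, p = 1)
  } else {
    dat <- data.frame(y = values, sex = f$sex, disease = f$disease)
    if (ssType == "III") {
      fit <- stats::lm(y ~ sex * disease, data = dat,
                       contrasts = list(sex = "contr.sum",
                                        disease = "contr.sum"))
      an <- car::Anova(fit, type = "III")
    } else {
      fit <- stats::lm(y ~ sex * disease, data = dat)
      an <- car::Anova(fit, type = "II")
    }
    an <- an[terms, ]
    tab <- data.frame(term = terms, F = an[["F value"]], p = an[["Pr(>F)"]])
    tab$F[is.na(tab$F)] <- 0
    tab$p[is.na(tab$p)] <- 1
  }
  structure(list(table = tab, cells = cells, ssType = ssType),
            class = "anovaResult")
}

#' @export
print.anovaResult <- function(x, ...) {
  cat("Two-way ANOVA (Type", x$ssType, "SS)\n")
  print(x$table, row.names = FALSE)
  cat("\nCell summaries:\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up adjustment (default) or the
#' Benjamini-Yekutieli variant, with the rejection mask at level \code{q}.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @param method \code{"BH"} (default) or \code{"BY"}.
#' @return List with \code{adjusted} p-values and logical \code{reject}.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))$reject  # all TRUE at q = 0.05
#' @export
fdrAdjust <- function(p, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("all p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = method)
  list(adjusted = adj, reject = adj <= q)
}

#' Tukey post-hoc contrasts over the four design cells
#'
#' All six pairwise contrasts between the sex x disease cell means with
#' Tukey honest-significant-difference family-wise correction, flagging in
#' particular the patient-vs-control contrast within each sex.
#'
#' @param values numeric vector of per-subject metric values.
#' @param sex,disease two-level factors; all four cells must be populated.
#' @param alpha family-wise level for the significance flags (default 0.05).
#' @return data.frame with one row per contrast: \code{contrast},
#'   \code{diff}, \code{p_adj}, \code{significant}, and
#'   \code{within_sex_disease} marking the within-sex disease contrasts.
#' @export
posthocPairwise <- function(values, sex, disease, alpha = 0.05) {
  f <- .checkCells(sex, disease)
  cell <- interaction(f$sex, f$disease, sep = ":")
  fit <- stats::aov(values ~ cell)
  tk <- stats::TukeyHSD(fit)$cell
  parts <- strsplit(rownames(tk), "-", fixed = TRUE)
  sameSex <- vapply(parts, function(pp) {
    a <- strsplit(pp[1], ":")[[1]]; b <- strsplit(pp[2], ":")[[1]]
    a[1] == b[1] && a[2] != b[2]
  }, logical(1))
  data.frame(contrast = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], significant = tk[, "p adj"] < alpha,
             within_sex_disease = sameSex, row.names = NULL)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of x and y after linear regression
#' (with intercept) on the covariates; with no covariates this is exactly
#' the plain Pearson correlation. The p-value uses the t-distribution with
#' \eqn{n - 2 - k} degrees of freedom for k covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric vector, matrix or data.frame of
#'   control variables (e.g. age).
#' @return List of class \code{"partialCorrResult"}: \code{r}, \code{p},
#'   \code{n}, \code{df}, \code{covariates} (count).
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    z <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    z <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(z) == n)
  }
  k <- ncol(z)
  if (n <= k + 2) stop("need n > number of covariates + 2")
  design <- cbind(intercept = 1, z)
  if (qr(design)$rank < ncol(design))
    stop("covariates are collinear")
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(r = r, p = p, n = n, df = df, covariates = k),
            class = "partialCorrResult")
}

#' @export
print.partialCorrResult <- function(x, ...) {
  cat(sprintf("Partial correlation: r = %.3f, p = %.4g (n = %d, %d covariate%s)\n",
              x$r, x$p, x$n, x$covariates, if (x$covariates == 1) "" else "s"))
  invisible(x)
}

#' Edge-level two-way ANOVA on Fisher-z connectivity
#'
#' Applies the sex x disease two-way ANOVA (Type II sums of squares) to
#' every edge's Fisher-z weight simultaneously via shared projection
#' matrices, then FDR-corrects each term's p-values over all tested edges.
#' "Increased connection" means patient mean z above control mean z
#' together with a significant disease or interaction term.
#'
#' @param zMatrix subjects x edges matrix of Fisher-z edge weights
#'   (columns named by region pair).
#' @param sex,disease two-level factors.
#' @param q FDR level (default 0.05).
#' @param method FDR method, \code{"BH"} (default) or \code{"BY"}.
#' @return data.frame with one row per edge: F and raw/adjusted p per term,
#'   group mean difference (patient - control) and the increased-connection
#'   flag.
#' @export
edgeStats <- function(zMatrix, sex, disease, q = 0.05,
                      method = c("BH", "BY")) {
  method <- match.arg(method)
  f <- .checkCells(sex, disease)
  y <- as.matrix(zMatrix)
  stopifnot(nrow(y) == length(f$sex))
  n <- nrow(y)
  rssFor <- function(formula) {
    xm <- stats::model.matrix(formula,
                              data = data.frame(sex = f$sex,
                                                disease = f$disease))
    colSums(qr.resid(qr(xm), y)^2)
  }
  rssFull <- rssFor(~ sex * disease)
  rssAdd <- rssFor(~ sex + disease)
  rssSex <- rssFor(~ sex)
  rssDis <- rssFor(~ disease)
  dfRes <- n - 4
  mse <- rssFull / dfRes
  fSex <- (rssDis - rssAdd) / mse
  fDis <- (rssSex - rssAdd) / mse
  fInt <- (rssAdd - rssFull) / mse
  pFor <- function(fv) stats::pf(pmax(fv, 0), 1, dfRes, lower.tail = FALSE)
  pSex <- pFor(fSex); pDis <- pFor(fDis); pInt <- pFor(fInt)
  patient <- f$disease == levels(f$disease)[match("patient",
               levels(f$disease), nomatch = 2)]
  dirDiff <- colMeans(y[patient, , drop = FALSE]) -
    colMeans(y[!patient, , drop = FALSE])
  adjDis <- fdrAdjust(pDis, q, method)
  adjInt <- fdrAdjust(pInt, q, method)
  adjSex <- fdrAdjust(pSex, q, method)
  data.frame(edge = colnames(y) %||% as.character(seq_len(ncol(y))),
             F_sex = pmax(fSex, 0), p_sex = pSex, p_sex_adj = adjSex$adjusted,
             F_disease = pmax(fDis, 0), p_disease = pDis,
             p_disease_adj = adjDis$adjusted,
             F_interaction = pmax(fInt, 0), p_interaction = pInt,
             p_interaction_adj = adjInt$adjusted,
             diff_patient_minus_control = dirDiff,
             increased = dirDiff > 0 & (adjDis$reject | adjInt$reject),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
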