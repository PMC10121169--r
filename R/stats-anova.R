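#' Two-way ANOVA table
#'
#' Factorial analysis of variance for two crossed factors with interaction.
#' Balanced designs use the textbook partitioned sums of squares (sequential
#' SS from the linear model, which coincide with the partition for balanced
#' data); unbalanced designs use Type II SS. A design with every
#' observation equal is flagged degenerate (all SS zero, F undefined).
#'
#' @param values numeric response.
#' @param factorA,factorB factors (coerced), >= 2 levels each, every crossed
#'   cell non-empty.
#' @param type \code{"auto"} (Type II when unbalanced), \code{"balanced"}
#'   (error if the design is unbalanced) or \code{"typeII"}.
#' @return data.frame with rows A, B, A:B, Residuals and columns source, df,
#'   sumsq, meansq, statistic, p_value; attribute \code{degenerate};
#'   attribute \code{fit} carrying the underlying \code{aov} fit (used by
#'   \code{\link{tukeyHsd}}).
#' @examples
#' d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3)
#' d$y <- rnorm(nrow(d)) + (d$a == "x") * 2
#' twoWayAnova(d$y, d$a, d$b)
#' @export
twoWayAnova <- function(values, factorA, factorB,
                        type = c("auto", "balanced", "typeII")) {
  type <- match.arg(type)
  a <- factor(factorA); b <- factor(factorB)
  stopifnot(length(values) == length(a), length(a) == length(b))
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need at least two levels")
  cells <- table(a, b)
  if (any(cells == 0L))
    stop("empty design cell: ", paste(
      which(cells == 0L, arr.ind = TRUE), collapse = ","))
  balanced <- length(unique(as.vector(cells))) == 1L
  if (type == "balanced" && !balanced)
    stop("design is unbalanced but type = 'balanced' was requested")
  dat <- data.frame(y = values, A = a, B = b)
  fit <- stats::aov(y ~ A * B, data = dat)
  if (balanced || type == "balanced" || (type == "auto" && balanced)) {
    tab <- stats::anova(fit)
  } else {
    ctab <- car::Anova(stats::lm(y ~ A * B, data = dat), type = 2)
    tab <- ctab[c("A", "B", "A:B", "Residuals"),
                c("Sum Sq", "Df", "F value", "Pr(>F)")]
    tab <- data.frame(Df = tab$Df, `Sum Sq` = tab$`Sum Sq`,
                      `Mean Sq` = tab$`Sum Sq` / tab$Df,
                      `F value` = tab$`F value`, `Pr(>F)` = tab$`Pr(>F)`,
                      check.names = FALSE,
                      row.names = c("A", "B", "A:B", "Residuals"))
  }
  out <- data.frame(source = rownames(tab), df = tab$Df, sumsq = tab$`Sum Sq`,
                    meansq = tab$`Mean Sq`, statistic = tab$`F value`,
                    p_value = tab$`Pr(>F)`, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  degenerate <- isTRUE(all.equal(stats::var(values), 0)) ||
    sum(out$sumsq) < .Machine$double.eps * max(1, sum(values^2))
  attr(out, "degenerate") <- degenerate
  attr(out, "fit") <- fit
  out
}

#' Tukey's honestly-significant-difference comparisons
#'
#' Adjusted pairwise comparisons from the studentized range distribution on
#' the residual degrees of freedom of a two-way fit.
#'
#' @param values,factorA,factorB as in \code{\link{twoWayAnova}}; or pass a
#'   table returned by it via \code{anovaTable} to reuse the fit.
#' @param which which terms to compare (default all).
#' @param anovaTable optional result of \code{\link{twoWayAnova}}.
#' @return The \code{TukeyHSD} result (list of comparison matrices with
#'   adjusted p values).
#' @export
tukeyHsd <- function(values, factorA, factorB, which = NULL,
                     anovaTable = NULL) {
  fit <- if (!is.null(anovaTable)) attr(anovaTable, "fit")
         else attr(twoWayAnova(values, factorA, factorB), "fit")
  if (is.null(which)) stats::TukeyHSD(fit) else stats::TukeyHSD(fit, which)
}

#' Sidak multiple-comparison adjustment
#'
#' p_adj = 1 - (1 - p)^m, capped at 1.
#'
#' @param p p values.
#' @param m number of comparisons (default \code{length(p)}).
#' @return Adjusted p values.
#' @examples
#' sidakAdjust(0.05, 1)  # 0.05
#' @export
sidakAdjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  if (m == 1) return(p)   # exact identity, no float round-off
  pmin(1 - (1 - p)^m, 1)
}

#' Student's two-sample t test (equal variances)
#'
#' @param a,b numeric vectors.
#' @return list: t, df, p.
#' @export
studentT <- function(a, b) {
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Normalize a cytokine concentration to a reference protein content
#'
#' Scales an ELISA concentration (pg/ml) to what it would be at the
#' reference protein amount: 100 ug for microglia monocultures, 500 ug for
#' microglia-motor-neuron cocultures.
#'
#' @param concentration measured concentration, pg/ml.
#' @param proteinContent measured protein content, ug (> 0).
#' @param reference reference protein amount, ug (default 100).
#' @return Normalized concentration, pg/ml.
#' @examples
#' normalizeCytokine(200, 50, 100)   # 400
#' normalizeCytokine(100, 250, 500)  # 200
#' @export
normalizeCytokine <- function(concentration, proteinContent, reference = 100) {
  if (any(proteinContent <= 0))
    stop("protein content must be positive")
  if (any(reference <= 0)) stop("reference must be positive")
  concentration * reference / proteinContent
}
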