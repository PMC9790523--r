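# Agreement statistics: ICC(A,1) with F-based 95% CI, Bland-Altman
# bias/SD/limits of agreement, and a rater-simulation harness.

.checkRatings <- function(table, minK = 2L) {
  x <- as.matrix(table)
  ldAssert(is.numeric(x), "ratings must be numeric")
  ldAssert(nrow(x) >= 2L, "need at least 2 subjects")
  ldAssert(ncol(x) >= minK, sprintf("need at least %d raters/methods", minK))
  ldAssert(!anyNA(x), "ratings table must be complete (no missing cells)")
  x
}

#' Intraclass correlation ICC(A,1) with 95% confidence interval
#'
#' Two-way model, absolute agreement, single rater/measurement. From the
#' two-way ANOVA mean squares for subjects (MSR), raters (MSC) and
#' residual (MSE),
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' with the two-sided 95% confidence interval obtained from the
#' F-distribution construction for the absolute-agreement two-way model
#' (McGraw-Wong convention, as implemented in standard statistical
#' software). Absolute agreement penalizes systematic offsets between
#' raters, so adding a constant to one column strictly decreases the ICC.
#'
#' @param table numeric matrix or data.frame, rows = subjects, columns =
#'   raters/methods; complete (no missing cells).
#' @param conf confidence level (default 0.95).
#' @return An [AgreementResult-class] with `icc`, `ciLow`, `ciHigh` filled.
#' @examples
#' set.seed(1)
#' subj <- rnorm(20, 50, 10)
#' tab <- cbind(subj + rnorm(20), subj + rnorm(20))
#' iccA1(tab)
#' @export
iccA1 <- function(table, conf = 0.95) {
  x <- .checkRatings(table)
  n <- nrow(x); k <- ncol(x)
  if (var(as.vector(x)) == 0) {
    ldStop("constant ratings table: ICC undefined (zero variance)")
  }

  grand <- mean(x)
  rowM <- rowMeans(x)
  colM <- colMeans(x)
  MSR <- k * sum((rowM - grand)^2) / (n - 1)
  MSC <- n * sum((colM - grand)^2) / (k - 1)
  SSE <- sum((x - outer(rowM, colM, "+") + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))

  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf

  eps <- .Machine$double.eps * max(MSR, MSC, MSE, 1)
  if (MSE <= eps && MSC <= eps) {
    # perfect agreement: zero residual and zero rater variance
    lo <- 1; hi <- 1
  } else {
    v <- if (MSE <= eps) {
      # limit of the Satterthwaite df as the residual variance vanishes
      k - 1
    } else {
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    }
    fL <- qf(1 - alpha / 2, df1 = n - 1, df2 = v)
    fU <- qf(1 - alpha / 2, df1 = v, df2 = n - 1)
    lo <- n * (MSR - fL * MSE) /
      (fL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (fU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * fU * MSR)
    lo <- min(lo, icc)
    hi <- max(hi, icc)
  }
  new("AgreementResult",
    icc = icc, ciLow = lo, ciHigh = hi,
    bias = NA_real_, sdDiff = NA_real_, loaLow = NA_real_, loaHigh = NA_real_,
    n = n, k = as.integer(k),
    model = "ICC(A,1) two-way absolute agreement, single measurement"
  )
}

#' Bland-Altman analysis of two paired methods
#'
#' Differences are `column 1 - column 2`; the bias is their mean, the SD
#' uses the n-1 denominator, and the 95% limits of agreement are
#' `bias +/- 1.96 * SD`. The per-subject (mean, difference) points used
#' for plotting are attached as attribute `"points"`.
#'
#' @param pairs two-column numeric matrix or data.frame.
#' @return An [AgreementResult-class] with the Bland-Altman slots filled.
#' @examples
#' x <- c(10, 12, 9, 14); y <- c(11, 12, 10, 13)
#' blandAltman(cbind(x, y))
#' @export
blandAltman <- function(pairs) {
  x <- .checkRatings(pairs)
  ldAssert(ncol(x) == 2L, "Bland-Altman needs exactly two columns")
  d <- x[, 1] - x[, 2]
  bias <- mean(d)
  sdD <- sd(d)
  loa <- loaFromSummary(bias, sdD)
  out <- new("AgreementResult",
    icc = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
    bias = bias, sdDiff = sdD, loaLow = loa[["loaLow"]],
    loaHigh = loa[["loaHigh"]], n = nrow(x), k = 2L,
    model = "Bland-Altman"
  )
  attr(out, "points") <- data.frame(mean = rowMeans(x), difference = d)
  out
}

#' Limits of agreement from summary statistics
#'
#' `bias +/- 1.96 * sd`, the interval expected to contain 95% of the
#' differences between two methods.
#'
#' @param bias mean difference.
#' @param sdDiff SD of the differences (non-negative).
#' @return Named numeric vector `c(loaLow, loaHigh)`.
#' @examples
#' loaFromSummary(1.43, 2.82) # c(-4.10, 6.96) to two decimals
#' @export
loaFromSummary <- function(bias, sdDiff) {
  ldAssert(is.finite(bias), "bias must be finite")
  ldAssert(is.finite(sdDiff) && sdDiff >= 0, "sdDiff must be non-negative",
    class = "lgeDixon_value_error"
  )
  c(loaLow = bias - 1.96 * sdDiff, loaHigh = bias + 1.96 * sdDiff)
}

#' Simulate a complete ratings table
#'
#' `table[i, j] = trueValues[i] + raterBias[j] + N(0, noiseSd[j])`, seeded.
#' Enables parameter-recovery tests of the agreement statistics against
#' the closed-form ICC of the generating variance-components model.
#'
#' @param trueValues per-subject true values.
#' @param raterBias per-rater systematic offsets.
#' @param noiseSd per-rater noise SD (recycled if scalar).
#' @param seed RNG seed.
#' @return Numeric matrix, subjects x raters.
#' @examples
#' simulateRaters(c(10, 20, 30), c(0, 1), 0.5, seed = 7)
#' @export
simulateRaters <- function(trueValues, raterBias, noiseSd, seed = 1L) {
  k <- length(raterBias)
  n <- length(trueValues)
  noiseSd <- rep_len(noiseSd, k)
  ldAssert(all(noiseSd >= 0), "noise SD must be non-negative",
    class = "lgeDixon_value_error"
  )
  withSeed(seed, {
    tab <- sapply(seq_len(k), function(j) {
      trueValues + raterBias[j] + rnorm(n, 0, noiseSd[j])
    })
  })
  matrix(tab, nrow = n, ncol = k, dimnames = list(NULL, paste0("rater", seq_len(k))))
}
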