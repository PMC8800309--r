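# Hypothesis testing and summarisation: rank-sum and exact tests, signed
# effect sizes, median-p ensemble comparisons, one-sided permutation
# p-values, FDR correction and convergence diagnostics.

#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: "***", "**", "*" or "NS".
#' @export
starsFor <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS"))))
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Mann-Whitney U with a normal approximation using tie-corrected variance
#' and (by default) continuity correction; for small tie-free samples
#' (n_a + n_b <= exactMax) the two-sided p comes from the exact null
#' distribution of U. The signed z is retained for the r effect size,
#' which the standard test functions do not expose.
#'
#' @param a,b Non-empty numeric samples.
#' @param continuity Apply the continuity correction (default TRUE).
#' @param exactMax Use the exact distribution when n_a + n_b is at most
#'   this and there are no ties (default 16).
#' @return list(p, z, U, exact): two-sided p-value, signed z (positive
#'   when \code{a} tends larger), the U statistic for \code{a}, and
#'   whether the exact path was used.
#' @export
wilcoxonRankSum <- function(a, b, continuity = TRUE, exactMax = 16) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  N <- na + nb
  ties <- table(r)
  hasTies <- any(ties > 1)
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  d <- U - mu
  if (sigma2 <= 0) {
    z <- 0
  } else {
    cc <- if (continuity) sign(d) * 0.5 else 0
    z <- (d - cc) / sqrt(sigma2)
  }
  exact <- !hasTies && N <= exactMax
  if (exact) {
    p <- min(1, 2 * min(stats::pwilcox(U, na, nb),
                        1 - stats::pwilcox(U - 1, na, nb)))
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p = p, z = z, U = U, exact = exact)
}

#' Signed rank-biserial-style effect size r = |z| / sqrt(n)
#'
#' Positive when the TAD-side values exceed the null side, negative
#' otherwise (the reporting convention for all ensemble comparisons).
#'
#' @param z Normal-approximation z statistic.
#' @param nTotal Total sample size (n_a + n_b), at least 2.
#' @param direction +1 when the TAD-side median exceeds the null-side
#'   median, -1 when it is smaller, 0 for an exact tie.
#' @return r in [-1, 1].
#' @export
effectSizeR <- function(z, nTotal, direction) {
  stopifnot(nTotal >= 2)
  r <- abs(z) / sqrt(nTotal)
  r <- min(1, r)
  if (direction == 0) direction <- sign(z)
  r * sign(direction)
}

#' Rank-sum comparison of a TAD-side sample against a null-side sample
#'
#' @param tadValues,nullValues Numeric samples (TAD side first).
#' @param ... Passed to \code{\link{wilcoxonRankSum}}.
#' @return list(p, r, z): two-sided p and signed effect size.
#' @export
rankSumComparison <- function(tadValues, nullValues, ...) {
  w <- wilcoxonRankSum(tadValues, nullValues, ...)
  dir <- sign(stats::median(tadValues) - stats::median(nullValues))
  r <- effectSizeR(w$z, length(tadValues) + length(nullValues), dir)
  list(p = w$p, r = r, z = w$z)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p = sum of the hypergeometric probabilities, at fixed
#' margins, of every table as or less probable than the observed one.
#'
#' @param m 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return Two-sided p-value.
#' @export
fisherExact <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(2L, 2L)))
  if (any(m < 0) || any(m != round(m)))
    stop("fisherExact: counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("fisherExact: all margins must be positive")
  min(1, stats::fisher.test(m)$p.value)
}

# Signed phi coefficient of a 2x2 table (rows real/null, cols hit/other):
# effect-size analogue for the count-based comparisons.
.phi2x2 <- function(m) {
  num <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  den <- sqrt(prod(c(rowSums(m), colSums(m))))
  if (den == 0) return(0)
  num / den
}

#' Compare real data against every set of a null ensemble (median p)
#'
#' Applies the chosen test real-vs-each-null-set and reports the median
#' p-value and median signed effect size over the ensemble — the ensemble
#' testing scheme used for every TAD-vs-random comparison.
#'
#' For \code{test = "wilcoxon"}, \code{real} is a numeric value
#' distribution and each null set is one too. For \code{test = "fisher"},
#' \code{real} is a length-2 count vector (hits, non-hits) and so is each
#' null set; the effect size is the signed phi coefficient of each 2x2
#' table.
#'
#' @param real Real-data values (or counts).
#' @param nullList List with one element per null set.
#' @param test "wilcoxon" or "fisher".
#' @param statistic Label for the comparison.
#' @return A \code{ComparisonResult}.
#' @export
ensembleCompare <- function(real, nullList,
                            test = c("wilcoxon", "fisher"),
                            statistic = "comparison") {
  test <- match.arg(test)
  stopifnot(length(nullList) >= 1)
  n <- length(nullList)
  p <- numeric(n); r <- numeric(n)
  for (k in seq_len(n)) {
    nv <- nullList[[k]]
    if (test == "wilcoxon") {
      res <- rankSumComparison(real, nv)
      p[k] <- res$p; r[k] <- res$r
    } else {
      m <- rbind(real = real, null = nv)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
        # degenerate table (e.g. zero hits on both sides): no evidence
        p[k] <- 1; r[k] <- 0
      } else {
        p[k] <- fisherExact(m)
        prop <- real[1] / sum(real) - nv[1] / sum(nv)
        r[k] <- abs(.phi2x2(m)) * ifelse(prop == 0, 0, sign(prop))
      }
    }
  }
  realSummary <- if (test == "wilcoxon") stats::median(real)
                 else real[1] / sum(real)
  mp <- stats::median(p)
  new("ComparisonResult", statistic = statistic,
      realSummary = unname(realSummary), pValues = p, effectSizes = r,
      medianP = mp, medianEffectSize = stats::median(r),
      nNullSets = as.integer(n), stars = starsFor(mp))
}

#' One-sided permutation p-value ("higher" alternative)
#'
#' p = (number of null values >= the real value) / N. p = 0 is possible
#' and should be reported as "< 1/N".
#'
#' @param real Observed value.
#' @param nullValues Non-empty numeric vector of null values.
#' @return p in {0, 1/N, ..., 1}.
#' @export
permutationP <- function(real, nullValues) {
  if (!length(nullValues)) stop("nullValues must be non-empty")
  sum(nullValues >= real) / length(nullValues)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Step-up adjusted values, capped at 1.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Running-median convergence diagnostic for an ensemble summary
#'
#' Reports the running median of a per-set summary after each added set,
#' and the smallest k from which every later running median stays within
#' \code{tol} of the final median — the check that the ensemble size is
#' large enough for the median to have converged.
#'
#' @param perSet Numeric vector of per-set summaries (>= 2 sets).
#' @param tol Absolute tolerance band around the final median.
#' @return list(trace, stabilizationIndex, finalMedian).
#' @export
convergenceReport <- function(perSet, tol = 0.01) {
  stopifnot(length(perSet) >= 2)
  trace <- vapply(seq_along(perSet),
                  function(k) stats::median(perSet[seq_len(k)]), numeric(1))
  final <- trace[length(trace)]
  within <- abs(trace - final) <= tol
  # smallest k with all subsequent medians inside the band
  ok <- rev(cumprod(rev(as.integer(within)))) == 1
  stab <- if (any(ok)) which(ok)[1L] else NA_integer_
  list(trace = trace, stabilizationIndex = stab, finalMedian = final)
}

#' Pairwise occupancy-class constraint tests with FDR correction
#'
#' Runs a Wilcoxon rank-sum test between the per-TAD mean constraint
#' scores of every pair of occupancy classes (1, 2, 3, 4, 5, 6+) and
#' BH-adjusts the p-values across the whole comparison family.
#'
#' @param summary data.frame with columns \code{occupancy_class} and
#'   \code{mean_constraint} (one row per TAD), e.g. built from
#'   \code{\link{meanConstraint}} and \code{\link{occupancyClasses}}.
#' @return Symmetric matrix of FDR-adjusted p-values (classes x classes);
#'   classes with fewer than 2 TADs are skipped with a warning.
#' @export
occupancyConstraintTests <- function(summary) {
  lv <- c("1", "2", "3", "4", "5", "6+")
  cls <- factor(as.character(summary$occupancy_class), levels = lv)
  scores <- split(summary$mean_constraint, cls)
  nOk <- vapply(scores, length, integer(1))
  use <- names(scores)[nOk >= 2L]
  skipped <- setdiff(names(scores)[nOk > 0L], use)
  if (length(skipped))
    warning(sprintf("occupancy class(es) with < 2 TADs skipped: %s",
                    paste(skipped, collapse = ", ")))
  if (length(use) < 2L)
    stop("need at least two occupancy classes with >= 2 TADs each")
  cmb <- utils::combn(use, 2L)
  praw <- apply(cmb, 2L, function(cc)
    wilcoxonRankSum(scores[[cc[1L]]], scores[[cc[2L]]])$p)
  padj <- bhFdr(praw)
  out <- matrix(NA_real_, length(lv), length(lv),
                dimnames = list(lv, lv))
  for (j in seq_len(ncol(cmb))) {
    out[cmb[1L, j], cmb[2L, j]] <- padj[j]
    out[cmb[2L, j], cmb[1L, j]] <- padj[j]
  }
  out
}
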