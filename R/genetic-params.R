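#' Transform sire-MGS (co)variances to direct/maternal parameters
#'
#' Per-draw exact arithmetic on the underlying scale:
#' direct variance = 4 x sire variance;
#' maternal variance = 4 x MGS variance - 4 x covariance + sire variance;
#' direct-maternal covariance = 4 x covariance - 2 x sire variance;
#' correlation = covariance / sqrt(product of variances);
#' phenotypic variance = sire variance + MGS variance + 1 (unit residual);
#' heritabilities = variances / phenotypic variance.
#' Draws whose implied maternal variance is non-positive are flagged: their
#' correlation is NA and they are excluded (and counted) when summarizing
#' the correlation.
#'
#' @param sigma_s2,sigma_mgs2,sigma_s_mgs numeric vectors of draws (or a
#'   data.frame with those columns passed as \code{sigma_s2}).
#' @return data.frame of per-draw \code{sigma_D2}, \code{sigma_M2},
#'   \code{sigma_DM}, \code{r_DM}, \code{sigma_P2}, \code{h2_D},
#'   \code{h2_M}, and logical \code{excluded}.
#' @export
transformSample <- function(sigma_s2, sigma_mgs2 = NULL, sigma_s_mgs = NULL) {
  if (is.data.frame(sigma_s2)) {
    d <- sigma_s2
    sigma_s2 <- d$sigma_s2
    sigma_mgs2 <- d$sigma_mgs2
    sigma_s_mgs <- d$sigma_s_mgs
  }
  sigma_D2 <- 4 * sigma_s2
  sigma_M2 <- 4 * sigma_mgs2 - 4 * sigma_s_mgs + sigma_s2
  sigma_DM <- 4 * sigma_s_mgs - 2 * sigma_s2
  sigma_P2 <- sigma_s2 + sigma_mgs2 + 1
  excluded <- sigma_M2 <= 0 | sigma_D2 <= 0
  r_DM <- rep(NA_real_, length(sigma_D2))
  ok <- !excluded
  r_DM[ok] <- sigma_DM[ok] / sqrt(sigma_D2[ok] * sigma_M2[ok])
  data.frame(sigma_D2 = sigma_D2, sigma_M2 = sigma_M2,
             sigma_DM = sigma_DM, r_DM = r_DM, sigma_P2 = sigma_P2,
             h2_D = sigma_D2 / sigma_P2, h2_M = sigma_M2 / sigma_P2,
             excluded = excluded)
}

#' Highest-posterior-density interval by the shortest sorted window
#'
#' Sorts the draws and returns the shortest contiguous window containing
#' \code{ceiling(prob * n)} of them (first such window on ties).
#'
#' @param x numeric draws.
#' @param prob interval mass, default 0.95.
#' @return numeric c(lower, upper).
#' @export
hpdInterval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2) stop("summary error: need at least 2 finite draws")
  k <- ceiling(prob * n)
  if (k >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - k)
  width <- x[starts + k] - x[starts]
  s <- starts[which.min(width)]
  c(x[s], x[s + k])
}

#' Posterior mean and HPD bounds of a set of draws
#'
#' @param x numeric draws (at least 100).
#' @param prob HPD mass, default 0.95.
#' @return named numeric: mean, hpd_low, hpd_high.
#' @export
summarizePosterior <- function(x, prob = 0.95) {
  x <- x[is.finite(x)]
  if (length(x) < 100) stop("summary error: fewer than 100 retained samples")
  h <- hpdInterval(x, prob)
  c(mean = mean(x), hpd_low = h[1], hpd_high = h[2])
}

#' Posterior genetic parameters of a fitted S-MGS model
#'
#' Applies \code{\link{transformSample}} to every retained draw and
#' summarizes each parameter with its posterior mean and 95% HPD interval
#' (per-draw transform first, summary second, so printed means are means of
#' transforms rather than transforms of means).
#'
#' @param fit an \linkS4class{SmgsFit}, or a data.frame of variance draws
#'   with columns sigma_s2, sigma_mgs2, sigma_s_mgs.
#' @param prob HPD mass, default 0.95.
#' @return a \linkS4class{GeneticParameters}.
#' @export
geneticParameters <- function(fit, prob = 0.95) {
  v <- if (is(fit, "SmgsFit")) varianceSamples(fit) else fit
  tr <- transformSample(v)
  base <- cbind(v[c("sigma_s2", "sigma_mgs2", "sigma_s_mgs")],
                tr[c("sigma_D2", "sigma_M2", "sigma_DM", "r_DM",
                     "h2_D", "h2_M", "sigma_P2")])
  if ("sigma_hy2" %in% names(v)) base$sigma_hy2 <- v$sigma_hy2
  if (nrow(base) < 100)
    stop("summary error: fewer than 100 retained samples")
  # the >= 100 contract applies to the retained chain; the correlation is
  # summarized over whatever draws survive the exclusion rule
  summ <- do.call(rbind, lapply(names(base), function(p) {
    x <- base[[p]][is.finite(base[[p]])]
    h <- hpdInterval(x, prob)
    data.frame(parameter = p, mean = mean(x), hpd_low = h[1],
               hpd_high = h[2])
  }))
  rownames(summ) <- NULL
  new("GeneticParameters", summary = summ, draws = base,
      nExcluded = sum(tr$excluded))
}

#' Summary table of a GeneticParameters object
#' @param x a \linkS4class{GeneticParameters}.
#' @return data.frame: parameter, mean, hpd_low, hpd_high.
#' @export
setGeneric("parameterSummary",
           function(x) standardGeneric("parameterSummary"))

#' @rdname parameterSummary
#' @export
setMethod("parameterSummary", "GeneticParameters", function(x) x@summary)

#' Per-draw transformed values of a GeneticParameters object
#' @param x a \linkS4class{GeneticParameters}.
#' @return data.frame of per-draw values.
#' @export
setGeneric("parameterDraws", function(x) standardGeneric("parameterDraws"))

#' @rdname parameterDraws
#' @export
setMethod("parameterDraws", "GeneticParameters", function(x) x@draws)
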