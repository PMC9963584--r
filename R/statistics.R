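#' Descriptive summary of a per-frame descriptor distribution
#'
#' Produces the quantities displayed in box-and-whisker and violin summaries:
#' five-number summary (true minimum and maximum as whiskers, not 1.5 IQR
#' fences), mean, bias-corrected Fisher skewness and excess kurtosis, a
#' density-normalized histogram, and a Gaussian kernel density estimate
#' evaluated at the five quantiles and the mean (the violin annotation
#' points).  Quartiles use linear interpolation between order statistics
#' (`quantile` type 7).
#'
#' @param values numeric vector, length >= 4.
#' @param histogram_bins number of bins, a break vector, or the name of a
#'   rule understood by [graphics::hist()] (default `"FD"`,
#'   Freedman--Diaconis).  Integer-valued descriptors such as the face count
#'   are better served by `integer_bins = TRUE`.
#' @param integer_bins use unit-width bins centered on integers.
#' @return an object of class `distribution_summary`: `n`, `mean`, `q0`,
#'   `q1`, `median`, `q3`, `q4`, `skewness`, `excess_kurtosis`, `histogram`
#'   (list with `bin_edges`, `density`), `kde_at` (named density values at
#'   `q0`, `q1`, `median`, `q3`, `q4`, `mean`).
#' @examples
#' summarize_distribution(c(1, 2, 3, 4, 5))$median
#' @export
summarize_distribution <- function(values, histogram_bins = "FD",
                                   integer_bins = FALSE) {
  values <- as.numeric(values)
  if (anyNA(values)) values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4L) stop("need at least 4 values")
  q <- unname(quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  m <- mean(values)
  s <- sd(values)
  if (s > 0) {
    z <- (values - m) / s
    g1 <- mean(z^3)
    g2 <- mean(z^4) - 3
    # bias-corrected (Fisher) sample versions
    skew <- sqrt(n * (n - 1)) / (n - 2) * g1
    kurt <- (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * g2 + 6)
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  if (integer_bins) {
    breaks <- seq(floor(min(values)) - 0.5, ceiling(max(values)) + 0.5, by = 1)
  } else if (s == 0) {
    breaks <- c(m - 0.5, m + 0.5)
  } else {
    breaks <- histogram_bins
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  if (s > 0) {
    bw <- stats::bw.nrd(values)  # Scott-type normal-reference bandwidth
    at <- c(q0 = q[1], q1 = q[2], median = q[3], q3 = q[4], q4 = q[5],
            mean = m)
    kde_at <- vapply(at, function(x0) mean(dnorm((x0 - values) / bw)) / bw,
                     numeric(1))
  } else {
    kde_at <- c(q0 = NA_real_, q1 = NA_real_, median = NA_real_,
                q3 = NA_real_, q4 = NA_real_, mean = NA_real_)
  }
  structure(
    list(n = n, mean = m, q0 = q[1], q1 = q[2], median = q[3], q3 = q[4],
         q4 = q[5], skewness = skew, excess_kurtosis = kurt,
         histogram = list(bin_edges = h$breaks, density = h$density),
         kde_at = kde_at),
    class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat("<distribution_summary> n=", x$n,
      "  mean=", format(x$mean), "  median=", format(x$median),
      "  [Q1,Q3]=[", format(x$q1), ",", format(x$q3), "]",
      "  range=[", format(x$q0), ",", format(x$q4), "]\n",
      "  skewness=", format(x$skewness),
      "  excess kurtosis=", format(x$excess_kurtosis), "\n", sep = "")
  invisible(x)
}

#' Normality check by empirical-CDF sup-distance
#'
#' Computes the Kolmogorov--Smirnov-type statistic
#' \eqn{D = \sup_x |F_n(x) - \Phi((x-\bar x)/s)|} between the empirical CDF
#' and a normal fitted by moments, and compares it against the asymptotic
#' critical value \eqn{c(\alpha)/\sqrt{n}} (1.358 at \eqn{\alpha = 0.05}).
#' Parameters are estimated from the sample, so the decision is conservative
#' (accepts slightly too readily); it is intended as the descriptive
#' "does this distribution look normal" check used when reading violin
#' summaries, not as a calibrated hypothesis test.
#'
#' @param values numeric vector, length >= 20.
#' @param critical scaled critical value \eqn{c(\alpha)} (default 1.358,
#'   i.e. 5 percent level).
#' @return list with `statistic` (D), `threshold`, `consistent` (logical),
#'   `degenerate` (zero-variance flag).
#' @export
normality_check <- function(values, critical = 1.358) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 20L) stop("need at least 20 values")
  if (sd(values) == 0)
    return(list(statistic = 1, threshold = critical / sqrt(n),
                consistent = FALSE, degenerate = TRUE))
  x <- sort(values)
  fz <- pnorm(x, mean(values), sd(values))
  d <- max(seq_len(n) / n - fz, fz - (seq_len(n) - 1) / n)
  thr <- critical / sqrt(n)
  list(statistic = d, threshold = thr, consistent = d < thr,
       degenerate = FALSE)
}

#' Cross-state comparison of shell descriptors and RDF features
#'
#' Builds the per-state comparison of the three-dimensional shell descriptors
#' against the one-dimensional RDF features: mean/median/Q1/Q3 of cage radius
#' `R`, face-weighted radius `Rw`, face count `N_F`, volume, surface and
#' asphericity; the RDF features `Rmax`, `Rmin` and coordination numbers
#' `n(Rmax)`, `n(Rmin)`; and a classification of where `Rmax` falls relative
#' to the `Rw` distribution (`"below_Q1"`, `"within_IQR"`, `"above_Q3"`).
#'
#' @param states named list; each element a list with components `metrics`
#'   (an [analyze_trajectory()] table) and `rdf` (an `rdf_result` with
#'   features filled in, or `NULL`).
#' @return data.frame with one row per state, in input order.
#' @export
compare_states <- function(states) {
  if (!length(states)) stop("need at least one state")
  qs <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), median = median(x),
      q1 = unname(quantile(x, 0.25, type = 7)),
      q3 = unname(quantile(x, 0.75, type = 7)))
  }
  rows <- lapply(seq_along(states), function(i) {
    st <- states[[i]]
    met <- st$metrics[st$metrics$converged %in% TRUE, , drop = FALSE]
    if (!nrow(met)) stop("state ", i, " has no converged cells")
    nm <- names(states)[i]
    if (is.null(names(states)) || is.na(nm) || !nzchar(nm)) nm <- as.character(i)
    row <- data.frame(state = nm)
    for (col in c("cage_radius", "rw", "nf", "volume", "surface", "alpha")) {
      v <- qs(met[[col]])
      names(v) <- paste(col, names(v), sep = "_")
      row <- cbind(row, as.data.frame(as.list(v)))
    }
    rdf <- st$rdf
    if (!is.null(rdf) && !is.na(rdf$Rmax)) {
      row$Rmax <- rdf$Rmax
      row$Rmin <- rdf$Rmin
      row$n_at_Rmax <- rdf$n_at_Rmax
      row$n_at_Rmin <- rdf$n_at_Rmin
      row$rmax_vs_rw <-
        if (rdf$Rmax < row$rw_q1) "below_Q1"
        else if (rdf$Rmax > row$rw_q3) "above_Q3"
        else "within_IQR"
    } else {
      row$Rmax <- NA_real_; row$Rmin <- NA_real_
      row$n_at_Rmax <- NA_real_; row$n_at_Rmin <- NA_real_
      row$rmax_vs_rw <- NA_character_
    }
    row
  })
  do.call(rbind, rows)
}

#' Serialize a distribution summary to JSON
#'
#' @param summary a `distribution_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
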