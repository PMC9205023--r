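# Kernel-density analysis of Ks distributions and minimal
# Gaussian-mixture curve fitting to locate polyploidy peaks. The
# mixture is fitted to the density curve itself by nonlinear least
# squares (not to the sample by EM), adding components until the
# curve-level R-squared reaches its threshold.

#' Gaussian kernel density of a Ks sample
#'
#' @param ks Numeric vector of Ks values; non-finite values and values
#'   at or above `sat_cutoff` (saturated pairs) are dropped.
#' @param bandwidth Kernel standard deviation (default 0.05).
#' @param n_grid Grid resolution over `[0, max(ks) + 3 * bandwidth]`.
#' @param sat_cutoff Saturation cutoff; defaults to 3.
#' @return List `grid`, `density`, `bandwidth`, `n` (values used).
#' @export
kdeKs <- function(ks, bandwidth = 0.05, n_grid = 512, sat_cutoff = 3) {
  ks <- ks[is.finite(ks) & ks < sat_cutoff]
  if (length(ks) < 2) stop("need at least two finite Ks values below cutoff")
  d <- density(ks, bw = bandwidth, kernel = "gaussian", from = 0,
               to = max(ks) + 3 * bandwidth, n = n_grid)
  list(grid = d$x, density = d$y, bandwidth = bandwidth, n = length(ks))
}

.localMaxima <- function(y) {
  n <- length(y)
  if (n < 3) return(which.max(y))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  if (!length(i)) i <- which.max(y)
  i[order(y[i], decreasing = TRUE)]
}

#' Fit the minimal Gaussian mixture to a density curve
#'
#' Fits a sum of `k` Gaussians to the KDE curve by nonlinear least
#' squares for `k = 1, 2, ...`, initialized from the `k` largest local
#' maxima of the curve, and returns the first `k` whose curve-level
#' R-squared reaches `r2_threshold` ("the smallest number of normal
#' distributions"). If the threshold is never reached, the best fit is
#' returned with `converged = FALSE`.
#'
#' @param curve A [kdeKs()] result (list with `grid`, `density`).
#' @param r2_threshold Minimum acceptable R-squared (default 0.95).
#' @param max_components Largest mixture size tried.
#' @return A [KsMixtureFit-class].
#' @export
fitMinGaussians <- function(curve, r2_threshold = 0.95, max_components = 5) {
  x <- curve$grid; y <- curve$density
  if (all(y <= 0) || !any(is.finite(y)) || sum(y > 0) < 3)
    stop("degenerate density curve: nothing to fit")
  ss_tot <- sum((y - mean(y))^2)
  peaks <- .localMaxima(y)
  best <- NULL
  for (k in seq_len(max_components)) {
    mu0 <- x[peaks[seq_len(min(k, length(peaks)))]]
    if (length(mu0) < k)
      mu0 <- c(mu0, quantile(x, seq(0.2, 0.8, length.out = k - length(mu0))))
    A0 <- vapply(mu0, function(m) max(y[which.min(abs(x - m))], 1e-4),
                 numeric(1))
    sg0 <- rep(max(diff(range(x)) / (6 * k), curve$bandwidth), k)
    # scalar parameters A_i, mu_i, sg_i (bounded nlsLM needs scalars)
    terms <- paste(sprintf("A%d * exp(-(x - mu%d)^2 / (2 * sg%d^2))",
                           seq_len(k), seq_len(k), seq_len(k)),
                   collapse = " + ")
    start <- c(setNames(as.list(A0), paste0("A", seq_len(k))),
               setNames(as.list(as.numeric(mu0)), paste0("mu", seq_len(k))),
               setNames(as.list(sg0), paste0("sg", seq_len(k))))
    fit <- tryCatch(
      minpack.lm::nlsLM(stats::as.formula(paste("y ~", terms)),
                        data = data.frame(x = x, y = y), start = start,
                        lower = c(rep(1e-8, k), rep(min(x), k),
                                  rep(1e-4, k)),
                        upper = c(rep(Inf, k), rep(max(x), k),
                                  rep(diff(range(x)), k)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r2 <- 1 - sum(resid(fit)^2) / ss_tot
    cf <- coef(fit)
    A <- cf[paste0("A", seq_len(k))]
    mu <- cf[paste0("mu", seq_len(k))]
    sg <- cf[paste0("sg", seq_len(k))]
    comp <- data.frame(weight = A * sg * sqrt(2 * pi), mean = mu, sd = sg)
    comp <- comp[order(comp$mean), ]
    rownames(comp) <- NULL
    cand <- methods::new("KsMixtureFit", bandwidth = curve$bandwidth,
                         grid = x, density = y, components = comp,
                         rSquared = min(r2, 1), converged = r2 >= r2_threshold)
    if (is.null(best) || r2 > best@rSquared) best <- cand
    if (r2 >= r2_threshold) return(cand)
  }
  if (is.null(best)) stop("mixture fitting failed at every size")
  best
}

#' Translate fitted mixture components into event Ks windows
#'
#' Events are supplied youngest first (e.g. `c("SCT", "ECH")` for an
#' intra-genome distribution, `"ORTHOLOG"` for an inter-genome one).
#' When the fit holds more components than events, each event is
#' represented by its principal component: the `length(events)`
#' largest-weight components are taken and assigned to events in order
#' of increasing mean. Windows are `mean +/- n_sd * sd`, truncated at
#' the midpoint between adjacent means so they stay disjoint.
#'
#' @param fit A [KsMixtureFit-class].
#' @param events Character vector of event names, youngest first.
#' @param n_sd Half-width of each window in component sds (default 2).
#' @return data.frame `event`, `lo`, `hi`, `mean`, `sd`.
#' @export
peaksToEventWindows <- function(fit, events, n_sd = 2) {
  comp <- mixtureComponents(fit)
  if (nrow(comp) < length(events))
    stop("fit has fewer components (", nrow(comp), ") than events (",
         length(events), ")")
  comp <- comp[order(comp$weight, decreasing = TRUE), ][seq_along(events), ]
  comp <- comp[order(comp$mean), ]
  out <- data.frame(event = events,
                    lo = pmax(comp$mean - n_sd * comp$sd, 0),
                    hi = comp$mean + n_sd * comp$sd,
                    mean = comp$mean, sd = comp$sd,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out) - 1)) {
      cut <- (out$mean[i] + out$mean[i + 1]) / 2
      if (out$hi[i] > cut || out$lo[i + 1] < cut) {
        out$hi[i] <- min(out$hi[i], cut)
        out$lo[i + 1] <- max(out$lo[i + 1], cut * (1 + 1e-9))
      }
    }
  }
  out
}

#' JSON report of a mixture fit
#' @param fit A [KsMixtureFit-class].
#' @param path Output JSON path.
#' @export
writeKsFit <- function(fit, path) {
  jsonlite::write_json(list(bandwidth = fit@bandwidth,
                            r_squared = fit@rSquared,
                            n_components = nrow(fit@components),
                            converged = fit@converged,
                            components = fit@components),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(fit)
}
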