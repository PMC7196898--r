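# FRAP normalization / mobile fraction and ROS-burst integration.

#' Double-normalize a FRAP trace
#'
#' Background-subtracts the bleached and reference channels, divides by the
#' reference to cancel acquisition bleaching, and scales by the prebleach
#' mean of that ratio so the prebleach level of the normalized trace is
#' exactly 1:
#' \deqn{F_{norm}(t) = \frac{(F(t)-B(t))/(R(t)-B(t))}
#'   {\mathrm{mean}_{pre}[(F-B)/(R-B)]}}
#'
#' @param trace a \linkS4class{FrapTrace}.
#' @return numeric vector, the normalized trace (prebleach mean 1).
#' @export
normalizeFrap <- function(trace) {
  f <- trace@bleachRoi; b <- trace@backgroundRoi; r <- trace@referenceRoi
  pre <- seq_len(bleachFrameIndex(trace) - 1L)
  if (mean(f[pre]) <= mean(b[pre]))
    stop("normalization error: prebleach signal does not exceed background")
  if (any(r <= b))
    stop("normalization error: reference does not exceed background")
  ratio <- (f - b) / (r - b)
  ratio / mean(ratio[pre])
}

#' Estimate the FRAP mobile fraction
#'
#' On the double-normalized trace with first postbleach value \eqn{F_0},
#' the endpoint estimate is \eqn{M_f = 100 (\bar F_{eval} - F_0)/(1 - F_0)}
#' where \eqn{\bar F_{eval}} is the mean of \code{endpointWindow} frames
#' nearest \code{tEval} seconds postbleach. The "exp_fit" method instead
#' fits \eqn{F_0 + (P - F_0)(1 - e^{-t/\tau})} and uses the fitted plateau
#' P.
#'
#' @param trace a \linkS4class{FrapTrace}.
#' @param tEval evaluation time, s postbleach (default 60).
#' @param method "endpoint" (default) or "exp_fit".
#' @param endpointWindow frames averaged around tEval (default 3).
#' @return list with \code{mobileFraction} (percent; flagged if outside
#'   [0, 100]), \code{method}, \code{normalizedTrace}, and for exp_fit the
#'   fitted \code{plateau} and \code{recoveryTau}.
#' @export
mobileFraction <- function(trace, tEval = 60,
                           method = c("endpoint", "exp_fit"),
                           endpointWindow = 3L) {
  method <- match.arg(method)
  fn <- normalizeFrap(trace)
  bi <- bleachFrameIndex(trace)
  tPost <- frapTime(trace) - frapTime(trace)[bi]
  f0 <- fn[bi]
  post <- seq(bi, length(fn))
  out <- list(method = method, normalizedTrace = fn)
  if (method == "endpoint") {
    if (max(tPost) < tEval)
      stop("trace does not cover tEval = ", tEval, " s postbleach")
    ord <- post[order(abs(tPost[post] - tEval))]
    fEval <- mean(fn[sort(ord[seq_len(min(endpointWindow, length(ord)))])])
    out$mobileFraction <- 100 * (fEval - f0) / (1 - f0)
  } else {
    tt <- tPost[post]; yy <- fn[post]
    obj <- function(th) {
      f0f <- th[1]; p <- th[2]; tau <- exp(th[3])
      sum((yy - (f0f + (p - f0f) * (1 - exp(-tt / tau))))^2)
    }
    o <- optim(c(f0, max(yy), log(max(tEval / 4, 1))), obj,
               method = "BFGS", control = list(maxit = 1000, reltol = 1e-12))
    if (o$convergence != 0) stop("exp_fit failed to converge")
    out$plateau <- o$par[2]
    out$recoveryTau <- exp(o$par[3])
    out$mobileFraction <- 100 * (o$par[2] - o$par[1]) / (1 - o$par[1])
  }
  out$flagged <- out$mobileFraction < 0 || out$mobileFraction > 100
  if (out$flagged)
    warning("mobile fraction outside [0, 100] percent; flagged")
  out
}

#' Pairwise Welch comparisons of mobile fractions
#'
#' @param groups named list, condition -> numeric vector of per-cell mobile
#'   fractions. Groups with n < 3 are excluded with a warning; at least two
#'   usable groups are required.
#' @return data.frame: groupA, groupB, meanA, meanB, seA, seB, statistic,
#'   df, p_value, stars.
#' @export
compareMobileFractions <- function(groups) {
  ok <- vapply(groups, length, integer(1)) >= 3
  if (any(!ok))
    warning("excluding groups with n < 3: ",
            paste(names(groups)[!ok], collapse = ", "))
  groups <- groups[ok]
  if (length(groups) < 2) stop("need at least two groups with n >= 3")
  nm <- names(groups)
  res <- list()
  for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
    a <- groups[[i]]; b <- groups[[j]]
    tt <- t.test(a, b)                      # Welch by default
    res[[length(res) + 1L]] <- data.frame(
      groupA = nm[i], groupB = nm[j],
      meanA = mean(a), meanB = mean(b),
      seA = sd(a) / sqrt(length(a)), seB = sd(b) / sqrt(length(b)),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, stars = pStars(tt$p.value),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

pStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

# trapezoidal integral of y(t) over [a, b], interpolating at the window
# edges so the result is additive over adjacent sub-windows
trapzWindow <- function(time, y, a, b) {
  inside <- time > a & time < b
  tt <- c(a, time[inside], b)
  yy <- c(approx(time, y, a)$y, y[inside], approx(time, y, b)$y)
  sum(diff(tt) * (head(yy, -1) + yy[-1]) / 2)
}

#' Integrate a ROS-burst luminescence trace
#'
#' Trapezoidal integral of the background-corrected signal over the window
#' (default the first 25 min after elicitation at t = 0). Background is the
#' mean pre-elicitation signal (samples before \code{elicitationTime},
#' default) or a paired water-control trace whose integral over the same
#' window is subtracted. With a fixed background the integral is additive
#' over adjacent sub-windows.
#'
#' @param trace data.frame with \code{time} (min) and \code{rlu}.
#' @param window numeric c(start, end), min.
#' @param backgroundMode "pre_window_mean" or "paired_mock_mean".
#' @param mockTrace paired control trace (required for paired mode).
#' @param elicitationTime elicitor-addition time, min (default 0); baseline
#'   is estimated from samples strictly before it.
#' @return integrated RLU.min above background.
#' @export
integrateLuminescence <- function(trace, window = c(0, 25),
                                  backgroundMode = c("pre_window_mean",
                                                     "paired_mock_mean"),
                                  mockTrace = NULL, elicitationTime = 0) {
  backgroundMode <- match.arg(backgroundMode)
  time <- trace$time; rlu <- trace$rlu
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (min(time) > window[1] || max(time) < window[2])
    stop("trace does not cover the integration window")
  total <- trapzWindow(time, rlu, window[1], window[2])
  if (backgroundMode == "pre_window_mean") {
    pre <- time < elicitationTime
    if (!any(pre)) stop("no pre-elicitation samples to estimate background from")
    total - mean(rlu[pre]) * diff(window)
  } else {
    if (is.null(mockTrace)) stop("paired_mock_mean needs a mockTrace")
    total - trapzWindow(mockTrace$time, mockTrace$rlu, window[1], window[2])
  }
}
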