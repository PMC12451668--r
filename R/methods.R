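#' @export
print.hmodel_fit <- function(x, ...) {
  cat("Minimal-basis hydrogen cluster model fit\n")
  cat(sprintf("  task %d, r = %.4g bohr, %d multistart(s), seed %d\n",
              x$task, x$r, x$n_starts, x$seed))
  cat(sprintf("  free parameters: %s\n", paste(x$free, collapse = ", ")))
  cat(sprintf("  RMS energy error: %.6e hartree\n", x$rms))
  print(x$params)
  invisible(x)
}

#' @export
coef.hmodel_fit <- function(object, ...) object$coefficients

#' @export
summary.hmodel_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, residuals = res,
                 worst = res[which.max(abs(res$residual)), ]),
            class = "summary.hmodel_fit")
}

#' @export
print.summary.hmodel_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  start RMS values: best %.3e (start %d), worst %.3e\n",
              min(x$fit$start_rms), x$fit$best_start, max(x$fit$start_rms)))
  cat("\nPer-target deviations (hartree):\n")
  df <- x$residuals
  df$residual <- sprintf("% .3e", df$residual)
  print(df[, c("system", "N", "Sz", "S", "index", "model", "reference",
               "residual")], row.names = FALSE)
  invisible(x)
}

#' Model sector spectra at the fitted parameters
#'
#' @param object an \code{hmodel_fit}.
#' @param r distance at which to evaluate (defaults to the fitted
#'   distance; other distances reuse the fitted parameter values as-is
#'   and are mainly useful for channel-based parameter objects).
#' @param ... unused.
#' @return spectrum data frame for both clusters.
#' @export
predict.hmodel_fit <- function(object, r = object$r, ...) {
  .model_both(object$coefficients, object$eps, r,
              trimer_kind = object$trimer_kind)
}

#' @export
residuals.hmodel_fit <- function(object, ...) {
  energy_residuals(predict(object), object$reference, object$task)
}

#' Residual bar chart of a fitted hydrogen model
#'
#' @param x an \code{hmodel_fit}.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.hmodel_fit <- function(x, ...) {
  res <- residuals(x)
  lab <- ifelse(is.na(res$S),
                sprintf("%s N%d Sz%g #%d", res$system, res$N, res$Sz,
                        res$index),
                sprintf("%s N%d S%g", res$system, res$N, res$S))
  graphics::barplot(res$residual, names.arg = lab, las = 2,
                    ylab = "model - reference (hartree)",
                    cex.names = 0.6, ...)
  graphics::abline(h = c(-0.0016, 0.0016), lty = 3)
  invisible(x)
}

#' @export
print.hmodel_scan <- function(x, ...) {
  cat(sprintf("Per-distance fit protocol (task %d), U frozen at %.6f hartree\n",
              attr(x, "task"), x$U[1]))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Parameter and error curves of a distance scan
#'
#' Two panels in the style of tight-binding parameter plots: the fitted
#' two-center parameters against distance, and the RMS energy error on a
#' log scale with the 0.0016-hartree chemical-accuracy line.
#'
#' @param x an \code{hmodel_scan}.
#' @param ... unused.
#' @export
plot.hmodel_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  pars <- c("S", "H", "Vee", "VeH", "VHH")
  cols <- seq_along(pars) + 1
  graphics::matplot(x$r, as.matrix(x[, pars]), type = "b", pch = 16,
                    lty = 1, col = cols, xlab = "r (bohr)",
                    ylab = "parameter value (a.u.)")
  graphics::legend("topright", legend = pars, col = cols, lty = 1, pch = 16,
                   cex = 0.8, bty = "n")
  graphics::plot(x$r, x$rms, log = "y", type = "b", pch = 16,
                 xlab = "r (bohr)", ylab = "RMS energy error (hartree)")
  graphics::abline(h = 0.0016, lty = 3)
  graphics::mtext("chemical accuracy", side = 4, at = 0.0016, cex = 0.7)
  invisible(x)
}
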