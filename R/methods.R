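#' @export
print.smar <- function(x, ...) {
  cat(sprintf("SMAR multistart fit: %d trials (%s mode, t = %.2f)\n",
              length(x$trials), x$mode, x$t))
  conv <- vapply(x$trials, function(tr) tr$converged, logical(1))
  cat(sprintf("  converged trials: %d / %d\n", sum(conv), length(conv)))
  cat(sprintf("  best final R_delta: %.3f (seed %d)\n",
              x$final_R_delta[1], x$best$seed))
  if (!is.null(x$scores))
    cat(sprintf("  best trial vs truth: mean phase error %.1f deg, map CC %.3f\n",
                x$scores[[1]]$mean_phase_error, x$scores[[1]]$map_cc))
  invisible(x)
}

#' @export
summary.smar <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$trials, function(tr) {
    last <- tr$history[nrow(tr$history), ]
    data.frame(seed = tr$seed, iterations = tr$iterations,
               converged = tr$converged, R_delta = last$R_delta,
               minus2S_delta = last$minus2S_delta,
               CC_rho_prime = last$CC_rho_prime,
               zero_pct = last$zero_pct)
  }))
  if (!is.null(object$scores)) {
    tab$mean_phase_error <- vapply(object$scores,
                                   function(s) s$mean_phase_error, numeric(1))
    tab$map_cc <- vapply(object$scores, function(s) s$map_cc, numeric(1))
  }
  structure(list(table = tab, mode = object$mode), class = "summary.smar")
}

#' @export
print.summary.smar <- function(x, ...) {
  cat(sprintf("SMAR trial summary (%s mode), ranked by final R_delta:\n",
              x$mode))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.smar <- function(x, ...) {
  hs <- lapply(x$trials, function(tr) tr$history$R_delta)
  n <- max(vapply(hs, length, integer(1)))
  graphics::matplot(do.call(cbind, lapply(hs, function(h) c(h, rep(NA, n - length(h))))),
                    type = "l", lty = 1, xlab = "iteration",
                    ylab = expression(R[delta]),
                    main = "SMAR residual trajectories", ...)
  graphics::abline(h = r_delta_floor(mean(x$best$history$zero_pct[1] / 100)),
                   lty = 3)
  invisible(x)
}

#' Phases of the best trial
#'
#' @param object A `"smar"` or `"delta_recycling"` fit.
#' @param ... Unused.
#' @return `data.frame` with `h`, `k`, `l`, `E`, `phi` (radians) for the
#'   best-ranked trial.
#' @export
coef.smar <- function(object, ...) {
  data.frame(h = object$refl$hkl[, 1], k = object$refl$hkl[, 2],
             l = object$refl$hkl[, 3], E = object$refl$E,
             phi = wrap_angle(object$best$phi))
}

#' @export
print.delta_recycling <- function(x, ...) {
  cat(sprintf("delta-recycling multistart fit: %d trials (t1 = %.2f)\n",
              length(x$trials), x$t1))
  conv <- vapply(x$trials, function(tr) tr$converged, logical(1))
  cat(sprintf("  solution candidates: %d / %d\n", sum(conv), length(conv)))
  cat(sprintf("  best figure of merit: %.3f (seed %d)\n",
              x$fom[1], x$best$seed))
  if (!is.null(x$scores))
    cat(sprintf("  best trial vs truth: mean phase error %.1f deg, map CC %.3f\n",
                x$scores[[1]]$mean_phase_error, x$scores[[1]]$map_cc))
  invisible(x)
}

#' @rdname coef.smar
#' @export
coef.delta_recycling <- function(object, ...) {
  data.frame(h = object$refl$hkl[, 1], k = object$refl$hkl[, 2],
             l = object$refl$hkl[, 3], E = object$refl$E,
             phi = wrap_angle(object$best$phi))
}

#' @export
plot.delta_recycling <- function(x, ...) {
  hs <- lapply(x$trials, function(tr) tr$history$phase_change_deg)
  n <- max(vapply(hs, length, integer(1)))
  graphics::matplot(do.call(cbind, lapply(hs, function(h) c(h, rep(NA, n - length(h))))),
                    type = "l", lty = 1, xlab = "iteration",
                    ylab = "mean phase change (deg)",
                    main = "delta-recycling trajectories", ...)
  invisible(x)
}
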