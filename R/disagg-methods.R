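#' Methods for disaggregation fits
#'
#' A `disagg_fit` (returned by [disaggregate()]) behaves like a fitted model:
#' `coef()` extracts the solved per-stratum rate schedules, `residuals()` the
#' per-cycle consistency residuals (stratum sums minus the aggregate; the
#' method's guarantee is that these vanish to solver precision under
#' business-as-usual), `fitted()` the per-stratum compartment trajectories,
#' and `summary()` a compact report of both.
#'
#' @param object,x a `disagg_fit`.
#' @param ... unused.
#' @name disagg_fit-methods
NULL

#' @rdname disagg_fit-methods
#' @export
coef.disagg_mortality <- function(object, ...) {
  list(mortality = object$rates, yld = object$yld)
}

#' @rdname disagg_fit-methods
#' @export
coef.disagg_disease <- function(object, ...) {
  list(incidence = object$incidence, fatality = object$fatality)
}

#' @rdname disagg_fit-methods
#' @export
residuals.disagg_mortality <- function(object, ...) {
  T <- length(object$aggregate$life_years)
  rbind(alive = colSums(object$alive)[-1L] - object$aggregate$alive[-1L],
        halys = colSums(object$halys) - object$aggregate$halys)
}

#' @rdname disagg_fit-methods
#' @export
residuals.disagg_disease <- function(object, ...) {
  rbind(healthy = colSums(object$healthy)[-1L] - object$aggregate$healthy[-1L],
        diseased = colSums(object$diseased)[-1L] - object$aggregate$diseased[-1L])
}

#' @rdname disagg_fit-methods
#' @export
fitted.disagg_mortality <- function(object, ...) {
  do.call(rbind, lapply(names(object$strata), function(k) {
    cbind(stratum = k, as.data.frame(object$strata[[k]]))
  }))
}

#' @rdname disagg_fit-methods
#' @export
fitted.disagg_disease <- function(object, ...) {
  do.call(rbind, lapply(names(object$strata), function(k) {
    cbind(stratum = k, as.data.frame(object$strata[[k]]))
  }))
}

#' @rdname disagg_fit-methods
#' @export
print.disagg_fit <- function(x, ...) {
  kind <- if (inherits(x, "disagg_mortality")) "mortality/morbidity" else
    sprintf("disease (%s)", x$aggregate$disease_name)
  cat(sprintf("Disaggregated %s lifetable: %d strata, %d cycles\n",
              kind, length(x$spec$labels),
              ncol(if (is.null(x$rates)) x$incidence else x$rates)))
  cat(sprintf("  max |consistency residual|: %.3g persons\n",
              max(abs(residuals(x)))))
  invisible(x)
}

#' @rdname disagg_fit-methods
#' @export
summary.disagg_fit <- function(object, ...) {
  res <- residuals(object)
  co <- coef(object)
  out <- list(
    n_strata = length(object$spec$labels),
    labels = object$spec$labels,
    n_cycles = ncol(co[[1L]]),
    max_abs_residual = apply(abs(res), 1L, max),
    rate_range = lapply(co, function(m) apply(m, 1L, range))
  )
  class(out) <- "summary.disagg_fit"
  out
}

#' @export
print.summary.disagg_fit <- function(x, ...) {
  cat(sprintf("Disaggregation fit: %d strata x %d cycles\n", x$n_strata, x$n_cycles))
  cat("Max |consistency residual| by compartment (persons):\n")
  print(signif(x$max_abs_residual, 3))
  for (q in names(x$rate_range)) {
    cat(sprintf("Solved %s rate range by stratum:\n", q))
    rr <- x$rate_range[[q]]
    rownames(rr) <- c("min", "max")
    print(signif(rr, 4))
  }
  invisible(x)
}

#' @rdname disagg_fit-methods
#' @export
plot.disagg_mortality <- function(x, ...) {
  T <- length(x$aggregate$life_years)
  graphics::matplot(1:T, t(rbind(aggregate = x$aggregate$life_years,
                                 x$life_years)),
                    type = "b", pch = 1, lty = 1,
                    xlab = "annual cycle", ylab = "person-years lived", ...)
  graphics::legend("topright", legend = c("aggregate", x$spec$labels),
                   col = seq_len(nrow(x$life_years) + 1L), lty = 1, bty = "n")
  invisible(x)
}
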