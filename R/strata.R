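#' Describe population strata for disaggregation
#'
#' Collects everything needed to split an aggregate cohort into `n` strata:
#' labels (the first stratum is the reference, whose rate ratios are all 1),
#' initial population shares, and per-quantity rate-ratio schedules. A ratio
#' schedule may be a length-`n` vector (constant over cycles) or an
#' `n x T` matrix (one column per cycle).
#'
#' @param labels character vector of stratum names; the first is the
#'   reference stratum.
#' @param shares initial population shares, non-negative, summing to 1 within
#'   1e-12. A share of exactly 0 marks a degenerate stratum carried with zero
#'   counts.
#' @param mort_ratios all-cause mortality rate ratios relative to the
#'   reference stratum (vector or matrix; reference row identically 1).
#' @param morb_ratios YLD (morbidity) rate ratios; defaults to 1 for all
#'   strata.
#' @param diseases named list, one entry per disease, each a list with
#'   elements `inc_ratios`, `fat_ratios` (vectors or matrices) and
#'   `prev_ratios` (length-`n` vector of initial prevalence ratios).
#' @return an object of class `strata_spec`.
#' @examples
#' strata_spec(c("low", "high"), c(0.5, 0.5), mort_ratios = c(1, 2))
#' @export
strata_spec <- function(labels, shares, mort_ratios,
                        morb_ratios = NULL, diseases = list()) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 1L) stop("at least one stratum is required", call. = FALSE)
  if (anyDuplicated(labels)) stop("stratum labels must be unique", call. = FALSE)
  shares <- as.numeric(shares)
  if (length(shares) != n || any(shares < 0) || anyNA(shares)) {
    stop("`shares` must be one non-negative fraction per stratum", call. = FALSE)
  }
  if (abs(sum(shares) - 1) > 1e-12) {
    stop("initial shares must sum to 1 (within 1e-12)", call. = FALSE)
  }
  check_ratios <- function(r, what) {
    rm <- if (is.matrix(r)) r else matrix(as.numeric(r), nrow = n)
    if (nrow(rm) != n) {
      stop(sprintf("`%s` must have one row/value per stratum", what), call. = FALSE)
    }
    if (any(!is.finite(rm)) || any(rm <= 0)) {
      stop(sprintf("`%s` must be positive and finite", what), call. = FALSE)
    }
    if (any(abs(rm[1L, ] - 1) > 1e-12)) {
      stop(sprintf("reference stratum's `%s` must be identically 1", what),
           call. = FALSE)
    }
    r
  }
  mort_ratios <- check_ratios(mort_ratios, "mort_ratios")
  morb_ratios <- check_ratios(morb_ratios %||% rep(1, n), "morb_ratios")
  diseases <- lapply(diseases, function(d) {
    d$inc_ratios <- check_ratios(d$inc_ratios, "inc_ratios")
    d$fat_ratios <- check_ratios(d$fat_ratios, "fat_ratios")
    d$prev_ratios <- as.numeric(check_ratios(d$prev_ratios %||% rep(1, n),
                                             "prev_ratios"))
    d
  })
  structure(list(labels = labels, shares = shares,
                 mort_ratios = mort_ratios, morb_ratios = morb_ratios,
                 diseases = diseases),
            class = "strata_spec")
}

#' @export
print.strata_spec <- function(x, ...) {
  cat(sprintf("Strata specification: %d strata (reference: %s)\n",
              length(x$labels), x$labels[1L]))
  cat("  shares:", paste(sprintf("%s=%.3g", x$labels, x$shares), collapse = ", "), "\n")
  if (length(x$diseases)) {
    cat("  diseases:", paste(names(x$diseases), collapse = ", "), "\n")
  }
  invisible(x)
}

# Expand a ratio input (length-n vector or n x T matrix) to an n x T matrix.
ratio_matrix <- function(r, n, T) {
  if (is.matrix(r)) {
    if (nrow(r) != n) stop("ratio matrix must have one row per stratum", call. = FALSE)
    if (ncol(r) == T) return(r)
    if (ncol(r) == 1L) return(r[, rep(1L, T), drop = FALSE])
    stop(sprintf("ratio schedule covers %d cycles but %d are required",
                 ncol(r), T), call. = FALSE)
  }
  matrix(rep(as.numeric(r), T), nrow = n)
}
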