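#' @title R-factor quality filtering
#' @name quality_filter
#' @description Removes structures with a potentially poor fit to the
#'   electron density. A structure is admissible iff (1) `R_work <= 0.98 *
#'   R_free` and (2) `R_free <= min(0.3, max(0.2, cutoff(resolution)))`,
#'   where the resolution-dependent cutoff is a monotone polynomial fitted to
#'   the 90th percentile of `R_free` in 12 equiprobable resolution bins over
#'   0.5-3.5 Angstroms.
NULL

CUTOFF_DOMAIN <- c(0.5, 3.5)

#' Fit the resolution-dependent R-free cutoff model
#'
#' Resolutions outside the fit domain are ignored. Bin edges are resolution
#' quantiles (equiprobable bins); within each bin the 90th percentile of
#' `R_free` is taken (linear interpolation between order statistics) and the
#' bin is represented by its median resolution. A cubic polynomial is fitted
#' by least squares with a non-negative-derivative constraint enforced on a
#' dense grid (quadratic penalty, refined from the unconstrained fit).
#'
#' @param points Data frame with columns `resolution` and `r_free`.
#' @param n_bins Number of equiprobable bins (default 12).
#' @param degree Polynomial degree (default 3).
#' @return A `resolution_cutoff_model`: coefficients (intercept first),
#'   domain, bin edges, per-bin percentiles and bin representatives.
#' @export
fit_cutoff <- function(points, n_bins = 12, degree = 3) {
  stopifnot(is.data.frame(points),
            all(c("resolution", "r_free") %in% names(points)))
  keep <- !is.na(points$resolution) & !is.na(points$r_free) &
    points$resolution >= CUTOFF_DOMAIN[1] & points$resolution <= CUTOFF_DOMAIN[2]
  pts <- points[keep, , drop = FALSE]
  if (nrow(pts) < 2 * n_bins) {
    stop("fit_cutoff: need at least ", 2 * n_bins,
         " points within [", CUTOFF_DOMAIN[1], ", ", CUTOFF_DOMAIN[2], "]")
  }
  edges <- unname(quantile(pts$resolution, probs = seq(0, 1, length.out = n_bins + 1)))
  edges[1] <- edges[1] - 1e-9
  bin <- cut(pts$resolution, breaks = edges, labels = FALSE)
  mids <- pctl <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    in_bin <- which(bin == b)
    mids[b] <- median(pts$resolution[in_bin])
    pctl[b] <- unname(quantile(pts$r_free[in_bin], probs = 0.9, type = 7))
  }
  X <- outer(mids, 0:degree, `^`)
  fit <- lm.fit(X, pctl)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  grid <- seq(CUTOFF_DOMAIN[1], CUTOFF_DOMAIN[2], length.out = 201)
  dmat <- outer(grid, 0:(degree - 1), function(x, k) (k + 1) * x^k)
  deriv_min <- function(b) min(dmat %*% b[-1])
  if (deriv_min(beta) < -1e-9) {
    obj <- function(b) {
      sum((X %*% b - pctl)^2) + 1e4 * sum(pmin(dmat %*% b[-1], 0)^2)
    }
    beta <- optim(beta, obj, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12))$par
    if (deriv_min(beta) < -1e-6) {
      # fall back to the best monotone constant/linear description
      slope <- max(0, coef(lm(pctl ~ mids))[2])
      icpt <- mean(pctl - slope * mids)
      beta <- c(icpt, slope, rep(0, degree - 1))
    }
  }
  structure(list(coefficients = unname(beta), degree = degree,
                 domain = CUTOFF_DOMAIN, bin_edges = edges,
                 bin_mids = mids, bin_percentiles = pctl),
            class = "resolution_cutoff_model")
}

#' Evaluate the fitted cutoff at given resolutions
#'
#' Resolutions are clamped to the fit domain before evaluation.
#'
#' @param object A `resolution_cutoff_model`.
#' @param resolution Numeric vector of resolutions (Angstroms).
#' @param ... Unused.
#' @return Numeric vector of cutoff values.
#' @export
predict.resolution_cutoff_model <- function(object, resolution, ...) {
  x <- pmin(pmax(resolution, object$domain[1]), object$domain[2])
  drop(outer(x, 0:object$degree, `^`) %*% object$coefficients)
}

#' Structure admissibility under the two R-factor criteria
#'
#' The effective bound `min(0.3, max(0.2, cutoff(resolution)))` always lies
#' in `[0.2, 0.3]` regardless of the fitted polynomial. Missing R-factors
#' make a structure inadmissible.
#'
#' @param r_work,r_free,resolution Numeric vectors (recycled).
#' @param model A `resolution_cutoff_model`, or `NULL` to use the constant
#'   bound 0.3 (criterion 2 reduces to the cap).
#' @return Logical vector.
#' @export
is_admissible <- function(r_work, r_free, resolution, model = NULL) {
  n <- max(length(r_work), length(r_free), length(resolution))
  r_work <- rep_len(r_work, n); r_free <- rep_len(r_free, n)
  resolution <- rep_len(resolution, n)
  cutoff <- if (is.null(model)) rep(0.3, n) else predict(model, resolution)
  bound <- pmin(0.3, pmax(0.2, cutoff))
  ok <- !is.na(r_work) & !is.na(r_free) &
    (r_work <= 0.98 * r_free) & (r_free <= bound)
  ok[is.na(ok)] <- FALSE
  ok
}

#' Serialize / restore a cutoff model as a JSON sidecar
#'
#' @param model A `resolution_cutoff_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored model (read).
#' @export
write_cutoff_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cutoff_model
#' @export
read_cutoff_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "resolution_cutoff_model")
}
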