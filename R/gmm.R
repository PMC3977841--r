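# Univariate Gaussian mixture fitting for per-probe copy-state clustering.
# Deterministic by construction: initial values come from quantile splits
# and fixed-center k-means, never from random draws, so repeated fits of
# the same vector are bit-identical without touching the RNG.

# One EM run from given start values; unequal variances with a floor.
em_gmm1d <- function(x, mu, var, w, max_iter = 60, tol = 1e-6, var_floor) {
  n <- length(x)
  g <- length(mu)
  ll_old <- -Inf
  resp <- NULL
  ll <- NA_real_
  for (it in seq_len(max_iter)) {
    # component densities, inlined for speed: n x g matrix
    dev2 <- (x - rep(mu, each = n))^2
    dens <- matrix(
      exp(-0.5 * dev2 / rep(var, each = n)) *
        rep(w / sqrt(2 * pi * var), each = n),
      nrow = n)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(resp * x) / nk
    var <- colSums(resp * (x - rep(mu, each = n))^2) / nk
    var[var < var_floor] <- var_floor
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(mu = mu, var = var, w = w, loglik = ll, resp = resp)
}

# Deterministic start values for a g-component fit: quantile splits at
# three interior offsets plus a fixed-center k-means partition.
gmm_starts <- function(x, g) {
  v0 <- stats::var(x)
  starts <- list()
  for (off in c(0.5, 0.25)) {
    mu <- unname(quantile(x, (seq_len(g) - off) / g, type = 7))
    starts[[length(starts) + 1]] <-
      list(mu = mu, var = rep(max(v0 / g^2, 1e-8), g), w = rep(1 / g, g))
  }
  centers <- unique(unname(quantile(x, (seq_len(g) - 0.5) / g, type = 7)))
  if (length(centers) == g && g > 1) {
    km <- suppressWarnings(kmeans(x, centers = matrix(centers, ncol = 1)))
    mu <- as.numeric(km$centers)
    v <- vapply(seq_len(g), function(k) {
      xs <- x[km$cluster == k]
      if (length(xs) > 1) stats::var(xs) else v0 / g^2
    }, numeric(1))
    starts[[length(starts) + 1]] <-
      list(mu = mu, var = pmax(v, 1e-8), w = km$size / length(x))
  }
  starts
}

#' Fit a per-probe Gaussian mixture and call copy states
#'
#' Fits univariate Gaussian mixtures with 1, 2 and 3 components to one
#' probe's normalized values across subjects, selects the order by BIC,
#' and assigns each subject to its maximum-responsibility component.
#' Components are ordered by mean; the largest-weight component is
#' anchored as the normal state (2), components below it in mean are loss
#' (1) and above it gain (3). Zero-variance input degenerates cleanly to a
#' single normal-state component.
#'
#' @param values Numeric vector, one normalized (log2-scale) value per
#'   subject; at least 10 non-missing values required.
#' @param max_components Largest mixture order tried (default 3:
#'   loss / normal / gain).
#' @return A `probe_mixture` list: `n_components`, `means`, `vars`,
#'   `weights` (ordered by mean), `states` (per-subject integer 1/2/3, NA
#'   where the input was NA), `bic` (selected order's value), `loglik`.
#' @export
fit_probe_mixture <- function(values, max_components = 3) {
  ok <- is.finite(values)
  x <- values[ok]
  n <- length(x)
  if (n < 10) abort("fit_probe_mixture needs >= 10 finite values")
  out_states <- rep(NA_integer_, length(values))

  if (sd(x) < 1e-12) {
    out_states[ok] <- 2L
    return(structure(list(n_components = 1L, means = mean(x), vars = 0,
                          weights = 1, states = out_states, bic = NA_real_,
                          loglik = NA_real_),
                     class = "probe_mixture"))
  }

  var_floor <- max(1e-4 * stats::var(x), 1e-10)
  best <- NULL
  best_bic <- -Inf
  for (g in seq_len(max_components)) {
    if (g > length(unique(x))) break
    fit_g <- NULL
    for (s in gmm_starts(x, g)) {
      f <- em_gmm1d(x, s$mu, s$var, s$w, var_floor = var_floor)
      if (is.null(fit_g) || f$loglik > fit_g$loglik) fit_g <- f
    }
    bic <- 2 * fit_g$loglik - (3 * g - 1) * log(n)
    if (bic > best_bic) {
      best_bic <- bic
      best <- c(fit_g, list(g = g))
    }
  }

  ord <- order(best$mu)
  means <- best$mu[ord]
  vars <- best$var[ord]
  weights <- best$w[ord]
  comp <- max.col(best$resp[, ord, drop = FALSE])
  anchor <- which.max(weights)
  state_of <- ifelse(seq_along(means) < anchor, 1L,
                     ifelse(seq_along(means) > anchor, 3L, 2L))
  out_states[ok] <- state_of[comp]

  structure(list(n_components = best$g, means = means, vars = vars,
                 weights = weights, states = out_states, bic = best_bic,
                 loglik = best$loglik),
            class = "probe_mixture")
}

#' @export
print.probe_mixture <- function(x, ...) {
  cat("Per-probe Gaussian mixture:", x$n_components, "component(s)\n")
  cat("  means:  ", paste(signif(x$means, 4), collapse = ", "), "\n")
  cat("  weights:", paste(signif(x$weights, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_probe_mixture
#' @param x A `probe_mixture` object.
#' @param ... Unused.
#' @export
tidy.probe_mixture <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 mean = x$means, sd = sqrt(x$vars), weight = x$weights)
}
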