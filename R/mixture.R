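#' Fit a binomial mixture with a discrete-uniform noise component
#'
#' Workhorse EM fitter used both for genotype classification of normal
#' allele fractions and for tumor allele-fraction clustering. The model is
#' a mixture of `K` binomial components with success probabilities `p_k`
#' plus (optionally) a noise component whose density at an observation with
#' depth `d` is the discrete uniform `1/(d + 1)` over `{0, ..., d}`. A
#' binomial-plus-noise mixture keeps highly variable allele fractions in
#' the noise class instead of absorbing them into an over-dispersed
#' component, which is what an over-flexible beta-binomial would do.
#'
#' The fit is fully deterministic: components start from `p_init` and
#' uniform weights, and after every M-step success probabilities are
#' clamped to their component-specific bounds. When all components share
#' the same bounds they are instead kept sorted by `p`, so component
#' identity can never swap between iterations.
#'
#' @param data Data frame with columns `alt` (alt read count) and `depth`.
#' @param p_init Numeric vector of initial success probabilities, one per
#'   binomial component; names become component labels.
#' @param p_lower,p_upper Per-component clamp bounds (recycled).
#' @param estimate_p Update `p_k` in the M-step? With fewer observations
#'   than components, estimation is disabled and the initial values are
#'   kept (with a warning).
#' @param noise Include the discrete-uniform noise component?
#' @param tol Convergence tolerance on the change in log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `binom_mixture`: a list with elements
#'   `weights`, `p`, `posterior` (n x K matrix), `labels` (hard
#'   assignments, ties resolved to `"noise"`), `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, and `data`.
#' @export
#' @examples
#' obs <- tibble::tibble(alt = rbinom(200, 100, 0.5), depth = 100)
#' fit <- fit_binom_mixture(obs, p_init = c(err = 0.01, het = 0.5, hom = 0.99))
#' fit$weights
fit_binom_mixture <- function(data,
                              p_init,
                              p_lower = 1e-4,
                              p_upper = 1 - 1e-4,
                              estimate_p = TRUE,
                              noise = TRUE,
                              tol = 1e-6,
                              max_iter = 500L) {
  stopifnot(is.data.frame(data), all(c("alt", "depth") %in% names(data)))
  a <- as.numeric(data$alt)
  d <- as.numeric(data$depth)
  if (length(a) < 1L) stop("at least one observation is required")
  if (any(d < 1)) stop("all depths must be >= 1")
  if (any(a > d) || any(a < 0)) stop("alt counts must lie in [0, depth]")

  K <- length(p_init)
  comp_names <- names(p_init)
  if (is.null(comp_names)) comp_names <- paste0("c", seq_len(K))
  p_lower <- rep_len(p_lower, K)
  p_upper <- rep_len(p_upper, K)
  shared_bounds <- length(unique(p_lower)) == 1L && length(unique(p_upper)) == 1L

  if (estimate_p && length(a) < K + as.integer(noise)) {
    warning("fewer observations than mixture components; keeping fixed p",
            call. = FALSE)
    estimate_p <- FALSE
  }

  p <- pmin(pmax(as.numeric(p_init), p_lower), p_upper)
  n_comp <- K + as.integer(noise)
  w <- rep(1 / n_comp, n_comp)
  all_names <- c(comp_names, if (noise) "noise")

  log_noise <- -log(d + 1)
  comp_loglik <- function(p) {
    ll <- vapply(p, function(pk) dbinom(a, d, pk, log = TRUE), numeric(length(a)))
    ll <- matrix(ll, nrow = length(a))
    if (noise) ll <- cbind(ll, log_noise)
    ll
  }

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  r <- NULL
  repeat {
    iter <- iter + 1L
    lw <- sweep(comp_loglik(p), 2L, log(pmax(w, 1e-300)), `+`)
    m <- apply(lw, 1L, max)
    lse <- m + log(rowSums(exp(lw - m)))
    ll <- sum(lse)
    if (!is.finite(ll)) stop("non-finite mixture log-likelihood")
    trace <- c(trace, ll)
    r <- exp(lw - lse)

    if (abs(ll - ll_old) < tol || iter >= max_iter) {
      converged <- abs(ll - ll_old) < tol
      break
    }
    ll_old <- ll

    w <- colMeans(r)
    if (estimate_p) {
      for (k in seq_len(K)) {
        denom <- sum(r[, k] * d)
        if (denom > 0) p[k] <- sum(r[, k] * a) / denom
      }
      p <- pmin(pmax(p, p_lower), p_upper)
      if (shared_bounds && is.unsorted(p)) {
        ord <- order(p)
        p <- p[ord]
        w[seq_len(K)] <- w[ord]
        r[, seq_len(K)] <- r[, ord, drop = FALSE]
      }
    }
  }

  colnames(r) <- all_names
  labels <- hard_labels(r, noise)
  structure(
    list(
      weights = setNames(w, all_names),
      p = setNames(p, comp_names),
      posterior = r,
      labels = labels,
      loglik = trace[length(trace)],
      loglik_trace = trace,
      n_iter = iter,
      converged = converged,
      noise = noise,
      data = tibble(alt = a, depth = d)
    ),
    class = "binom_mixture"
  )
}

# Hard assignment with ties resolved in favour of noise: an observation the
# model cannot separate from the uniform background stays out of the
# genotype pools.
hard_labels <- function(r, noise) {
  nm <- colnames(r)
  idx <- max.col(r, ties.method = "first")
  lab <- nm[idx]
  if (noise) {
    rmax <- r[cbind(seq_len(nrow(r)), idx)]
    lab[r[, "noise"] >= rmax - 1e-12] <- "noise"
  }
  lab
}

#' Posterior responsibilities of a fitted mixture at new observations
#'
#' @param object A `binom_mixture` fit.
#' @param newdata Data frame with columns `alt` and `depth`.
#' @param ... Unused.
#' @return A tibble with one posterior-probability column per component and
#'   a `label` column with the hard assignment (ties go to `"noise"`).
#' @export
predict.binom_mixture <- function(object, newdata, ...) {
  a <- as.numeric(newdata$alt)
  d <- as.numeric(newdata$depth)
  ll <- vapply(object$p, function(pk) dbinom(a, d, pk, log = TRUE),
               numeric(length(a)))
  ll <- matrix(ll, nrow = length(a))
  if (object$noise) ll <- cbind(ll, -log(d + 1))
  lw <- sweep(ll, 2L, log(pmax(object$weights, 1e-300)), `+`)
  m <- apply(lw, 1L, max)
  r <- exp(lw - (m + log(rowSums(exp(lw - m)))))
  colnames(r) <- names(object$weights)
  out <- as_tibble(as.data.frame(r))
  out$label <- hard_labels(r, object$noise)
  out
}

#' @export
print.binom_mixture <- function(x, ...) {
  cat("Binomial mixture (", length(x$p), " components",
      if (x$noise) " + noise", ")\n", sep = "")
  cat("  n =", nrow(x$data), " loglik =", format(x$loglik, digits = 6),
      " iterations =", x$n_iter,
      if (!x$converged) " (not converged)", "\n")
  print(tibble(component = names(x$weights),
               weight = unname(x$weights),
               p = unname(x$p)[match(names(x$weights), names(x$p))]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted binomial mixture
#'
#' @param x A `binom_mixture` object.
#' @param ... Unused.
#' @return One row per mixture component with its weight, success
#'   probability (`NA` for the noise component) and hard-assignment count.
#' @export
tidy.binom_mixture <- function(x, ...) {
  tibble(
    component = names(x$weights),
    weight = unname(x$weights),
    p = unname(x$p)[match(names(x$weights), names(x$p))],
    n_assigned = as.integer(table(factor(x$labels, names(x$weights))))
  )
}

#' One-row summary of a fitted binomial mixture
#'
#' @param x A `binom_mixture` object.
#' @param ... Unused.
#' @export
glance.binom_mixture <- function(x, ...) {
  tibble(
    n_obs = nrow(x$data),
    n_components = length(x$p) + as.integer(x$noise),
    loglik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Plot a fitted allele-fraction mixture
#'
#' Histogram of observed allele fractions coloured by hard component
#' assignment.
#'
#' @param object A `binom_mixture` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binom_mixture <- function(object, bins = 60, ...) {
  df <- dplyr::mutate(object$data,
                      vaf = alt / depth,
                      component = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = vaf, fill = component)) +
    ggplot2::geom_histogram(bins = bins, position = "stack") +
    ggplot2::labs(x = "allele fraction", y = "loci", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
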