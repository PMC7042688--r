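# QFASA estimation engine.
#
# Diet is estimated by finding the simplex vector alpha minimizing the
# symmetrized Kullback-Leibler distance between the calibration-corrected
# predator signature and the convex mixture of prey species mean signatures.
# alpha lives in fatty-acid (lipid) space; biomass diet proportions pi are
# obtained by dividing by each species' lipid fraction f_k and re-closing:
#   pi_k = (alpha_k / f_k) / sum_j (alpha_j / f_j).

#' Symmetrized Kullback-Leibler distance between two signatures
#'
#' \eqn{d(a,b) = \sum_i (a_i - b_i)\,\log(a_i/b_i)}.  Symmetric, nonnegative,
#' zero iff the signatures coincide.  Inputs must be zero-replaced (see
#' [replace_zeros()]): any nonpositive component is an error.
#'
#' @param a,b aligned signature vectors summing to 1.
#' @return nonnegative scalar.
#' @export
kl_distance <- function(a, b) {
  if (length(a) != length(b)) stop("signatures differ in length")
  if (any(a <= 0) || any(b <= 0)) {
    stop("kl_distance needs strictly positive components; apply replace_zeros() first")
  }
  sum((a - b) * log(a / b))
}

#' Mixture signature under fatty-acid-space coefficients
#'
#' @param alpha simplex vector over prey species.
#' @param means matrix of species mean signatures (species in rows), each row
#'   summing to 1.
#' @return convex combination, re-closed to sum 1.
#' @export
mixture_signature <- function(alpha, means) {
  if (length(alpha) != nrow(means)) stop("alpha does not match species count")
  out <- drop(crossprod(means, alpha))
  out / sum(out)
}

#' Convert fatty-acid-space coefficients to biomass diet proportions
#'
#' @param alpha simplex vector over species.
#' @param lipid per-species lipid fractions f_k in (0, 1].
#' @return biomass-space simplex vector pi.
#' @export
alpha_to_pi <- function(alpha, lipid) {
  if (length(alpha) != length(lipid)) stop("alpha/lipid length mismatch")
  if (any(lipid <= 0)) stop("lipid fractions must be > 0")
  w <- alpha / lipid
  w / sum(w)
}

# softmax parameterization keeps the optimizer unconstrained; z is clamped so
# exp() stays finite and a vertex is representable to ~1e-14.
.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(pmax(z, -34))
  e / sum(e)
}

.kl_objective <- function(pred, means) {
  lp <- log(pred)
  function(z) {
    alpha <- .softmax(z)
    mix <- drop(crossprod(means, alpha))
    mix <- mix / sum(mix)
    sum((pred - mix) * (lp - log(mix)))
  }
}

#' Estimate the diet of one predator
#'
#' Runs a multi-start simplex-constrained minimization of [kl_distance()]
#' between the calibration-corrected, subset-restricted predator signature
#' and the prey mean mixture.  Starts are the K vertices, the barycenter and
#' seeded random points; the best optimum is kept.
#'
#' @param pred named predator signature vector (predator space).
#' @param lib a [prey_library()].
#' @param cc calibration coefficients aligned to the library fatty acid set
#'   (default all 1: no correction).
#' @param fa_subset fatty acid subset used for modelling (default full set).
#' @param lipid_overrides named per-species lipid fractions overriding the
#'   library's (e.g. `c(ringed_seal = 0.8)`).
#' @param eps zero-replacement constant.
#' @param n_random number of random starts added to the vertex and barycenter
#'   starts.
#' @param seed integer seed for the random starts.
#' @return list of class `diet_estimate`: `alpha`, `pi`, `optimum_distance`,
#'   `converged`, `n_starts_agreeing`.
#' @export
estimate_diet <- function(pred, lib, cc = NULL, fa_subset = NULL,
                          lipid_overrides = NULL, eps = 1e-5,
                          n_random = 3L, seed = 1L) {
  if (is.null(fa_subset)) fa_subset <- lib$fa
  if (is.null(cc)) cc <- stats::setNames(rep(1, length(lib$fa)), lib$fa)
  if (is.null(names(pred))) names(pred) <- lib$fa
  means <- prey_means(lib, fa_subset = fa_subset, eps = eps)
  p <- apply_calibration(pred[lib$fa], cc[lib$fa], "predator_to_prey")
  p <- replace_zeros(restrict_signature(p, fa_subset), eps = eps)
  lipid <- lib$lipid
  if (!is.null(lipid_overrides)) {
    unknown <- setdiff(names(lipid_overrides), lib$species)
    if (length(unknown)) stop("lipid override for unknown species: ",
                              paste(unknown, collapse = ", "))
    lipid[names(lipid_overrides)] <- lipid_overrides
  }
  fit <- .optimize_alpha(p, means, n_random = n_random, seed = seed)
  structure(list(alpha = stats::setNames(fit$alpha, lib$species),
                 pi = stats::setNames(alpha_to_pi(fit$alpha, lipid),
                                      lib$species),
                 optimum_distance = fit$value,
                 converged = fit$converged,
                 n_starts_agreeing = fit$n_agree),
            class = "diet_estimate")
}

.optimize_alpha <- function(pred, means, n_random = 3L, seed = 1L,
                            tol = 1e-10) {
  k <- nrow(means)
  starts <- list()
  for (i in seq_len(k)) {                       # near-vertex starts
    z <- rep(0, k); z[i] <- 8
    starts[[length(starts) + 1L]] <- z
  }
  starts[[length(starts) + 1L]] <- rep(0, k)    # barycenter
  if (n_random > 0L) {
    rand <- .with_subseed(seed, "starts", {
      matrix(stats::rnorm(n_random * k, sd = 2), n_random, k)
    })
    for (i in seq_len(n_random)) {
      z <- rand[i, ]
      starts[[length(starts) + 1L]] <- z - mean(z)
    }
  }
  obj <- .kl_objective(pred, means)
  best <- NULL
  values <- numeric(length(starts))
  any_conv <- FALSE
  for (s in seq_along(starts)) {
    fit <- stats::optim(starts[[s]], obj, method = "L-BFGS-B",
                        lower = -30, upper = 30,
                        control = list(factr = 1e4, pgtol = 1e-12,
                                       maxit = 500L))
    values[s] <- fit$value
    if (fit$convergence == 0L) any_conv <- TRUE
    # ties between starts: lowest distance wins, then lowest start index
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!any_conv) warning("optimizer failed to converge from every start")
  alpha <- .softmax(best$par)
  list(alpha = alpha, value = best$value, converged = any_conv,
       n_agree = sum(values <= best$value + 1e-6))
}

#' @export
print.diet_estimate <- function(x, ...) {
  cat("Diet estimate (biomass proportions):\n")
  print(round(100 * x$pi, 1))
  cat(sprintf("KL optimum %.3g; converged: %s (%d/%d starts agree)\n",
              x$optimum_distance, x$converged, x$n_starts_agreeing,
              x$n_starts_agreeing))
  invisible(x)
}

#' Estimate diets for a cohort of predators
#'
#' @param predators a [predator_set()].
#' @inheritParams estimate_diet
#' @return list of class `diet_table`: `estimates` (data.frame: id, class,
#'   year, one pi column per species, `optimum_distance`, `converged`) and
#'   `summary` (per-species mean and SE of pi, on the percent scale).
#' @export
batch_estimate <- function(predators, lib, cc = NULL, fa_subset = NULL,
                           lipid_overrides = NULL, eps = 1e-5, seed = 1L) {
  n <- nrow(predators$sig)
  if (n == 0L) stop("empty predator set")
  ests <- vector("list", n)
  for (i in seq_len(n)) {
    ests[[i]] <- estimate_diet(predators$sig[i, ], lib, cc = cc,
                               fa_subset = fa_subset,
                               lipid_overrides = lipid_overrides,
                               eps = eps, seed = seed + i - 1L)
  }
  pis <- do.call(rbind, lapply(ests, `[[`, "pi"))
  out <- cbind(predators$info[c("id", "class", "year")],
               as.data.frame(pis),
               optimum_distance = vapply(ests, `[[`, numeric(1),
                                         "optimum_distance"),
               converged = vapply(ests, `[[`, logical(1), "converged"))
  rownames(out) <- NULL
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  summ <- data.frame(species = lib$species,
                     mean_pct = 100 * colMeans(pis),
                     se_pct = 100 * apply(pis, 2L, se),
                     row.names = NULL)
  structure(list(estimates = out, summary = summ, species = lib$species),
            class = "diet_table")
}

#' @export
print.diet_table <- function(x, ...) {
  cat("Diet estimates for", nrow(x$estimates), "predators\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %5.1f ± %.1f%%\n",
                s$species[i], s$mean_pct[i], s$se_pct[i]))
  }
  invisible(x)
}

#' Diet proportion matrix from a diet table
#'
#' @param diet a `diet_table` from [batch_estimate()] (or a data.frame with
#'   the species columns).
#' @param species species column names (taken from the object if absent).
#' @return numeric matrix, one row per predator, columns the species pi.
#' @export
diet_matrix <- function(diet, species = NULL) {
  if (is.matrix(diet)) {
    if (is.null(species)) return(diet)
    return(diet[, species, drop = FALSE])
  }
  df <- if (inherits(diet, "diet_table")) diet$estimates else diet
  if (is.null(species)) {
    species <- if (inherits(diet, "diet_table")) diet$species else
      setdiff(names(df), c("id", "class", "year", "optimum_distance",
                           "converged"))
  }
  as.matrix(df[species])
}

#' Exhaustive grid search over the simplex (oracle for small problems)
#'
#' Enumerates all compositions over `k` species at the given resolution and
#' returns the one minimizing the KL distance to the predator signature.
#' Exponential in `k`; intended for k <= 3 validation only.
#'
#' @param pred zero-replaced predator signature in prey space (already
#'   calibrated and restricted).
#' @param means species mean matrix as in [mixture_signature()].
#' @param resolution grid step on each coordinate.
#' @return list `alpha`, `value`.
#' @export
grid_search_diet <- function(pred, means, resolution = 0.01) {
  k <- nrow(means)
  if (k > 4L) stop("grid search is for small species counts")
  steps <- round(1 / resolution)
  grid <- .simplex_grid(k, steps)
  best_v <- Inf; best_a <- NULL
  lp <- log(pred)
  for (i in seq_len(nrow(grid))) {
    a <- grid[i, ]
    mix <- drop(crossprod(means, a))
    mix <- mix / sum(mix)
    v <- sum((pred - mix) * (lp - log(mix)))
    if (v < best_v) { best_v <- v; best_a <- a }
  }
  list(alpha = best_a, value = best_v)
}

.simplex_grid <- function(k, steps) {
  if (k == 1L) return(matrix(1, 1, 1))
  recurse <- function(k, total) {
    if (k == 1L) return(matrix(total, 1, 1))
    out <- lapply(0:total, function(i) cbind(i, recurse(k - 1L, total - i)))
    do.call(rbind, out)
  }
  recurse(k, steps) / steps
}
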