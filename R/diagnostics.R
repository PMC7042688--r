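# Model-adequacy simulations: prey-on-prey identification and
# pseudo-predator diet recovery.

#' Prey-on-prey simulation
#'
#' Splits each species' specimens at random into a "predator" test set and a
#' reduced prey library, runs every test specimen through [estimate_diet()]
#' against the reduced library, and scores the proportion attributed back to
#' the specimen's own species.  Test specimens are mapped into predator
#' space with the inverse calibration before estimation, so the engine's
#' forward correction is exercised consistently.
#'
#' @param lib a [prey_library()]; species with fewer than 2 specimens are
#'   excluded with a warning.
#' @param cc calibration coefficients (default all 1).
#' @param fa_subset fatty acid subset for modelling.
#' @param lipids optional per-species lipid fractions used for the pi
#'   conversion; default all 1 (identification read on the alpha scale).
#' @param split_fraction fraction of each species placed in the test set
#'   (test set size rounds down on odd counts).
#' @param n_reps number of random split replicates.
#' @param metric "proportion" (mean estimated share assigned to the true
#'   species, the reporting default) or "classification" (majority vote).
#' @param seed integer seed.
#' @param eps zero-replacement constant.
#' @return list of class `prey_on_prey_result`: `summary` (per-species
#'   correct-identification mean and SD, percent) and `attributions`
#'   (data.frame of every test specimen's full attribution vector).
#' @export
prey_on_prey <- function(lib, cc = NULL, fa_subset = NULL, lipids = NULL,
                         split_fraction = 0.5, n_reps = 100L,
                         metric = c("proportion", "classification"),
                         seed = 1L, eps = 1e-5) {
  metric <- match.arg(metric)
  stopifnot(split_fraction > 0, split_fraction < 1, n_reps >= 1L)
  counts <- vapply(lib$signatures, nrow, integer(1))
  if (any(counts < 2L)) {
    warning("excluding species with a single specimen: ",
            paste(lib$species[counts < 2L], collapse = ", "))
    keep <- lib$species[counts >= 2L]
    lib <- prey_library(lib$signatures[keep], lipid = lib$lipid[keep])
  }
  if (is.null(cc)) cc <- stats::setNames(rep(1, length(lib$fa)), lib$fa)
  rows <- .with_subseed(seed, "prey_on_prey", {
    out <- list()
    for (rep_i in seq_len(n_reps)) {
      split <- lapply(lib$signatures, function(m) {
        n_test <- max(1L, floor(nrow(m) * split_fraction))
        if (n_test >= nrow(m)) n_test <- nrow(m) - 1L
        test <- sample.int(nrow(m), n_test)
        list(test = m[test, , drop = FALSE],
             train = m[-test, , drop = FALSE])
      })
      red_lib <- prey_library(lapply(split, `[[`, "train"),
                              lipid = lib$lipid)
      for (k in lib$species) {
        tm <- split[[k]]$test
        for (i in seq_len(nrow(tm))) {
          pred <- apply_calibration(tm[i, ], cc[lib$fa], "prey_to_predator")
          names(pred) <- lib$fa
          est <- estimate_diet(pred, red_lib, cc = cc,
                               fa_subset = fa_subset,
                               lipid_overrides = lipids, eps = eps,
                               seed = sample.int(2^30, 1L))
          out[[length(out) + 1L]] <-
            data.frame(rep = rep_i, species = k, t(est$pi))
        }
      }
    }
    out
  })
  attributions <- do.call(rbind, rows)
  own <- mapply(function(r, k) attributions[r, k],
                seq_len(nrow(attributions)), attributions$species)
  score <- if (metric == "proportion") 100 * own else {
    est_mat <- as.matrix(attributions[lib$species])
    100 * (lib$species[max.col(est_mat)] == attributions$species)
  }
  summary <- do.call(rbind, lapply(lib$species, function(k) {
    s <- score[attributions$species == k]
    data.frame(species = k, correct_id_mean = mean(s),
               correct_id_sd = stats::sd(s), n = length(s))
  }))
  structure(list(summary = summary, attributions = attributions,
                 metric = metric, n_reps = n_reps, seed = seed),
            class = "prey_on_prey_result")
}

#' @export
print.prey_on_prey_result <- function(x, ...) {
  cat("Prey-on-prey simulation (", x$n_reps, " splits, metric = ",
      x$metric, "):\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %5.1f ± %.1f%% correct\n",
                s$species[i], s$correct_id_mean[i], s$correct_id_sd[i]))
  }
  invisible(x)
}

#' Pseudo-predator simulation
#'
#' For each run, specimens are bootstrap-resampled within each species, the
#' resampled species means are combined with fat-weighted coefficients
#' \eqn{\alpha_k \propto \pi_k f_k} at the stated true diet, the mixture is
#' distorted into predator space with the inverse calibration, and the
#' resulting pseudo-predator is handed to [estimate_diet()].
#'
#' @param true_diet named simplex vector of biomass diet proportions over
#'   the library species.
#' @param lib a [prey_library()].
#' @param cc calibration coefficients (default all 1).
#' @param fa_subset fatty acid subset.
#' @param lipids per-species lipid fractions (default: the library's).
#' @param n_runs number of simulation runs (default 100).
#' @param seed integer seed.
#' @param eps zero-replacement constant.
#' @return list of class `pseudo_predator_result`: `true_diet`, `runs`
#'   (matrix of recovered pi, one row per run), `summary` (per-species mean
#'   and SD of recovered pi, percent).
#' @export
pseudo_predator <- function(true_diet, lib, cc = NULL, fa_subset = NULL,
                            lipids = NULL, n_runs = 100L, seed = 1L,
                            eps = 1e-5) {
  if (length(true_diet) != length(lib$species)) {
    stop("true_diet does not match the library species count")
  }
  if (!is.null(names(true_diet))) true_diet <- true_diet[lib$species]
  true_diet <- true_diet / sum(true_diet)
  if (is.null(lipids)) lipids <- lib$lipid
  lipids <- lipids[lib$species]
  if (is.null(cc)) cc <- stats::setNames(rep(1, length(lib$fa)), lib$fa)
  alpha_true <- true_diet * lipids
  alpha_true <- alpha_true / sum(alpha_true)
  runs <- .with_subseed(seed, "pseudo_predator", {
    t(vapply(seq_len(n_runs), function(run) {
      boot_means <- t(vapply(lib$species, function(k) {
        m <- lib$signatures[[k]]
        idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
        mu <- colMeans(replace_zeros(m[idx, , drop = FALSE], eps = eps))
        mu / sum(mu)
      }, numeric(length(lib$fa))))
      mix <- mixture_signature(alpha_true, boot_means)
      pred <- apply_calibration(mix, cc[lib$fa], "prey_to_predator")
      names(pred) <- lib$fa
      est <- estimate_diet(pred, lib, cc = cc, fa_subset = fa_subset,
                           lipid_overrides = lipids, eps = eps,
                           seed = sample.int(2^30, 1L))
      est$pi
    }, numeric(length(lib$species))))
  })
  colnames(runs) <- lib$species
  summary <- data.frame(species = lib$species,
                        true_pct = 100 * as.numeric(true_diet),
                        estimate_mean = 100 * colMeans(runs),
                        estimate_sd = 100 * apply(runs, 2L, stats::sd),
                        row.names = NULL)
  structure(list(true_diet = stats::setNames(as.numeric(true_diet),
                                             lib$species),
                 runs = runs, summary = summary, n_runs = n_runs,
                 seed = seed),
            class = "pseudo_predator_result")
}

#' @export
print.pseudo_predator_result <- function(x, ...) {
  cat("Pseudo-predator simulation (", x$n_runs, " runs):\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s true %5.1f%%  recovered %5.1f ± %.1f%%\n",
                s$species[i], s$true_pct[i], s$estimate_mean[i],
                s$estimate_sd[i]))
  }
  invisible(x)
}
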