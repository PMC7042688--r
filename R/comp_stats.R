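# Distance-based permutation statistics on diet-proportion matrices.
#
# The perMANOVA engine partitions a Gower-centered squared-distance matrix
# with sequential (Type I) sums of squares, computes a pseudo-F per model
# term, and obtains p-values by free permutation of observation labels with
# the add-one convention p = (1 + #{F* >= F}) / (1 + n_perm).

#' Chi-square distance matrix between proportion profiles
#'
#' \eqn{d(i,j) = \sqrt{ \sum_c (p_{ic}/p_{i+} - p_{jc}/p_{j+})^2 / (p_{+c}/p_{++}) }}
#' with row totals \eqn{p_{i+}}, column totals \eqn{p_{+c}} and grand total
#' \eqn{p_{++}}: profile-standardized Euclidean distance, column-weighted by
#' inverse column mass.
#'
#' @param P nonnegative matrix, observations in rows.
#' @return symmetric `dist`-convertible matrix with zero diagonal.
#' @export
chi_square_distance <- function(P) {
  P <- as.matrix(P)
  if (any(P < 0)) stop("negative entries in proportion matrix")
  rt <- rowSums(P)
  if (any(rt == 0)) stop("all-zero row(s): ",
                         paste(which(rt == 0), collapse = ", "))
  ct <- colSums(P)
  if (any(ct == 0)) {
    bad <- colnames(P)[ct == 0]
    if (is.null(bad)) bad <- which(ct == 0)
    stop("all-zero column(s): ", paste(bad, collapse = ", "))
  }
  prof <- P / rt
  w <- ct / sum(P)
  scaled <- sweep(prof, 2L, sqrt(w), "/")
  d <- as.matrix(stats::dist(scaled))
  dimnames(d) <- list(rownames(P), rownames(P))
  d
}

# Gower-centered matrix G from a distance matrix: SS_total = tr(G).
.gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
}

# Hat matrix via QR, tolerant of rank deficiency.
.hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# Build cumulative hat matrices for sequential SS from a formula + data.
.build_terms <- function(formula, data) {
  tt <- stats::terms(formula)
  labels <- attr(tt, "term.labels")
  if (length(labels) == 0L) stop("formula has no terms")
  for (v in all.vars(formula)) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L) {
      stop("factor '", v, "' has a single level")
    }
  }
  n <- nrow(data)
  hats <- vector("list", length(labels) + 1L)
  hats[[1L]] <- matrix(1 / n, n, n)        # intercept
  ranks <- integer(length(labels))
  prev_rank <- 1L
  for (j in seq_along(labels)) {
    f <- stats::reformulate(labels[seq_len(j)])
    X <- stats::model.matrix(f, data)
    q_rank <- qr(X)$rank
    if (q_rank == prev_rank) {
      stop("term '", labels[j], "' is confounded with earlier terms")
    }
    hats[[j + 1L]] <- .hat_matrix(X)
    ranks[j] <- q_rank - prev_rank
    prev_rank <- q_rank
  }
  list(labels = labels, hats = hats, df = ranks,
       rank_full = prev_rank, data = data)
}

#' Distance-based permutation MANOVA
#'
#' @param D symmetric distance matrix (or `dist`) over observations.
#' @param data data.frame of factors/covariates aligned to `D`'s rows.
#' @param formula right-hand-side formula of main effects, optionally an
#'   interaction or a continuous covariate, e.g. `~ class * year`.
#' @param n_perm number of random permutations (>= 99), ignored when
#'   `exact = TRUE`.
#' @param seed integer seed for the permutation stream.
#' @param exact if TRUE, enumerate all n! permutations (n <= 9 enforced) and
#'   report the exact permutation p (plain proportion including identity).
#' @return data.frame of class `permanova_result`: one row per term plus a
#'   residual and total row, with `df`, `SS`, `pseudo_F`, `p_perm`.
#' @export
permanova <- function(D, data, formula, n_perm = 999L, seed = 1L,
                      exact = FALSE) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (nrow(data) != n) stop("factor table does not match the distance matrix")
  if (!exact && n_perm < 99L) stop("n_perm must be at least 99")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  G <- .gower_center(D)
  bt <- .build_terms(formula, data)
  if (n - bt$rank_full < 1L) {
    stop("model saturates the design: no residual degrees of freedom")
  }
  m <- length(bt$labels)
  ss_total <- sum(diag(G))
  stat_fun <- function(Gp) {
    tr <- vapply(bt$hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(tr)                       # sequential SS per term
    ss_res <- sum(diag(Gp)) - tr[m + 1L]
    df_res <- n - bt$rank_full
    ms_res <- ss_res / df_res
    f <- ifelse(ss <= 1e-12, 0,
                (ss / bt$df) / if (ms_res > 1e-12) ms_res else Inf)
    f[!is.finite(f)] <- 0
    list(ss = ss, ss_res = ss_res, df_res = df_res, f = f)
  }
  obs <- stat_fun(G)
  if (exact) {
    if (n > 9L) stop("exact enumeration supported for n <= 9 only")
    perms <- .all_permutations(n)
    count <- integer(m)
    for (i in seq_len(nrow(perms))) {
      p <- perms[i, ]
      fp <- stat_fun(G[p, p])$f
      count <- count + (fp >= obs$f - 1e-12)
    }
    p_perm <- count / nrow(perms)
    n_used <- nrow(perms)
  } else {
    count <- .with_subseed(seed, "permanova", {
      cnt <- integer(m)
      for (i in seq_len(n_perm)) {
        p <- sample.int(n)
        fp <- stat_fun(G[p, p])$f
        cnt <- cnt + (fp >= obs$f - 1e-12)
      }
      cnt
    })
    p_perm <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }
  out <- data.frame(term = c(bt$labels, "Residual", "Total"),
                    df = c(bt$df, obs$df_res, n - 1L),
                    SS = c(obs$ss, obs$ss_res, ss_total),
                    pseudo_F = c(obs$f, NA, NA),
                    p_perm = c(p_perm, NA, NA))
  attr(out, "n_perm") <- n_used
  attr(out, "seed") <- seed
  class(out) <- c("permanova_result", "data.frame")
  out
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    if (pos == 1L) cbind(n, sub, deparse.level = 0)
    else if (pos == n) cbind(sub, n, deparse.level = 0)
    else cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
               sub[, pos:(n - 1L), drop = FALSE], deparse.level = 0)
  }))
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("Distance-based permutation MANOVA (", attr(x, "n_perm"),
      " permutations)\n", sep = "")
  print.data.frame(cbind(x[1], round(x[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' Holm step-down multiple-comparison adjustment
#'
#' Sort ascending; the i-th smallest raw p becomes
#' \eqn{\max_{j \le i} \min(1, (m - j + 1) p_{(j)})}; original order is
#' restored.  Adjusted values are never below raw; the smallest equals its
#' Bonferroni value.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted vector in the original order.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1L) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Per-prey perMANOVAs on (p_k, 1 - p_k) compositions
#'
#' For each prey k the two-column composition (p_k, 1 - p_k) is formed, a
#' chi-square distance matrix built, and a perMANOVA run with the supplied
#' model terms; p-values for each term are Holm-adjusted across the prey set.
#'
#' @param diet diet table or matrix accepted by [diet_matrix()].
#' @param data factor table aligned to the rows.
#' @param formula model formula (typically the significant overall terms).
#' @inheritParams permanova
#' @return data.frame: one row per prey x term with raw and Holm-adjusted p.
#' @export
per_prey_permanova <- function(diet, data, formula, n_perm = 999L,
                               seed = 1L) {
  P <- diet_matrix(diet)
  species <- colnames(P)
  res <- do.call(rbind, lapply(seq_along(species), function(k) {
    comp <- cbind(p = P[, k], q = 1 - P[, k])
    if (stats::sd(comp[, 1]) == 0) {
      bt <- stats::terms(formula)
      labs <- attr(bt, "term.labels")
      return(data.frame(species = species[k], term = labs, df = NA,
                        pseudo_F = 0, p_raw = 1))
    }
    pr <- permanova(chi_square_distance(comp), data, formula,
                    n_perm = n_perm, seed = .subseed(seed, species[k]))
    terms_only <- pr[!pr$term %in% c("Residual", "Total"), ]
    data.frame(species = species[k], term = terms_only$term,
               df = terms_only$df, pseudo_F = terms_only$pseudo_F,
               p_raw = terms_only$p_perm)
  }))
  res$p_holm <- NA_real_
  for (tm in unique(res$term)) {
    i <- res$term == tm
    res$p_holm[i] <- holm_adjust(res$p_raw[i])
  }
  rownames(res) <- NULL
  res
}

#' Pairwise sex/age class perMANOVAs for one prey
#'
#' One (p_k, 1 - p_k) perMANOVA per class pair, Holm-adjusted over the
#' pairs.  Classes with fewer than 2 members are excluded with a warning.
#'
#' @param diet diet table or matrix.
#' @param class_labels vector of class labels aligned to the rows.
#' @param species prey species (column) to test.
#' @inheritParams permanova
#' @return data.frame with one row per class pair: raw and adjusted p.
#' @export
pairwise_class_tests <- function(diet, class_labels, species,
                                 n_perm = 999L, seed = 1L) {
  P <- diet_matrix(diet)
  if (!species %in% colnames(P)) stop("unknown prey species: ", species)
  class_labels <- as.character(class_labels)
  sizes <- table(class_labels)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding classes with < 2 members: ",
            paste(small, collapse = ", "))
  }
  classes <- sort(names(sizes)[sizes >= 2L])
  if (length(classes) < 2L) stop("need at least 2 classes with >= 2 members")
  pairs <- utils::combn(classes, 2L)
  res <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    keep <- class_labels %in% c(a, b)
    comp <- cbind(p = P[keep, species], q = 1 - P[keep, species])
    dat <- data.frame(class = factor(class_labels[keep]))
    pr <- permanova(chi_square_distance(comp), dat, ~ class,
                    n_perm = n_perm, seed = .subseed(seed, paste(a, b)))
    data.frame(class_a = a, class_b = b,
               pseudo_F = pr$pseudo_F[1L], p_raw = pr$p_perm[1L])
  }))
  res$p_holm <- holm_adjust(res$p_raw)
  rownames(res) <- NULL
  res
}

#' Spearman trend of annual mean diet proportions
#'
#' Per prey: the annual mean of pi is computed, then the Spearman rank
#' correlation of annual means against year (exact p for n <= 9 years,
#' normal approximation above).
#'
#' @param diet diet table or matrix.
#' @param years capture year per row.
#' @return data.frame per prey: `r_s`, `p`, `n` (number of years).
#' @export
annual_mean_trend <- function(diet, years) {
  P <- diet_matrix(diet)
  yrs <- sort(unique(years))
  if (length(yrs) < 3L) stop("need at least 3 distinct years")
  res <- do.call(rbind, lapply(colnames(P), function(k) {
    ann <- vapply(yrs, function(y) mean(P[years == y, k]), numeric(1))
    ct <- suppressWarnings(
      stats::cor.test(ann, yrs, method = "spearman",
                      exact = length(yrs) <= 9L))
    data.frame(species = k, r_s = unname(ct$estimate), p = ct$p.value,
               n = length(yrs))
  }))
  rownames(res) <- NULL
  res
}

#' perMANOVA with a sea-ice covariate replacing capture year
#'
#' The chosen annual ice index (1 df continuous covariate) enters the
#' sequential partition first, with sex/age class retained.
#'
#' @param diet diet table or matrix.
#' @param data factor table with columns `class` and `year`.
#' @param ice ice-index table with columns `year` and the chosen index.
#' @param index one of "ifd50", "ifd15", "melt_season".
#' @inheritParams permanova
#' @return a `permanova_result`.
#' @export
ice_covariate_permanova <- function(diet, data, ice,
                                    index = c("ifd50", "ifd15",
                                              "melt_season"),
                                    n_perm = 999L, seed = 1L) {
  index <- match.arg(index)
  missing_years <- setdiff(unique(data$year), ice$year)
  if (length(missing_years)) {
    stop("years absent from the ice table: ",
         paste(sort(missing_years), collapse = ", "))
  }
  P <- diet_matrix(diet)
  dat <- data.frame(ice = ice[[index]][match(data$year, ice$year)],
                    class = factor(data$class))
  if (stats::sd(dat$ice) == 0) {
    # constant covariate carries no SS; report a zero row without fitting
    D <- chi_square_distance(P)
    pr <- permanova(D, dat["class"], ~ class, n_perm = n_perm, seed = seed)
    zero <- data.frame(term = "ice", df = 1L, SS = 0, pseudo_F = 0,
                       p_perm = 1)
    out <- rbind(zero, pr)
    class(out) <- class(pr)
    attr(out, "n_perm") <- attr(pr, "n_perm")
    return(out)
  }
  permanova(chi_square_distance(P), dat, ~ ice + class,
            n_perm = n_perm, seed = seed)
}
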