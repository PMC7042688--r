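# Fatty acid signatures are compositions: nonnegative vectors over a fixed,
# ordered set of fatty acid labels (e.g. "16:0", "20:5n3", "22:6n3"),
# closed to sum 1.  External files may carry them on the 0-100 (mass percent
# of total FAME) scale; internally everything is a proportion.

SEX_AGE_CLASSES <- c("AF", "AM", "SF", "SM")

#' Validate a fatty acid label set
#'
#' @param names character vector of fatty acid shorthand labels.
#' @return the validated character vector.
#' @export
fa_set <- function(names) {
  if (length(names) == 0L) stop("fatty acid set must be non-empty")
  names <- as.character(names)
  if (anyDuplicated(names)) {
    stop("duplicate fatty acid labels: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  names
}

#' Close a nonnegative vector to a unit-sum signature
#'
#' @param raw nonnegative numeric vector (optionally named by fatty acid).
#' @param id specimen identifier used in error messages.
#' @return numeric vector of the same length summing to 1.
#' @examples
#' normalize_signature(c(1, 1, 2))
#' @export
normalize_signature <- function(raw, id = "signature") {
  if (length(raw) == 0L) stop("empty signature for ", id)
  if (anyNA(raw) || !is.numeric(raw)) stop("non-numeric values in ", id)
  if (any(raw < 0)) stop("negative values in ", id)
  s <- sum(raw)
  if (s <= 0) stop("all-zero signature for ", id)
  raw / s
}

#' Replace zeros in a signature by a small constant and re-close
#'
#' KL-type distances are undefined at zero components, so zeros are replaced
#' by a small positive constant before any logarithmic distance.
#'
#' @param sig signature vector (or matrix with specimens in rows).
#' @param eps replacement constant, default 1e-5.
#' @return zero-free signature(s), re-closed to sum 1.
#' @export
replace_zeros <- function(sig, eps = 1e-5) {
  if (is.matrix(sig)) return(t(apply(sig, 1L, replace_zeros, eps = eps)))
  sig[sig < eps] <- eps
  sig / sum(sig)
}

#' Apply (or invert) calibration coefficients
#'
#' Calibration coefficients (CCs) describe the per-fatty-acid multiplicative
#' distortion between diet and predator adipose signatures.  The forward
#' direction maps a predator signature into prey space by dividing each
#' component by its CC and re-closing; the inverse direction (multiply then
#' re-close) is used when building simulated predators from prey mixtures.
#'
#' @param sig signature vector aligned to `cc`.
#' @param cc strictly positive calibration coefficients, one per fatty acid.
#' @param direction "predator_to_prey" (divide, default) or
#'   "prey_to_predator" (multiply).
#' @return calibrated signature summing to 1.
#' @export
apply_calibration <- function(sig, cc,
                              direction = c("predator_to_prey",
                                            "prey_to_predator")) {
  direction <- match.arg(direction)
  if (length(sig) != length(cc)) stop("signature and cc lengths differ")
  if (any(!is.finite(cc)) || any(cc <= 0)) {
    stop("calibration coefficients must be strictly positive")
  }
  out <- if (direction == "predator_to_prey") sig / cc else sig * cc
  normalize_signature(out)
}

#' Restrict a signature to a fatty acid subset and re-close
#'
#' @param sig named signature vector.
#' @param subset character vector of fatty acid labels to keep.
#' @return re-closed signature over `subset`, in `subset` order.
#' @export
restrict_signature <- function(sig, subset) {
  if (is.null(names(sig))) stop("signature must carry fatty acid names")
  missing_fa <- setdiff(subset, names(sig))
  if (length(missing_fa)) {
    stop("fatty acids absent from signature: ",
         paste(missing_fa, collapse = ", "))
  }
  out <- sig[subset]
  if (sum(out) <= 0) stop("zero total mass on requested fatty acid subset")
  out / sum(out)
}

# ---- containers -------------------------------------------------------------

#' Construct a prey library
#'
#' @param signatures named list (one entry per species) of numeric matrices,
#'   specimens in rows, fatty acids in columns; all matrices must share one
#'   column set in one order.
#' @param lipid named numeric vector of per-species lipid fractions in (0, 1]:
#'   the proportion of consumed prey mass that is lipid.
#' @return object of class `prey_library` with elements `species`, `fa`,
#'   `signatures` (rows re-closed to sum 1) and `lipid`.
#' @export
prey_library <- function(signatures, lipid = NULL) {
  if (length(signatures) < 2L) stop("prey library needs at least 2 species")
  species <- names(signatures)
  if (is.null(species) || any(species == "")) {
    stop("signatures list must be named by species")
  }
  fa <- colnames(signatures[[1L]])
  if (is.null(fa)) stop("signature matrices must carry fatty acid colnames")
  fa <- fa_set(fa)
  sigs <- lapply(species, function(k) {
    m <- as.matrix(signatures[[k]])
    if (!identical(colnames(m), fa)) {
      stop("species ", k, " fatty acid columns differ from the library set")
    }
    t(apply(m, 1L, normalize_signature, id = paste0(k, " specimen")))
  })
  names(sigs) <- species
  if (is.null(lipid)) lipid <- stats::setNames(rep(1, length(species)), species)
  if (!all(species %in% names(lipid))) {
    stop("lipid fractions missing for: ",
         paste(setdiff(species, names(lipid)), collapse = ", "))
  }
  lipid <- lipid[species]
  if (any(lipid <= 0 | lipid > 1)) stop("lipid fractions must lie in (0, 1]")
  structure(list(species = species, fa = fa, signatures = sigs,
                 lipid = lipid),
            class = "prey_library")
}

#' @export
print.prey_library <- function(x, ...) {
  cat("Prey library:", length(x$species), "species,",
      length(x$fa), "fatty acids\n")
  n <- vapply(x$signatures, nrow, integer(1))
  for (k in x$species) {
    cat(sprintf("  %-14s n = %3d  lipid = %.2f\n", k, n[[k]], x$lipid[[k]]))
  }
  invisible(x)
}

#' Per-species mean signatures of a prey library
#'
#' Means are taken after zero replacement and optional subset restriction,
#' then re-closed, matching standard QFASA practice of modelling the prey
#' side by species mean signatures.
#'
#' @param lib a [prey_library()].
#' @param fa_subset fatty acid labels to restrict to (default: full set).
#' @param eps zero-replacement constant.
#' @return matrix, species in rows, fatty acids in columns, rows sum to 1.
#' @export
prey_means <- function(lib, fa_subset = NULL, eps = 1e-5) {
  if (is.null(fa_subset)) fa_subset <- lib$fa
  m <- t(vapply(lib$species, function(k) {
    sigs <- replace_zeros(lib$signatures[[k]], eps = eps)
    colnames(sigs) <- lib$fa
    mu <- colMeans(sigs)
    restrict_signature(mu, fa_subset)
  }, numeric(length(fa_subset))))
  colnames(m) <- fa_subset
  m
}

#' Construct a predator set
#'
#' @param info data.frame with columns `id`, `class` (one of AF, AM, SF, SM)
#'   and `year`.
#' @param sig numeric matrix of signatures, one row per predator, fatty acid
#'   columns named.
#' @param year_range optional allowed span of capture years.
#' @return object of class `predator_set` with `info`, `sig`, `fa`.
#' @export
predator_set <- function(info, sig, year_range = NULL) {
  stopifnot(is.data.frame(info), nrow(info) == nrow(sig))
  req <- c("id", "class", "year")
  if (!all(req %in% names(info))) {
    stop("predator info needs columns: ", paste(req, collapse = ", "))
  }
  bad <- !info$class %in% SEX_AGE_CLASSES
  if (any(bad)) {
    stop("unknown sex/age class (rows ", paste(which(bad), collapse = ", "),
         "): ", paste(unique(info$class[bad]), collapse = ", "),
         "; allowed: ", paste(SEX_AGE_CLASSES, collapse = ", "),
         " (dependent young are excluded)")
  }
  if (!is.null(year_range) &&
      any(info$year < min(year_range) | info$year > max(year_range))) {
    stop("capture years outside the configured study span")
  }
  fa <- fa_set(colnames(sig))
  sig <- t(apply(as.matrix(sig), 1L, normalize_signature))
  colnames(sig) <- fa
  rownames(sig) <- info$id
  structure(list(info = info, sig = sig, fa = fa), class = "predator_set")
}

#' @export
print.predator_set <- function(x, ...) {
  cat("Predator set:", nrow(x$sig), "individuals,",
      length(x$fa), "fatty acids; classes:",
      paste(names(table(x$info$class)), table(x$info$class),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

# Rows on the mass-percent scale (sums near 100) are detected by row sums
# exceeding 1.5 and rescaled to proportions.
.rescale_percent <- function(m) {
  rs <- rowSums(m)
  if (any(rs > 1.5)) m <- m / rs
  m
}

.read_delim <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a predator signature table
#'
#' Expects delimited text (comma default, tab accepted) with columns `id`,
#' `class`, `year`, then one column per fatty acid.  Percent-scale rows are
#' rescaled to proportions automatically.
#'
#' @param path file path.
#' @param sep field separator; auto-detected if NULL.
#' @param year_range optional allowed capture year span.
#' @return a [predator_set()].
#' @export
read_predator_table <- function(path, sep = NULL, year_range = NULL) {
  df <- .read_delim(path, sep)
  req <- c("id", "class", "year")
  if (!all(req %in% names(df))) {
    stop("missing required columns in ", path, ": ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  fa_cols <- setdiff(names(df), req)
  if (length(fa_cols) == 0L) stop("no fatty acid columns in ", path)
  m <- as.matrix(df[fa_cols])
  if (!is.numeric(m)) {
    bad <- which(apply(df[fa_cols], 1L, function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop("non-numeric fatty acid entries in ", path, " at data row(s): ",
         paste(bad, collapse = ", "))
  }
  m <- .rescale_percent(m)
  predator_set(df[req], m, year_range = year_range)
}

#' Read a prey signature table plus lipid fractions
#'
#' The prey file carries a `species` column then fatty acid columns; the
#' lipid file is two columns, `species` and `lipid_fraction`.
#'
#' @param path prey signature file.
#' @param lipid_path optional lipid-fraction file; default lipid 1 per species.
#' @param sep separator, auto-detected if NULL.
#' @return a [prey_library()].
#' @export
read_prey_table <- function(path, lipid_path = NULL, sep = NULL) {
  df <- .read_delim(path, sep)
  if (!"species" %in% names(df)) stop("missing 'species' column in ", path)
  fa_cols <- setdiff(names(df), "species")
  m <- .rescale_percent(as.matrix(df[fa_cols]))
  colnames(m) <- fa_cols
  sigs <- lapply(split(seq_len(nrow(m)), df$species),
                 function(i) m[i, , drop = FALSE])
  lipid <- NULL
  if (!is.null(lipid_path)) {
    lf <- .read_delim(lipid_path, sep)
    if (!all(c("species", "lipid_fraction") %in% names(lf))) {
      stop("lipid file needs columns species, lipid_fraction")
    }
    lipid <- stats::setNames(lf$lipid_fraction, lf$species)
  }
  prey_library(sigs, lipid = lipid)
}

#' Read a calibration coefficient table
#'
#' Two columns: `fatty_acid`, `cc`.
#'
#' @param path file path.
#' @param fa optional fatty acid set to align and order against.
#' @inheritParams read_prey_table
#' @return named numeric vector of CCs.
#' @export
read_cc_table <- function(path, fa = NULL, sep = NULL) {
  df <- .read_delim(path, sep)
  if (!all(c("fatty_acid", "cc") %in% names(df))) {
    stop("cc file needs columns fatty_acid, cc")
  }
  cc <- stats::setNames(df$cc, df$fatty_acid)
  if (any(cc <= 0)) stop("calibration coefficients must be > 0")
  if (!is.null(fa)) {
    missing_fa <- setdiff(fa, names(cc))
    if (length(missing_fa)) {
      stop("cc table missing fatty acids: ", paste(missing_fa, collapse = ", "))
    }
    cc <- cc[fa]
  }
  cc
}

#' Read an ice-index table
#'
#' Columns `year`, `ifd50`, `ifd15`, `melt_season`; durations in days.
#'
#' @inheritParams read_cc_table
#' @return data.frame of class `ice_index_table`.
#' @export
read_ice_table <- function(path, sep = NULL) {
  df <- .read_delim(path, sep)
  req <- c("year", "ifd50", "ifd15", "melt_season")
  if (!all(req %in% names(df))) {
    stop("ice table needs columns: ", paste(req, collapse = ", "))
  }
  dur <- as.matrix(df[c("ifd50", "ifd15", "melt_season")])
  if (any(dur < 0 | dur > 366)) stop("ice durations must lie in [0, 366] days")
  class(df) <- c("ice_index_table", "data.frame")
  df
}

#' Write a results table with a provenance header comment
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed,params optional provenance recorded in the `#` header line.
#' @export
write_result_table <- function(df, path, seed = NULL, params = NULL) {
  hdr <- paste0("# fasdiet ",
                as.character(utils::packageVersion("fasdiet")),
                if (!is.null(seed)) paste0(" seed=", seed),
                if (!is.null(params))
                  paste0(" ", paste(names(params), params,
                                    sep = "=", collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
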