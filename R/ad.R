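# Applicability domain via k-nearest-neighbour weighted Euclidean distances:
# cutoff Dc = Dbar + Z*s, retained-subset attribute ranges in original
# units, nominal level sets, and in-domain testing of new samples.

#' Weighted Euclidean distance between two attribute vectors
#'
#' `sqrt(sum(w_j (a_j - b_j)^2))`.
#'
#' @param a,b Numeric vectors of equal length.
#' @param weights Non-negative weights, recycled to the vector length;
#'   default 1 (plain Euclidean).
#' @return A non-negative scalar.
#' @export
weighted_distance <- function(a, b, weights = 1) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length", call. = FALSE)
  }
  w <- rep_len(weights, length(a))
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  sqrt(sum(w * (a - b)^2))
}

#' Mean distance of each sample to its k nearest neighbours
#'
#' Computes all pairwise weighted Euclidean distances in the (normalized)
#' numeric attribute matrix and averages, for every sample, the distances to
#' its `k` nearest neighbours (itself excluded; rank ties broken by sample
#' index).
#'
#' @param x Numeric matrix, one row per sample.
#' @param k Neighbour count, `1 <= k <= nrow(x) - 1`.
#' @param weights Non-negative per-column weights, default uniform.
#' @return Numeric vector of length `nrow(x)`.
#' @export
knn_mean_distances <- function(x, k, weights = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k >= n) {
    stop("`k` must satisfy 1 <= k <= n - 1", call. = FALSE)
  }
  w <- rep_len(weights, ncol(x))
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  d <- as.matrix(stats::dist(sweep(x, 2, sqrt(w), "*")))
  vapply(seq_len(n), function(i) {
    others <- d[i, -i]
    mean(others[order(others)[seq_len(k)]])
  }, numeric(1))
}

#' Distance cutoff defining the applicability domain
#'
#' `Dc = Dbar + Z * s`, where `Dbar` and `s` are the mean and standard
#' deviation of the per-sample distance statistics and `Z` sets the
#' confidence level; `Z = 1.645` corresponds to 95 percent one-tailed
#' confidence.
#'
#' @param dists Non-empty numeric vector of per-sample distances.
#' @param Z Confidence parameter, default 1.645.
#' @return The cutoff `Dc`.
#' @export
distance_cutoff <- function(dists, Z = 1.645) {
  if (length(dists) == 0) stop("`dists` must be non-empty", call. = FALSE)
  s <- if (length(dists) > 1) stats::sd(dists) else 0
  mean(dists) + Z * s
}

#' Build an applicability-domain profile from a training set
#'
#' Z-normalizes the numeric modeling attributes, computes each training
#' sample's mean distance to its `k` nearest neighbours, derives the cutoff
#' `Dc = Dbar + Z*s`, retains the samples whose statistic is at most `Dc`,
#' and reports per-attribute min/max ranges of the retained subset in
#' original units together with the observed level sets of the nominal
#' attributes.
#'
#' @param train Record tibble (a training partition or dataset tier) with
#'   no missing values in the profiled attributes.
#' @param k Neighbour count, default 5.
#' @param Z Confidence parameter, default 1.645 (95 percent one-tailed).
#' @param weights Non-negative per-attribute weights on the normalized
#'   numeric attributes; default uniform.
#' @param numeric_attrs,nominal_attrs Profiled attributes; defaults are the
#'   numeric and nominal modeling attributes.
#' @return An object of class `ad_profile`: `k`, `Z`, `weights`, `D_bar`,
#'   `s`, `D_c`, `distances`, `retained` (logical), `ranges` (tibble of
#'   attribute/min/max in original units), `nominal_domains` (named list of
#'   level sets), `n`.
#' @export
build_ad_profile <- function(train, k = 5, Z = 1.645, weights = 1,
                             numeric_attrs = setdiff(
                               c(model_feature_columns(c("dose", "pchem",
                                                         "qm", "tox"))),
                               tox_nominal_attributes()),
                             nominal_attrs = tox_nominal_attributes()) {
  stopifnot(is.data.frame(train))
  if (nrow(train) < k + 1) {
    stop("need at least k + 1 training samples", call. = FALSE)
  }
  x_raw <- as.matrix(train[numeric_attrs])
  if (anyNA(x_raw)) {
    stop("profiled numeric attributes contain missing values", call. = FALSE)
  }
  stats <- feature_stats(train, numeric_attrs)
  x <- as.matrix(normalize_features(train, stats)[numeric_attrs])
  dists <- knn_mean_distances(x, k, weights)
  d_bar <- mean(dists)
  s <- if (length(dists) > 1) stats::sd(dists) else 0
  d_c <- d_bar + Z * s
  retained <- dists <= d_c
  if (!any(retained)) stop("retained subset is empty", call. = FALSE)
  kept <- x_raw[retained, , drop = FALSE]
  ranges <- tibble::tibble(
    attribute = numeric_attrs,
    min = unname(apply(kept, 2, min)),
    max = unname(apply(kept, 2, max))
  )
  nominal_domains <- purrr::map(
    rlang::set_names(nominal_attrs),
    function(col) sort(unique(train[[col]]))
  )
  structure(
    list(k = k, Z = Z, weights = rep_len(weights, length(numeric_attrs)),
         D_bar = d_bar, s = s, D_c = d_c, distances = dists,
         retained = retained, ranges = ranges,
         nominal_domains = nominal_domains, n = nrow(train)),
    class = "ad_profile"
  )
}

#' @export
print.ad_profile <- function(x, ...) {
  cat(sprintf(
    "Applicability domain: k = %d, Z = %.3f, Dbar = %.4f, s = %.4f, Dc = %.4f\n",
    x$k, x$Z, x$D_bar, x$s, x$D_c))
  cat(sprintf("Retained %d of %d training samples\n", sum(x$retained), x$n))
  print(x$ranges)
  invisible(x)
}

#' Tidy the attribute ranges of an applicability domain
#'
#' @param x An `ad_profile`.
#' @param ... Unused.
#' @return Tibble with `attribute`, `min`, `max` (original units).
#' @export
tidy.ad_profile <- function(x, ...) {
  x$ranges
}

#' One-row summary of an applicability domain
#'
#' @param x An `ad_profile`.
#' @param ... Unused.
#' @return One-row tibble with `k`, `Z`, `D_bar`, `s`, `D_c`, `n_retained`,
#'   `n`.
#' @export
glance.ad_profile <- function(x, ...) {
  tibble::tibble(k = x$k, Z = x$Z, D_bar = x$D_bar, s = x$s, D_c = x$D_c,
                 n_retained = sum(x$retained), n = x$n)
}

#' Test whether samples fall inside an applicability domain
#'
#' A sample is in-domain when every profiled numeric attribute lies within
#' the retained-subset range (bounds inclusive) and every nominal
#' attribute's level was observed in training.
#'
#' @param samples Record tibble; profiled attributes must be present and
#'   non-missing.
#' @param profile An [build_ad_profile()] result.
#' @return Tibble with `record_id`, `in_domain` and a `violations` string
#'   (comma-separated offending attributes, `""` when in-domain).
#' @export
in_domain <- function(samples, profile) {
  stopifnot(inherits(profile, "ad_profile"), is.data.frame(samples))
  num <- profile$ranges$attribute
  missing_cols <- setdiff(c(num, names(profile$nominal_domains)),
                          names(samples))
  if (length(missing_cols) > 0) {
    stop("samples lack profiled attribute(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(samples[c(num, names(profile$nominal_domains))])) {
    stop("profiled attributes contain missing values", call. = FALSE)
  }
  viol <- matrix(FALSE, nrow(samples), 0)
  for (i in seq_along(num)) {
    v <- samples[[num[i]]] < profile$ranges$min[i] |
      samples[[num[i]]] > profile$ranges$max[i]
    viol <- cbind(viol, v)
    colnames(viol)[ncol(viol)] <- num[i]
  }
  for (col in names(profile$nominal_domains)) {
    v <- !samples[[col]] %in% profile$nominal_domains[[col]]
    viol <- cbind(viol, v)
    colnames(viol)[ncol(viol)] <- col
  }
  tibble::tibble(
    record_id = samples$record_id,
    in_domain = rowSums(viol) == 0,
    violations = unname(apply(viol, 1, function(r) {
      paste(colnames(viol)[r], collapse = ",")
    }))
  )
}

#' Serialize an applicability-domain profile to JSON
#'
#' @param profile An `ad_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ad_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ad_profile"))
  obj <- list(
    k = profile$k, Z = profile$Z, weights = profile$weights,
    D_bar = profile$D_bar, s = profile$s, D_c = profile$D_c,
    n = profile$n, n_retained = sum(profile$retained),
    ranges = profile$ranges, nominal_domains = profile$nominal_domains
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
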