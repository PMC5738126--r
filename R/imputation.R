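#' Default feature-to-category map
#'
#' Assigns every feature column to one of the five feature categories
#' (personality, location, call, facebook, person-to-person interactions)
#' by naming convention: trait columns to `personality`, `location_*` /
#' `n_unique*` to `location`, `call_*` / `text_*` to `call`, `facebook_*`
#' to `facebook`, `proximity_*` to `person_to_person`.
#'
#' @param feature_names character vector of feature column names.
#' @return Named character vector feature -> category.
#' @export
feature_categories <- function(feature_names) {
  cat <- ifelse(grepl("^proximity", feature_names), "person_to_person",
         ifelse(grepl("^facebook", feature_names), "facebook",
         ifelse(grepl("^(call|text)", feature_names), "call",
         ifelse(grepl("^(location|n_unique)", feature_names), "location",
                "personality"))))
  setNames(cat, feature_names)
}

#' Drop participants with too many missing feature categories
#'
#' Removes participants whose features are missing in more than two of the
#' five feature categories; a category counts as missing only when *all*
#' its features are missing for that participant.
#'
#' @param table data frame of numeric features, rownames = participant id.
#' @param categories named character vector feature -> category (default:
#'   [feature_categories()] on the column names).
#' @return Filtered feature table.
#' @export
category_filter <- function(table, categories = feature_categories(names(table))) {
  if (!all(names(table) %in% names(categories)))
    stop("every feature needs a category assignment")
  cats <- unique(categories[names(table)])
  cat_missing <- vapply(cats, function(cc) {
    cols <- names(table)[categories[names(table)] == cc]
    apply(is.na(table[, cols, drop = FALSE]), 1, all)
  }, logical(nrow(table)))
  if (is.null(dim(cat_missing)))
    cat_missing <- matrix(cat_missing, nrow = nrow(table))
  n_missing <- rowSums(cat_missing)
  table[n_missing <= 2, , drop = FALSE]
}

#' Overlap distance between two feature vectors
#'
#' The mean absolute difference over the features observed in both vectors
#' (`L_uv = F_u` intersect `F_v`). Vectors with no overlapping observed
#' feature are incomparable, encoded as `Inf`.
#'
#' @param u,v numeric vectors of equal length, `NA` = missing.
#' @return Mean absolute difference over the overlap, or `Inf`.
#' @export
overlap_distance <- function(u, v) {
  ok <- !is.na(u) & !is.na(v)
  if (!any(ok)) return(Inf)
  mean(abs(u[ok] - v[ok]))
}

overlap_distance_matrix <- function(m) {
  n <- nrow(m)
  obs <- !is.na(m)
  m0 <- m; m0[!obs] <- 0
  dsum <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (j in seq_len(ncol(m))) {
    o <- obs[, j]
    dsum[o, o] <- dsum[o, o] + abs(outer(m0[o, j], m0[o, j], "-"))
    cnt[o, o] <- cnt[o, o] + 1L
  }
  d <- ifelse(cnt > 0, dsum / cnt, Inf)
  diag(d) <- Inf  # a participant is never their own neighbour
  d
}

#' Overlap-distance k-nearest-neighbour imputation
#'
#' Features are z-standardized (using observed cells) so heterogeneously
#' scaled indicators contribute comparably to the overlap distance; each
#' participant's k nearest comparable neighbours are found (distance ties
#' at the k-th position broken by ascending participant id, so the result
#' does not depend on row order); each missing cell is filled with the mean
#' of the neighbours' observed values for that feature — copied directly if
#' only one neighbour observes it, and falling back to the cohort mean
#' (with a warning) if none does. Observed cells are never altered, and
#' imputed values are returned on the original feature scale.
#'
#' @param table data frame of numeric features, rownames = participant id,
#'   already passed through [category_filter()].
#' @param k number of neighbours (default 7).
#' @param standardize z-scale features before computing distances.
#' @return Complete feature table; attribute `imputation_log` records every
#'   filled cell (id, feature, value, n_neighbours_used).
#' @export
knn_impute <- function(table, k = 7L, standardize = TRUE) {
  if (length(k) != 1 || is.na(k) || k < 1)
    stop("k must be a positive integer")
  m <- as.matrix(table)
  ord <- order(rownames(m))  # id-ordered for deterministic tie-breaks
  m <- m[ord, , drop = FALSE]
  n <- nrow(m)
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, sd, na.rm = TRUE)
  sdv[is.na(sdv) | sdv == 0] <- 1
  z <- if (standardize) sweep(sweep(m, 2, mu), 2, sdv, "/") else m
  d <- overlap_distance_matrix(z)

  log_id <- character(0); log_feat <- character(0)
  log_val <- numeric(0); log_nn <- integer(0)
  out <- m
  for (i in seq_len(n)) {
    if (!anyNA(m[i, ])) next
    comparable <- which(is.finite(d[i, ]))
    if (length(comparable) < 1)
      stop("participant ", rownames(m)[i],
           " has no comparable neighbour in the cohort")
    nb <- comparable[order(d[i, comparable], rownames(m)[comparable])]
    nb <- nb[seq_len(min(k, length(nb)))]
    for (j in which(is.na(m[i, ]))) {
      vals <- m[nb, j]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) {
        warning("no neighbour observes feature ", colnames(m)[j],
                " for participant ", rownames(m)[i],
                "; falling back to the cohort mean")
        filled <- mu[j]
      } else {
        filled <- mean(vals)
      }
      out[i, j] <- filled
      log_id <- c(log_id, rownames(m)[i])
      log_feat <- c(log_feat, colnames(m)[j])
      log_val <- c(log_val, filled)
      log_nn <- c(log_nn, length(vals))
    }
  }
  res <- as.data.frame(out)[rownames(table), , drop = FALSE]
  attr(res, "imputation_log") <- data.frame(
    id = log_id, feature = log_feat, value = log_val,
    n_neighbours_used = log_nn, stringsAsFactors = FALSE)
  res
}
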