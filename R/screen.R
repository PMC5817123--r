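#' Jaw-width / head-width ratio criterion
#'
#' The simple literature screening rule for cannibal-morph larvae: a
#' specimen is flagged when its jaw width to head width ratio strictly
#' exceeds the threshold (default 0.9). Strict inequality at the boundary,
#' as the rule is printed.
#'
#' @param measurements A validated measurement tibble (see
#'   [read_measurements_csv()]).
#' @param threshold Ratio threshold (default 0.9).
#' @param jaw Which jaw width to use, `"JW1"` (default) or `"JW2"`; the
#'   published rule says only "jaw width".
#' @return Logical vector, one element per specimen.
#' @export
ratio_criterion <- function(measurements, threshold = 0.9, jaw = c("JW1", "JW2")) {
  jaw <- match.arg(jaw)
  for (cl in c(jaw, "HW")) {
    if (!cl %in% names(measurements) || any(!is.finite(measurements[[cl]]))) {
      abort(sprintf("missing or non-finite dimension column: %s", cl))
    }
  }
  if (any(measurements$HW <= 0)) abort("HW must be positive")
  measurements[[jaw]] / measurements$HW > threshold
}

screen_features <- function(measurements) {
  m <- measurements
  cbind(
    as.matrix(m[measurement_dims]),
    jaw_ratio = m$JW1 / m$HW,
    head_body = m$HW / m$SVL
  )
}

#' Screen survivors into cannibals and noncannibals
#'
#' Semi-supervised classification of surviving larvae from their body
#' dimension measurements. Specimens with direct evidence (a conspecific
#' visible in the stomach, or visual identification from an enlarged jaw
#' and large body) seed the cannibal class; all remaining specimens seed
#' the noncannibal class. A diagonal linear discriminant (pooled
#' within-class variance, independent features) on the seven head
#' dimensions, SVL, and the ratios JW1/HW and HW/SVL is then refit while
#' unflagged specimens are relabelled by their posterior probability,
#' until the labels stabilise (at most `max_rounds` rounds). The diagonal
#' form keeps every feature weight aligned with its class-mean difference,
#' so enlarging a cannibal-typical dimension (e.g. the jaw) can never push
#' a specimen towards the noncannibal class — a guarantee a full-covariance
#' discriminant does not give on strongly correlated dimensions. Stomach
#' evidence always forces the cannibal label. With no seed evidence at all
#' the classifier cannot be anchored and the screen falls back to the
#' jaw/head ratio rule.
#'
#' @param measurements Validated measurement tibble with flag columns
#'   `stomach_conspecific` and `visual_cannibal` (>= 5 records).
#' @param max_rounds Maximum self-training rounds (default 20).
#' @return A tibble with columns `specimen_id`, `label` (`"cannibal"` /
#'   `"noncannibal"`), `score` (posterior probability of the cannibal
#'   class, in \[0, 1\] and monotone in the discriminant value), and
#'   `basis` (`"stomach"`, `"visual"`, `"classifier"`, or `"ratio"`).
#' @export
screen_population <- function(measurements, max_rounds = 20) {
  m <- validate_measurements(measurements)
  if (nrow(m) < 5) abort("screening needs at least 5 records")
  feats <- screen_features(m)
  if (all(apply(feats, 2, function(z) length(unique(z)) == 1))) {
    abort("all records identical; screening impossible")
  }
  seeded <- m$stomach_conspecific | m$visual_cannibal
  if (!any(seeded)) {
    ratio <- m$JW1 / m$HW
    lab <- ratio_criterion(m)
    return(tibble::tibble(
      specimen_id = m$specimen_id,
      label = ifelse(lab, "cannibal", "noncannibal"),
      score = stats::plogis(10 * (ratio - 0.9)),
      basis = "ratio"
    ))
  }
  # drop constant columns (lda cannot use them)
  keep <- apply(feats, 2, function(z) stats::sd(z) > 0)
  feats <- feats[, keep, drop = FALSE]
  labels <- ifelse(seeded, "cannibal", "noncannibal")
  post <- ifelse(seeded, 1, 0)
  if (!all(seeded)) {
    for (round in seq_len(max_rounds)) {
      if (length(unique(labels)) < 2) break
      pr <- diag_lda_posterior(feats, labels == "cannibal")
      if (is.null(pr)) break
      new_labels <- ifelse(seeded | pr > 0.5, "cannibal", "noncannibal")
      post <- pr
      if (all(new_labels == labels)) {
        labels <- new_labels
        break
      }
      labels <- new_labels
    }
  }
  tibble::tibble(
    specimen_id = m$specimen_id,
    label = labels,
    score = pmin(pmax(ifelse(m$stomach_conspecific, 1, post), 0), 1),
    basis = dplyr::case_when(
      m$stomach_conspecific ~ "stomach",
      m$visual_cannibal ~ "visual",
      TRUE ~ "classifier"
    )
  )
}


# Diagonal linear discriminant with equal priors: per-feature pooled
# within-class variance, weight (mu_c - mu_n) / s^2, posterior via the
# logistic of the discriminant value. Linear and sign-faithful per feature.
diag_lda_posterior <- function(feats, is_cannibal) {
  if (sum(is_cannibal) < 1 || sum(!is_cannibal) < 1) {
    return(NULL)
  }
  mu_c <- colMeans(feats[is_cannibal, , drop = FALSE])
  mu_n <- colMeans(feats[!is_cannibal, , drop = FALSE])
  dev <- rbind(
    sweep(feats[is_cannibal, , drop = FALSE], 2, mu_c),
    sweep(feats[!is_cannibal, , drop = FALSE], 2, mu_n)
  )
  s2 <- colMeans(dev^2)
  s2 <- pmax(s2, 1e-12 * mean(s2) + 1e-300)
  w <- (mu_c - mu_n) / s2
  z <- sweep(feats, 2, (mu_c + mu_n) / 2) %*% w
  stats::plogis(as.vector(z))
}
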