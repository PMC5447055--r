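#' Split-half reproducibility of the group parcellation
#'
#' Subjects are divided into two random equal groups (odd cohorts give the
#' extra subject to the first half) `n_reps` times; per repetition the
#' maximum probability maps of the two halves are built, their labels
#' aligned by optimal assignment, and Cramer's V, Dice, NMI and VI
#' computed between them.
#'
#' @param parcellations Per-subject relabeled [parcellation()]s (shared
#'   grid and k).
#' @param n_reps Number of random splits (default 100).
#' @param seed Integer seed; replicate r uses a derived substream.
#' @return Tibble with columns `scheme`, `rep`, `index`, `value`.
#' @export
split_half <- function(parcellations, n_reps = 100, seed = 1L) {
  n <- length(parcellations)
  if (n < 4) stop("split-half needs at least 4 subjects", call. = FALSE)
  half_mpm <- function(idx) {
    mpm_parcellation(
      maximum_probability_map(probability_maps(parcellations[idx]))
    )
  }
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    perm <- with_seed(derive_seed(seed, r), sample.int(n))
    h1 <- perm[seq_len(ceiling(n / 2))]
    h2 <- perm[(ceiling(n / 2) + 1):n]
    vals <- compare_parcellations(half_mpm(h1), half_mpm(h2), align = TRUE)
    out[[r]] <- tibble::tibble(
      scheme = "split_half", rep = r, index = vals$index, value = vals$value
    )
  }
  dplyr::bind_rows(out)
}

#' Pairwise reproducibility across subjects
#'
#' The four overlap indices computed directly between the (already
#' relabeled) parcellations of every pair of subjects: n(n-1)/2
#' replicates.
#'
#' @inheritParams split_half
#' @return Tibble with columns `scheme`, `rep`, `index`, `value`.
#' @export
pairwise_indices <- function(parcellations) {
  n <- length(parcellations)
  if (n < 2) stop("pairwise needs at least 2 subjects", call. = FALSE)
  out <- list()
  r <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- r + 1
      vals <- compare_parcellations(
        parcellations[[i]], parcellations[[j]],
        align = FALSE
      )
      out[[r]] <- tibble::tibble(
        scheme = "pairwise", rep = r, index = vals$index, value = vals$value
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Leave-one-out reproducibility
#'
#' Each subject's parcellation is compared with the maximum probability
#' map of the remaining subjects: n replicates.
#'
#' @inheritParams split_half
#' @return Tibble with columns `scheme`, `rep`, `index`, `value`.
#' @export
leave_one_out <- function(parcellations) {
  n <- length(parcellations)
  if (n < 3) stop("leave-one-out needs at least 3 subjects", call. = FALSE)
  out <- vector("list", n)
  for (s in seq_len(n)) {
    rest <- mpm_parcellation(
      maximum_probability_map(probability_maps(parcellations[-s]))
    )
    vals <- compare_parcellations(rest, parcellations[[s]], align = FALSE)
    out[[s]] <- tibble::tibble(
      scheme = "leave_one_out", rep = s, index = vals$index, value = vals$value
    )
  }
  dplyr::bind_rows(out)
}

#' Variation-of-information stability rule over k
#'
#' A solution k is flagged stable when the VI increase from k to k + 1 is
#' considerable (above the mean of the increments by `rule_sd` standard
#' deviations) while the increase from k - 1 to k is not above the mean.
#'
#' @param vi_means Tibble with columns `k` and `mean` (mean VI per k over
#'   a contiguous range of at least 3 values).
#' @param rule_sd Multiplier on the sd of the increments (default 1).
#' @return Tibble with columns `k`, `dvi` (VI(k+1) - VI(k)), `flagged`.
#' @export
stability_profile <- function(vi_means, rule_sd = 1) {
  vi_means <- dplyr::arrange(vi_means, .data$k)
  ks <- vi_means$k
  if (length(ks) < 3 || !all(diff(ks) == 1)) {
    stop("need VI means over a contiguous k range of length >= 3", call. = FALSE)
  }
  v <- vi_means$mean
  dvi <- diff(v)
  mu <- mean(dvi)
  sdv <- stats::sd(dvi)
  hi <- mu + rule_sd * sdv
  flagged <- logical(length(dvi))
  for (i in seq_along(dvi)) {
    big_jump_after <- dvi[i] > hi
    calm_before <- if (i == 1) TRUE else dvi[i - 1] <= mu
    flagged[i] <- big_jump_after && calm_before
  }
  tibble::tibble(k = ks[-length(ks)], dvi = dvi, flagged = flagged)
}

# Local extrema of a series over contiguous k, in the favorable direction.
# Interior points must be >= both neighbors and > at least one (<= / < for
# minima); endpoints must strictly beat their single neighbor.
good_k_extrema <- function(ks, values, direction = c("max", "min")) {
  direction <- match.arg(direction)
  v <- if (direction == "max") values else -values
  n <- length(v)
  if (n == 1) {
    return(ks)
  }
  good <- logical(n)
  for (i in seq_len(n)) {
    if (i == 1) {
      good[i] <- v[1] > v[2]
    } else if (i == n) {
      good[i] <- v[n] > v[n - 1]
    } else {
      good[i] <- v[i] >= v[i - 1] && v[i] >= v[i + 1] &&
        (v[i] > v[i - 1] || v[i] > v[i + 1])
    }
  }
  ks[good]
}

#' Majority-vote suggestion of the number of subregions
#'
#' Each validity-index series over k nominates its "good" solutions: local
#' extrema in the favorable direction (maxima for Cramer's V, Dice, NMI,
#' silhouette, continuity and the hierarchy index; minima for the
#' topological distance) and the stability rule of [stability_profile()]
#' for VI. The suggested k is the mode of all nominations (ties to the
#' smallest k). The suggestion is advisory output; nothing downstream
#' applies it silently.
#'
#' @param report Tibble with columns `index`, `scheme`, `k`, `mean` (as
#'   produced by [compute_validity()]).
#' @param vi_rule_sd Multiplier for the VI stability rule.
#' @return Object of class `k_suggestion`: list with `k` (the suggestion)
#'   and `votes` (tibble of voter and nominated k).
#' @export
suggest_k <- function(report, vi_rule_sd = 1) {
  stopifnot(all(c("index", "scheme", "k", "mean") %in% names(report)))
  maximize <- c("cv", "dice", "nmi", "silhouette", "continuity", "hi")
  votes <- list()
  series <- dplyr::group_split(
    dplyr::group_by(report, .data$index, .data$scheme)
  )
  for (s in series) {
    s <- dplyr::arrange(s, .data$k)
    idx <- s$index[1]
    voter <- paste(idx, s$scheme[1], sep = "/")
    flagged <- if (idx %in% maximize) {
      good_k_extrema(s$k, s$mean, "max")
    } else if (idx == "tpd") {
      good_k_extrema(s$k, s$mean, "min")
    } else if (idx == "vi") {
      if (nrow(s) < 3) {
        integer(0)
      } else {
        sp <- stability_profile(s[, c("k", "mean")], rule_sd = vi_rule_sd)
        sp$k[sp$flagged]
      }
    } else {
      integer(0)
    }
    if (length(flagged) > 0) {
      votes[[voter]] <- tibble::tibble(voter = voter, k = flagged)
    }
  }
  votes <- dplyr::bind_rows(votes)
  if (nrow(votes) == 0) {
    return(structure(list(k = NA_integer_, votes = votes),
      class = "k_suggestion"
    ))
  }
  tab <- table(votes$k)
  best <- as.integer(names(tab)[tab == max(tab)])
  structure(
    list(k = min(best), votes = votes),
    class = "k_suggestion"
  )
}

#' @export
print.k_suggestion <- function(x, ...) {
  cat("<k_suggestion> suggested k =", x$k, "\n")
  if (nrow(x$votes) > 0) {
    tab <- sort(table(x$votes$k), decreasing = TRUE)
    cat(
      "  votes:",
      paste(sprintf("k=%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}
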