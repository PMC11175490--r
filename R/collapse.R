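#' Pair adjacent strata into pseudo-strata
#'
#' Groups strata, taken in stratum-score order, into consecutive pairs
#' `(1,2), (3,4), ...`; when the number of strata is odd the final group
#' takes three. Pairing on the population structure (never on sample values)
#' keeps the collapsed estimator's bias driven only by how well neighbouring
#' true totals match.
#'
#' @param strata A per-stratum tibble with columns `stratum` and `x` (e.g.
#'   from [pop_strata()] or [ht_totals()]), or a vector of stratum labels
#'   already in x-order.
#' @param group_size Target group size; only 2 is supported (the final group
#'   absorbs the leftover stratum when `H` is odd).
#' @return A collapsing plan: tibble with columns `stratum`, `group`.
#' @examples
#' make_pairing(tibble::tibble(stratum = 1:5, x = 1:5 / 5))
#' @export
make_pairing <- function(strata, group_size = 2) {
  if (is.data.frame(strata)) {
    strata <- dplyr::arrange(strata, .data$x, .data$stratum)
    ids <- strata$stratum
  } else {
    ids <- strata
  }
  H <- length(ids)
  if (H < 2) {
    abort("cannot collapse: need at least 2 strata",
          class = "finestrat_cannot_collapse")
  }
  if (group_size != 2) {
    abort("only pair collapsing (group_size = 2) is supported",
          class = "finestrat_config_error")
  }
  group <- (seq_len(H) + 1L) %/% 2L
  if (H %% 2 == 1) group[H] <- group[H - 1L]  # odd H: last group of three
  tibble::tibble(stratum = ids, group = group)
}

#' Collapsing indicator matrix
#'
#' Realises the indicator `c_j(i)`: 1 when strata `i != j` share a
#' pseudo-stratum, 0 otherwise (zero diagonal, symmetric).
#'
#' @param plan A collapsing plan from [make_pairing()].
#' @return An `H x H` 0/1 matrix in plan row order.
#' @export
collapse_matrix <- function(plan) {
  g <- plan$group
  C <- outer(g, g, `==`) * 1
  diag(C) <- 0
  dimnames(C) <- list(as.character(plan$stratum), as.character(plan$stratum))
  C
}

collapse_deviations <- function(t, plan) {
  stopifnot(length(t) == nrow(plan))
  C <- collapse_matrix(plan)
  as.numeric(t - C %*% t)
}

#' Collapsed-stratum variance estimator
#'
#' The classical fine-stratification variance estimator
#' `V_col = 1/2 * sum_i (t_hat_i - sum_j c_j(i) t_hat_j)^2`, which for pure
#' pair collapsing reduces to the sum of squared within-pair differences of
#' the HT stratum totals. It is design-biased upwards by the same quadratic
#' form evaluated at the true totals (see [collapsed_bias_exact()]).
#'
#' @param that Numeric vector of HT stratum totals in plan order (or the
#'   tibble returned by [ht_totals()]).
#' @param plan Collapsing plan from [make_pairing()].
#' @return An [fs_estimate()] with the plan in `diagnostics`.
#' @examples
#' plan <- make_pairing(tibble::tibble(stratum = 1:4, x = 1:4))
#' v_collapsed(c(10, 12, 20, 23), plan)$value  # 13
#' @export
v_collapsed <- function(that, plan) {
  if (is.data.frame(that)) that <- that$that
  dev <- collapse_deviations(that, plan)
  fs_estimate(0.5 * sum(dev^2), "collapsed",
              diagnostics = list(plan = plan))
}

#' Exact design bias of the collapsed-stratum estimator
#'
#' Evaluates `1/2 * sum_i (t_i - sum_j c_j(i) t_j)^2` at the *true* stratum
#' totals: the exact (always nonnegative) design bias of [v_collapsed()]
#' under pure pair collapsing, vanishing when paired strata have equal
#' totals.
#'
#' @param t True stratum totals in plan order.
#' @param plan Collapsing plan.
#' @return Nonnegative scalar.
#' @export
collapsed_bias_exact <- function(t, plan) {
  dev <- collapse_deviations(t, plan)
  0.5 * sum(dev^2)
}

#' Merge single-unit strata into pseudo-strata
#'
#' Resampling needs at least two units per stratum, so every stratum with a
#' single sampled unit is merged with the not-yet-merged stratum having the
#' smallest sample size (ties broken by nearest stratum score, then smallest
#' label). If a lone singleton remains with no unmerged partner it joins the
#' nearest pseudo-stratum. Strata that already hold two or more units and
#' are not needed as partners stay as their own pseudo-stratum.
#'
#' @param sample A `strat_sample` tibble.
#' @return A list with `sample` (the input with a `pseudo` column naming the
#'   pseudo-stratum of each unit), `plan` (tibble `stratum`, `pseudo`, `n`)
#'   and `merges` (log of the merges performed).
#' @export
collapse_singletons <- function(sample) {
  sample <- as_strat_sample(sample)
  if (nrow(sample) < 2) {
    abort("cannot bootstrap: fewer than 2 sampled units in total",
          class = "finestrat_cannot_bootstrap")
  }
  info <- dplyr::summarise(dplyr::group_by(sample, .data$stratum),
                           x = .data$x[1], n = dplyr::n(), .groups = "drop")
  info <- dplyr::arrange(info, .data$x, .data$stratum)
  H <- nrow(info)
  pseudo <- rep(NA_character_, H)
  merged <- rep(FALSE, H)    # TRUE once a stratum has been used in a merge
  merges <- list()
  for (i in seq_len(H)) {
    if (info$n[i] >= 2 || merged[i]) next
    cand <- which(!merged & seq_len(H) != i)
    if (length(cand) == 0) {
      # lone leftover singleton: join the nearest existing pseudo-stratum
      done <- which(merged & seq_len(H) != i)
      j <- done[order(abs(info$x[done] - info$x[i]),
                      as.character(info$stratum[done]))][1]
      pseudo[i] <- pseudo[j]
      merged[i] <- TRUE
      merges[[length(merges) + 1]] <-
        tibble::tibble(singleton = info$stratum[i], partner = info$stratum[j])
      next
    }
    j <- cand[order(info$n[cand], abs(info$x[cand] - info$x[i]),
                    as.character(info$stratum[cand]))][1]
    lab <- paste0(info$stratum[i], "+", info$stratum[j])
    pseudo[c(i, j)] <- lab
    merged[c(i, j)] <- TRUE
    merges[[length(merges) + 1]] <-
      tibble::tibble(singleton = info$stratum[i], partner = info$stratum[j])
  }
  pseudo[is.na(pseudo)] <- as.character(info$stratum[is.na(pseudo)])
  plan <- tibble::tibble(stratum = info$stratum, pseudo = pseudo, n = info$n)
  out <- dplyr::left_join(sample, plan[, c("stratum", "pseudo")],
                          by = "stratum")
  class(out) <- class(sample)
  list(sample = out, plan = plan,
       merges = if (length(merges)) dplyr::bind_rows(merges)
                else tibble::tibble(singleton = character(),
                                    partner = character()))
}
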