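# Small populations and fixtures built in code for the oracle-backed tests.

# H strata on the grid x_i = i/H; `base` is the within-stratum value multiset,
# `shift` a per-stratum location shift. Location shifts leave the stratum
# design variances untouched, so shift-only populations are homoscedastic.
toy_pop <- function(base_list, shifts = rep(0, length(base_list))) {
  H <- length(base_list)
  tibble::tibble(
    stratum = rep(sprintf("S%02d", seq_len(H)), lengths(base_list)),
    x = rep(seq_len(H) / H, lengths(base_list)),
    y = unlist(base_list) + rep(shifts, lengths(base_list))
  ) |> stratified_population()
}

# homoscedastic toy: same base values in every stratum, shifted
toy_pop_const_var <- function(H, base = c(1, 2, 3), shifts = seq_len(H)) {
  toy_pop(rep(list(base), H), shifts)
}

# a census-style sample (every unit, pi = 1)
census_sample <- function(population) {
  strata <- pop_strata(population)
  s <- dplyr::left_join(population, strata[, c("stratum", "N")],
                        by = "stratum")
  s$pi <- 1
  as_strat_sample(s)
}

# synthetic frame shaped like the 1998 mental-health-organisations survey:
# 16 strata, four of them (7, 9, 14, 15) entirely zero-bed so the beds > 0
# filter removes them, leaving 8 analysis strata after the stated merges.
make_smho_fixture <- function(seed = 42) {
  set.seed(seed)
  sizes <- c(30, 25, 20, 12, 10, 8, 15, 9, 14, 7, 6, 5, 6, 10, 8, 18)
  zero_bed <- c(7, 9, 14, 15)
  purrr::map_dfr(1:16, function(st) {
    n <- sizes[st]
    beds <- if (st %in% zero_bed) rep(0, n) else rpois(n, 20 + 5 * st)
    tibble::tibble(stratum = st, beds = beds,
                   exp_total = exp(rnorm(n, 8, 0.5)) * (1 + beds / 50))
  })
}
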