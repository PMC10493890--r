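# Variant pools and phenotypes: the ground-truth state the sort-seq simulator
# evolves and the analysis tries to recover.

#' Hill-type induction response
#'
#' Fractional occupancy `dnt^h / (dnt^h + half_max^h)`; 0 at `dnt = 0`,
#' tending to 1 at saturating inducer.
#'
#' @param dnt Inducer concentration (mg/L), vectorized.
#' @param half_max Half-maximal concentration (mg/L).
#' @param hill Hill coefficient.
#' @return Numeric in [0, 1).
#' @export
hill_response <- function(dnt, half_max, hill) {
  stopifnot(all(dnt >= 0), half_max > 0, hill > 0)
  ifelse(dnt == 0, 0, dnt^hill / (dnt^hill + half_max^hill))
}

#' Construct a variant phenotype
#'
#' The per-variant response model: mean fluorescence at inducer concentration
#' `d` is `basal_signal * (1 + (induction_fold - 1) * hill_response(d))`, so
#' the mean equals `basal_signal` uninduced and approaches
#' `basal_signal * induction_fold` at saturation. Cell-to-cell variability is
#' multiplicative log-normal with `noise_sd_log` on the natural-log scale.
#'
#' @param basal_signal Mean uninduced fluorescence (arbitrary units, > 0).
#' @param induction_fold Saturating fold induction (>= 1).
#' @param half_max_dnt Half-maximal inducer concentration (mg/L, > 0).
#' @param hill_coeff Hill coefficient (> 0).
#' @param noise_sd_log Log-scale SD of multiplicative cell noise (>= 0).
#' @return An object of class `variant_phenotype`.
#' @export
variant_phenotype <- function(basal_signal = 100, induction_fold = 5,
                              half_max_dnt = 10, hill_coeff = 1.5,
                              noise_sd_log = 0.3) {
  stopifnot(basal_signal > 0, induction_fold >= 1, half_max_dnt > 0,
            hill_coeff > 0, noise_sd_log >= 0)
  structure(list(basal_signal = basal_signal,
                 induction_fold = induction_fold,
                 half_max_dnt = half_max_dnt,
                 hill_coeff = hill_coeff,
                 noise_sd_log = noise_sd_log),
            class = "variant_phenotype")
}

#' Mean fluorescence of a phenotype at a given inducer concentration
#'
#' @param phenotype A [variant_phenotype()].
#' @param dnt Inducer concentration (mg/L), vectorized.
#' @return Mean signal in arbitrary units.
#' @export
phenotype_mean_signal <- function(phenotype, dnt) {
  stopifnot(inherits(phenotype, "variant_phenotype"))
  phenotype$basal_signal *
    (1 + (phenotype$induction_fold - 1) *
       hill_response(dnt, phenotype$half_max_dnt, phenotype$hill_coeff))
}

#' Assemble a doped variant pool
#'
#' Draws `n_distinct` distinct variant keys where each diversified position
#' independently carries the template residue with probability `wt_doping`
#' and each of the other `|alphabet| - 1` residues with probability
#' `(1 - wt_doping) / (|alphabet| - 1)` -- the doping scheme used in library
#' synthesis QC, where the wild-type residue is held at an elevated per-site
#' frequency. `n_cells` cells are then distributed over the keys by an
#' equal-probability multinomial, `n_winners` keys are designated true
#' high-performers (induction fold multiplied by `winner_fold_mult`,
#' half-max divided by `winner_half_max_div`), and the remaining keys get the
#' `baseline` phenotype.
#'
#' @param design A [saturation_design()].
#' @param n_distinct Number of distinct variants in the pool.
#' @param n_cells Total cell count, distributed over variants.
#' @param wt_doping Per-position template-residue probability in [0, 1)
#'   (default 0.27, the midpoint of a 25--30% doping window).
#' @param n_winners Number of true high-performer variants (default 0).
#' @param seed RNG seed.
#' @param baseline Baseline [variant_phenotype()].
#' @param winner_fold_mult Multiplier on `induction_fold` for winners
#'   (default 10).
#' @param winner_half_max_div Divisor on `half_max_dnt` for winners
#'   (default 5).
#' @return An object of class `pool_state`: a list with `keys` (character),
#'   `counts` (integer, same order), `phenotypes` (data frame of per-key
#'   response parameters with logical column `winner`), and the `design`.
#' @export
make_pool <- function(design, n_distinct, n_cells, wt_doping = 0.27,
                      n_winners = 0L, seed,
                      baseline = variant_phenotype(),
                      winner_fold_mult = 10, winner_half_max_div = 5) {
  stopifnot(inherits(design, "saturation_design"),
            n_distinct >= 1, n_cells >= 1,
            wt_doping >= 0, wt_doping < 1,
            n_winners >= 0, n_winners <= n_distinct)
  if (n_distinct > library_space_size(design)) {
    stop("`n_distinct` exceeds the library space size")
  }
  k <- length(design$positions)
  wt <- strsplit(template_key(design), "")[[1]]
  others <- lapply(seq_len(k), function(i) setdiff(design$alphabet, wt[i]))
  with_seed(seed, {
    keys <- character(0)
    while (length(keys) < n_distinct) {
      m <- ceiling(1.25 * (n_distinct - length(keys))) + 10L
      slots <- vapply(seq_len(k), function(i) {
        use_wt <- runif(m) < wt_doping
        out <- sample(others[[i]], m, replace = TRUE)
        out[use_wt] <- wt[i]
        out
      }, character(m))
      keys <- unique(c(keys, apply(slots, 1L, paste, collapse = "")))
    }
    keys <- keys[seq_len(n_distinct)]
    counts <- as.integer(rmultinom(1L, n_cells, rep(1, n_distinct)))
    winner <- rep(FALSE, n_distinct)
    if (n_winners > 0L) winner[sample.int(n_distinct, n_winners)] <- TRUE
    phen <- data.frame(
      key = keys,
      basal_signal = rep(baseline$basal_signal, n_distinct),
      induction_fold = ifelse(winner,
                              baseline$induction_fold * winner_fold_mult,
                              baseline$induction_fold),
      half_max_dnt = ifelse(winner,
                            baseline$half_max_dnt / winner_half_max_div,
                            baseline$half_max_dnt),
      hill_coeff = rep(baseline$hill_coeff, n_distinct),
      noise_sd_log = rep(baseline$noise_sd_log, n_distinct),
      winner = winner,
      stringsAsFactors = FALSE
    )
    new_pool_state(keys, counts, phen, design)
  })
}

#' @noRd
new_pool_state <- function(keys, counts, phenotypes, design) {
  stopifnot(length(keys) == length(counts),
            all(counts >= 0), sum(counts) > 0,
            all(keys %in% phenotypes$key))
  structure(list(keys = keys, counts = counts,
                 phenotypes = phenotypes, design = design),
            class = "pool_state")
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf("Variant pool: %s distinct keys, %s cells, %d winner(s)\n",
              format(length(x$keys), big.mark = ","),
              format(sum(x$counts), big.mark = ","),
              sum(x$phenotypes$winner[match(x$keys, x$phenotypes$key)])))
  invisible(x)
}

# Rebuild a pool from a vector of surviving cells' keys, keeping phenotypes.
#' @noRd
pool_from_cells <- function(pool, cell_keys) {
  tab <- table(cell_keys)
  new_pool_state(names(tab), as.integer(tab), pool$phenotypes, pool$design)
}
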