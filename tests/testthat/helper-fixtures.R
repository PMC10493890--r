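# Shared fixtures, built in code.

# A tiny design whose full variant space can be brute-force enumerated.
small_design <- function(alphabet = c("A", "C", "D"),
                         positions = c(2L, 4L),
                         template = "AAAAA") {
  saturation_design(template, positions = positions, alphabet = alphabet)
}

# A codon usage table with exactly one codon per amino acid (forced codons),
# so expected DNA sequences are deterministic.
forced_usage <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  pick <- tapply(names(sense), sense, function(x) sort(x)[1])
  codon_usage(data.frame(codon = unname(pick), aa = names(pick),
                         fraction = 1, stringsAsFactors = FALSE))
}

# Build a pool with explicit per-variant phenotypes (bypasses make_pool's
# winner/baseline dichotomy).
manual_pool <- function(design, keys, counts,
                        basal = 100, fold = 5, half_max = 10,
                        hill = 1.5, noise = 0.3) {
  n <- length(keys)
  phen <- data.frame(
    key = keys,
    basal_signal = rep_len(basal, n),
    induction_fold = rep_len(fold, n),
    half_max_dnt = rep_len(half_max, n),
    hill_coeff = rep_len(hill, n),
    noise_sd_log = rep_len(noise, n),
    winner = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  sortscreen:::new_pool_state(keys, as.integer(counts), phen, design)
}

# Random two-slot toy keys and their tally, for enrichment oracles.
random_toy_keys <- function(n, alphabet = c("A", "C", "D"), seed = 1) {
  withr::with_seed(seed, {
    paste0(sample(alphabet, n, TRUE), sample(alphabet, n, TRUE))
  })
}

table_counts <- function(keys) {
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

# A normalized-scale plate table built directly from a ratio model, for
# hand-worked dose-response arithmetic. `signal_fun(dnt_ug_per_l, time)`.
manual_plate <- function(times, concs_ug, signal_fun, od = 1) {
  grid <- expand.grid(time_min = times, dnt_ug_per_l = concs_ug)
  tibble::tibble(
    time_min = grid$time_min,
    well = sprintf("c%g", grid$dnt_ug_per_l),
    dnt_ug_per_l = grid$dnt_ug_per_l,
    od600 = od,
    signal = mapply(signal_fun, grid$dnt_ug_per_l, grid$time_min),
    replicate = 1L
  )
}
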