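# Gating, sorting selection, MFI and campaign/coverage statistics over
# cytometer event tables.

#' Gate the main cell population by scatter
#'
#' Density gate on (log FSC, log SSC): retains the requested fraction of
#' events with the smallest Mahalanobis distance from the scatter centroid,
#' emulating the routine main-population gate that removes debris and
#' doublets (typically ~77% of events retained). Selection is by genotype-
#' blind scatter only.
#'
#' @param events A `cell_events` table (columns `FSC`, `SSC`, `GFP`).
#' @param fraction Fraction of events to retain, in (0, 1].
#' @return A `gate_result`: list with `selected_indices` (row indices into
#'   `events`, in input order), `fraction_selected`, and `mfi` (mean GFP of
#'   the selected events).
#' @export
gate_main_population <- function(events, fraction) {
  assert_scalar_fraction(fraction, "fraction")
  n <- nrow(events)
  if (is.null(n) || n < 2L) stop("need at least 2 events to gate")
  x <- cbind(log(events$FSC), log(events$SSC))
  S <- cov(x)
  if (!all(is.finite(S)) || det(S) <= .Machine$double.eps) {
    stop("degenerate scatter covariance; cannot gate identical events")
  }
  d2 <- mahalanobis(x, colMeans(x), S)
  k <- max(1L, round(fraction * n))
  sel <- sort(order(d2)[seq_len(k)])
  new_gate_result(sel, n, events$GFP[sel])
}

#' Select a fluorescence fraction of events
#'
#' Rank selection on GFP: the top (or bottom) `round(fraction * n)` events.
#' Ties are broken by stable input order, as a sorter processing events in
#' sequence would.
#'
#' @param events A `cell_events` table.
#' @param fraction Fraction to select, in (0, 1].
#' @param direction `"top"` (positive sorting, highest fluorescence) or
#'   `"bottom"` (negative sorting, lowest fluorescence).
#' @return A `gate_result` (see [gate_main_population()]).
#' @export
select_fluorescence_fraction <- function(events, fraction,
                                         direction = c("top", "bottom")) {
  assert_scalar_fraction(fraction, "fraction")
  direction <- match.arg(direction)
  n <- nrow(events)
  if (is.null(n) || n < 1L) stop("empty event set")
  k <- round(fraction * n)
  if (k < 1L) stop("fraction ", fraction, " selects zero of ", n, " events")
  ord <- order(events$GFP, decreasing = (direction == "top"))
  sel <- sort(ord[seq_len(k)])
  new_gate_result(sel, n, events$GFP[sel])
}

#' @noRd
new_gate_result <- function(selected, n_input, gfp_selected) {
  structure(list(selected_indices = selected,
                 fraction_selected = length(selected) / n_input,
                 mfi = mean(gfp_selected)),
            class = "gate_result")
}

#' Mean fluorescence intensity of an event set
#'
#' @param events A `cell_events` table.
#' @return Arithmetic mean of `GFP`.
#' @export
mfi <- function(events) {
  n <- nrow(events)
  if (is.null(n) || n < 1L) stop("empty event set")
  mean(events$GFP)
}

#' Percent of scanned events collected
#'
#' The sorting-statistics percentage, reported to one decimal place.
#'
#' @param collected Events collected.
#' @param scanned Events scanned (> 0).
#' @return `100 * collected / scanned`, rounded to one decimal.
#' @examples
#' collected_fraction(3680000, 9e7)  # 4.1
#' @export
collected_fraction <- function(collected, scanned) {
  stopifnot(length(collected) == 1L, length(scanned) == 1L)
  if (scanned <= 0) stop("`scanned` must be positive")
  if (collected < 0 || collected > scanned) {
    stop("`collected` must be in [0, scanned]")
  }
  round(100 * collected / scanned, 1)
}

#' Expected library coverage of a sampling campaign
#'
#' Expected fraction of distinct library members observed at least once when
#' `n_draws` cells are drawn uniformly from a library of `library_size`
#' variants, under the Poisson approximation `1 - exp(-n/L)`. Scanning 9e7
#' cells of a 6.4e7-variant library covers ~75% of the space.
#'
#' @param n_draws Number of cells drawn (>= 0).
#' @param library_size Number of distinct variants (> 0).
#' @return Expected covered fraction in [0, 1).
#' @examples
#' expected_coverage(9e7, 6.4e7)  # ~0.755
#' @export
expected_coverage <- function(n_draws, library_size) {
  stopifnot(n_draws >= 0, library_size > 0)
  1 - exp(-n_draws / library_size)
}

#' Specify one sorting round
#'
#' @param dnt_mg_per_l Inducer concentration during the round (mg/L).
#' @param fluor_gate_fraction Fluorescence-gate fraction in (0, 1].
#' @param direction `"top"` (positive selection) or `"bottom"` (negative
#'   selection of minimally fluorescent cells).
#' @param scatter_gate_fraction Main-population scatter-gate fraction
#'   (default 0.77).
#' @return A `sort_round_spec`.
#' @export
sort_round_spec <- function(dnt_mg_per_l, fluor_gate_fraction,
                            direction = c("top", "bottom"),
                            scatter_gate_fraction = 0.77) {
  stopifnot(dnt_mg_per_l >= 0)
  assert_scalar_fraction(fluor_gate_fraction, "fluor_gate_fraction")
  assert_scalar_fraction(scatter_gate_fraction, "scatter_gate_fraction")
  structure(list(dnt_mg_per_l = dnt_mg_per_l,
                 scatter_gate_fraction = scatter_gate_fraction,
                 fluor_gate_fraction = fluor_gate_fraction,
                 direction = match.arg(direction)),
            class = "sort_round_spec")
}

#' The default three-round sorting campaign
#'
#' Two positive rounds under decreasing inducer (15 mg/L top 4.1%, then
#' 9 mg/L top 1.1%) followed by a negative round without inducer collecting
#' the 18.1% least fluorescent cells, which removes constitutively
#' fluorescent false positives.
#'
#' @return List of three [sort_round_spec()]s.
#' @export
default_campaign_rounds <- function() {
  list(sort_round_spec(15, 0.041, "top"),
       sort_round_spec(9, 0.011, "top"),
       sort_round_spec(0, 0.181, "bottom"))
}

#' Run a multi-round sorting campaign
#'
#' For each round: simulate events from the current pool at the round's
#' inducer concentration, apply the scatter gate, then the fluorescence gate
#' in the round's direction, and rebuild the pool from the collected cells.
#' Sorting physically collects cells, so the pool is rebuilt from the
#' collected events' variants; gating itself never reads variant labels.
#'
#' In the statistics table, `events_scanned` counts events inside the
#' main-population scatter gate (the denominator under which the collected
#' percentage equals the configured fluorescence-gate fraction);
#' `events_total` is the raw number of events simulated.
#'
#' @param pool Starting `pool_state`.
#' @param rounds List of [sort_round_spec()]s
#'   (default [default_campaign_rounds()]).
#' @param events_per_round Integer vector, events simulated per round
#'   (recycled if length 1).
#' @param seed RNG seed; per-round seeds are derived from it.
#' @return List with `pool` (final `pool_state`), `stats` (tibble with one
#'   row per round: `round`, `dnt_mg_per_l`, `events_total`,
#'   `events_scanned`, `cells_collected`, `percent_collected`, `mfi`), and
#'   `history` (list of per-round pools).
#' @export
run_campaign <- function(pool, rounds = default_campaign_rounds(),
                         events_per_round, seed) {
  stopifnot(inherits(pool, "pool_state"), length(rounds) >= 1)
  events_per_round <- rep_len(as.integer(events_per_round), length(rounds))
  stats <- vector("list", length(rounds))
  history <- vector("list", length(rounds))
  for (i in seq_along(rounds)) {
    r <- rounds[[i]]
    stopifnot(inherits(r, "sort_round_spec"))
    ev <- simulate_events(pool, r$dnt_mg_per_l, events_per_round[i],
                          seed = derive_seed(seed, i))
    g_sc <- gate_main_population(ev, r$scatter_gate_fraction)
    ev_main <- ev[g_sc$selected_indices, ]
    g_fl <- select_fluorescence_fraction(ev_main, r$fluor_gate_fraction,
                                         r$direction)
    collected <- ev_main[g_fl$selected_indices, ]
    if (nrow(collected) == 0L) {
      stop("round ", i, " collected zero events")
    }
    pool <- pool_from_cells(pool, collected$source_key)
    history[[i]] <- pool
    stats[[i]] <- tibble::tibble(
      round = paste0("R", i),
      dnt_mg_per_l = r$dnt_mg_per_l,
      events_total = events_per_round[i],
      events_scanned = nrow(ev_main),
      cells_collected = nrow(collected),
      percent_collected = collected_fraction(nrow(collected), nrow(ev_main)),
      mfi = g_fl$mfi
    )
  }
  list(pool = pool, stats = dplyr::bind_rows(stats), history = history)
}

#' Write / read cytometer event tables as CSV
#'
#' Columns `FSC`, `SSC`, `GFP` and, if present, `source_key`.
#'
#' @param events A `cell_events` table.
#' @param path CSV path.
#' @return `path` invisibly; `read_events_csv()` returns a `cell_events`
#'   table.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("FSC", "SSC", "GFP") %in% names(ev)))
  class(ev) <- c("cell_events", class(ev))
  ev
}
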