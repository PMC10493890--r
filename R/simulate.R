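# Forward simulation of the sort-seq experiment: cytometer events, amplicon
# reads, and plate-reader kinetics.

#' Simulate cytometer events from a variant pool
#'
#' Each event's source variant is drawn with probability proportional to the
#' pool's cell counts. GFP is log-normal around the variant's Hill-model mean
#' at the given inducer concentration (the log-normal is mean-matched, i.e.
#' `meanlog = log(mean) - sd^2/2`, so the expected GFP equals the model
#' mean). Forward and side scatter are drawn from a correlated bivariate
#' log-normal that is independent of genotype: scatter carries no variant
#' signal, so scatter gating is genotype-neutral.
#'
#' @param pool A `pool_state` from [make_pool()].
#' @param dnt Inducer concentration (mg/L).
#' @param n_events Number of events to draw.
#' @param seed RNG seed.
#' @param scatter_meanlog Length-2 log-scale means for (FSC, SSC).
#' @param scatter_sdlog Log-scale SD of scatter (default 0.25).
#' @param scatter_cor Correlation of log-FSC and log-SSC (default 0.6).
#' @return A `tbl_df` of class `cell_events` with columns `FSC`, `SSC`,
#'   `GFP`, `source_key`. `source_key` is a ground-truth label retained for
#'   validation only; no gating or counting operation reads it.
#' @export
simulate_events <- function(pool, dnt, n_events, seed,
                            scatter_meanlog = log(c(5e4, 3e4)),
                            scatter_sdlog = 0.25, scatter_cor = 0.6) {
  stopifnot(inherits(pool, "pool_state"), dnt >= 0, n_events >= 1)
  phen <- pool$phenotypes[match(pool$keys, pool$phenotypes$key), ]
  mu <- phen$basal_signal *
    (1 + (phen$induction_fold - 1) *
       dnt_occupancy(dnt, phen$half_max_dnt, phen$hill_coeff))
  with_seed(seed, {
    idx <- sample.int(length(pool$keys), n_events, replace = TRUE,
                      prob = pool$counts)
    sd <- phen$noise_sd_log[idx]
    gfp <- rlnorm(n_events, meanlog = log(mu[idx]) - sd^2 / 2, sdlog = sd)
    z1 <- rnorm(n_events)
    z2 <- scatter_cor * z1 + sqrt(1 - scatter_cor^2) * rnorm(n_events)
    ev <- tibble::tibble(
      FSC = exp(scatter_meanlog[1] + scatter_sdlog * z1),
      SSC = exp(scatter_meanlog[2] + scatter_sdlog * z2),
      GFP = gfp,
      source_key = pool$keys[idx]
    )
    class(ev) <- c("cell_events", class(ev))
    ev
  })
}

# Vectorized Hill occupancy over per-variant parameters.
#' @noRd
dnt_occupancy <- function(dnt, half_max, hill) {
  if (dnt == 0) return(rep(0, length(half_max)))
  dnt^hill / (dnt^hill + half_max^hill)
}

#' Simulate amplicon reads from a variant pool
#'
#' Each read originates from a variant drawn proportional to pool counts. The
#' read is the reference gene with the codons at the diversified positions
#' replaced by a codon for the variant's residue (sampled from the usage
#' table), then corrupted by i.i.d. substitution errors at `per_base_error`.
#' Indels are out of scope of this error model. Reads are returned as a
#' [Biostrings::DNAStringSet]; write them out with [write_reads_fastq()].
#'
#' @param pool A `pool_state`.
#' @param design The pool's [saturation_design()].
#' @param reference_dna Reference nucleotide string; must translate to the
#'   design's template protein.
#' @param n_reads Number of reads.
#' @param per_base_error Per-base substitution probability in [0, 1).
#' @param seed RNG seed.
#' @param usage Codon usage table for the diversified codons.
#' @return A named `DNAStringSet`; `S4Vectors::mcols(reads)$source_key`
#'   carries the ground-truth key of each read (validation only).
#' @export
simulate_amplicon_reads <- function(pool, design, reference_dna, n_reads,
                                    per_base_error = 0, seed,
                                    usage = ecoli_codon_usage()) {
  stopifnot(inherits(pool, "pool_state"),
            inherits(design, "saturation_design"),
            n_reads >= 1, per_base_error >= 0, per_base_error < 1)
  if (translate_dna(reference_dna) != design$template_protein) {
    stop("`reference_dna` does not translate to the design template protein")
  }
  L <- nchar(reference_dna)
  ref_chars <- strsplit(reference_dna, "")[[1]]
  codon_starts <- (design$positions - 1L) * 3L + 1L
  by_aa <- split(usage, usage$aa)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    key_idx <- sample.int(length(pool$keys), n_reads, replace = TRUE,
                          prob = pool$counts)
    keys <- pool$keys[key_idx]
    key_mat <- do.call(rbind, strsplit(keys, ""))
    # sample replacement codons for every (read, slot) in bulk
    codon_mat <- matrix("", nrow = n_reads, ncol = length(codon_starts))
    for (j in seq_along(codon_starts)) {
      res <- key_mat[, j]
      for (aa in unique(res)) {
        tab <- by_aa[[aa]]
        if (is.null(tab)) stop("no codon for residue ", aa, " in usage table")
        sel <- res == aa
        codon_mat[sel, j] <- sample(tab$codon, sum(sel), replace = TRUE,
                                    prob = tab$fraction)
      }
    }
    n_err <- rbinom(n_reads, L, per_base_error)
    out <- character(n_reads)
    for (i in seq_len(n_reads)) {
      rd <- ref_chars
      for (j in seq_along(codon_starts)) {
        s <- codon_starts[j]
        rd[s:(s + 2L)] <- strsplit(codon_mat[i, j], "")[[1]]
      }
      k <- n_err[i]
      if (k > 0L) {
        pos <- sample.int(L, k)
        # substitution to a uniformly random *different* base
        cur <- rd[pos]
        sub <- bases[(match(cur, bases) - 1L + sample.int(3L, k, replace = TRUE)) %% 4L + 1L]
        rd[pos] <- sub
      }
      out[i] <- paste(rd, collapse = "")
    }
    reads <- Biostrings::DNAStringSet(out)
    names(reads) <- sprintf("read_%06d", seq_len(n_reads))
    S4Vectors::mcols(reads)$source_key <- keys
    reads
  })
}

#' Write / read amplicon reads as FASTQ
#'
#' Reads are written with a flat quality string (Phred 40, "I"), matching the
#' simulator's quality-free substitution error model.
#'
#' @param reads A `DNAStringSet`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(methods::is(reads, "DNAStringSet"))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Simulate plate-reader kinetics for one variant
#'
#' Emulates a 96-well induction assay read at fixed intervals. Optical
#' density follows logistic growth from `od0` towards `od_max`. Per-cell
#' reporter fluorescence is the sum of a basal component accumulating with
#' time constant `tau_basal_min` and an induced component
#' `basal * (induction_fold - 1) * hill(dnt)` that starts only after
#' `lag_induced_min` minutes and accumulates more slowly
#' (`tau_induced_min`), reflecting inducer uptake, transcription and
#' reporter maturation. The recorded raw signal is
#' `od600 * per_cell * exp(noise)` with mean-matched log-normal noise. A
#' DNT-free control series is always included, so downstream normalization
#' and induction ratios are computable; with this model the
#' background-subtracted induction ratio rises monotonically towards
#' `1 + (induction_fold - 1) * hill(dnt)`.
#'
#' @param phenotype A [variant_phenotype()].
#' @param dnt_concs Inducer concentrations in mg/L (0 is added if absent).
#' @param duration_min Total observation time (default 720 min).
#' @param interval_min Sampling interval; must divide `duration_min`
#'   (default 20 min).
#' @param seed RNG seed.
#' @param n_replicates Wells per concentration (default 2, internal
#'   duplicates).
#' @param od0,od_max,growth_rate Logistic growth parameters (default 0.05,
#'   1.0, 0.01 per min).
#' @param tau_basal_min,tau_induced_min Accumulation time constants of the
#'   basal and induced reporter components (default 120 and 240 min).
#' @param lag_induced_min Delay before the induced component starts
#'   accumulating (default 40 min).
#' @return A `tbl_df` of class `plate_timeseries` with columns `time_min`,
#'   `well`, `dnt_ug_per_l`, `od600`, `signal`, `replicate`.
#' @export
simulate_plate_timeseries <- function(phenotype, dnt_concs,
                                      duration_min = 720, interval_min = 20,
                                      seed = 1L, n_replicates = 2L,
                                      od0 = 0.05, od_max = 1.0,
                                      growth_rate = 0.01,
                                      tau_basal_min = 120,
                                      tau_induced_min = 240,
                                      lag_induced_min = 40) {
  stopifnot(inherits(phenotype, "variant_phenotype"),
            duration_min > 0, interval_min > 0)
  if (duration_min %% interval_min != 0) {
    stop("`interval_min` must divide `duration_min`")
  }
  dnt_concs <- sort(unique(c(0, dnt_concs)))
  times <- seq(0, duration_min, by = interval_min)
  grid <- expand.grid(time_min = times,
                      replicate = seq_len(n_replicates),
                      dnt_mg_per_l = dnt_concs)
  od <- od0 * od_max / (od0 + (od_max - od0) * exp(-growth_rate * grid$time_min))
  h <- hill_response(grid$dnt_mg_per_l, phenotype$half_max_dnt,
                     phenotype$hill_coeff)
  t_ind <- pmax(0, grid$time_min - lag_induced_min)
  per_cell <- phenotype$basal_signal *
    ((1 - exp(-grid$time_min / tau_basal_min)) +
       (phenotype$induction_fold - 1) * h *
       (1 - exp(-t_ind / tau_induced_min)))
  sdl <- phenotype$noise_sd_log
  with_seed(seed, {
    noise <- if (sdl > 0) {
      exp(rnorm(nrow(grid), -sdl^2 / 2, sdl))
    } else {
      rep(1, nrow(grid))
    }
    ts <- tibble::tibble(
      time_min = grid$time_min,
      well = sprintf("c%g_r%d", grid$dnt_mg_per_l, grid$replicate),
      dnt_ug_per_l = grid$dnt_mg_per_l * 1000,
      od600 = od,
      signal = od * per_cell * noise,
      replicate = grid$replicate
    )
    class(ts) <- c("plate_timeseries", class(ts))
    ts
  })
}
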