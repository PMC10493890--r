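# Codon-level sequence work: usage tables, codon-sampled gene synthesis under
# a sliding-window GC cap, and GC window scans.

#' Translate a DNA string to protein
#'
#' Thin wrapper over [Biostrings::translate()] returning a plain string.
#'
#' @param dna Nucleotide string (length a multiple of 3).
#' @return Amino-acid string ("*" for stop codons).
#' @export
translate_dna <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) %% 3L != 0L) stop("DNA length must be a multiple of 3")
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

#' Load a codon usage table
#'
#' Reads a TSV with columns `codon`, `aa`, `fraction` where `fraction` is the
#' relative frequency of the codon *within its amino acid's codon set*. Stop
#' codons are dropped. Frequencies are renormalized per amino acid on load; a
#' warning is raised if any amino acid's input fractions deviate from 1 by
#' more than `tolerance`.
#'
#' @param path Path to the TSV file.
#' @param tolerance Allowed deviation of per-amino-acid sums from 1 before
#'   warning (default 1e-6).
#' @return A `codon_usage` data frame with columns `codon`, `aa`, `fraction`.
#' @seealso [ecoli_codon_usage()] for the bundled E. coli table.
#' @export
load_codon_usage <- function(path, tolerance = 1e-6) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("codon", "aa", "fraction")
  if (!all(req %in% names(df))) {
    stop("codon usage table must have columns: ", paste(req, collapse = ", "))
  }
  codon_usage(df[req], tolerance = tolerance)
}

#' @rdname load_codon_usage
#' @param df Data frame with columns `codon`, `aa`, `fraction`.
#' @export
codon_usage <- function(df, tolerance = 1e-6) {
  df$codon <- toupper(df$codon)
  if (any(nchar(df$codon) != 3L) || anyDuplicated(df$codon)) {
    stop("codons must be distinct 3-nt strings")
  }
  stops <- df$aa %in% "*" | df$codon %in% c("TAA", "TAG", "TGA")
  if (any(stops)) df <- df[!stops, , drop = FALSE]
  if (any(df$fraction < 0)) stop("codon fractions must be non-negative")
  sums <- tapply(df$fraction, df$aa, sum)
  off <- abs(sums - 1) > tolerance
  if (any(off)) {
    warning("codon fractions renormalized; per-amino-acid sums deviated from 1 for: ",
            paste(names(sums)[off], collapse = ", "))
  }
  df$fraction <- df$fraction / as.vector(sums[df$aa])
  rownames(df) <- NULL
  class(df) <- c("codon_usage", "data.frame")
  df
}

#' Bundled E. coli K-12 codon usage table
#'
#' Within-amino-acid relative codon frequencies for all 61 sense codons,
#' derived from the standard E. coli K-12 per-thousand usage compilation.
#'
#' @return A `codon_usage` data frame (61 rows).
#' @export
ecoli_codon_usage <- function() {
  load_codon_usage(system.file("extdata", "ecoli_codon_usage.tsv",
                               package = "sortscreen", mustWork = TRUE))
}

#' GC fraction of sliding windows
#'
#' @param dna Nucleotide string.
#' @param window_nt Window length in nucleotides (default 100).
#' @param step Step between window starts (default 1).
#' @return Numeric vector of GC fractions, one per window, in order.
#' @examples
#' gc_windows("GCAT", window_nt = 2, step = 1)  # 1.0 0.5 0.0
#' @export
gc_windows <- function(dna, window_nt = 100L, step = 1L) {
  stopifnot(is.character(dna), length(dna) == 1L)
  n <- nchar(dna)
  if (n == 0L) stop("empty sequence")
  window_nt <- as.integer(window_nt)
  step <- as.integer(step)
  if (window_nt < 1L || window_nt > n) {
    stop("`window_nt` must be in [1, sequence length]")
  }
  is_gc <- strsplit(chartr("acgt", "ACGT", dna), "")[[1]] %in% c("G", "C")
  cs <- c(0, cumsum(is_gc))
  starts <- seq.int(1L, n - window_nt + 1L, by = step)
  (cs[starts + window_nt] - cs[starts]) / window_nt
}

#' Synthesize a codon-sampled gene for a protein
#'
#' Draws one codon per residue, independently, with the codon's relative
#' frequency within its amino acid's codon set -- i.e. the synthesized gene
#' mirrors the organism's transcriptome-wide codon composition. Optionally
#' enforces a sliding-window GC cap: any window exceeding `gc_cap` has the
#' codons it overlaps resampled, up to `max_retries` times, mimicking the
#' removal of long high-GC stretches that defeat gene synthesis.
#'
#' @param protein Amino-acid string (no stops).
#' @param usage A `codon_usage` table (default [ecoli_codon_usage()]).
#' @param seed RNG seed; the result is a deterministic function of
#'   (protein, usage, seed, gc_cap, window_nt).
#' @param gc_cap Optional maximum GC fraction allowed in any window
#'   (e.g. 0.70); `NULL` disables the constraint.
#' @param window_nt GC window length in nucleotides (default 100).
#' @param max_retries Maximum number of window resampling rounds before the
#'   constraint is declared unsatisfiable (default 10000).
#' @return Nucleotide string of length `3 * nchar(protein)` translating back
#'   to `protein`.
#' @examples
#' dna <- sample_codon_dna("MKV", seed = 1)
#' translate_dna(dna)
#' @export
sample_codon_dna <- function(protein, usage = ecoli_codon_usage(), seed,
                             gc_cap = NULL, window_nt = 100L,
                             max_retries = 10000L) {
  stopifnot(is.character(protein), length(protein) == 1L, nchar(protein) > 0L,
            inherits(usage, "codon_usage"))
  residues <- strsplit(protein, "")[[1]]
  missing <- setdiff(residues, usage$aa)
  if (length(missing)) {
    stop("no codon in the usage table for residue(s): ",
         paste(missing, collapse = ", "))
  }
  by_aa <- split(usage, usage$aa)
  draw <- function(aa, n) {
    tab <- by_aa[[aa]]
    sample(tab$codon, n, replace = TRUE, prob = tab$fraction)
  }
  if (!is.null(gc_cap)) assert_scalar_fraction(gc_cap, "gc_cap")
  with_seed(seed, {
    codons <- character(length(residues))
    for (aa in unique(residues)) {
      idx <- which(residues == aa)
      codons[idx] <- draw(aa, length(idx))
    }
    if (!is.null(gc_cap)) {
      w <- min(as.integer(window_nt), 3L * length(residues))
      tries <- 0L
      repeat {
        gc <- gc_windows(paste(codons, collapse = ""), w, step = 1L)
        bad <- which(gc > gc_cap)
        if (!length(bad)) break
        if (tries >= max_retries) {
          stop("GC cap of ", gc_cap, " unsatisfiable within ", max_retries,
               " resampling rounds")
        }
        tries <- tries + 1L
        # resample every codon overlapping the first offending window
        s <- bad[1L]
        res_idx <- unique((seq.int(s, s + w - 1L) - 1L) %/% 3L + 1L)
        for (aa in unique(residues[res_idx])) {
          idx <- res_idx[residues[res_idx] == aa]
          codons[idx] <- draw(aa, length(idx))
        }
      }
    }
    paste(codons, collapse = "")
  })
}
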