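# Decoding variant keys from amplicon reads and computing per-variant and
# per-position enrichment statistics across sorting rounds.

#' Decode the variant key of a single amplicon read
#'
#' Compares the read to the reference gene and extracts the codons at the
#' design's diversified positions. Reads whose length equals the reference
#' are decoded by direct positional comparison (the substitution-only fast
#' path); length-discordant reads are globally aligned
#' ([Biostrings::pairwiseAlignment()], affine gaps) and decoded through the
#' alignment. A read is rejected when any diversified codon is disrupted by
#' an indel, ambiguity or stop codon, or when it carries more than
#' `max_mismatch_outside` mismatches outside the diversified codons. If the
#' forward comparison fails the mismatch rule, the reverse complement is
#' tried before rejecting.
#'
#' @param read Nucleotide string (or `DNAString`).
#' @param design A [saturation_design()].
#' @param reference_dna Reference gene; must translate to the design
#'   template.
#' @param max_mismatch_outside Maximum tolerated mismatches outside the
#'   diversified codons (default 30).
#' @return The decoded variant key (string), or `NA_character_` with
#'   attribute `"reason"` when rejected.
#' @export
decode_read <- function(read, design, reference_dna,
                        max_mismatch_outside = 30L) {
  read <- as.character(read)
  stopifnot(length(read) == 1L)
  res <- decode_read_set(Biostrings::DNAStringSet(read), design,
                         reference_dna, max_mismatch_outside)
  key <- res$key[1L]
  if (is.na(key)) attr(key, "reason") <- res$reason[1L]
  key
}

# Vectorized decoder over a DNAStringSet. Returns data.frame(key, reason).
#' @noRd
decode_read_set <- function(reads, design, reference_dna,
                            max_mismatch_outside = 30L) {
  stopifnot(inherits(design, "saturation_design"))
  if (translate_dna(reference_dna) != design$template_protein) {
    stop("`reference_dna` does not translate to the design template protein")
  }
  L <- nchar(reference_dna)
  rd_chr <- as.character(reads)
  wd <- nchar(rd_chr)
  key <- rep(NA_character_, length(reads))
  reason <- rep(NA_character_, length(reads))

  eq <- which(wd == L)
  if (length(eq)) {
    r <- decode_equal_length(rd_chr[eq], design, reference_dna,
                             max_mismatch_outside)
    # retry mismatch-failures as reverse complements
    retry <- which(r$reason %in% "mismatch_outside")
    if (length(retry)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(rd_chr[eq][retry])))
      r2 <- decode_equal_length(rc, design, reference_dna,
                                max_mismatch_outside)
      ok <- !is.na(r2$key)
      r$key[retry[ok]] <- r2$key[ok]
      r$reason[retry[ok]] <- NA_character_
    }
    key[eq] <- r$key
    reason[eq] <- r$reason
  }
  ne <- which(wd != L)
  for (i in ne) {
    r <- decode_read_aligned(rd_chr[i], design, reference_dna,
                             max_mismatch_outside)
    key[i] <- r$key
    reason[i] <- r$reason
  }
  data.frame(key = key, reason = reason, stringsAsFactors = FALSE)
}

# Fast path: reads with reference length, substitution errors only.
# Mismatches are counted by chunked byte comparison against the reference.
#' @noRd
decode_equal_length <- function(rd_chr, design, reference_dna,
                                max_mismatch_outside) {
  n <- length(rd_chr)
  L <- nchar(reference_dna)
  starts <- (design$positions - 1L) * 3L + 1L
  div_mask <- rep(FALSE, L)
  for (s in starts) div_mask[s:(s + 2L)] <- TRUE
  ref_raw <- charToRaw(reference_dna)
  outside_mm <- integer(n)
  chunk <- 20000L
  for (lo in seq.int(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    m <- matrix(charToRaw(paste(rd_chr[lo:hi], collapse = "")), nrow = L)
    mm <- m != ref_raw            # ref recycled down columns
    mm[div_mask, ] <- FALSE
    outside_mm[lo:hi] <- colSums(mm)
  }
  # decode the six codons by position
  aa_mat <- matrix(NA_character_, nrow = n, ncol = length(starts))
  for (j in seq_along(starts)) {
    codon <- substring(rd_chr, starts[j], starts[j] + 2L)
    aa_mat[, j] <- unname(Biostrings::GENETIC_CODE[codon])
  }
  bad_codon <- apply(aa_mat, 1L, function(a) anyNA(a) || any(a == "*"))
  key <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  ok <- !bad_codon & outside_mm <= max_mismatch_outside
  if (any(ok)) {
    key[ok] <- do.call(paste0, asplit(aa_mat[ok, , drop = FALSE], 2L))
  }
  reason[bad_codon] <- "bad_codon"
  reason[!bad_codon & !ok] <- "mismatch_outside"
  list(key = key, reason = reason)
}

# Slow path: global affine-gap alignment for length-discordant reads.
#' @noRd
decode_read_aligned <- function(read, design, reference_dna,
                                max_mismatch_outside) {
  align_once <- function(rd) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(rd), Biostrings::DNAString(reference_dna),
      type = "global", gapOpening = 10, gapExtension = 4)
  }
  pa <- align_once(read)
  if (Biostrings::pid(pa) < 60) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(read)))
    pa_rc <- align_once(rc)
    if (S4Vectors::score(pa_rc) > S4Vectors::score(pa)) pa <- pa_rc
  }
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  L <- nchar(reference_dna)
  starts <- (design$positions - 1L) * 3L + 1L
  div_mask <- rep(FALSE, L)
  for (s in starts) div_mask[s:(s + 2L)] <- TRUE

  read_at <- rep(NA_character_, L)   # read base aligned to each ref position
  ref_pos <- 0L
  edits_outside <- 0L
  for (i in seq_along(sub)) {
    if (sub[i] == "-") {
      # insertion in the read, between ref_pos and ref_pos + 1
      inside <- (ref_pos >= 1L && div_mask[ref_pos]) ||
        (ref_pos < L && div_mask[ref_pos + 1L])
      if (inside) {
        return(list(key = NA_character_, reason = "indel_in_codon"))
      }
      edits_outside <- edits_outside + 1L
    } else {
      ref_pos <- ref_pos + 1L
      if (pat[i] == "-") {
        if (div_mask[ref_pos]) {
          return(list(key = NA_character_, reason = "indel_in_codon"))
        }
        edits_outside <- edits_outside + 1L
      } else {
        read_at[ref_pos] <- pat[i]
        if (!div_mask[ref_pos] && pat[i] != sub[i]) {
          edits_outside <- edits_outside + 1L
        }
      }
    }
  }
  if (edits_outside > max_mismatch_outside) {
    return(list(key = NA_character_, reason = "mismatch_outside"))
  }
  aa <- character(length(starts))
  for (j in seq_along(starts)) {
    codon <- read_at[starts[j]:(starts[j] + 2L)]
    if (anyNA(codon)) return(list(key = NA_character_, reason = "indel_in_codon"))
    a <- unname(Biostrings::GENETIC_CODE[paste(codon, collapse = "")])
    if (is.na(a) || a == "*") {
      return(list(key = NA_character_, reason = "bad_codon"))
    }
    aa[j] <- a
  }
  list(key = paste(aa, collapse = ""), reason = NA_character_)
}

#' Tally variant keys across a read set
#'
#' Decodes every read (see [decode_read()]) and counts the recovered keys.
#' Rejected reads are counted, never silently dropped:
#' `sum(counts) + n_reads_rejected == n_reads_total`.
#'
#' @param reads A `DNAStringSet` (e.g. from [simulate_amplicon_reads()] or
#'   [read_reads_fastq()]).
#' @param design A [saturation_design()].
#' @param reference_dna Reference gene string.
#' @param round_label Label for the sequenced pool (e.g. `"R0"`, `"R3"`).
#' @param max_mismatch_outside Passed to the decoder.
#' @return A `variant_counts` object: list with `round_label`, `counts`
#'   (named integer vector, decreasing), `n_reads_total`, `n_reads_rejected`.
#' @export
count_variants <- function(reads, design, reference_dna, round_label = "R?",
                           max_mismatch_outside = 30L) {
  if (length(reads) == 0L) stop("empty read set")
  dec <- decode_read_set(reads, design, reference_dna, max_mismatch_outside)
  keys <- dec$key[!is.na(dec$key)]
  if (!length(keys)) {
    warning("all ", length(reads), " reads were rejected")
    counts <- integer(0)
  } else {
    tab <- table(keys)
    counts <- setNames(as.integer(tab), names(tab))
    counts <- sort(counts, decreasing = TRUE)
  }
  structure(list(round_label = round_label,
                 counts = counts,
                 n_reads_total = length(reads),
                 n_reads_rejected = sum(is.na(dec$key))),
            class = "variant_counts")
}

#' Build variant counts directly from a key tally
#'
#' For oracle tests and for counting a pool without sequencing noise.
#'
#' @param counts Named non-negative integer vector (names = variant keys).
#' @param round_label Pool label.
#' @param n_rejected Rejected-read count (default 0).
#' @return A `variant_counts`.
#' @export
variant_counts <- function(counts, round_label = "R?", n_rejected = 0L) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  structure(list(round_label = round_label,
                 counts = setNames(as.integer(counts), names(counts)),
                 n_reads_total = sum(counts) + n_rejected,
                 n_reads_rejected = as.integer(n_rejected)),
            class = "variant_counts")
}

#' @export
print.variant_counts <- function(x, ...) {
  cat(sprintf("Variant counts [%s]: %s keys, %s reads (%s rejected)\n",
              x$round_label, format(length(x$counts), big.mark = ","),
              format(x$n_reads_total, big.mark = ","),
              format(x$n_reads_rejected, big.mark = ",")))
  invisible(x)
}

#' Per-variant log2 enrichment between two sequenced pools
#'
#' For each key observed in either pool, computes pseudocounted frequencies
#' `(count + p) / (total + p * K)` (K = number of keys observed in either
#' pool) and the log2 ratio of post- to pre-sorting frequency. Keys absent
#' from one pool are treated as count 0; the pseudocount keeps every ratio
#' finite.
#'
#' @param pre,post `variant_counts` for the pre- and post-sorting pools.
#' @param pseudocount Pseudocount `p > 0` (default 1 read per key per pool).
#' @return An `enrichment_table` tibble with columns `key`, `pre_count`,
#'   `post_count`, `pre_freq`, `post_freq`, `log2_enrichment`, sorted by
#'   decreasing enrichment; attribute `pseudocount`.
#' @export
variant_enrichment <- function(pre, post, pseudocount = 1) {
  stopifnot(inherits(pre, "variant_counts"), inherits(post, "variant_counts"))
  if (pseudocount <= 0) stop("`pseudocount` must be > 0")
  keys <- union(names(pre$counts), names(post$counts))
  if (!length(keys)) stop("no keys observed in either pool")
  K <- length(keys)
  cpre <- ifelse(is.na(pre$counts[keys]), 0L, pre$counts[keys])
  cpost <- ifelse(is.na(post$counts[keys]), 0L, post$counts[keys])
  tot_pre <- sum(pre$counts)
  tot_post <- sum(post$counts)
  f_pre <- (cpre + pseudocount) / (tot_pre + pseudocount * K)
  f_post <- (cpost + pseudocount) / (tot_post + pseudocount * K)
  out <- tibble::tibble(
    key = keys,
    pre_count = as.integer(cpre),
    post_count = as.integer(cpost),
    pre_freq = unname(f_pre),
    post_freq = unname(f_post),
    log2_enrichment = unname(log2(f_post / f_pre))
  )
  out <- out[order(-out$log2_enrichment), ]
  attr(out, "pseudocount") <- pseudocount
  attr(out, "rounds") <- c(pre = pre$round_label, post = post$round_label)
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Per-position, per-residue log2 enrichment matrix
#'
#' Marginalizes the key counts of each pool to (diversified slot, residue)
#' counts, then computes the log2 ratio of pseudocounted post- to
#' pre-sorting marginal frequencies -- the position x mutation enrichment
#' heat map of a sort-seq screen.
#'
#' @param pre,post `variant_counts`.
#' @param design The [saturation_design()] (supplies slot count and
#'   alphabet).
#' @param pseudocount Pseudocount per (slot, residue) cell (default 1).
#' @return A numeric matrix (`position_enrichment` class), rows = diversified
#'   positions, columns = alphabet.
#' @export
position_enrichment <- function(pre, post, design, pseudocount = 1) {
  stopifnot(inherits(pre, "variant_counts"),
            inherits(post, "variant_counts"),
            inherits(design, "saturation_design"))
  if (pseudocount <= 0) stop("`pseudocount` must be > 0")
  A <- design$alphabet
  k <- length(design$positions)
  marg <- function(vc) {
    m <- matrix(0, nrow = k, ncol = length(A),
                dimnames = list(as.character(design$positions), A))
    if (length(vc$counts)) {
      km <- do.call(rbind, strsplit(names(vc$counts), ""))
      for (j in seq_len(k)) {
        s <- tapply(vc$counts, km[, j], sum)
        m[j, names(s)] <- s
      }
    }
    m
  }
  mpre <- marg(pre)
  mpost <- marg(post)
  fpre <- (mpre + pseudocount) / (sum(pre$counts) + pseudocount * length(A))
  fpost <- (mpost + pseudocount) / (sum(post$counts) + pseudocount * length(A))
  out <- log2(fpost / fpre)
  class(out) <- c("position_enrichment", class(out))
  out
}

#' Correlation between sequencing enrichment and measured fluorescence
#'
#' Pearson correlation between per-variant log2 enrichment and an
#' independently measured fluorescence value, over the variants present in
#' both. Both `r` and `r^2` are reported.
#'
#' @param table An `enrichment_table` from [variant_enrichment()].
#' @param measured Named numeric vector: variant key -> measured
#'   fluorescence.
#' @return List with `pearson_r`, `r_squared`, `n`.
#' @export
enrichment_fluorescence_correlation <- function(table, measured) {
  stopifnot(inherits(table, "enrichment_table"),
            is.numeric(measured), !is.null(names(measured)))
  keys <- intersect(table$key, names(measured))
  if (length(keys) < 3L) stop("need >= 3 overlapping variants")
  x <- table$log2_enrichment[match(keys, table$key)]
  y <- unname(measured[keys])
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance; correlation undefined")
  }
  r <- cor(x, y)
  list(pearson_r = r, r_squared = r^2, n = length(keys))
}

#' @importFrom stats sd
NULL
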