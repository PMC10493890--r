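#' The 20 standard amino acids
#'
#' One-letter codes, alphabetically ordered. The default alphabet of a
#' [saturation_design()].
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Wild-type residues of the regulator at the six diversified positions
# (L31, D87, M154, I162, Q233, A274).
DEFAULT_POSITIONS <- c(31L, 87L, 154L, 162L, 233L, 274L)
DEFAULT_WT_RESIDUES <- c("L", "D", "M", "I", "Q", "A")

#' Define a multi-position saturation mutagenesis design
#'
#' A saturation design fixes a template protein and an ordered set of residue
#' positions that are diversified to every letter of the alphabet. The variant
#' space it defines has `length(alphabet) ^ length(positions)` members, each
#' identified by a *variant key*: the string of residues occupying the
#' diversified positions (slot i = residue at `positions[i]`).
#'
#' @param template_protein Single amino-acid string (one-letter codes).
#' @param positions Strictly increasing 1-based residue indices to diversify.
#'   Defaults to the six positions of the DNT-sensing regulator screen
#'   (31, 87, 154, 162, 233, 274).
#' @param template_dna Optional nucleotide string of length
#'   `3 * nchar(template_protein)`; must translate to `template_protein`.
#' @param alphabet Character vector of allowed residues (default: the 20
#'   standard amino acids).
#' @return An object of class `saturation_design`.
#' @examples
#' d <- saturation_design(strrep("A", 50), positions = c(3, 17))
#' library_space_size(d)
#' @seealso [library_space_size()], [enumerate_variants()], [apply_variant()]
#' @export
saturation_design <- function(template_protein,
                              positions = DEFAULT_POSITIONS,
                              template_dna = NULL,
                              alphabet = AA_ALPHABET) {
  stopifnot(is.character(template_protein), length(template_protein) == 1L)
  n <- nchar(template_protein)
  positions <- as.integer(positions)
  if (length(positions) == 0L || anyNA(positions)) {
    stop("`positions` must be a non-empty vector of residue indices")
  }
  if (any(diff(positions) <= 0L)) {
    stop("`positions` must be strictly increasing")
  }
  if (positions[1L] < 1L || positions[length(positions)] > n) {
    stop("`positions` must lie in [1, ", n, "]")
  }
  alphabet <- as.character(alphabet)
  if (any(nchar(alphabet) != 1L) || anyDuplicated(alphabet)) {
    stop("`alphabet` must be distinct single characters")
  }
  if (!is.null(template_dna)) {
    stopifnot(is.character(template_dna), length(template_dna) == 1L)
    if (nchar(template_dna) != 3L * n) {
      stop("`template_dna` must have length 3 * protein length")
    }
    if (translate_dna(template_dna) != template_protein) {
      stop("`template_dna` does not translate to `template_protein`")
    }
  }
  structure(
    list(template_protein = template_protein,
         template_dna = template_dna,
         positions = positions,
         alphabet = alphabet),
    class = "saturation_design"
  )
}

#' @export
print.saturation_design <- function(x, ...) {
  cat(sprintf(
    "Saturation design: %d-residue template, %d diversified positions (%s)\n",
    nchar(x$template_protein), length(x$positions),
    paste(x$positions, collapse = ", ")))
  cat(sprintf("Alphabet size %d; variant space %s\n",
              length(x$alphabet),
              format(library_space_size(x), big.mark = ",")))
  invisible(x)
}

#' Residues of the template at the diversified positions
#'
#' The variant key that leaves the template unchanged.
#'
#' @param design A [saturation_design()].
#' @return Single string of length `length(design$positions)`.
#' @export
template_key <- function(design) {
  stopifnot(inherits(design, "saturation_design"))
  paste(strsplit(design$template_protein, "")[[1]][design$positions],
        collapse = "")
}

#' Size of the variant space of a saturation design
#'
#' Number of distinct protein variants: `|alphabet| ^ n_positions`. For the
#' default six-position, 20-letter design this is 20^6 = 6.4e7.
#'
#' @param design A [saturation_design()].
#' @return A single numeric count.
#' @examples
#' library_space_size(example_design())  # 64,000,000
#' @export
library_space_size <- function(design) {
  stopifnot(inherits(design, "saturation_design"))
  length(design$alphabet)^length(design$positions)
}

#' Enumerate or sample variant keys
#'
#' Without `limit`, yields every key of the design exactly once, in
#' lexicographic order (slot 1 most significant). With `limit`, draws a
#' uniform random sample of distinct keys from the full space.
#'
#' @param design A [saturation_design()].
#' @param limit Optional number of keys to sample (must not exceed
#'   [library_space_size()]).
#' @param seed RNG seed; required when `limit` is given.
#' @return Character vector of variant keys.
#' @examples
#' enumerate_variants(saturation_design("AC", positions = 1:2,
#'                                      alphabet = c("A", "C")))
#' @export
enumerate_variants <- function(design, limit = NULL, seed = NULL) {
  stopifnot(inherits(design, "saturation_design"))
  space <- library_space_size(design)
  if (is.null(limit)) {
    if (space > 5e6) {
      stop("refusing to exhaustively enumerate ", format(space, big.mark = ","),
           " keys; supply `limit` to sample")
    }
    k <- length(design$positions)
    # expand.grid varies its first factor fastest; feed slots in reverse so
    # slot 1 is most significant, then sort within-slot by alphabet order.
    g <- do.call(expand.grid,
                 c(rev(replicate(k, design$alphabet, simplify = FALSE)),
                   stringsAsFactors = FALSE))
    keys <- do.call(paste0, rev(g))
    return(sort(keys, method = "radix"))
  }
  limit <- as.double(limit)
  if (limit > space) stop("`limit` exceeds the library space size")
  if (is.null(seed)) stop("`seed` is required when sampling keys")
  with_seed(seed, {
    if (space <= 2e6) {
      sample(enumerate_variants(design), limit)
    } else {
      # rejection sampling of uniform random keys until `limit` are distinct;
      # collision probability is negligible at these scales
      keys <- character(0)
      while (length(keys) < limit) {
        m <- ceiling(1.2 * (limit - length(keys))) + 10L
        draw <- random_keys(design$alphabet, length(design$positions), m)
        keys <- unique(c(keys, draw))
      }
      keys[seq_len(limit)]
    }
  })
}

#' @noRd
random_keys <- function(alphabet, k, n) {
  m <- matrix(sample(alphabet, n * k, replace = TRUE), nrow = n)
  do.call(paste0, asplit(m, 2))
}

#' Apply a variant key to the template protein
#'
#' Replaces the residue at `positions[i]` with `substr(key, i, i)`; all other
#' residues are untouched. Applying the [template_key()] returns the template
#' itself.
#'
#' @param design A [saturation_design()].
#' @param key Variant key (string of length `length(design$positions)`).
#' @return The full-length mutant protein string.
#' @examples
#' d <- example_design()
#' v <- apply_variant(d, "MVTFRV")  # the sextuple mutant
#' substr(v, 31, 31)
#' @export
apply_variant <- function(design, key) {
  stopifnot(inherits(design, "saturation_design"),
            is.character(key), length(key) == 1L)
  k <- length(design$positions)
  if (nchar(key) != k) {
    stop("`key` must have length ", k, " (one residue per diversified position)")
  }
  res <- strsplit(key, "")[[1]]
  bad <- setdiff(res, design$alphabet)
  if (length(bad)) {
    stop("key contains residues outside the design alphabet: ",
         paste(unique(bad), collapse = ", "))
  }
  prot <- strsplit(design$template_protein, "")[[1]]
  prot[design$positions] <- res
  paste(prot, collapse = "")
}

#' Deterministic synthetic template protein
#'
#' Generates a synthetic 298-residue protein standing in for the engineered
#' regulator (whose exact sequence is not bundled). The six canonical
#' diversified positions carry the regulator's wild-type residues
#' (L31, D87, M154, I162, Q233, A274) so that mutation nomenclature such as
#' L31M reads the same; every other residue is drawn at random.
#'
#' @param length Protein length (default 298).
#' @param seed RNG seed (default 20230817).
#' @return Amino-acid string.
#' @export
synthetic_template_protein <- function(length = 298L, seed = 20230817L) {
  stopifnot(length >= max(DEFAULT_POSITIONS))
  with_seed(seed, {
    prot <- sample(AA_ALPHABET, length, replace = TRUE)
    prot[DEFAULT_POSITIONS] <- DEFAULT_WT_RESIDUES
    paste(prot, collapse = "")
  })
}

#' Default six-position design on the synthetic template
#'
#' Convenience constructor for the study design: a synthetic 298-residue
#' template diversified at positions 31, 87, 154, 162, 233 and 274 over the
#' 20 standard amino acids, giving a 6.4e7-variant space.
#'
#' @param seed Seed forwarded to [synthetic_template_protein()].
#' @return A [saturation_design()].
#' @export
example_design <- function(seed = 20230817L) {
  saturation_design(synthetic_template_protein(seed = seed))
}
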