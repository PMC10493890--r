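test_that("library space size follows |alphabet|^positions", {
  expect_equal(library_space_size(example_design()), 64e6)
  d1 <- saturation_design("AAAA", positions = 2L)
  expect_equal(library_space_size(d1), 20)
  expect_equal(library_space_size(small_design(c("A", "C", "G", "T"))), 16)
})

test_that("space size matches exhaustive enumeration on small designs", {
  cases <- list(
    small_design(c("A", "C")),
    small_design(c("A", "C", "D")),
    small_design(c("A", "C", "D", "E"), positions = c(1L, 3L, 5L))
  )
  for (d in cases) {
    keys <- enumerate_variants(d)
    expect_equal(length(keys), library_space_size(d))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("enumeration is lexicographic and sampling yields distinct keys", {
  d <- saturation_design("A", positions = 1L, alphabet = c("A", "C"))
  expect_identical(enumerate_variants(d), c("A", "C"))
  d2 <- small_design(c("A", "C", "D"))
  keys <- enumerate_variants(d2)
  expect_identical(keys, sort(keys, method = "radix"))
  samp <- enumerate_variants(example_design(), limit = 1000, seed = 5)
  expect_equal(length(samp), 1000L)
  expect_equal(anyDuplicated(samp), 0L)
  expect_identical(samp, enumerate_variants(example_design(), limit = 1000,
                                            seed = 5))
  expect_error(enumerate_variants(d, limit = 5, seed = 1), "exceeds")
})

test_that("apply_variant replaces exactly the diversified positions", {
  d <- example_design()
  mutant <- apply_variant(d, "MVTFRV")
  res <- strsplit(mutant, "")[[1]]
  expect_identical(res[d$positions], c("M", "V", "T", "F", "R", "V"))
  # identity: the template's own residues leave it unchanged
  expect_identical(apply_variant(d, template_key(d)), d$template_protein)
  # differences confined to the position set
  ala <- apply_variant(d, "AAAAAA")
  diff_at <- which(strsplit(ala, "")[[1]] !=
                     strsplit(d$template_protein, "")[[1]])
  expect_true(all(diff_at %in% d$positions))
  expect_lte(length(diff_at), 6L)
  # idempotent
  d2 <- saturation_design(ala, positions = d$positions)
  expect_identical(apply_variant(d2, "AAAAAA"), ala)
  expect_error(apply_variant(d, "AAA"), "length")
  expect_error(apply_variant(d, "AAAAA1"), "alphabet")
})

test_that("design invariants are enforced", {
  expect_error(saturation_design("AAAA", positions = c(3L, 2L)), "increasing")
  expect_error(saturation_design("AAAA", positions = 5L), "1, 4")
  expect_error(saturation_design("AAAA", positions = 1L,
                                 alphabet = c("A", "A")), "distinct")
  expect_error(saturation_design("MK", positions = 1L,
                                 template_dna = "ATGAAG"), NA)
  expect_error(saturation_design("MK", positions = 1L,
                                 template_dna = "ATGGAG"), "translate")
})

test_that("codon sampling respects forced codons and round-trips", {
  one <- codon_usage(data.frame(codon = "ATG", aa = "M", fraction = 1))
  expect_identical(sample_codon_dna("M", one, seed = 1), "ATG")
  for (s in 1:5) {
    prot <- paste(sample(AA_ALPHABET, 60, replace = TRUE), collapse = "")
    dna <- sample_codon_dna(prot, seed = s)
    expect_identical(translate_dna(dna), prot)
  }
  expect_error(sample_codon_dna("M?", one, seed = 1), "residue")
})

test_that("codon sampling matches the usage table frequencies", {
  usage <- ecoli_codon_usage()
  leu <- usage[usage$aa == "L", ]
  # 20 seeds x 500-residue poly-Leu = 1e4 multinomial draws
  draws <- unlist(lapply(1:20, function(s) {
    dna <- sample_codon_dna(strrep("L", 500), usage, seed = s)
    substring(dna, seq(1, nchar(dna) - 2, 3), seq(3, nchar(dna), 3))
  }))
  n <- length(draws)
  obs <- table(factor(draws, levels = leu$codon))
  for (i in seq_len(nrow(leu))) {
    p <- leu$fraction[i]
    se <- sqrt(n * p * (1 - p))
    expect_lt(abs(obs[[leu$codon[i]]] - n * p), 3 * se + 1)
  }
})

test_that("the sliding-window GC cap is enforced or fails loudly", {
  rich <- codon_usage(data.frame(codon = c("CGC", "AGA"), aa = c("R", "R"),
                                 fraction = c(0.5, 0.5)))
  # unconstrained draws exceed 70% GC in some 30-nt window; the cap is
  # achievable by shifting windows towards the low-GC codon
  dna0 <- sample_codon_dna(strrep("R", 90), rich, seed = 3)
  expect_gt(max(gc_windows(dna0, 30)), 0.70)
  dna <- sample_codon_dna(strrep("R", 90), rich, seed = 3, gc_cap = 0.70,
                          window_nt = 30)
  expect_true(all(gc_windows(dna, 30) <= 0.70))
  expect_identical(translate_dna(dna), strrep("R", 90))
  only_gcg <- codon_usage(data.frame(codon = "GCG", aa = "A", fraction = 1))
  expect_error(
    sample_codon_dna(strrep("A", 50), only_gcg, seed = 1, gc_cap = 0.70,
                     window_nt = 30, max_retries = 50),
    "unsatisfiable")
})

test_that("gc_windows computes per-window GC fractions", {
  expect_equal(gc_windows("GGGCCC", 6), 1.0)
  expect_equal(gc_windows("ATATAT", 6), 0.0)
  expect_equal(gc_windows("GCAT", 2, step = 1), c(1.0, 0.5, 0.0))
  expect_error(gc_windows("", 1), "empty")
  expect_error(gc_windows("AT", 3), "window_nt")
})

test_that("the usage table loader normalizes and screens input", {
  u <- ecoli_codon_usage()
  expect_equal(nrow(u), 61L)
  sums <- tapply(u$fraction, u$aa, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_warning(
    codon_usage(data.frame(codon = c("GCG", "GCT"), aa = "A",
                           fraction = c(0.6, 0.6))),
    "renormalized")
})
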