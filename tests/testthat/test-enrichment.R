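# A small concrete decoding fixture: 12-residue template, two diversified
# positions, forced codons so reference DNA is deterministic.
decode_fixture <- function() {
  template <- "MKLVDAGHWEST"
  d <- saturation_design(template, positions = c(3L, 8L))
  ref <- sample_codon_dna(template, forced_usage(), seed = 1)
  list(design = d, ref = ref)
}

test_that("decoding recovers keys from clean and substituted reads", {
  fx <- decode_fixture()
  expect_identical(decode_read(fx$ref, fx$design, fx$ref), "LH")
  # replace the second diversified codon (residue 8) with GCG -> Ala
  read <- fx$ref
  substr(read, 22, 24) <- "GCG"
  expect_identical(decode_read(read, fx$design, fx$ref), "LA")
  # a mismatch outside the diversified codons is tolerated...
  read2 <- fx$ref
  substr(read2, 1, 1) <- "C"
  expect_identical(decode_read(read2, fx$design, fx$ref), "LH")
  # ...until the outside-mismatch budget is exhausted
  key <- decode_read(read2, fx$design, fx$ref, max_mismatch_outside = 0)
  expect_true(is.na(key))
  expect_identical(attr(key, "reason"), "mismatch_outside")
})

test_that("indels and stops inside diversified codons reject the read", {
  fx <- decode_fixture()
  # 1-nt deletion inside the first diversified codon (positions 7-9)
  del <- paste0(substr(fx$ref, 1, 7), substr(fx$ref, 9, nchar(fx$ref)))
  key <- decode_read(del, fx$design, fx$ref)
  expect_true(is.na(key))
  expect_identical(attr(key, "reason"), "indel_in_codon")
  # a stop codon in a diversified slot is not a valid residue
  stopread <- fx$ref
  substr(stopread, 7, 9) <- "TAA"
  key2 <- decode_read(stopread, fx$design, fx$ref)
  expect_true(is.na(key2))
  expect_identical(attr(key2, "reason"), "bad_codon")
  # an indel outside the diversified codons is survivable via alignment
  ins <- paste0(substr(fx$ref, 1, 12), "A", substr(fx$ref, 13, nchar(fx$ref)))
  expect_identical(decode_read(ins, fx$design, fx$ref), "LH")
})

test_that("reverse-complement reads are decoded", {
  fx <- decode_fixture()
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fx$ref)))
  expect_identical(decode_read(rc, fx$design, fx$ref,
                               max_mismatch_outside = 5), "LH")
})

test_that("counting conserves reads and recovers noise-free pools", {
  d <- example_design()
  ref <- sample_codon_dna(d$template_protein, seed = 2)
  pool <- make_pool(d, 100, 1000, seed = 3)
  reads <- simulate_amplicon_reads(pool, d, ref, 2000, 0, seed = 4)
  vc <- count_variants(reads, d, ref, "R0")
  expect_equal(sum(vc$counts) + vc$n_reads_rejected, 2000L)
  expect_equal(vc$n_reads_rejected, 0L)
  truth <- table(S4Vectors::mcols(reads)$source_key)
  expect_equal(vc$counts[sort(names(truth))],
               setNames(as.integer(truth), names(truth))[sort(names(truth))])
})

test_that("rejection rate is monotone in the per-base error rate", {
  d <- example_design()
  ref <- sample_codon_dna(d$template_protein, seed = 5)
  pool <- make_pool(d, 20, 200, seed = 6)
  rates <- vapply(c(0, 0.01, 0.05), function(e) {
    reads <- simulate_amplicon_reads(pool, d, ref, 400, e, seed = 7)
    vc <- count_variants(reads, d, ref)
    vc$n_reads_rejected / vc$n_reads_total
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0)
  expect_gt(rates[3], rates[1])
})

test_that("variant enrichment matches hand arithmetic", {
  pre <- variant_counts(c(A = 3, B = 1), "R0")
  post <- variant_counts(c(A = 1, B = 3), "R3")
  tab <- variant_enrichment(pre, post, pseudocount = 1)
  expect_equal(tab$log2_enrichment[tab$key == "B"],
               log2((4 / 6) / (2 / 6)))  # 1.0
  expect_equal(tab$log2_enrichment[tab$key == "A"], -1.0)
  # identical pools enrich nothing
  same <- variant_enrichment(pre, pre)
  expect_equal(same$log2_enrichment, rep(0, 2))
  # pseudocounted frequencies are proper distributions
  expect_equal(sum(tab$pre_freq), 1)
  expect_equal(sum(tab$post_freq), 1)
  expect_error(variant_enrichment(pre, post, pseudocount = 0), "pseudocount")
})

test_that("enrichment is antisymmetric under swapping pools", {
  for (s in 1:3) {
    keys <- random_toy_keys(30, seed = s)
    pre <- variant_counts(table_counts(keys[1:15]), "R0")
    post <- variant_counts(table_counts(keys[10:30]), "R3")
    fwd <- variant_enrichment(pre, post)
    rev <- variant_enrichment(post, pre)
    expect_equal(rev$log2_enrichment[match(fwd$key, rev$key)],
                 -fwd$log2_enrichment)
  }
})

test_that("keys absent from one pool are treated as zero counts", {
  pre <- variant_counts(c(A = 10), "R0")
  post <- variant_counts(c(A = 5, B = 5), "R3")
  tab <- variant_enrichment(pre, post, pseudocount = 1)
  b <- tab[tab$key == "B", ]
  expect_equal(b$pre_count, 0L)
  expect_equal(b$log2_enrichment, log2((6 / 12) / (1 / 12)))
})

test_that("position enrichment equals brute-force marginal recomputation", {
  d <- small_design(alphabet = c("A", "C", "D", "E"))
  pre_keys <- random_toy_keys(50, alphabet = c("A", "C", "D", "E"), seed = 11)
  post_keys <- random_toy_keys(50, alphabet = c("A", "C", "D", "E"), seed = 12)
  pre <- variant_counts(table_counts(pre_keys), "R0")
  post <- variant_counts(table_counts(post_keys), "R3")
  p <- 1
  mat <- position_enrichment(pre, post, d, pseudocount = p)
  # independent brute force straight from the raw key lists
  for (slot in 1:2) {
    for (aa in d$alphabet) {
      npre <- sum(substr(pre_keys, slot, slot) == aa)
      npost <- sum(substr(post_keys, slot, slot) == aa)
      fpre <- (npre + p) / (length(pre_keys) + p * 4)
      fpost <- (npost + p) / (length(post_keys) + p * 4)
      expect_equal(mat[slot, aa], log2(fpost / fpre))
    }
  }
  # identical pools give an all-zero matrix (template entries included)
  z <- position_enrichment(pre, pre, d)
  expect_true(all(z == 0))
})

test_that("enrichment-fluorescence correlation matches the closed form", {
  pre <- variant_counts(setNames(rep(10, 5), LETTERS[1:5]))
  post <- variant_counts(setNames(c(40, 20, 10, 5, 2), LETTERS[1:5]))
  tab <- variant_enrichment(pre, post)
  x <- tab$log2_enrichment
  fl <- setNames(c(5, 1, 4, 2, 8), tab$key)
  res <- enrichment_fluorescence_correlation(tab, fl)
  # textbook Pearson formula
  y <- unname(fl[tab$key])
  n <- 5
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(res$pearson_r, r_hand)
  expect_equal(res$r_squared, r_hand^2)
  expect_equal(res$n, 5L)
  # perfect linear relations
  perfect <- setNames(2 * x + 1, tab$key)
  expect_equal(enrichment_fluorescence_correlation(tab, perfect)$pearson_r, 1)
  neg <- setNames(-x, tab$key)
  expect_equal(enrichment_fluorescence_correlation(tab, neg)$pearson_r, -1)
  expect_error(enrichment_fluorescence_correlation(tab, fl[1:2]), ">= 3")
})
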