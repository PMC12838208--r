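test_that("CAI weights: hand-counted family, pseudocounts, max-weight-1 property", {
  # Lys codons AAA:30, AAG:10 in the reference
  ref_seq <- paste0("ATG", strrep("AAA", 30), strrep("AAG", 10), "TAA")
  ref <- cai_weights_from_reference(ref_seq)
  expect_equal(unname(ref$weights[["AAA"]]), 1)
  expect_equal(unname(ref$weights[["AAG"]]), 1/3)
  # sole family members get weight 1
  ref2 <- cai_weights_from_reference("ATGTGGTAA")
  expect_equal(unname(ref2$weights[["ATG"]]), 1)
  expect_equal(unname(ref2$weights[["TGG"]]), 1)
  expect_true(all(ref2$weights > 0))  # pseudocount smoothing
  expect_error(cai_weights_from_reference(character(0)), "empty")
  # every family's max weight is 1, over random references
  code <- Biostrings::GENETIC_CODE
  for (seed in 1:5) {
    r <- cai_weights_from_reference(vapply(1:5, function(i)
      random_cds(60, seed * 10 + i), character(1)))
    for (aa in setdiff(unique(code), "*")) {
      fam <- names(code)[code == aa]
      expect_equal(max(r$weights[fam]), 1)
    }
  }
})

test_that("CAI: geometric mean over eligible codons, against direct product", {
  ref_seq <- paste0("ATG", strrep("AAA", 30), strrep("AAG", 10), "TAA")
  ref <- cai_weights_from_reference(ref_seq)
  # only eligible codon is AAG with w = 1/3
  expect_equal(cai("ATGAAGTAA", ref), 1/3)
  # all-maximal-weight codons give exactly 1
  expect_equal(cai("ATGAAAAAATAA", ref), 1)
  # ATG/TGG/stops excluded: a gene of only those is undefined
  expect_true(is.na(cai("ATGTGGTAA", ref)))
  # brute-force product-then-root oracle on random CDS
  refs <- vapply(1:6, function(i) random_cds(80, 100 + i), character(1))
  r <- cai_weights_from_reference(refs)
  for (seed in 1:10) {
    x <- random_cds(40, 200 + seed)
    n <- nchar(x) %/% 3
    cods <- substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))
    cods <- cods[!cods %in% c("ATG", "TGG", "TAA", "TAG", "TGA")]
    expect_equal(cai(x, r), prod(r$weights[cods])^(1 / length(cods)))
  }
})

test_that("tAI: geometric mean over sense codons with supplied weights", {
  sense <- setdiff(sort(names(Biostrings::GENETIC_CODE)),
                   c("TAA", "TAG", "TGA"))
  ones <- setNames(rep(1, length(sense)), sense)
  expect_equal(tai("ATGAAATAA", ones), 1)
  w <- ones
  w[["ATG"]] <- 0.25
  w[["AAA"]] <- 1
  expect_equal(tai("ATGAAATAA", w), sqrt(0.25 * 1))  # 0.5
  # monotonicity: swapping in a higher-weight synonym never decreases tAI
  set.seed(3)
  w2 <- setNames(runif(length(sense), 0.05, 1), sense)
  code <- Biostrings::GENETIC_CODE
  for (seed in 1:5) {
    x <- random_cds(10, 300 + seed)
    base_tai <- tai(x, w2)
    n <- nchar(x) %/% 3
    cods <- substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))
    for (i in setdiff(seq_len(n), n)) {
      fam <- names(code)[code == code[[cods[i]]]]
      for (alt in fam) {
        if (w2[[alt]] >= w2[[cods[i]]]) {
          y <- cods; y[i] <- alt
          expect_gte(tai(paste(y, collapse = ""), w2), base_tai - 1e-12)
        }
      }
    }
  }
})

test_that("dos-Reis-style tAI weights normalize and respond to copy number", {
  cn <- c(AAA = 6, AAG = 1, GGT = 2, GGC = 4, TGG = 1, ATG = 8)
  w <- tai_weights_from_trna(cn)
  expect_s3_class(w, "tai_weights")
  expect_equal(max(w$weights), 1)
  expect_true(all(w$weights > 0 & w$weights <= 1))
  # more copies -> higher weight within a family
  expect_gt(w$weights[["AAA"]], w$weights[["AAG"]])
  # wobble: AAG is still decodable via the unmodified-U anticodon of AAA
  w0 <- tai_weights_from_trna(c(AAA = 6, ATG = 8))
  expect_gt(w0$weights[["AAG"]], 0)
})

test_that("GC content counts literally", {
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_true(is.na(gc_content("")))
  # consistency with the vocabulary GC lookup
  for (seed in 1:10) {
    x <- random_cds(20, 400 + seed)
    toks <- tokenize_cds(x)
    expect_equal(gc_content(x), mean(VOCAB$gc_fraction[toks]))
  }
})

test_that("cis-element counting: planted motifs, overlaps, maximal runs", {
  expect_identical(count_negative_cis("ATGGCAGCATAA"), 0L)
  # one planted internal SD
  expect_identical(count_negative_cis(paste0("ATGGCA", "AGGAGG", "GCATAA")), 1L)
  # leading AGGAGG overlapping codon 1 is out of scope (internal only)
  expect_identical(count_negative_cis("AGGAGGTGGTAA"), 0L)
  # self-overlapping SD: AGGAGGAGG contains two overlapping hits
  expect_identical(count_negative_cis(paste0("ATG", "AGGAGGAGG", "TAA")), 2L)
  # poly-U: a 7-T run counts once (maximal run), two separated runs count twice
  expect_identical(count_negative_cis(paste0("ATG", "TTTTTTT", "AGTAA")), 1L)
  expect_identical(count_negative_cis(paste0("ATG", "TTTTT", "GCA", "TTTTT", "TAA")), 2L)
  # 4-T run is below threshold
  expect_identical(count_negative_cis(paste0("ATG", "TTTT", "GGTAA")), 0L)
  expect_warning(n <- count_negative_cis("ATGTAA", default_cis_catalogue()[0, ]),
                 "empty")
  expect_identical(n, 0L)
  # the shipped catalogue file matches the built-in default
  path <- system.file("extdata", "cis_catalogue_default.tsv", package = "codonopt")
  expect_identical(as.data.frame(read_cis_catalogue(path)),
                   as.data.frame(default_cis_catalogue()))
})

test_that("Nussinov fallback matches exhaustive structure enumeration", {
  expect_equal(mfe_5prime("AAAAAAAAAA"), 0)
  expect_equal(mfe_5prime("GGGAAAACCC"), -3)
  set.seed(11)
  for (i in 1:15) {
    n <- sample(5:14, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    expect_equal(mfe_5prime(s), -max_pairs_enum(s), label = s)
  }
})

test_that("delta 5' MFE: zero on identity, antisymmetric, sign by construction", {
  x <- random_cds(30, 500)
  y <- random_cds(30, 501)
  expect_equal(delta_mfe_5prime(x, x), 0)
  expect_equal(delta_mfe_5prime(x, y), -delta_mfe_5prime(y, x))
  # sequence with no pairable window vs a strongly pairing one
  unpaired <- strrep("A", 60)
  paired <- paste0(strrep("G", 10), strrep("A", 10), strrep("C", 10), strrep("A", 30))
  expect_gt(delta_mfe_5prime(unpaired, paired), 0)
})
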