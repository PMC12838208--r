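test_that("greedy decoding is deterministic and protein-preserving", {
  b <- noisy_backend(1, context_width = 1L)
  expect_identical(greedy_decode("MW", b), "ATGTGG")
  expect_identical(greedy_decode("MW", reference_backend(VOCAB, 0L)), "ATGTGG")
  for (seed in 1:10) {
    p <- random_protein(sample(5:40, 1), 900 + seed)
    d1 <- greedy_decode(p, b)
    expect_identical(d1, greedy_decode(p, b))
    expect_identical(translate_cds(d1), p)
  }
  # uniform untrained model: lexicographic tie-break
  expect_identical(greedy_decode("K", reference_backend(VOCAB, 0L)), "AAA")
})

test_that("temperature sampling: greedy limit, reproducibility, frequency recovery", {
  b <- noisy_backend(2, context_width = 0L)
  p <- random_protein(25, 910)
  expect_identical(sample_decode(p, b, temperature = 1e-9, seed = 1),
                   greedy_decode(p, b))
  expect_identical(sample_decode(p, b, temperature = 1, seed = 7),
                   sample_decode(p, b, temperature = 1, seed = 7))
  # empirical codon frequencies at T = 1 approach the model probabilities
  probs <- codonopt:::position_probs(b, "K")[[1]]
  draws <- vapply(1:2000, function(i) sample_decode("K", b, 1, seed = i),
                  character(1))
  obs <- table(factor(draws, levels = names(probs)))
  chisq <- sum((obs - 2000 * probs)^2 / (2000 * probs))
  expect_lt(chisq, qchisq(0.999, df = length(probs) - 1))
})

test_that("constrained beam search: forced, constrained-flip, infeasible cases", {
  b0 <- reference_backend(VOCAB, 0L)
  r <- constrained_beam_search("MW", b0)        # GC exactly 0.50, inclusive
  expect_identical(r$dna, "ATGTGG")
  expect_equal(r$gc, 0.5)
  # Lys-Lys: backend favoring AAA, bounds forcing at least 2 G/C over 6 nt
  bk <- reference_backend(VOCAB, 0L)
  bk$params[["K"]]$base <- c(2, 0)              # aaa favored
  cfg <- decoding_config(gc_lower = 0.30, gc_upper = 0.60)
  r2 <- constrained_beam_search("KK", bk, cfg)
  expect_identical(r2$dna, "AAGAAG")            # only feasible assignment
  # poly-Phe cannot reach 50% GC (TTT/TTC max 1/3)
  r3 <- constrained_beam_search(strrep("F", 12), b0)
  expect_s3_class(r3, "infeasibility_report")
  expect_lt(r3$achievable_gc[2], 0.5)
  expect_error(constrained_beam_search("", b0), "empty")
})

test_that("beam search equals the exhaustive constrained argmax on small proteins", {
  set.seed(42)
  agree <- 0
  for (i in 1:100) {
    b <- noisy_backend(1000 + i, scale = 1.5,
                       context_width = sample(0:1, 1))
    n <- sample(2:8, 1)
    p <- random_protein(n, 2000 + i)
    sizes <- prod(vapply(strsplit(p, "")[[1]],
                         function(a) length(VOCAB$families[[a]]), numeric(1)))
    cfg <- decoding_config(beam_size = max(64, sizes))
    bs <- constrained_beam_search(p, b, cfg)
    bf <- brute_force_constrained_argmax(p, b, c(cfg$gc_lower, cfg$gc_upper))
    if (inherits(bf, "infeasibility_report")) {
      expect_s3_class(bs, "infeasibility_report")
    } else {
      expect_identical(bs$dna, bf$dna)
      expect_equal(bs$logp, bf$logp, tolerance = 1e-9)
      agree <- agree + 1
    }
  }
  expect_gt(agree, 30)   # the sweep must exercise plenty of feasible cases
})

test_that("emitted beam sequences always satisfy the GC bounds", {
  cfg <- decoding_config()
  for (seed in 1:40) {
    b <- noisy_backend(3000 + seed, scale = 1, context_width = 1L)
    p <- random_protein(sample(10:80, 1), 4000 + seed)
    r <- constrained_beam_search(p, b, cfg)
    if (!inherits(r, "infeasibility_report")) {
      gc <- gc_content(r$dna)
      expect_gte(gc, cfg$gc_lower - 1e-12)
      expect_lte(gc, cfg$gc_upper + 1e-12)
      expect_identical(translate_cds(r$dna), p)
    }
  }
})

test_that("enlarging the beam never lowers the returned score, pruning never adds work", {
  b <- noisy_backend(5, scale = 1.5, context_width = 1L)
  for (seed in 1:10) {
    p <- random_protein(30, 5000 + seed)
    scores <- vapply(c(1, 2, 5, 10, 25), function(k) {
      r <- constrained_beam_search(p, b, decoding_config(beam_size = k))
      if (inherits(r, "infeasibility_report")) NA_real_ else r$score
    }, numeric(1))
    sc <- scores[!is.na(scores)]
    expect_true(all(diff(sc) >= -1e-12))
    # constrained expansion count <= unconstrained (bounds [0, 1])
    rc <- constrained_beam_search(p, b, decoding_config(beam_size = 5))
    ru <- constrained_beam_search(p, b, decoding_config(beam_size = 5,
                                                        gc_lower = 0,
                                                        gc_upper = 1))
    if (!inherits(rc, "infeasibility_report")) {
      expect_lte(rc$n_expansions, ru$n_expansions)
    }
  }
})

test_that("optimize_cds: start codon frozen, stop re-chosen, idempotent greedy", {
  b <- noisy_backend(6, scale = 1, context_width = 1L)
  dna <- "TTGAAACTGTGGTAA"      # TTG start
  out <- optimize_cds(dna, b, decoding_config(strategy = "greedy"))
  expect_identical(substr(out$dna, 1, 3), "TTG")
  expect_true(substring(out$dna, nchar(out$dna) - 2) %in% c("TAA", "TAG", "TGA"))
  expect_identical(translate_cds(out$dna), translate_cds(dna))
  # greedy re-optimization is a fixed point
  out2 <- optimize_cds(out$dna, b, decoding_config(strategy = "greedy"),
                       add_stop = FALSE)
  expect_identical(out2$dna, out$dna)
  # protein input gains a stop and preserves identity
  outp <- optimize_cds("MKLW", b, decoding_config(strategy = "greedy"))
  expect_identical(translate_cds(outp$dna), "MKLW*")
  # batch property over a random FASTA-like frame
  tab <- sample_usage_table(1, 0, seed = 6)
  recs <- generate_cds(generator_config(10, tab, min_len = 20, mean_len = 30,
                                        max_len = 50, seed = 6))
  for (i in seq_len(nrow(recs))) {
    o <- optimize_cds(recs$sequence[i], b, decoding_config(strategy = "greedy"))
    expect_identical(translate_cds(o$dna), translate_cds(recs$sequence[i]))
  }
})

test_that("optimize_cds beam outputs stay within bounds and flag success", {
  b <- noisy_backend(7, scale = 1, context_width = 1L)
  tab <- sample_usage_table(1, 0, seed = 7)
  recs <- generate_cds(generator_config(8, tab, min_len = 30, mean_len = 60,
                                        max_len = 90, seed = 7))
  cfg <- decoding_config(strategy = "beam")
  for (i in seq_len(nrow(recs))) {
    o <- optimize_cds(recs$sequence[i], b, cfg)
    if (o$feasible) {
      expect_gte(o$metrics$gc, cfg$gc_lower - 1e-12)
      expect_lte(o$metrics$gc, cfg$gc_upper + 1e-12)
      expect_true(o$metrics$success)
    } else {
      expect_s3_class(o$result, "infeasibility_report")
      expect_false(o$metrics$success)
    }
  }
})
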