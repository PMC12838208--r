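toy_batch <- function(probs, gold, vocab = VOCAB) {
  m <- matrix(0, length(gold), length(vocab$tokens),
              dimnames = list(NULL, vocab$tokens))
  for (i in seq_along(gold)) m[i, names(probs[[i]])] <- probs[[i]]
  list(distributions = m, gold = gold)
}

test_that("MLM loss is the mean negative log-probability of the gold tokens", {
  b1 <- toy_batch(list(c(m_atg = 1), c(w_tgg = 1)), c("m_atg", "w_tgg"))
  expect_equal(mlm_loss(b1), 0)
  b2 <- toy_batch(list(c(k_aaa = exp(-1), k_aag = 1 - exp(-1))), "k_aaa")
  expect_equal(mlm_loss(b2), 1)
  # matches direct recomputation on random batches
  set.seed(2)
  fams <- VOCAB$families[c("K", "L", "G", "S")]
  for (rep in 1:5) {
    gold <- character(0); probs <- list()
    for (i in 1:6) {
      f <- fams[[sample(length(fams), 1)]]
      p <- runif(length(f)); p <- p / sum(p)
      probs[[i]] <- setNames(p, f)
      gold[i] <- sample(f, 1)
    }
    b <- toy_batch(probs, gold)
    direct <- -mean(log(mapply(function(p, g) p[[g]], probs, gold)))
    expect_equal(mlm_loss(b), direct)
  }
  b3 <- toy_batch(list(c(k_aaa = 0, k_aag = 1)), "k_aaa")
  expect_warning(l <- mlm_loss(b3), "floor")
  expect_equal(l, -log(1e-12))
})

test_that("expected GC is the probability-weighted token GC", {
  b <- toy_batch(list(c(g_ggc = 1), c(g_ggc = 1)), c("g_ggc", "g_ggc"))
  expect_equal(expected_gc(b$distributions), 1)
  # 50/50 mix of gc 1/3 and 2/3 tokens
  b2 <- toy_batch(list(c(k_aag = 0.5, d_gac = 0.5)), "k_aag")
  expect_equal(expected_gc(b2$distributions), 0.5)
  # one-hot rows equal the literal GC of the decoded codons
  for (seed in 1:8) {
    x <- random_cds(15, 600 + seed)
    toks <- tokenize_cds(x)
    b3 <- toy_batch(lapply(toks, function(t) setNames(1, t)), toks)
    expect_equal(expected_gc(b3$distributions), gc_content(detokenize(toks)))
  }
})

test_that("GC smoothing is an initialized EMA with fixed-point behavior", {
  cc <- constraint_config(smoothing_alpha = 0.5)
  st <- lagrangian_state(cc)
  st <- smooth_gc(st, 0.50, cc)
  expect_equal(st$gc_sm, 0.50)          # first call initializes
  st <- smooth_gc(st, 0.54, cc)
  expect_equal(st$gc_sm, 0.52)          # (0.5)(0.50) + (0.5)(0.54)
  cc1 <- constraint_config(smoothing_alpha = 1)
  st1 <- smooth_gc(smooth_gc(lagrangian_state(cc1), 0.3, cc1), 0.61, cc1)
  expect_equal(st1$gc_sm, 0.61)         # alpha = 1 tracks the batch
  for (i in 1:50) st <- smooth_gc(st, 0.52, cc)
  expect_equal(st$gc_sm, 0.52, tolerance = 1e-6)
})

test_that("total loss decomposes per the augmented-Lagrangian form", {
  cc <- constraint_config(mu = 0.52)
  st <- lagrangian_state(cc)
  st$lambda_k <- 0.1; st$rho_k <- 2
  lb <- total_loss(1, 0.55, st, cc)
  expect_equal(lb$linear_term, 0.003)
  expect_equal(lb$quadratic_term, 0.0009)
  expect_equal(lb$l_total, 1.0039)
  expect_equal(lb$l_total, lb$l_mlm + lb$linear_term + lb$quadratic_term)
  # at the target the constraint vanishes regardless of lambda/rho
  st$lambda_k <- 7; st$rho_k <- 50
  expect_equal(total_loss(1, 0.52, st, cc)$l_total, 1)
  # warm-up disables the constraint terms even far from target
  lb_w <- total_loss(1, 0.9, st, cc, in_warmup = TRUE)
  expect_equal(lb_w$l_total, 1)
  expect_equal(lb_w$linear_term, 0)
})

test_that("dual update moves lambda by rho * delta with matching sign", {
  cc <- constraint_config()
  st <- lagrangian_state(cc)
  st$rho_k <- 10; st$delta_k <- 0.02
  expect_equal(dual_update(st)$lambda_k, 0.2)
  st$delta_k <- 0
  expect_equal(dual_update(st)$lambda_k, st$lambda_k)
  st$lambda_k <- 1; st$delta_k <- -0.05
  expect_lt(dual_update(st)$lambda_k, 1)
})

test_that("penalty update doubles only on inadequate progress, clamped", {
  cc <- constraint_config(epsilon = 0.005, eta = 0.05, p_inc = 2,
                          rho_min = 0.1, rho_max = 100)
  st <- lagrangian_state(cc)
  # violation within tolerance: unchanged
  st$v_k <- 0.004; st$v_prev <- 0.004; st$rho_k <- 1
  expect_equal(penalty_update(st, cc)$rho_k, 1)
  # persistent violation, inadequate improvement: doubled
  st$v_k <- 0.02; st$v_prev <- 0.0201; st$rho_k <- 1
  expect_equal(penalty_update(st, cc)$rho_k, 2)
  # adequate improvement: unchanged even though violated
  st$v_k <- 0.01; st$v_prev <- 0.02; st$rho_k <- 4
  expect_equal(penalty_update(st, cc)$rho_k, 4)
  # clamped at rho_max
  st$v_k <- 0.02; st$v_prev <- 0.02; st$rho_k <- 80
  expect_equal(penalty_update(st, cc)$rho_k, 100)
  # rho never decreases while violations persist, and stays bounded
  st <- lagrangian_state(cc); st$v_prev <- 0.5
  rhos <- numeric(20)
  for (i in 1:20) {
    st$v_k <- 0.5
    st <- penalty_update(st, cc)
    rhos[i] <- st$rho_k
  }
  expect_true(all(diff(rhos) >= 0))
  expect_true(all(rhos <= 100))
})

test_that("scheduling: cadence and warm-up gating, history always appended", {
  cc <- constraint_config(warmup_epochs = 3, update_every_steps = 20)
  st <- lagrangian_state(cc)
  st$epoch <- 4; st$step <- 19
  expect_identical(schedule_step(st, cc)$action, "none")
  st$step <- 20
  expect_identical(schedule_step(st, cc)$action, "dual_and_penalty_update")
  st$epoch <- 2; st$step <- 40
  expect_identical(schedule_step(st, cc)$action, "none")
  out <- schedule_step(st, cc)
  expect_length(out$state$history, length(st$history) + 1)
  expect_identical(history_df(out$state)$step[nrow(history_df(out$state))], 40)
})

test_that("constraint gradients agree with finite differences", {
  b <- noisy_backend(77, scale = 0.5, context_width = 0L)
  dna <- random_cds(12, 701)
  batch <- list(codonopt:::prepare_example(b, dna))
  cc <- constraint_config(gc_estimator = "expectation")
  tc <- training_config(learning_rate = 1, seed = 1)
  st <- lagrangian_state(cc)
  st$lambda_k <- 0.7; st$rho_k <- 3
  loss_of <- function(bk) {
    r <- codonopt:::sgd_step(bk, batch, st, cc, tc, lr = 0, in_warmup = FALSE)
    r$l_total
  }
  lr <- 1e-3
  stepped <- codonopt:::sgd_step(b, batch, st, cc, tc, lr = lr,
                                 in_warmup = FALSE)$backend
  for (f in c("K", "L", "G")) {
    if (is.null(stepped$params[[f]])) next
    analytic <- (b$params[[f]]$base - stepped$params[[f]]$base) / lr
    fd <- vapply(seq_along(analytic), function(j) {
      h <- 1e-6
      bp <- b; bp$params[[f]]$base[j] <- bp$params[[f]]$base[j] + h
      bm <- b; bm$params[[f]]$base[j] <- bm$params[[f]]$base[j] - h
      (loss_of(bp) - loss_of(bm)) / (2 * h)
    }, numeric(1))
    expect_equal(analytic, fd, tolerance = 1e-5)
  }
})

test_that("descending the constraint terms drives expected GC toward the target", {
  # frozen MLM: pure constraint descent on a toy family distribution
  vocabK <- VOCAB$families[["K"]]           # aaa (gc 0), aag (gc 1/3)
  gcf <- VOCAB$gc_fraction[vocabK]
  z <- c(2, 0)                              # start biased to low GC
  mu <- 0.25
  lambda <- 0; rho <- 20
  for (i in 1:500) {
    p <- exp(z - max(z)); p <- p / sum(p)
    gc <- sum(p * gcf)
    coef <- lambda + rho * (gc - mu)
    z <- z - 0.5 * coef * p * (gcf - gc)
  }
  p <- exp(z - max(z)); p <- p / sum(p)
  expect_equal(sum(p * gcf), mu, tolerance = 1e-3)
})
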